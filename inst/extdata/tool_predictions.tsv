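allergen	tool	positions
Ses i 1	dnastar	39~49, 5~52, 56, 60~70, 73, 78~81, 83, 85~87, 96~98, 100, 116~119, 123~126, 131~135, 138, 142~144
Ses i 2	dnastar	38~40, 61~64, 76, 78~79, 111~113, 139
Ses i 3	dnastar	23, 25~28, 60~68, 81~85, 92, 96, 99~101, 115~135, 142~145, 151, 162~172, 174~175, 178~180, 186, 188~191, 193, 207~212, 220~225, 240~242, 262, 270~273, 280, 298~300, 316~317, 328~330, 332, 348~353, 359~361, 378~380, 390~392, 399~408, 416~418, 423, 445~448, 469~485, 492~493, 512~515, 525~529, 535~537, 563~566, 573~582
Ses i 4	dnastar	5~7, 29~30, 32~37, 117~121, 125, 132, 151, 153~162
Ses i 5	dnastar	5~7, 9, 19~22, 103~109, 132~135, 142
Ses i 6	dnastar	25~30, 32, 42, 44, 51~53, 56, 75~78, 87~90, 99, 118~123, 133~136, 148, 166~168, 185, 201~203, 239~241, 261~263, 268, 270~275, 278, 290, 292, 305, 312~315, 327~330, 352, 354, 364, 372, 374, 385, 391~392, 404, 406~409, 429, 433~434, 436~437, 444~447, 455~456
Ses i 7	dnastar	29, 34~38, 40, 45~47, 60, 74~78, 104~105, 115, 131~141, 146~149, 154, 172~173, 206~212, 214~219, 221~223, 232, 252~257, 273~274, 280~286, 307~308, 315~316, 366, 376, 404~407, 415~419, 447~450, 456~457, 461, 466~470, 473~478, 483~485
Ses i 1	sopma	21~24, 33~34, 38~39, 50~52, 61~70, 78~85, 117~122, 134~149
Ses i 2	sopma	22~24, 31, 62~67, 75~79, 94~97, 133~144
Ses i 3	sopma	2~5, 24~29, 61~72, 82~85, 94~96, 99~102, 119~133, 142~151, 167~175, 179~181, 189~195, 199~201, 208~213, 240~244, 248~254, 261~264, 270~275, 280~283, 288~291, 297~302, 311~319, 325~330, 348~349, 359~363, 368~369, 381~394, 399~410, 414~420, 434~438, 441~449, 456~460, 465~483, 492~496, 501~505, 511~515, 524~530, 535~536, 553~555, 566~569, 574~584
Ses i 4	sopma	2~37, 47~51, 57~58, 71~73, 78~84, 95, 98~103, 120~123, 157~160
Ses i 5	sopma	5~15, 18~21, 33~37, 43~45, 47~49, 56~58, 63~70, 79~80, 85~88, 103~110, 135~145
Ses i 6	sopma	22~32, 41~54, 59~62, 77~92, 98~101, 107~140, 147~151, 156~159, 165~170, 178~183, 187~191, 197~213, 220~221, 231~232, 242~247, 253~256, 260~264, 268~275, 291~298, 302~307, 312~317, 332~335, 338~346, 353~356, 363~366, 373~377, 382~384, 391~396, 403~407, 414~415, 421~423, 433~434, 444~448, 453~459
Ses i 7	sopma	27~29, 36~47, 56~69, 74~78, 93~107, 113~117, 122~142, 145~146, 154~157, 162~165, 171~176, 184~190, 195~196, 203~225, 231~233, 243~244, 253~259, 265~268, 271~290, 303~310, 314~319, 324~329, 339~340, 344~347, 350~358, 365~368, 375~378, 385~389, 394~396, 403~409, 414~419, 427~428, 434~436, 446~447, 457~460, 466~485
Ses i 1	bepipred	22~45, 61~75, 78~87, 112~130, 134, 140~142
Ses i 2	bepipred	29~46, 63~65, 74~79, 112~118, 120, 138, 140
Ses i 3	bepipred	22~31, 38, 40~49, 62~75, 80~86, 94~104, 113~134, 143~152, 155~193, 240, 243~245, 250~253, 274, 312~318, 325~332, 370~373, 378~394, 400~409, 411, 413~414, 416~417, 436~447, 460, 468~487, 511, 513, 525~533, 545, 556~567, 575~585
Ses i 4	bepipred	1~25, 29~38, 119~135, 138~166
Ses i 5	bepipred	3~13, 23, 31~34, 104~116, 118~122, 125~145
Ses i 6	bepipred	21~31, 40~60, 62~64, 77~91, 111~113, 116, 121~137, 154~155, 157, 164~170, 198~211, 230~232, 234, 236~245, 259~278, 293~296, 326~327, 329~331, 336~338, 340~343, 354~358, 363, 373~374, 384~395, 403~413, 431~440, 455~459
Ses i 7	bepipred	24~27, 29~30, 35~43, 55~64, 67~68, 74~75, 77~80, 103~104, 116~118, 122~124, 127~139, 172~176, 186~191, 204~227, 250~257, 272~291, 303~320, 378~379, 402~408, 416~422, 446~451, 4576~459, 461~464, 467~484
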