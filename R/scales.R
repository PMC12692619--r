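#' Amino-acid propensity scales
#'
#' Lookup tables used throughout the package, keyed by one-letter residue
#' code over the 20 standard amino acids:
#' \describe{
#'   \item{\code{"kyte-doolittle"}}{Hydropathy (positive = hydrophobic);
#'     the scale averaged by \code{\link{gravy}}.}
#'   \item{\code{"hopp-woods"}}{Hydrophilicity (positive = hydrophilic).}
#'   \item{\code{"parker"}}{HPLC-derived hydrophilicity.}
#'   \item{\code{"emini"}}{Fractional surface probabilities; the product
#'     form over hexapeptides is normalised so that 1.0 is the random
#'     expectation (see \code{\link{eminiProfile}}).}
#'   \item{\code{"karplus-schulz"}}{Normalised crystallographic B-factor
#'     flexibility propensities; 1.0 is average backbone mobility.}
#' }
#'
#' @param name Scale name (see above), partially matched.
#' @return Named numeric vector of length 20.
#' @examples
#' propensityScale("kyte-doolittle")[["I"]]  # 4.5
#' @export
propensityScale <- function(name = c("kyte-doolittle", "hopp-woods", "parker",
                                     "emini", "karplus-schulz")) {
  name <- match.arg(name)
  .SCALES[[name]]
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.aa_vec <- function(...) {
  x <- c(...)
  stopifnot(length(x) == 20L)
  names(x) <- AA20
  x
}

.SCALES <- list(
  `kyte-doolittle` = .aa_vec(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4,
                             -3.2, 4.5, 3.8, -3.9, 1.9, 2.8, -1.6, -0.8,
                             -0.7, -0.9, -1.3, 4.2),
  `hopp-woods`     = .aa_vec(-0.5, 3.0, 0.2, 3.0, -1.0, 0.2, 3.0, 0.0,
                             -0.5, -1.8, -1.8, 3.0, -1.3, -2.5, 0.0, 0.3,
                             -0.4, -3.4, -2.3, -1.5),
  parker           = .aa_vec(2.1, 4.2, 7.0, 10.0, 1.4, 6.0, 7.8, 5.7,
                             2.1, -8.0, -9.2, 5.7, -4.2, -9.2, 2.1, 6.5,
                             5.2, -10.0, -1.9, -3.7),
  emini            = .aa_vec(0.49, 0.95, 0.81, 0.78, 0.26, 0.84, 0.84, 0.48,
                             0.66, 0.34, 0.40, 0.97, 0.48, 0.42, 0.75, 0.65,
                             0.70, 0.51, 0.76, 0.36),
  `karplus-schulz` = .aa_vec(1.041, 1.038, 1.117, 1.033, 0.846, 1.165, 1.094,
                             1.142, 0.982, 1.002, 0.967, 1.093, 0.947, 0.930,
                             1.055, 1.169, 1.073, 0.904, 0.929, 0.982)
)

#' Chou-Fasman conformational parameters
#'
#' Per-residue helix (\code{Pa}), sheet (\code{Pb}) and turn (\code{Pt})
#' conformational propensities (scaled so 100 is indifferent), together
#' with the positional turn bend frequencies \code{f0}..\code{f3} used in
#' the tetrapeptide turn probability p(t) = f(i) f(i+1) f(i+2) f(i+3).
#'
#' @return A data.frame with one row per standard residue.
#' @export
chouFasmanTable <- function() .CF_TABLE

.CF_TABLE <- local({
  d <- data.frame(
    aa = AA20,
    Pa = c(142,  98,  67, 101,  70, 111, 151,  57, 100, 108,
           121, 114, 145, 113,  57,  77,  83, 108,  69, 106),
    Pb = c( 83,  93,  89,  54, 119, 110,  37,  75,  87, 160,
           130,  74, 105, 138,  55,  75, 119, 137, 147, 170),
    Pt = c( 66,  95, 156, 146, 119,  98,  74, 156,  95,  47,
            59, 101,  60,  60, 152, 143,  96,  96, 114,  50),
    f0 = c(0.060, 0.070, 0.161, 0.147, 0.149, 0.074, 0.056, 0.102, 0.140,
           0.043, 0.061, 0.055, 0.068, 0.059, 0.102, 0.120, 0.086, 0.077,
           0.082, 0.062),
    f1 = c(0.076, 0.106, 0.083, 0.110, 0.050, 0.098, 0.060, 0.085, 0.047,
           0.034, 0.025, 0.115, 0.082, 0.041, 0.301, 0.139, 0.108, 0.013,
           0.065, 0.048),
    f2 = c(0.035, 0.099, 0.191, 0.179, 0.117, 0.037, 0.077, 0.190, 0.093,
           0.013, 0.036, 0.072, 0.014, 0.065, 0.034, 0.125, 0.065, 0.064,
           0.114, 0.028),
    f3 = c(0.058, 0.085, 0.091, 0.081, 0.128, 0.098, 0.064, 0.152, 0.054,
           0.056, 0.070, 0.095, 0.055, 0.065, 0.068, 0.106, 0.079, 0.167,
           0.125, 0.053)
  )
  rownames(d) <- d$aa
  d
})

# Average residue (not free amino acid) masses in Da; peptide MW adds one water.
.RESIDUE_MASS <- .aa_vec(
  71.0788, 156.1875, 114.1038, 115.0886, 103.1388, 128.1307, 129.1155,
  57.0519, 137.1411, 113.1594, 113.1594, 128.1741, 131.1926, 147.1766,
  97.1167, 87.0782, 101.1051, 186.2132, 163.1760, 99.1326)

.WATER_MASS <- 18.01524

#' Ionisable-group pKa set used for isoelectric point
#'
#' The EMBOSS pKa table: a single fixed published set, recorded here so that
#' \code{\link{isoelectricPoint}} is fully specified.
#'
#' @return Named numeric vector (termini and ionisable side chains).
#' @export
pkaSet <- function() c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5,
                       H = 6.5, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

# Theoretical maximum accessible surface areas (A^2) per residue type
# (Tien et al. theoretical values), used to normalise ASA to RSA.
.MAX_ASA <- .aa_vec(129, 274, 195, 193, 167, 225, 223, 104, 224, 197,
                    201, 236, 224, 240, 159, 155, 172, 285, 263, 174)

# Van der Waals radii (A) by element symbol for Shrake-Rupley.
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                H = 1.20, SE = 1.90)

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
             MSE = "M", SEC = "C")

#' Directional information parameters for GOR-style prediction
#'
#' Returns the directional information array used by \code{\link{gorPredict}}:
#' \code{info[residue, offset, state]} over offsets \code{-halfWindow ..
#' +halfWindow} and states H/E/T/C. The shipped parameter set
#' (\code{"cf-decay-v1"}) is derived in-package from log Chou-Fasman
#' conformational propensities spread over the window with a triangular
#' distance decay; it is a documented stand-in parameter set, not a
#' transcription of the historical GOR tables (see the package vignette).
#'
#' @param halfWindow Half window width; the full window is
#'   \code{2 * halfWindow + 1} residues (default 8, window 17).
#' @return 3-d numeric array \code{[20, 2*halfWindow+1, 4]} with dimnames.
#' @export
gorParameters <- function(halfWindow = 8L) {
  halfWindow <- as.integer(halfWindow)
  stopifnot(halfWindow >= 1L)
  cf <- chouFasmanTable()
  base <- cbind(H = log(cf$Pa / 100),
                E = log(cf$Pb / 100),
                T = log(cf$Pt / 100))
  base <- cbind(base, C = -rowMeans(base))
  offsets <- -halfWindow:halfWindow
  decay <- 1 - abs(offsets) / (halfWindow + 1)
  arr <- array(0, dim = c(20L, length(offsets), 4L),
               dimnames = list(AA20, as.character(offsets),
                               c("H", "E", "T", "C")))
  for (s in 1:4)
    arr[, , s] <- outer(base[, s], decay)
  attr(arr, "parameter_table_id") <- "cf-decay-v1"
  arr
}
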