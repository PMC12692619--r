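# bcepitope

Linear B-cell epitopes — short, contiguous stretches of a protein that
antibodies recognise — are the first thing an immunologist maps when
characterising a food allergen: they drive IgE binding in the
early-phase allergic response and are the raw material for diagnostic
peptides and hypoallergen design. `bcepitope` implements the classical
sequence-based prediction pipeline for them, end to end, as an R
package in the Bioconductor idiom (S4 classes, `IRanges` intervals,
`Biostrings` sequences). It is written for allergen researchers who
want the whole chain — propensity profiles, secondary structure,
hidden-state scoring, multi-predictor consensus, structural mapping —
reproducible in one place, with the seven sesame (*Sesamum indicum*)
allergens (Ses i 1–7) shipped as a fully worked case study.

## What it computes

**Per-residue tracks.** Sliding-window propensity profiles over
published scales: Hopp-Woods and Kyte-Doolittle hydropathy, Parker
hydrophilicity, Karplus-Schulz flexibility (windowed means), and Emini
surface probability, the product form over hexapeptides

&nbsp;&nbsp;&nbsp;&nbsp;*S*<sub>n</sub> = (0.37)<sup>−6</sup> ∏<sub>i=n</sub><sup>n+5</sup> δ<sub>i</sub>,

normalised so *S* = 1 is the random expectation. The Jameson-Wolf
antigenic index combines discretized hydrophilicity (h), surface (s)
and flexibility (f) classes with a secondary-structure term c:

&nbsp;&nbsp;&nbsp;&nbsp;AI(i) = 0.3 h(i) + 0.15 s(i) + 0.15 f(i) + 0.4 c(i).

**Secondary structure.** Chou-Fasman (nucleation/extension/turn
tetrapeptide rules) and a GOR-style directional-information predictor
over a 17-residue window, with per-position majority consensus over
the four states H/E/T/C and composition statistics (e.g. the coil
fraction inside epitope regions).

**Hidden-state scoring.** A two-state (epitope/background) HMM with
supervised re-estimation and exact forward–backward posteriors, mixed
with a standardised hydrophilicity track:
score(i) = w·(2·posterior(i) − 1) + (1 − w)·z(Parker(i)), thresholded
at 0.35.

**Region calling and consensus.** Residue-wise selection (positive
hydrophilicity and antigenic index, surface > 1, flexibility > 1;
lengths clamped to 5–30) turns tracks into candidate intervals, and
the core **k-of-n residue-overlap consensus** merges predictors: a
residue is consensus-supported when at least k of n tools cover it;
maximal supported runs of ≥ 5 residues are the consensus epitopes, so
tools predicting `ABCDEFG` and `CDEFGH` agree on exactly `CDEFG`.

**Structure mapping.** Consensus epitopes are mapped onto predicted 3D
models (PDB/mmCIF): deterministic Shrake-Rupley solvent-accessible
surface area, relative accessibility (RSA = ASA / max-ASA), per-epitope
mean pLDDT read from the B-factor column, and an exposure call at
RSA ≥ 0.25.

**Synthetic data.** Seeded generators plant hydrophilic/flexible/
coil-prone segments in random proteins and simulate noisy multi-tool
predictions with known truth, so every stage is testable without
downloads.

## Worked example

The packaged fixtures transcribe the published per-tool epitope tables
for the seven sesame allergens. For Ses i 2 (a 2S albumin), the three
tools and their k = 2-of-3 consensus:

```r
library(bcepitope)
fx <- loadFixture("Ses i 2")
consensusRegions(fx$predictions, length = fx$length, k = 2, minLen = 5)
#> IRanges object with 1 range and 2 metadata columns:
#>           start       end     width |                support    nTools
#>       <integer> <integer> <integer> |            <character> <integer>
#>   [1]        75        79         5 | dnastar,sopma,bepipred         3
```

One five-residue consensus epitope at 75–79 — the published consensus
row for this allergen, which sits inside the experimentally validated
IgE-binding region 76–86. The profile side of the pipeline on a short
2S-albumin-like sequence:

```r
s <- "MVAFRDQDTKLSPQQQYLECQKRCEQQEPRAQKQCQKYCEEQRGQ"
sprintf("GRAVY %.3f  MW %.1f Da  pI %.2f",
        gravy(s), molecularWeight(s), isoelectricPoint(s))
#> [1] "GRAVY -1.727  MW 5493.1 Da  pI 7.91"

hy <- windowedProfile(s, "hopp-woods", 7)
su <- eminiProfile(s); fl <- karplusSchulzProfile(s)
ss <- ssConsensus(list(chouFasman(s), gorPredict(s)))
ai <- jamesonWolfProfile(hy, su, fl, ss)
callRegionsMulti(hy, ai, su, fl, ss = ss)
#> IRanges object with 3 ranges and 2 metadata columns:
#>           start       end     width |          tool     score
#>   [1]         6        13         8 | profile-suite  0.313125
#>   [2]        19        35        17 | profile-suite  0.316765
#>   [3]        38        45         8 | profile-suite  0.330000
```

The negative GRAVY marks a hydrophilic protein; the three called
intervals are runs of residues that pass every selection criterion
simultaneously, scored by their mean antigenic index.

A thin shell wrapper over the same functions is included:

```sh
Rscript inst/scripts/epitope-consensus.R --fixture "Ses i 5"
```

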