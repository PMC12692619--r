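---
title: "Methods: linear B-cell epitope profiling, consensus and structural mapping"
author: "bcepitope"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: linear B-cell epitope profiling, consensus and structural mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcepitope)
```

# The problem and the model

Linear B-cell epitopes are contiguous runs of residues that antibodies
bind. Decades of structural immunology condensed this into a small set
of sequence-level signals: epitopes tend to be hydrophilic, flexible,
solvent-exposed and to sit in turns or random coil rather than in
packed helices or sheets. The classical prediction pipeline therefore
computes several per-residue propensity tracks, predicts secondary
structure, selects residues that satisfy all signals at once, and —
because each individual predictor is noisy — keeps only regions on
which independent predictors agree. `bcepitope` implements this chain
with the seven sesame allergens as its packaged case study.

This vignette is the package's account of the methods, their tunable
parameters and the design decisions taken where the underlying
literature leaves the choice open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

# Per-residue tracks

`windowedProfile()` averages a propensity scale over a centred odd
window. Defaults follow the original publications of each method:
Hopp-Woods 7, Kyte-Doolittle 9, Parker 7, Karplus-Schulz 7 — all
config-overridable, since downstream callers only see a
`ResidueProfile`. Two edge policies exist: `"shrink"` (default)
truncates the window at the termini so the track keeps one value per
residue — important because published per-tool epitope tables do report
terminal predictions (positions 1–2) and interval calling must be able
to reach them — and `"undefined"` yields `NA` there instead. A profile
always has exactly one slot per residue; positions are 1-based
throughout the package, matching the `38~45` notation of the published
tables it ships.

`eminiProfile()` is product-form rather than additive: for the
hexapeptide starting at n, S = (0.37)^-6 × Π δ_i over the six
fractional surface probabilities, so S = 1 is the random expectation
and S > 1 flags above-random surface probability. The value anchors at
position n+2; a centre-ish anchor keeps interval calling symmetric (the
method's original description fixes the window, not the anchor). Under
`"shrink"` the terminal products run over the truncated window with the
normaliser adjusted to its length, preserving the S = 1 anchor point.

`jamesonWolfProfile()` combines the tracks into the antigenic index

AI(i) = 0.3·h(i) + 0.15·s(i) + 0.15·f(i) + 0.4·c(i),

with h, s, f the hydrophilicity, surface and flexibility tracks
discretized to the five classes {−0.6, −0.3, 0, +0.3, +0.6} and
c(i) = +0.6 for turn/coil consensus at i, −0.6 otherwise. Two choices
here are the package's own. First, the discretization thresholds are
the quintiles of each track's own distribution: the commercial
implementation's absolute cutoffs were never published, and
per-sequence quantiles keep class occupancy stable across proteins of
very different composition (a constant track maps to the neutral
class). Second, the original method weighted two secondary-structure
propensity terms at 0.2 each; this package produces a single
secondary-structure consensus, so the two terms collapse into one
0.4-weighted term. AI is monotone non-decreasing in each input class,
which the suite checks as a property.

# Secondary structure

`chouFasman()` implements the classical propensity rules: helix
nucleation where ≥ 4 of 6 consecutive residues have P(helix) ≥ 100,
extension one residue at a time while the region's mean P(helix) stays
≥ 100; sheet nucleation at ≥ 3 of 5 with mean-P(sheet) ≥ 105
extension; helix/sheet overlaps resolved toward the higher region-mean
propensity; turns assigned to tetrapeptides whose bend-frequency
product exceeds 7.5e-5 with mean P(turn) > 100 dominating both other
propensities. Everything else is coil. Four states H/E/T/C are kept
end-to-end — turn is deliberately not folded into coil, because the
selection criteria downstream favour turn and coil residues
separately, and the coil-fraction statistic (`coilFractionOfRegions()`)
offers both conventions via `includeTurn`.

`gorPredict()` is an information-sum predictor: state(i) = argmax over
H/E/T/C of the summed directional information contributed by residues
at offsets −8..+8 (window 17, the convention of the GOR family as run
by common web servers), ties resolving to coil. The shipped parameter
set (`gorParameters()`, id `"cf-decay-v1"`) is derived in-package: log
Chou-Fasman propensities spread over the window with a triangular
distance decay, with the coil column balancing the other three. This
is a documented stand-in, not a transcription of the historical GOR
information tables, which are not redistributable here; the algorithm,
its window convention and its tie rule are independent of the table,
and the suite verifies the summation against a brute-force oracle.
Users with a preferred published table can pass it directly — the
function accepts any `[residue, offset, state]` array.

Server-grade predictors in this family (SOPMA and kin) additionally
average over database homologs; that database state is not
reproducible offline, so the package's "SOPMA-like" track is the
majority consensus of its own two predictors (`ssConsensus()`, ties to
coil by default). Reproduction of published SOPMA percentages is
explicitly not asserted anywhere in the suite.

# Hidden-state scoring

`trainTwoState()` estimates a two-state (epitope/background) HMM by
supervised counting with add-one smoothing on both emissions (20
residues per state) and label-run transitions — the smoothing guards
zero probabilities on small corpora, and counting makes the estimate
deterministic and order-independent. `posteriorProfile()` runs scaled
forward–backward initialised at the transition chain's stationary
distribution; with identical emissions the posterior is exactly the
stationary epitope probability, a degenerate case the suite pins down,
and for sequences of length ≤ 8 the posterior equals exhaustive
enumeration over all 2^n state paths.

`bepipredProfile()` mixes the posterior with hydrophilicity:
score(i) = w·(2·posterior(i) − 1) + (1 − w)·z(Parker(i)). The original
server's trained weights are unavailable, so this scorer is an honest
stand-in: its interval outputs are interchangeable with the packaged
fixture intervals everywhere downstream, which decouples the consensus
machinery from scorer fidelity. The decision threshold 0.35 is the
published convention for this score family and is kept as the default;
w defaults to 0.5 (equal weight, recorded in the model object and its
JSON serialisation), and the affine calibration (2·posterior − 1 and a
per-sequence z-score put both terms on comparable, roughly symmetric
scales) is the package's documented choice. `defaultTwoStateModel()`
trains on a fixed-seed synthetic corpus so the package ships no binary
weights.

# Region calling

`callRegionsMulti()` applies the residue-wise selection rule: positive
hydrophilicity, positive antigenic index, surface probability > 1,
flexibility > 1, optionally restricted to turn/coil. The conjunction
is evaluated per residue (residue-wise AND rather than region-averaged
criteria — the stricter and simpler reading of "regions satisfying all
criteria"), maximal passing runs become candidates, runs shorter than
`minLen = 5` are dropped and runs longer than `maxLen = 30` are split
recursively at their weakest antigenic-index residue, which is
removed. The 5–30 length band reflects the observed size range of
linear epitopes; the split-at-weakest-AI mechanism is the package's
own, honouring the upper bound with a defensible tie-break.
"Flexibility" is operationalised as Karplus-Schulz index > 1.0, the
scale's average-mobility baseline, since the selection rule's source
names the signal but not a cutoff; all thresholds are
config-overridable through `callCriteria()`.

`mergeAdjacent()` defines its gap as the number of *uncovered residues*
between two intervals: `1~5` and `6~9` have gap 0 and merge at
`maxGap = 0`; `1~5` and `8~9` have gap 2 and need `maxGap ≥ 2`. This
convention is stated here because "gap" is ambiguous in interval
algebra and silent off-by-ones here would shift epitope boundaries.

# The k-of-n consensus

`consensusRegions()` implements residue-level support counting: a
residue is consensus-supported when ≥ k of n tools cover it (duplicate
intervals within one tool deduplicated first), maximal supported runs
form consensus epitopes, and runs shorter than `minLen = 5` are
discarded. Residue-level counting — rather than pairwise interval
intersection — is a deliberate semantic choice: it reproduces both the
canonical worked example (ABCDEFG ∩ CDEFGH → CDEFG) and the published
sesame consensus rows, including one (Ses i 1, 38–45) that pairwise
intersection cannot produce because its support is stitched from two
different tool pairs along the run. In the limit k = 1, minLen = 1 the
operation reduces to the sorted union of all intervals, a property the
suite checks along with permutation- and split-invariance and
equivalence to a brute-force counting oracle.

## The packaged sesame tables and their corrections

The per-tool epitope tables for Ses i 1–7 ship as plain-text fixtures
(`loadFixture()`). Two printed entries are evident typos and are
corrected *as data, not code*: the corrections live in
`inst/extdata/corrections.tsv` with their rationale, are applied at
load time, reported via `message()`, and returned to the caller.
Ses i 1's `5~52` reads as `50~52` (the printed token contradicts the
published consensus row under any k-of-n rule, and flanking tokens
indicate a dropped digit); Ses i 7's `4576~459` reads as `457~459`
(out of range). Each published consensus row carries a reproducibility
flag: Ses i 1, 2, 3 and 5 are `rule-consistent` (the k=2-of-3,
min-length-5 rule on the published inputs reproduces them exactly);
Ses i 4 and Ses i 6 are `discrepant` (for example, their first rows
truncate intersections the printed inputs clearly support), and
Ses i 7 is `discrepant` by one region — the rule yields an additional
415–419 region that the printed per-tool rows support but the
published consensus omits. Whether manual curation or unprinted
intermediate data intervened is unknowable from the published record,
so these rows are flagged and reported, never forced and never
asserted in tests.

# Structural mapping

`readStructure()` parses PDB/mmCIF via bio3d, keeping the first
protein chain's heavy atoms and the B-factor column, which in
predicted models carries per-residue pLDDT. `shrakeRupleySasa()` uses
a probe of 1.4 Å (water) and a *deterministic* golden-spiral point set
(default 960 points/atom) — determinism makes results exactly
reproducible and lets the suite assert closed-form cases (an isolated
atom's ASA is within 1% of 4π(r + 1.4)²) and rigid-motion invariance
at 0.5%. RSA divides per-residue ASA by a fixed published theoretical
maximum-ASA table; the exposure call uses RSA ≥ 0.25, the common
buried/exposed convention — no quantitative exposure criterion exists
in the epitope literature this pipeline descends from, so the
threshold is explicitly this package's own and is a parameter of
`epitopeReport()`. pLDDT scale is auto-detected (files on 0–1 are
multiplied by 100). Because models frequently cover the mature
sequence while epitopes are numbered on another form, the
sequence-to-model numbering shift is an explicit `offset` argument
rather than a heuristic. Model-level quality metrics that upstream
structure predictors report (pTM, ranking scores) are pass-through
inputs; the package never recomputes them.

# Synthetic data: what it emulates, and what it does not

`generateProtein()` draws a uniform-composition background and plants
segments from a biased alphabet (K, E, D, G, S, P at 0.12 each,
0.72 total) — hydrophilic, flexible, turn/coil-prone residues, i.e.
exactly the signal structure the selection criteria reward. This makes
the end-to-end recovery test meaningful (the pipeline must find the
planted signal through its real scoring path) instead of circular
per-module assertions. `generateToolPredictions()` simulates tool
noise: boundary jitter, per-tool drop-outs and Poisson false
positives, all seeded; all generators are bit-reproducible given
(spec, seed).

`endToEndRecovery()` has two modes. `"simulated"` (default) feeds the
planted truth through the tool simulator and the consensus; with zero
noise this round-trip is exactly lossless for segments ≥ minLen, which
anchors the recovery guarantees (recall 1.0 noiseless; jittered
consensus recall ≥ mean single-tool recall over seeds). `"profile"`
runs the real scorers (propensity profiles, secondary structure,
hidden-state scorer, region calling) and reports whatever
precision/recall they achieve — no guarantee is asserted, because
propensity scorers on random-background synthetic proteins have no
lossless-recovery property. The split resolves an ambiguity between
the recovery guarantee (which only the simulated path can carry) and
the wish to exercise the full pipeline; both are tested for what they
are. What the synthetic generator does **not** emulate: real allergen
family composition, homology structure, domain architecture or
length/composition correlations — so green recovery tests demonstrate
algorithmic correctness of the pipeline, not predictive accuracy on
real allergens.

# Numerical choices and degenerate inputs

* Ambiguity letters U/B/Z/J map to X at parse time with a warning;
  numeric operations reject X explicitly (no published scale value
  exists for it) rather than guessing.
* Isoelectric point: bisection on [0, 14] to |net charge| < 1e-4 under
  the EMBOSS pKa set (`pkaSet()`), a single fixed published table —
  the commercial tool behind the published global properties uses an
  internal table that is not public.
* Percent identity: identities / alignment columns × 100 under
  match 1 / mismatch 0 / gap −1 (global or local), a deliberately
  substitution-free scheme; the alignment convention behind published
  cross-allergen identity percentages is unstated, so this utility
  documents its own denominator and is checked against exhaustive
  alignment enumeration at small lengths.
* Secondary-structure consensus ties resolve to coil (the least
  structured state, and the conservative choice for epitope calling,
  where T/C is the permissive class); configurable.
* GOR ties resolve to coil; window positions outside the sequence
  contribute nothing.
* Empty interval lists: `coilFractionOfRegions()` errors ("no epitope
  residues") rather than returning 0/0; `consensusRegions()` with a
  silenced tool simply counts it as covering nothing.
* Seeds: every stochastic helper takes an explicit seed
  (`plantSpec`/`jitterSpec`) or uses `withr::with_seed`, so no global
  RNG state leaks.

# Problem sizes used by the shipped checks

The test suite and acceptance script run at desk scale, chosen to make
the oracles exhaustive rather than sampled: consensus vs brute-force
counting on 1000 random instances (≤ 4 tools, length ≤ 200),
region-calling vs mask oracle on random tracks, forward–backward vs
all 2^n paths at n ≤ 8, GOR vs independent summation on 30-mers,
SASA on single atoms and short extended backbones (240–3840 sphere
points), and recovery simulations on 100–150-residue proteins over 20
seeds. The sesame case study itself is exact arithmetic on the
packaged tables.

# Known limitations

* The propensity/HMM scorers are faithful to their published method
  families but are not numerically identical to the retired or
  commercial servers whose outputs the packaged tables transcribe;
  the consensus machinery is therefore validated on the tables
  themselves, and scorer outputs are validated against oracles and
  properties, not against those servers.
* The GOR parameter set is a documented in-package derivation, not the
  historical table (see above).
* Structure mapping reports per-epitope means (RSA, pLDDT) and an
  exposure flag; it does not attempt spatial clustering of epitopes or
  conformational-epitope prediction.
* The published GRAVY comparison needs the UniProt sequences, which
  are not redistributed; `physchemTable()` works on any FASTA the user
  supplies.
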