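mkp <- function(v) new("ResidueProfile", method = "t", window = 1L,
                       values = v, edgePolicy = "shrink")

test_that("multi-track calling returns maximal passing runs under the criteria", {
  n <- 12L
  sat <- callRegionsMulti(mkp(rep(1, n)), mkp(rep(1, n)),
                          mkp(rep(2, n)), mkp(rep(2, n)))
  expect_true(rangesEqual(sat, IRanges::IRanges(1, 12)))

  v <- rep(-1, 10); v[3:6] <- 1  # run of 4 < minLen 5
  short <- callRegionsMulti(mkp(v), mkp(rep(1, 10)), mkp(rep(2, 10)),
                            mkp(rep(2, 10)))
  expect_length(short, 0L)

  # crafted passes at 3-9 and 15-26, checked against the mask oracle
  n <- 30L
  hy <- rep(-1, n); hy[c(3:9, 15:26)] <- 1
  got <- callRegionsMulti(mkp(hy), mkp(rep(1, n)), mkp(rep(2, n)),
                          mkp(rep(2, n)))
  mask <- hy > 0
  expect_true(rangesEqual(got, bruteMaskRuns(mask, 5L)))
  expect_true(rangesEqual(got, IRanges::IRanges(c(3, 15), c(9, 26))))

  expect_error(callRegionsMulti(NULL, mkp(hy), mkp(hy), mkp(hy)),
               "hydrophilicity")
  crit <- callCriteria(requireSS = c("T", "C"))
  expect_error(callRegionsMulti(mkp(hy), mkp(rep(1, n)), mkp(rep(2, n)),
                                mkp(rep(2, n)), criteria = crit), "ss")
})

test_that("multi-track calling equals the residue-mask oracle on random tracks", {
  withr::with_seed(51, for (i in 1:1000) {
    n <- sample(20:60, 1)
    hy <- stats::runif(n, -1, 1); ai <- stats::runif(n, -1, 1)
    su <- stats::runif(n, 0, 2); fl <- stats::runif(n, 0, 2)
    got <- callRegionsMulti(mkp(hy), mkp(ai), mkp(su), mkp(fl),
                            criteria = callCriteria(minLen = 2L))
    mask <- hy > 0 & ai > 0 & su > 1 & fl > 1
    expect_true(rangesEqual(got, bruteMaskRuns(mask, 2L)))
    expect_true(all(IRanges::start(got) >= 1 & IRanges::end(got) <= n))
  })
})

test_that("tightening any single criterion never enlarges the called set", {
  residues_of <- function(ir) {
    if (length(ir) == 0L) return(integer(0))
    unlist(lapply(seq_along(ir), function(k)
      IRanges::start(ir)[k]:IRanges::end(ir)[k]))
  }
  withr::with_seed(52, for (i in 1:50) {
    n <- 40L
    hy <- stats::runif(n, -1, 1); ai <- stats::runif(n, -1, 1)
    su <- stats::runif(n, 0, 2); fl <- stats::runif(n, 0, 2)
    base <- residues_of(callRegionsMulti(mkp(hy), mkp(ai), mkp(su),
                                         mkp(fl),
                                         criteria = callCriteria(minLen = 1L)))
    tight <- residues_of(callRegionsMulti(
      mkp(hy), mkp(ai), mkp(su), mkp(fl),
      criteria = callCriteria(hydrophilicityMin = 0.3, minLen = 1L)))
    expect_true(all(tight %in% base))
  })
})

test_that("long runs are split at the weakest antigenic-index position", {
  n <- 40L
  ai <- stats::runif(n, 1, 2); ai[18] <- 0.5  # weakest residue
  got <- callRegionsMulti(mkp(rep(1, n)), mkp(ai), mkp(rep(2, n)),
                          mkp(rep(2, n)),
                          criteria = callCriteria(antigenicIndexMin = 0,
                                                  minLen = 5, maxLen = 30))
  expect_true(all(IRanges::width(got) <= 30))
  expect_false(18 %in% unlist(lapply(seq_along(got), function(k)
    IRanges::start(got)[k]:IRanges::end(got)[k])))
})

test_that("threshold calling keeps runs above the cutoff", {
  sp <- function(v, th = 0.35) new("ScoreProfile", method = "s",
                                   values = v, threshold = th)
  expect_length(callRegionsThreshold(sp(rep(0, 10))), 0L)
  whole <- callRegionsThreshold(sp(rep(1, 10)))
  expect_true(rangesEqual(whole, IRanges::IRanges(1, 10)))
  withr::with_seed(53, for (i in 1:200) {
    v <- stats::runif(30, 0, 1)
    got <- callRegionsThreshold(sp(v), minLen = 3L)
    expect_true(rangesEqual(got, bruteMaskRuns(v > 0.35, 3L)))
  })
})

test_that("interval merging counts uncovered residues as the gap", {
  expect_equal(formatIntervalSpec(mergeAdjacent("1~5, 6~9")), "1~9")
  expect_equal(formatIntervalSpec(mergeAdjacent("1~5, 8~9", maxGap = 1)),
               "1~5, 8~9")
  expect_equal(formatIntervalSpec(mergeAdjacent("1~5, 8~9", maxGap = 2)),
               "1~9")
  expect_equal(formatIntervalSpec(mergeAdjacent("1~5, 3~7")), "1~7")
})
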