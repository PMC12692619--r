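test_that("protein generation is seed-reproducible and respects the spec", {
  spec0 <- plantSpec(length = 60L, seed = 1L)
  g0 <- generateProtein(spec0)
  expect_length(g0$truth, 0L)
  expect_identical(nchar(g0$sequence), 60L)

  spec <- plantSpec(length = 100L,
                    segments = data.frame(start = c(11L, 51L),
                                          end = c(30L, 70L)),
                    seed = 7L)
  expect_identical(generateProtein(spec), generateProtein(spec))
  expect_error(plantSpec(length = 50L,
                         segments = data.frame(start = c(1L, 5L),
                                               end = c(10L, 12L))),
               "overlap")
})

test_that("planted segments are hydrophilic relative to background", {
  hw <- propensityScale("hopp-woods")
  wins <- vapply(1:100, function(i) {
    spec <- plantSpec(length = 100L,
                      segments = data.frame(start = 31L, end = 60L),
                      seed = 9000 + i)
    ch <- strsplit(generateProtein(spec)$sequence, "")[[1]]
    mean(hw[ch[31:60]]) > mean(hw[ch[-(31:60)]])
  }, logical(1))
  # sign test: planted hydrophilicity should exceed background nearly
  # always, far beyond the binomial null
  expect_gt(sum(wins), stats::qbinom(0.999, 100, 0.5))
})

test_that("noiseless simulated tools reproduce the truth exactly", {
  spec <- plantSpec(length = 120L,
                    segments = data.frame(start = c(21L, 61L),
                                          end = c(35L, 80L)),
                    seed = 3L)
  g <- generateProtein(spec)
  preds <- generateToolPredictions(g$truth, 120L, jitterSpec(seed = 3L))
  for (p in preds) expect_true(rangesEqual(p, g$truth))
  cons <- consensusRegions(preds, length = 120L)
  expect_true(rangesEqual(cons, g$truth))

  # one tool silenced entirely: k = 2 of the remaining two still recovers
  preds$tool3 <- IRanges::IRanges()
  cons2 <- consensusRegions(preds, length = 120L, k = 2)
  expect_true(rangesEqual(cons2, g$truth))
})

test_that("end-to-end recovery is lossless without noise and deterministic", {
  spec <- plantSpec(length = 150L,
                    segments = data.frame(start = c(31L, 101L),
                                          end = c(45L, 120L)),
                    seed = 42L)
  r <- endToEndRecovery(spec, jitterSpec(seed = 42L))
  expect_equal(r$recall, 1.0)
  expect_equal(r$precision, 1.0)
  r2 <- endToEndRecovery(spec, jitterSpec(seed = 42L))
  expect_identical(r$sequence, r2$sequence)
  expect_true(rangesEqual(r$consensus, r2$consensus))

  # degenerate spec: nothing planted gives a defined empty report
  r0 <- endToEndRecovery(plantSpec(length = 40L, seed = 5L),
                         jitterSpec(seed = 5L))
  expect_true(is.na(r0$recall))
  expect_length(r0$truth, 0L)
})

test_that("consensus recovery under jitter beats the average single tool", {
  gains <- vapply(1:20, function(i) {
    spec <- plantSpec(length = 150L,
                      segments = data.frame(start = c(31L, 101L),
                                            end = c(45L, 120L)),
                      seed = 100 + i)
    r <- endToEndRecovery(spec, jitterSpec(jitter = 2L, fpRate = 0.02,
                                           seed = 200 + i))
    r$recall - mean(r$perTool[, "recall"])
  }, numeric(1))
  expect_gte(mean(gains), 0)
})

test_that("the profile-mode pipeline runs end to end and reports recovery", {
  spec <- plantSpec(length = 100L,
                    segments = data.frame(start = c(21L, 61L),
                                          end = c(35L, 72L)),
                    seed = 42L)
  r <- endToEndRecovery(spec, mode = "profile",
                        model = defaultTwoStateModel(nSequences = 8L))
  expect_true(is.finite(r$precision) && is.finite(r$recall))
  expect_true(all(IRanges::width(r$consensus) >= 5L))
  expect_identical(names(r$predictions),
                   c("profile-suite", "sopma-like", "bepipred-like"))
})
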