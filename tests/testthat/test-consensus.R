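test_that("residue support counts distinct tools with per-tool dedup", {
  expect_equal(residueSupport(list(a = "1~3"), 5), c(1, 1, 1, 0, 0))
  expect_equal(residueSupport(list(a = "2~4", b = "2~4"), 5),
               c(0, 2, 2, 2, 0))
  expect_equal(residueSupport(list(a = "1~3, 2~5"), 5), rep(1, 5))
  expect_error(residueSupport(list(mytool = "2~9"), 5), "mytool")
})

test_that("the worked two-tool example yields the common five-residue segment", {
  # tool A predicts ABCDEFG (1-7), tool B CDEFGH (3-8): consensus CDEFG
  cons <- consensusRegions(list(A = "1~7", B = "3~8"), length = 8,
                           k = 2, minLen = 5, sequence = "ABCDEFGH")
  expect_length(cons, 1L)
  expect_equal(IRanges::start(cons), 3L)
  expect_equal(IRanges::end(cons), 7L)
  expect_identical(S4Vectors::mcols(cons)$peptide, "CDEFG")
  expect_identical(S4Vectors::mcols(cons)$support, "A,B")

  # disjoint single-tool predictions never reach k = 2
  expect_length(consensusRegions(list(A = "1~6", B = "10~15"),
                                 length = 20), 0L)
})

test_that("consensus equals the brute-force counting oracle on random instances", {
  withr::with_seed(61, for (i in 1:1000) {
    len <- sample(20:200, 1)
    nTools <- sample(2:4, 1)
    preds <- replicate(nTools, randomIRanges(len), simplify = FALSE)
    names(preds) <- paste0("t", seq_len(nTools))
    k <- sample(seq_len(nTools), 1)
    minLen <- sample(1:6, 1)
    got <- consensusRegions(preds, length = len, k = k, minLen = minLen)
    expect_true(rangesEqual(got, bruteConsensus(preds, len, k, minLen)))
    # region invariants: every residue supported by >= k tools, width ok
    if (length(got)) {
      sup <- residueSupport(preds, len)
      for (r in seq_along(got))
        expect_true(all(sup[IRanges::start(got)[r]:IRanges::end(got)[r]] >= k))
      expect_true(all(IRanges::width(got) >= minLen))
      expect_true(all(diff(IRanges::start(got)) > 0))
    }
  })
})

test_that("consensus is invariant to tool order and to splitting intervals", {
  withr::with_seed(62, for (i in 1:50) {
    len <- 120L
    preds <- list(a = randomIRanges(len), b = randomIRanges(len),
                  c = randomIRanges(len))
    got <- consensusRegions(preds, length = len)
    perm <- consensusRegions(preds[c(3, 1, 2)], length = len)
    expect_true(rangesEqual(got, perm))
    # split one tool's intervals into abutting halves
    split1 <- unlist(lapply(seq_along(preds$a), function(j) {
      s <- IRanges::start(preds$a)[j]; e <- IRanges::end(preds$a)[j]
      if (e > s) list(c(s, s + (e - s) %/% 2),
                      c(s + (e - s) %/% 2 + 1, e))
      else list(c(s, e))
    }), recursive = FALSE)
    preds2 <- preds
    preds2$a <- IRanges::IRanges(vapply(split1, `[`, numeric(1), 1),
                                 vapply(split1, `[`, numeric(1), 2))
    expect_true(rangesEqual(got, consensusRegions(preds2, length = len)))
  })
})

test_that("k = 1 with minLen = 1 reduces to the union of all intervals", {
  withr::with_seed(63, for (i in 1:20) {
    len <- 80L
    preds <- list(a = randomIRanges(len), b = randomIRanges(len))
    got <- consensusRegions(preds, length = len, k = 1, minLen = 1)
    expect_true(rangesEqual(got, IRanges::reduce(c(preds$a, preds$b))))
  })
})

test_that("peptide extraction slices 1-based inclusive intervals", {
  expect_identical(extractPeptides("ABCDEFGH", "3~7"), "CDEFG")
  expect_identical(extractPeptides("ABCDEFGH", "1~1"), "A")
  expect_error(extractPeptides("ABCDEFGH", "5~9"), "outside")
})

test_that("fixtures load the printed tables, log corrections and reproduce rows", {
  expect_error(loadFixture("Ses i 9"), "unknown allergen")

  expect_message(fx1 <- loadFixture("Ses i 1"), "5~52.*50~52")
  expect_identical(nrow(fx1$corrections), 1L)
  # the corrected token replaces the printed one
  expect_true(any(IRanges::start(fx1$predictions$dnastar) == 50 &
                    IRanges::end(fx1$predictions$dnastar) == 52))
  expect_false(any(IRanges::start(fx1$predictions$dnastar) == 5 &
                     IRanges::end(fx1$predictions$dnastar) == 52))

  fx2 <- loadFixture("Ses i 2", quiet = TRUE)
  expect_identical(names(fx2$predictions),
                   c("dnastar", "sopma", "bepipred"))
  cons2 <- consensusRegions(fx2$predictions, length = fx2$length)
  expect_true(rangesEqual(cons2, IRanges::IRanges(75, 79)))

  fx5 <- loadFixture("Ses i 5", quiet = TRUE)
  expect_true(rangesEqual(fx5$expected,
                          IRanges::IRanges(c(5, 103, 132),
                                           c(13, 110, 145))))
  expect_identical(fx5$flag, "rule-consistent")

  # corrected out-of-range entry is gone from the bepipred set of Ses i 7
  fx7 <- loadFixture("Ses i 7", quiet = TRUE)
  expect_lt(max(IRanges::end(fx7$predictions$bepipred)), 1000L)
})

test_that("consensus reports write 1-based coordinates with support and peptides", {
  cons <- consensusRegions(list(A = "1~7", B = "3~8"), length = 8,
                           sequence = "ABCDEFGH")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeConsensusReport(cons, f)
  lines <- readLines(f)
  expect_match(lines[1], "1-based inclusive")
  tab <- utils::read.delim(f, comment.char = "#")
  expect_identical(tab$peptide, "CDEFG")
  expect_identical(tab$start, 3L)
})
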