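# Independent brute-force oracles and tiny fixture builders used across
# the suite. These deliberately avoid the package's own code paths
# (coverage/slice/forward-backward/etc.) so agreement is informative.

suppressPackageStartupMessages({
  library(IRanges)
  library(S4Vectors)
})

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Per-position distinct-tool support by explicit looping.
bruteSupport <- function(preds, len) {
  support <- integer(len)
  for (iv in preds) {
    cov <- rep(FALSE, len)
    for (i in seq_along(iv))
      cov[IRanges::start(iv)[i]:IRanges::end(iv)[i]] <- TRUE
    support <- support + as.integer(cov)
  }
  support
}

# Maximal runs of TRUE in a mask, dropping runs shorter than minLen.
bruteMaskRuns <- function(mask, minLen = 1L) {
  st <- en <- integer(0)
  i <- 1L; n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1L]) j <- j + 1L
      if (j - i + 1L >= minLen) { st <- c(st, i); en <- c(en, j) }
      i <- j + 1L
    } else i <- i + 1L
  }
  IRanges(start = st, end = en)
}

bruteConsensus <- function(preds, len, k, minLen) {
  dedup <- lapply(preds, IRanges::reduce)
  bruteMaskRuns(bruteSupport(dedup, len) >= k, minLen)
}

# Exhaustive posterior over all 2^n state paths (state 1 = epitope).
bruteForwardBackward <- function(chars, emissions, transitions) {
  n <- length(chars)
  init <- c(transitions[2, 1], transitions[1, 2])
  init <- init / sum(init)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  probs <- apply(paths, 1L, function(p) {
    pr <- init[p[1]] * emissions[p[1], chars[1]]
    if (n > 1) for (t in 2:n)
      pr <- pr * transitions[p[t - 1], p[t]] * emissions[p[t], chars[t]]
    pr
  })
  vapply(seq_len(n), function(i)
    sum(probs[paths[, i] == 1]) / sum(probs), numeric(1))
}

# Independent GOR re-summation with plain loops.
bruteGorStates <- function(chars, params) {
  offsets <- as.integer(dimnames(params)[[2]])
  statesd <- dimnames(params)[[3]]
  n <- length(chars)
  out <- character(n)
  for (i in seq_len(n)) {
    s <- setNames(numeric(length(statesd)), statesd)
    for (k in seq_along(offsets)) {
      j <- i + offsets[k]
      if (j >= 1 && j <= n)
        for (st in statesd) s[st] <- s[st] + params[chars[j], k, st]
    }
    top <- names(s)[s == max(s)]
    out[i] <- if (length(top) > 1L) "C" else top
  }
  paste(out, collapse = "")
}

# Enumerate all global alignments of a and b (gap in either, or match
# column); returns the set of pid values among score-optimal alignments.
bruteOptimalPids <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  best <- -Inf; pids <- numeric(0)
  rec <- function(i, j, score, cols, ids) {
    if (i > length(a) && j > length(b)) {
      if (score > best) { best <<- score; pids <<- numeric(0) }
      if (score == best) pids <<- c(pids, 100 * ids / cols)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      rec(i + 1L, j + 1L, score + s, cols + 1L,
          ids + as.integer(a[i] == b[j]))
    }
    if (i <= length(a)) rec(i + 1L, j, score + gap, cols + 1L, ids)
    if (j <= length(b)) rec(i, j + 1L, score + gap, cols + 1L, ids)
  }
  rec(1L, 1L, 0, 0L, 0L)
  unique(pids)
}

# Minimal extended poly-GLY backbone PDB / mmCIF writers (B = pLDDT).
writeTestPDB <- function(path, nres = 5L, b = 90, shift = c(0, 0, 0),
                         rot = diag(3)) {
  lines <- character(0); no <- 1L
  for (i in seq_len(nres)) {
    base <- rbind(c(i * 3.8, 0, 0), c(i * 3.8 + 1, 1, 0),
                  c(i * 3.8 + 2, 0, 0), c(i * 3.8 + 2, -1.2, 0))
    xyz <- t(rot %*% t(base)) + matrix(shift, 4, 3, byrow = TRUE)
    nm <- c("N", "CA", "C", "O"); el <- c("N", "C", "C", "O")
    for (k in 1:4) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s GLY A%4d    %8.3f%8.3f%8.3f  1.00%6.2f           %s",
        no, nm[k], i, xyz[k, 1], xyz[k, 2], xyz[k, 3], b, el[k]))
      no <- no + 1L
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

writeTestCIF <- function(path, nres = 5L, b = 90) {
  hdr <- c("data_test", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id",
                    "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                    "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                    "auth_seq_id", "auth_comp_id", "auth_asym_id",
                    "auth_atom_id", "pdbx_PDB_model_num")))
  rows <- character(0); no <- 1L
  for (i in seq_len(nres)) {
    xyz <- rbind(c(i * 3.8, 0, 0), c(i * 3.8 + 1, 1, 0),
                 c(i * 3.8 + 2, 0, 0), c(i * 3.8 + 2, -1.2, 0))
    nm <- c("N", "CA", "C", "O"); el <- c("N", "C", "C", "O")
    for (k in 1:4) {
      rows <- c(rows, sprintf(
        "ATOM %d %s %s . GLY A 1 %d ? %.3f %.3f %.3f 1.00 %.2f ? %d GLY A %s 1",
        no, el[k], nm[k], i, xyz[k, 1], xyz[k, 2], xyz[k, 3], b, i, nm[k]))
      no <- no + 1L
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

randomSeq <- function(n) paste(sample(AA20, n, replace = TRUE),
                               collapse = "")

randomTwoStateModel <- function() {
  em <- matrix(stats::runif(40, 0.1, 1), 2, 20)
  em <- em / rowSums(em)
  tr <- matrix(stats::runif(4, 0.1, 1), 2, 2)
  tr <- tr / rowSums(tr)
  twoStateModel(em, tr)
}

rangesEqual <- function(x, y) {
  length(x) == length(y) &&
    all(IRanges::start(x) == IRanges::start(y)) &&
    all(IRanges::end(x) == IRanges::end(y))
}

randomIRanges <- function(len, maxIv = 5L) {
  nIv <- sample(0:maxIv, 1L)
  if (nIv == 0L) return(IRanges())
  st <- sample(seq_len(len), nIv, replace = TRUE)
  w <- sample(1:12, nIv, replace = TRUE)
  IRanges(start = st, end = pmin(len, st + w - 1L))
}
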