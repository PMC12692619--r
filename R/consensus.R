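#' Per-residue tool support counts
#'
#' For each position 1..length, the number of distinct tools with at
#' least one interval covering it. Duplicate or overlapping intervals
#' from the same tool count once (each tool's set is normalised with
#' \code{\link[IRanges]{reduce}} first).
#'
#' @param predictions Named list (or \code{IRangesList}) of per-tool
#'   interval sets; each element an \code{IRanges}, a data.frame with
#'   \code{start}/\code{end}, or an interval-spec string.
#' @param length Protein length in residues.
#' @return Integer vector of length \code{length}.
#' @examples
#' residueSupport(list(a = "1~3"), length = 5)  # 1 1 1 0 0
#' @export
residueSupport <- function(predictions, length) {
  preds <- .as_prediction_list(predictions)
  length <- as.integer(length)
  stopifnot(length >= 1L)
  support <- integer(length)
  for (nm in names(preds)) {
    iv <- preds[[nm]]
    if (base::length(iv) == 0L) next
    if (min(start(iv)) < 1L || max(end(iv)) > length)
      stop("tool '", nm, "' has interval [",
           start(iv)[which.max(end(iv))], ",", max(end(iv)),
           "] outside [1, ", length, "]")
    cov <- IRanges::coverage(IRanges::reduce(iv), width = length)
    support <- support + as.integer(cov > 0L)
  }
  support
}

#' k-of-n residue-overlap consensus of per-tool epitope predictions
#'
#' The consensus rule: a residue is supported when at least \code{k} of
#' the tools predict it; maximal runs of supported residues form
#' consensus regions, and runs shorter than \code{minLen} residues are
#' discarded. Boundaries are therefore the exact contiguous segment
#' shared by the supporting predictions — two tools predicting
#' \code{ABCDEFG} and \code{CDEFGH} yield the common segment
#' \code{CDEFG}.
#'
#' @inheritParams residueSupport
#' @param k Minimum number of supporting tools per residue (default 2).
#' @param minLen Minimum consensus region length (default 5).
#' @param sequence Optional sequence; when given, peptides are attached.
#' @return Sorted, disjoint \code{IRanges}; metadata columns:
#'   \code{support} (comma-separated names of tools covering >= 1
#'   residue of the region), \code{nTools}, and \code{peptide} when a
#'   sequence is supplied.
#' @examples
#' consensusRegions(list(A = "1~7", B = "3~8"), length = 8,
#'                  sequence = "ABCDEFGH")
#' @export
consensusRegions <- function(predictions, length, k = 2L, minLen = 5L,
                             sequence = NULL) {
  preds <- .as_prediction_list(predictions)
  k <- as.integer(k); minLen <- as.integer(minLen)
  stopifnot(k >= 1L, k <= base::length(preds), minLen >= 1L)
  support <- residueSupport(preds, length)
  runs <- IRanges::slice(Rle(support), lower = k, rangesOnly = TRUE)
  runs <- runs[width(runs) >= minLen]
  sup <- vapply(seq_along(runs), function(i) {
    hit <- vapply(preds, function(iv)
      base::length(iv) > 0L &&
        any(start(iv) <= end(runs)[i] & end(iv) >= start(runs)[i]),
      logical(1))
    paste(names(preds)[hit], collapse = ",")
  }, character(1))
  mc <- DataFrame(support = sup,
                  nTools = vapply(strsplit(sup, ","), base::length,
                                  integer(1)))
  if (!is.null(sequence)) {
    s <- .as_label_string(sequence)
    if (nchar(s) < length)
      stop("sequence shorter than the stated length")
    mc$peptide <- substring(s, start(runs), end(runs))
  }
  mcols(runs) <- mc
  runs
}

#' Extract epitope peptides from a sequence
#'
#' @param sequence Sequence (character / AAString / length-1
#'   AAStringSet).
#' @param epitopes \code{IRanges} (or interval-spec string) of 1-based
#'   inclusive intervals.
#' @return Character vector of peptides, one per interval.
#' @examples
#' extractPeptides("ABCDEFGH", "3~7")  # "CDEFG"
#' @export
extractPeptides <- function(sequence, epitopes) {
  s <- .as_label_string(sequence)
  if (is.character(epitopes)) epitopes <- parseIntervalSpec(epitopes)
  if (base::length(epitopes) == 0L) return(character(0))
  if (min(start(epitopes)) < 1L || max(end(epitopes)) > nchar(s))
    stop("interval outside the sequence (length ", nchar(s), ")")
  substring(s, start(epitopes), end(epitopes))
}

#' Export consensus regions as a TSV report
#'
#' Writes \code{start, end, length, support, peptide} with a header line
#' noting that coordinates are 1-based inclusive (unlike BED).
#'
#' @param regions Result of \code{\link{consensusRegions}}.
#' @param file Output path or open connection.
#' @return \code{file}, invisibly.
#' @export
writeConsensusReport <- function(regions, file) {
  df <- data.frame(start = start(regions), end = end(regions),
                   length = width(regions),
                   support = mcols(regions)$support,
                   peptide = if (!is.null(mcols(regions)$peptide))
                     mcols(regions)$peptide else NA_character_)
  if (inherits(file, "connection")) {
    con <- file
  } else {
    con <- file(file, "w")
    on.exit(close(con))
  }
  writeLines("# consensus epitope regions; coordinates are 1-based inclusive",
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
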