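#' Selection criteria for multi-track epitope region calling
#'
#' The residue-wise selection rule: positive hydrophilicity, positive
#' antigenic index, surface probability above 1 (the random expectation)
#' and flexibility above 1 (average backbone mobility), optionally
#' restricted to turn/coil residues. Candidate regions are maximal runs
#' of residues passing every enabled criterion; runs shorter than
#' \code{minLen} are dropped and runs longer than \code{maxLen} are split
#' recursively at their weakest antigenic-index position (linear epitopes
#' typically span 5-7 and at most 30 residues).
#'
#' @param hydrophilicityMin,antigenicIndexMin Exclusive lower bounds
#'   (default 0).
#' @param surfaceMin,flexibilityMin Exclusive lower bounds (default 1).
#' @param requireSS Subset of \code{c("T", "C")}; when non-empty the
#'   consensus state must be one of these. Default empty.
#' @param minLen,maxLen Length bounds in residues (defaults 5 and 30).
#' @return A list of class \code{"CallCriteria"}.
#' @export
callCriteria <- function(hydrophilicityMin = 0, antigenicIndexMin = 0,
                         surfaceMin = 1, flexibilityMin = 1,
                         requireSS = character(0),
                         minLen = 5L, maxLen = 30L) {
  stopifnot(all(requireSS %in% c("T", "C")),
            minLen >= 1L, maxLen >= minLen)
  structure(list(hydrophilicityMin = hydrophilicityMin,
                 antigenicIndexMin = antigenicIndexMin,
                 surfaceMin = surfaceMin, flexibilityMin = flexibilityMin,
                 requireSS = requireSS,
                 minLen = as.integer(minLen), maxLen = as.integer(maxLen)),
            class = "CallCriteria")
}

# Split runs longer than maxLen at the weakest antigenic-index residue,
# recursively; the weakest residue itself is removed.
.split_long_runs <- function(ir, ai, maxLen) {
  out <- list()
  recurse <- function(lo, hi) {
    if (hi - lo + 1L <= maxLen) {
      out[[length(out) + 1L]] <<- c(lo, hi)
      return()
    }
    cut <- lo + which.min(ai[lo:hi]) - 1L
    if (cut > lo) recurse(lo, cut - 1L)
    if (cut < hi) recurse(cut + 1L, hi)
  }
  for (k in seq_along(ir)) recurse(start(ir)[k], end(ir)[k])
  if (!length(out)) return(IRanges())
  IRanges(vapply(out, `[`, numeric(1), 1), vapply(out, `[`, numeric(1), 2))
}

#' Call candidate epitope regions from aligned per-residue tracks
#'
#' A residue passes when every enabled criterion of
#' \code{\link{callCriteria}} holds; maximal runs of passing residues
#' become candidate intervals, filtered by \code{minLen} and split at
#' their weakest antigenic-index position when longer than \code{maxLen}.
#'
#' @param hydrophilicity,antigenicIndex,surface,flexibility
#'   \code{\link{ResidueProfile-class}} tracks aligned to one sequence.
#' @param ss Optional \code{\link{SSAssignment-class}}; required when
#'   \code{criteria$requireSS} is non-empty.
#' @param criteria A \code{\link{callCriteria}} object.
#' @param tool Label stored on the result (default
#'   \code{"profile-suite"}).
#' @return \code{IRanges} of 1-based inclusive candidate regions with
#'   metadata columns \code{tool} and \code{score} (mean antigenic
#'   index).
#' @export
callRegionsMulti <- function(hydrophilicity, antigenicIndex, surface,
                             flexibility, ss = NULL,
                             criteria = callCriteria(),
                             tool = "profile-suite") {
  tracks <- list(hydrophilicity = hydrophilicity,
                 antigenicIndex = antigenicIndex,
                 surface = surface, flexibility = flexibility)
  for (nm in names(tracks)) {
    if (is.null(tracks[[nm]]) || !is(tracks[[nm]], "ResidueProfile"))
      stop("missing or invalid required track: ", nm)
  }
  vals <- lapply(tracks, profileValues)
  n <- length(vals[[1]])
  if (any(vapply(vals, length, integer(1)) != n))
    stop("all tracks must be aligned to the same sequence length")
  pass <- vals$hydrophilicity > criteria$hydrophilicityMin &
    vals$antigenicIndex > criteria$antigenicIndexMin &
    vals$surface > criteria$surfaceMin &
    vals$flexibility > criteria$flexibilityMin
  pass[is.na(pass)] <- FALSE
  if (length(criteria$requireSS)) {
    if (is.null(ss)) stop("missing required track: ss")
    st <- ssStates(ss)
    if (length(st) != n)
      stop("ss assignment length does not match the tracks")
    pass <- pass & st %in% criteria$requireSS
  }
  runs <- IRanges::slice(Rle(as.integer(pass)), lower = 1L, rangesOnly = TRUE)
  runs <- .split_long_runs(runs, vals$antigenicIndex, criteria$maxLen)
  runs <- runs[width(runs) >= criteria$minLen]
  runs <- sort(runs)
  mcols(runs) <- DataFrame(
    tool = rep(tool, length(runs)),
    score = vapply(seq_along(runs), function(k)
      mean(vals$antigenicIndex[start(runs)[k]:end(runs)[k]]), numeric(1)))
  runs
}

#' Call regions from a thresholded score profile
#'
#' Maximal runs of residues whose score strictly exceeds the threshold,
#' keeping runs of at least \code{minLen} residues.
#'
#' @param score A \code{\link{ScoreProfile-class}}.
#' @param threshold Score cutoff; defaults to the profile's stored
#'   threshold (0.35 for \code{\link{bepipredProfile}}).
#' @param minLen Minimum run length (default 5).
#' @param tool Label stored on the result.
#' @return \code{IRanges} with metadata columns \code{tool} and
#'   \code{score} (mean score in the run).
#' @export
callRegionsThreshold <- function(score, threshold = scoreThreshold(score),
                                 minLen = 5L, tool = profileMethod(score)) {
  stopifnot(is(score, "ScoreProfile"))
  v <- profileValues(score)
  pass <- v > threshold
  pass[is.na(pass)] <- FALSE
  runs <- IRanges::slice(Rle(as.integer(pass)), lower = 1L, rangesOnly = TRUE)
  runs <- runs[width(runs) >= minLen]
  mcols(runs) <- DataFrame(
    tool = rep(tool, length(runs)),
    score = vapply(seq_along(runs), function(k)
      mean(v[start(runs)[k]:end(runs)[k]]), numeric(1)))
  runs
}

#' Merge nearby intervals
#'
#' Unions intervals that overlap or are separated by at most
#' \code{maxGap} uncovered residues. With \code{maxGap = 0}, abutting
#' intervals (no uncovered residue between them, e.g. 1-5 and 6-9) merge;
#' intervals leaving >= 1 uncovered residue do not.
#'
#' @param intervals \code{IRanges} (or interval-spec string /
#'   data.frame).
#' @param maxGap Maximum number of uncovered residues bridged (default
#'   0).
#' @return Sorted, disjoint \code{IRanges}.
#' @export
mergeAdjacent <- function(intervals, maxGap = 0L) {
  if (is.character(intervals)) intervals <- parseIntervalSpec(intervals)
  if (is.data.frame(intervals))
    intervals <- IRanges(start = intervals$start, end = intervals$end)
  stopifnot(maxGap >= 0L)
  IRanges::reduce(intervals, min.gapwidth = maxGap + 1L)
}
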