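#' Specification for a synthetic protein with planted epitope-like
#' segments
#'
#' Describes a random protein: uniform background composition, with
#' planted non-overlapping segments drawn from a biased alphabet
#' enriched in hydrophilic, flexible, turn/coil-prone residues (K, E, D,
#' G, S, P by default) — the residue classes that linear-epitope
#' selection criteria reward, so that pipeline recovery tests are
#' meaningful end to end rather than circular per module.
#'
#' @param length Protein length in residues.
#' @param segments data.frame with \code{start}/\code{end} (1-based
#'   inclusive, non-overlapping, within bounds); zero rows plant
#'   nothing.
#' @param seed Integer seed; identical spec + seed gives identical
#'   output.
#' @param biasResidues Residues enriched inside planted segments.
#' @param biasWeight Total probability mass given to the bias residues
#'   inside segments (default 0.72, i.e. 0.12 each for the default six).
#' @return A list of class \code{"PlantSpec"}.
#' @export
plantSpec <- function(length = 100L, segments = data.frame(
                        start = integer(0), end = integer(0)),
                      seed = 42L,
                      biasResidues = c("K", "E", "D", "G", "S", "P"),
                      biasWeight = 0.72) {
  length <- as.integer(length)
  stopifnot(length >= 1L, is.data.frame(segments),
            all(biasResidues %in% AA20),
            biasWeight > 0, biasWeight < 1)
  if (nrow(segments)) {
    segments <- segments[order(segments$start), , drop = FALSE]
    stopifnot(all(segments$start >= 1L), all(segments$end <= length),
              all(segments$start <= segments$end))
    if (nrow(segments) > 1L &&
        any(segments$start[-1L] <= segments$end[-nrow(segments)]))
      stop("planted segments must not overlap")
  }
  structure(list(length = length, segments = segments,
                 seed = as.integer(seed), biasResidues = biasResidues,
                 biasWeight = biasWeight),
            class = "PlantSpec")
}

#' Noise model for simulated per-tool predictions
#'
#' @param jitter Maximum boundary jitter in residues (each interval
#'   boundary moves by a uniform integer in [-jitter, jitter]).
#' @param fpRate Expected false-positive intervals per 100 residues.
#' @param dropProb Probability that a tool drops a true interval.
#' @param seed Integer seed.
#' @return A list of class \code{"JitterSpec"}.
#' @export
jitterSpec <- function(jitter = 0L, fpRate = 0, dropProb = 0,
                       seed = 42L) {
  stopifnot(jitter >= 0L, fpRate >= 0, fpRate <= 1,
            dropProb >= 0, dropProb <= 1)
  structure(list(jitter = as.integer(jitter), fpRate = fpRate,
                 dropProb = dropProb, seed = as.integer(seed)),
            class = "JitterSpec")
}

#' Generate a synthetic protein with planted segments
#'
#' @param spec A \code{\link{plantSpec}}.
#' @return List with \code{sequence} (character) and \code{truth}
#'   (\code{IRanges} of the planted segments).
#' @export
generateProtein <- function(spec) {
  stopifnot(inherits(spec, "PlantSpec"))
  pBias <- rep(0, 20); names(pBias) <- AA20
  pBias[spec$biasResidues] <- spec$biasWeight / length(spec$biasResidues)
  rest <- setdiff(AA20, spec$biasResidues)
  pBias[rest] <- (1 - spec$biasWeight) / length(rest)
  ch <- withr::with_seed(spec$seed, {
    bg <- sample(AA20, spec$length, replace = TRUE)
    for (i in seq_len(nrow(spec$segments))) {
      idx <- spec$segments$start[i]:spec$segments$end[i]
      bg[idx] <- sample(AA20, length(idx), replace = TRUE, prob = pBias)
    }
    bg
  })
  list(sequence = paste(ch, collapse = ""),
       truth = IRanges(start = as.integer(spec$segments$start),
                       end = as.integer(spec$segments$end)))
}

#' Simulate noisy per-tool predictions from known truth
#'
#' Each simulated tool receives the truth intervals with boundaries
#' jittered, some intervals dropped, plus random false positives, under
#' a seed derived from \code{jitter$seed} and the tool index.
#'
#' @param truth \code{IRanges} of true epitope segments.
#' @param length Protein length.
#' @param jitter A \code{\link{jitterSpec}}.
#' @param nTools Number of simulated tools (default 3).
#' @return Named list of \code{IRanges}, one per tool.
#' @export
generateToolPredictions <- function(truth, length, jitter = jitterSpec(),
                                    nTools = 3L) {
  stopifnot(inherits(jitter, "JitterSpec"), nTools >= 1L)
  length <- as.integer(length)
  if (base::length(truth) &&
      (min(start(truth)) < 1L || max(end(truth)) > length))
    stop("truth intervals outside [1, ", length, "]")
  jit <- function() {
    if (jitter$jitter == 0L) return(0L)
    sample(seq(-jitter$jitter, jitter$jitter), 1L)
  }
  out <- withr::with_seed(jitter$seed, {
    lapply(seq_len(nTools), function(t) {
      st <- en <- integer(0)
      for (i in seq_along(truth)) {
        if (stats::runif(1) < jitter$dropProb) next
        s <- start(truth)[i] + jit()
        e <- end(truth)[i] + jit()
        s <- max(1L, min(s, length)); e <- max(1L, min(e, length))
        if (s > e) { tmp <- s; s <- e; e <- tmp }
        st <- c(st, s); en <- c(en, e)
      }
      nfp <- stats::rpois(1L, jitter$fpRate * length / 100)
      for (f in seq_len(nfp)) {
        w <- sample(5:10, 1L)
        s <- sample(seq_len(max(1L, length - w + 1L)), 1L)
        st <- c(st, s); en <- c(en, min(length, s + w - 1L))
      }
      IRanges(start = st, end = en)
    })
  })
  names(out) <- paste0("tool", seq_len(nTools))
  out
}

# Residue-level precision/recall of predicted vs true intervals.
.residue_pr <- function(predicted, truth, length) {
  pv <- rep(FALSE, length); tv <- rep(FALSE, length)
  for (i in seq_along(predicted))
    pv[start(predicted)[i]:end(predicted)[i]] <- TRUE
  for (i in seq_along(truth))
    tv[start(truth)[i]:end(truth)[i]] <- TRUE
  tp <- sum(pv & tv)
  c(precision = if (sum(pv)) tp / sum(pv) else NA_real_,
    recall = if (sum(tv)) tp / sum(tv) else NA_real_)
}

#' End-to-end recovery of planted epitopes by the consensus pipeline
#'
#' Generates a protein from \code{spec}, derives three predictions and
#' their k-of-n consensus, and reports residue-level precision and
#' recall against the planted truth.
#'
#' Two modes: \code{"simulated"} (default) feeds the truth through
#' \code{\link{generateToolPredictions}} — the round-trip is exactly
#' lossless when the noise is zero, which anchors the recovery tests;
#' \code{"profile"} runs the real scoring pipeline (propensity profiles,
#' secondary structure, hidden-state scorer, region calling) on the
#' generated sequence, reporting whatever recovery the scorers achieve
#' with no guarantee attached.
#'
#' @param spec A \code{\link{plantSpec}}.
#' @param jitter A \code{\link{jitterSpec}} (used in \code{"simulated"}
#'   mode).
#' @param k,minLen Consensus parameters (defaults 2 and 5).
#' @param mode \code{"simulated"} or \code{"profile"}.
#' @param model Optional \code{\link{TwoStateModel-class}} for
#'   \code{"profile"} mode (default \code{\link{defaultTwoStateModel}}).
#' @return List with \code{sequence}, \code{truth}, \code{predictions},
#'   \code{consensus}, \code{precision}, \code{recall}, and
#'   \code{perTool} (per-tool precision/recall matrix).
#' @export
endToEndRecovery <- function(spec, jitter = jitterSpec(), k = 2L,
                             minLen = 5L,
                             mode = c("simulated", "profile"),
                             model = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "PlantSpec"))
  g <- generateProtein(spec)
  n <- spec$length
  if (mode == "simulated") {
    preds <- generateToolPredictions(g$truth, n, jitter = jitter)
  } else {
    hydro <- windowedProfile(g$sequence, "hopp-woods", window = 7L)
    surf <- eminiProfile(g$sequence)
    flex <- karplusSchulzProfile(g$sequence)
    ss <- ssConsensus(list(chouFasman(g$sequence),
                           gorPredict(g$sequence)))
    ai <- jamesonWolfProfile(hydro, surf, flex, ss)
    if (is.null(model)) model <- defaultTwoStateModel()
    bep <- bepipredProfile(g$sequence, model)
    preds <- list(
      `profile-suite` = callRegionsMulti(hydro, ai, surf, flex, ss = ss,
                                         criteria = callCriteria(minLen = minLen)),
      `sopma-like` = callRegionsThreshold(
        new("ScoreProfile", method = "sopma-like",
            values = as.numeric(ssStates(ss) %in% c("T", "C")),
            threshold = 0.5), minLen = minLen),
      `bepipred-like` = callRegionsThreshold(bep, minLen = minLen))
  }
  cons <- consensusRegions(preds, length = n, k = k, minLen = minLen)
  pr <- .residue_pr(cons, g$truth, n)
  perTool <- t(vapply(preds, .residue_pr, numeric(2),
                      truth = g$truth, length = n))
  list(sequence = g$sequence, truth = g$truth, predictions = preds,
       consensus = cons, precision = unname(pr["precision"]),
       recall = unname(pr["recall"]), perTool = perTool)
}
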