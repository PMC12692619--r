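#' Construct a two-state epitope/background HMM
#'
#' @param emissions 2 x 20 matrix (rows \code{epitope}, \code{background};
#'   columns the 20 standard residues), rows summing to 1.
#' @param transitions 2 x 2 stochastic matrix over the same two states.
#' @param w Mixing weight in [0, 1] between the HMM posterior and the
#'   standardised hydrophilicity track (default 0.5).
#' @return A \code{\link{TwoStateModel-class}}.
#' @export
twoStateModel <- function(emissions, transitions, w = 0.5) {
  dimnames(emissions) <- list(c("epitope", "background"), AA20)
  dimnames(transitions) <- list(c("epitope", "background"),
                                c("epitope", "background"))
  new("TwoStateModel", emissions = emissions, transitions = transitions,
      w = w)
}

#' Estimate the two-state model from labelled sequences
#'
#' Supervised re-estimation: residues inside the given intervals are
#' labelled epitope, all others background. Emissions are add-one
#' smoothed residue counts per state; transitions are add-one smoothed
#' label-run counts. The result depends only on aggregate counts, so it
#' is deterministic and order-independent.
#'
#' @param seqs List (or AAStringSet) of sequences.
#' @param intervals List of epitope interval sets, one per sequence
#'   (\code{IRanges}, data.frame with start/end, or interval-spec string).
#' @param w Mixing weight stored in the model (default 0.5).
#' @return A \code{\link{TwoStateModel-class}}.
#' @export
trainTwoState <- function(seqs, intervals, w = 0.5) {
  if (is(seqs, "XStringSet")) seqs <- as.list(as.character(seqs))
  if (!is.list(seqs)) seqs <- list(seqs)
  if (!is.list(intervals)) intervals <- list(intervals)
  if (length(seqs) != length(intervals))
    stop("need one interval set per sequence")
  emit <- matrix(1, 2, 20, dimnames = list(c("epitope", "background"),
                                           AA20))   # add-one smoothing
  trans <- matrix(1, 2, 2)
  for (i in seq_along(seqs)) {
    ch <- .residue_chars(seqs[[i]])
    ch[ch == "X"] <- NA   # X carries no emission information
    iv <- intervals[[i]]
    if (is.character(iv)) iv <- parseIntervalSpec(iv)
    if (is.data.frame(iv)) iv <- IRanges(start = iv$start, end = iv$end)
    lab <- rep(2L, length(ch))   # background
    if (length(iv)) {
      if (min(start(iv)) < 1L || max(end(iv)) > length(ch))
        stop("epitope interval outside sequence ", i,
             " (length ", length(ch), ")")
      for (k in seq_along(iv)) lab[start(iv)[k]:end(iv)[k]] <- 1L
    }
    for (s in 1:2) {
      tb <- table(factor(ch[lab == s], levels = AA20))
      emit[s, ] <- emit[s, ] + as.numeric(tb)
    }
    if (length(lab) > 1L)
      for (j in 2:length(lab))
        trans[lab[j - 1L], lab[j]] <- trans[lab[j - 1L], lab[j]] + 1
  }
  twoStateModel(emit / rowSums(emit), trans / rowSums(trans), w = w)
}

# Stationary distribution of a 2x2 transition matrix.
.stationary2 <- function(P) {
  a <- P[1, 2]; b <- P[2, 1]
  c(epitope = b / (a + b), background = a / (a + b))
}

#' Posterior probability of the epitope state per residue
#'
#' Scaled forward-backward over the two-state model, initialised at the
#' stationary distribution of the transition chain. With identical
#' emissions in both states the posterior is the stationary epitope
#' probability at every position.
#'
#' @param x Sequence (character / AAString / length-1 AAStringSet).
#' @param model A \code{\link{TwoStateModel-class}}.
#' @return A \code{\link{ScoreProfile-class}} with values in [0, 1]
#'   (method \code{"posterior"}, threshold 0.5).
#' @export
posteriorProfile <- function(x, model) {
  stopifnot(is(model, "TwoStateModel"))
  validObject(model)
  ch <- .residue_chars(x)
  .stop_if_X(ch, "the HMM posterior")
  n <- length(ch)
  E <- model@emissions[, ch, drop = FALSE]   # 2 x n
  P <- model@transitions
  init <- .stationary2(P)
  alpha <- matrix(0, 2, n); beta <- matrix(0, 2, n)
  scale <- numeric(n)
  a <- init * E[, 1]
  scale[1] <- sum(a)
  if (scale[1] <= 0) stop("zero forward probability at position 1")
  alpha[, 1] <- a / scale[1]
  if (n > 1) for (t in 2:n) {
    a <- (t(P) %*% alpha[, t - 1L]) * E[, t]
    scale[t] <- sum(a)
    if (scale[t] <= 0) stop("zero forward probability at position ", t)
    alpha[, t] <- a / scale[t]
  }
  beta[, n] <- 1
  if (n > 1) for (t in (n - 1L):1L) {
    b <- P %*% (E[, t + 1L] * beta[, t + 1L])
    beta[, t] <- b / scale[t + 1L]
  }
  post <- alpha * beta
  post <- sweep(post, 2L, colSums(post), "/")
  new("ScoreProfile", method = "posterior", values = post[1, ],
      threshold = 0.5)
}

#' Hidden-state epitope score with hydrophilicity mixing
#'
#' Per-residue linear B-cell epitope score combining the HMM posterior
#' with a hydrophilicity propensity track:
#' score(i) = w (2 post(i) - 1) + (1 - w) z(parker(i)),
#' where z is per-sequence standardisation of the Parker track. Scores
#' above the stored threshold (default 0.35) flag putative epitope
#' residues; interval calling happens downstream
#' (\code{\link{callRegionsThreshold}}).
#'
#' @inheritParams posteriorProfile
#' @param parker A \code{\link{ResidueProfile-class}} hydrophilicity
#'   track aligned to \code{x} (default: Parker profile, window 7).
#' @param w Mixing weight; defaults to the model's stored weight.
#' @param threshold Decision threshold stored on the result (default
#'   0.35).
#' @return A \code{\link{ScoreProfile-class}} (method
#'   \code{"bepipred-like"}).
#' @export
bepipredProfile <- function(x, model, parker = NULL, w = NULL,
                            threshold = 0.35) {
  stopifnot(is(model, "TwoStateModel"))
  if (is.null(parker)) parker <- windowedProfile(x, "parker", window = 7L)
  stopifnot(is(parker, "ResidueProfile"))
  if (is.null(w)) w <- model@w
  post <- profileValues(posteriorProfile(x, model))
  pv <- profileValues(parker)
  if (length(pv) != length(post))
    stop("hydrophilicity track length (", length(pv),
         ") does not match sequence length (", length(post), ")")
  sdv <- stats::sd(pv)
  z <- if (is.na(sdv) || sdv == 0) rep(0, length(pv))
       else (pv - mean(pv)) / sdv
  new("ScoreProfile", method = "bepipred-like",
      values = w * (2 * post - 1) + (1 - w) * z, threshold = threshold)
}

#' Write / read a two-state model as JSON
#'
#' Plain JSON serialisation (emissions, transitions, mixing weight) so a
#' trained model can travel with an analysis.
#'
#' @param model A \code{\link{TwoStateModel-class}}.
#' @param path File path.
#' @return \code{writeTwoStateModel} returns \code{path} invisibly;
#'   \code{readTwoStateModel} returns the model.
#' @export
writeTwoStateModel <- function(model, path) {
  stopifnot(is(model, "TwoStateModel"))
  obj <- list(
    residues = AA20,
    emissions = list(epitope = unname(model@emissions["epitope", ]),
                     background = unname(model@emissions["background", ])),
    transitions = list(epitope = unname(model@transitions["epitope", ]),
                       background = unname(model@transitions["background", ])),
    w = model@w)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTwoStateModel
#' @export
readTwoStateModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  em <- rbind(obj$emissions$epitope, obj$emissions$background)
  colnames(em) <- obj$residues
  em <- em[, AA20]
  tr <- rbind(obj$transitions$epitope, obj$transitions$background)
  twoStateModel(em, tr, w = obj$w)
}

#' Default two-state model trained on a deterministic synthetic corpus
#'
#' Trains \code{\link{trainTwoState}} on sequences generated by
#' \code{\link{generateProtein}} with planted hydrophilic/flexible
#' segments, under a fixed seed, so the package works out of the box
#' without shipped binary weights.
#'
#' @param nSequences Number of training sequences (default 25).
#' @param seed Seed for the training corpus (default 20240701).
#' @return A \code{\link{TwoStateModel-class}}.
#' @export
defaultTwoStateModel <- function(nSequences = 25L, seed = 20240701L) {
  seqs <- list(); ivs <- list()
  for (i in seq_len(nSequences)) {
    spec <- plantSpec(length = 120L,
                      segments = data.frame(start = c(21L, 81L),
                                            end = c(40L, 95L)),
                      seed = seed + i)
    g <- generateProtein(spec)
    seqs[[i]] <- g$sequence
    ivs[[i]] <- g$truth
  }
  trainTwoState(seqs, ivs)
}
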