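#' Sliding-window mean propensity profile
#'
#' Averages a per-residue propensity scale over a centred odd window,
#' giving one value per residue. Under \code{edgePolicy = "shrink"} the
#' window is truncated at the termini (so the track keeps full length and
#' terminal regions remain callable); under \code{"undefined"} those
#' positions are \code{NA}.
#'
#' @param x Sequence (character / AAString / length-1 AAStringSet).
#' @param scale A scale name accepted by \code{\link{propensityScale}} or
#'   a named numeric vector covering the 20 standard residues.
#' @param window Odd window width, \code{<= nchar(x)}.
#' @param edgePolicy \code{"shrink"} (default) or \code{"undefined"}.
#' @param method Track label; defaults to the scale name.
#' @return A \code{\link{ResidueProfile-class}} object.
#' @examples
#' windowedProfile("KAKAKAK", "hopp-woods", window = 3)
#' @export
windowedProfile <- function(x, scale, window = 7L,
                            edgePolicy = c("shrink", "undefined"),
                            method = NULL) {
  edgePolicy <- match.arg(edgePolicy)
  if (is.character(scale) && length(scale) == 1L) {
    if (is.null(method)) method <- scale
    scale <- propensityScale(scale)
  }
  if (is.null(method)) method <- "custom"
  if (!all(AA20 %in% names(scale)))
    stop("scale must cover all 20 standard residues")
  ch <- .residue_chars(x)
  .stop_if_X(ch, paste0("the '", method, "' profile"))
  n <- length(ch)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd, got ", window)
  if (window > n)
    stop("window (", window, ") exceeds sequence length (", n, ")")
  v <- unname(scale[ch])
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(v))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  vals <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  if (edgePolicy == "undefined")
    vals[(hi - lo + 1L) < window] <- NA_real_
  new("ResidueProfile", method = method, window = window,
      values = vals, edgePolicy = edgePolicy)
}

#' Emini surface probability profile
#'
#' Product-form surface probability over hexapeptides: for the hexapeptide
#' starting at n, S = (0.37)^-6 times the product of the six residues'
#' fractional surface probabilities, assigned to position n + 2. S = 1 is
#' the random expectation; S > 1 marks above-random surface probability.
#' Terminal positions with no full hexapeptide are computed over the
#' truncated window (with the normaliser adjusted to its length) under
#' \code{"shrink"}, or \code{NA} under \code{"undefined"}.
#'
#' @inheritParams windowedProfile
#' @return A \code{\link{ResidueProfile-class}} object (method
#'   \code{"emini"}, window 6).
#' @export
eminiProfile <- function(x, edgePolicy = c("shrink", "undefined")) {
  edgePolicy <- match.arg(edgePolicy)
  ch <- .residue_chars(x)
  .stop_if_X(ch, "the Emini surface profile")
  n <- length(ch)
  if (n < 6L) stop("Emini profile needs at least 6 residues, got ", n)
  delta <- .SCALES[["emini"]][ch] / 0.37
  cs <- c(0, cumsum(log(delta)))
  # hexapeptide n..n+5 anchors at n+2: window i-2 .. i+3 around position i
  lo <- pmax(1L, seq_len(n) - 2L)
  hi <- pmin(n, seq_len(n) + 3L)
  vals <- exp(cs[hi + 1L] - cs[lo])
  if (edgePolicy == "undefined")
    vals[(hi - lo + 1L) < 6L] <- NA_real_
  new("ResidueProfile", method = "emini", window = 6L,
      values = unname(vals), edgePolicy = edgePolicy)
}

#' Karplus-Schulz backbone flexibility profile
#'
#' Windowed mean of normalised crystallographic B-factor propensities.
#' Values near 1.0 are average backbone mobility; > 1.0 flexible.
#'
#' @inheritParams windowedProfile
#' @return A \code{\link{ResidueProfile-class}} object.
#' @export
karplusSchulzProfile <- function(x, window = 7L,
                                 edgePolicy = c("shrink", "undefined")) {
  windowedProfile(x, "karplus-schulz", window = window,
                  edgePolicy = match.arg(edgePolicy))
}

# Discretize a track to the five Jameson-Wolf classes
# {-0.6, -0.3, 0, +0.3, +0.6} by quintiles of its own distribution.
.jw_classes <- c(-0.6, -0.3, 0, 0.3, 0.6)

.discretize_track <- function(v) {
  br <- unique(stats::quantile(v, probs = c(0.2, 0.4, 0.6, 0.8),
                               na.rm = TRUE, names = FALSE))
  if (length(br) < 4L && length(unique(v[!is.na(v)])) == 1L)
    return(rep(0, length(v)))  # constant track: neutral class
  cls <- findInterval(v, br, left.open = TRUE) + 1L
  # map interval index 1..(length(br)+1) onto the symmetric class ladder
  ladder <- .jw_classes[round(seq(1L, 5L, length.out = length(br) + 1L))]
  ladder[cls]
}

#' Jameson-Wolf antigenic index
#'
#' Combines hydrophilicity, surface probability and backbone flexibility
#' tracks with a secondary-structure term into a per-residue antigenic
#' index: AI(i) = 0.3 h(i) + 0.15 s(i) + 0.15 f(i) + 0.4 c(i). The three
#' numeric tracks are first discretized to the classes \{-0.6, -0.3, 0,
#' +0.3, +0.6\} by quintiles of each track's own distribution (the
#' original method's absolute cutoffs are not published; per-sequence
#' quantiles keep class occupancy stable across proteins). The structure
#' term is c(i) = +0.6 when the consensus state at i is turn or coil and
#' -0.6 otherwise, folding the original method's two 0.2-weighted
#' surface-propensity terms into the single consensus assignment this
#' package produces.
#'
#' @param hydro,surface,flex \code{\link{ResidueProfile-class}} tracks of
#'   equal length (hydrophilicity, surface probability, flexibility).
#' @param ss \code{\link{SSAssignment-class}} of the same length.
#' @return A \code{\link{ResidueProfile-class}} (method
#'   \code{"jameson-wolf"}); positive values flag antigenic potential.
#' @export
jamesonWolfProfile <- function(hydro, surface, flex, ss) {
  stopifnot(is(hydro, "ResidueProfile"), is(surface, "ResidueProfile"),
            is(flex, "ResidueProfile"), is(ss, "SSAssignment"))
  n <- length(hydro@values)
  if (length(surface@values) != n || length(flex@values) != n ||
      length(ssStates(ss)) != n)
    stop("all tracks must be aligned to the same sequence length")
  h <- .discretize_track(hydro@values)
  s <- .discretize_track(surface@values)
  f <- .discretize_track(flex@values)
  cc <- ifelse(ssStates(ss) %in% c("T", "C"), 0.6, -0.6)
  ai <- 0.3 * h + 0.15 * s + 0.15 * f + 0.4 * cc
  new("ResidueProfile", method = "jameson-wolf", window = 1L,
      values = ai, edgePolicy = hydro@edgePolicy)
}

#' Export per-residue profiles as a table
#'
#' @param x Sequence the tracks belong to.
#' @param ... Named \code{ResidueProfile} / \code{ScoreProfile} /
#'   \code{SSAssignment} objects, all aligned to \code{x}.
#' @param file Optional path; when given the table is written as TSV.
#' @return data.frame with \code{position}, \code{residue} and one column
#'   per supplied track (invisibly when \code{file} is given).
#' @export
profileTable <- function(x, ..., file = NULL) {
  ch <- .residue_chars(x)
  tracks <- list(...)
  if (length(tracks) == 0L) stop("supply at least one track")
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stop("all tracks must be named")
  cols <- lapply(tracks, function(t) {
    v <- if (is(t, "SSAssignment")) ssStates(t) else profileValues(t)
    if (length(v) != length(ch))
      stop("track length does not match sequence length")
    v
  })
  out <- data.frame(position = seq_along(ch), residue = ch, cols,
                    check.names = FALSE)
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
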