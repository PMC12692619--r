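#' Chou-Fasman secondary-structure prediction
#'
#' Classical propensity-based predictor over the four states helix (H),
#' sheet (E), turn (T) and coil (C):
#' \itemize{
#'   \item helix nucleation where >= 4 of 6 consecutive residues are helix
#'     formers (P(helix) >= 100), extended one residue at a time while the
#'     running mean P(helix) of the region stays >= 100;
#'   \item sheet nucleation where >= 3 of 5 consecutive residues are sheet
#'     formers (P(sheet) >= 100), extended while mean P(sheet) >= 105;
#'   \item overlapping helix/sheet regions resolved toward the higher
#'     region-mean propensity;
#'   \item turn at tetrapeptides where the bend probability
#'     p(t) = f(i) f(i+1) f(i+2) f(i+3) > 7.5e-5, mean P(turn) > 100 and
#'     mean P(turn) exceeds both mean P(helix) and mean P(sheet); all four
#'     residues are assigned T (overriding H/E, which the propensity
#'     condition already dominates);
#'   \item everything unassigned is coil (C).
#' }
#'
#' @param x Sequence (character / AAString / length-1 AAStringSet),
#'   length >= 6; X is not allowed.
#' @return An \code{\link{SSAssignment-class}} (method
#'   \code{"chou-fasman"}).
#' @export
chouFasman <- function(x) {
  ch <- .residue_chars(x)
  .stop_if_X(ch, "Chou-Fasman prediction")
  n <- length(ch)
  if (n < 6L) stop("Chou-Fasman needs at least 6 residues, got ", n)
  cf <- chouFasmanTable()
  pa <- cf[ch, "Pa"]; pb <- cf[ch, "Pb"]; pt <- cf[ch, "Pt"]

  grow <- function(score, seed_lo, seed_hi, floor) {
    lo <- seed_lo; hi <- seed_hi
    while (lo > 1L && mean(score[(lo - 1L):hi]) >= floor) lo <- lo - 1L
    while (hi < n && mean(score[lo:(hi + 1L)]) >= floor) hi <- hi + 1L
    c(lo, hi)
  }
  regions <- function(score, win, kmin, floor) {
    out <- list()
    if (n >= win) {
      formers <- score >= 100
      for (i in 1:(n - win + 1L)) {
        if (sum(formers[i:(i + win - 1L)]) >= kmin) {
          r <- grow(score, i, i + win - 1L, floor)
          out[[length(out) + 1L]] <- r
        }
      }
    }
    if (!length(out)) return(out)
    # merge duplicates/overlaps of the same type
    ir <- IRanges::reduce(IRanges(vapply(out, `[`, numeric(1), 1),
                                  vapply(out, `[`, numeric(1), 2)))
    lapply(seq_along(ir), function(k) c(start(ir)[k], end(ir)[k]))
  }

  hreg <- regions(pa, 6L, 4L, 100)
  ereg <- regions(pb, 5L, 3L, 105)

  state <- rep("C", n)
  occupied <- rep("", n)   # competing propensity per assigned position
  assign_region <- function(r, sym, score) {
    idx <- r[1]:r[2]
    m <- mean(score[idx])
    for (i in idx) {
      if (state[i] == "C") {
        state[i] <<- sym; occupied[i] <<- m
      } else if (m > as.numeric(occupied[i])) {
        state[i] <<- sym; occupied[i] <<- m
      }
    }
  }
  for (r in hreg) assign_region(r, "H", pa)
  for (r in ereg) assign_region(r, "E", pb)

  f <- as.matrix(cf[ch, c("f0", "f1", "f2", "f3")])
  if (n >= 4L) {
    for (i in 1:(n - 3L)) {
      idx <- i:(i + 3L)
      ptu <- f[i, 1] * f[i + 1L, 2] * f[i + 2L, 3] * f[i + 3L, 4]
      if (ptu > 7.5e-5 && mean(pt[idx]) > 100 &&
          mean(pt[idx]) > mean(pa[idx]) && mean(pt[idx]) > mean(pb[idx]))
        state[idx] <- "T"
    }
  }
  new("SSAssignment", method = "chou-fasman",
      states = paste(state, collapse = ""))
}

#' GOR-style secondary-structure prediction
#'
#' Information-sum predictor: the state of residue i is the argmax over
#' H/E/T/C of the summed directional information values contributed by
#' the residues at offsets -halfWindow .. +halfWindow (window 17 by
#' default); window positions outside the sequence contribute nothing.
#' Ties resolve to C. The shipped parameter set is described in
#' \code{\link{gorParameters}}.
#'
#' @inheritParams chouFasman
#' @param params Directional information array as returned by
#'   \code{\link{gorParameters}}.
#' @return An \code{\link{SSAssignment-class}} (method \code{"gor"}).
#' @export
gorPredict <- function(x, params = gorParameters()) {
  ch <- .residue_chars(x)
  .stop_if_X(ch, "GOR prediction")
  if (length(params) == 0L || length(dim(params)) != 3L)
    stop("params must be a non-empty [residue, offset, state] array")
  offsets <- as.integer(dimnames(params)[[2]])
  statesd <- dimnames(params)[[3]]
  n <- length(ch)
  score <- matrix(0, n, length(statesd), dimnames = list(NULL, statesd))
  ridx <- match(ch, dimnames(params)[[1]])
  for (k in seq_along(offsets)) {
    d <- offsets[k]
    i <- seq_len(n)
    j <- i + d                     # neighbour residue feeding position i
    keep <- j >= 1L & j <= n
    score[i[keep], ] <- score[i[keep], ] + params[ridx[j[keep]], k, ]
  }
  pick <- apply(score, 1L, function(s) {
    top <- which(s == max(s))
    if (length(top) > 1L) "C" else statesd[top]
  })
  new("SSAssignment", method = "gor", states = paste(pick, collapse = ""))
}

#' Majority consensus of secondary-structure assignments
#'
#' Per-position majority vote over any number of equal-length
#' assignments; positions where the vote ties resolve to the
#' \code{tiePolicy} state (default C, the least structured).
#'
#' @param assignments List of \code{\link{SSAssignment-class}} objects.
#' @param tiePolicy State assigned on ties (one of H, E, T, C).
#' @return An \code{\link{SSAssignment-class}} (method
#'   \code{"consensus"}).
#' @export
ssConsensus <- function(assignments, tiePolicy = "C") {
  stopifnot(is.list(assignments), length(assignments) >= 1L,
            tiePolicy %in% c("H", "E", "T", "C"))
  mats <- lapply(assignments, function(a) {
    stopifnot(is(a, "SSAssignment"))
    ssStates(a)
  })
  n <- length(mats[[1]])
  if (any(vapply(mats, length, integer(1)) != n))
    stop("all assignments must have equal length")
  m <- do.call(rbind, mats)
  pick <- apply(m, 2L, function(col) {
    tab <- table(factor(col, levels = c("H", "E", "T", "C")))
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) tiePolicy else top
  })
  new("SSAssignment", method = "consensus",
      states = paste(pick, collapse = ""))
}

#' State composition of a secondary-structure assignment
#'
#' @param a An \code{\link{SSAssignment-class}}.
#' @return Named numeric vector \code{c(helix, sheet, turn, coil)} of
#'   fractions summing to 1.
#' @export
stateFractions <- function(a) {
  stopifnot(is(a, "SSAssignment"))
  st <- ssStates(a)
  tab <- table(factor(st, levels = c("H", "E", "T", "C"))) / length(st)
  c(helix = unname(tab["H"]), sheet = unname(tab["E"]),
    turn = unname(tab["T"]), coil = unname(tab["C"]))
}

#' Coil fraction within epitope regions
#'
#' Fraction of residues inside the union of the given intervals whose
#' consensus state is coil (optionally coil or turn) — the statistic
#' behind the observation that random coil dominates predicted epitope
#' regions.
#'
#' @param a An \code{\link{SSAssignment-class}}.
#' @param intervals \code{IRanges} (or anything
#'   \code{\link{parseIntervalSpec}} accepts) of 1-based inclusive
#'   epitope regions.
#' @param includeTurn When TRUE, count T as well as C.
#' @return Fraction in [0, 1].
#' @export
coilFractionOfRegions <- function(a, intervals, includeTurn = FALSE) {
  stopifnot(is(a, "SSAssignment"))
  if (is.character(intervals)) intervals <- parseIntervalSpec(intervals)
  if (is.data.frame(intervals))
    intervals <- IRanges(start = intervals$start, end = intervals$end)
  st <- ssStates(a)
  if (length(intervals) == 0L)
    stop("no epitope residues: interval list is empty")
  if (min(start(intervals)) < 1L || max(end(intervals)) > length(st))
    stop("interval outside the sequence (length ", length(st), ")")
  idx <- unique(unlist(lapply(seq_along(intervals), function(k)
    start(intervals)[k]:end(intervals)[k])))
  want <- if (includeTurn) c("C", "T") else "C"
  mean(st[idx] %in% want)
}
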