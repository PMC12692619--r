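#' @import methods
#' @importFrom S4Vectors Rle runValue runLength mcols mcols<- DataFrame
#' @importFrom BiocGenerics sort
#' @importClassesFrom IRanges IRanges
NULL

#' ResidueProfile: a per-residue numeric track
#'
#' One numeric value per residue of a protein sequence, 1-based, produced
#' by a sliding-window propensity method. Window positions that do not fit
#' are either computed over the truncated window (\code{edgePolicy =
#' "shrink"}) or set to \code{NA} (\code{"undefined"}) — never dropped, so
#' the track always aligns with the sequence.
#'
#' @slot method Name of the generating method.
#' @slot window Window width used (odd integer).
#' @slot values Numeric vector, one value per residue.
#' @slot edgePolicy \code{"shrink"} or \code{"undefined"}.
#' @exportClass ResidueProfile
setClass("ResidueProfile",
         representation(method = "character", window = "integer",
                        values = "numeric", edgePolicy = "character"))

setValidity("ResidueProfile", function(object) {
  msg <- NULL
  if (length(object@values) < 1L)
    msg <- c(msg, "profile must contain at least one value")
  if (length(object@window) != 1L || is.na(object@window) ||
      object@window < 1L)
    msg <- c(msg, "window must be a single integer >= 1")
  if (!object@edgePolicy %in% c("shrink", "undefined"))
    msg <- c(msg, "edgePolicy must be 'shrink' or 'undefined'")
  if (is.null(msg)) TRUE else msg
})

#' SSAssignment: per-residue secondary-structure states
#'
#' A string over the four-state alphabet H (helix), E (sheet), T (turn),
#' C (coil), one state per residue.
#'
#' @slot method Name of the predictor.
#' @slot states Single character string over \{H, E, T, C\}.
#' @exportClass SSAssignment
setClass("SSAssignment",
         representation(method = "character", states = "character"))

setValidity("SSAssignment", function(object) {
  if (length(object@states) != 1L || nchar(object@states) < 1L)
    return("states must be a single non-empty string")
  bad <- setdiff(strsplit(object@states, "")[[1]], c("H", "E", "T", "C"))
  if (length(bad))
    return(paste0("invalid secondary-structure symbol(s): ",
                  paste(unique(bad), collapse = ", ")))
  TRUE
})

#' ScoreProfile: per-residue epitope scores with a decision threshold
#'
#' @slot method Name of the scorer.
#' @slot values Numeric score per residue (unbounded).
#' @slot threshold Decision threshold applied downstream (default 0.35).
#' @exportClass ScoreProfile
setClass("ScoreProfile",
         representation(method = "character", values = "numeric",
                        threshold = "numeric"))

setValidity("ScoreProfile", function(object) {
  if (length(object@values) < 1L)
    return("score profile must contain at least one value")
  if (length(object@threshold) != 1L || is.na(object@threshold))
    return("threshold must be a single number")
  TRUE
})

#' TwoStateModel: two-state HMM over residues (epitope vs background)
#'
#' @slot emissions 2 x 20 matrix of emission probabilities (rows
#'   \code{"epitope"}, \code{"background"}; columns the standard residues);
#'   each row sums to 1.
#' @slot transitions 2 x 2 stochastic matrix of state transitions.
#' @slot w Mixing weight in [0, 1] between the HMM posterior and the
#'   standardised hydrophilicity track (see \code{\link{bepipredProfile}}).
#' @exportClass TwoStateModel
setClass("TwoStateModel",
         representation(emissions = "matrix", transitions = "matrix",
                        w = "numeric"))

setValidity("TwoStateModel", function(object) {
  msg <- NULL
  if (!identical(dim(object@emissions), c(2L, 20L)))
    msg <- c(msg, "emissions must be a 2 x 20 matrix")
  else if (any(abs(rowSums(object@emissions) - 1) > 1e-9) ||
           any(object@emissions <= 0))
    msg <- c(msg, "emission rows must be strictly positive and sum to 1")
  if (!identical(dim(object@transitions), c(2L, 2L)))
    msg <- c(msg, "transitions must be a 2 x 2 matrix")
  else if (any(abs(rowSums(object@transitions) - 1) > 1e-9) ||
           any(object@transitions <= 0))
    msg <- c(msg, "transition rows must be strictly positive and sum to 1")
  if (length(object@w) != 1L || is.na(object@w) ||
      object@w < 0 || object@w > 1)
    msg <- c(msg, "w must be a single number in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' StructureModel: atoms and per-residue confidence of a 3D model
#'
#' A light container around the atom table of a (predicted) protein
#' structure: one row per non-hydrogen atom with residue number, residue
#' type, element, coordinates in Angstrom and the B-factor column, which
#' for predicted models carries per-residue pLDDT confidence.
#'
#' @slot chain Chain identifier the model was read from.
#' @slot atoms data.frame with columns \code{resno}, \code{resid},
#'   \code{element}, \code{x}, \code{y}, \code{z}, \code{b}.
#' @exportClass StructureModel
setClass("StructureModel",
         representation(chain = "character", atoms = "data.frame"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("resno", "resid", "element", "x", "y", "z", "b")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) < 1L) return("model contains no atoms")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    return("atom coordinates must be finite")
  if (is.unsorted(unique(a$resno), strictly = TRUE))
    return("residue numbers must be strictly increasing")
  TRUE
})

## ---- accessors ----

#' @describeIn ResidueProfile-class Numeric values of a per-residue track
#'   (works for \code{ResidueProfile} and \code{ScoreProfile}).
#' @param x A profile object.
#' @export
profileValues <- function(x) x@values

#' @describeIn ResidueProfile-class Name of the generating method.
#' @export
profileMethod <- function(x) x@method

#' @describeIn SSAssignment-class Per-residue states as a character vector.
#' @param x An \code{SSAssignment}.
#' @export
ssStates <- function(x) strsplit(x@states, "")[[1]]

#' @describeIn ScoreProfile-class Decision threshold of a score profile.
#' @param x A \code{ScoreProfile}.
#' @export
scoreThreshold <- function(x) x@threshold

#' @describeIn StructureModel-class Atom table of a structure model.
#' @param x A \code{StructureModel}.
#' @export
modelAtoms <- function(x) x@atoms

#' @describeIn StructureModel-class Ordered unique residue numbers.
#' @export
modelResidues <- function(x) unique(x@atoms$resno)

setMethod("show", "ResidueProfile", function(object) {
  v <- object@values
  cat("ResidueProfile '", object@method, "' (window ", object@window,
      ", edge '", object@edgePolicy, "')\n", sep = "")
  cat("  ", length(v), " residues; range ",
      sprintf("%.3f .. %.3f", min(v, na.rm = TRUE), max(v, na.rm = TRUE)),
      "\n", sep = "")
})

setMethod("show", "SSAssignment", function(object) {
  st <- ssStates(object)
  frac <- table(factor(st, levels = c("H", "E", "T", "C"))) / length(st)
  cat("SSAssignment '", object@method, "': ", length(st), " residues (",
      paste(sprintf("%s %.0f%%", names(frac), 100 * frac), collapse = ", "),
      ")\n", sep = "")
})

setMethod("show", "ScoreProfile", function(object) {
  cat("ScoreProfile '", object@method, "': ", length(object@values),
      " residues, threshold ", object@threshold, "; ",
      sum(object@values > object@threshold), " residues above threshold\n",
      sep = "")
})

setMethod("show", "TwoStateModel", function(object) {
  cat("TwoStateModel (epitope/background), mixing weight w =",
      object@w, "\n")
  top <- colnames(object@emissions)[
    order(object@emissions["epitope", ] /
            object@emissions["background", ], decreasing = TRUE)[1:5]]
  cat("  residues most enriched in the epitope state:",
      paste(top, collapse = " "), "\n")
})

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel: chain '", object@chain, "', ",
      length(modelResidues(object)), " residues, ",
      nrow(object@atoms), " atoms\n", sep = "")
})
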