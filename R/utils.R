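#' @importFrom IRanges IRanges start end width reduce coverage slice
#' @importFrom Biostrings AAStringSet BStringSet readBStringSet
NULL

# Normalise any sequence-like input (character, AAString, length-1
# AAStringSet) to a single uppercase residue string.
.as_residues <- function(x, allowX = TRUE) {
  if (is(x, "XStringSet")) {
    if (length(x) != 1L)
      stop("expected a single sequence, got ", length(x))
    x <- as.character(x)
  } else if (is(x, "XString")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1L)
    stop("sequence must be a single character string or AAString(Set)")
  x <- toupper(x)
  if (nchar(x) < 1L) stop("sequence is empty")
  letters <- strsplit(x, "")[[1]]
  ok <- c(AA20, if (allowX) "X")
  bad <- which(!letters %in% ok)
  if (length(bad))
    stop("invalid residue '", letters[bad[1]], "' at position ", bad[1])
  x
}

# Like .as_residues but for plain residue *labels* (peptide slicing,
# worked examples): any uppercase letter is allowed.
.as_label_string <- function(x) {
  if (is(x, "XStringSet")) {
    if (length(x) != 1L) stop("expected a single sequence, got ", length(x))
    x <- as.character(x)
  } else if (is(x, "XString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop("sequence must be a single character string or AAString(Set)")
  x <- toupper(x)
  if (nchar(x) < 1L) stop("sequence is empty")
  if (grepl("[^A-Z]", x))
    stop("sequence contains non-letter characters")
  x
}

.residue_chars <- function(x, allowX = TRUE)
  strsplit(.as_residues(x, allowX = allowX), "")[[1]]

.stop_if_X <- function(chars, what) {
  if (any(chars == "X"))
    stop(what, " is undefined for sequences containing X ",
         "(ambiguity codes are mapped to X at parse time); mask or remove ",
         "X positions first (first X at position ",
         which(chars == "X")[1], ")")
}

#' Parse a printed interval specification into an IRanges
#'
#' Parses strings in the \code{"38~45, 61~70, 56"} notation used by the
#' packaged epitope tables (1-based inclusive; a bare number is a
#' single-residue interval; \code{"-"} is also accepted as separator).
#'
#' @param spec Character scalar like \code{"38~45, 61~70, 56"}; an empty
#'   string yields an empty \code{IRanges}.
#' @return \code{\link[IRanges]{IRanges}} in the order given.
#' @examples
#' parseIntervalSpec("38~45, 56")
#' @export
parseIntervalSpec <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  spec <- trimws(spec)
  if (!nzchar(spec)) return(IRanges())
  parts <- trimws(strsplit(spec, ",")[[1]])
  parts <- parts[nzchar(parts)]
  se <- lapply(parts, function(p) {
    tok <- strsplit(p, "[~–-]")[[1]]
    tok <- tok[nzchar(trimws(tok))]
    v <- suppressWarnings(as.integer(trimws(tok)))
    if (any(is.na(v)) || !length(v) %in% 1:2)
      stop("cannot parse interval token '", p, "'")
    if (length(v) == 1L) v <- c(v, v)
    if (v[1] > v[2] || v[1] < 1L)
      stop("invalid interval '", p, "' (start must be >= 1 and <= end)")
    v
  })
  IRanges(start = vapply(se, `[`, integer(1), 1L),
          end = vapply(se, `[`, integer(1), 2L))
}

#' Format an IRanges back into the printed interval notation
#'
#' Inverse of \code{\link{parseIntervalSpec}}: single-residue intervals
#' print as a bare position, others as \code{start~end}.
#'
#' @param x An \code{IRanges}.
#' @return Character scalar.
#' @export
formatIntervalSpec <- function(x) {
  if (length(x) == 0L) return("")
  paste(ifelse(width(x) == 1L, start(x),
               paste0(start(x), "~", end(x))), collapse = ", ")
}

# Coerce tool predictions given as IRanges, data.frame(start,end) or
# interval-spec strings into a named list of IRanges.
.as_prediction_list <- function(predictions) {
  if (is(predictions, "IRangesList")) predictions <- as.list(predictions)
  if (!is.list(predictions))
    stop("predictions must be a (named) list of interval sets")
  out <- lapply(predictions, function(p) {
    if (is(p, "IRanges")) p
    else if (is.character(p)) parseIntervalSpec(p)
    else if (is.data.frame(p)) IRanges(start = p$start, end = p$end)
    else stop("each tool's predictions must be an IRanges, a data.frame ",
              "with start/end, or an interval-spec string")
  })
  if (is.null(names(out)) || any(!nzchar(names(out))))
    names(out) <- paste0("tool", seq_along(out))
  out
}
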