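#' Read protein sequences from a FASTA file
#'
#' Reads a FASTA file into an \code{\link[Biostrings]{AAStringSet}} with
#' sequence ids as names and full headers kept in the element metadata.
#' Residues are uppercased; the ambiguity letters U, B, Z and J are mapped
#' to X with a warning. Any remaining non-amino-acid character is an
#' error naming the record and position.
#'
#' @param path Path to a FASTA file.
#' @return \code{AAStringSet}; \code{mcols()$description} carries the
#'   full header line of each record.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a demo", "MKV"), f)
#' readProteins(f)
#' @export
readProteins <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  headers <- names(raw)
  seqs <- toupper(as.character(raw))
  mapped <- chartr("UBZJ", "XXXX", seqs)
  nmap <- sum(nchar(gsub("[^UBZJ]", "", seqs)))
  if (nmap > 0L)
    warning(nmap, " ambiguity residue(s) (U/B/Z/J) mapped to X")
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  for (i in seq_along(mapped)) {
    ch <- strsplit(mapped[i], "")[[1]]
    if (length(ch) == 0L) stop("record '", ids[i], "' is empty")
    bad <- which(!ch %in% c(AA20, "X"))
    if (length(bad))
      stop("record '", ids[i], "': invalid character '", ch[bad[1]],
           "' at position ", bad[1])
  }
  out <- Biostrings::AAStringSet(mapped)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = headers)
  out
}

#' Trim an annotated signal peptide to obtain the mature sequence
#'
#' Returns residues \code{signalEnd + 1 .. length}; \code{signalEnd = 0}
#' returns the sequence unchanged. Positions are 1-based, matching signal
#' peptide annotations of the form "1..signalEnd".
#'
#' @param x Sequence (character, \code{AAString}, or length-1
#'   \code{AAStringSet}).
#' @param signalEnd Last residue of the signal peptide (0 for none).
#' @return Character string with the mature sequence.
#' @examples
#' matureSequence("MKVLAQ", 3)  # "LAQ"
#' @export
matureSequence <- function(x, signalEnd) {
  s <- .as_residues(x)
  signalEnd <- as.integer(signalEnd)
  if (length(signalEnd) != 1L || is.na(signalEnd) || signalEnd < 0L)
    stop("signalEnd must be a single integer >= 0")
  if (signalEnd >= nchar(s))
    stop("signalEnd (", signalEnd, ") must be smaller than the sequence ",
         "length (", nchar(s), ")")
  substring(s, signalEnd + 1L)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues; negative values
#' indicate a hydrophilic protein. Undefined for sequences containing X.
#'
#' @param x Sequence (character / AAString / length-1 AAStringSet).
#' @return Dimensionless mean hydropathy in [-4.5, 4.5].
#' @examples
#' gravy("IL")  # (4.5 + 3.8) / 2
#' @export
gravy <- function(x) {
  ch <- .residue_chars(x)
  .stop_if_X(ch, "GRAVY")
  mean(.SCALES[["kyte-doolittle"]][ch])
}

#' Molecular weight of a peptide
#'
#' Sum of average residue masses plus one water (Da).
#'
#' @inheritParams gravy
#' @return Molecular weight in Da.
#' @examples
#' molecularWeight("GG")  # ~132.12
#' @export
molecularWeight <- function(x) {
  ch <- .residue_chars(x)
  .stop_if_X(ch, "molecular weight")
  sum(.RESIDUE_MASS[ch]) + .WATER_MASS
}

# Net charge at a given pH under Henderson-Hasselbalch with the fixed
# pKa set of pkaSet().
.net_charge <- function(counts, pH) {
  pka <- pkaSet()
  pos <- c("Nterm", "K", "R", "H")
  neg <- c("Cterm", "D", "E", "C", "Y")
  n <- c(Nterm = 1, Cterm = 1, counts[c("K", "R", "H", "D", "E", "C", "Y")])
  charge <- sum(n[pos] / (1 + 10^(pH - pka[pos]))) -
    sum(n[neg] / (1 + 10^(pka[neg] - pH)))
  charge
}

#' Theoretical isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge of the peptide is zero,
#' found by bisection on [0, 14] to |charge| < 1e-4, using the fixed pKa
#' set returned by \code{\link{pkaSet}}.
#'
#' @inheritParams gravy
#' @return pI in pH units.
#' @export
isoelectricPoint <- function(x) {
  ch <- .residue_chars(x)
  .stop_if_X(ch, "isoelectric point")
  counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                   function(a) sum(ch == a), numeric(1))
  lo <- 0; hi <- 14
  if (.net_charge(counts, lo) < 0) return(lo)
  if (.net_charge(counts, hi) > 0) return(hi)
  repeat {
    mid <- (lo + hi) / 2
    q <- .net_charge(counts, mid)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-10) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Percent identity between two sequences
#'
#' Aligns two sequences under a substitution-free scheme (match 1,
#' mismatch 0, gap -1) and reports identities / alignment columns x 100.
#' Alignment columns include gapped columns of the pairwise alignment
#' (global) or of the best local alignment.
#'
#' @param a,b Sequences (character / AAString / length-1 AAStringSet).
#' @param mode \code{"global"} (Needleman-Wunsch, end gaps penalised) or
#'   \code{"local"} (Smith-Waterman).
#' @param match,mismatch,gap Scoring scheme (defaults 1 / 0 / -1).
#' @return Percent identity in [0, 100].
#' @examples
#' percentIdentity("PEPTIDE", "PEPTIDE")  # 100
#' @export
percentIdentity <- function(a, b, mode = c("global", "local"),
                            match = 1, mismatch = 0, gap = -1) {
  mode <- match.arg(mode)
  sa <- .as_residues(a); sb <- .as_residues(b)
  alpha <- c(AA20, "X")
  mat <- matrix(mismatch, 21, 21, dimnames = list(alpha, alpha))
  diag(mat) <- match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    type = mode, substitutionMatrix = mat,
    gapOpening = 0, gapExtension = -gap)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(p == s & p != "-") / length(p)
}

#' Physicochemical summary table for a set of sequences
#'
#' @param seqs \code{AAStringSet} (e.g. from \code{\link{readProteins}}).
#' @return data.frame with columns \code{id}, \code{length}, \code{gravy},
#'   \code{mw}, \code{pi}; \code{gravy}/\code{mw}/\code{pi} are \code{NA}
#'   for sequences containing X.
#' @export
physchemTable <- function(seqs) {
  stopifnot(is(seqs, "XStringSet"))
  safe <- function(f, s) tryCatch(f(s), error = function(e) NA_real_)
  s <- as.character(seqs)
  data.frame(
    id = if (is.null(names(seqs))) as.character(seq_along(seqs))
         else names(seqs),
    length = nchar(s),
    gravy = vapply(s, function(z) safe(gravy, z), numeric(1)),
    mw = vapply(s, function(z) safe(molecularWeight, z), numeric(1)),
    pi = vapply(s, function(z) safe(isoelectricPoint, z), numeric(1)),
    row.names = NULL)
}
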