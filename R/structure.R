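#' Read a protein structure model from PDB or mmCIF
#'
#' Parses the file with bio3d, keeps the first model and the requested
#' (or first) protein chain, drops hydrogens and non-ATOM records, and
#' returns a \code{\link{StructureModel-class}} whose B-factor column
#' carries whatever the file stored there — for predicted models,
#' per-residue pLDDT confidence.
#'
#' @param path Path to a \code{.pdb}/\code{.ent} or
#'   \code{.cif}/\code{.mmcif} file (format chosen by extension).
#' @param chain Chain id; default: first protein chain in the file.
#' @return A \code{\link{StructureModel-class}}.
#' @export
readStructure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty structure file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch({
    if (ext %in% c("cif", "mmcif")) suppressWarnings(bio3d::read.cif(path))
    else bio3d::read.pdb(path, multi = FALSE)
  }, error = function(e)
    stop("cannot parse structure file ", path, ": ", conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no protein chain in ", path)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms for chain '", chain, "' in ", path)
  elem <- toupper(trimws(at$elesy))
  noel <- which(is.na(elem) | elem == "")
  if (length(noel))   # fall back to the first letter of the atom name
    elem[noel] <- substr(gsub("[0-9]", "", toupper(at$elety[noel])), 1, 1)
  keep <- elem != "H"
  at <- at[keep, , drop = FALSE]; elem <- elem[keep]
  if (nrow(at) == 0L) stop("no heavy atoms in ", path)
  new("StructureModel", chain = as.character(chain),
      atoms = data.frame(resno = at$resno, resid = toupper(at$resid),
                         element = elem, x = at$x, y = at$y, z = at$z,
                         b = at$b))
}

# Deterministic unit sphere point set (golden-section spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-residue accessible surface area (A^2) by deterministic sphere
#' point sampling: each atom's solvent sphere (van der Waals radius +
#' probe) is covered with a fixed golden-spiral point set; points inside
#' any neighbouring atom's solvent sphere are occluded, and the
#' accessible fraction scales the sphere area. Determinism (no random
#' point set) makes results exactly reproducible.
#'
#' @param model A \code{\link{StructureModel-class}}.
#' @param probeRadius Solvent probe radius in Angstrom (default 1.4, a
#'   water molecule).
#' @param nPoints Sphere sample points per atom (default 960).
#' @return Named numeric vector of per-residue ASA in A^2 (names =
#'   residue numbers); attribute \code{"atomASA"} carries per-atom
#'   values.
#' @export
shrakeRupleySasa <- function(model, probeRadius = 1.4, nPoints = 960L) {
  stopifnot(is(model, "StructureModel"))
  at <- model@atoms
  unknown <- setdiff(unique(at$element), names(.VDW_RADII))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "), " (atoms ",
         paste(which(at$element %in% unknown)[1:min(3, sum(at$element %in% unknown))],
               collapse = ", "), ")")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- unname(.VDW_RADII[at$element]) + probeRadius
  n <- nrow(at)
  pts <- .sphere_points(as.integer(nPoints))
  atomASA <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    sp <- sweep(pts * rad[i], 2L, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(sp))
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 >= rad[j]^2
    }
    atomASA[i] <- 4 * pi * rad[i]^2 * sum(acc) / nrow(sp)
  }
  res <- tapply(atomASA, at$resno, sum)
  out <- as.numeric(res)
  names(out) <- names(res)
  attr(out, "atomASA") <- atomASA
  out
}

#' Relative solvent accessibility
#'
#' RSA = residue ASA divided by the theoretical maximum ASA of its
#' residue type (the fixed normalisation table shipped with the
#' package); isolated residues can slightly exceed 1.
#'
#' @param asa Named per-residue ASA as returned by
#'   \code{\link{shrakeRupleySasa}}.
#' @param residueTypes One-letter or three-letter residue types, one per
#'   entry of \code{asa}.
#' @return Numeric vector of RSA fractions.
#' @export
relativeAccessibility <- function(asa, residueTypes) {
  stopifnot(length(asa) == length(residueTypes))
  rt <- toupper(residueTypes)
  three <- nchar(rt) == 3L
  rt[three] <- .AA3TO1[rt[three]]
  bad <- is.na(rt) | !rt %in% AA20
  if (any(bad))
    stop("no maximal-ASA reference for residue type(s): ",
         paste(unique(residueTypes[bad]), collapse = ", "))
  unname(as.numeric(asa) / .MAX_ASA[rt])
}

#' Mean model confidence (pLDDT) of a structure model
#'
#' Mean of the B-factor column over all residues, auto-scaled to 0-100
#' (files storing pLDDT on 0-1 are multiplied by 100).
#'
#' @param model A \code{\link{StructureModel-class}}.
#' @return Single number on the 0-100 scale.
#' @export
modelQuality <- function(model) {
  stopifnot(is(model, "StructureModel"))
  b <- model@atoms$b
  if (max(b, na.rm = TRUE) <= 1.0) b <- b * 100
  resb <- tapply(b, model@atoms$resno, mean)
  mean(resb)
}

#' Map epitopes onto a structure model
#'
#' For each epitope interval: mean relative solvent accessibility, mean
#' model confidence (pLDDT, from the B-factor column, auto-scaled to
#' 0-100), and an exposure call at \code{meanRSA >= rsaThreshold}.
#' Sequence-based epitope coordinates can be shifted into the model's
#' residue numbering with \code{offset} (model resno = sequence position
#' + offset), e.g. when the model covers the mature sequence.
#'
#' @param model A \code{\link{StructureModel-class}}.
#' @param epitopes \code{IRanges} (or interval-spec string) of epitopes
#'   in sequence coordinates.
#' @param rsaThreshold Exposure cutoff on mean RSA (default 0.25, the
#'   common buried/exposed convention).
#' @param offset Added to epitope coordinates to reach model numbering
#'   (default 0).
#' @param probeRadius,nPoints Passed to \code{\link{shrakeRupleySasa}}.
#' @return data.frame with one row per epitope: \code{start},
#'   \code{end}, \code{meanRSA}, \code{meanPLDDT}, \code{exposed}.
#' @export
epitopeReport <- function(model, epitopes, rsaThreshold = 0.25,
                          offset = 0L, probeRadius = 1.4,
                          nPoints = 960L) {
  stopifnot(is(model, "StructureModel"))
  if (is.character(epitopes)) epitopes <- parseIntervalSpec(epitopes)
  if (length(epitopes) == 0L) stop("no epitopes supplied")
  at <- model@atoms
  resno <- unique(at$resno)
  asa <- shrakeRupleySasa(model, probeRadius = probeRadius,
                          nPoints = nPoints)
  types <- at$resid[match(as.integer(names(asa)), at$resno)]
  rsa <- relativeAccessibility(asa, types)
  b <- at$b
  if (max(b, na.rm = TRUE) <= 1.0) b <- b * 100
  resb <- tapply(b, at$resno, mean)
  out <- lapply(seq_along(epitopes), function(k) {
    lo <- start(epitopes)[k] + offset; hi <- end(epitopes)[k] + offset
    idx <- match(lo:hi, as.integer(names(asa)))
    if (anyNA(idx))
      stop("epitope [", start(epitopes)[k], ",", end(epitopes)[k],
           "] (model residues ", lo, "..", hi, ") is outside the model; ",
           "model covers ", min(resno), "..", max(resno),
           " — check the numbering offset")
    meanRSA <- mean(rsa[idx])
    data.frame(start = start(epitopes)[k], end = end(epitopes)[k],
               meanRSA = meanRSA, meanPLDDT = mean(resb[idx]),
               exposed = meanRSA >= rsaThreshold)
  })
  do.call(rbind, out)
}
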