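#' Read an atomic structure into a Calpha residue table
#'
#' Parses a PDB or mmCIF file and reduces it to one row per residue of the
#' modelled sequence with the Calpha coordinate.  Residues listed in the
#' sequence (SEQRES) but without deposited coordinates are flagged absent --
#' this is how unresolved flexible regions appear in deposited models and is
#' what the topology builder uses to decide which beads are flexible.
#'
#' @param path path to a PDB or mmCIF file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by file extension).
#' @param seqres if `TRUE` (default) fill in absent residues from SEQRES
#'   records when present.
#' @return An object of class `ca_structure`: a list with element `atoms`, a
#'   data frame with columns `chain`, `resno`, `resname`, `x`, `y`, `z`,
#'   `present`.  Residue numbers are the author numbering, kept verbatim.
#' @details Only the first altloc of each atom is used; insertion codes are
#'   rejected so that (chain, residue number) is always a unique key.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           seqres = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_structure: file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("read_structure: cannot parse '", path,
                             "' as ", format, ": ", conditionMessage(e)))
  at <- pdb$atom
  ca <- at[at$elety == "CA" & at$type == "ATOM", , drop = FALSE]
  if (nrow(ca) == 0) stop("read_structure: structure contains no Calpha atoms")
  if (any(!is.na(ca$insert) & nzchar(ca$insert)))
    stop("read_structure: insertion codes are not supported; ",
         "renumber the structure first")
  # first altloc only
  key <- paste(ca$chain, ca$resno)
  ca <- ca[!duplicated(key), , drop = FALSE]
  atoms <- data.frame(chain = as.character(ca$chain),
                      resno = as.integer(ca$resno),
                      resname = as.character(ca$resid),
                      x = ca$x, y = ca$y, z = ca$z,
                      present = TRUE, stringsAsFactors = FALSE)

  # merge SEQRES-only residues as absent
  if (seqres && format == "pdb") {
    sq <- .read_seqres(path)
    if (nrow(sq)) {
      have <- paste(atoms$chain, atoms$resno)
      add <- sq[!(paste(sq$chain, sq$resno) %in% have), , drop = FALSE]
      if (nrow(add)) {
        add$x <- NA_real_; add$y <- NA_real_; add$z <- NA_real_
        add$present <- FALSE
        atoms <- rbind(atoms, add[, names(atoms)])
      }
    }
  }
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  if (any(duplicated(paste(atoms$chain, atoms$resno))))
    stop("read_structure: duplicate (chain, residue) keys after parsing")
  new_ca_structure(atoms, source = path)
}

# SEQRES does not carry author numbering; assume it starts at the chain's
# first deposited residue number minus the number of preceding unresolved
# residues is unknowable, so SEQRES residues are numbered 1..N per chain.
# This matches the synthetic fixtures (numbered from 1) and real entries
# whose author numbering starts at 1.
.read_seqres <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sq <- grep("^SEQRES", lines, value = TRUE)
  if (!length(sq))
    return(data.frame(chain = character(), resno = integer(),
                      resname = character(), stringsAsFactors = FALSE))
  chain <- substr(sq, 12, 12)
  out <- list()
  for (ch in unique(chain)) {
    res <- unlist(strsplit(trimws(substr(sq[chain == ch], 20, 70)), "\\s+"))
    out[[ch]] <- data.frame(chain = ch, resno = seq_along(res),
                            resname = res, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

new_ca_structure <- function(atoms, source = NA_character_) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "x", "y", "z", "present") %in% names(atoms)))
  if (!"resname" %in% names(atoms)) atoms$resname <- "ALA"
  pres <- atoms$present
  if (any(!is.finite(as.matrix(atoms[pres, c("x", "y", "z")]))))
    stop("ca_structure: present residues must have finite coordinates")
  for (ch in unique(atoms$chain)) {
    r <- atoms$resno[atoms$chain == ch]
    if (any(diff(r) <= 0))
      stop("ca_structure: residue numbers must be strictly increasing in chain ", ch)
  }
  structure(list(atoms = atoms, source = source), class = "ca_structure")
}

#' @export
print.ca_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Calpha structure: %d residues in %d chain(s) [%s], %d resolved, %d absent\n",
              nrow(a), length(unique(a$chain)),
              paste(unique(a$chain), collapse = ","),
              sum(a$present), sum(!a$present)))
  invisible(x)
}

.get_residue <- function(structure, chain, resno, require_present = TRUE) {
  a <- structure$atoms
  i <- which(a$chain == chain & a$resno == resno)
  if (!length(i))
    stop(sprintf("residue %s:%d not in structure", chain, resno))
  if (require_present && !a$present[i])
    stop(sprintf("residue %s:%d has no deposited coordinates (unmappable)", chain, resno))
  i
}

#' Calpha-Calpha distance between two residues
#'
#' @param structure a [read_structure()] result.
#' @param a,b residue selectors, each `c(chain, resno)` (chain as character).
#' @return distance in Angstrom.
#' @export
ca_distance <- function(structure, a, b) {
  ia <- .get_residue(structure, as.character(a[[1]]), as.integer(a[[2]]))
  ib <- .get_residue(structure, as.character(b[[1]]), as.integer(b[[2]]))
  at <- structure$atoms
  sqrt((at$x[ia] - at$x[ib])^2 + (at$y[ia] - at$y[ib])^2 + (at$z[ia] - at$z[ib])^2)
}

#' All-pairs Calpha distance matrix over resolved residues
#'
#' @param structure a [read_structure()] result.
#' @return a symmetric matrix (Angstrom) with dimnames `"chain:resno"`.
#' @export
ca_distance_matrix <- function(structure) {
  a <- structure$atoms[structure$atoms$present, , drop = FALSE]
  m <- as.matrix(stats::dist(a[, c("x", "y", "z")]))
  dimnames(m) <- list(paste0(a$chain, ":", a$resno), paste0(a$chain, ":", a$resno))
  m
}

# Kabsch: rotation R (applied as x %*% R) minimizing |x R - y|, both centred
.kabsch <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Least-squares rigid-body superposition of two structures
#'
#' Superposes the mobile structure onto the reference over a selection of
#' Calpha atoms (Kabsch algorithm) and reports the post-fit RMSD over the
#' same selection.  This is the operation used both to compare deposited
#' models and to align ensemble frames on the rigid core.
#'
#' @param mobile,reference `ca_structure` objects.
#' @param selection a data frame with columns `chain` and `resno`; default is
#'   every residue resolved in both structures.
#' @return An object of class `superposition`: list with `rotation` (3x3,
#'   det +1), `translation` (length-3, in Angstrom; the fitted coordinates
#'   are `coords %*% t(rotation) + translation`), `rmsd` (Angstrom), and
#'   `n` (selection size).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  if (is.null(selection)) {
    am <- mobile$atoms[mobile$atoms$present, c("chain", "resno")]
    ar <- reference$atoms[reference$atoms$present, c("chain", "resno")]
    selection <- merge(am, ar)
  }
  if (!nrow(selection)) stop("superpose: empty selection")
  if (nrow(selection) < 3)
    stop("superpose: fewer than 3 selected residues; superposition is under-determined")
  idx <- function(s, st) {
    miss <- character()
    out <- integer(nrow(s))
    for (i in seq_len(nrow(s))) {
      j <- tryCatch(.get_residue(st, as.character(s$chain[i]), as.integer(s$resno[i])),
                    error = function(e) NA_integer_)
      if (is.na(j)) miss <- c(miss, paste0(s$chain[i], ":", s$resno[i]))
      out[i] <- j
    }
    if (length(miss))
      stop("superpose: selected residues missing: ", paste(miss, collapse = ", "))
    out
  }
  im <- idx(selection, mobile)
  ir <- idx(selection, reference)
  xm <- as.matrix(mobile$atoms[im, c("x", "y", "z")])
  xr <- as.matrix(reference$atoms[ir, c("x", "y", "z")])
  fit <- superpose_coords(xm, xr)
  fit$n <- nrow(selection)
  fit
}

#' Superpose two coordinate matrices
#'
#' Lower-level form of [superpose()] operating directly on matched n x 3
#' coordinate matrices (used per-frame on ensembles).
#'
#' @param mobile,reference n x 3 matrices with matched rows.
#' @return class `superposition` (see [superpose()]).
#' @export
superpose_coords <- function(mobile, reference) {
  stopifnot(nrow(mobile) == nrow(reference), ncol(mobile) == 3)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  xm <- sweep(mobile, 2, cm); xr <- sweep(reference, 2, cr)
  rot <- .kabsch(xm, xr)
  fitted <- xm %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - xr)^2)))
  structure(list(rotation = t(rot),
                 translation = as.numeric(cr - cm %*% rot),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition: rmsd = %.4f A%s\n", x$rmsd,
              if (!is.null(x$n)) sprintf(" over %d residues", x$n) else ""))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sp a `superposition`.
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  sweep(coords %*% t(sp$rotation), 2, sp$translation, "+")
}

#' Write a Calpha-only (multi-model) PDB file
#'
#' Writes one MODEL/ENDMDL block per frame with one CA ATOM record per bead,
#' preserving chain identifiers and residue numbering.  Used to export
#' simulated ensembles and synthetic structures.
#'
#' @param coords an n x 3 matrix or a 3-D array `frames x beads` (as stored
#'   in a `cg_ensemble`, dims `c(3, n, nframes)`), or a list of n x 3
#'   matrices.
#' @param residues data frame with columns `chain`, `resno` and optionally
#'   `resname` (one row per bead).
#' @param path output file.
#' @param seqres optional data frame (`chain`, `resno`, `resname`) describing
#'   the full sequence, written as SEQRES records (so absent residues
#'   round-trip through [read_structure()]).
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(coords, residues, path, seqres = NULL) {
  frames <- if (is.list(coords)) coords
  else if (length(dim(coords)) == 3) lapply(seq_len(dim(coords)[3]),
                                            function(k) t(coords[, , k]))
  else list(coords)
  n <- nrow(residues)
  resname <- if ("resname" %in% names(residues)) residues$resname else rep("ALA", n)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seqres)) {
    for (ch in unique(seqres$chain)) {
      rn <- seqres$resname[seqres$chain == ch]
      nres <- length(rn)
      for (s in seq_len(ceiling(nres / 13))) {
        block <- rn[((s - 1) * 13 + 1):min(s * 13, nres)]
        writeLines(sprintf("SEQRES %3d %s %4d  %-51s", s, ch, nres,
                           paste(sprintf("%-3s", block), collapse = " ")), con)
      }
    }
  }
  multi <- length(frames) > 1
  for (k in seq_along(frames)) {
    xyz <- frames[[k]]
    stopifnot(nrow(xyz) == n)
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n) %% 100000, resname, residues$chain, residues$resno,
      xyz[, 1], xyz[, 2], xyz[, 3]), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
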