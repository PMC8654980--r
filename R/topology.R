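#' Build a coarse-grained bead topology from a structure
#'
#' One bead per residue at the Calpha position.  Residues with deposited
#' coordinates form the quasi-rigid core: consecutive rigid beads are joined
#' by pseudo-bonds at their reference length and rigid pairs within
#' `go_cutoff` (and at least 3 apart along the chain) become native contacts
#' of a 12-10 Go potential whose minimum is the reference structure.
#' Residues without coordinates (or listed in `flexible_override`) are
#' flexible: bonds at `b_0` = 3.8 A and angle terms (on every consecutive
#' triple containing at least one flexible bead) at `a_0` = 112 degrees.
#' Every non-bonded, non-contact bead pair repels as
#' `eps_R (sig_R / r)^12`.
#'
#' @param structure a [read_structure()] result.
#' @param full_sequences named list, one integer vector of residue numbers
#'   per chain, covering the complete sequence to model.  Defaults to the
#'   residues already listed in `structure` (resolved or absent).
#' @param flexible_override optional data frame (`chain`, `resno`) of
#'   residues to force flexible even if resolved.
#' @param params an [ff_params()] object.
#' @param linkable_every designate every k-th residue of each chain as a
#'   cross-linkable site (a stand-in for the lysine positions of a real
#'   sequence); residues named `LYS` are always linkable.
#' @return An object of class `cg_topology`: list with `beads` (data frame:
#'   `chain`, `resno`, `flexible`, reference `x`,`y`,`z` for rigid beads),
#'   `bonds` (`i`,`j`,`b0`), `angles` (`i`,`j`,`k`), `contacts`
#'   (`i`,`j`,`r0`), `linkable` (bead indices), and `params`.
#' @export
build_topology <- function(structure, full_sequences = NULL,
                           flexible_override = NULL, params = ff_params(),
                           linkable_every = 7) {
  at <- structure$atoms
  if (is.null(full_sequences)) {
    full_sequences <- lapply(split(at$resno, at$chain), identity)
  }
  beads <- list()
  for (ch in names(full_sequences)) {
    resno <- as.integer(full_sequences[[ch]])
    if (!length(resno)) stop("build_topology: chain '", ch, "' has zero residues")
    if (any(diff(resno) <= 0)) stop("build_topology: residue numbers must increase in chain ", ch)
    m <- match(paste(ch, resno), paste(at$chain, at$resno))
    pres <- !is.na(m) & at$present[ifelse(is.na(m), 1L, m)]
    beads[[ch]] <- data.frame(
      chain = ch, resno = resno,
      resname = ifelse(is.na(m), "ALA", at$resname[ifelse(is.na(m), 1L, m)]),
      flexible = !pres,
      x = ifelse(pres, at$x[m], NA_real_),
      y = ifelse(pres, at$y[m], NA_real_),
      z = ifelse(pres, at$z[m], NA_real_),
      stringsAsFactors = FALSE)
  }
  beads <- do.call(rbind, beads)
  rownames(beads) <- NULL
  if (!is.null(flexible_override) && nrow(flexible_override)) {
    ov <- paste(flexible_override$chain, flexible_override$resno)
    hit <- paste(beads$chain, beads$resno) %in% ov
    if (!any(hit)) warning("build_topology: flexible_override matched no residues")
    beads$flexible[hit] <- TRUE
    beads$x[hit] <- NA_real_; beads$y[hit] <- NA_real_; beads$z[hit] <- NA_real_
  }
  n <- nrow(beads)

  # bonds: consecutive residues within a chain; rigid-rigid pairs keep their
  # reference separation, anything touching a flexible bead uses b_0
  bi <- integer(); bj <- integer(); bb <- numeric()
  ang <- matrix(integer(), ncol = 3)
  for (ch in unique(beads$chain)) {
    idx <- which(beads$chain == ch)
    if (length(idx) > 1) {
      i <- idx[-length(idx)]; j <- idx[-1]
      rigid2 <- !beads$flexible[i] & !beads$flexible[j]
      d <- sqrt((beads$x[i] - beads$x[j])^2 + (beads$y[i] - beads$y[j])^2 +
                  (beads$z[i] - beads$z[j])^2)
      bi <- c(bi, i); bj <- c(bj, j)
      bb <- c(bb, ifelse(rigid2, d, params$b_0))
    }
    if (length(idx) > 2) {
      a <- cbind(idx[1:(length(idx) - 2)], idx[2:(length(idx) - 1)],
                 idx[3:length(idx)])
      anyflex <- beads$flexible[a[, 1]] | beads$flexible[a[, 2]] |
        beads$flexible[a[, 3]]
      ang <- rbind(ang, a[anyflex, , drop = FALSE])
    }
  }

  # native contacts: rigid pairs within go_cutoff, sequence separation >= 3
  rig <- which(!beads$flexible)
  ci <- integer(); cj <- integer(); c0 <- numeric()
  if (length(rig) > 1) {
    xyz <- as.matrix(beads[rig, c("x", "y", "z")])
    dm <- as.matrix(stats::dist(xyz))
    for (a in seq_len(length(rig) - 1)) {
      for (b in (a + 1):length(rig)) {
        i <- rig[a]; j <- rig[b]
        if (dm[a, b] > params$go_cutoff) next
        if (beads$chain[i] == beads$chain[j] && abs(j - i) < 3) next
        ci <- c(ci, i); cj <- c(cj, j); c0 <- c(c0, dm[a, b])
      }
    }
  }

  linkable <- which(beads$resname == "LYS")
  if (linkable_every > 0) {
    extra <- unlist(lapply(split(seq_len(n), beads$chain), function(idx)
      idx[seq_along(idx) %% linkable_every == 0]), use.names = FALSE)
    linkable <- sort(unique(c(linkable, extra)))
  }

  topo <- structure(list(
    beads = beads,
    bonds = data.frame(i = bi, j = bj, b0 = bb),
    angles = data.frame(i = ang[, 1], j = ang[, 2], k = ang[, 3]),
    contacts = data.frame(i = ci, j = cj, r0 = c0),
    linkable = linkable,
    params = params), class = "cg_topology")
  topo
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("CG topology: %d beads (%d rigid, %d flexible), %d bonds, %d angles, %d native contacts\n",
              nrow(x$beads), sum(!x$beads$flexible), sum(x$beads$flexible),
              nrow(x$bonds), nrow(x$angles), nrow(x$contacts)))
  invisible(x)
}

#' Turn cross-link records into restraint bead pairs
#'
#' Maps residue-pair cross-links onto topology bead indices, dropping pairs
#' with endpoints outside the topology.
#'
#' @param topology a `cg_topology`.
#' @param links data frame with columns `chain_a`, `res_a`, `chain_b`,
#'   `res_b` (as returned by [read_crosslinks()]).
#' @return data frame with columns `i`, `j` (bead indices) and the original
#'   residue identifiers.
#' @export
restraints_from_links <- function(topology, links) {
  key <- paste(topology$beads$chain, topology$beads$resno)
  i <- match(paste(links$chain_a, links$res_a), key)
  j <- match(paste(links$chain_b, links$res_b), key)
  ok <- !is.na(i) & !is.na(j) & i != j
  data.frame(i = i[ok], j = j[ok],
             chain_a = links$chain_a[ok], res_a = links$res_a[ok],
             chain_b = links$chain_b[ok], res_b = links$res_b[ok])
}

# flat list consumed by the C++ kernels; restraints: data.frame(i, j) or NULL
.topo_cpp <- function(topology, restraints = NULL) {
  p <- topology$params
  r <- restraints
  list(n = nrow(topology$beads),
       bond_i = as.integer(topology$bonds$i - 1L),
       bond_j = as.integer(topology$bonds$j - 1L),
       bond_b0 = as.numeric(topology$bonds$b0),
       ang_i = as.integer(topology$angles$i - 1L),
       ang_j = as.integer(topology$angles$j - 1L),
       ang_k = as.integer(topology$angles$k - 1L),
       con_i = as.integer(topology$contacts$i - 1L),
       con_j = as.integer(topology$contacts$j - 1L),
       con_r0 = as.numeric(topology$contacts$r0),
       res_i = if (is.null(r)) integer() else as.integer(r$i - 1L),
       res_j = if (is.null(r)) integer() else as.integer(r$j - 1L),
       k_b = p$k_b, k_a = p$k_a, a_0 = p$a_0, go_eps = p$go_epsilon,
       eps_r = p$eps_r, sig_r = p$sig_r, rep_cutoff = p$rep_cutoff,
       k_xl = p$k_xl, beta = p$beta, l_0 = p$l_0)
}

#' Serialize a topology to JSON
#'
#' @param topology a `cg_topology`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, path) {
  obj <- list(beads = topology$beads, bonds = topology$bonds,
              angles = topology$angles, contacts = topology$contacts,
              linkable = topology$linkable,
              params = unclass(topology$params))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Read a topology from its JSON serialization
#'
#' @param path a file written by [write_topology_json()].
#' @return a `cg_topology`.
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pr <- obj$params
  params <- ff_params(k_b = pr$k_b, b_0 = pr$b_0, k_a = pr$k_a, a_0 = pr$a_0,
                      eps_r = pr$eps_r, sig_r = pr$sig_r, k_xl = pr$k_xl,
                      beta = pr$beta, l_0 = pr$l_0, n_c = pr$n_c,
                      tau_xl = pr$tau_xl, go_epsilon = pr$go_epsilon,
                      go_cutoff = pr$go_cutoff, rep_cutoff = pr$rep_cutoff)
  empty_df <- function(d, cols) {
    if (is.null(d) || !length(d)) as.data.frame(setNames(lapply(cols, function(.) numeric(0)), cols))
    else as.data.frame(d)
  }
  structure(list(beads = as.data.frame(obj$beads),
                 bonds = empty_df(obj$bonds, c("i", "j", "b0")),
                 angles = empty_df(obj$angles, c("i", "j", "k")),
                 contacts = empty_df(obj$contacts, c("i", "j", "r0")),
                 linkable = as.integer(obj$linkable),
                 params = params), class = "cg_topology")
}
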