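# Backbone-geometry descriptor block (P2).
#
# A protein is summarized by the mean and sample standard deviation of 15
# internal-coordinate classes measured over all residues where they are
# defined: five bond lengths, six bond angles and four dihedrals.  The
# fixed class list and feature order are frozen here so that models built
# from the block are reproducible.

.geom_classes <- c(
  "len.N_CA", "len.CA_C", "len.C_O", "len.C_Nnext", "len.CA_CB",
  "ang.N_CA_C", "ang.CA_C_Nnext", "ang.CA_C_O", "ang.C_N_CA",
  "ang.N_CA_CB", "ang.C_CA_CB",
  "dih.phi", "dih.psi", "dih.omega", "dih.chi1"
)

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# first side-chain gamma atom used for chi1, in order of preference
.gamma_atoms <- c("CG", "CG1", "OG", "OG1", "SG")

#' Geometry descriptor feature names
#'
#' The fixed, ordered list of the 30 geometry features: the mean and sample
#' standard deviation of each of the 15 internal-coordinate classes (bond
#' lengths in Angstrom, angles and dihedrals in degrees).
#'
#' @return Character vector of length 30.
#' @export
geometry_feature_names <- function() {
  as.vector(t(outer(.geom_classes, c("mean", "sd"), paste, sep = ".")))
}

vnorm <- function(v) sqrt(sum(v * v))

bond_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# IUPAC sign convention, degrees in (-180, 180]
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Parse a PDB (path or bio3d pdb object) into an ordered list of residues,
# each a list of atom coordinates keyed by atom name.  First model, first
# alternate conformer, standard residues only.
.residue_list <- function(structure, chain = NULL) {
  pdb <- if (inherits(structure, "pdb")) structure
         else bio3d::read.pdb(structure, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% .standard_aa, , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  if ("alt" %in% names(at))
    at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (nrow(at) == 0L) stop("no standard protein residues found")
  key <- paste(at$chain, at$resno)
  ord <- order(at$chain, at$resno)
  at <- at[ord, , drop = FALSE]
  key <- key[ord]
  res <- split(at, factor(key, levels = unique(key)))
  lapply(res, function(r) {
    coords <- lapply(seq_len(nrow(r)), function(i)
      c(r$x[i], r$y[i], r$z[i]))
    names(coords) <- r$elety
    coords <- coords[!duplicated(names(coords))]
    list(atoms = coords, resno = r$resno[1], chain = r$chain[1])
  })
}

#' Backbone-geometry descriptors for a protein structure (P2)
#'
#' Measures, over all residues where the atoms are present, the 15
#' internal-coordinate classes: bond lengths N-CA, CA-C, C-O, C-N(next),
#' CA-CB; bond angles N-CA-C, CA-C-N(next), CA-C-O, C-N-CA, N-CA-CB,
#' C-CA-CB; and the dihedrals phi, psi, omega (CA-C-N'-CA') and chi1
#' (N-CA-CB-gamma).  Each class contributes its mean and sample standard
#' deviation, giving 30 features in the order of
#' [geometry_feature_names()].  Dihedral classes use the circular mean
#' and circular (angular) standard deviation, since trans-peptide omega
#' values straddle the +/-180 degree boundary.  Terminal residues lacking phi or psi are
#' skipped, not imputed; a class with no instances (e.g. chi1 in a
#' poly-alanine chain) yields `NA` features and is listed in the
#' `"missing_classes"` attribute.
#'
#' @param structure Path to a PDB file, or a `bio3d` `pdb` object.  Only
#'   the first model and first alternate conformer are used; HETATM and
#'   non-standard residues are excluded.
#' @param chain Optional chain id(s) to restrict to.
#' @return Named numeric vector of length 30.
#' @export
geometry_descriptors <- function(structure, chain = NULL) {
  res <- .residue_list(structure, chain)
  n <- length(res)
  consec <- function(i, j) {
    res[[j]]$chain == res[[i]]$chain && res[[j]]$resno == res[[i]]$resno + 1
  }
  # longest stretch of consecutive residues
  longest <- if (n <= 1) n else max(tapply(
    rep(1L, n),
    cumsum(!c(TRUE, vapply(seq_len(n - 1), function(i) consec(i, i + 1),
                           logical(1)))), sum))
  if (longest < 3)
    stop("insufficient structure: need at least 3 consecutive residues")

  obs <- setNames(vector("list", length(.geom_classes)), .geom_classes)
  add <- function(cls, x) obs[[cls]] <<- c(obs[[cls]], x)
  g <- function(r, nm) r$atoms[[nm]]

  for (i in seq_len(n)) {
    r <- res[[i]]
    N <- g(r, "N"); CA <- g(r, "CA"); C <- g(r, "C"); O <- g(r, "O")
    CB <- g(r, "CB")
    if (!is.null(N) && !is.null(CA)) add("len.N_CA", vnorm(CA - N))
    if (!is.null(CA) && !is.null(C)) add("len.CA_C", vnorm(C - CA))
    if (!is.null(C) && !is.null(O)) add("len.C_O", vnorm(O - C))
    if (!is.null(CA) && !is.null(CB)) add("len.CA_CB", vnorm(CB - CA))
    if (!is.null(N) && !is.null(CA) && !is.null(C))
      add("ang.N_CA_C", bond_angle(N, CA, C))
    if (!is.null(CA) && !is.null(C) && !is.null(O))
      add("ang.CA_C_O", bond_angle(CA, C, O))
    if (!is.null(N) && !is.null(CA) && !is.null(CB))
      add("ang.N_CA_CB", bond_angle(N, CA, CB))
    if (!is.null(C) && !is.null(CA) && !is.null(CB))
      add("ang.C_CA_CB", bond_angle(C, CA, CB))
    gam <- NULL
    for (ga in .gamma_atoms) if (!is.null(g(r, ga))) { gam <- g(r, ga); break }
    if (!is.null(N) && !is.null(CA) && !is.null(CB) && !is.null(gam))
      add("dih.chi1", dihedral_angle(N, CA, CB, gam))

    if (i < n && consec(i, i + 1)) {
      r2 <- res[[i + 1]]
      N2 <- g(r2, "N"); CA2 <- g(r2, "CA"); C2 <- g(r2, "C")
      if (!is.null(C) && !is.null(N2)) add("len.C_Nnext", vnorm(N2 - C))
      if (!is.null(CA) && !is.null(C) && !is.null(N2))
        add("ang.CA_C_Nnext", bond_angle(CA, C, N2))
      if (!is.null(C) && !is.null(N2) && !is.null(CA2))
        add("ang.C_N_CA", bond_angle(C, N2, CA2))
      if (!is.null(N) && !is.null(CA) && !is.null(C) && !is.null(N2))
        add("dih.psi", dihedral_angle(N, CA, C, N2))
      if (!is.null(CA) && !is.null(C) && !is.null(N2) && !is.null(CA2))
        add("dih.omega", dihedral_angle(CA, C, N2, CA2))
      if (!is.null(C) && !is.null(N2) && !is.null(CA2) && !is.null(C2))
        add("dih.phi", dihedral_angle(C, N2, CA2, C2))
    }
  }

  out <- setNames(rep(NA_real_, 2 * length(.geom_classes)),
                  geometry_feature_names())
  missing_classes <- character(0)
  for (cls in .geom_classes) {
    x <- obs[[cls]]
    if (is.null(x) || length(x) == 0L) {
      missing_classes <- c(missing_classes, cls)
      next
    }
    if (startsWith(cls, "dih.")) {
      # circular statistics: dihedrals live on (-180, 180] and the
      # trans-peptide omega straddles the boundary
      rad <- x * pi / 180
      s <- mean(sin(rad)); co <- mean(cos(rad))
      out[paste0(cls, ".mean")] <- atan2(s, co) * 180 / pi
      R <- min(1, sqrt(s^2 + co^2))
      out[paste0(cls, ".sd")] <- if (length(x) >= 2)
        sqrt(max(0, -2 * log(max(R, 1e-12)))) * 180 / pi else NA_real_
    } else {
      out[paste0(cls, ".mean")] <- mean(x)
      out[paste0(cls, ".sd")] <- if (length(x) >= 2) sd(x) else NA_real_
    }
  }
  attr(out, "missing_classes") <- missing_classes
  out
}

#' Geometry descriptor block for a set of structures
#'
#' @param structures Named character vector of PDB paths (names become
#'   target ids) or named list of `pdb` objects.
#' @param chain Optional chain id passed to [geometry_descriptors()].
#' @return Numeric matrix (targets x 30).
#' @export
build_p2 <- function(structures, chain = NULL) {
  if (is.null(names(structures))) stop("structures must be named")
  t(vapply(structures, function(s) geometry_descriptors(s, chain),
           numeric(30)))
}
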