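# Synthetic PCM data with known ground truth.
#
# Descriptor-level simulation: protein and ligand descriptors are drawn
# standard normal (with one protein dimension encoding the HDAC class),
# and the pair response is additive protein and ligand main effects plus a
# bilinear protein x ligand interaction and Gaussian noise:
#
#   pIC50(t, c) = baseline + beta_p' p_t + beta_l' l_c + p_t' W l_c + eps
#
# The last ligand dimension is reserved as a "class-affinity channel": it
# carries no main effect but is coupled to the class-encoding protein
# dimension through W, so class-selective activity is a genuine
# protein-ligand interaction that a cross-term model can learn.  Planted
# selective compounds are ordinary compounds with a strong signature on
# that channel.  Per-target pair counts are unbalanced, mirroring the
# 215/197/531/46/286 shape of the real HDAC panel scaled to the compound
# library size.

#' Configuration for the synthetic PCM generator
#'
#' Defaults define the package's reference simulation scenario: 5 targets
#' with the HDAC panel class structure, 200 compounds, 5 protein and 32
#' ligand descriptor dimensions, per-target pair counts 43/39/106/9/57
#' (the real panel's proportions at one fifth scale), a mild bilinear
#' interaction and noise sd 0.1 pIC50 units.
#'
#' @param n_targets,n_compounds Panel and library sizes.
#' @param d_protein,d_ligand Descriptor dimensionalities.
#' @param pairs_per_target Integer vector (length `n_targets`) of pair
#'   counts sampled without replacement from the compound library.
#' @param target_classes HDAC-style class per target (`"I"`, `"IIa"`,
#'   `"IIb"`, ...).
#' @param beta_protein,beta_ligand Main-effect coefficient vectors;
#'   `NULL` uses the frozen defaults (a small decaying protein pattern;
#'   alternating +/-0.32 for ligands with the last, class-coupled
#'   dimension at 0).
#' @param interaction `"mild"` (default), `"none"` or `"strong"`, or a
#'   custom `d_protein x d_ligand` matrix W.
#' @param noise_sd Gaussian noise sd in pIC50 units (default 0.1).
#' @param baseline Mean pIC50 level (default 6).
#' @param class_code_sd Jitter sd of the class-encoding protein dimension
#'   (default 0.2).
#' @param planted_selectives List of `list(compound = <index>, class =
#'   "I"|"II")` entries marking compounds whose activity is dominated by
#'   the class-affinity channel.
#' @param planted_signature Magnitude on the class channel for planted
#'   compounds (default 5; positive for class I, negative for class II).
#' @param planted_shrink Factor shrinking a planted compound's remaining
#'   descriptor dimensions (default 0.2), keeping its overall potency
#'   near average.
#' @param seed Integer seed; the same configuration and seed always yield
#'   the identical data set.
#' @return Object of class `"synth_config"`.
#' @export
synth_config <- function(n_targets = 5, n_compounds = 200,
                         d_protein = 5, d_ligand = 32,
                         pairs_per_target = c(43, 39, 106, 9, 57),
                         target_classes = c("I", "IIa", "IIb", "IIa", "I"),
                         beta_protein = NULL, beta_ligand = NULL,
                         interaction = c("mild", "none", "strong"),
                         noise_sd = 0.1, baseline = 6,
                         class_code_sd = 0.2,
                         planted_selectives = list(),
                         planted_signature = 5, planted_shrink = 0.2,
                         seed = 1) {
  if (length(pairs_per_target) != n_targets)
    stop("pairs_per_target must have length n_targets")
  if (length(target_classes) != n_targets)
    stop("target_classes must have length n_targets")
  if (any(pairs_per_target > n_compounds))
    stop("pairs_per_target cannot exceed n_compounds")
  if (any(pairs_per_target < 1))
    stop("pairs_per_target must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(planted_selectives) &&
      any(pairs_per_target < length(planted_selectives)))
    stop("each target needs at least as many pairs as planted compounds")
  for (p in planted_selectives) {
    if (!is.list(p) || is.null(p$compound) || is.null(p$class) ||
        !p$class %in% c("I", "II") || p$compound > n_compounds)
      stop("planted_selectives entries must be list(compound =, ",
           "class = 'I'|'II') with a valid compound index")
  }
  if (is.null(beta_protein))
    beta_protein <- rep_len(c(0.3, -0.25, 0.2, -0.15, 0.1), d_protein)
  if (is.null(beta_ligand)) {
    beta_ligand <- 0.32 * (-1)^(0:(d_ligand - 1))
    beta_ligand[d_ligand] <- 0
  }
  if (length(beta_protein) != d_protein ||
      length(beta_ligand) != d_ligand)
    stop("coefficient vectors must match the descriptor dimensions")
  if (is.matrix(interaction)) {
    W <- interaction
    if (!all(dim(W) == c(d_protein, d_ligand)))
      stop("interaction matrix must be d_protein x d_ligand")
  } else {
    interaction <- match.arg(interaction)
    W <- matrix(0, d_protein, d_ligand)
    put <- function(i, j, v) if (i <= d_protein && j <= d_ligand)
      W[i, j] <<- v
    if (interaction == "mild") {
      put(1, d_ligand, 0.6)
      put(2, 2, 0.2)
    } else if (interaction == "strong") {
      put(1, d_ligand, 1); put(2, 1, 1); put(3, 2, -1)
      put(1, 2, 1); put(2, 5, -1)
      W <- W * sqrt(3.5 / sum(W^2))
    }
  }
  structure(list(
    n_targets = n_targets, n_compounds = n_compounds,
    d_protein = d_protein, d_ligand = d_ligand,
    pairs_per_target = as.integer(pairs_per_target),
    target_classes = target_classes,
    beta_protein = beta_protein, beta_ligand = beta_ligand, W = W,
    noise_sd = noise_sd, baseline = baseline,
    class_code_sd = class_code_sd,
    planted_selectives = planted_selectives,
    planted_signature = planted_signature,
    planted_shrink = planted_shrink,
    seed = as.integer(seed)), class = "synth_config")
}

#' Generate a synthetic PCM data set
#'
#' @param config A [synth_config()].
#' @return List with `protein_block` (targets x d_p, the first column
#'   encoding the class), `ligand_block` (compounds x d_l), `records`
#'   (one row per sampled pair, with `ic50_nm` and `pic50` filled in and
#'   `split = "unassigned"`), `classes` (named target -> class map) and
#'   `truth` (the generating coefficients and planted compounds).
#' @export
#' @examples
#' syn <- generate_dataset(synth_config(seed = 42))
#' table(syn$records$target_id)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  nt <- config$n_targets; nc <- config$n_compounds
  dp <- config$d_protein; dl <- config$d_ligand
  target_ids <- paste0("T", seq_len(nt))
  compound_ids <- sprintf("C%03d", seq_len(nc))

  code <- ifelse(config$target_classes == "I", 1,
                 ifelse(grepl("^II", config$target_classes), -1, 0))
  P <- matrix(rnorm(nt * dp), nt, dp,
              dimnames = list(target_ids, paste0("p", seq_len(dp))))
  P[, 1] <- code + rnorm(nt, sd = config$class_code_sd)
  L <- matrix(rnorm(nc * dl), nc, dl,
              dimnames = list(compound_ids, paste0("l", seq_len(dl))))
  planted_idx <- vapply(config$planted_selectives, `[[`, numeric(1),
                        "compound")
  planted_class <- vapply(config$planted_selectives, `[[`, character(1),
                          "class")
  for (k in seq_along(planted_idx)) {
    i <- planted_idx[k]
    L[i, ] <- config$planted_shrink * rnorm(dl)
    L[i, dl] <- config$planted_signature *
      if (planted_class[k] == "I") 1 else -1
  }

  pairs <- do.call(rbind, lapply(seq_len(nt), function(t) {
    pick <- sample(nc, config$pairs_per_target[t])
    if (length(planted_idx))
      pick <- union(planted_idx, pick)[seq_len(config$pairs_per_target[t])]
    data.frame(target = t, compound = pick)
  }))
  Pp <- P[pairs$target, , drop = FALSE]
  Lp <- L[pairs$compound, , drop = FALSE]
  pic50 <- config$baseline +
    as.numeric(Pp %*% config$beta_protein) +
    as.numeric(Lp %*% config$beta_ligand) +
    rowSums((Pp %*% config$W) * Lp) +
    rnorm(nrow(pairs), sd = config$noise_sd)

  records <- data.frame(
    compound_id = compound_ids[pairs$compound],
    smiles = NA_character_,
    target_id = target_ids[pairs$target],
    ic50_nm = 10^(9 - pic50),
    pic50 = pic50,
    y_scaled = NA_real_,
    split = "unassigned",
    stringsAsFactors = FALSE)

  list(protein_block = P, ligand_block = L, records = records,
       classes = setNames(config$target_classes, target_ids),
       config = config,
       truth = list(beta_protein = config$beta_protein,
                    beta_ligand = config$beta_ligand, W = config$W,
                    planted = if (length(planted_idx))
                      data.frame(compound_id = compound_ids[planted_idx],
                                 class = planted_class,
                                 stringsAsFactors = FALSE)
                    else NULL))
}

# ---- synthetic protein structures -------------------------------------

# ideal backbone internal coordinates (Angstrom / degrees) for an
# alpha-helical poly-alanine chain
.helix_ideal <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  a_n_ca_cb = 110.4,
  phi = -57, psi = -47, omega = 180, o_torsion = 133, cb_torsion = -122.6
)

# place atom D given positions A, B, C, the bond |C-D|, angle B-C-D and
# dihedral A-B-C-D (natural extension reference frame)
.nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + cbind(bc, m, n) %*% d2
}

#' Generate an ideal poly-alanine helix as a PDB file
#'
#' Builds backbone coordinates (N, CA, C, O, CB per residue) from ideal
#' internal coordinates with alpha-helical torsions (phi -57, psi -47,
#' omega 180), optionally jittered by isotropic Gaussian coordinate
#' noise, and writes a standard single-model PDB file.  The generator's
#' internal-coordinate constants double as the ground truth for
#' [geometry_descriptors()] round-trip checks.
#'
#' @param n_residues Chain length, >= 3.
#' @param noise_A Coordinate jitter sd in Angstrom (default 0).
#' @param seed Seed for the jitter.
#' @param file Output path (default: a tempfile).
#' @return The PDB file path (invisibly carries the coordinate matrix as
#'   attribute `"xyz"`).
#' @export
generate_helix_structure <- function(n_residues, noise_A = 0, seed = 1,
                                     file = tempfile(fileext = ".pdb")) {
  if (n_residues < 3) stop("need at least 3 residues")
  ic <- .helix_ideal
  coords <- list()  # per residue: N, CA, C, O, CB
  # first residue: N at origin, CA along x, C in the xy-plane
  N <- c(0, 0, 0)
  CA <- c(ic$b_n_ca, 0, 0)
  ang <- ic$a_n_ca_c * pi / 180
  C <- CA + ic$b_ca_c * c(-cos(ang), sin(ang), 0)
  coords[[1]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n_residues - 1) + 1) {
    prev <- coords[[i - 1]]
    N <- .nerf_place(prev$N, prev$CA, prev$C, ic$b_c_n, ic$a_ca_c_n,
                     ic$psi)
    CA <- .nerf_place(prev$CA, prev$C, N, ic$b_n_ca, ic$a_c_n_ca,
                      ic$omega)
    C <- .nerf_place(prev$C, N, CA, ic$b_ca_c, ic$a_n_ca_c, ic$phi)
    coords[[i]] <- list(N = c(N), CA = c(CA), C = c(C))
  }
  for (i in seq_len(n_residues)) {
    r <- coords[[i]]
    coords[[i]]$O <- c(.nerf_place(r$N, r$CA, r$C, ic$b_c_o, ic$a_ca_c_o,
                                   ic$o_torsion))
    coords[[i]]$CB <- c(.nerf_place(r$C, r$N, r$CA, ic$b_ca_cb,
                                    ic$a_n_ca_cb, ic$cb_torsion))
  }
  atom_order <- c("N", "CA", "C", "O", "CB")
  xyz <- do.call(rbind, lapply(coords, function(r)
    do.call(rbind, r[atom_order])))
  if (noise_A > 0) {
    set.seed(as.integer(seed))
    xyz <- xyz + matrix(rnorm(length(xyz), sd = noise_A), nrow(xyz))
  }
  n_at <- nrow(xyz)
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(xyz)),
                   resno = rep(seq_len(n_residues), each = 5),
                   resid = rep("ALA", n_at),
                   elety = rep(atom_order, n_residues),
                   chain = rep("A", n_at))
  invisible(structure(file, xyz = xyz))
}
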