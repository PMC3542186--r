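# Ligand descriptor blocks.
#
# Two fixed feature sets describe each inhibitor:
#   GD  - 32 physical-property descriptors: approximate per-atom van der
#         Waals surface areas binned by the atom's additive logP
#         contribution (10 bins), molar-refractivity contribution (8 bins)
#         and Gasteiger partial charge (10 bins), plus whole-molecule logP,
#         molar refractivity, total surface area and formal-charge sum.
#   DLI - 28 topological drug-like indices: counts and graph statistics
#         covering rings, the ring/linker framework, flexibility, polarity
#         and the degree distribution.
#
# The feature lists, bin edges and the additive atomic contribution scheme
# are frozen constants of this package; externally computed tables with the
# same dimensions can be used instead via read_descriptor_table().

# ---- frozen constants -------------------------------------------------

.gd_logp_edges <- c(-0.6, -0.4, -0.2, 0, 0.1, 0.2, 0.3, 0.4, 0.6)   # 10 bins
.gd_mr_edges   <- c(0.5, 1.5, 2.5, 3.5, 4.5, 6, 9)                   # 8 bins
.gd_q_edges    <- c(-0.3, -0.2, -0.1, -0.05, 0, 0.05, 0.1, 0.2, 0.3) # 10 bins

# additive logP / molar-refractivity contributions per heavy-atom class;
# implicit hydrogens add .h_logp / .h_mr each
.atom_contrib <- data.frame(
  class = c("C.ar", "C.sp3", "C.sp3.het", "C.unsat", "N.ar", "N",
            "O.2", "O.3", "S", "P", "F", "Cl", "Br", "I", "other"),
  logp = c(0.29, 0.14, -0.06, 0.08, -0.49, -0.60,
           -0.12, -0.47, 0.65, 0.86, 0.44, 0.61, 0.86, 1.16, 0.00),
  mr   = c(3.51, 2.60, 2.43, 3.11, 2.50, 2.10,
           0.77, 1.55, 7.37, 6.92, 0.89, 5.85, 8.74, 13.95, 3.00),
  stringsAsFactors = FALSE
)
.h_logp <- 0.12
.h_mr   <- 1.06

.bondi <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
            S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)
.rcov  <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07,
            S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39)
.valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
              I = 1, B = 3, Si = 4)
.halogens <- c("F", "Cl", "Br", "I")

#' GD feature names
#' @return Character vector of length 32, in frozen order.
#' @export
gd_feature_names <- function() {
  c(paste0("slogp_vsa", 1:10), paste0("smr_vsa", 1:8),
    paste0("peoe_vsa", 1:10),
    "logp", "mr", "vsa_total", "formal_charge")
}

#' DLI feature names
#' @return Character vector of length 28, in frozen order.
#' @export
dli_feature_names <- function() {
  c("n_atoms", "n_bonds", "n_rings", "n_aromatic_rings", "n_ring_systems",
    "largest_ring", "n_ring_atoms", "framework_atoms", "framework_bonds",
    "linker_bonds", "sidechain_atoms", "rotatable_bonds", "rigid_bonds",
    "hbd", "hba", "n_halogen", "n_hetero", "sp3_carbon_pct",
    "n_chiral", "graph_diameter", "graph_radius", "n_terminal",
    "n_branch", "deg1", "deg2", "deg3", "deg4", "max_degree")
}

# ---- molecule parsing -------------------------------------------------

# whole-molecule properties straight from OpenBabel (avoids an SDF round
# trip, which chokes on bond-less molecules)
ob_props <- function(smiles) {
  out <- try(ChemmineOB::forEachMol("SMILES", smiles,
                                    ChemmineOB::prop_OB), silent = TRUE)
  if (inherits(out, "try-error") || length(out) == 0L)
    stop("property computation failed for ", smiles)
  out[[1]]
}

# Parse SMILES via OpenBabel into a heavy-atom graph description.  Salts /
# mixtures: the largest covalent fragment is retained.  Explicit hydrogens
# are not represented as graph nodes.
parse_molecule <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles) ||
      is.na(smiles))
    stop("smiles must be a non-empty character scalar")
  sdf <- try(suppressWarnings(ChemmineR::smiles2sdf(smiles)), silent = TRUE)
  if (inherits(sdf, "try-error"))
    stop("unparsable SMILES: ", smiles)
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (is.null(ab) || nrow(ab) == 0L) stop("unparsable SMILES: ", smiles)
  elem <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  bb <- try(ChemmineR::bondblock(mol), silent = TRUE)
  bonds <- if (inherits(bb, "try-error") || is.null(bb) ||
               nrow(bb) == 0L || ncol(bb) < 3)
    matrix(numeric(0), 0, 3) else unname(as.matrix(bb[, 1:3, drop = FALSE]))

  # aromatic atoms from ring perception
  arom_atoms <- rep(FALSE, n)
  if (nrow(bonds) > 0) {
    rg <- try(suppressWarnings(ChemmineR::rings(mol, type = "all",
                                                arom = TRUE)), silent = TRUE)
    if (!inherits(rg, "try-error") && length(rg$RINGS) > 0) {
      aridx <- unlist(rg$RINGS[unlist(rg$AROMATIC)])
      if (length(aridx))
        arom_atoms[as.integer(sub("^.*_", "", aridx))] <- TRUE
    }
  }

  # Gasteiger partial charges from an OpenBabel mol2 conversion (same atom
  # order as the SDF conversion of the same SMILES)
  charges <- rep(0, n)
  m2 <- try(suppressWarnings(
    ChemmineOB::convertFormat("SMILES", "MOL2", source = smiles)),
    silent = TRUE)
  if (!inherits(m2, "try-error")) {
    lines <- strsplit(m2, "\n", fixed = TRUE)[[1]]
    a0 <- which(lines == "@<TRIPOS>ATOM")
    if (length(a0) == 1L) {
      rest <- lines[(a0 + 1):length(lines)]
      stopat <- grep("^@<TRIPOS>", rest)
      if (length(stopat)) rest <- rest[seq_len(stopat[1] - 1)]
      q <- suppressWarnings(as.numeric(vapply(strsplit(trimws(rest), "\\s+"),
                                              function(x) x[length(x)],
                                              character(1))))
      if (length(q) == n && !anyNA(q)) charges <- q
    }
  }

  # largest covalent fragment
  if (nrow(bonds) > 0 || n > 1) {
    g <- igraph::graph_from_edgelist(
      cbind(bonds[, 1], bonds[, 2]), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
  } else keep <- 1L
  if (length(keep) < n) {
    old2new <- match(seq_len(n), keep)
    bonds <- bonds[bonds[, 1] %in% keep & bonds[, 2] %in% keep, ,
                   drop = FALSE]
    bonds[, 1] <- old2new[bonds[, 1]]
    bonds[, 2] <- old2new[bonds[, 2]]
    elem <- elem[keep]; arom_atoms <- arom_atoms[keep]
    charges <- charges[keep]
    n <- length(keep)
  }

  deg <- rep(0L, n)
  bosum <- rep(0, n)
  maxorder <- rep(1, n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]; o <- bonds[k, 3]
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
      bosum[i] <- bosum[i] + o; bosum[j] <- bosum[j] + o
      maxorder[i] <- max(maxorder[i], o); maxorder[j] <- max(maxorder[j], o)
    }
  }
  val <- .valence[elem]
  val[is.na(val)] <- bosum[is.na(val)]
  nH <- pmax(0, round(val - bosum))
  # formal charge sum parsed from bracket atoms of the input SMILES
  br <- regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles))[[1]]
  fc <- 0L
  for (tok in br) {
    sgn <- regmatches(tok, gregexpr("\\+[0-9]*|-[0-9]*", tok))[[1]]
    for (sg in sgn) {
      mult <- suppressWarnings(as.integer(substring(sg, 2)))
      if (is.na(mult)) mult <- nchar(sg)  # "++" style counts characters
      fc <- fc + if (substring(sg, 1, 1) == "+") mult else -mult
    }
  }

  list(smiles = smiles, n = n, elem = elem, bonds = bonds, degree = deg,
       aromatic = arom_atoms, charges = charges, n_h = nH,
       max_order = maxorder, formal_charge = fc, sdf = sdf)
}

.atom_class <- function(mol) {
  vapply(seq_len(mol$n), function(i) {
    e <- mol$elem[i]
    if (e == "C") {
      if (mol$aromatic[i]) return("C.ar")
      if (mol$max_order[i] >= 2) return("C.unsat")
      nb <- .neighbors(mol, i)
      if (any(mol$elem[nb] %in% c("N", "O", "S", "P", .halogens)))
        return("C.sp3.het")
      return("C.sp3")
    }
    if (e == "N") return(if (mol$aromatic[i]) "N.ar" else "N")
    if (e == "O") return(if (mol$max_order[i] >= 2) "O.2" else "O.3")
    if (e %in% c("S", "P", .halogens)) return(e)
    "other"
  }, character(1))
}

.neighbors <- function(mol, i) {
  if (nrow(mol$bonds) == 0) return(integer(0))
  c(mol$bonds[mol$bonds[, 1] == i, 2], mol$bonds[mol$bonds[, 2] == i, 1])
}

# Approximate accessible van der Waals surface area per heavy atom: sphere
# area at the Bondi radius minus spherical caps removed by each bonded
# neighbor (including implicit hydrogens), with bond lengths taken as the
# sum of covalent radii.  A topological approximation in the spirit of
# Labute's VSA scheme; no 3D conformer is generated.
.atom_vsa <- function(mol) {
  r <- .bondi[mol$elem]; r[is.na(r)] <- 1.70
  rc <- .rcov[mol$elem]; rc[is.na(rc)] <- 0.77
  area <- 4 * pi * r^2
  cap <- function(ri, rj, d) {
    x <- (d^2 + ri^2 - rj^2) / (2 * d)
    h <- ri - x
    h <- max(0, min(2 * ri, h))
    2 * pi * ri * h
  }
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[k, 1]; j <- mol$bonds[k, 2]
      d <- rc[i] + rc[j]
      area[i] <- area[i] - cap(r[i], r[j], d)
      area[j] <- area[j] - cap(r[j], r[i], d)
    }
  }
  dH <- rc + .rcov[["H"]]
  area <- area - mol$n_h * vapply(seq_len(mol$n), function(i)
    cap(r[i], .bondi[["H"]], dH[i]), numeric(1))
  pmax(area, 0)
}

# ---- GD ---------------------------------------------------------------

#' General Descriptors (GD): 32 physical-property features
#'
#' Surface-area descriptors in the VSA style: every heavy atom (with its
#' implicit hydrogens) carries an approximate van der Waals surface area,
#' an additive logP contribution, an additive molar-refractivity
#' contribution and a Gasteiger partial charge; atom areas are summed into
#' fixed property bins (10 logP bins, 8 molar-refractivity bins, 10 charge
#' bins).  Four whole-molecule features complete the vector: logP, molar
#' refractivity, total surface area and the formal-charge sum.  For salts
#' and mixtures the largest covalent fragment is used.
#'
#' @param smiles A SMILES string.
#' @return Named numeric vector of length 32 (order of
#'   [gd_feature_names()]).
#' @export
#' @examples
#' compute_gd("CCO")["logp"] < compute_gd("c1ccccc1")["logp"]
compute_gd <- function(smiles) {
  mol <- parse_molecule(smiles)
  cls <- .atom_class(mol)
  tab <- .atom_contrib[match(cls, .atom_contrib$class), ]
  alogp <- tab$logp + mol$n_h * .h_logp
  amr <- tab$mr + mol$n_h * .h_mr
  vsa <- .atom_vsa(mol)

  binsum <- function(x, edges, nbins) {
    b <- findInterval(x, edges) + 1L
    vapply(seq_len(nbins), function(k) sum(vsa[b == k]), numeric(1))
  }
  props <- ob_props(mol$smiles)
  out <- c(binsum(alogp, .gd_logp_edges, 10),
           binsum(amr, .gd_mr_edges, 8),
           binsum(mol$charges, .gd_q_edges, 10),
           props$logP[1], props$MR[1], sum(vsa), mol$formal_charge)
  if (any(!is.finite(out)))
    stop("descriptor computation failed for ", smiles)
  setNames(out, gd_feature_names())
}

# ---- DLI --------------------------------------------------------------

# smallest ring through each cyclic edge; used for SSSR-style ring stats
.ring_info <- function(mol) {
  nb <- nrow(mol$bonds)
  empty <- list(n_rings = 0L, ring_atoms = integer(0), largest = 0L,
                n_systems = 0L, rings = list(), bridge_edges = seq_len(nb))
  if (nb == 0) return(empty)
  g <- igraph::graph_from_edgelist(cbind(mol$bonds[, 1], mol$bonds[, 2]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, mol$n - igraph::vcount(g)))
  br <- as.integer(igraph::bridges(g))
  cyc <- setdiff(seq_len(nb), br)
  n_rings <- nb - mol$n + igraph::components(g)$no  # cycle rank
  rings <- list()
  for (k in cyc) {
    g2 <- igraph::delete_edges(g, k)
    sp <- igraph::shortest_paths(g2, from = mol$bonds[k, 1],
                                 to = mol$bonds[k, 2])$vpath[[1]]
    if (length(sp) > 1) rings[[length(rings) + 1L]] <-
        sort(as.integer(sp))
  }
  rings <- unique(rings)
  ring_atoms <- sort(unique(c(mol$bonds[cyc, 1], mol$bonds[cyc, 2])))
  # ring systems: connected components of the cyclic-edge subgraph
  n_systems <- if (length(cyc)) {
    gs <- igraph::graph_from_edgelist(
      cbind(mol$bonds[cyc, 1], mol$bonds[cyc, 2]), directed = FALSE)
    gs <- igraph::delete_vertices(gs, which(igraph::degree(gs) == 0))
    igraph::components(gs)$no
  } else 0L
  list(n_rings = as.integer(n_rings), ring_atoms = ring_atoms,
       largest = if (length(rings)) max(lengths(rings)) else 0L,
       n_systems = as.integer(n_systems), rings = rings,
       bridge_edges = br)
}

#' Drug-Like Index (DLI): 28 topological features
#'
#' Simple graph-topological counts and indices on the heavy-atom graph,
#' measuring the hierarchy of a drug structure in terms of rings, linkers
#' and molecular framework: atom/bond counts, ring statistics (smallest-set
#' rings, aromatic rings, ring systems, largest ring, ring atoms),
#' Murcko-style framework atom/bond counts with linker bonds and side-chain
#' atoms, flexibility (rotatable/rigid bonds), polarity (H-bond donors and
#' acceptors, halogens, heteroatoms), the sp3-carbon percentage, explicit
#' stereocentre count, graph diameter and radius, terminal and branch
#' atoms, and the degree distribution.
#'
#' @param smiles A SMILES string.
#' @return Named integer-valued numeric vector of length 28 (order of
#'   [dli_feature_names()]).
#' @export
#' @examples
#' compute_dli("c1ccccc1")[c("n_rings", "n_aromatic_rings", "n_ring_atoms")]
compute_dli <- function(smiles) {
  mol <- parse_molecule(smiles)
  ri <- .ring_info(mol)
  nb <- nrow(mol$bonds)

  # Murcko-style framework: iteratively strip terminal atoms
  keep <- rep(TRUE, mol$n)
  degs <- mol$degree
  bonds <- mol$bonds
  repeat {
    leaf <- which(keep & degs <= 1)
    if (length(leaf) == 0 || sum(keep) == 0) break
    keep[leaf] <- FALSE
    if (nrow(bonds)) {
      drop <- bonds[, 1] %in% leaf | bonds[, 2] %in% leaf
      for (k in which(drop)) {
        degs[bonds[k, 1]] <- degs[bonds[k, 1]] - 1L
        degs[bonds[k, 2]] <- degs[bonds[k, 2]] - 1L
      }
      bonds <- bonds[!drop, , drop = FALSE]
    }
  }
  fw_atoms <- sum(keep)
  fw_bonds <- nrow(bonds)
  linker <- if (fw_bonds) sum(!paste(bonds[, 1], bonds[, 2]) %in%
                              paste(mol$bonds[setdiff(seq_len(nb),
                                                      ri$bridge_edges), 1],
                                    mol$bonds[setdiff(seq_len(nb),
                                                      ri$bridge_edges), 2]))
            else 0L

  rot <- 0L
  if (nb) {
    for (k in seq_len(nb)) {
      if (mol$bonds[k, 3] == 1 && k %in% ri$bridge_edges &&
          mol$degree[mol$bonds[k, 1]] >= 2 &&
          mol$degree[mol$bonds[k, 2]] >= 2)
        rot <- rot + 1L
    }
  }

  if (nb) {
    g <- igraph::graph_from_edgelist(cbind(mol$bonds[, 1], mol$bonds[, 2]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, mol$n - igraph::vcount(g)))
    dmat <- igraph::distances(g)
    ecc <- apply(dmat, 1, max)
    diam <- max(ecc); radi <- min(ecc)
  } else { diam <- 0; radi <- 0 }

  arom_ring <- if (length(ri$rings))
    sum(vapply(ri$rings, function(rr) all(mol$aromatic[rr]), logical(1)))
  else 0L
  ncarbon <- sum(mol$elem == "C")
  sp3c <- sum(mol$elem == "C" & !mol$aromatic & mol$max_order < 2)
  sp3pct <- if (ncarbon) 100 * sp3c / ncarbon else 0
  chiral <- length(gregexpr("@@|@", smiles)[[1]])
  if (!grepl("@", smiles)) chiral <- 0L
  props <- ob_props(smiles)

  out <- c(
    n_atoms = mol$n, n_bonds = nb, n_rings = ri$n_rings,
    n_aromatic_rings = arom_ring, n_ring_systems = ri$n_systems,
    largest_ring = ri$largest, n_ring_atoms = length(ri$ring_atoms),
    framework_atoms = fw_atoms, framework_bonds = fw_bonds,
    linker_bonds = linker, sidechain_atoms = mol$n - fw_atoms,
    rotatable_bonds = rot, rigid_bonds = nb - rot,
    hbd = props$HBD[1], hba = props$HBA1[1],
    n_halogen = sum(mol$elem %in% .halogens),
    n_hetero = sum(!mol$elem %in% c("C", "H")),
    sp3_carbon_pct = sp3pct, n_chiral = chiral,
    graph_diameter = diam, graph_radius = radi,
    n_terminal = sum(mol$degree == 1),
    n_branch = sum(mol$degree >= 3),
    deg1 = sum(mol$degree == 1), deg2 = sum(mol$degree == 2),
    deg3 = sum(mol$degree == 3), deg4 = sum(mol$degree == 4),
    max_degree = if (mol$n) max(mol$degree) else 0
  )
  setNames(as.numeric(out), dli_feature_names())
}

# ---- block construction ------------------------------------------------

#' Compute a ligand descriptor block from SMILES
#'
#' Applies [compute_gd()] or [compute_dli()] to each compound; molecules
#' that fail to parse or compute are dropped with a warning and recorded in
#' the `"failures"` attribute.
#'
#' @param smiles Character vector of SMILES.
#' @param ids Compound ids (row names); default `names(smiles)` or
#'   `cmpd1..n`.
#' @param kind `"GD"` or `"DLI"`.
#' @return Numeric matrix (compounds x 32 or 28) with attribute
#'   `"kind"`.
#' @export
ligand_block <- function(smiles, ids = names(smiles),
                         kind = c("GD", "DLI")) {
  kind <- match.arg(kind)
  if (is.null(ids)) ids <- paste0("cmpd", seq_along(smiles))
  if (anyDuplicated(ids)) stop("duplicate compound ids")
  f <- if (kind == "GD") compute_gd else compute_dli
  rows <- lapply(smiles, function(s) tryCatch(f(s), error = function(e) e))
  bad <- vapply(rows, inherits, logical(1), what = "error")
  if (any(bad))
    warning("dropped ", sum(bad), " compound(s): ",
            paste(ids[bad], collapse = ", "))
  if (all(bad)) stop("no computable compounds in input")
  out <- do.call(rbind, rows[!bad])
  rownames(out) <- ids[!bad]
  attr(out, "kind") <- kind
  attr(out, "failures") <- ids[bad]
  out
}

#' Read a precomputed ligand descriptor table
#'
#' Ingests externally computed descriptors (e.g. from commercial modeling
#' suites) as a block, enforcing the expected dimensionality.
#'
#' @param path CSV with a `compound_id` column plus `expected_dim` numeric
#'   columns.
#' @param kind `"GD"` or `"DLI"` (sets the default expected dimension, 32
#'   or 28).
#' @param expected_dim Override for the required number of descriptor
#'   columns.
#' @return Numeric matrix with compound ids as row names and attribute
#'   `"kind"`.
#' @export
read_descriptor_table <- function(path, kind = c("GD", "DLI"),
                                  expected_dim = NULL) {
  kind <- match.arg(kind)
  if (is.null(expected_dim)) expected_dim <- if (kind == "GD") 32L else 28L
  if (!file.exists(path)) stop("descriptor table not found: ", path)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"compound_id" %in% names(raw))
    stop("descriptor table must contain a compound_id column")
  ids <- raw$compound_id
  m <- raw[, setdiff(names(raw), "compound_id"), drop = FALSE]
  if (ncol(m) != expected_dim)
    stop("descriptor table has ", ncol(m), " columns, expected ",
         expected_dim, " for kind ", kind)
  for (j in seq_along(m)) {
    v <- m[[j]]
    if (!is.numeric(v) || anyNA(v)) {
      i <- which(is.na(suppressWarnings(as.numeric(v))) | is.na(v))[1]
      stop("non-numeric or missing value at row ", ids[i], ", column '",
           names(m)[j], "'")
    }
  }
  out <- as.matrix(m)
  rownames(out) <- ids
  attr(out, "kind") <- kind
  out
}
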