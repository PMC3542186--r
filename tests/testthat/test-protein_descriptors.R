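test_that("global identity is symmetric, 100 on self and 0 with no matches", {
  expect_equal(global_identity("MKVLHEAG", "MKVLHEAG"), 100)
  expect_equal(global_identity("AAAA", "CCCC"), 0)
  a <- "HEAGAWGHEE"; b <- "PAWHEAE"
  expect_equal(global_identity(a, b), global_identity(b, a))
  expect_error(global_identity("", "MKV"), "non-empty")
  expect_error(global_identity("MKZ1", "MKV"), "non-amino-acid")
  # X is tolerated
  expect_silent(global_identity("MKXV", "MKVV"))
})

test_that("global identity agrees with an independent affine-gap DP oracle", {
  # The optimal alignment may not be unique, so identities of two optimal
  # alignments can differ; the sharp invariants are (a) the alignment the
  # package scores is optimal (its score equals the oracle's DP optimum)
  # and (b) the reported identity is matches / alignment length of that
  # alignment.
  score_alignment <- function(pa, sa) {
    sm <- local({
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      e$BLOSUM62
    })
    p <- strsplit(pa, "")[[1]]; s <- strsplit(sa, "")[[1]]
    sc <- 0; gap <- ""  # track affine gaps in either string
    for (i in seq_along(p)) {
      if (p[i] == "-" || s[i] == "-") {
        side <- if (p[i] == "-") "p" else "s"
        sc <- sc - 0.5 - if (!identical(gap, side)) 10 else 0
        gap <- side
      } else {
        sc <- sc + sm[p[i], s[i]]
        gap <- ""
      }
    }
    sc
  }
  set.seed(31)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:25) {
    a <- paste(sample(aa, sample(4:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(4:12, 1), replace = TRUE), collapse = "")
    ora <- gotoh_identity(a, b)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10,
      gapExtension = 0.5, type = "global")
    pa <- as.character(Biostrings::alignedPattern(al))
    sa <- as.character(Biostrings::alignedSubject(al))
    expect_equal(score_alignment(pa, sa), ora$score, tolerance = 1e-9,
                 info = paste(a, b))
    p <- strsplit(pa, "")[[1]]; s <- strsplit(sa, "")[[1]]
    ident <- 100 * sum(p == s & p != "-") / length(p)
    expect_equal(global_identity(a, b), ident, tolerance = 1e-9,
                 info = paste(a, b))
  }
})

test_that("P0 block assembly covers the panel x reference grid", {
  expect_equal(build_p0(c(x = "MKVH"), c(x = "MKVH")),
               matrix(100, 1, 1, dimnames = list("x", "x")))
  p0 <- build_p0(c(a = "MKVLHEAG", b = "MKVAHEAG"),
                 c(r1 = "MKVLHEAG", r2 = "AAAA", r3 = "MKV"))
  expect_equal(dim(p0), c(2L, 3L))
  expect_equal(p0["a", "r1"], 100)
  expect_warning(build_p0(c(a = "MKV"), c(r = "MKV", r = "MKVH")),
                 "duplicate")
  expect_error(build_p0(c(a = ""), c(r = "MKV")), "empty")
})

test_that("similarity-matrix ingestion validates shape, values and diagonal", {
  p1 <- hdac_p1()
  expect_equal(dim(p1), c(5L, 5L))
  expect_equal(p1["HDAC4", "HDAC7"], 0.706)
  expect_equal(p1, t(p1))
  expect_equal(unname(diag(p1)), rep(1, 5))
  p0 <- hdac_p0()
  expect_equal(dim(p0), c(5L, 11L))
  expect_equal(p0["HDAC2", "HDAC8"], 30.7)
  expect_equal(unname(vapply(rownames(p0), function(t) p0[t, t],
                             numeric(1))), rep(100, 5))

  tmp <- tempfile(fileext = ".csv")
  writeLines(c("id,A,B", "A,1.0,0.2", "B,0.2,1.0"), tmp)
  expect_silent(read_similarity_matrix(tmp, self_value = 1))
  writeLines(c("id,A,B", "A,0.9,0.2", "B,0.2,1.0"), tmp)
  expect_error(read_similarity_matrix(tmp, self_value = 1),
               "self-similarity")
  writeLines(c("id,A,B", "A,1.0,oops", "B,0.2,1.0"), tmp)
  expect_error(read_similarity_matrix(tmp), "non-numeric")
})

test_that("geometry descriptors recover the helix generator's internal coordinates", {
  f <- generate_helix_structure(20, noise_A = 0, seed = 1)
  g <- geometry_descriptors(f)
  expect_length(g, 30L)
  expect_identical(names(g), geometry_feature_names())
  expect_gt(g[["len.C_Nnext.mean"]], 1.30)
  expect_lt(g[["len.C_Nnext.mean"]], 1.36)
  expect_lt(g[["len.C_Nnext.sd"]], 0.02)
  # bond-length spreads for ideal geometry are limited only by the PDB
  # format's 0.001 A coordinate precision
  len_sd <- g[grep("^len.*\\.sd$", names(g))]
  expect_lt(max(len_sd, na.rm = TRUE), 2e-3)
  expect_equal(g[["dih.phi.mean"]], -57, tolerance = 0.1)
  expect_equal(g[["dih.psi.mean"]], -47, tolerance = 0.1)
  expect_lt(circ_diff(g[["dih.omega.mean"]], 180), 0.1)
  # poly-alanine has no gamma atom: chi1 is flagged missing
  expect_true("dih.chi1" %in% attr(g, "missing_classes"))
  expect_true(all(is.na(g[c("dih.chi1.mean", "dih.chi1.sd")])))
})

test_that("geometry descriptors are invariant under rigid-body motion", {
  # rotate the coordinates in memory (a file round trip would quantize
  # them to the PDB's 0.001 A precision)
  f <- generate_helix_structure(12, noise_A = 0.02, seed = 5)
  pdb <- bio3d::read.pdb(f, verbose = FALSE)
  g <- geometry_descriptors(pdb)
  set.seed(9)
  th <- rnorm(3)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                 0, sin(th[1]), cos(th[1])), 3, byrow = TRUE)
  Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0,
                 -sin(th[2]), 0, cos(th[2])), 3, byrow = TRUE)
  xyz <- as.matrix(pdb$atom[, c("x", "y", "z")])
  moved <- xyz %*% t(Rx %*% Ry) +
    matrix(rep(c(5, -3, 2), each = nrow(xyz)), ncol = 3)
  pdb2 <- pdb
  pdb2$atom$x <- moved[, 1]; pdb2$atom$y <- moved[, 2]
  pdb2$atom$z <- moved[, 3]
  g2 <- geometry_descriptors(pdb2)
  dih <- grepl("^dih\\.", names(g))
  expect_lt(max(abs(g[!dih] - g2[!dih]), na.rm = TRUE), 1e-6)
  expect_lt(max(circ_diff(g[dih & grepl("mean$", names(g))],
                          g2[dih & grepl("mean$", names(g2))]),
                na.rm = TRUE), 1e-6)
})

test_that("too-short fragments are rejected", {
  f <- generate_helix_structure(3, noise_A = 0, seed = 1)
  g <- geometry_descriptors(f)  # minimal valid structure
  expect_length(g, 30L)
  # truncate to two residues
  pdb <- bio3d::read.pdb(f, verbose = FALSE)
  short <- bio3d::trim.pdb(pdb, resno = 1:2)
  expect_error(geometry_descriptors(short), "nsufficient")
})
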