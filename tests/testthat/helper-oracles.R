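# Independent reference implementations used as oracles in the tests.
# These deliberately share no code with the package internals.

# Gotoh affine-gap global alignment (gap of length L costs open + L * ext,
# matching the package's aligner convention) with traceback, returning the
# optimal score and the percent identity over the full alignment length.
gotoh_identity <- function(a, b, open = 10, ext = 0.5) {
  sm <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  ptM <- ptX <- ptY <- matrix("", n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) {
    Ix[i, 1] <- -(open + ext * (i - 1))
    ptX[i, 1] <- if (i == 2) "M" else "X"
  }
  for (j in 2:(m + 1)) {
    Iy[1, j] <- -(open + ext * (j - 1))
    ptY[1, j] <- if (j == 2) "M" else "Y"
  }
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- sm[A[i - 1], B[j - 1]]
    cand <- c(M = M[i - 1, j - 1], X = Ix[i - 1, j - 1],
              Y = Iy[i - 1, j - 1])
    k <- which.max(cand)
    M[i, j] <- cand[k] + s; ptM[i, j] <- names(cand)[k]
    cand <- c(M = M[i - 1, j] - open - ext, X = Ix[i - 1, j] - ext)
    k <- which.max(cand)
    Ix[i, j] <- cand[k]; ptX[i, j] <- names(cand)[k]
    cand <- c(M = M[i, j - 1] - open - ext, Y = Iy[i, j - 1] - ext)
    k <- which.max(cand)
    Iy[i, j] <- cand[k]; ptY[i, j] <- names(cand)[k]
  }
  fin <- c(M = M[n + 1, m + 1], X = Ix[n + 1, m + 1], Y = Iy[n + 1, m + 1])
  state <- names(fin)[which.max(fin)]
  score <- max(fin)
  i <- n + 1; j <- m + 1; ident <- 0L; len <- 0L
  while (i > 1 || j > 1) {
    len <- len + 1L
    if (state == "M") {
      if (A[i - 1] == B[j - 1]) ident <- ident + 1L
      state <- ptM[i, j]; i <- i - 1; j <- j - 1
    } else if (state == "X") {
      state <- ptX[i, j]; i <- i - 1
    } else {
      state <- ptY[i, j]; j <- j - 1
    }
  }
  list(score = score, identity = 100 * ident / len)
}

# All-pairs shortest paths by Floyd-Warshall on an unweighted edge list.
fw_distances <- function(n, edges) {
  d <- matrix(Inf, n, n); diag(d) <- 0
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    d[edges[k, 1], edges[k, 2]] <- 1
    d[edges[k, 2], edges[k, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Graph facts for a parsed molecule by brute force: connectivity-based
# cycle rank, bridges by edge-removal reachability, eccentricities.
graph_oracle <- function(n, edges) {
  reach <- function(ed) {
    d <- fw_distances(n, ed)
    is.finite(d)
  }
  conn_comp <- function(ed) {
    r <- reach(ed)
    length(unique(apply(r, 1, function(x) paste(which(x), collapse = ","))))
  }
  nc <- conn_comp(edges)
  cyc_rank <- nrow(edges) - n + nc
  bridge <- logical(nrow(edges))
  if (nrow(edges)) for (k in seq_len(nrow(edges)))
    bridge[k] <- conn_comp(edges[-k, , drop = FALSE]) > nc
  d <- fw_distances(n, edges)
  ecc <- apply(d, 1, max)
  list(cycle_rank = cyc_rank, bridges = bridge,
       diameter = max(ecc), radius = min(ecc))
}

# circular difference in degrees, for dihedral comparisons
circ_diff <- function(a, b) {
  x <- (a - b + 180) %% 360 - 180
  abs(x)
}

# Write a synthetic activity CSV with given per-target pair counts.
write_activity_fixture <- function(path, counts = c(
  HDAC2 = 215, HDAC4 = 197, HDAC6 = 531, HDAC7 = 46, HDAC8 = 286)) {
  rows <- do.call(rbind, lapply(names(counts), function(t) {
    k <- counts[[t]]
    data.frame(compound_id = sprintf("%s_c%04d", t, seq_len(k)),
               smiles = "CCO",
               target_id = t,
               ic50_nm = round(10^runif(k, 0, 4), 3),
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}
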