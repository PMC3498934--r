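# Independent oracles used to check the package's own implementations.
# Nothing here calls the code path under test: rotations are searched
# numerically, lattice minima are enumerated by brute force, and alignment
# identity is recomputed with a standalone DP.

# --- rotation-search oracle for superposition -------------------------------

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  )
}

# best proper-rotation RMSD of two centred point sets by multi-start
# quaternion optimization (independent of the SVD solution)
brute_force_rmsd <- function(p, q, n_starts = 24) {
  p0 <- sweep(p, 2, colMeans(p))
  q0 <- sweep(q, 2, colMeans(q))
  obj <- function(par) {
    r <- quat_to_rot(par)
    sqrt(sum((p0 %*% t(r) - q0)^2) / nrow(p0))
  }
  best <- Inf
  starts <- matrix(stats::rnorm(4 * n_starts), ncol = 4)
  starts[1, ] <- c(1, 0, 0, 0)
  for (i in seq_len(n_starts)) {
    fit <- stats::optim(starts[i, ], obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (fit$value < best) best <- fit$value
  }
  best
}

# min over the six joint axis relabellings, each fit by rotation search
brute_force_cell_rmsd <- function(query, candidate) {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  vq <- cell_vertices(query)
  len <- c(candidate$a, candidate$b, candidate$c)
  ang <- c(candidate$alpha, candidate$beta, candidate$gamma)
  best <- Inf
  for (i in 1:6) {
    p <- perms[i, ]
    cc <- unit_cell(len[p[1]], len[p[2]], len[p[3]],
                    ang[p[1]], ang[p[2]], ang[p[3]])
    best <- min(best, brute_force_rmsd(vq, cell_vertices(cc)))
  }
  best
}

# --- lattice oracle for Niggli reduction ------------------------------------

# successive minima of a lattice by enumerating small integer combinations
# of an arbitrary generating basis
lattice_minima <- function(basis, range = 3L) {
  idx <- as.matrix(expand.grid(-range:range, -range:range, -range:range))
  idx <- idx[rowSums(idx != 0) > 0, , drop = FALSE]
  vecs <- idx %*% basis
  lens <- sqrt(rowSums(vecs^2))
  ord <- order(lens)
  vecs <- vecs[ord, , drop = FALSE]
  lens <- lens[ord]
  v1 <- vecs[1, ]
  m1 <- lens[1]
  i2 <- which(vapply(seq_len(nrow(vecs)), function(i) {
    sum(pracma_cross(v1, vecs[i, ])^2) > 1e-9 * m1^4
  }, logical(1)))[1]
  v2 <- vecs[i2, ]; m2 <- lens[i2]
  i3 <- which(vapply(seq_len(nrow(vecs)), function(i) {
    abs(det(rbind(v1, v2, vecs[i, ]))) > 1e-6 * m1^3
  }, logical(1)))[1]
  c(m1, m2, lens[i3])
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# random integer unimodular matrix (det +1) from elementary shears
random_unimodular <- function(n_shears = 4L) {
  m <- diag(3)
  for (k in seq_len(n_shears)) {
    ij <- sample(1:3, 2)
    s <- diag(3)
    s[ij[1], ij[2]] <- sample(c(-2L, -1L, 1L, 2L), 1)
    m <- m %*% s
  }
  m
}

random_valid_cell <- function(len_range = c(5, 50), ang_range = c(60, 120)) {
  repeat {
    cand <- tryCatch(
      unit_cell(stats::runif(1, len_range[1], len_range[2]),
                stats::runif(1, len_range[1], len_range[2]),
                stats::runif(1, len_range[1], len_range[2]),
                stats::runif(1, ang_range[1], ang_range[2]),
                stats::runif(1, ang_range[1], ang_range[2]),
                stats::runif(1, ang_range[1], ang_range[2])),
      error = function(e) NULL
    )
    if (!is.null(cand)) return(cand)
  }
}

# --- alignment oracle for pairwise identity ---------------------------------

# With match +1 / mismatch 0 and gap costs 10 + 0.5k, any optimal global
# alignment of short sequences (<= ~15 residues) has the minimal number of
# gapped positions: none if the lengths are equal, otherwise one contiguous
# run of length |diff| in the shorter sequence. The oracle enumerates every
# placement of that run and maximizes the match count.
oracle_identity <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  d <- length(b) - length(a)
  shorter <- length(a)
  best <- 0L
  for (pos in 0:shorter) {
    aligned <- append(a, rep(NA, d), after = pos)
    m <- sum(!is.na(aligned) & aligned == b)
    if (m > best) best <- m
  }
  best / shorter
}

random_sequence <- function(n, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
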