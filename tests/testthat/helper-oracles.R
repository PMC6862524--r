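# Independent oracles used to cross-check the package's own implementations.
# They deliberately avoid the code paths they validate.

# quaternion characteristic-polynomial RMSD (independent of the Kabsch/SVD
# route): largest eigenvalue of the Horn key matrix
oracle_quaternion_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  M <- crossprod(A, B)
  K <- matrix(0, 4, 4)
  K[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  K[1, 2] <- K[2, 1] <- M[2, 3] - M[3, 2]
  K[1, 3] <- K[3, 1] <- M[3, 1] - M[1, 3]
  K[1, 4] <- K[4, 1] <- M[1, 2] - M[2, 1]
  K[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  K[2, 3] <- K[3, 2] <- M[1, 2] + M[2, 1]
  K[2, 4] <- K[4, 2] <- M[1, 3] + M[3, 1]
  K[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  K[3, 4] <- K[4, 3] <- M[2, 3] + M[3, 2]
  K[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, sum(A^2) + sum(B^2) - 2 * lmax) / nrow(A))
}

# Monte-Carlo (rejection sampling) solvent-accessible surface area
oracle_mc_sasa <- function(coords, radii, probe, n_total = 1e5) {
  R <- radii + probe
  n_per <- round(n_total * R^2 / sum(R^2))
  total <- 0
  for (i in seq_len(nrow(coords))) {
    u <- matrix(stats::rnorm(n_per[i] * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * R[i], 2, coords[i, ], "+")
    ok <- rep(TRUE, n_per[i])
    for (j in seq_len(nrow(coords))) {
      if (j != i) {
        ok <- ok & (rowSums(sweep(pts, 2, coords[j, ])^2) >= R[j]^2)
      }
    }
    total <- total + 4 * pi * R[i]^2 * mean(ok)
  }
  total
}

# exhaustive minimum-image distance over the 27 periodic image translations
oracle_image_distance <- function(p, q, box) {
  if (length(box) == 1L) box <- rep(box, 3L)
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- sqrt(sum((p - (q + c(i, j, k) * box))^2))
    best <- min(best, d)
  }
  best
}

# direct re-implementation of greedy neighbour-count clustering, using the
# quaternion RMSD oracle for the pairwise matrix
oracle_gromos <- function(frames, cutoff) {
  nf <- length(frames)
  rmsd <- matrix(0, nf, nf)
  for (i in seq_len(nf)) for (j in seq_len(nf)) {
    if (i < j) {
      rmsd[i, j] <- rmsd[j, i] <- oracle_quaternion_rmsd(frames[[i]],
                                                         frames[[j]])
    }
  }
  alive <- rep(TRUE, nf)
  clusters <- list()
  while (any(alive)) {
    best_n <- -1L; best_i <- NA_integer_
    for (i in seq_len(nf)) {
      if (!alive[i]) next
      n_i <- sum(alive & rmsd[, i] <= cutoff)
      if (n_i > best_n) { best_n <- n_i; best_i <- i }
    }
    member <- which(alive & rmsd[, best_i] <= cutoff)
    clusters[[length(clusters) + 1L]] <- member
    alive[member] <- FALSE
  }
  clusters
}
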