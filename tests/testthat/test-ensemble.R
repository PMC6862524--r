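test_that("clustering collapses identical frames and isolates distant ones", {
  sel <- fixture_helix$atoms$name %in% c("N", "CA", "C")
  a <- fixture_helix$coords[sel, ]
  same <- replicate(7, a, simplify = FALSE)
  cs <- gromos_cluster(same, 0.3)
  expect_length(cs$clusters, 1L)
  expect_identical(sort(cs$clusters[[1]]), 1:7)

  apart <- lapply(seq(0, 150, by = 30), function(ang) {
    if (ang == 0) a else
      build_bent_conformer(fixture_helix, c(10, 11), ang)$coords[sel, ]
  })
  singletons <- gromos_cluster(apart, 0.05)
  expect_length(singletons$clusters, length(apart))
  expect_error(gromos_cluster(list(), 0.3), "empty")
})

test_that("clustering matches a brute-force oracle on a two-basin set", {
  tb <- two_basin_frames()
  cs <- gromos_cluster(tb$frames, 0.3)
  oracle <- oracle_gromos(tb$frames, 0.3)
  canon <- function(cl) {
    cl <- lapply(cl, sort)
    cl[order(vapply(cl, min, 0L))]
  }
  expect_identical(canon(cs$clusters), canon(oracle))
  # the two clusters recover the generating basins
  expect_length(cs$clusters, 2L)
  for (cl in cs$clusters) {
    expect_length(unique(tb$labels[cl]), 1L)
  }
})

test_that("cluster properties: partition, centroid membership, size order", {
  tb <- two_basin_frames(15, 25)
  cs <- gromos_cluster(tb$frames, 0.3)
  expect_identical(sort(unlist(cs$clusters)), seq_along(tb$frames))
  for (k in seq_along(cs$clusters)) {
    expect_true(cs$centroids[k] %in% cs$clusters[[k]])
  }
  expect_true(all(diff(lengths(cs$clusters)) <= 0))
  expect_identical(sum(lengths(cs$clusters)), length(tb$frames))
})

test_that("clustering is invariant to frame order", {
  tb <- two_basin_frames(12, 12, seed = 6)
  cs1 <- gromos_cluster(tb$frames, 0.3)
  perm <- rev(seq_along(tb$frames))
  cs2 <- gromos_cluster(tb$frames[perm], 0.3)
  sets1 <- lapply(cs1$clusters, function(m) sort(tb$labels[m]))
  sets2 <- lapply(cs2$clusters, function(m) sort(tb$labels[perm][m]))
  expect_identical(lengths(sets1), lengths(sets2))
  expect_setequal(vapply(sets1, paste, "", collapse = ""),
                  vapply(sets2, paste, "", collapse = ""))
})

test_that("backbone PCA spans 60 atoms / 180 coordinates for 20 residues", {
  tr <- bend_sweep_trajectory(bombinin, c(20, 60, 100, 120))
  model <- cartesian_pca(tr, "A")
  expect_length(model$mean, 180L)
  expect_identical(nrow(model$atoms), 60L)
  expect_error(cartesian_pca(
    trajectory(tr$coords[, , 1, drop = FALSE], tr$atoms, 0, 15, bombinin)),
    "2 frames")
})

test_that("static trajectories have zero eigenvalues", {
  coords <- array(fixture_bent$coords, c(nrow(fixture_bent$coords), 3, 5))
  tr <- trajectory(coords, fixture_bent$atoms, 0:4, 15, bombinin)
  model <- cartesian_pca(tr, "A")
  expect_lt(max(model$values), 1e-20)
  expect_true(all(eigen_rmsf(model, 1)$rmsf_nm < 1e-10))
})

test_that("eigenvalue sum equals the covariance trace and PCs reconstruct", {
  tr <- bend_sweep_trajectory(bombinin, seq(15, 120, length.out = 25),
                              noise_sigma_nm = 0.01, seed = 8)
  model <- cartesian_pca(tr, "A")
  # independent covariance trace: total variance of the fitted coordinates
  idx <- which(tr$atoms$name %in% c("N", "CA", "C"))
  ref <- tr$coords[idx, , 1]
  X <- t(vapply(seq_len(n_frames(tr)), function(f) {
    x <- tr$coords[idx, , f]
    as.numeric(t(apply_transform(x, kabsch_superpose(x, ref))))
  }, numeric(180)))
  expect_equal(sum(model$values), sum(apply(X, 2, stats::var)),
               tolerance = 1e-8)
  expect_true(all(diff(model$values) <= 1e-12))
  expect_equal(crossprod(model$vectors), diag(180), tolerance = 1e-8,
               ignore_attr = TRUE)
  # reconstruction from all PCs
  Xc <- sweep(X, 2, model$mean)
  expect_lt(max(abs(model$projections %*% t(model$vectors) - Xc)), 1e-8)
  # projection variance identity and zero-mean projections
  expect_equal(stats::var(model$projections[, 1]), model$values[1],
               tolerance = 1e-8)
  expect_lt(max(abs(colMeans(model$projections))), 1e-10)
})

test_that("a pure bending motion loads on PC1 and tracks compactness", {
  angles <- seq(15, 120, length.out = 60)
  tr <- bend_sweep_trajectory(bombinin, angles)
  model <- cartesian_pca(tr, "A")
  expect_gt(model$values[1] / sum(model$values), 0.9)
  rg <- vapply(seq_len(60), function(f) {
    radius_of_gyration(get_conformation(tr, "A", f))
  }, 0)
  expect_gt(abs(stats::cor(model$projections[, 1], rg)), 0.9)
})

test_that("PC1 fluctuation profile peaks at the termini, dips at the hinge", {
  tr <- bend_sweep_trajectory(bombinin, seq(15, 120, length.out = 40))
  prof <- eigen_rmsf(cartesian_pca(tr, "A"), 1)
  ca <- prof[prof$name == "CA", ]
  expect_gt(min(ca$rmsf_nm[c(1, 20)]), max(ca$rmsf_nm[10:11]))
  expect_true(all(prof$rmsf_nm >= 0))
  expect_error(eigen_rmsf(cartesian_pca(tr, "A"), 200), "out of range")
})

test_that("the same scripted motion yields matching profiles in context", {
  angles <- seq(20, 120, length.out = 30)
  mono <- bend_sweep_trajectory(bombinin, angles, noise_sigma_nm = 0.002,
                                seed = 31)
  moving <- bend_sweep_trajectory(bombinin, angles, noise_sigma_nm = 0.002,
                                  seed = 32)
  static <- generate_trajectory(scenario(n_chains = 1, duration_ns = 29,
                                         spacing_nm = 1,
                                         noise_sigma_nm = 0.002, seed = 33))
  in_agg <- merge_trajectories(list(moving, static), c("A", "B"))
  p_mono <- eigen_rmsf(cartesian_pca(mono, "A"), 1)$rmsf_nm
  p_agg <- eigen_rmsf(cartesian_pca(in_agg, "A"), 1)$rmsf_nm
  expect_lt(max(abs(p_agg - p_mono) / pmax(p_mono, 0.01)), 0.10)
})

test_that("two-basin projections are bimodal", {
  tb <- two_basin_frames(20, 20, sigma = 0.01, seed = 9)
  nat <- nrow(tb$frames[[1]])
  coords <- array(unlist(tb$frames), c(nat, 3, length(tb$frames)))
  atoms <- fixture_helix$atoms[fixture_helix$atoms$name %in%
                                 c("N", "CA", "C"), ]
  tr <- trajectory(coords, atoms, seq_along(tb$frames) - 1, 15, bombinin)
  model <- cartesian_pca(tr, "A", selection = c("N", "CA", "C"))
  pc1 <- sort(model$projections[, 1])
  gaps <- diff(pc1)
  # the inter-basin gap dwarfs any within-basin spacing
  expect_gt(max(gaps), 5 * max(gaps[-which.max(gaps)]))
  # the gap splits the frames into the two generating basins (20 + 20)
  expect_identical(which.max(gaps), 20L)
})

test_that("projection errors are caught", {
  tr <- bend_sweep_trajectory(bombinin, c(20, 60, 100))
  model <- cartesian_pca(tr, "A")
  expect_error(pca_project(tr, model, 0), "out of range")
  ca_only <- cartesian_pca(tr, "A", selection = "CA")
  expect_error(pca_project(tr, ca_only, 1, chain = "missing"),
               "mismatch|selection")
})
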