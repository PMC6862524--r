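test_that("ideal helix has canonical dihedrals, rise and compactness", {
  dh <- backbone_dihedrals(fixture_helix)
  expect_true(all(abs(dh$phi[2:20] - (-57)) <= 2))
  expect_true(all(abs(dh$psi[1:19] - (-47)) <= 2))
  ca <- fixture_helix$coords[fixture_helix$atoms$name == "CA", ]
  axis <- svd(sweep(ca, 2, colMeans(ca)), nu = 0, nv = 1)$v[, 1]
  extent <- abs(sum((ca[20, ] - ca[1, ]) * axis))
  expect_gt(extent, 2.75)
  expect_lt(extent, 2.95)
  rg <- radius_of_gyration(fixture_helix)
  expect_gt(rg, 0.80)
  expect_lt(rg, 1.10)
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(d >= 0.36 & d <= 0.40))
})

test_that("bent conformer hits the requested inter-segment angle", {
  for (ang in c(30, 60, 90, 120, 150)) {
    b <- build_bent_conformer(fixture_helix, c(10, 11), ang)
    expect_lt(abs(segment_axis_angle(b) - ang), 5)
    ca <- b$coords[b$atoms$name == "CA", ]
    d <- sqrt(rowSums(diff(ca)^2))
    expect_true(all(d >= 0.36 & d <= 0.40))
  }
})

test_that("default bent conformer matches the compact-state geometry", {
  rg <- radius_of_gyration(fixture_bent)
  expect_gt(rg, 0.55)
  expect_lt(rg, 0.80)
  hel <- assign_helix(fixture_bent)
  expect_true(all(hel[c(2:8, 13:19)]))
  expect_false(all(hel[10:11]))   # the hinge is broken
})

test_that("zero bend angle returns the input unchanged", {
  b0 <- build_bent_conformer(fixture_helix, c(10, 11), 0)
  expect_equal(b0$coords, fixture_helix$coords, tolerance = 1e-12)
})

test_that("bent conformer rejects invalid hinges", {
  expect_error(build_bent_conformer(fixture_helix, c(1, 2), 90), "interior")
  expect_error(build_bent_conformer(fixture_helix, c(19, 20), 90), "interior")
  expect_error(build_bent_conformer(fixture_helix, c(5, 7), 90), "consecutive")
  expect_error(build_bent_conformer(fixture_helix, c(10, 11), 200), "0, 180")
})

test_that("grid placement keeps chains separated beyond 1 nm", {
  sc <- scenario(duration_ns = 2, noise_sigma_nm = 0)
  tr <- generate_trajectory(sc)
  for (f in seq_len(n_frames(tr))) {
    adj <- chain_contact_graph(tr, f, cutoff_nm = 1.0)
    expect_false(any(adj))
  }
})

test_that("straightening events switch exactly the scheduled chains", {
  st <- data.frame(time_ns = c(5, 9, 12), chain = c("B", "D", "A"))
  sc <- scenario(n_chains = 4, duration_ns = 15, straightenings = st,
                 noise_sigma_nm = 0)
  tr <- generate_trajectory(sc)
  final <- vapply(trajectory_chains(tr), function(ch) {
    classify_state(get_conformation(tr, ch, n_frames(tr)))
  }, "")
  expect_identical(sum(final == "single-helix"), 3L)
  expect_identical(unname(final["C"]), "helix-loop-helix")
  ledger <- attr(tr, "ledger")
  expect_identical(ledger$chains[ledger$event == "straighten"],
                   c("B", "D", "A"))
})

test_that("generation is bitwise deterministic under a fixed seed", {
  sc <- scenario(n_chains = 3, duration_ns = 5, noise_sigma_nm = 0.005,
                 seed = 99L)
  t1 <- generate_trajectory(sc)
  t2 <- generate_trajectory(sc)
  expect_identical(t1$coords, t2$coords)
})

test_that("noise-free frames are exact rigid copies of the templates", {
  st <- data.frame(time_ns = 4, chain = "A")
  sc <- scenario(n_chains = 2, duration_ns = 8, straightenings = st,
                 noise_sigma_nm = 0)
  tr <- generate_trajectory(sc)
  straight <- build_ideal_helix(tr$sequence)
  bent <- build_bent_conformer(straight, c(10, 11), 120)
  for (f in c(1, 5, 9)) {
    for (ch in c("A", "B")) {
      x <- get_conformation(tr, ch, f)$coords
      rmsds <- c(kabsch_superpose(straight$coords, x)$rmsd,
                 kabsch_superpose(bent$coords, x)$rmsd)
      expect_lt(min(rmsds), 1e-9)
    }
  }
})

test_that("merge events refuse infeasible schedules", {
  mg <- data.frame(time_ns = c(5, 8), a = c("A", "A"), b = c("B", "B"))
  sc <- scenario(n_chains = 2, duration_ns = 10, merges = mg,
                 noise_sigma_nm = 0)
  expect_error(generate_trajectory(sc), "already")
  expect_error(scenario(n_chains = 2, duration_ns = 10,
                        merges = data.frame(time_ns = 50, a = "A", b = "B")),
               "within")
  expect_error(scenario(n_chains = 27, box_nm = 8, spacing_nm = 5), "grid")
})

test_that("trajectories round-trip through multi-model PDB", {
  sc <- scenario(n_chains = 2, duration_ns = 2, noise_sigma_nm = 0.005,
                 frame_interval_ns = 0.7)
  tr <- generate_trajectory(sc)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, path)
  rt <- read_trajectory(path)
  expect_lt(max(abs(rt$coords - tr$coords)), 1.0001e-4)  # 1e-3 Angstrom
  expect_identical(rt$times, tr$times)
  expect_identical(rt$atoms$chain, tr$atoms$chain)
  expect_identical(rt$atoms$name, tr$atoms$name)
  expect_equal(rt$box, tr$box)
  expect_identical(paste(rt$sequence$residues, collapse = ""),
                   paste(tr$sequence$residues, collapse = ""))
  # deterministic writer: identical bytes on rewrite
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("PDB coordinates agree with an independent reader", {
  skip_if_not_installed("bio3d")
  sc <- scenario(n_chains = 2, duration_ns = 1, noise_sigma_nm = 0)
  tr <- generate_trajectory(sc)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, path)
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  expect_identical(nrow(pdb$atom), dim(tr$coords)[1])
  for (f in 1:2) {
    xyz <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE) / 10
    expect_lt(max(abs(xyz - tr$coords[, , f])), 1.0001e-4)
  }
})

test_that("malformed trajectory files are rejected", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), empty)
  expect_error(read_trajectory(empty), "empty|no ATOM")

  sc <- scenario(n_chains = 1, duration_ns = 2, noise_sigma_nm = 0)
  tr <- generate_trajectory(sc)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, path)
  lines <- readLines(path)

  # drop one ATOM record from the second model
  atom_rows <- grep("^ATOM", lines)
  truncated <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[-atom_rows[length(atom_rows)]], truncated)
  expect_error(read_trajectory(truncated), "atom counts")

  # nested MODEL records
  bad <- withr::local_tempfile(fileext = ".pdb")
  first_model <- grep("^MODEL", lines)[1]
  writeLines(append(lines, "MODEL        99", after = first_model), bad)
  expect_error(read_trajectory(bad), "nesting")
})

test_that("zero-duration scenarios give a single frame", {
  sc <- scenario(n_chains = 2, duration_ns = 0, noise_sigma_nm = 0)
  tr <- generate_trajectory(sc)
  expect_identical(n_frames(tr), 1L)
})
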