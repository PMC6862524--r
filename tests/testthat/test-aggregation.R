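test_that("grid-separated chains form no contacts", {
  sc <- scenario(duration_ns = 0, noise_sigma_nm = 0)
  tr <- generate_trajectory(sc)
  adj <- chain_contact_graph(tr, 1, 0.5)
  expect_false(any(adj))
  agg <- aggregate_series(tr, 0.5)
  expect_identical(agg$summary$n_aggregates, 27L)
  expect_identical(agg$summary$max_size, 1L)
})

test_that("contact transitivity yields connected components", {
  # A-B docked, B-C docked, A-C far: one component of three
  mg <- data.frame(time_ns = c(3, 6), a = c("A", "B"), b = c("B", "C"))
  sc <- scenario(n_chains = 4, duration_ns = 8, merges = mg,
                 noise_sigma_nm = 0)
  tr <- generate_trajectory(sc)
  f <- n_frames(tr)
  adj <- chain_contact_graph(tr, f, 0.5)
  expect_true(adj["A", "B"] || adj["A", "C"])  # B docked to the A aggregate
  agg <- aggregate_series(tr, 0.5, frames = f)
  expect_identical(agg$summary$membership, "ABC|D")
})

test_that("merge-only scenarios give monotone aggregate series", {
  mg <- data.frame(time_ns = c(4, 8, 12), a = c("A", "A", "E"),
                   b = c("B", "C", "F"))
  sc <- scenario(n_chains = 8, duration_ns = 16, noise_sigma_nm = 0,
                 merges = mg)
  tr <- generate_trajectory(sc)
  agg <- aggregate_series(tr, 0.5)
  expect_true(all(diff(agg$summary$n_aggregates) <= 0))
  expect_true(all(diff(agg$summary$max_size) >= 0))
  expect_identical(agg$summary$n_aggregates[1], 8L)
  expect_identical(agg$summary$n_aggregates[nrow(agg$summary)], 5L)
  expect_identical(agg$summary$max_size[nrow(agg$summary)], 3L)
  # component sizes always partition the chain set
  for (p in agg$partitions) expect_identical(sum(lengths(p)), 8L)
})

test_that("full coalescence ends in a single aggregate", {
  ids <- chain_ids(8)
  mg <- data.frame(time_ns = seq(2, by = 2, length.out = 7),
                   a = "A", b = ids[-1])
  sc <- scenario(n_chains = 8, duration_ns = 16, merges = mg,
                 noise_sigma_nm = 0)
  tr <- generate_trajectory(sc)
  agg <- aggregate_series(tr, 0.5, frames = n_frames(tr))
  expect_identical(agg$summary$n_aggregates, 1L)
  expect_identical(agg$summary$max_size, 8L)
})

test_that("partitions are invariant under chain relabelling", {
  mg <- data.frame(time_ns = 4, a = "A", b = "C")
  sc <- scenario(n_chains = 4, duration_ns = 6, merges = mg,
                 noise_sigma_nm = 0)
  tr <- generate_trajectory(sc)
  perm <- c(A = "C", B = "D", C = "A", D = "B")
  tr2 <- tr
  tr2$atoms$chain <- unname(perm[tr2$atoms$chain])
  p1 <- aggregate_series(tr, frames = n_frames(tr))$partitions[[1]]
  p2 <- aggregate_series(tr2, frames = n_frames(tr))$partitions[[1]]
  mapped <- lapply(p1, function(x) sort(unname(perm[x])))
  expect_setequal(vapply(mapped, paste, "", collapse = ""),
                  vapply(lapply(p2, sort), paste, "", collapse = ""))
})

test_that("periodic contacts match a brute-force image search", {
  # place two chains across the periodic boundary
  a <- fixture_bent; a$atoms$chain <- "A"
  bcoords <- sweep(fixture_bent$coords, 2, c(14.8, 7.5, 7.5), "+")
  acoords <- sweep(fixture_bent$coords, 2, c(0.6, 7.5, 7.5), "+")
  atoms <- rbind(a$atoms,
                 transform(fixture_bent$atoms, chain = "B"))
  coords <- array(rbind(acoords, bcoords), c(2 * nrow(acoords), 3, 1))
  tr <- trajectory(coords, atoms, 0, 15, bombinin)
  for (cutoff in c(0.3, 0.5, 1.0, 2.0)) {
    adj <- chain_contact_graph(tr, 1, cutoff)
    brute <- FALSE
    for (i in seq_len(nrow(acoords))) {
      for (j in seq_len(nrow(bcoords))) {
        if (oracle_image_distance(acoords[i, ], bcoords[j, ],
                                  c(15, 15, 15)) < cutoff) brute <- TRUE
      }
      if (brute) break
    }
    expect_identical(unname(adj["A", "B"]), brute)
  }
})

test_that("neighbour lookup reports docked partners", {
  mg <- data.frame(time_ns = 5, a = "A", b = "B")
  sc <- scenario(n_chains = 3, duration_ns = 8, merges = mg,
                 noise_sigma_nm = 0)
  tr <- generate_trajectory(sc)
  expect_identical(neighbors_at_time(tr, "A", 8), "B")
  expect_identical(neighbors_at_time(tr, "C", 8), character(0))
  expect_identical(neighbors_at_time(tr, "A", 0), character(0))
  expect_error(neighbors_at_time(tr, "Z", 5), "unknown chain")
})

test_that("isolated monomers build no intermolecular contacts", {
  sc <- scenario(n_chains = 4, duration_ns = 2, noise_sigma_nm = 0)
  tr <- generate_trajectory(sc)
  contacts <- intermolecular_contacts(tr, state_series(tr))
  expect_true(all(contacts$mean_contacts == 0))
})

test_that("contacts localise to the docked interface residues", {
  # end-to-end dimer: C-terminus of A against the N-terminal region of B
  straight <- build_ideal_helix(bombinin, chain = "A")
  ca <- straight$coords[straight$atoms$name == "CA", ]
  axis <- svd(sweep(ca, 2, colMeans(ca)), nu = 0, nv = 1)$v[, 1]
  if (sum(axis * (ca[20, ] - ca[1, ])) < 0) axis <- -axis
  b <- build_ideal_helix(bombinin, chain = "B")
  b$coords <- sweep(straight$coords, 2, axis * 3.35, "+")
  tr <- conformations_to_trajectory(
    list(conformation(sweep(straight$coords, 2, rep(7.5, 3), "+"),
                      bombinin, "A"),
         conformation(sweep(b$coords, 2, rep(7.5, 3), "+"), bombinin, "B")))
  labels <- matrix("single-helix", 2, 1, dimnames = list(c("A", "B"), NULL))
  contacts <- intermolecular_contacts(tr, make_state_series(labels, 0), 0.5)
  touched <- contacts$residue[contacts$mean_contacts > 0]
  expect_true(length(touched) > 0)
  expect_true(all(touched >= 15 | touched <= 6))
  # deduplicated counts never exceed the atom-pair counts
  dedup <- intermolecular_contacts(tr, make_state_series(labels, 0), 0.5,
                                   dedup = TRUE)
  expect_true(all(dedup$mean_contacts <= contacts$mean_contacts))
})

test_that("contact means group by conformational state", {
  # same dimer geometry, but in 'single-helix' frames the partner sits closer,
  # giving more interface atom pairs
  base <- build_ideal_helix(bombinin)
  mk_frame <- function(gap) {
    a <- conformation(sweep(base$coords, 2, c(5, 7.5, 7.5), "+"),
                      bombinin, "A")
    b <- conformation(sweep(base$coords, 2, c(5, 7.5 + gap, 7.5), "+"),
                      bombinin, "B")
    conformations_to_trajectory(list(a, b))
  }
  frames <- list(mk_frame(1.0), mk_frame(1.0), mk_frame(0.85), mk_frame(0.85))
  coords <- array(NA_real_, c(dim(frames[[1]]$coords)[1], 3, 4))
  for (f in 1:4) coords[, , f] <- frames[[f]]$coords[, , 1]
  tr <- trajectory(coords, frames[[1]]$atoms, 0:3, 15, bombinin)
  labels <- matrix(rep(c("helix-loop-helix", "single-helix"), each = 2),
                   2, 4, byrow = TRUE,
                   dimnames = list(c("A", "B"), NULL))
  labels[2, ] <- labels[1, ]   # both chains share the schedule
  contacts <- intermolecular_contacts(tr, make_state_series(labels, 0:3), 0.6)
  sh <- contacts[contacts$state == "single-helix", ]
  hl <- contacts[contacts$state == "helix-loop-helix", ]
  interface <- sh$residue[sh$mean_contacts > 0]
  expect_true(length(interface) > 0)
  expect_true(all(sh$mean_contacts[sh$residue %in% interface] >=
                    hl$mean_contacts[hl$residue %in% interface]))
  expect_gt(sum(sh$mean_contacts), sum(hl$mean_contacts))
})

test_that("state/frame misalignment is rejected", {
  sc <- scenario(n_chains = 2, duration_ns = 3, noise_sigma_nm = 0)
  tr <- generate_trajectory(sc)
  labels <- matrix("single-helix", 2, 2, dimnames = list(c("A", "B"), NULL))
  expect_error(intermolecular_contacts(tr, make_state_series(labels, 0:1)),
               "align")
})
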