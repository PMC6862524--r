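# Shared fixtures, all generated in code.

bombinin <- parse_sequence("IIGPVLGLVGSALGGLLKKI", name = "bombinin H2")

fixture_helix <- build_ideal_helix(bombinin)
fixture_bent <- build_bent_conformer(fixture_helix, c(10, 11), 120)
fixture_extended <- build_backbone(bombinin, -120, 120)

# two-basin frame set for clustering / projection tests: n1 frames jittering
# around the straight template, n2 around the bent one (backbone N/CA/C)
two_basin_frames <- function(n1 = 20, n2 = 20, sigma = 0.02, seed = 5) {
  set.seed(seed)
  sel <- fixture_helix$atoms$name %in% c("N", "CA", "C")
  a <- fixture_helix$coords[sel, ]
  b <- fixture_bent$coords[sel, ]
  frames <- c(
    lapply(seq_len(n1), function(i) a + matrix(rnorm(length(a), 0, sigma),
                                               ncol = 3)),
    lapply(seq_len(n2), function(i) b + matrix(rnorm(length(b), 0, sigma),
                                               ncol = 3))
  )
  labels <- rep(c("straight", "bent"), c(n1, n2))
  ord <- sample(length(frames))
  list(frames = frames[ord], labels = labels[ord])
}

# combine single-chain trajectories (same frame count and box) into one
# multi-chain trajectory with fresh chain ids
merge_trajectories <- function(trajs, ids) {
  stopifnot(length(trajs) == length(ids))
  nf <- n_frames(trajs[[1]])
  atoms <- do.call(rbind, lapply(seq_along(trajs), function(i) {
    a <- trajs[[i]]$atoms
    a$chain <- ids[i]
    a
  }))
  coords <- array(NA_real_, c(nrow(atoms), 3L, nf))
  at <- 0L
  for (tr in trajs) {
    n <- dim(tr$coords)[1]
    coords[(at + 1):(at + n), , ] <- tr$coords
    at <- at + n
  }
  trajectory(coords, atoms, trajs[[1]]$times, trajs[[1]]$box,
             trajs[[1]]$sequence)
}

# one-frame trajectory from a list of conformations (distinct chains)
conformations_to_trajectory <- function(confs, box = 15, time = 0) {
  atoms <- do.call(rbind, lapply(confs, function(cf) cf$atoms))
  coords <- array(do.call(rbind, lapply(confs, function(cf) cf$coords)),
                  dim = c(nrow(atoms), 3L, 1L))
  trajectory(coords, atoms, time, box, confs[[1]]$sequence)
}

# hand-built state series
make_state_series <- function(labels, times) {
  structure(list(labels = labels, times = times, chains = rownames(labels)),
            class = "state_series")
}

table1_scenario <- function(duration_ns = 2000, noise = 0) {
  tb <- bombinin_transitions()
  scenario(duration_ns = duration_ns,
           straightenings = data.frame(time_ns = tb$time_ns,
                                       chain = tb$chain),
           noise_sigma_nm = noise)
}
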