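# Trajectory container and the kinematic multi-chain generator.
#
# The generator is not a physics simulator: it emulates the observable
# structure of a self-association trajectory — chains start on a cubic grid,
# scripted merge events bring whole aggregates into contact along their
# centre-of-mass line, scripted straightening events switch a chain from the
# hinge-bent helix-loop-helix template to the straight single-helix template
# (superposed in place), and i.i.d. Gaussian positional noise models thermal
# jitter. Every event is recorded in a ground-truth ledger so detectors can
# be validated against the exact schedule.

#' Trajectory constructor
#'
#' @param coords natoms x 3 x nframes array (nm), atoms ordered as in
#'   \code{atoms}.
#' @param atoms data.frame with columns chain, residue, resname, name, mass.
#' @param times frame time stamps in ns, strictly increasing.
#' @param box box edge lengths in nm (scalar or length 3).
#' @param seq the \code{peptide_sequence} shared by all chains.
#' @return object of class \code{trajectory}.
#' @export
trajectory <- function(coords, atoms, times, box, seq) {
  if (length(box) == 1L) box <- rep(box, 3L)
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("coords must be an natoms x 3 x nframes array")
  }
  if (dim(coords)[1] != nrow(atoms)) stop("coords/atoms size mismatch")
  if (dim(coords)[3] != length(times)) stop("coords/times size mismatch")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  structure(list(coords = coords, atoms = atoms, times = as.numeric(times),
                 box = as.numeric(box), sequence = seq),
            class = "trajectory")
}

#' Number of frames in a trajectory
#' @param traj a \code{trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Chain identifiers of a trajectory
#' @param traj a \code{trajectory}.
#' @return character vector of chain ids, in atom-table order.
#' @export
trajectory_chains <- function(traj) unique(traj$atoms$chain)

#' Extract one chain of one frame as a conformation
#' @param traj a \code{trajectory}.
#' @param chain chain identifier.
#' @param frame frame index (1-based).
#' @return a \code{conformation}.
#' @export
get_conformation <- function(traj, chain, frame = 1L) {
  idx <- which(traj$atoms$chain == chain)
  if (length(idx) == 0L) stop("unknown chain: ", chain)
  conformation(traj$coords[idx, , frame], traj$sequence, chain)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d chains, %d atoms, %d frames (%.4g to %.4g ns), box %s nm\n",
    length(trajectory_chains(x)), dim(x$coords)[1], n_frames(x),
    min(x$times), max(x$times), paste(format(x$box), collapse = " x ")))
  invisible(x)
}

#' Chain identifiers used for multi-chain systems
#'
#' Uppercase letters followed by lowercase letters, matching the labelling
#' convention of multi-copy peptide simulations (chain 27 is \code{"a"}).
#'
#' @param n number of chains (<= 52).
#' @return character vector of length \code{n}.
#' @export
chain_ids <- function(n) {
  if (n > 52L) stop("at most 52 chains supported")
  c(LETTERS, letters)[seq_len(n)]
}

#' Define a multi-chain scenario
#'
#' Defaults reproduce the study conditions: 27 copies of the 20-residue
#' peptide in a 15 nm cubic periodic box on a 5 nm grid. Events are scripted:
#' \code{merges} brings the aggregates containing two named chains into
#' contact at the stated time; \code{straightenings} switches a named chain
#' from the bent to the straight conformer at the stated time.
#'
#' @param seq a \code{peptide_sequence}; default the bombinin H2 sequence.
#' @param n_chains number of chains.
#' @param box_nm cubic box edge (nm).
#' @param spacing_nm initial grid spacing (nm).
#' @param frame_interval_ns time between recorded frames (ns).
#' @param duration_ns total duration (ns); frames at 0, dt, ..., duration.
#' @param merges data.frame(time_ns, a, b) of merge events (chain ids name
#'   the aggregates containing them); times must be distinct and within the
#'   duration.
#' @param straightenings data.frame(time_ns, chain) of straightening events.
#' @param noise_sigma_nm standard deviation of the i.i.d. Gaussian positional
#'   noise added per atom coordinate per frame (nm).
#' @param bend_angle_deg bend angle of the helix-loop-helix template.
#' @param hinge hinge residue pair of the bent template.
#' @param orientation_deg optional named list: initial rotation of each chain,
#'   either a single angle (degrees, about the template helix axis x) or a
#'   length-3 vector of successive rotations about the x, y and z axes
#'   (degrees); chains not named get no rotation.
#' @param dock_gap_nm inter-aggregate minimum atom distance right after a
#'   merge; must be below the contact cutoff used in analysis.
#' @param standoff_gap_nm gap one frame before the merge completes.
#' @param rigid_diffusion_sigma_nm per-frame random-walk displacement shared
#'   by all chains of an aggregate (nm); 0 disables.
#' @param seed integer random seed.
#' @return object of class \code{scenario}.
#' @export
scenario <- function(seq = parse_sequence("IIGPVLGLVGSALGGLLKKI",
                                          name = "bombinin H2"),
                     n_chains = 27L,
                     box_nm = 15,
                     spacing_nm = 5,
                     frame_interval_ns = 1,
                     duration_ns = 100,
                     merges = NULL,
                     straightenings = NULL,
                     noise_sigma_nm = 0.005,
                     bend_angle_deg = 120,
                     hinge = c(10, 11),
                     orientation_deg = NULL,
                     dock_gap_nm = 0.35,
                     standoff_gap_nm = 1.0,
                     rigid_diffusion_sigma_nm = 0,
                     seed = 1L) {
  per_edge <- ceiling(n_chains^(1 / 3))
  if (spacing_nm * (per_edge - 1L) >= box_nm) {
    stop("grid spacing too large for the box")
  }
  check_events <- function(ev, cols) {
    if (is.null(ev) || nrow(ev) == 0L) {
      return(stats::setNames(
        as.data.frame(replicate(length(cols), vector(
          if (cols[1] == "time_ns") "numeric" else "character", 0),
          simplify = FALSE)), cols))
    }
    stopifnot(all(cols %in% names(ev)))
    if (any(ev$time_ns < 0 | ev$time_ns > duration_ns)) {
      stop("event times must lie within [0, duration]")
    }
    ev[order(ev$time_ns), cols, drop = FALSE]
  }
  merges <- check_events(merges, c("time_ns", "a", "b"))
  if (anyDuplicated(merges$time_ns)) stop("merge times must be distinct")
  straightenings <- check_events(straightenings, c("time_ns", "chain"))
  ids <- chain_ids(n_chains)
  ev_chains <- c(merges$a, merges$b, straightenings$chain)
  if (length(ev_chains) && !all(ev_chains %in% ids)) {
    stop("event references unknown chain: ",
         paste(setdiff(ev_chains, ids), collapse = ", "))
  }
  structure(list(
    seq = seq, n_chains = as.integer(n_chains), box_nm = box_nm,
    spacing_nm = spacing_nm, frame_interval_ns = frame_interval_ns,
    duration_ns = duration_ns, merges = merges,
    straightenings = straightenings, noise_sigma_nm = noise_sigma_nm,
    bend_angle_deg = bend_angle_deg, hinge = hinge,
    orientation_deg = orientation_deg, dock_gap_nm = dock_gap_nm,
    standoff_gap_nm = standoff_gap_nm,
    rigid_diffusion_sigma_nm = rigid_diffusion_sigma_nm,
    seed = as.integer(seed)
  ), class = "scenario")
}

# initial chain orientation: scalar = spin about the template helix axis (x);
# length 3 = successive rotations about x, y, z (degrees)
.orient <- function(xyz, ang) {
  ang <- rep(as.numeric(ang), length.out = if (length(ang) == 1L) 1L else 3L)
  if (length(ang) == 1L) ang <- c(ang, 0, 0)
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (k in 1:3) {
    if (ang[k] != 0) {
      xyz <- xyz %*% t(.rotation_matrix(axes[[k]], .deg2rad(ang[k])))
    }
  }
  xyz
}

# minimum inter-set atom distance when set B is translated by s along d
.gap_at <- function(A, B, d, s) {
  Bs <- sweep(B, 2, s * d, "+")
  d2 <- outer(rowSums(A^2), rowSums(Bs^2), "+") - 2 * tcrossprod(A, Bs)
  sqrt(max(0, min(d2)))
}

#' Generate a scripted multi-chain trajectory
#'
#' Frame 0 places all chains, in the bent template, on a cubic grid at the
#' scenario spacing. Each merge event translates the aggregate containing
#' chain \code{b} along the centre-of-mass line towards the aggregate
#' containing chain \code{a}: it approaches at constant velocity to a
#' standoff gap one frame before the event and docks to the scenario dock gap
#' at the event time, after which the merged aggregate moves as one body.
#' Each straightening event replaces the named chain by the straight
#' conformer, superposed on its location at that moment. Gaussian noise of
#' the scenario sigma is then added independently per atom and frame. The
#' generation is fully deterministic for a fixed seed, and the exact event
#' schedule is attached as the ground-truth ledger.
#'
#' @param sc a \code{scenario}.
#' @return a \code{trajectory} with attributes \code{ledger} (data.frame:
#'   event, time_ns, chains) and \code{scenario}.
#' @export
generate_trajectory <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  set.seed(sc$seed)
  ids <- chain_ids(sc$n_chains)
  dt <- sc$frame_interval_ns
  times <- seq(0, sc$duration_ns, by = dt)
  nf <- length(times)

  straight <- build_ideal_helix(sc$seq)
  bent <- build_bent_conformer(straight, sc$hinge, sc$bend_angle_deg)
  nat <- nrow(bent$coords)

  # grid placement, x fastest, grid centred in the box
  per_edge <- ceiling(sc$n_chains^(1 / 3))
  start <- (sc$box_nm - sc$spacing_nm * (per_edge - 1)) / 2
  site <- function(k) {
    k0 <- k - 1L
    start + sc$spacing_nm *
      c(k0 %% per_edge, (k0 %/% per_edge) %% per_edge,
        k0 %/% (per_edge * per_edge))
  }

  # per-chain template coordinates in the box frame (conformer + placement)
  conf <- vector("list", sc$n_chains); names(conf) <- ids
  place <- function(k) {
    xyz <- bent$coords
    if (!is.null(sc$orientation_deg) && ids[k] %in% names(sc$orientation_deg)) {
      xyz <- .orient(xyz, sc$orientation_deg[[ids[k]]])
    }
    sweep(xyz, 2, site(k), "+")
  }
  for (k in seq_along(ids)) conf[[k]] <- place(k)

  # piecewise-linear translation schedule per chain: breakpoints (t, 3-vec)
  sched <- lapply(ids, function(i) list(t = 0, o = matrix(0, 1, 3)))
  names(sched) <- ids
  add_bp <- function(s, t, o) {
    s$t <- c(s$t, t); s$o <- rbind(s$o, o); s
  }
  offset_at <- function(s, t) {
    if (t >= s$t[length(s$t)]) return(s$o[length(s$t), ])
    i <- findInterval(t, s$t)
    w <- (t - s$t[i]) / (s$t[i + 1] - s$t[i])
    (1 - w) * s$o[i, ] + w * s$o[i + 1, ]
  }

  members <- as.list(ids)               # aggregates as chain-id sets
  agg_of <- stats::setNames(seq_along(ids), ids)
  last_event <- stats::setNames(rep(0, sc$n_chains), ids)

  # process merges and straightenings jointly in time order so that docking
  # geometry sees the conformers current at the event time
  events <- rbind(
    if (nrow(sc$merges)) data.frame(time_ns = sc$merges$time_ns,
                                    kind = "merge", a = sc$merges$a,
                                    b = sc$merges$b,
                                    stringsAsFactors = FALSE),
    if (nrow(sc$straightenings)) data.frame(
      time_ns = sc$straightenings$time_ns, kind = "straighten",
      a = sc$straightenings$chain, b = NA_character_,
      stringsAsFactors = FALSE)
  )
  if (!is.null(events)) events <- events[order(events$time_ns), , drop = FALSE]

  chain_coords_at <- function(ch, t) {
    sweep(conf[[ch]], 2, offset_at(sched[[ch]], t), "+")
  }

  if (!is.null(events) && nrow(events)) {
    for (e in seq_len(nrow(events))) {
      t_ev <- events$time_ns[e]
      if (events$kind[e] == "straighten") {
        ch <- events$a[e]
        cur <- chain_coords_at(ch, t_ev)
        tr <- kabsch_superpose(straight$coords, cur)
        conf[[ch]] <- sweep(apply_transform(straight$coords, tr), 2,
                            offset_at(sched[[ch]], t_ev))
        next
      }
      ia <- agg_of[[events$a[e]]]; ib <- agg_of[[events$b[e]]]
      if (ia == ib) stop("merge event joins chains already aggregated: ",
                         events$a[e], "+", events$b[e])
      A <- do.call(rbind, lapply(members[[ia]], chain_coords_at, t = t_ev))
      B <- do.call(rbind, lapply(members[[ib]], chain_coords_at, t = t_ev))
      d <- colMeans(A) - colMeans(B)
      dlen <- sqrt(sum(d^2)); d <- d / dlen
      gap0 <- .gap_at(A, B, d, 0)
      if (gap0 <= sc$dock_gap_nm) stop("aggregates already in contact at merge")
      root <- function(target) {
        stats::uniroot(function(s) .gap_at(A, B, d, s) - target,
                       lower = 0, upper = dlen, tol = 1e-8)$root
      }
      s_dock <- root(sc$dock_gap_nm)
      t_start <- max(last_event[members[[ib]]])
      for (ch in members[[ib]]) {
        o0 <- offset_at(sched[[ch]], t_ev)   # constant since t_start
        if (gap0 > sc$standoff_gap_nm && t_ev - dt > t_start) {
          s_stand <- root(sc$standoff_gap_nm)
          sched[[ch]] <- add_bp(sched[[ch]], t_start, o0)
          sched[[ch]] <- add_bp(sched[[ch]], t_ev - dt, o0 + s_stand * d)
        }
        sched[[ch]] <- add_bp(sched[[ch]], t_ev, o0 + s_dock * d)
      }
      # overlap check against all other aggregates
      Bdock <- sweep(B, 2, s_dock * d, "+")
      others <- setdiff(seq_along(members)[!vapply(members, is.null, TRUE)],
                        c(ia, ib))
      for (io in others) {
        O <- do.call(rbind, lapply(members[[io]], chain_coords_at, t = t_ev))
        if (.gap_at(O, Bdock, c(1, 0, 0), 0) < 0.1) {
          stop("infeasible packing: merged aggregate overlaps another")
        }
      }
      members[[ia]] <- c(members[[ia]], members[[ib]])
      members[[ib]] <- NULL
      members <- members[!vapply(members, is.null, TRUE)]
      agg_of <- stats::setNames(rep(seq_along(members),
                                    lengths(members)), unlist(members))
      agg_of <- agg_of[ids[ids %in% names(agg_of)]]
      last_event[members[[agg_of[[events$a[e]]]]]] <- t_ev
    }
  }

  # frame assembly uses a fresh template set switched chronologically (the
  # first pass mutated conf[] only so that docking geometry at later merges
  # sees already-straightened chains)
  conf2 <- vector("list", sc$n_chains); names(conf2) <- ids
  for (k in seq_along(ids)) conf2[[k]] <- place(k)
  st <- sc$straightenings
  straighten_time <- stats::setNames(rep(Inf, sc$n_chains), ids)
  if (nrow(st)) straighten_time[st$chain] <- st$time_ns

  atoms <- do.call(rbind, lapply(ids, function(ch) .chain_atoms(sc$seq, ch)))
  rownames(atoms) <- NULL
  coords <- array(NA_real_, c(nat * sc$n_chains, 3L, nf))

  switched <- stats::setNames(rep(FALSE, sc$n_chains), ids)
  # rigid-body diffusion state (shared within an aggregate, resampled by
  # membership at each frame)
  diff_off <- matrix(0, sc$n_chains, 3L, dimnames = list(ids, NULL))
  part_sched <- .partition_schedule(ids, sc$merges)

  for (f in seq_len(nf)) {
    t <- times[f]
    if (sc$rigid_diffusion_sigma_nm > 0) {
      part <- part_sched(t)
      for (grp in part) {
        step <- stats::rnorm(3, 0, sc$rigid_diffusion_sigma_nm)
        diff_off[grp, ] <- sweep(diff_off[grp, , drop = FALSE], 2, step, "+")
      }
    }
    for (k in seq_along(ids)) {
      ch <- ids[k]
      if (!switched[ch] && t >= straighten_time[ch]) {
        cur <- sweep(conf2[[ch]], 2, offset_at(sched[[ch]], straighten_time[ch]),
                     "+")
        tr <- kabsch_superpose(straight$coords, cur)
        conf2[[ch]] <- sweep(apply_transform(straight$coords, tr), 2,
                             offset_at(sched[[ch]], straighten_time[ch]))
        switched[ch] <- TRUE
      }
      xyz <- sweep(conf2[[ch]], 2, offset_at(sched[[ch]], t) + diff_off[ch, ],
                   "+")
      coords[((k - 1) * nat + 1):(k * nat), , f] <- xyz
    }
    if (sc$noise_sigma_nm > 0) {
      coords[, , f] <- coords[, , f] +
        stats::rnorm(nat * sc$n_chains * 3L, 0, sc$noise_sigma_nm)
    }
  }

  traj <- trajectory(coords, atoms, times, sc$box_nm, sc$seq)
  ledger <- rbind(
    if (nrow(sc$merges)) data.frame(event = "merge",
                                    time_ns = sc$merges$time_ns,
                                    chains = paste(sc$merges$a, sc$merges$b,
                                                   sep = "+"),
                                    stringsAsFactors = FALSE),
    if (nrow(st)) data.frame(event = "straighten", time_ns = st$time_ns,
                             chains = st$chain, stringsAsFactors = FALSE)
  )
  if (is.null(ledger)) {
    ledger <- data.frame(event = character(), time_ns = numeric(),
                         chains = character(), stringsAsFactors = FALSE)
  } else {
    ledger <- ledger[order(ledger$time_ns), , drop = FALSE]
    rownames(ledger) <- NULL
  }
  attr(traj, "ledger") <- ledger
  attr(traj, "scenario") <- sc
  traj
}

# closure returning the aggregate partition implied by the merge schedule at
# a given time (ground truth, independent of coordinates)
.partition_schedule <- function(ids, merges) {
  function(t) {
    parent <- stats::setNames(ids, ids)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    if (nrow(merges)) {
      for (e in which(merges$time_ns <= t)) {
        ra <- find(merges$a[e]); rb <- find(merges$b[e])
        if (ra != rb) parent[[rb]] <- ra
      }
    }
    split(ids, vapply(ids, find, ""))
  }
}

#' Single-chain bend-sweep trajectory
#'
#' One chain whose bend angle follows a prescribed schedule, with optional
#' positional noise — the canonical fixture for essential-dynamics analyses
#' of the straightening/bending motion.
#'
#' @param seq a \code{peptide_sequence}.
#' @param angles_deg bend angle per frame (degrees).
#' @param hinge hinge residue pair.
#' @param noise_sigma_nm Gaussian positional noise sigma (nm).
#' @param frame_interval_ns frame spacing (ns).
#' @param box_nm box edge (nm).
#' @param seed random seed (used only when noise > 0).
#' @return a \code{trajectory} with one chain.
#' @export
bend_sweep_trajectory <- function(seq, angles_deg, hinge = c(10, 11),
                                  noise_sigma_nm = 0, frame_interval_ns = 1,
                                  box_nm = 15, seed = 1L) {
  set.seed(seed)
  straight <- build_ideal_helix(seq)
  nat <- nrow(straight$coords)
  nf <- length(angles_deg)
  coords <- array(NA_real_, c(nat, 3L, nf))
  centre <- rep(box_nm / 2, 3)
  for (f in seq_len(nf)) {
    cf <- build_bent_conformer(straight, hinge, angles_deg[f])
    xyz <- sweep(cf$coords, 2, centre, "+")
    if (noise_sigma_nm > 0) {
      xyz <- xyz + stats::rnorm(nat * 3L, 0, noise_sigma_nm)
    }
    coords[, , f] <- xyz
  }
  trajectory(coords, .chain_atoms(seq, "A"),
             seq(0, by = frame_interval_ns, length.out = nf), box_nm, seq)
}

#' Peptide concentration of a multi-chain box
#'
#' @param n_chains number of peptide copies.
#' @param box_nm cubic box edge length (nm).
#' @return concentration in mM.
#' @export
box_concentration_mM <- function(n_chains, box_nm) {
  avogadro <- 6.02214076e23
  litres <- (box_nm * 1e-8)^3           # edge nm -> dm; volume in L
  1000 * n_chains / (avogadro * litres)
}

#' Helix-straightening schedule of the bombinin H2 multi-chain study
#'
#' The nine per-chain transition times from the compact helix-loop-helix to
#' the linear single-helix state, with the neighbour chains within 0.5 nm at
#' the transition moment and the size of the containing oligomer. These
#' printed values serve as inputs for reconstruction scenarios.
#'
#' @return data.frame with columns \code{chain}, \code{time_ns},
#'   \code{neighbours}, \code{aggregate}.
#' @export
bombinin_transitions <- function() {
  data.frame(
    chain = c("A", "B", "D", "E", "F", "J", "V", "W", "a"),
    time_ns = c(903, 917, 931, 735, 404, 1516, 25, 70, 22),
    neighbours = c("E, F, M, W, Y", "G, H, K, N, P, S, Z", "H, O, P",
                   "A, K, M, R, S, T", "A, C, E, I, M, R, U, W, Y",
                   "N, U, V, a", "a", "A, F, Y", "V"),
    aggregate = c("27-mer", "27-mer", "27-mer", "27-mer", "19-mer",
                  "27-mer", "Dimer", "Tetramer", "Dimer"),
    stringsAsFactors = FALSE
  )
}
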