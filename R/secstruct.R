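# Helix assignment and conformational-state classification.
#
# A dihedral-window criterion stands in for hydrogen-bond-based assigners:
# a residue is helical when (phi, psi) fall in the alpha region and it is
# part of a run of at least `min_run` such residues. The peptide state is
# decided on a fixed residue span (default 5..17, the well-structured core):
# fully helical span -> single-helix; two helical segments separated by a
# break -> helix-loop-helix; anything else -> disordered.

# signed torsion angle (degrees) for row-matched point matrices
.torsion <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
              b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
              b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
              b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
              b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  m1 <- cbind(n1[, 2] * b2[, 3] - n1[, 3] * b2[, 2],
              n1[, 3] * b2[, 1] - n1[, 1] * b2[, 3],
              n1[, 1] * b2[, 2] - n1[, 2] * b2[, 1])
  b2n <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2) / b2n
  # IUPAC sign convention (clockwise positive viewed from b towards c)
  -.rad2deg(atan2(y, x))
}

#' Backbone dihedral angles
#'
#' @param conf a \code{conformation}.
#' @return data.frame with columns \code{residue}, \code{phi}, \code{psi}
#'   (degrees); \code{phi} is NA for the first residue and \code{psi} for the
#'   last.
#' @export
backbone_dihedrals <- function(conf) {
  stopifnot(inherits(conf, "conformation"))
  N <- .atom_coords(conf, "N"); CA <- .atom_coords(conf, "CA")
  C <- .atom_coords(conf, "C")
  n <- nrow(CA)
  if (nrow(N) != n || nrow(C) != n) stop("incomplete backbone")
  phi <- c(NA_real_,
           .torsion(C[-n, , drop = FALSE], N[-1, , drop = FALSE],
                    CA[-1, , drop = FALSE], C[-1, , drop = FALSE]))
  psi <- c(.torsion(N[-n, , drop = FALSE], CA[-n, , drop = FALSE],
                    C[-n, , drop = FALSE], N[-1, , drop = FALSE]),
           NA_real_)
  data.frame(residue = seq_len(n), phi = phi, psi = psi)
}

#' Per-residue helix assignment
#'
#' A residue is helical iff its backbone dihedrals fall inside the
#' alpha-helical window (phi in [-100, -30], psi in [-80, -5] degrees) and it
#' belongs to a run of at least \code{min_run} consecutive such residues.
#' Terminal residues, lacking a dihedral, are never helical.
#'
#' @param conf a \code{conformation}.
#' @param phi_range,psi_range numeric length-2 windows in degrees.
#' @param min_run minimum run length of in-window residues.
#' @return logical vector, one entry per residue.
#' @export
assign_helix <- function(conf, phi_range = c(-100, -30),
                         psi_range = c(-80, -5), min_run = 4L) {
  dh <- backbone_dihedrals(conf)
  ok <- !is.na(dh$phi) & !is.na(dh$psi) &
    dh$phi >= phi_range[1] & dh$phi <= phi_range[2] &
    dh$psi >= psi_range[1] & dh$psi <= psi_range[2]
  r <- rle(ok)
  r$values <- r$values & r$lengths >= min_run
  inverse.rle(r)
}

#' Classify the conformational state of a chain
#'
#' Over the classification span (default residues 5..17): all residues
#' helical gives \code{"single-helix"}; at least two helical runs of length
#' >= \code{min_segment} separated by a non-helical break gives
#' \code{"helix-loop-helix"}; anything else is \code{"disordered"}.
#'
#' @param conf a \code{conformation}.
#' @param span residue index range used for the call, default \code{c(5, 17)}.
#' @param min_segment minimum helical-run length for the two-segment test.
#' @param ... passed to \code{\link{assign_helix}}.
#' @return one of \code{"single-helix"}, \code{"helix-loop-helix"},
#'   \code{"disordered"}.
#' @export
classify_state <- function(conf, span = c(5, 17), min_segment = 3L, ...) {
  n <- length(conf$sequence$residues)
  if (n < span[2]) stop("chain shorter than the classification span")
  hel <- assign_helix(conf, ...)
  win <- hel[span[1]:span[2]]
  if (all(win)) return("single-helix")
  r <- rle(win)
  runs <- r$lengths[r$values]
  if (sum(runs >= min_segment) >= 2L && any(!win)) {
    return("helix-loop-helix")
  }
  "disordered"
}

# classification core working directly on N/CA/C coordinate matrices
.classify_backbone <- function(N, CA, C, span, min_segment, phi_range,
                               psi_range, min_run) {
  n <- nrow(CA)
  phi <- c(NA_real_,
           .torsion(C[-n, , drop = FALSE], N[-1, , drop = FALSE],
                    CA[-1, , drop = FALSE], C[-1, , drop = FALSE]))
  psi <- c(.torsion(N[-n, , drop = FALSE], CA[-n, , drop = FALSE],
                    C[-n, , drop = FALSE], N[-1, , drop = FALSE]),
           NA_real_)
  ok <- !is.na(phi) & !is.na(psi) &
    phi >= phi_range[1] & phi <= phi_range[2] &
    psi >= psi_range[1] & psi <= psi_range[2]
  r <- rle(ok)
  r$values <- r$values & r$lengths >= min_run
  hel <- inverse.rle(r)
  win <- hel[span[1]:span[2]]
  if (all(win)) return("single-helix")
  rw <- rle(win)
  if (sum(rw$lengths[rw$values] >= min_segment) >= 2L && any(!win)) {
    return("helix-loop-helix")
  }
  "disordered"
}

#' Per-chain, per-frame conformational state series
#'
#' @param traj a \code{trajectory}.
#' @param span,min_segment as in \code{\link{classify_state}}.
#' @param phi_range,psi_range,min_run as in \code{\link{assign_helix}}.
#' @return object of class \code{state_series}: list with \code{labels}
#'   (chains x frames character matrix), \code{times} (ns), \code{chains}.
#' @export
state_series <- function(traj, span = c(5, 17), min_segment = 3L,
                         phi_range = c(-100, -30), psi_range = c(-80, -5),
                         min_run = 4L) {
  stopifnot(inherits(traj, "trajectory"))
  chains <- trajectory_chains(traj)
  nf <- n_frames(traj)
  if (length(traj$sequence$residues) < span[2]) {
    stop("chain shorter than the classification span")
  }
  labels <- matrix(NA_character_, length(chains), nf,
                   dimnames = list(chains, NULL))
  for (ci in seq_along(chains)) {
    in_chain <- traj$atoms$chain == chains[ci]
    iN <- which(in_chain & traj$atoms$name == "N")
    iCA <- which(in_chain & traj$atoms$name == "CA")
    iC <- which(in_chain & traj$atoms$name == "C")
    for (f in seq_len(nf)) {
      labels[ci, f] <- .classify_backbone(
        traj$coords[iN, , f], traj$coords[iCA, , f], traj$coords[iC, , f],
        span, min_segment, phi_range, psi_range, min_run)
    }
  }
  structure(list(labels = labels, times = traj$times, chains = chains),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf("state_series: %d chains x %d frames (%.4g to %.4g ns)\n",
              nrow(x$labels), ncol(x$labels), min(x$times), max(x$times)))
  print(table(x$labels))
  invisible(x)
}

#' Windowed state occupancy
#'
#' Fraction of frames carrying a given state, per chain, in consecutive time
#' windows \code{[k w, (k+1) w)}. A final partial window is reported with its
#' own frame count.
#'
#' @param series a \code{state_series}.
#' @param state state label to score, default \code{"single-helix"}.
#' @param window_ns window length in ns.
#' @return data.frame with columns \code{chain}, \code{window_start_ns},
#'   \code{window_end_ns}, \code{n_frames}, \code{occupancy}.
#' @export
occupancy_windows <- function(series, state = "single-helix",
                              window_ns = 10) {
  stopifnot(inherits(series, "state_series"))
  if (length(series$times) == 0L) stop("empty state series")
  if (window_ns <= 0) stop("window_ns must be positive")
  bin <- floor(series$times / window_ns)
  bins <- sort(unique(bin))
  out <- lapply(rownames(series$labels), function(ch) {
    hits <- series$labels[ch, ] == state
    data.frame(
      chain = ch,
      window_start_ns = bins * window_ns,
      window_end_ns = (bins + 1) * window_ns,
      n_frames = as.integer(tapply(hits, bin, length)[as.character(bins)]),
      occupancy = as.numeric(tapply(hits, bin, mean)[as.character(bins)]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
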