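# Aggregate detection on the chain contact graph under periodic boundaries.
#
# Two chains are adjacent when any inter-chain atom pair lies within the
# contact cutoff under the minimum-image convention; aggregates are the
# connected components of this graph. A centroid/radius pre-filter keeps the
# per-frame cost low for well-separated chains.

# chain index bookkeeping for a trajectory
.chain_index <- function(traj) {
  chains <- trajectory_chains(traj)
  stats::setNames(lapply(chains, function(ch) which(traj$atoms$chain == ch)),
                  chains)
}

# minimum-image displacement of a coordinate matrix pair, all pairs
.pairwise_min_image_d2 <- function(A, B, box) {
  total <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    d <- outer(A[, k], B[, k], "-")
    d <- d - box[k] * round(d / box[k])
    total <- total + d * d
  }
  total
}

#' Chain contact adjacency of one frame
#'
#' @param traj a \code{trajectory}.
#' @param frame frame index.
#' @param cutoff_nm contact cutoff (nm), default 0.5 (the 5 Angstrom
#'   neighbour criterion).
#' @return symmetric logical adjacency matrix over chains (diagonal FALSE).
#' @export
chain_contact_graph <- function(traj, frame = 1L, cutoff_nm = 0.5) {
  stopifnot(inherits(traj, "trajectory"))
  if (cutoff_nm <= 0) stop("cutoff must be positive")
  idx <- .chain_index(traj)
  chains <- names(idx)
  nc <- length(chains)
  box <- traj$box
  xyz <- traj$coords[, , frame]
  centroid <- t(vapply(idx, function(i) colMeans(xyz[i, , drop = FALSE]),
                       numeric(3)))
  radius <- vapply(seq_len(nc), function(c) {
    sqrt(max(rowSums(sweep(xyz[idx[[c]], , drop = FALSE], 2,
                           centroid[c, ])^2)))
  }, 0)
  adj <- matrix(FALSE, nc, nc, dimnames = list(chains, chains))
  if (nc < 2L) return(adj)
  for (i in seq_len(nc - 1L)) {
    for (j in (i + 1L):nc) {
      cd <- min_image_distance(centroid[i, ], centroid[j, ], box)
      if (cd > radius[i] + radius[j] + cutoff_nm) next
      d2 <- .pairwise_min_image_d2(xyz[idx[[i]], , drop = FALSE],
                                   xyz[idx[[j]], , drop = FALSE], box)
      if (min(d2) < cutoff_nm^2) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  adj
}

# connected components of an adjacency matrix -> list of chain-id vectors
.components <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  unname(split(rownames(adj), comp$membership))
}

#' Aggregate time series of a trajectory
#'
#' Connected components of the chain contact graph per frame, with the
#' derived aggregate-count and maximal-size series.
#'
#' @param traj a \code{trajectory}.
#' @param cutoff_nm contact cutoff (nm).
#' @param frames frame indices (default all).
#' @return object of class \code{aggregate_series}: list with \code{summary}
#'   (data.frame: frame, time_ns, n_aggregates, max_size, membership — the
#'   partition as e.g. \code{"AB|C"}) and \code{partitions} (list of lists of
#'   chain-id vectors).
#' @export
aggregate_series <- function(traj, cutoff_nm = 0.5, frames = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  partitions <- lapply(frames, function(f) {
    comps <- .components(chain_contact_graph(traj, f, cutoff_nm))
    comps[order(-lengths(comps),
                vapply(comps, function(x) sort(x)[1], ""))]
  })
  summary <- data.frame(
    frame = frames,
    time_ns = traj$times[frames],
    n_aggregates = lengths(partitions),
    max_size = vapply(partitions, function(p) max(lengths(p)), 0L),
    membership = vapply(partitions, function(p) {
      paste(vapply(p, function(x) paste(sort(x), collapse = ""), ""),
            collapse = "|")
    }, ""),
    stringsAsFactors = FALSE
  )
  structure(list(summary = summary, partitions = partitions),
            class = "aggregate_series")
}

#' @export
print.aggregate_series <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "aggregate_series: %d frames; aggregates %d -> %d, max size %d -> %d\n",
    nrow(s), s$n_aggregates[1], s$n_aggregates[nrow(s)], s$max_size[1],
    s$max_size[nrow(s)]))
  invisible(x)
}

#' Neighbour chains of a chain at a given time
#'
#' @param traj a \code{trajectory}.
#' @param chain query chain id.
#' @param t time in ns (nearest frame is used).
#' @param cutoff_nm contact cutoff (nm).
#' @return character vector of chain ids within the cutoff (possibly empty).
#' @export
neighbors_at_time <- function(traj, chain, t, cutoff_nm = 0.5) {
  stopifnot(inherits(traj, "trajectory"))
  if (!chain %in% trajectory_chains(traj)) stop("unknown chain: ", chain)
  f <- which.min(abs(traj$times - t))
  adj <- chain_contact_graph(traj, f, cutoff_nm)
  names(which(adj[chain, ]))
}

#' Per-residue intermolecular contacts grouped by conformational state
#'
#' A contact is an inter-chain atom pair within the cutoff (minimum-image);
#' it is attributed to the residues of both atoms. For every chain and frame
#' the per-residue contact count is accumulated under the chain's state label
#' for that frame, and means per frame are reported per state group.
#'
#' @param traj a \code{trajectory}.
#' @param states a \code{state_series} aligned with the trajectory frames.
#' @param cutoff_nm contact cutoff (nm).
#' @param dedup if TRUE, count each residue pair at most once per chain pair
#'   and frame instead of once per atom pair.
#' @param frames frame indices (default all).
#' @return data.frame with columns \code{residue}, \code{resname},
#'   \code{state}, \code{mean_contacts}, \code{n_observations} (chain-frames
#'   in the group).
#' @export
intermolecular_contacts <- function(traj, states, cutoff_nm = 0.5,
                                    dedup = FALSE, frames = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(states, "state_series"))
  if (ncol(states$labels) != n_frames(traj)) {
    stop("state series does not align with trajectory frames")
  }
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  idx <- .chain_index(traj)
  chains <- names(idx)
  nres <- length(traj$sequence$residues)
  box <- traj$box
  acc <- list()   # state -> residue-count matrix accumulator
  nobs <- list()
  for (st in unique(as.vector(states$labels))) {
    acc[[st]] <- numeric(nres); nobs[[st]] <- 0L
  }
  for (f in frames) {
    xyz <- traj$coords[, , f]
    counts <- matrix(0, length(chains), nres,
                     dimnames = list(chains, NULL))
    for (i in seq_len(length(chains) - 1L)) {
      for (j in (i + 1L):length(chains)) {
        d2 <- .pairwise_min_image_d2(xyz[idx[[i]], , drop = FALSE],
                                     xyz[idx[[j]], , drop = FALSE], box)
        hit <- which(d2 < cutoff_nm^2, arr.ind = TRUE)
        if (nrow(hit) == 0L) next
        ri <- traj$atoms$residue[idx[[i]]][hit[, 1]]
        rj <- traj$atoms$residue[idx[[j]]][hit[, 2]]
        if (dedup) {
          keep <- !duplicated(paste(ri, rj))
          ri <- ri[keep]; rj <- rj[keep]
        }
        ti <- tabulate(ri, nres); tj <- tabulate(rj, nres)
        counts[i, ] <- counts[i, ] + ti
        counts[j, ] <- counts[j, ] + tj
      }
    }
    for (ci in seq_along(chains)) {
      st <- states$labels[chains[ci], f]
      acc[[st]] <- acc[[st]] + counts[ci, ]
      nobs[[st]] <- nobs[[st]] + 1L
    }
  }
  out <- do.call(rbind, lapply(names(acc), function(st) {
    data.frame(residue = seq_len(nres),
               resname = traj$sequence$residues,
               state = st,
               mean_contacts = acc[[st]] / max(1L, nobs[[st]]),
               n_observations = nobs[[st]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
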