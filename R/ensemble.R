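# Conformational ensemble analysis: GROMOS clustering and Cartesian
# backbone principal component analysis (essential dynamics).

# frame coordinate list for a chain/selection of a trajectory
.frame_coords <- function(traj, chain, selection) {
  idx <- which(traj$atoms$chain == chain & traj$atoms$name %in% selection)
  if (length(idx) == 0L) stop("empty selection")
  lapply(seq_len(n_frames(traj)), function(f) traj$coords[idx, , f])
}

#' GROMOS conformational clustering
#'
#' Greedy neighbour-count clustering: pairwise RMSDs are computed after
#' per-pair optimal superposition; the frame with the most neighbours within
#' the cutoff becomes a cluster centroid, that cluster is removed, and the
#' procedure repeats on the remainder. When two frames have equal neighbour
#' counts, the earlier frame index wins (deterministic tie rule).
#'
#' @param frames list of row-matched n x 3 coordinate matrices, or a
#'   \code{trajectory} (then \code{chain} and \code{selection} pick the
#'   coordinates).
#' @param cutoff_nm RMSD cutoff (nm), default 0.3.
#' @param chain,selection used when \code{frames} is a trajectory; default
#'   backbone N, CA, C.
#' @return object of class \code{cluster_set}: list with \code{clusters}
#'   (list of integer frame-index vectors, size-descending), \code{centroids}
#'   (integer vector, one per cluster), \code{rmsd_matrix}.
#' @export
gromos_cluster <- function(frames, cutoff_nm = 0.3, chain = NULL,
                           selection = c("N", "CA", "C")) {
  if (inherits(frames, "trajectory")) {
    if (is.null(chain)) chain <- trajectory_chains(frames)[1]
    frames <- .frame_coords(frames, chain, selection)
  }
  nf <- length(frames)
  if (nf == 0L) stop("empty frame set")
  rmsd <- matrix(0, nf, nf)
  if (nf > 1L) {
    for (i in seq_len(nf - 1L)) {
      for (j in (i + 1L):nf) {
        rmsd[i, j] <- rmsd[j, i] <-
          kabsch_superpose(frames[[j]], frames[[i]])$rmsd
      }
    }
  }
  neighbour <- rmsd <= cutoff_nm
  alive <- rep(TRUE, nf)
  clusters <- list(); centroids <- integer(0)
  while (any(alive)) {
    counts <- colSums(neighbour[alive, , drop = FALSE])
    counts[!alive] <- -1L
    centre <- which.max(counts)          # ties: earliest index wins
    member <- which(alive & neighbour[, centre])
    clusters[[length(clusters) + 1L]] <- member
    centroids <- c(centroids, centre)
    alive[member] <- FALSE
  }
  ord <- order(-lengths(clusters), centroids)
  structure(list(clusters = clusters[ord], centroids = centroids[ord],
                 rmsd_matrix = rmsd),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters over %d frames; sizes: %s\n",
              length(x$clusters), nrow(x$rmsd_matrix),
              paste(utils::head(lengths(x$clusters), 10), collapse = ", ")))
  invisible(x)
}

#' Cartesian principal component analysis of backbone motion
#'
#' Frames are least-squares fitted to the starting conformation on the
#' selection, the positional covariance of the 3N fitted coordinates is
#' eigendecomposed, and per-frame projections onto the eigenvectors are
#' returned. For a 20-residue chain the default selection (N, CA, C) spans
#' 60 atoms, i.e. 180 Cartesian coordinates.
#'
#' @param traj a \code{trajectory}.
#' @param chain chain identifier (first chain by default).
#' @param selection atom names entering the analysis.
#' @return object of class \code{pca_model}: list with \code{mean} (3N),
#'   \code{values} (eigenvalues, nm^2, descending), \code{vectors}
#'   (3N x 3N orthonormal columns), \code{projections} (frames x 3N, nm),
#'   \code{reference} (fitting reference coordinates), \code{selection},
#'   \code{chain}, \code{atoms} (selected atom table).
#' @export
cartesian_pca <- function(traj, chain = NULL, selection = c("N", "CA", "C")) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2L) stop("PCA requires at least 2 frames")
  if (is.null(chain)) chain <- trajectory_chains(traj)[1]
  idx <- which(traj$atoms$chain == chain & traj$atoms$name %in% selection)
  if (length(idx) == 0L) stop("empty selection")
  nf <- n_frames(traj)
  ref <- traj$coords[idx, , 1L]
  X <- matrix(NA_real_, nf, length(idx) * 3L)
  for (f in seq_len(nf)) {
    x <- traj$coords[idx, , f]
    X[f, ] <- as.numeric(t(apply_transform(x, kabsch_superpose(x, ref))))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nf - 1L)
  e <- eigen(C, symmetric = TRUE)
  values <- pmax(e$values, 0)
  structure(list(mean = mu, values = values, vectors = e$vectors,
                 projections = Xc %*% e$vectors, reference = ref,
                 selection = selection, chain = chain,
                 atoms = traj$atoms[idx, , drop = FALSE]),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  share <- if (sum(x$values) > 0) x$values / sum(x$values) else x$values
  cat(sprintf(
    "pca_model: chain %s, %d coordinates, %d frames; PC1 share %.1f%%\n",
    x$chain, length(x$mean), nrow(x$projections), 100 * share[1]))
  invisible(x)
}

#' Per-atom RMSF generated by one principal component
#'
#' RMS displacement amplitude of each atom along the chosen eigenvector,
#' scaled by the square root of its eigenvalue.
#'
#' @param model a \code{pca_model}.
#' @param component component index (1 = largest eigenvalue).
#' @return data.frame with columns \code{residue}, \code{name},
#'   \code{rmsf_nm}.
#' @export
eigen_rmsf <- function(model, component = 1L) {
  stopifnot(inherits(model, "pca_model"))
  if (component < 1L || component > length(model$values)) {
    stop("component index out of range")
  }
  v <- matrix(model$vectors[, component], ncol = 3L, byrow = TRUE)
  data.frame(residue = model$atoms$residue, name = model$atoms$name,
             rmsf_nm = sqrt(model$values[component]) * sqrt(rowSums(v^2)),
             stringsAsFactors = FALSE)
}

#' Project a trajectory onto a principal component
#'
#' Each frame is fitted to the model's reference structure on the model
#' selection, mean-centred with the model mean, and projected onto the
#' chosen eigenvector.
#'
#' @param traj a \code{trajectory}.
#' @param model a \code{pca_model}.
#' @param component component index.
#' @param chain chain to project; default the model's chain.
#' @return numeric vector of per-frame projections (nm).
#' @export
pca_project <- function(traj, model, component = 1L, chain = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(model, "pca_model"))
  if (component < 1L || component > length(model$values)) {
    stop("component index out of range")
  }
  if (is.null(chain)) chain <- model$chain
  idx <- which(traj$atoms$chain == chain &
                 traj$atoms$name %in% model$selection)
  if (length(idx) * 3L != length(model$mean)) {
    stop("selection mismatch between trajectory and model")
  }
  v <- model$vectors[, component]
  vapply(seq_len(n_frames(traj)), function(f) {
    x <- traj$coords[idx, , f]
    xf <- as.numeric(t(apply_transform(x, kabsch_superpose(x, model$reference))))
    sum((xf - model$mean) * v)
  }, 0)
}
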