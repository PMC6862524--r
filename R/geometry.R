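#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of a mobile point set onto a reference by the
#' Kabsch SVD construction. Returns the proper rotation and translation that
#' minimise the RMSD, together with the minimised RMSD itself.
#'
#' @param mobile,reference n x 3 coordinate matrices (nm), n >= 3,
#'   row-matched, not collinear.
#' @return list of class \code{rigid_transform} with elements
#'   \code{rotation} (3 x 3, det +1), \code{translation} (length 3) and
#'   \code{rmsd} (nm). Applying the transform as
#'   \code{coords \%*\% t(rotation) + translation} maps \code{mobile} onto
#'   \code{reference} at the stated RMSD.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L) {
    stop("coordinate matrices must have 3 columns")
  }
  if (nrow(mobile) != nrow(reference)) {
    stop("point counts differ: ", nrow(mobile), " vs ", nrow(reference))
  }
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  pm <- sweep(mobile, 2, cm); pr <- sweep(reference, 2, cr)
  # degenerate (collinear) sets have no unique rotation
  if (svd(pm)$d[2] < 1e-10 || svd(pr)$d[2] < 1e-10) {
    stop("degenerate (collinear) point set")
  }
  s <- svd(crossprod(pm, pr))          # H = t(pm) %*% pr = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- pm %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - pr)^2)))
  structure(
    list(rotation = rot,
         translation = as.numeric(cr - rot %*% cm),
         rmsd = rmsd),
    class = "rigid_transform"
  )
}

#' Apply a rigid transform to coordinates
#' @param coords n x 3 matrix (nm).
#' @param transform a \code{rigid_transform}.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  sweep(as.matrix(coords) %*% t(transform$rotation), 2,
        transform$translation, "+")
}

#' Radius of gyration
#'
#' Mass-weighted RMS distance of atoms from their centre of mass.
#'
#' @param x a \code{conformation} or an n x 3 coordinate matrix (nm).
#' @param masses atom masses; taken from the conformation when available,
#'   else unit masses.
#' @return radius of gyration in nm.
#' @export
radius_of_gyration <- function(x, masses = NULL) {
  if (inherits(x, "conformation")) {
    if (is.null(masses)) masses <- x$atoms$mass
    x <- x$coords
  }
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("need at least one atom")
  if (is.null(masses)) masses <- rep(1, nrow(x))
  w <- masses / sum(masses)
  com <- colSums(x * w)
  sqrt(sum(w * rowSums(sweep(x, 2, com)^2)))
}

#' Minimum-image distance in an orthorhombic periodic box
#'
#' @param p,q points: length-3 vectors or n x 3 matrices (nm).
#' @param box positive edge lengths (length 3, or scalar for a cubic box), nm.
#' @return distance(s) under the minimum-image convention.
#' @export
min_image_distance <- function(p, q, box) {
  if (length(box) == 1L) box <- rep(box, 3L)
  if (any(box <= 0)) stop("box edges must be positive")
  p <- rbind(p); q <- rbind(q)
  d <- p - q
  d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  unname(sqrt(rowSums(d^2)))
}

#' Per-residue root-mean-square fluctuation
#'
#' Each frame of the chain is superposed onto the first frame (fitting on all
#' of the chain's atoms by default), then the RMSF of each residue's C-alpha
#' about its time-average position is computed.
#'
#' @param traj a \code{trajectory}.
#' @param chain chain identifier.
#' @param selection atom names whose fluctuation is reported, per residue;
#'   default \code{"CA"}.
#' @param fit_selection atom names used in the superposition; default all
#'   atoms of the chain.
#' @param fit_reference \code{"first"} (default) fits to the first frame;
#'   \code{"mean"} iterates the fit against the running mean structure once.
#' @return data.frame with columns \code{residue}, \code{resname},
#'   \code{rmsf_nm}.
#' @export
rmsf_per_residue <- function(traj, chain, selection = "CA",
                             fit_selection = NULL,
                             fit_reference = c("first", "mean")) {
  stopifnot(inherits(traj, "trajectory"))
  fit_reference <- match.arg(fit_reference)
  nf <- n_frames(traj)
  if (nf < 2L) stop("RMSF requires at least 2 frames")
  idx <- which(traj$atoms$chain == chain)
  if (length(idx) == 0L) stop("unknown chain: ", chain)
  atoms <- traj$atoms[idx, , drop = FALSE]
  fit_idx <- if (is.null(fit_selection)) {
    seq_along(idx)
  } else {
    which(atoms$name %in% fit_selection)
  }
  sel_idx <- which(atoms$name %in% selection)
  if (length(sel_idx) == 0L) stop("empty report selection")

  fitted <- array(NA_real_, c(length(idx), 3L, nf))
  ref <- traj$coords[idx, , 1L]
  for (f in seq_len(nf)) {
    x <- traj$coords[idx, , f]
    tr <- kabsch_superpose(x[fit_idx, , drop = FALSE],
                           ref[fit_idx, , drop = FALSE])
    fitted[, , f] <- apply_transform(x, tr)
  }
  if (fit_reference == "mean") {
    mean_ref <- apply(fitted, c(1, 2), mean)
    for (f in seq_len(nf)) {
      x <- traj$coords[idx, , f]
      tr <- kabsch_superpose(x[fit_idx, , drop = FALSE],
                             mean_ref[fit_idx, , drop = FALSE])
      fitted[, , f] <- apply_transform(x, tr)
    }
  }
  mu <- apply(fitted[sel_idx, , , drop = FALSE], c(1, 2), mean)
  dev2 <- sapply(seq_len(nf), function(f) {
    rowSums((fitted[sel_idx, , f] - mu)^2)
  })
  dev2 <- matrix(dev2, nrow = length(sel_idx))
  data.frame(
    residue = atoms$residue[sel_idx],
    resname = atoms$resname[sel_idx],
    rmsf_nm = sqrt(rowMeans(dev2)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
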