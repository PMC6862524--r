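# Solvent-accessible surface area by the Shrake-Rupley method.
#
# Each atom sphere is inflated by the probe radius and covered with an
# (almost) even golden-spiral quadrature; the accessible area is the
# unoccluded fraction of quadrature points times the inflated sphere area.
# In the reduced chain representation, backbone atoms carry standard
# van-der-Waals radii and the side-chain pseudo-atom a residue-class radius.

#' Golden-spiral quadrature directions
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param coords n x 3 atom coordinates (nm).
#' @param radii atomic van-der-Waals radii (nm), length n.
#' @param probe_radius probe sphere radius (nm), default 0.14.
#' @param n_points quadrature points per atom, default 960.
#' @return numeric vector of per-atom accessible areas (nm^2).
#' @export
shrake_rupley <- function(coords, radii, probe_radius = 0.14,
                          n_points = 960L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(radii) != n) stop("radii/coords length mismatch")
  if (any(radii <= 0)) stop("radii must be positive")
  if (probe_radius <= 0) stop("probe_radius must be positive")
  if (n_points < 16L) stop("n_points must be at least 16")
  R <- radii + probe_radius
  # reject coincident atoms (undefined occlusion)
  if (n > 1L) {
    d2 <- outer(rowSums(coords^2), rowSums(coords^2), "+") -
      2 * tcrossprod(coords)
    diag(d2) <- Inf
    if (min(d2) < 1e-12) stop("coincident atoms (distance < 1e-6 nm)")
  }
  dirs <- sphere_points(n_points)
  area <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(dirs * R[i], 2, coords[i, ], "+")
    if (n > 1L) {
      dd <- sqrt(rowSums(sweep(coords, 2, coords[i, ])^2))
      nb <- which(dd < R[i] + R & seq_len(n) != i)
    } else nb <- integer(0)
    exposed <- n_points
    if (length(nb) > 0L) {
      nbc <- coords[nb, , drop = FALSE]
      d2 <- outer(rowSums(pts^2), rowSums(nbc^2), "+") -
        2 * tcrossprod(pts, nbc)
      occluded <- rowSums(d2 < rep(R[nb]^2, each = n_points)) > 0
      exposed <- sum(!occluded)
    }
    area[i] <- 4 * pi * R[i]^2 * exposed / n_points
  }
  area
}

#' Van-der-Waals radii for a reduced-representation atom table
#'
#' Backbone atoms (N, CA, C, O) take a standard protein radius set; the CB
#' side-chain pseudo-atom takes a radius determined by the residue class of
#' its parent residue under the given scheme.
#'
#' @param atoms atom table (columns name, resname).
#' @param scheme a \code{residue_class_scheme}.
#' @return numeric vector of radii (nm).
#' @export
atom_radii <- function(atoms, scheme = default_class_scheme()) {
  r <- unname(.BACKBONE_RADIUS[atoms$name])
  cb <- atoms$name == "CB"
  r[cb] <- .PSEUDO_RADIUS[unclass(scheme)[atoms$resname[cb]]]
  if (anyNA(r)) stop("unknown atom name(s): ",
                     paste(unique(atoms$name[is.na(r)]), collapse = ", "))
  r
}

#' Class-decomposed SASA of a set of atoms
#'
#' @param coords n x 3 coordinates (nm).
#' @param atoms matching atom table.
#' @param scheme residue-class scheme.
#' @param probe_radius,n_points passed to \code{\link{shrake_rupley}}.
#' @return object of class \code{sasa_result}: list with \code{per_atom},
#'   \code{per_residue} (data.frame chain, residue, resname, class,
#'   area_nm2), \code{per_class} (named numeric: hydrophobic, polar,
#'   charged), \code{total}.
#' @export
sasa_decompose <- function(coords, atoms, scheme = default_class_scheme(),
                           probe_radius = 0.14, n_points = 960L) {
  if (nrow(coords) == 0L) {
    per_class <- c(hydrophobic = 0, polar = 0, charged = 0)
    return(structure(list(per_atom = numeric(0),
                          per_residue = data.frame(),
                          per_class = per_class, total = 0),
                     class = "sasa_result"))
  }
  area <- shrake_rupley(coords, atom_radii(atoms, scheme),
                        probe_radius, n_points)
  cls <- unclass(scheme)[atoms$resname]
  key <- paste(atoms$chain, atoms$residue)
  per_res <- rowsum(area, key, reorder = FALSE)
  first <- !duplicated(key)
  per_residue <- data.frame(
    chain = atoms$chain[first],
    residue = atoms$residue[first],
    resname = atoms$resname[first],
    class = cls[first],
    area_nm2 = as.numeric(per_res),
    stringsAsFactors = FALSE
  )
  per_class <- vapply(c("hydrophobic", "polar", "charged"),
                      function(k) sum(area[cls == k]), 0)
  structure(list(per_atom = area, per_residue = per_residue,
                 per_class = per_class, total = sum(area)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf(
    "sasa_result: total %.3f nm^2 (hydrophobic %.3f, polar %.3f, charged %.3f)\n",
    x$total, x$per_class["hydrophobic"], x$per_class["polar"],
    x$per_class["charged"]))
  invisible(x)
}

#' Per-class SASA time series of a trajectory
#'
#' All chains are pooled per frame, so inter-chain burial reduces the totals.
#'
#' @param traj a \code{trajectory}.
#' @param scheme residue-class scheme.
#' @param probe_radius,n_points passed to \code{\link{shrake_rupley}}.
#' @param frames frame indices to evaluate (default all).
#' @return data.frame with columns \code{time_ns}, \code{hydrophobic_nm2},
#'   \code{polar_nm2}, \code{charged_nm2}, \code{total_nm2}.
#' @export
sasa_by_class <- function(traj, scheme = default_class_scheme(),
                          probe_radius = 0.14, n_points = 960L,
                          frames = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  rows <- lapply(frames, function(f) {
    res <- sasa_decompose(traj$coords[, , f], traj$atoms, scheme,
                          probe_radius, n_points)
    data.frame(time_ns = traj$times[f],
               hydrophobic_nm2 = res$per_class[["hydrophobic"]],
               polar_nm2 = res$per_class[["polar"]],
               charged_nm2 = res$per_class[["charged"]],
               total_nm2 = res$total)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Polar-to-hydrophobic SASA ratio
#'
#' The ratio A_polar(t) / A_hydrophobic(t) for a per-class SASA time series.
#' Frames with zero hydrophobic area are flagged with \code{NA} and a
#' warning.
#'
#' @param series data.frame from \code{\link{sasa_by_class}}.
#' @return the input with an added \code{ratio} column.
#' @export
polar_hydrophobic_ratio <- function(series) {
  stopifnot(all(c("polar_nm2", "hydrophobic_nm2") %in% names(series)))
  bad <- series$hydrophobic_nm2 <= 0
  if (any(bad)) {
    warning(sum(bad), " frame(s) with zero hydrophobic area flagged as NA")
  }
  series$ratio <- ifelse(bad, NA_real_,
                         series$polar_nm2 / series$hydrophobic_nm2)
  series
}
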