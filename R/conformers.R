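# Reduced-representation conformer builders.
#
# Chains are modelled by their backbone heavy atoms (N, CA, C, O) plus one
# side-chain pseudo-atom (named CB) per non-glycine residue, placed along the
# C-alpha -> C-beta direction at the rotamer-averaged side-chain centroid
# distance and carrying the full side-chain mass. This keeps compactness,
# surface and contact analyses meaningful at a fraction of all-atom cost.

# Rodrigues rotation matrix about a unit axis
.rotation_matrix <- function(axis, angle_rad) {
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(angle_rad); st <- sin(angle_rad)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * ct + st * ux + (1 - ct) * tcrossprod(u)
}

# natural-extension-reference-frame placement: position atom d given a, b, c
# with bond |c-d|, angle b-c-d and torsion a-b-c-d (degrees, Angstrom)
.nerf <- function(a, b, c, bond, angle, torsion) {
  ang <- .deg2rad(angle); tor <- .deg2rad(torsion)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- bond * (-cos(ang) * bc + sin(ang) * cos(tor) * m + sin(ang) * sin(tor) * n)
  c + d
}

# atom table for one chain of a given sequence (reduced representation)
.chain_atoms <- function(seq, chain = "A") {
  res <- seq$residues
  n <- length(res)
  nat <- ifelse(res == "G", 4L, 5L)
  residue <- rep(seq_len(n), nat)
  resname <- res[residue]
  name <- unlist(lapply(seq_len(n), function(i) {
    if (res[i] == "G") c("N", "CA", "C", "O") else c("N", "CA", "C", "O", "CB")
  }), use.names = FALSE)
  mass <- ifelse(name == "CB", .SIDECHAIN_MASS[resname],
                 .BACKBONE_MASS[name])
  data.frame(chain = chain, residue = residue, resname = resname,
             name = name, mass = unname(mass), stringsAsFactors = FALSE)
}

#' Construct a conformation object
#'
#' @param coords n x 3 matrix of coordinates in nm, rows matching the atom
#'   table implied by \code{seq} (per residue: N, CA, C, O, and a CB
#'   side-chain pseudo-atom for non-glycine residues).
#' @param seq a \code{peptide_sequence}.
#' @param chain chain identifier (single character).
#' @return object of class \code{conformation}: list with \code{coords},
#'   \code{atoms} (data.frame: chain, residue, resname, name, mass),
#'   \code{chain}, \code{sequence}.
#' @export
conformation <- function(coords, seq, chain = "A") {
  atoms <- .chain_atoms(seq, chain)
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(atoms) || ncol(coords) != 3L) {
    stop(sprintf("expected %d x 3 coordinates, got %d x %d",
                 nrow(atoms), nrow(coords), ncol(coords)))
  }
  dimnames(coords) <- NULL
  structure(list(coords = coords, atoms = atoms, chain = chain,
                 sequence = seq),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("conformation: chain %s, %d residues, %d atoms\n",
              x$chain, length(x$sequence$residues), nrow(x$coords)))
  invisible(x)
}

# coordinates of the named atoms of a conformation, one row per residue
# (residues lacking the atom are dropped)
.atom_coords <- function(conf, name) {
  conf$coords[conf$atoms$name == name, , drop = FALSE]
}

#' Build a backbone chain with uniform dihedrals
#'
#' Chains backbone atoms with canonical bond geometry and the given
#' (phi, psi) dihedrals (omega = 180 deg), placing one side-chain
#' pseudo-atom along the idealised C-beta direction per non-glycine residue.
#'
#' @param seq a \code{peptide_sequence}.
#' @param phi,psi backbone dihedrals in degrees, applied to every residue.
#' @param chain chain identifier.
#' @return a \code{conformation}, centred at the origin.
#' @export
build_backbone <- function(seq, phi, psi, chain = "A") {
  n <- length(seq$residues)
  out <- .build_chain(seq, rep(phi, length.out = n),
                      rep(psi, length.out = n), chain)
  xyz <- sweep(out$coords, 2, colMeans(out$coords))
  conformation(xyz, seq, chain)
}

# NeRF chain construction with per-residue dihedral vectors (degrees);
# phiv[1] and psiv[n] are not used geometrically except for O placement
.build_chain <- function(seq, phiv, psiv, chain = "A") {
  res <- seq$residues
  n <- length(res)
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  # first residue in a canonical frame (Angstrom)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BOND["N_CA"], 0, 0)
  a <- .deg2rad(180 - .ANGLE["N_CA_C"])
  C[1, ] <- CA[1, ] + .BOND["CA_C"] * c(cos(a), sin(a), 0)
  for (i in seq_len(n)) {
    if (i < n) {
      N[i + 1, ] <- .nerf(N[i, ], CA[i, ], C[i, ], .BOND["C_N"],
                          .ANGLE["CA_C_N"], psiv[i])
      CA[i + 1, ] <- .nerf(CA[i, ], C[i, ], N[i + 1, ], .BOND["N_CA"],
                           .ANGLE["C_N_CA"], 180)
      C[i + 1, ] <- .nerf(C[i, ], N[i + 1, ], CA[i + 1, ], .BOND["CA_C"],
                          .ANGLE["N_CA_C"], phiv[i + 1])
    }
    O[i, ] <- .nerf(N[i, ], CA[i, ], C[i, ], .BOND["C_O"],
                    .ANGLE["CA_C_O"], psiv[i] + 180)
  }
  # side-chain pseudo-atoms along the idealised C-beta direction
  coords <- vector("list", n)
  for (i in seq_len(n)) {
    block <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    if (res[i] != "G") {
      b <- CA[i, ] - N[i, ]; cc <- C[i, ] - CA[i, ]
      av <- c(b[2] * cc[3] - b[3] * cc[2],
              b[3] * cc[1] - b[1] * cc[3],
              b[1] * cc[2] - b[2] * cc[1])
      cb <- -0.58273431 * av + 0.56802827 * b - 0.54067466 * cc
      dir <- cb / sqrt(sum(cb^2))
      block <- rbind(block,
                     CA[i, ] + dir * .SIDECHAIN_EXTENT[res[i]] * 10)
    }
    coords[[i]] <- block
  }
  xyz <- do.call(rbind, coords) / 10  # Angstrom -> nm
  xyz <- sweep(xyz, 2, colMeans(xyz))
  conformation(xyz, seq, chain)
}

#' Build an ideal alpha-helix conformation
#'
#' Canonical alpha-helical dihedrals (phi = -57.8 deg, psi = -47.0 deg),
#' giving the classical ~0.15 nm per-residue rise along the helix axis
#' (approximately the x direction).
#'
#' @param seq a \code{peptide_sequence}.
#' @param chain chain identifier.
#' @return a \code{conformation}.
#' @export
build_ideal_helix <- function(seq, chain = "A") {
  build_backbone(seq, .HELIX_PHI, .HELIX_PSI, chain)
}

# principal axis of a set of points, oriented from first to last point
.principal_axis <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  v <- svd(xc, nu = 0, nv = 1)$v[, 1]
  if (sum(v * (x[nrow(x), ] - x[1, ])) < 0) v <- -v
  v
}

#' Bend a helix at a hinge into a helix-loop-helix conformer
#'
#' Rebuilds the chain from internal coordinates with the psi dihedrals of the
#' two hinge residues lowered by a common offset, solved so that the angle
#' between the principal axes of the two helical segments matches
#' \code{bend_angle}. Bond lengths and angles stay canonical and every
#' dihedral outside the hinge residues keeps its input value, so the
#' flanking segments remain exactly helical.
#'
#' @param helix a \code{conformation} (typically from
#'   \code{\link{build_ideal_helix}}).
#' @param hinge integer pair of consecutive residue indices, interior to the
#'   chain, e.g. \code{c(10, 11)}.
#' @param bend_angle angle in degrees between the two helical segment axes
#'   after bending (0 = straight, returns the input unchanged). The two
#'   segment axes of a finite ideal helix already subtend a few degrees, so
#'   requested angles below ~10 degrees are treated as 0.
#' @return a \code{conformation}, centred at the origin.
#' @export
build_bent_conformer <- function(helix, hinge = c(10, 11), bend_angle = 120) {
  stopifnot(inherits(helix, "conformation"))
  n <- length(helix$sequence$residues)
  if (length(hinge) != 2L || hinge[2] != hinge[1] + 1L) {
    stop("hinge must be a pair of consecutive residue indices")
  }
  if (hinge[1] < 2L || hinge[2] > n - 1L) {
    stop("hinge must be interior to the chain")
  }
  if (bend_angle < 0 || bend_angle > 180) {
    stop("bend_angle must be in [0, 180] degrees")
  }
  dh <- backbone_dihedrals(helix)
  phiv <- dh$phi; psiv <- dh$psi
  phiv[1] <- .HELIX_PHI; psiv[n] <- .HELIX_PSI   # termini (unused downstream)
  seg1 <- seq_len(hinge[1]); seg2 <- hinge[2]:n
  angle_at <- function(t) {
    q <- psiv; q[hinge] <- q[hinge] - t
    ca <- .atom_coords(.build_chain(helix$sequence, phiv, q, helix$chain),
                       "CA")
    a1 <- .principal_axis(ca[seg1, , drop = FALSE])
    a2 <- .principal_axis(ca[seg2, , drop = FALSE])
    .rad2deg(acos(pmin(1, pmax(-1, sum(a1 * a2)))))
  }
  base <- angle_at(0)
  if (bend_angle <= base) return(helix)
  # the angle grows monotonically with the common psi offset up to ~150-160
  # degrees for helical segments; locate the first crossing
  upper <- 10
  while (upper < 360 && angle_at(upper) < bend_angle) upper <- upper + 10
  if (upper >= 360) stop("requested bend_angle is not reachable at this hinge")
  t_star <- stats::uniroot(function(t) angle_at(t) - bend_angle,
                           lower = upper - 10, upper = upper,
                           tol = 1e-10)$root
  psiv[hinge] <- psiv[hinge] - t_star
  out <- .build_chain(helix$sequence, phiv, psiv, helix$chain)
  xyz <- sweep(out$coords, 2, colMeans(out$coords))
  conformation(xyz, helix$sequence, helix$chain)
}

#' Angle between the two helical segment axes of a conformation
#'
#' Utility used to verify bent conformers: fits a principal axis to the
#' C-alpha atoms of each segment and returns the angle between them.
#'
#' @param conf a \code{conformation}.
#' @param hinge hinge residue pair splitting the segments.
#' @return angle in degrees, in [0, 180].
#' @export
segment_axis_angle <- function(conf, hinge = c(10, 11)) {
  ca <- .atom_coords(conf, "CA")
  n <- nrow(ca)
  a1 <- .principal_axis(ca[seq_len(hinge[1]), , drop = FALSE])
  a2 <- .principal_axis(ca[hinge[2]:n, , drop = FALSE])
  .rad2deg(acos(pmin(1, pmax(-1, sum(a1 * a2)))))
}
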