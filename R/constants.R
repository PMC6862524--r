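# Amino-acid reference tables and backbone geometry constants.
# All coordinates handled by the package are in nm; the helix builder works
# internally in Angstrom (standard values below) and converts on output.

# one-letter -> three-letter code
.AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

.AA_CODES <- names(.AA3)

# side-chain masses (Da), hydrogens included, everything beyond the C-alpha;
# glycine's side chain is a single hydrogen
.SIDECHAIN_MASS <- c(
  A = 15.03, R = 100.14, N = 58.06, D = 59.04, C = 47.10,
  Q = 72.09, E = 73.07, G = 1.01, H = 81.10, I = 57.11,
  L = 57.11, K = 72.13, M = 75.15, F = 91.13, P = 41.07,
  S = 31.03, T = 45.06, W = 130.17, Y = 107.13, V = 43.09
)

# distance (nm) from C-alpha to the side-chain heavy-atom centroid, used to
# place the single side-chain pseudo-atom along the C-beta direction; values
# follow rotamer-averaged geometries of the standard residues
.SIDECHAIN_EXTENT <- c(
  A = 0.152, R = 0.415, N = 0.247, D = 0.246, C = 0.205,
  Q = 0.311, E = 0.310, G = 0.100, H = 0.302, I = 0.231,
  L = 0.261, K = 0.354, M = 0.287, F = 0.338, P = 0.186,
  S = 0.192, T = 0.194, W = 0.388, Y = 0.381, V = 0.196
)

# backbone heavy-atom masses (Da), hydrogens lumped onto the bonded heavy atom
.BACKBONE_MASS <- c(N = 15.01, CA = 13.02, C = 12.01, O = 16.00)

# van-der-Waals radii (nm) for the reduced representation: backbone atoms take
# a standard protein set; the side-chain pseudo-atom radius depends on the
# residue class of its parent residue (see .PSEUDO_RADIUS)
.BACKBONE_RADIUS <- c(N = 0.155, CA = 0.170, C = 0.170, O = 0.152)

# side-chain pseudo-atom radius (nm) per residue class; sized so that a
# pseudo-sphere roughly matches the solvent-exposed extent of an average
# side chain in the class (charged = long lysine/arginine-like chains)
.PSEUDO_RADIUS <- c(hydrophobic = 0.240, polar = 0.210, charged = 0.260)

# ideal backbone internal coordinates (Angstrom / degrees), Engh-Huber-like
.BOND <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231)
.ANGLE <- c(C_N_CA = 121.7, N_CA_C = 111.2, CA_C_N = 116.2, CA_C_O = 120.8)

# canonical alpha-helix dihedrals (degrees), classic 3.6(13) values giving a
# ~0.15 nm per-residue rise with the bond geometry above
.HELIX_PHI <- -57.8
.HELIX_PSI <- -47.0

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi
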