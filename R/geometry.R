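# Internal-coordinate geometry: place an atom D at given bond length to C,
# bond angle B-C-D and dihedral A-B-C-D (NeRF construction).  Coordinates in
# Angstrom, angles in degrees.
.place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma::cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma::cross(n, bc)
  d2 <- bond * c(-cos(ang), cos(dih) * sin(ang), sin(dih) * sin(ang))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# ideal backbone geometry (Engh-Huber-like averages), Angstrom / degrees
.BB <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231, b_CA_CB = 1.521,
  a_N_CA_C = 111.0, a_CA_C_N = 116.6, a_C_N_CA = 121.7,
  a_CA_C_O = 120.8, a_N_CA_CB = 110.5, a_C_CA_CB = 110.1
)

# synthesise CB from backbone N, CA, C (also used for glycine sites)
.make_cb <- function(N, CA, C) {
  .place_atom(N, C, CA, .BB$b_CA_CB, 109.5, 121.9) # approx tetrahedral branch
}

#' Idealized poly-alanine helix-dimer test structure
#'
#' Two identical ideal alpha-helices (phi = -57, psi = -47 degrees) with
#' backbone N, CA, C, O and CB atoms, the second chain a pure translation of
#' the first by `separation` along x.  Deterministic; serves as a
#' download-free stand-in for deposited coordinates in spin-labelling tests.
#'
#' @param n_res residues per chain (>= 10).
#' @param separation inter-chain offset, nm (>= 1).
#' @param sites optional residue indices that must exist (validated).
#' @return a `mol_structure` (see [read_pdb()]).
#' @export
helix_dimer_fixture <- function(n_res = 20, separation = 3.0, sites = NULL) {
  if (n_res < 10) stop("n_res must be >= 10")
  if (separation < 1) stop("separation must be >= 1 nm")
  if (!is.null(sites) && any(sites < 1 | sites > n_res))
    stop("sites outside chain")
  phi <- -57; psi <- -47; omega <- 180
  # seed atoms for residue 1
  N <- c(0, 0, 0)
  CA <- c(.BB$b_N_CA, 0, 0)
  C <- .place_atom(c(-1, 1, 0), N, CA, .BB$b_CA_C, .BB$a_N_CA_C, psi + 60)
  rows <- list()
  serial <- 0L
  add <- function(name, xyz, resno) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      eleno = serial, elety = name, resid = "ALA", chain = "A",
      resno = resno, x = xyz[1], y = xyz[2], z = xyz[3],
      element = substr(name, 1, 1), stringsAsFactors = FALSE)
  }
  prevN <- N; prevCA <- CA; prevC <- C
  for (i in seq_len(n_res)) {
    O <- .place_atom(prevN, prevCA, prevC, .BB$b_C_O, .BB$a_CA_C_O,
                     if (i < n_res) psi + 180 else psi)
    CB <- .make_cb(prevN, prevCA, prevC)
    add("N", prevN, i); add("CA", prevCA, i); add("C", prevC, i)
    add("O", O, i); add("CB", CB, i)
    if (i < n_res) {
      Nn <- .place_atom(prevN, prevCA, prevC, .BB$b_C_N, .BB$a_CA_C_N, psi)
      CAn <- .place_atom(prevCA, prevC, Nn, .BB$b_N_CA, .BB$a_C_N_CA, omega)
      Cn <- .place_atom(prevC, Nn, CAn, .BB$b_CA_C, .BB$a_N_CA_C, phi)
      prevN <- Nn; prevCA <- CAn; prevC <- Cn
    }
  }
  atoms <- do.call(rbind, rows)
  # chain B: translate along x by separation (nm -> Angstrom)
  b <- atoms
  b$chain <- "B"
  b$x <- b$x + separation * 10
  b$eleno <- b$eleno + nrow(atoms)
  structure(list(atoms = rbind(atoms, b), source = "helix_dimer_fixture"),
            class = "mol_structure")
}
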