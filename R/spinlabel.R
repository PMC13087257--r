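#' Read a protein structure from PDB format
#'
#' Thin wrapper around bio3d's PDB reader: keeps the first model only,
#' altloc 'A' or blank, drops waters and hydrogens are retained but ignored
#' by the clash detector.
#'
#' @param x path to a PDB file, or a character vector of PDB-format lines.
#' @return object of class `mol_structure`: list with `atoms` (data.frame
#'   eleno, elety, resid, chain, resno, x, y, z, element; coordinates in
#'   Angstrom) and `source`.
#' @export
read_pdb <- function(x) {
  if (length(x) == 1 && file.exists(x)) {
    lines <- readLines(x)
    src <- x
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
    src <- "text"
  }
  atom_lines <- grep("^(ATOM  |HETATM)", lines)
  if (length(atom_lines) == 0) stop("no ATOM records found")
  # validate coordinate fields up front so errors carry a line number
  for (i in atom_lines) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed coordinate field at line ", i)
  }
  # keep the first model only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1])]
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  keep <- (a$alt %in% c("", "A", NA)) & !(a$resid %in% c("HOH", "WAT", "TIP3"))
  a <- a[keep, , drop = FALSE]
  elem <- a$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- substr(trimws(a$elety[bad]), 1, 1)
  atoms <- data.frame(eleno = a$eleno, elety = trimws(a$elety),
                      resid = a$resid, chain = a$chain, resno = a$resno,
                      x = a$x, y = a$y, z = a$z, element = trimws(elem),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(atoms[, c("chain", "resno", "elety")]))
    atoms <- atoms[!duplicated(atoms[, c("chain", "resno", "elety")]), ]
  structure(list(atoms = atoms, source = src), class = "mol_structure")
}

#' Write a `mol_structure` to PDB format
#' @param structure a `mol_structure`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_pdb <- function(structure, file) {
  stopifnot(inherits(structure, "mol_structure"))
  a <- structure$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain)
  invisible(file)
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("Structure (%s): %d atoms, chains %s, residues %d-%d\n",
              x$source, nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ","),
              min(x$atoms$resno), max(x$atoms$resno)))
  invisible(x)
}

# R1 (MTSSL) side-chain template: internal coordinates placing each atom from
# three predecessors (NeRF).  chi1-chi5 are the sampled dihedrals; ring
# geometry is idealized planar and held rigid.  Bond lengths in Angstrom,
# angles in degrees.
.R1_TEMPLATE <- list(
  list(name = "SG", ref = c("N", "CA", "CB"), bond = 1.81, angle = 114.0, chi = 1),
  list(name = "SD", ref = c("CA", "CB", "SG"), bond = 2.04, angle = 104.0, chi = 2),
  list(name = "CE", ref = c("CB", "SG", "SD"), bond = 1.82, angle = 104.0, chi = 3),
  list(name = "C3", ref = c("SG", "SD", "CE"), bond = 1.50, angle = 113.0, chi = 4),
  list(name = "C4", ref = c("SD", "CE", "C3"), bond = 1.34, angle = 126.0, chi = 5),
  list(name = "C5", ref = c("CE", "C3", "C4"), bond = 1.51, angle = 112.0, dihedral = 180),
  list(name = "N1", ref = c("C3", "C4", "C5"), bond = 1.47, angle = 101.0, dihedral = 0),
  list(name = "C2", ref = c("C4", "C5", "N1"), bond = 1.48, angle = 113.0, dihedral = 0),
  list(name = "O1", ref = c("C2", "N1", "C5"), bond = 1.27, angle = 121.0, dihedral = 180),
  list(name = "C6", ref = c("N1", "C2", "C3"), bond = 1.53, angle = 110.0, dihedral = 120),
  list(name = "C7", ref = c("N1", "C2", "C3"), bond = 1.53, angle = 110.0, dihedral = -120),
  list(name = "C8", ref = c("N1", "C5", "C4"), bond = 1.53, angle = 110.0, dihedral = 120),
  list(name = "C9", ref = c("N1", "C5", "C4"), bond = 1.53, angle = 110.0, dihedral = -120)
)

# build one R1 conformer from backbone anchors and 5 dihedrals (radians ->
# degrees handled here); returns named 3-column matrix of side-chain atoms
.build_r1 <- function(N, CA, CB, chi) {
  pos <- list(N = N, CA = CA, CB = CB)
  for (a in .R1_TEMPLATE) {
    dih <- if (!is.null(a$chi)) chi[a$chi] * 180 / pi else a$dihedral
    pos[[a$name]] <- .place_atom(pos[[a$ref[1]]], pos[[a$ref[2]]],
                                 pos[[a$ref[3]]], a$bond, a$angle, dih)
  }
  do.call(rbind, pos[vapply(.R1_TEMPLATE, `[[`, character(1), "name")])
}

.get_atom <- function(atoms, chain, resno, name) {
  i <- which(atoms$chain == chain & atoms$resno == resno &
               atoms$elety == name)
  if (length(i) == 0) return(NULL)
  as.numeric(atoms[i[1], c("x", "y", "z")])
}

#' Accessible-volume rotamer search for the R1 spin label
#'
#' Replaces the side chain at a site with the R1 (nitroxide) label and
#' samples its five rotatable dihedrals uniformly, accepting a conformer iff
#' its heavy atoms make at most `max_clashes` contacts closer than the VDW
#' cutoff to protein heavy atoms (the labelled residue's own side chain is
#' excluded).  "loose" restraints mean cutoff 2.5 A with up to 5 clashes;
#' "tight" means 3.4 A with none.  The search stops at `max_rotamers`
#' accepted conformers (200, the conventional ensemble size) or when the try
#' budget (30000 for "thorough", 3000 for "quick") is exhausted.
#'
#' @param structure a `mol_structure`.
#' @param site list or vector with `chain` and `resno`.
#' @param mode "thorough" or "quick" (try budget).
#' @param vdw "loose" or "tight" (clash rule).
#' @param max_rotamers maximum accepted conformers.
#' @param seed RNG seed.
#' @return object of class `rotamer_ensemble`: `midpoints` (accepted
#'   nitroxide N-O bond midpoints, Angstrom), `coords` (list of side-chain
#'   coordinate matrices), `clashes`, `tries`, `site`, search settings.
#' @export
attach_rotamers <- function(structure, site, mode = c("thorough", "quick"),
                            vdw = c("loose", "tight"), max_rotamers = 200,
                            seed = 1) {
  mode <- match.arg(mode)
  vdw <- match.arg(vdw)
  stopifnot(inherits(structure, "mol_structure"))
  site <- as.list(site)
  chain <- as.character(site$chain)
  resno <- as.integer(site$resno)
  atoms <- structure$atoms
  N <- .get_atom(atoms, chain, resno, "N")
  CA <- .get_atom(atoms, chain, resno, "CA")
  C <- .get_atom(atoms, chain, resno, "C")
  if (is.null(N) || is.null(CA) || is.null(C))
    stop(sprintf("site %s:%d lacks backbone N/CA/C", chain, resno))
  CB <- .get_atom(atoms, chain, resno, "CB")
  if (is.null(CB)) CB <- .make_cb(N, CA, C)  # glycine: synthesise CB
  # refuse disulfide-bonded cysteines (SG-SG < 2.5 A)
  here <- atoms$chain == chain & atoms$resno == resno
  if (any(atoms$resid[here] == "CYS")) {
    SG <- .get_atom(atoms, chain, resno, "SG")
    others <- atoms[atoms$elety == "SG" & !here, , drop = FALSE]
    if (!is.null(SG) && nrow(others)) {
      dd <- sqrt(colSums((t(as.matrix(others[, c("x", "y", "z")])) - SG)^2))
      if (any(dd < 2.5))
        stop(sprintf("site %s:%d is a disulfide-bonded cysteine; not labellable",
                     chain, resno))
    }
  }
  cutoff <- if (vdw == "loose") 2.5 else 3.4
  max_clashes <- if (vdw == "loose") 5L else 0L
  budget <- if (mode == "thorough") 30000L else 3000L
  # clash environment: heavy atoms, labelled residue excluded entirely,
  # prefiltered to a 20 A sphere around CB
  env <- atoms[!(atoms$element %in% c("H", "D")) & !here, , drop = FALSE]
  exyz <- as.matrix(env[, c("x", "y", "z")])
  near <- rowSums(sweep(exyz, 2, CB)^2) < 20^2
  exyz <- exyz[near, , drop = FALSE]
  accepted <- list()
  clashes <- integer(0)
  tries <- 0L
  with_seed(seed, {
    while (tries < budget && length(accepted) < max_rotamers) {
      tries <- tries + 1L
      chi <- runif(5, -pi, pi)
      sc <- .build_r1(N, CA, CB, chi)
      nc <- if (nrow(exyz)) {
        d2 <- outer(rowSums(sc^2), rowSums(exyz^2), `+`) -
          2 * sc %*% t(exyz)
        sum(d2 < cutoff^2)
      } else 0L
      if (nc <= max_clashes) {
        accepted[[length(accepted) + 1L]] <- sc
        clashes <- c(clashes, nc)
      }
    }
  })
  if (length(accepted) == 0)
    stop(sprintf("rotamer starvation at site %s:%d (0 accepted in %d tries)",
                 chain, resno, tries))
  mids <- t(vapply(accepted, function(sc)
    (sc["N1", ] + sc["O1", ]) / 2, numeric(3)))
  structure(list(site = list(chain = chain, resno = resno),
                 midpoints = mids, coords = accepted, clashes = clashes,
                 tries = tries, accepted = length(accepted),
                 mode = mode, vdw = vdw, cutoff = cutoff,
                 max_clashes = max_clashes, seed = seed),
            class = "rotamer_ensemble")
}

#' @export
print.rotamer_ensemble <- function(x, ...) {
  cat(sprintf(
    "Rotamer ensemble at %s:%d: %d accepted / %d tries (%s, vdw %s)\n",
    x$site$chain, x$site$resno, x$accepted, x$tries, x$mode, x$vdw))
  invisible(x)
}

#' Inter-label distance distribution from two rotamer ensembles
#'
#' Histograms all pairwise nitroxide-midpoint distances between two
#' ensembles (all possible spin-spin distance vectors) into a density on a
#' regular nm grid, and reports the mean and SD of the raw distances.
#'
#' @param ensA,ensB `rotamer_ensemble` objects.
#' @param bin_width histogram bin width, nm.
#' @return list with `distribution` (a `ddist`), `mean_nm`, `sd_nm`,
#'   `n_pairs`.
#' @export
pair_distance_distribution <- function(ensA, ensB, bin_width = 0.05) {
  stopifnot(inherits(ensA, "rotamer_ensemble"),
            inherits(ensB, "rotamer_ensemble"))
  A <- ensA$midpoints
  B <- ensB$midpoints
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  d_nm <- sqrt(pmax(d2, 0)) / 10
  d_nm <- as.vector(d_nm)
  if (any(d_nm < 0.5 | d_nm > 9))
    warning("predicted distances outside [0.5, 9] nm; check the input geometry")
  lo <- max(0, floor(min(d_nm) / bin_width) - 2) * bin_width
  hi <- (ceiling(max(d_nm) / bin_width) + 2) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(d_nm, breaks = breaks, plot = FALSE)
  dist <- distance_distribution(h$mids, h$counts / (length(d_nm) * bin_width),
                                normalize = TRUE)
  list(distribution = dist, mean_nm = mean(d_nm), sd_nm = stats::sd(d_nm),
       n_pairs = length(d_nm))
}

#' In-silico distance prediction for a labelled site pair
#'
#' Composes the rotamer search at two sites with the pairwise distance
#' histogram - the route used to screen site pairs for their ability to
#' discriminate the swapped and non-swapped states.  With
#' `homodimer = TRUE`, the second site is the same residue number on the
#' partner chain (homodimeric single-site labelling); the default is
#' intra-subunit heterologous labelling (both sites on one chain).
#'
#' @param structure a `mol_structure`.
#' @param siteA,siteB site specs (`chain`, `resno`).
#' @param mode,vdw,seed passed to [attach_rotamers()].
#' @param bin_width histogram bin width, nm.
#' @return object of class `pair_prediction`: per-site ensembles, the
#'   distance `distribution`, `mean_nm`, `sd_nm`, most probable distance
#'   `mode_nm`.
#' @export
predict_pair <- function(structure, siteA, siteB, mode = "thorough",
                         vdw = "loose", seed = 1, bin_width = 0.05) {
  ensA <- attach_rotamers(structure, siteA, mode, vdw, seed = seed)
  ensB <- attach_rotamers(structure, siteB, mode, vdw, seed = seed + 1)
  pd <- pair_distance_distribution(ensA, ensB, bin_width)
  structure(list(ensA = ensA, ensB = ensB,
                 distribution = pd$distribution, mean_nm = pd$mean_nm,
                 sd_nm = pd$sd_nm,
                 mode_nm = pd$distribution$r[which.max(pd$distribution$P)]),
            class = "pair_prediction")
}

#' @export
print.pair_prediction <- function(x, ...) {
  cat(sprintf(
    "Pair prediction %s:%d - %s:%d: mean %.2f nm, sd %.2f nm, mode %.2f nm\n",
    x$ensA$site$chain, x$ensA$site$resno, x$ensB$site$chain,
    x$ensB$site$resno, x$mean_nm, x$sd_nm, x$mode_nm))
  invisible(x)
}
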