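# Structure geometry: dihedral computation, internal-to-Cartesian (NeRF)
# construction, ideal side-chain topologies, PDB I/O, and extraction of
# (phi, psi, chi) angle tables from coordinates.
#
# Bond lengths and angles are fixed at ideal values (Engh-Huber-type); the
# chi dihedrals are the only side-chain degrees of freedom. Coordinates are
# Angstroms, angles radians internally (the topology table below is written
# in degrees for legibility and converted once at load).

#' Dihedral angle of four points
#'
#' IUPAC sign convention (cis = 0, anticlockwise positive looking from p2 to
#' p3); result in the half-open interval `[-pi, pi)`, so a trans-planar
#' chain reports `-pi`.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstroms).
#' @return dihedral angle in radians.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-14 || sum(n2^2) < 1e-14) {
    stop("undefined dihedral: colinear points", call. = FALSE)
  }
  m <- cross3(n1, b2 / sqrt(sum(b2^2)))
  wrap_angle(atan2(-sum(m * n2), sum(n1 * n2)))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D from reference chain A-B-C with bond |CD|, bond angle B-C-D
# (radians) and dihedral A-B-C-D (radians): the NeRF construction.
place_atom <- function(A, B, C, bond, angle, dihedral) {
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(B - A, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(dihedral),
          bond * sin(angle) * sin(dihedral))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Ideal side-chain internal coordinates. Columns: amino acid, atom, the
# three reference atoms (dihedral r1-r2-r3-atom), bond length (A), bond
# angle r2-r3-atom (deg), dihedral type (x1..x4 = that chi plus the offset,
# f = fixed) and the offset/fixed dihedral value (deg).
sidechain_topology_text <- "
aa  atom r1 r2 r3 bond angle dih dval
ARG CG  N  CA CB 1.530 114.1 x2_ref 0
ARG CD  CA CB CG 1.520 111.3 x2 0
ARG NE  CB CG CD 1.461 112.0 x3 0
ARG CZ  CG CD NE 1.329 124.2 x4 0
ARG NH1 CD NE CZ 1.326 120.0 f 0
ARG NH2 CD NE CZ 1.326 120.0 f 180
ASN CG  N  CA CB 1.516 112.6 x2_ref 0
ASN OD1 CA CB CG 1.231 120.8 x2 0
ASN ND2 CA CB CG 1.328 116.4 x2 180
ASP CG  N  CA CB 1.516 112.6 x2_ref 0
ASP OD1 CA CB CG 1.249 118.4 x2 0
ASP OD2 CA CB CG 1.249 118.4 x2 180
CYS SG  N  CA CB 1.808 113.8 x1 0
GLN CG  N  CA CB 1.530 114.1 x2_ref 0
GLN CD  CA CB CG 1.516 112.6 x3_ref 0
GLN OE1 CB CG CD 1.231 120.8 x3 0
GLN NE2 CB CG CD 1.328 116.4 x3 180
GLU CG  N  CA CB 1.530 114.1 x2_ref 0
GLU CD  CA CB CG 1.516 112.6 x3_ref 0
GLU OE1 CB CG CD 1.249 118.4 x3 0
GLU OE2 CB CG CD 1.249 118.4 x3 180
HIS CG  N  CA CB 1.497 113.8 x2_ref 0
HIS ND1 CA CB CG 1.378 122.7 x2 0
HIS CD2 CA CB CG 1.354 131.1 x2 180
HIS CE1 CB CG ND1 1.321 109.3 f 180
HIS NE2 CB CG CD2 1.374 107.2 f 180
ILE CG1 N  CA CB 1.530 110.4 x2_ref 0
ILE CG2 N  CA CB 1.521 110.5 x1 -120
ILE CD1 CA CB CG1 1.513 113.9 x2 0
LEU CG  N  CA CB 1.530 116.3 x2_ref 0
LEU CD1 CA CB CG 1.521 110.7 x2 0
LEU CD2 CA CB CG 1.521 110.7 x2 120
LYS CG  N  CA CB 1.530 114.1 x2_ref 0
LYS CD  CA CB CG 1.520 111.3 x3_ref 0
LYS CE  CB CG CD 1.520 111.3 x4_ref 0
LYS NZ  CG CD CE 1.489 111.9 x4 0
MET CG  N  CA CB 1.530 114.1 x2_ref 0
MET SD  CA CB CG 1.803 112.7 x3_ref 0
MET CE  CB CG SD 1.791 100.9 x3 0
PHE CG  N  CA CB 1.502 113.8 x2_ref 0
PHE CD1 CA CB CG 1.384 120.7 x2 0
PHE CD2 CA CB CG 1.384 120.7 x2 180
PHE CE1 CB CG CD1 1.382 120.7 f 180
PHE CE2 CB CG CD2 1.382 120.7 f 180
PHE CZ  CG CD1 CE1 1.382 120.0 f 0
PRO CG  N  CA CB 1.492 104.5 x2_ref 0
PRO CD  CA CB CG 1.503 106.1 x2 0
SER OG  N  CA CB 1.417 110.8 x1 0
THR OG1 N  CA CB 1.433 109.6 x1 0
THR CG2 N  CA CB 1.521 110.5 x1 -120
TRP CG  N  CA CB 1.498 113.6 x2_ref 0
TRP CD1 CA CB CG 1.365 126.9 x2 0
TRP CD2 CA CB CG 1.433 126.6 x2 180
TRP NE1 CB CG CD1 1.374 110.2 f 180
TRP CE2 CD1 CG CD2 1.409 107.2 f 0
TRP CE3 CD1 CG CD2 1.398 133.9 f 180
TRP CZ2 CG CD2 CE2 1.398 122.4 f 180
TRP CZ3 CG CD2 CE3 1.392 118.6 f 180
TRP CH2 CD2 CE2 CZ2 1.372 117.5 f 0
TYR CG  N  CA CB 1.502 113.8 x2_ref 0
TYR CD1 CA CB CG 1.384 120.7 x2 0
TYR CD2 CA CB CG 1.384 120.7 x2 180
TYR CE1 CB CG CD1 1.382 120.7 f 180
TYR CE2 CB CG CD2 1.382 120.7 f 180
TYR CZ  CG CD1 CE1 1.382 120.0 f 0
TYR OH  CD1 CE1 CZ 1.376 119.9 f 180
VAL CG1 N  CA CB 1.521 110.5 x1 0
VAL CG2 N  CA CB 1.521 110.5 x1 120
"
# Notes on the encoding:
# - Every amino acid also gets a CB atom (added in code) at the calibrated
#   improper N-C-CA-CB = 122.6 deg, C-CA-CB = 110.5 deg, CA-CB = 1.530 A.
# - "x1" rows with dval 0 define the chi1 quadruple (N, CA, CB, atom);
#   branch atoms reuse the chi with a +/-120 deg offset.
# - "x2_ref" marks the gamma atom: it is placed by chi1 (dihedral
#   N-CA-CB-atom = chi1) and serves as the reference third atom of chi2.
#   Likewise x3_ref/x4_ref mark the delta/epsilon atoms placed by
#   chi2/chi3. "x2".."x4" rows are placed by that chi plus dval.
# - "f" rows are fixed dihedrals (ring closure, terminal sp2 groups).

# Parse the table once at load into a per-amino-acid list.
build_topology <- function() {
  tab <- utils::read.table(text = sidechain_topology_text, header = TRUE,
                           stringsAsFactors = FALSE)
  out <- list()
  for (a in unique(tab$aa)) {
    sub <- tab[tab$aa == a, ]
    rows <- list(list(atom = "CB", r1 = "N", r2 = "C", r3 = "CA",
                      bond = 1.530, angle = 110.5, chi = 0L,
                      dval = 122.6))
    for (i in seq_len(nrow(sub))) {
      d <- sub$dih[i]
      chi <- if (d == "f") 0L
             else as.integer(sub("^x([1-4]).*$", "\\1", d)) -
               as.integer(grepl("_ref", d))
      # x2_ref is placed by chi1, x3_ref by chi2, x4_ref by chi3
      rows[[length(rows) + 1]] <- list(atom = sub$atom[i], r1 = sub$r1[i],
                                       r2 = sub$r2[i], r3 = sub$r3[i],
                                       bond = sub$bond[i],
                                       angle = sub$angle[i],
                                       chi = chi, dval = sub$dval[i])
    }
    out[[a]] <- do.call(rbind, lapply(rows, as.data.frame))
  }
  out
}

topology_env <- new.env(parent = emptyenv())

#' Ideal side-chain topology table
#'
#' Per amino acid: the ordered side-chain heavy atoms with their reference
#' atoms and ideal internal coordinates (bond length in Angstroms, bond
#' angle in degrees, and the dihedral: `chi = k` means chi_k plus the offset
#' `dval`; `chi = 0` means a fixed dihedral of `dval` degrees).
#'
#' @param aa optional 3-letter code; with no argument the full list is
#'   returned.
#' @return a data.frame (one amino acid) or named list of data.frames.
#' @export
sidechain_topology <- function(aa = NULL) {
  if (is.null(topology_env$topo)) topology_env$topo <- build_topology()
  if (is.null(aa)) return(topology_env$topo)
  t <- topology_env$topo[[aa]]
  if (is.null(t)) stop("no side-chain topology for ", aa, call. = FALSE)
  t
}

# Canonical chi dihedral quadruples, derived from the topology: the chi_k
# quadruple is (r1, r2, r3, atom) of the first atom placed by chi_k with
# zero offset.
chi_quadruples <- function(aa) {
  topo <- sidechain_topology(aa)
  nchi <- chi_counts()[[aa]]
  lapply(seq_len(nchi), function(k) {
    # chi1's quadruple is (N, CA, CB, gamma-atom); the gamma atom is the
    # one placed by chi1 with zero offset (dval == 0)
    i <- which(topo$chi == k & topo$dval == 0)[1]
    c(topo$r1[i], topo$r2[i], topo$r3[i], topo$atom[i])
  })
}

#' Construct side-chain atoms from chi angles
#'
#' Places the side-chain heavy atoms of one residue by sequential
#' internal-to-Cartesian construction from the backbone (N, CA, C), using
#' ideal bond lengths and angles; the chi dihedrals are the supplied values.
#' Extracting chi from the built atoms reproduces the input.
#'
#' @param N,CA,C backbone atom coordinates (length-3, Angstroms).
#' @param aa 3-letter amino-acid code with at least one chi angle.
#' @param chi numeric vector of chi angles (radians), length `n_chi`.
#' @return matrix of side-chain atom coordinates, rownames = PDB atom names
#'   (starting with CB).
#' @export
build_side_chain <- function(N, CA, C, aa, chi) {
  topo <- sidechain_topology(aa)
  nchi <- chi_counts()[[aa]]
  if (length(chi) != nchi) {
    stop(aa, " needs ", nchi, " chi angle(s), got ", length(chi),
         call. = FALSE)
  }
  pos <- list(N = N, CA = CA, C = C)
  for (i in seq_len(nrow(topo))) {
    r <- topo[i, ]
    dih <- if (r$chi == 0) r$dval * pi / 180
           else chi[r$chi] + r$dval * pi / 180
    pos[[r$atom]] <- place_atom(pos[[r$r1]], pos[[r$r2]], pos[[r$r3]],
                                r$bond, r$angle * pi / 180, dih)
  }
  atoms <- vapply(seq_len(nrow(topo)), function(i) topo$atom[i], "")
  out <- do.call(rbind, pos[atoms])
  rownames(out) <- atoms
  out
}

# ---- Structures ------------------------------------------------------------

# A protein structure is a data.frame of heavy atoms with columns
# chain, resno, resid (3-letter), atom (PDB name), x, y, z, o, b.

new_structure <- function(df) {
  need <- c("chain", "resno", "resid", "atom", "x", "y", "z")
  stopifnot(all(need %in% names(df)))
  if (is.null(df$o)) df$o <- 1
  if (is.null(df$b)) df$b <- 0
  class(df) <- c("protein_structure", "data.frame")
  df
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("Protein structure: %d atoms, %d residues\n",
              nrow(x), length(unique(paste(x$chain, x$resno)))))
  invisible(x)
}

#' Read a PDB file into a structure table
#'
#' Parsing is delegated to bio3d; the result is a flat atom table. Hetero
#' atoms are dropped by default, hydrogens always. For alternate locations
#' the highest-occupancy copy wins. Chain breaks (consecutive CA-CA distance
#' above `break_cutoff`) and residues with incomplete backbones are reported
#' via warnings and recorded in attributes `breaks` and `incomplete`.
#'
#' @param path PDB file path.
#' @param backbone_only keep only N, CA, C, O atoms.
#' @param drop_hetero drop HETATM records.
#' @param break_cutoff CA-CA chain-break threshold in Angstroms.
#' @return a `protein_structure` data.frame.
#' @export
read_structure <- function(path, backbone_only = FALSE, drop_hetero = TRUE,
                           break_cutoff = 4.5) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (drop_hetero) at <- at[at$type == "ATOM", ]
  at <- at[is.na(at$elesy) | at$elesy != "H", ]
  at <- at[!grepl("^H", at$elety), ]
  # alternate locations: keep the highest-occupancy copy of each atom
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    ord <- order(key, -at$o)
    at <- at[ord, ][!duplicated(key[ord]), ]
    at <- at[order(as.numeric(rownames(at))), ]
  }
  if (backbone_only) at <- at[at$elety %in% c("N", "CA", "C", "O"), ]
  s <- new_structure(data.frame(chain = ifelse(is.na(at$chain), "A",
                                               at$chain),
                                resno = at$resno, resid = at$resid,
                                atom = at$elety,
                                x = at$x, y = at$y, z = at$z,
                                o = at$o, b = at$b,
                                stringsAsFactors = FALSE))
  ca <- s[s$atom == "CA", ]
  if (nrow(ca) > 1) {
    d <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
    br <- which(d > break_cutoff & diff(ca$resno) == 1)
    if (length(br)) {
      warning("chain break(s) after residue(s): ",
              paste(ca$resno[br], collapse = ", "))
    }
    attr(s, "breaks") <- ca$resno[br]
  }
  inc <- c()
  for (rn in unique(s$resno)) {
    have <- s$atom[s$resno == rn]
    if (!all(c("N", "CA", "C") %in% have)) inc <- c(inc, rn)
  }
  if (length(inc)) {
    warning("incomplete backbone for residue(s): ", paste(inc, collapse = ", "))
  }
  attr(s, "incomplete") <- inc
  s
}

#' Write a structure table as PDB
#'
#' @param structure a `protein_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  s <- structure
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
                   resno = s$resno, resid = s$resid, chain = s$chain,
                   elety = s$atom, o = s$o, b = s$b)
  invisible(path)
}

# Coordinates of one atom of one residue (length-3), or NULL if absent.
atom_xyz <- function(s, resno, atom, chain = NULL) {
  sel <- s$resno == resno & s$atom == atom
  if (!is.null(chain)) sel <- sel & s$chain == chain
  i <- which(sel)
  if (length(i) == 0) return(NULL)
  as.numeric(s[i[1], c("x", "y", "z")])
}

#' Extract backbone and side-chain dihedrals from a structure
#'
#' Computes phi/psi (missing at chain termini) and the canonical chi
#' dihedrals per residue. Residues whose side chain is incomplete get `NA`
#' chi values and are listed in the `flagged` attribute; amino acids without
#' chi angles (Ala/Gly and unknown names) get all-`NA` chi.
#'
#' @param structure a `protein_structure`.
#' @return a `chi_angles` data.frame with extra columns `chain` and `resno`,
#'   one row per residue, angles in radians.
#' @export
residue_angles <- function(structure) {
  s <- structure
  res <- unique(s[, c("chain", "resno", "resid")])
  res <- res[order(res$chain, res$resno), ]
  n <- nrow(res)
  phi <- psi <- rep(NA_real_, n)
  chi <- matrix(NA_real_, n, 4)
  flagged <- c()
  cc <- chi_counts()
  for (i in seq_len(n)) {
    rn <- res$resno[i]; ch <- res$chain[i]
    N <- atom_xyz(s, rn, "N", ch); CA <- atom_xyz(s, rn, "CA", ch)
    C <- atom_xyz(s, rn, "C", ch)
    if (is.null(N) || is.null(CA) || is.null(C)) { flagged <- c(flagged, rn); next }
    if (i > 1 && res$chain[i - 1] == ch && res$resno[i - 1] == rn - 1) {
      Cp <- atom_xyz(s, rn - 1, "C", ch)
      if (!is.null(Cp)) phi[i] <- dihedral_angle(Cp, N, CA, C)
    }
    if (i < n && res$chain[i + 1] == ch && res$resno[i + 1] == rn + 1) {
      Nn <- atom_xyz(s, rn + 1, "N", ch)
      if (!is.null(Nn)) psi[i] <- dihedral_angle(N, CA, C, Nn)
    }
    aa <- res$resid[i]
    if (aa %in% names(cc)) {
      quads <- chi_quadruples(aa)
      ok <- TRUE
      for (k in seq_along(quads)) {
        p <- lapply(quads[[k]], function(at) atom_xyz(s, rn, at, ch))
        if (any(vapply(p, is.null, TRUE))) { ok <- FALSE; break }
        chi[i, k] <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
      }
      if (!ok) { chi[i, ] <- NA_real_; flagged <- c(flagged, rn) }
    }
  }
  out <- angle_table(res$resid, phi, psi, chi)
  out <- cbind(data.frame(chain = res$chain, resno = res$resno), out)
  class(out) <- c("chi_angles", "data.frame")
  attr(out, "flagged") <- flagged
  out
}

#' Replace the side chains of a structure with rebuilt ones
#'
#' Keeps all backbone atoms (N, CA, C, O) and replaces every rotameric
#' residue's side-chain atoms with ideal-geometry atoms built from the given
#' chi assignment. Residues absent from `chi` (and Ala/Gly) keep only their
#' backbone.
#'
#' @param structure a `protein_structure` (side chains, if any, are
#'   discarded).
#' @param chi named list: `chi[["<resno>"]]` is the chi vector (radians) for
#'   that residue.
#' @return a `protein_structure` with rebuilt side chains.
#' @export
rebuild_side_chains <- function(structure, chi) {
  s <- structure[structure$atom %in% c("N", "CA", "C", "O"), ]
  res <- unique(s[, c("chain", "resno", "resid")])
  add <- list()
  for (i in seq_len(nrow(res))) {
    key <- as.character(res$resno[i])
    if (is.null(chi[[key]])) next
    rn <- res$resno[i]; ch <- res$chain[i]
    sc <- build_side_chain(atom_xyz(s, rn, "N", ch),
                           atom_xyz(s, rn, "CA", ch),
                           atom_xyz(s, rn, "C", ch),
                           res$resid[i], chi[[key]])
    add[[length(add) + 1]] <- data.frame(chain = ch, resno = rn,
                                         resid = res$resid[i],
                                         atom = rownames(sc),
                                         x = sc[, 1], y = sc[, 2],
                                         z = sc[, 3], o = 1, b = 0,
                                         stringsAsFactors = FALSE)
  }
  out <- rbind(as.data.frame(s), do.call(rbind, add))
  out <- out[order(out$chain, out$resno), ]
  rownames(out) <- NULL
  new_structure(out)
}

#' Build an ideal-geometry backbone from phi/psi angles
#'
#' Constructs a single-chain poly-peptide backbone (N, CA, C, O per residue)
#' with ideal bond lengths/angles and trans peptide bonds, from per-residue
#' phi/psi. phi of the first residue and psi of the last are not needed
#' (any finite value is accepted and ignored).
#'
#' @param aa character vector of 3-letter codes.
#' @param phi,psi numeric vectors of backbone dihedrals in radians.
#' @param omega peptide-bond dihedral (radians), default trans.
#' @return a `protein_structure` with residues numbered from 1, chain "A".
#' @export
build_backbone <- function(aa, phi, psi, omega = pi) {
  n <- length(aa)
  stopifnot(length(phi) == n, length(psi) == n)
  rows <- list()
  put <- function(rn, resid, atom, p) {
    rows[[length(rows) + 1]] <<- data.frame(chain = "A", resno = rn,
                                            resid = resid, atom = atom,
                                            x = p[1], y = p[2], z = p[3],
                                            o = 1, b = 0,
                                            stringsAsFactors = FALSE)
  }
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  th <- 111.2 * pi / 180
  C <- place_atom(c(0, 1, 0), N, CA, 1.525, th, phi[1])
  for (i in seq_len(n)) {
    put(i, aa[i], "N", N); put(i, aa[i], "CA", CA); put(i, aa[i], "C", C)
    O <- place_atom(N, CA, C, 1.231, 120.5 * pi / 180,
                    wrap_angle(psi[i] + pi))
    put(i, aa[i], "O", O)
    if (i < n) {
      Nn <- place_atom(N, CA, C, 1.329, 116.2 * pi / 180, psi[i])
      CAn <- place_atom(CA, C, Nn, 1.458, 121.7 * pi / 180, omega)
      Cn <- place_atom(C, Nn, CAn, 1.525, 111.2 * pi / 180, phi[i + 1])
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  new_structure(do.call(rbind, rows))
}
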