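# Deterministic synthetic peptide structures built from internal
# coordinates (ideal bond lengths/angles, prescribed phi/psi/chi), written
# as PDB-format text. These are the fixtures for descriptor testing: the
# prescribed geometry is the ground truth the extractors must recover.

# Ideal heavy-atom internal coordinates (Engh-Huber-style constants).
IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.531, b_cb_cg = 1.507, b_cg_od1 = 1.213, b_cg_nd2 = 1.348,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  a_c_ca_cb = 110.5, a_ca_cb_cg = 109.5, a_cb_cg_od1 = 120.0,
  a_cb_cg_nd2 = 120.0,
  # improper torsion N-C-CA-CB fixing L-chirality
  t_cb_improper = -120.0,
  omega = 180
)

#' Specification of a synthetic peptide
#'
#' @param sequence 1-letter amino-acid string (standard 20 codes; residues
#'   other than Gly get a C-beta, Asn gets a full side chain).
#' @param phi,psi Backbone torsions in degrees, recycled along the chain.
#' @param chi1,chi2 Asn side-chain torsions in degrees, recycled over the
#'   Asn residues.
#' @param bfactor Per-atom B-factors: a single value, a per-residue
#'   vector, or a function(atom_count) returning one value per atom.
#' @param chain_id Single-character chain identifier.
#' @param cage If `TRUE`, surround the peptide with a shell of carbon-like
#'   pseudo-atoms 4 Angstrom from each peptide atom (burial construction
#'   for solvent-accessibility tests).
#' @return An object of class `peptide_spec`.
#' @export
peptide_spec <- function(sequence, phi = -60, psi = -45, chi1 = -65,
                         chi2 = -20, bfactor = 20, chain_id = "A",
                         cage = FALSE) {
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) < 2) stop("sequence must have at least 2 residues")
  bad <- !aa %in% unname(AA3TO1)
  if (any(bad)) stop("invalid residue code(s): ", paste(aa[bad], collapse = ", "))
  ang_ok <- function(x) all(x > -180 & x <= 180)
  if (!ang_ok(phi) || !ang_ok(psi) || !ang_ok(chi1) || !ang_ok(chi2)) {
    stop("torsions must lie in (-180, 180]")
  }
  structure(list(
    sequence = aa,
    phi = rep_len(phi, length(aa)), psi = rep_len(psi, length(aa)),
    chi1 = chi1, chi2 = chi2,
    bfactor = bfactor, chain_id = chain_id, cage = cage
  ), class = "peptide_spec")
}

# Full-precision atom table for a peptide spec: one row per atom with
# residue index, names and coordinates, plus cage pseudo-atoms if asked.
build_peptide_atoms <- function(spec) {
  stopifnot(inherits(spec, "peptide_spec"))
  g <- IDEAL_GEOM
  aa1to3 <- stats::setNames(names(AA3TO1), unname(AA3TO1))
  nres <- length(spec$sequence)
  chi1 <- rep_len(spec$chi1, nres)
  chi2 <- rep_len(spec$chi2, nres)

  atoms <- list() # each: list(res, name, element, xyz)
  push <- function(res, name, element, xyz) {
    atoms[[length(atoms) + 1]] <<- list(res = res, name = name,
                                        element = element, xyz = xyz)
  }

  # residue 1 backbone seeds a canonical frame
  N <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  th <- (180 - g$a_n_ca_c) * pi / 180
  C <- CA + g$b_ca_c * c(cos(th), sin(th), 0)
  prevN <- prevCA <- prevC <- NULL

  for (i in seq_len(nres)) {
    if (i > 1) {
      N <- nerf_place(prevN, prevCA, prevC, g$b_c_n, g$a_ca_c_n, spec$psi[i - 1])
      CA <- nerf_place(prevCA, prevC, N, g$b_n_ca, g$a_c_n_ca, g$omega)
      C <- nerf_place(prevC, N, CA, g$b_ca_c, g$a_n_ca_c, spec$phi[i])
    }
    res3 <- aa1to3[[spec$sequence[i]]]
    push(i, "N", "N", N)
    push(i, "CA", "C", CA)
    push(i, "C", "C", C)
    # carbonyl O: anti to the next N, i.e. torsion psi + 180 about CA-C
    push(i, "O", "O",
         nerf_place(N, CA, C, g$b_c_o, g$a_ca_c_o, spec$psi[i] + 180))
    if (spec$sequence[i] != "G") {
      CB <- nerf_place(N, C, CA, g$b_ca_cb, g$a_c_ca_cb, g$t_cb_improper)
      push(i, "CB", "C", CB)
      if (spec$sequence[i] == "N") {
        CG <- nerf_place(N, CA, CB, g$b_cb_cg, g$a_ca_cb_cg, chi1[i])
        push(i, "CG", "C", CG)
        push(i, "OD1", "O",
             nerf_place(CA, CB, CG, g$b_cg_od1, g$a_cb_cg_od1, chi2[i]))
        push(i, "ND2", "N",
             nerf_place(CA, CB, CG, g$b_cg_nd2, g$a_cb_cg_nd2, chi2[i] + 180))
      }
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }

  natoms <- length(atoms)
  bf <- spec$bfactor
  if (is.function(bf)) {
    bf <- bf(natoms)
  } else if (length(bf) == nres) {
    bf <- bf[vapply(atoms, `[[`, numeric(1), "res")]
  } else {
    bf <- rep_len(bf, natoms)
  }

  tab <- data.frame(
    res = vapply(atoms, `[[`, numeric(1), "res"),
    resname = aa1to3[spec$sequence[vapply(atoms, `[[`, numeric(1), "res")]],
    name = vapply(atoms, `[[`, character(1), "name"),
    element = vapply(atoms, `[[`, character(1), "element"),
    x = vapply(atoms, function(a) a$xyz[1], numeric(1)),
    y = vapply(atoms, function(a) a$xyz[2], numeric(1)),
    z = vapply(atoms, function(a) a$xyz[3], numeric(1)),
    bfactor = bf, hetero = FALSE, stringsAsFactors = FALSE
  )

  if (isTRUE(spec$cage)) {
    # dodecahedral shell of carbon-like pseudo-atoms 4 A from every
    # peptide atom: a reproducible burial construction
    gr <- (1 + sqrt(5)) / 2
    verts <- rbind(
      expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)),
      data.frame(x = 0, y = c(-1, 1, -1, 1) / gr, z = c(-gr, -gr, gr, gr)),
      data.frame(x = c(-1, 1, -1, 1) / gr, y = c(-gr, -gr, gr, gr), z = 0),
      data.frame(x = c(-gr, -gr, gr, gr), y = 0, z = c(-1, 1, -1, 1) / gr)
    )
    verts <- as.matrix(verts) / sqrt(3) * 4
    cage <- do.call(rbind, lapply(seq_len(natoms), function(k) {
      data.frame(res = 900 + k, resname = "CAG", name = "C", element = "C",
                 x = atoms[[k]]$xyz[1] + verts[, 1],
                 y = atoms[[k]]$xyz[2] + verts[, 2],
                 z = atoms[[k]]$xyz[3] + verts[, 3],
                 bfactor = 20, hetero = TRUE, stringsAsFactors = FALSE)
    }))
    tab <- rbind(tab, cage)
  }
  tab
}

#' Build PDB-format text from a peptide specification
#'
#' Grows the backbone by natural-extension (NeRF) placement with ideal
#' bond geometry, omega fixed at 180 degrees and the prescribed phi/psi;
#' Asn side chains are placed at the prescribed chi1/chi2. The output
#' parses through [read_structure()]. Coordinates carry the PDB format's
#' 3-decimal precision; for exact-precision work use
#' [build_peptide_structure()].
#'
#' @param spec A `peptide_spec`.
#' @return Character vector of PDB lines.
#' @export
build_peptide <- function(spec) {
  tab <- build_peptide_atoms(spec)
  serial <- seq_len(nrow(tab))
  nm <- ifelse(nchar(tab$name) >= 4, tab$name, sprintf(" %-3s", tab$name))
  lines <- sprintf(
    "%s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(tab$hetero, "HETATM", "ATOM  "), serial, nm, tab$resname,
    ifelse(tab$hetero, "X", spec$chain_id), tab$res,
    tab$x, tab$y, tab$z, 1.00, tab$bfactor, tab$element)
  c(lines, "END")
}

#' Build an in-memory structure from a peptide specification
#'
#' Identical geometry to [build_peptide()] but without the round trip
#' through PDB text, so coordinates keep full double precision and the
#' prescribed torsions round-trip to 1e-6 degrees and better.
#'
#' @param spec A `peptide_spec`.
#' @return A `deam_structure`.
#' @export
build_peptide_structure <- function(spec) {
  tab <- build_peptide_atoms(spec)
  mk <- function(t, chain) data.frame(
    record = ifelse(t$hetero, "HETATM", "ATOM  "), name = t$name,
    altloc = rep(" ", nrow(t)), resname = t$resname,
    chain = rep(chain, nrow(t)), resseq = t$res,
    icode = rep("", nrow(t)), x = t$x, y = t$y, z = t$z,
    occupancy = rep(1, nrow(t)), bfactor = t$bfactor, element = t$element,
    stringsAsFactors = FALSE)
  prot <- mk(tab[!tab$hetero, , drop = FALSE], spec$chain_id)
  lig <- mk(tab[tab$hetero, , drop = FALSE], "X")
  structure(list(atoms = prot, ligand = lig, resolution = NA_real_,
                 chain_order = spec$chain_id),
            class = "deam_structure")
}
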