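# Per-site structural descriptors: normalized B-factors, dihedrals and
# the nucleophilic attack distance.

# A not-predictable marker carrying the reason(s).
site_status <- function(reason) {
  structure(list(predictable = FALSE, reason = reason), class = "site_status")
}

is_site_status <- function(x) inherits(x, "site_status")

#' Normalize crystallographic B-factors to z-scores
#'
#' z = (B - mu) / sigma, where mu and sigma are the mean and population
#' standard deviation of the B-factors of all heavy protein atoms of the
#' whole structure (all chains; waters, ligands and hydrogens excluded).
#' Relative flexibility is thereby comparable across structures solved at
#' different resolutions.
#'
#' @param structure A `deam_structure`.
#' @return Numeric vector of z-scores, one per row of `structure$atoms`.
#' @export
normalize_bfactors <- function(structure) {
  b <- structure$atoms$bfactor
  if (length(b) < 2) stop("need at least 2 heavy atoms to normalize B-factors")
  mu <- mean(b)
  sigma <- sqrt(mean((b - mu)^2)) # population sd
  if (sigma == 0) {
    warning("uniform B-factors: all z-scores set to 0")
    return(rep(0, length(b)))
  }
  (b - mu) / sigma
}

#' B-factor descriptors of an Asn site
#'
#' Returns the z-scores of the four key carbons of the Asn residue:
#' backbone carbonyl C, C-alpha, C-beta and C-gamma.
#'
#' @param structure A `deam_structure`.
#' @param site One site row from [enumerate_asn_sites()].
#' @param zscores Optional precomputed result of [normalize_bfactors()].
#' @return Named numeric vector (zb_c, zb_ca, zb_cb, zb_cg), or a
#'   `site_status` when a carbon is missing.
#' @export
bfactor_descriptors <- function(structure, site, zscores = NULL) {
  if (is.null(zscores)) zscores <- normalize_bfactors(structure)
  a <- structure$atoms
  sel <- a$chain == site$chain & residue_key(a$resseq, a$icode) == site$key
  want <- c("C", "CA", "CB", "CG")
  idx <- match(want, a$name[sel])
  if (anyNA(idx)) {
    return(site_status(sprintf("Asn %s missing atom(s): %s", site$key,
                               paste(want[is.na(idx)], collapse = ", "))))
  }
  stats::setNames(zscores[which(sel)[idx]], c("zb_c", "zb_ca", "zb_cb", "zb_cg"))
}

#' Nucleophilic attack distance of an Asn site
#'
#' Distance between the Asn side-chain carbonyl carbon (CG) and the
#' backbone amide nitrogen of the following residue, the two atoms that
#' must approach to form the succinimide intermediate.
#'
#' @param structure A `deam_structure`.
#' @param chain Residue data frame from [select_chain()].
#' @param site One site row.
#' @return Distance in Angstrom, or a `site_status`.
#' @export
attack_distance <- function(structure, chain, site) {
  i <- match(site$key, chain$key)
  cg <- atom_xyz(residue_atoms(structure, site$chain, site$key), "CG")
  nn <- NULL
  if (!is.na(i) && i < nrow(chain)) {
    nn <- atom_xyz(residue_atoms(structure, site$chain, chain$key[i + 1]), "N")
  }
  if (is.null(cg) || is.null(nn)) {
    miss <- c(if (is.null(cg)) "CG", if (is.null(nn)) "N(i+1)")
    return(site_status(sprintf("Asn %s missing atom(s): %s", site$key,
                               paste(miss, collapse = ", "))))
  }
  d <- dist3(cg, nn)
  if (d == 0) warning(sprintf("Asn %s: attack distance is 0 (coincident atoms)", site$key))
  d
}

#' Backbone and side-chain dihedrals of an Asn site
#'
#' phi = C(i-1)-N-CA-C, psi = N-CA-C-N(i+1), chi1 = N-CA-CB-CG,
#' chi2 = CA-CB-CG-OD1 (IUPAC atom choice for asparagine). An N-terminal
#' Asn has no phi and is reported not predictable.
#'
#' @param structure A `deam_structure`.
#' @param chain Residue data frame from [select_chain()].
#' @param site One site row.
#' @return Named numeric vector (phi, psi, chi1, chi2) in degrees, or a
#'   `site_status`.
#' @export
site_dihedrals <- function(structure, chain, site) {
  i <- match(site$key, chain$key)
  res <- residue_atoms(structure, site$chain, site$key)
  n <- atom_xyz(res, "N"); ca <- atom_xyz(res, "CA"); cc <- atom_xyz(res, "C")
  cb <- atom_xyz(res, "CB"); cg <- atom_xyz(res, "CG"); od1 <- atom_xyz(res, "OD1")
  c_prev <- if (!is.na(i) && i > 1)
    atom_xyz(residue_atoms(structure, site$chain, chain$key[i - 1]), "C") else NULL
  n_next <- if (!is.na(i) && i < nrow(chain))
    atom_xyz(residue_atoms(structure, site$chain, chain$key[i + 1]), "N") else NULL

  miss <- character(0)
  for (nm in c("N", "CA", "C", "CB", "CG", "OD1")) {
    if (is.null(get(c(N = "n", CA = "ca", C = "cc", CB = "cb", CG = "cg",
                      OD1 = "od1")[[nm]]))) miss <- c(miss, nm)
  }
  if (is.null(n_next)) miss <- c(miss, "N(i+1)")
  if (length(miss)) {
    return(site_status(sprintf("Asn %s missing atom(s): %s", site$key,
                               paste(miss, collapse = ", "))))
  }
  if (is.null(c_prev)) {
    return(site_status(sprintf("Asn %s is N-terminal: phi undefined", site$key)))
  }
  c(phi  = dihedral(c_prev, n, ca, cc),
    psi  = dihedral(n, ca, cc, n_next),
    chi1 = dihedral(n, ca, cb, cg),
    chi2 = dihedral(ca, cb, cg, od1))
}
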