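# Solvent-accessible surface area by sphere sampling (Shrake-Rupley) and
# the percent-accessibility descriptors PSA / PSSA.

# van der Waals radii (Angstrom) by element; default carbon-like.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Deterministic quasi-uniform points on the unit sphere (Fibonacci
# lattice); no RNG so SASA is bit-reproducible.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Absolute SASA (A^2) per atom over a set of atoms given as a data frame
# with x, y, z, element. O(n * neighbours) with a cutoff-based neighbour
# list; adequate for single structures.
shrake_rupley <- function(atoms, probe = 1.4, n_points = 960) {
  n <- nrow(atoms)
  pts <- fibonacci_sphere(n_points)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- VDW_RADII[atoms$element]
  r[is.na(r)] <- 1.70
  r <- r + probe
  out <- numeric(n)
  maxr <- max(r)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2]
    sp <- pts * r[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dd <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        acc <- acc & dd > r[j]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    out[i] <- frac * 4 * pi * r[i]^2
  }
  out
}

# Cache for the Asn maximal-ASA reference (depends on n_points).
.asn_ref_cache <- new.env(parent = emptyenv())

# Reference maximal ASA of Asn (residue and side chain), computed from a
# fully extended synthetic Gly-Asn-Gly tripeptide built by the package's
# own peptide generator. Self-consistent with the sampling algorithm and
# swappable via the `reference` argument of accessibility().
asn_reference_asa <- function(probe = 1.4, n_points = 960) {
  key <- sprintf("p%d_%.2f", n_points, probe)
  if (!is.null(.asn_ref_cache[[key]])) return(.asn_ref_cache[[key]])
  spec <- peptide_spec("GNG", phi = 180, psi = 180, chi1 = -65, chi2 = -20)
  s <- read_structure(build_peptide(spec))
  asa <- shrake_rupley(s$atoms, probe = probe, n_points = n_points)
  sel <- s$atoms$resname == "ASN"
  side <- sel & !(s$atoms$name %in% BACKBONE_ATOMS)
  ref <- c(residue = sum(asa[sel]), sidechain = sum(asa[side]))
  .asn_ref_cache[[key]] <- ref
  ref
}

#' Percent solvent accessibility of an Asn site
#'
#' Absolute accessible surface area is computed by sphere sampling over
#' all heavy protein atoms of the structure (probe 1.4 Angstrom), then
#' expressed as a percentage of the maximal ASA of Asn in an extended
#' Gly-Asn-Gly reference tripeptide: PSA over all residue atoms, PSSA
#' over side-chain atoms only. Ratios above 100 (more exposed than the
#' reference) are clipped with a warning.
#'
#' @param structure A `deam_structure`.
#' @param site One site row.
#' @param probe Probe radius, Angstrom.
#' @param n_points Sphere sample points per atom.
#' @param reference Optional numeric vector `c(residue =, sidechain =)`
#'   of maximal ASA values to use instead of the built-in reference.
#' @param asa Optional precomputed per-atom ASA for `structure$atoms`.
#' @param include_ligand Occlude the protein surface with non-water
#'   hetero atoms as well (default `FALSE`: protein atoms only).
#' @return Named vector (psa, pssa) in percent, or a `site_status`.
#' @export
accessibility <- function(structure, site, probe = 1.4, n_points = 960,
                          reference = NULL, asa = NULL,
                          include_ligand = FALSE) {
  a <- structure$atoms
  sel <- a$chain == site$chain & residue_key(a$resseq, a$icode) == site$key
  if (!any(sel)) return(site_status(sprintf("Asn %s has no atoms", site$key)))
  side <- sel & !(a$name %in% BACKBONE_ATOMS)
  if (!any(side)) {
    return(site_status(sprintf("Asn %s has no side-chain atoms", site$key)))
  }
  if (is.null(asa)) {
    pool <- a
    if (include_ligand && nrow(structure$ligand)) {
      lig <- structure$ligand
      lig <- lig[!lig$resname %in% WATER_NAMES, , drop = FALSE]
      pool <- rbind(a, lig)
    }
    asa <- shrake_rupley(pool, probe = probe, n_points = n_points)[seq_len(nrow(a))]
  }
  if (is.null(reference)) reference <- asn_reference_asa(probe, n_points)
  psa <- 100 * sum(asa[sel]) / reference[["residue"]]
  pssa <- 100 * sum(asa[side]) / reference[["sidechain"]]
  if (psa > 100 || pssa > 100) {
    warning(sprintf("Asn %s more exposed than the reference (PSA %.1f, PSSA %.1f); clipping to 100",
                    site$key, psa, pssa))
  }
  c(psa = min(psa, 100), pssa = min(pssa, 100))
}
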