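# Assembly of the 13-descriptor feature vector per Asn site and the
# structure -> feature-table pipeline.

# Canonical descriptor order of the feature set.
FEATURE_NAMES <- c("half_life", "phi", "psi", "chi1", "chi2",
                   "secondary_structure", "zb_c", "zb_ca", "zb_cb", "zb_cg",
                   "psa", "pssa", "attack_distance")

#' Compute the 13-descriptor feature vector for one Asn site
#'
#' Combines the penta-peptide half-life lookup with the structural
#' descriptors: backbone/side-chain dihedrals, the 4-level secondary
#' structure code, normalized B-factors of the four key carbons, percent
#' solvent accessibilities and the nucleophilic attack distance. Any
#' unpredictable sub-result (Yyy = Q, missing atoms, N-terminal phi)
#' propagates to a `site_status` whose reason concatenates all causes.
#'
#' @param structure A `deam_structure`.
#' @param chain Residue data frame from [select_chain()].
#' @param site One site row from [enumerate_asn_sites()].
#' @param half_life_table A `half_life_table`.
#' @param zscores,asa,ss Optional precomputed whole-structure results
#'   (B-factor z-scores, per-atom ASA, per-residue secondary structure)
#'   to avoid recomputation across sites.
#' @return Named numeric vector of the 13 descriptors, or a `site_status`.
#' @export
featurize <- function(structure, chain, site, half_life_table,
                      zscores = NULL, asa = NULL, ss = NULL) {
  reasons <- character(0)

  hl <- lookup_half_life(half_life_table, site)
  if (!hl$predictable) reasons <- c(reasons, hl$reason)

  dih <- site_dihedrals(structure, chain, site)
  if (is_site_status(dih)) reasons <- c(reasons, dih$reason)

  zb <- bfactor_descriptors(structure, site, zscores = zscores)
  if (is_site_status(zb)) reasons <- c(reasons, zb$reason)

  acc <- accessibility(structure, site, asa = asa)
  if (is_site_status(acc)) reasons <- c(reasons, acc$reason)

  ad <- attack_distance(structure, chain, site)
  if (is_site_status(ad)) reasons <- c(reasons, ad$reason)

  if (length(reasons)) return(site_status(paste(unique(reasons), collapse = "; ")))

  if (is.null(ss)) ss <- secondary_structure(structure, chain)
  ss_i <- ss[match(site$key, chain$key)]

  out <- c(half_life = hl$half_life, dih["phi"], dih["psi"], dih["chi1"],
           dih["chi2"], secondary_structure = ss_i, zb, acc,
           attack_distance = ad)
  stats::setNames(out[FEATURE_NAMES], FEATURE_NAMES)
}

#' Extract the feature table for all Asn sites of a structure
#'
#' @param structure A `deam_structure`.
#' @param half_life_table A `half_life_table`.
#' @param chain_id Optional chain identifier (default: most complete chain).
#' @param n_points Sphere sample points for the accessibility descriptors.
#' @return A data frame with site identity columns (chain, resseq, icode,
#'   xxx, yyy), a `status` column ("ok" or the not-predictable reason)
#'   and the 13 descriptor columns (`NA` on unpredictable rows).
#' @export
extract_features <- function(structure, half_life_table, chain_id = NULL,
                             n_points = 960) {
  chain <- select_chain(structure, chain_id)
  sites <- enumerate_asn_sites(chain)
  empty <- data.frame(matrix(numeric(0), ncol = length(FEATURE_NAMES),
                             dimnames = list(NULL, FEATURE_NAMES)))
  if (!nrow(sites)) {
    return(cbind(sites[, c("chain", "resseq", "icode", "xxx", "yyy")],
                 status = character(0), empty))
  }
  zscores <- normalize_bfactors(structure)
  asa <- shrake_rupley(structure$atoms, n_points = n_points)
  ss <- secondary_structure(structure, chain)

  rows <- lapply(seq_len(nrow(sites)), function(i) {
    fv <- featurize(structure, chain, sites[i, ], half_life_table,
                    zscores = zscores, asa = asa, ss = ss)
    if (is_site_status(fv)) {
      c(list(status = fv$reason),
        stats::setNames(as.list(rep(NA_real_, length(FEATURE_NAMES))),
                        FEATURE_NAMES))
    } else {
      c(list(status = "ok"), as.list(fv))
    }
  })
  cbind(sites[, c("chain", "resseq", "icode", "xxx", "yyy")],
        do.call(rbind, lapply(rows, as.data.frame)))
}

#' Write a feature table as CSV
#'
#' @param features Data frame from [extract_features()].
#' @param path Output path.
#' @param keep_unpredictable Keep rows whose status is not "ok" (with
#'   explicit missing markers) for audit; default drops them.
#' @export
write_features_csv <- function(features, path, keep_unpredictable = FALSE) {
  if (!keep_unpredictable) {
    features <- features[features$status == "ok", , drop = FALSE]
  }
  utils::write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}
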