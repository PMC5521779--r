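# Penta-peptide deamidation half-life lookup (Gly-Xxx-Asn-Yyy-Gly) with
# the substitution rules for residues missing from the measured table.
# The numeric half-lives are an experimental data set that is supplied by
# the user as CSV; a coverage-validated template ships with the package.

# Residue coverage of the measured table. Xxx = N and Q fall back to G;
# Yyy = P gets the 999-day sentinel, Yyy = N shifts the window, Yyy = Q is
# not predictable.
HALF_LIFE_XXX <- c("G", "S", "T", "C", "M", "F", "Y", "D", "E", "H", "K",
                   "R", "A", "L", "V", "I", "W", "P")
HALF_LIFE_YYY <- c("G", "H", "S", "A", "D", "T", "C", "K", "M", "E", "R",
                   "F", "Y", "W", "L", "V", "I")

# Proline's backbone nitrogen cannot perform the nucleophilic attack, so
# Yyy = P is assigned this sentinel half-life (days).
PROLINE_SENTINEL_DAYS <- 999

#' Read and validate a penta-peptide half-life table
#'
#' The CSV must have columns `xxx,yyy,half_life_days` and cover every
#' (Xxx, Yyy) pair of the measured residue sets (18 Xxx times 17 Yyy).
#'
#' @param path CSV path, or a data frame with the same columns.
#' @return An object of class `half_life_table`.
#' @export
read_half_life_table <- function(path) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("xxx", "yyy", "half_life_days")
  if (!all(need %in% names(df))) {
    stop("half-life table must have columns: ", paste(need, collapse = ", "))
  }
  df$half_life_days <- as.numeric(df$half_life_days)
  if (anyNA(df$half_life_days)) {
    stop("half-life table contains missing values; fill in the placeholder column ",
         "of the shipped template with measured half-lives (days)")
  }
  if (any(df$half_life_days <= 0)) stop("half-lives must be positive (days)")
  want <- expand.grid(xxx = HALF_LIFE_XXX, yyy = HALF_LIFE_YYY,
                      stringsAsFactors = FALSE)
  have <- paste(df$xxx, df$yyy)
  missing <- !(paste(want$xxx, want$yyy) %in% have)
  if (any(missing)) {
    stop(sprintf("half-life table is missing %d (Xxx, Yyy) pairs, e.g. (%s, %s)",
                 sum(missing), want$xxx[which(missing)[1]], want$yyy[which(missing)[1]]))
  }
  tab <- stats::setNames(df$half_life_days, paste(df$xxx, df$yyy))
  structure(list(entries = tab), class = "half_life_table")
}

#' Look up the deamidation half-life for an Asn site
#'
#' Applies the substitution rules in order: (1) Yyy = P receives the
#' 999-day sentinel (proline cannot attack); (2) Yyy = Q is not
#' predictable; (3) Yyy = N shifts the penta-peptide window one residue
#' towards the C-terminus (Xxx becomes N, Yyy becomes the i+2 residue,
#' rules 1-2 re-applied); (4) Xxx in {N, Q} or absent is substituted by G
#' (Xxx hardly affects the half-life); (5) otherwise direct lookup.
#'
#' @param table A `half_life_table`.
#' @param site One row of [enumerate_asn_sites()] output (or any list with
#'   `xxx`, `yyy`, `yyy2` 1-letter codes).
#' @return A list with `predictable` (logical) and either `half_life`
#'   (days) or `reason`.
#' @export
lookup_half_life <- function(table, site) {
  stopifnot(inherits(table, "half_life_table"))
  xxx <- site$xxx
  yyy <- site$yyy
  if (is.null(yyy) || is.na(yyy)) {
    return(list(predictable = FALSE, reason = "no C-terminal neighbour (Yyy)"))
  }
  if (yyy == "P") {
    return(list(predictable = TRUE, half_life = PROLINE_SENTINEL_DAYS))
  }
  if (yyy == "Q") {
    return(list(predictable = FALSE, reason = "Yyy = Q has no measured half-life"))
  }
  if (yyy == "N") {
    yyy2 <- site$yyy2
    if (is.null(yyy2) || is.na(yyy2)) {
      return(list(predictable = FALSE,
                  reason = "Yyy = N shift needs residue i+2, which is absent"))
    }
    # shifted penta-peptide: Xxx = N (-> G by rule 4), Yyy = residue i+2
    return(lookup_half_life(table, list(xxx = "N", yyy = yyy2, yyy2 = NA)))
  }
  if (is.null(xxx) || is.na(xxx) || xxx %in% c("N", "Q")) xxx <- "G"
  key <- paste(xxx, yyy)
  if (!key %in% names(table$entries)) {
    stop(sprintf("half-life table has no entry for (Xxx = %s, Yyy = %s)", xxx, yyy))
  }
  list(predictable = TRUE, half_life = unname(table$entries[key]))
}

#' Write the half-life table template
#'
#' Emits a CSV covering every required (Xxx, Yyy) pair with the
#' `half_life_days` column left as the placeholder `NA`, to be filled in
#' from the experimental penta-peptide measurements.
#'
#' @param path Output CSV path.
#' @export
write_half_life_template <- function(path) {
  want <- expand.grid(xxx = HALF_LIFE_XXX, yyy = HALF_LIFE_YYY,
                      stringsAsFactors = FALSE)
  want$half_life_days <- NA_real_
  utils::write.csv(want, path, row.names = FALSE, na = "NA")
  invisible(path)
}
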