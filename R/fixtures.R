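# Synthetic data generation for model testing: feature tables with
# planted signal emulating the study-like class proportions (194 sites /
# 28 deamidated for training, 81 / 5 for testing), a paired benchmark,
# a synthetic penta-peptide half-life table, and the NG-motif test-set
# composition. Everything is seed-deterministic.

# Feature columns with planted class signal, and their shift weights
# (multiplied by `effect`, in units of the feature's sd). The design
# mirrors the qualitative importance structure of real deamidation data:
# half-life dominant, a few dihedral/B-factor features moderate, and
# secondary structure carrying no signal at all.
PLANTED_WEIGHTS <- c(psi = 0.6, chi2 = 0.55, phi = 0.5,
                     zb_cb = 0.55, zb_ca = 0.45)

#' Specification of a synthetic feature table
#'
#' @param n Number of sites (rows), at least 10.
#' @param prevalence Positive (deamidated) fraction; the realized count
#'   is exactly `round(n * prevalence)`.
#' @param effect Class separation of the informative features, in sd
#'   units (scaled per feature by the built-in weights).
#' @param seed Integer seed.
#' @return A `table_spec` list.
#' @export
table_spec <- function(n = 194, prevalence = 28 / 194, effect = 2,
                       seed = 20170721) {
  stopifnot(n >= 10, prevalence > 0, prevalence < 1)
  if (round(n * prevalence) < 1) stop("prevalence too low: no positive rows")
  structure(list(n = n, prevalence = prevalence, effect = effect,
                 seed = as.integer(seed)), class = "table_spec")
}

#' Generate a synthetic 13-descriptor feature table with planted signal
#'
#' Columns are the canonical descriptor set in its standard order. The
#' half-life column is a label-correlated bimodal mixture (short-lived
#' versus 999-like sentinel values), emulating its dominant importance in
#' real deamidation data; the informative structural columns are
#' class-shifted normals; the remaining columns are class-independent
#' noise on realistic scales.
#'
#' @param spec A [table_spec()].
#' @return List with `features` (data frame, 13 columns), `labels`
#'   (integer, 1 = deamidated) and `manifest` (planted ground truth).
#' @export
build_feature_table <- function(spec) {
  stopifnot(inherits(spec, "table_spec"))
  set.seed(spec$seed)
  n <- spec$n
  npos <- round(n * spec$prevalence)
  y <- sample(c(rep(1L, npos), rep(0L, n - npos)))

  # half-life: deamidated sites are mostly fast (days-weeks); stable
  # sites a mixture of slow peptides and the 999-day proline-like
  # sentinel. The label correlation scales with `effect` so that
  # effect = 0 yields a genuinely null table.
  stable_draw <- function(m) {
    slow <- stats::runif(m) < 0.6
    out <- exp(stats::rnorm(m, log(250), 0.7))
    out[slow] <- 999
    out
  }
  pos <- y == 1
  p_fast <- 0.9 * min(1, spec$effect / 2)
  fast <- pos & stats::runif(n) < p_fast
  hl <- numeric(n)
  hl[fast] <- exp(stats::rnorm(sum(fast), log(8), 0.8))
  hl[!fast] <- stable_draw(sum(!fast))

  base <- list(
    phi = c(-80, 35), psi = c(-10, 60), chi1 = c(-65, 30), chi2 = c(-20, 45),
    zb_c = c(0, 1), zb_ca = c(0, 1), zb_cb = c(0, 1), zb_cg = c(0, 1),
    psa = c(45, 20), pssa = c(50, 22), attack_distance = c(4.6, 0.7)
  )
  col <- function(nm) {
    mu <- base[[nm]][1]; sdv <- base[[nm]][2]
    shift <- if (nm %in% names(PLANTED_WEIGHTS))
      spec$effect * PLANTED_WEIGHTS[[nm]] * sdv else 0
    stats::rnorm(n, mu, sdv) + y * shift
  }
  features <- data.frame(
    half_life = hl,
    phi = col("phi"), psi = col("psi"), chi1 = col("chi1"), chi2 = col("chi2"),
    secondary_structure = sample(1:4, n, replace = TRUE),
    zb_c = col("zb_c"), zb_ca = col("zb_ca"), zb_cb = col("zb_cb"),
    zb_cg = col("zb_cg"),
    psa = pmin(pmax(col("psa"), 0), 100),
    pssa = pmin(pmax(col("pssa"), 0), 100),
    attack_distance = pmax(col("attack_distance"), 2.5)
  )
  manifest <- list(
    informative = c("half_life", names(PLANTED_WEIGHTS)),
    noise = setdiff(FEATURE_NAMES, c("half_life", names(PLANTED_WEIGHTS))),
    effect = spec$effect, weights = as.list(PLANTED_WEIGHTS),
    n = n, n_positive = npos, seed = spec$seed
  )
  list(features = features, labels = y, manifest = manifest)
}

#' Paired train/test benchmark with one generating mechanism
#'
#' Training table with the 194-site / 28-positive composition and a test
#' table with the 81-site / 5-positive composition, drawn from the same
#' planted-signal mechanism (planted effect 2 sd by default).
#'
#' @param seed Integer seed.
#' @param effect Planted effect size in sd units.
#' @return List with `train`, `test` (each features/labels) and
#'   `manifest`.
#' @export
build_benchmark <- function(seed = 20170721, effect = 2) {
  tr <- build_feature_table(table_spec(n = 194, prevalence = 28 / 194,
                                       effect = effect, seed = seed))
  te <- build_feature_table(table_spec(n = 81, prevalence = 5 / 81,
                                       effect = effect, seed = seed + 1L))
  list(train = tr[c("features", "labels")], test = te[c("features", "labels")],
       manifest = tr$manifest)
}

#' Synthetic penta-peptide half-life table
#'
#' A stand-in for the experimentally measured half-life table (which is
#' not redistributable with the package): plausible, fully covered,
#' seed-deterministic values in days, with the C-terminal neighbour
#' dominating the rate (glycine fastest, branched/bulky slowest) and a
#' mild multiplicative modulation by the N-terminal neighbour. Clearly
#' synthetic; use your measured table for real predictions.
#'
#' @param seed Integer seed.
#' @return A `half_life_table`.
#' @export
synthetic_half_life_table <- function(seed = 1) {
  yyy_base <- c(G = 2, S = 15, T = 25, H = 10, A = 30, D = 35, C = 40,
                K = 60, M = 70, E = 80, R = 90, F = 180, Y = 200, W = 250,
                L = 300, V = 350, I = 400)
  grid <- expand.grid(xxx = HALF_LIFE_XXX, yyy = HALF_LIFE_YYY,
                      stringsAsFactors = FALSE)
  set.seed(seed)
  jitter <- exp(stats::rnorm(nrow(grid), 0, 0.15))
  grid$half_life_days <- round(yyy_base[grid$yyy] * jitter, 2)
  read_half_life_table(grid)
}

#' Test-set composition for the NG-motif baseline worked example
#'
#' Site list with 5 deamidated NG motifs, 7 stable NG motifs and 69
#' stable non-NG Asn sites (81 sites, 5 positives), the composition on
#' which the NG-motif baseline yields confusion (5, 7, 69, 0).
#'
#' @return List with `sites` (data frame with a `yyy` column) and
#'   `truth` (integer labels).
#' @export
build_ng_test_sites <- function() {
  yyy <- c(rep("G", 5), rep("G", 7),
           rep_len(c("S", "T", "A", "L", "V", "D", "E", "K", "F", "H",
                     "M", "R", "W", "Y", "I", "C"), 69))
  sites <- data.frame(
    chain = "A", resseq = seq_along(yyy), icode = "",
    xxx = rep_len(c("A", "G", "S", "L"), length(yyy)), yyy = yyy,
    stringsAsFactors = FALSE
  )
  list(sites = sites, truth = c(rep(1L, 5), rep(0L, length(yyy) - 5)))
}
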