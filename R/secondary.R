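# Secondary-structure assignment by backbone hydrogen bonds, in the
# Kabsch-Sander style, reduced to the 4-level encoding used by the
# descriptor set: alpha helix = 1, beta sheet/bridge = 2, coil = 3,
# turn = 4.

SS_HELIX <- 1L
SS_SHEET <- 2L
SS_COIL <- 3L
SS_TURN <- 4L

# Electrostatic H-bond energy (kcal/mol) between donor N-H of residue i
# and acceptor C=O of residue j. The amide hydrogen is rebuilt on N along
# the previous residue's C=O direction (standard Kabsch-Sander
# reconstruction); an i without a predecessor, or a proline, donates no
# hydrogen bond.
.hbond_energy <- function(bb, i, j) {
  N <- bb$N[[i]]; H <- bb$H[[i]]
  C <- bb$C[[j]]; O <- bb$O[[j]]
  if (is.null(N) || is.null(H) || is.null(C) || is.null(O)) return(Inf)
  q1q2f <- 0.42 * 0.20 * 332
  e <- q1q2f * (1 / dist3(O, N) + 1 / dist3(C, H) -
                  1 / dist3(O, H) - 1 / dist3(C, N))
  if (!is.finite(e)) Inf else e
}

#' Assign per-residue secondary structure
#'
#' Backbone hydrogen bonds are detected with the Kabsch-Sander
#' electrostatic energy rule (cutoff -0.5 kcal/mol). Residues in runs of
#' consecutive n-turns (n = 3, 4, 5) are helix (1); residues in parallel
#' or antiparallel bridges are sheet (2); residues bracketed by a single
#' n-turn hydrogen bond are turn (4); everything else is coil (3).
#' Chains shorter than 3 residues are all coil.
#'
#' @param structure A `deam_structure`.
#' @param chain Residue data frame from [select_chain()].
#' @param energy_cutoff H-bond energy threshold, kcal/mol.
#' @return Integer vector in {1, 2, 3, 4}, one per chain residue.
#' @export
secondary_structure <- function(structure, chain, energy_cutoff = -0.5) {
  n <- nrow(chain)
  if (n < 3) return(rep(SS_COIL, n))

  bb <- list(N = vector("list", n), CA = vector("list", n),
             C = vector("list", n), O = vector("list", n),
             H = vector("list", n))
  for (i in seq_len(n)) {
    res <- residue_atoms(structure, chain$chain[i], chain$key[i])
    bb$N[[i]] <- atom_xyz(res, "N")
    bb$CA[[i]] <- atom_xyz(res, "CA")
    bb$C[[i]] <- atom_xyz(res, "C")
    bb$O[[i]] <- atom_xyz(res, "O")
  }
  for (i in 2:n) {
    # rebuilt amide H: 1.0 A from N opposite the previous carbonyl O
    if (chain$resname[i] != "PRO" && !is.null(bb$N[[i]]) &&
        !is.null(bb$C[[i - 1]]) && !is.null(bb$O[[i - 1]])) {
      d <- bb$C[[i - 1]] - bb$O[[i - 1]]
      bb$H[[i]] <- bb$N[[i]] + d / vnorm(d)
    }
  }

  # hbond[i, j] TRUE when N-H of i donates to C=O of j; sequence
  # separation below 3 excluded (no bond there is sterically plausible)
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) >= 3 && .hbond_energy(bb, i, j) < energy_cutoff) {
        hb[i, j] <- TRUE
      }
    }
  }

  # n-turn at i: C=O of i accepts from N-H of i+n
  turn_at <- function(k) {
    v <- rep(FALSE, n)
    idx <- seq_len(n - k)
    v[idx] <- hb[cbind(idx + k, idx)]
    v
  }
  t3 <- turn_at(3); t4 <- turn_at(4); t5 <- turn_at(5)

  ss <- rep(SS_COIL, n)

  # turns: residues bracketed by any single n-turn
  for (k in c(3, 4, 5)) {
    tt <- list(`3` = t3, `4` = t4, `5` = t5)[[as.character(k)]]
    for (i in which(tt)) ss[(i + 1):(i + k - 1)] <- SS_TURN
  }

  # bridges (beta): Kabsch-Sander parallel/antiparallel patterns
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) < 3) next
      par <- (hb[j, i - 1] && hb[i + 1, j]) || (hb[i, j - 1] && hb[j + 1, i])
      anti <- (hb[j, i] && hb[i, j]) || (hb[j + 1, i - 1] && hb[i + 1, j - 1])
      if (par || anti) ss[c(i, j)] <- SS_SHEET
    }
  }

  # helices: two consecutive n-turns cover residues i..i+k-1 (priority
  # over turn and sheet labels)
  for (k in c(3, 4, 5)) {
    tt <- list(`3` = t3, `4` = t4, `5` = t5)[[as.character(k)]]
    for (i in which(tt[-1]) + 1) {
      if (tt[i - 1]) ss[i:(i + k - 1)] <- SS_HELIX
    }
  }

  ss
}
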