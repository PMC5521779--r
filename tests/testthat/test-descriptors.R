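# Per-site descriptors: B-factor z-scores, attack distance, site
# dihedrals.

test_that("B-factor z-scores use the whole-structure population moments", {
  # two atoms B = {10, 20}: mu = 15, population sigma = 5 -> z = {-1, +1}
  lines <- c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00 20.00           C")
  s <- read_structure(lines)
  expect_equal(normalize_bfactors(s), c(-1, 1))

  expect_warning(z0 <- normalize_bfactors(
    build_peptide_structure(peptide_spec("GNG", bfactor = 7))), "uniform")
  expect_true(all(z0 == 0))

  # z-score identity on an arbitrary fixture, and against brute force
  set.seed(11)
  s2 <- build_peptide_structure(peptide_spec("GANGAANG",
    bfactor = function(n) stats::runif(n, 5, 60)))
  z <- normalize_bfactors(s2)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
  b <- s2$atoms$bfactor
  expect_equal(z, (b - mean(b)) / sqrt(mean((b - mean(b))^2)))
})

test_that("bfactor_descriptors picks the four key carbons", {
  # plan B-factors so the Asn carbons sit at known offsets from the mean
  s <- build_peptide_structure(peptide_spec("GANGA", bfactor = 20))
  i <- with(s$atoms, which(resname == "ASN" & name == "CB"))
  s$atoms$bfactor[i] <- 30
  # mu and sigma recomputed over all atoms; brute-force expectation
  b <- s$atoms$bfactor
  mu <- mean(b); sigma <- sqrt(mean((b - mu)^2))
  site <- enumerate_asn_sites(select_chain(s))[1, ]
  zb <- bfactor_descriptors(s, site)
  expect_named(zb, c("zb_c", "zb_ca", "zb_cb", "zb_cg"))
  expect_equal(unname(zb["zb_cb"]), (30 - mu) / sigma)
  expect_equal(unname(zb["zb_c"]), (20 - mu) / sigma)

  s$atoms <- s$atoms[s$atoms$name != "CG" | s$atoms$resname != "ASN", ]
  st <- bfactor_descriptors(s, site)
  expect_s3_class(st, "site_status")
  expect_match(st$reason, "CG")
})

test_that("attack distance is the CG to next-residue-N separation", {
  s <- build_peptide_structure(peptide_spec("GANGA"))
  ch <- select_chain(s)
  site <- enumerate_asn_sites(ch)[1, ]
  a <- s$atoms
  cg <- unlist(a[a$resname == "ASN" & a$name == "CG", c("x", "y", "z")])
  nn <- unlist(a[a$resseq == site$resseq + 1 & a$name == "N", c("x", "y", "z")])
  expect_equal(attack_distance(s, ch, site), sqrt(sum((cg - nn)^2)))

  # hand-checked arithmetic: CG = (1,2,2), N = (0,0,0) -> 3 A
  s2 <- s
  s2$atoms[a$resname == "ASN" & a$name == "CG", c("x", "y", "z")] <- c(1, 2, 2)
  s2$atoms[a$resseq == site$resseq + 1 & a$name == "N", c("x", "y", "z")] <- c(0, 0, 0)
  expect_equal(attack_distance(s2, ch, site), 3.0)

  s3 <- s
  s3$atoms <- a[!(a$resname == "ASN" & a$name == "CG"), ]
  expect_s3_class(attack_distance(s3, ch, site), "site_status")
})

test_that("site dihedrals round-trip the builder and match the oracle", {
  s <- test_peptide_structure()
  ch <- select_chain(s)
  site <- enumerate_asn_sites(ch)[1, ]
  d <- site_dihedrals(s, ch, site)
  expect_equal(unname(d), c(-60, -45, -65, -20), tolerance = 1e-6)

  ext <- build_peptide_structure(peptide_spec("GANGA", phi = 180, psi = 180))
  dext <- site_dihedrals(ext, select_chain(ext),
                         enumerate_asn_sites(select_chain(ext))[1, ])
  expect_equal(abs(unname(dext[c("phi", "psi")])), c(180, 180), tolerance = 1e-6)

  # arbitrary geometry: all four angles equal the rotation-matrix oracle
  sp <- peptide_spec("AANAA", phi = c(-150, -70, -60, 50, 120),
                     psi = c(100, -30, 140, -50, 60), chi1 = 47, chi2 = -130)
  s2 <- build_peptide_structure(sp)
  ch2 <- select_chain(s2)
  site2 <- enumerate_asn_sites(ch2)[1, ]
  d2 <- site_dihedrals(s2, ch2, site2)
  at <- function(res, nm) {
    a <- s2$atoms
    unlist(a[a$resseq == res & a$name == nm, c("x", "y", "z")])
  }
  expect_equal(unname(d2["phi"]), oracle_dihedral(at(2, "C"), at(3, "N"), at(3, "CA"), at(3, "C")))
  expect_equal(unname(d2["psi"]), oracle_dihedral(at(3, "N"), at(3, "CA"), at(3, "C"), at(4, "N")))
  expect_equal(unname(d2["chi1"]), oracle_dihedral(at(3, "N"), at(3, "CA"), at(3, "CB"), at(3, "CG")))
  expect_equal(unname(d2["chi2"]), oracle_dihedral(at(3, "CA"), at(3, "CB"), at(3, "CG"), at(3, "OD1")))

  # N-terminal Asn: phi undefined -> excluded with reason
  s3 <- build_peptide_structure(peptide_spec("NGA"))
  ch3 <- select_chain(s3)
  st <- site_dihedrals(s3, ch3, enumerate_asn_sites(ch3)[1, ])
  expect_s3_class(st, "site_status")
  expect_match(st$reason, "N-terminal")
})
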