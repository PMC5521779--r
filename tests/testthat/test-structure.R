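# Structure model: PDB parsing, sanitization, chain selection and Asn
# site enumeration.

test_that("generated fixture round-trips through parse and re-serialize", {
  spec <- peptide_spec("GANGA", phi = -60, psi = -45)
  s1 <- read_structure(build_peptide(spec))
  expect_s3_class(s1, "deam_structure")
  expect_equal(length(unique(s1$atoms$chain)), 1)
  expect_equal(length(unique(s1$atoms$resseq)), 5)

  s2 <- read_structure(write_structure(s1))
  expect_equal(s2$atoms$name, s1$atoms$name)
  expect_equal(s2$atoms$bfactor, s1$atoms$bfactor)
  expect_equal(s2$atoms[, c("x", "y", "z")], s1$atoms[, c("x", "y", "z")],
               tolerance = 1e-9)
})

test_that("altloc groups keep the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N   ASN A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ASN A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  CG AASN A   1       2.000   1.000   0.000  0.60 11.00           C",
    "ATOM      4  CG BASN A   1       2.000  -1.000   0.000  0.40 12.00           C",
    "ATOM      5  CB AASN A   1       2.500   1.000   0.000  0.50 13.00           C",
    "ATOM      6  CB BASN A   1       2.500  -1.000   0.000  0.50 14.00           C")
  s <- read_structure(lines)
  cg <- s$atoms[s$atoms$name == "CG", ]
  expect_equal(nrow(cg), 1)
  expect_equal(cg$occupancy, 0.6)
  expect_equal(cg$y, 1.0) # conformer A
  cb <- s$atoms[s$atoms$name == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$altloc, "A") # occupancy tie -> alphabetically first
  # invariant: no duplicated atom names within a residue
  expect_false(anyDuplicated(s$atoms$name) > 0)
})

test_that("parse errors name the offending line; hetero handling works", {
  bad <- c(
    "ATOM      1  N   ASN A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ASN A   1       xx.xxx   0.000   0.000  1.00 10.00           C")
  expect_error(read_structure(bad), "line 2")
  expect_error(read_structure("REMARK nothing here"), "no ATOM records")

  mixed <- c(
    "ATOM      1  N   ASN A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ASN A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  H   ASN A   1       0.500   0.500   0.000  1.00 10.00           H",
    "HETATM    4 SE   MSE A   2       3.000   0.000   0.000  1.00 20.00          SE",
    "HETATM    5  O   HOH A 101       8.000   0.000   0.000  1.00 30.00           O",
    "HETATM    6 ZN    ZN A 102       9.000   0.000   0.000  1.00 30.00          ZN")
  s <- read_structure(mixed)
  expect_false("H" %in% s$atoms$element)       # hydrogens dropped
  expect_true("MET" %in% s$atoms$resname)      # MSE mapped to parent
  expect_false("HOH" %in% s$atoms$resname)     # water out of the chain
  expect_setequal(s$ligand$resname, c("HOH", "ZN"))
})

test_that("resolution is parsed and a warning is issued above 2.5 A", {
  pep <- build_peptide(peptide_spec("GNG"))
  s <- read_structure(c("REMARK   2 RESOLUTION.    2.00 ANGSTROMS.", pep))
  expect_equal(s$resolution, 2.0)
})

test_that("select_chain prefers backbone-complete chains and honours ties", {
  a <- build_peptide(peptide_spec("GANGA", chain_id = "A"))
  b <- build_peptide(peptide_spec("GNG", chain_id = "B"))
  s <- read_structure(c(a, b))
  expect_equal(select_chain(s)$chain[1], "A")          # 5 complete > 3
  expect_equal(nrow(select_chain(s, "B")), 3)          # explicit selection
  expect_error(select_chain(s, "Z"), "available chains: A, B")

  # equal completeness, file order B then A -> B wins
  s2 <- read_structure(c(build_peptide(peptide_spec("GNG", chain_id = "B")),
                         build_peptide(peptide_spec("ANA", chain_id = "A"))))
  expect_equal(select_chain(s2)$chain[1], "B")
})

test_that("enumerate_asn_sites fills neighbours and excludes C-terminal Asn", {
  s <- test_peptide_structure()
  sites <- enumerate_asn_sites(select_chain(s))
  expect_equal(nrow(sites), 1)
  expect_equal(sites$xxx, "A")
  expect_equal(sites$yyy, "G")
  expect_equal(sites$yyy2, "A")

  s2 <- build_peptide_structure(peptide_spec("GAN"))
  expect_warning(sites2 <- enumerate_asn_sites(select_chain(s2)),
                 "C-terminal Asn")
  expect_equal(nrow(sites2), 0)

  s3 <- build_peptide_structure(peptide_spec("NNG"))
  ch3 <- select_chain(s3)
  sites3 <- enumerate_asn_sites(ch3)
  expect_equal(nrow(sites3), 2)
  expect_equal(sites3$yyy, c("N", "G"))
  expect_equal(sites3$yyy2[1], "G")
  # invariant: count equals Asn residues with a successor
  expect_equal(nrow(sites3), sum(ch3$resname == "ASN" &
                                   seq_len(nrow(ch3)) < nrow(ch3)))
})
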