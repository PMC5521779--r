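# PDB-format structure model: parsing, sanitization, chain selection and
# Asn-site enumeration. Columns follow the wwPDB v3.3 fixed-width layout;
# mmCIF is out of scope.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

# Common non-standard residues mapped to their parent amino acid.
# Unmapped hetero residues are excluded from protein chains.
NONSTANDARD_MAP <- c(
  MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR", HYP = "PRO",
  MLY = "LYS", CSO = "CYS", SEC = "CYS", PCA = "GLU", KCX = "LYS"
)

WATER_NAMES <- c("HOH", "DOD", "WAT", "H2O")

.parse_num <- function(txt, lineno, what) {
  out <- suppressWarnings(as.numeric(txt))
  bad <- is.na(out) & !grepl("^\\s*$", txt)
  bad <- bad | is.na(out)
  if (any(bad)) {
    stop(sprintf("malformed ATOM record at line %d: non-numeric %s field '%s'",
                 lineno[which(bad)[1]], what, trimws(txt[which(bad)[1]])))
  }
  out
}

#' Read a protein structure from PDB-format text
#'
#' Parses ATOM/HETATM records into an internal structure model. Hydrogens
#' are dropped, waters and unmapped hetero residues are moved to a separate
#' ligand store, common modified residues (e.g. MSE) are mapped to their
#' parent amino acid, and alternate locations are resolved by keeping the
#' highest-occupancy conformer (ties broken by the alphabetically first
#' altloc code).
#'
#' @param pdb Either a path to a PDB file or a character vector of
#'   PDB-format lines.
#' @return An object of class `deam_structure`: a list with elements
#'   `atoms` (data frame of protein heavy atoms), `ligand` (data frame of
#'   water/hetero atoms), `resolution` (Angstrom, `NA` if absent) and
#'   `chain_order` (chains in file order).
#' @export
read_structure <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
  } else if (length(pdb) == 1 && grepl("\n", pdb)) {
    lines <- strsplit(pdb, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- pdb
  }

  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("empty structure: no ATOM records found")

  resolution <- NA_real_
  rem <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (length(rem)) {
    tail_txt <- substr(rem[1], 23, 80)
    m <- regmatches(tail_txt, regexpr("[0-9]+\\.?[0-9]*", tail_txt))
    if (length(m)) resolution <- suppressWarnings(as.numeric(m))
    if (!is.na(resolution) && resolution > 2.5) {
      warning(sprintf("resolution %.2f A is worse than 2.5 A; B-factor descriptors may be unreliable", resolution))
    }
  }

  al <- lines[is_atom]
  lineno <- which(is_atom)
  # pad short lines so substr() on optional columns is safe
  al <- formatC(al, width = 80, flag = "-")

  atoms <- data.frame(
    record  = substr(al, 1, 6),
    name    = trimws(substr(al, 13, 16)),
    altloc  = substr(al, 17, 17),
    resname = trimws(substr(al, 18, 20)),
    chain   = substr(al, 22, 22),
    resseq  = suppressWarnings(as.integer(trimws(substr(al, 23, 26)))),
    icode   = trimws(substr(al, 27, 27)),
    x = .parse_num(substr(al, 31, 38), lineno, "x"),
    y = .parse_num(substr(al, 39, 46), lineno, "y"),
    z = .parse_num(substr(al, 47, 54), lineno, "z"),
    occupancy = suppressWarnings(as.numeric(substr(al, 55, 60))),
    bfactor   = suppressWarnings(as.numeric(substr(al, 61, 66))),
    element   = trimws(substr(al, 77, 78)),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$resseq)) {
    stop(sprintf("malformed ATOM record at line %d: bad residue number",
                 lineno[which(is.na(atoms$resseq))[1]]))
  }
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$bfactor[is.na(atoms$bfactor)] <- 0
  noel <- atoms$element == ""
  if (any(noel)) {
    # derive element from the atom name: first alphabetic character
    atoms$element[noel] <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                               gsub("^[0-9]+", "", atoms$name[noel])), 1, 1))
  }

  # drop hydrogens everywhere (descriptors are defined on heavy atoms)
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]

  std <- atoms$resname %in% names(AA3TO1)
  mapped <- atoms$resname %in% names(NONSTANDARD_MAP)
  water <- atoms$resname %in% WATER_NAMES
  is_protein <- (std | mapped) & !water
  ligand <- atoms[!is_protein, , drop = FALSE]
  atoms <- atoms[is_protein, , drop = FALSE]
  if (!nrow(atoms)) stop("empty structure: no protein atoms after sanitization")
  atoms$resname[atoms$resname %in% names(NONSTANDARD_MAP)] <-
    NONSTANDARD_MAP[atoms$resname[atoms$resname %in% names(NONSTANDARD_MAP)]]

  # altloc resolution: within each (chain, residue, atom-name) group keep
  # the highest-occupancy conformer; ties -> alphabetically first altloc
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$occupancy, atoms$altloc)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
    # restore file order
    atoms <- atoms[order(match(
      paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name, sep = "\r"),
      unique(key))), , drop = FALSE]
  }
  rownames(atoms) <- NULL

  structure(
    list(atoms = atoms, ligand = ligand, resolution = resolution,
         chain_order = unique(atoms$chain)),
    class = "deam_structure"
  )
}

#' @export
print.deam_structure <- function(x, ...) {
  cat(sprintf("<deam_structure> %d protein atoms, chains: %s, resolution: %s\n",
              nrow(x$atoms), paste(x$chain_order, collapse = ","),
              ifelse(is.na(x$resolution), "NA", sprintf("%.2f A", x$resolution))))
  invisible(x)
}

# Composite residue key used throughout: author number plus insertion code.
residue_key <- function(resseq, icode) {
  ifelse(icode == "" | is.na(icode), as.character(resseq),
         paste0(resseq, icode))
}

# Residues of one chain in file order, as a list-backed data frame:
# one row per residue (chain, resseq, icode, resname, key) with atoms
# retrievable through chain_atoms().
chain_residues <- function(structure, chain_id) {
  a <- structure$atoms[structure$atoms$chain == chain_id, , drop = FALSE]
  key <- residue_key(a$resseq, a$icode)
  idx <- !duplicated(key)
  data.frame(chain = chain_id, resseq = a$resseq[idx], icode = a$icode[idx],
             resname = a$resname[idx], key = key[idx],
             stringsAsFactors = FALSE)
}

# All atoms of one residue identified by its key.
residue_atoms <- function(structure, chain_id, key) {
  a <- structure$atoms
  a[a$chain == chain_id & residue_key(a$resseq, a$icode) == key, , drop = FALSE]
}

# Coordinates of a named atom in a residue, or NULL when absent.
atom_xyz <- function(res_atoms, name) {
  i <- which(res_atoms$name == name)
  if (!length(i)) return(NULL)
  as.numeric(res_atoms[i[1], c("x", "y", "z")])
}

#' Select the working chain of a structure
#'
#' When `chain_id` is given that chain is returned; otherwise the chain
#' with the most residues carrying a complete backbone (N, CA, C, O) is
#' chosen, ties broken by chain order in the file.
#'
#' @param structure A `deam_structure`.
#' @param chain_id Optional chain identifier.
#' @return A data frame of the chain's residues (one row per residue).
#' @export
select_chain <- function(structure, chain_id = NULL) {
  stopifnot(inherits(structure, "deam_structure"))
  if (!is.null(chain_id)) {
    if (!chain_id %in% structure$chain_order) {
      stop(sprintf("chain '%s' not present; available chains: %s",
                   chain_id, paste(structure$chain_order, collapse = ", ")))
    }
    return(chain_residues(structure, chain_id))
  }
  completeness <- vapply(structure$chain_order, function(ch) {
    a <- structure$atoms[structure$atoms$chain == ch, , drop = FALSE]
    keys <- residue_key(a$resseq, a$icode)
    sum(vapply(split(a$name, keys),
               function(nm) all(c("N", "CA", "C", "O") %in% nm), logical(1)))
  }, numeric(1))
  best <- structure$chain_order[which.max(completeness)]
  chain_residues(structure, best)
}

#' Enumerate candidate asparagine deamidation sites
#'
#' One site per Asn residue of the chain, annotated with its sequence
#' neighbours: `xxx` (residue i-1), `yyy` (residue i+1) and `yyy2`
#' (residue i+2, needed when Yyy is itself Asn and the penta-peptide
#' window shifts). A C-terminal Asn has no successor backbone nitrogen to
#' perform the nucleophilic attack, so it is excluded with a warning.
#'
#' @param chain Residue data frame from [select_chain()].
#' @return Data frame with columns chain, resseq, icode, key, xxx, yyy,
#'   yyy2 (1-letter codes, `NA` when the neighbour is absent).
#' @export
enumerate_asn_sites <- function(chain) {
  stopifnot(nrow(chain) > 0)
  one <- unname(AA3TO1[chain$resname])
  idx <- which(chain$resname == "ASN")
  n <- nrow(chain)
  drop_cterm <- idx[idx == n]
  if (length(drop_cterm)) {
    warning(sprintf("excluding C-terminal Asn %s (no i+1 backbone N for nucleophilic attack)",
                    chain$key[drop_cterm]))
    idx <- idx[idx != n]
  }
  if (!length(idx)) {
    return(data.frame(chain = character(), resseq = integer(),
                      icode = character(), key = character(),
                      xxx = character(), yyy = character(),
                      yyy2 = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    chain = chain$chain[idx], resseq = chain$resseq[idx],
    icode = chain$icode[idx], key = chain$key[idx],
    xxx  = ifelse(idx > 1, one[pmax(idx - 1, 1)], NA_character_),
    yyy  = one[idx + 1],
    yyy2 = ifelse(idx + 2 <= n, one[pmin(idx + 2, n)], NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Write a structure back to PDB-format text
#'
#' @param structure A `deam_structure`.
#' @return Character vector of PDB lines (protein atoms only).
#' @export
write_structure <- function(structure) {
  a <- structure$atoms
  name_fmt <- ifelse(nchar(a$name) >= 4, a$name, sprintf(" %-3s", a$name))
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(a)), name_fmt, " ", a$resname, a$chain, a$resseq,
          ifelse(a$icode == "", " ", a$icode),
          a$x, a$y, a$z, a$occupancy, a$bfactor, a$element)
}

#' Write an Asn site list as CSV
#'
#' @param sites Data frame from [enumerate_asn_sites()].
#' @param path Output file path.
#' @export
write_sites_csv <- function(sites, path) {
  utils::write.csv(sites[, c("chain", "resseq", "icode", "xxx", "yyy", "yyy2")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}
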