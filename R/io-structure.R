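# Single-chain structure models.
#
# A `pm_structure` is a list with:
#   id    - character scalar
#   atoms - tibble: auth_seq_id (author residue number, strictly increasing
#           across residues), res_name (3-letter), atom_name, element,
#           x, y, z (Angstrom), confidence (per-residue, B-factor column,
#           NA when absent)
# Residue numbering follows the source file (author numbering) so that
# catalytic-site positions reported for deposited structures line up;
# waters and heteroatoms are dropped on read.

new_structure <- function(id, atoms) {
  atoms <- as_tibble(atoms)
  needed <- c("auth_seq_id", "res_name", "atom_name", "element",
              "x", "y", "z", "confidence")
  missing <- setdiff(needed, names(atoms))
  if (length(missing)) {
    pm_abort(paste0("structure atoms missing columns: ",
                    paste(missing, collapse = ", ")), "petminer_format_error")
  }
  if (nrow(atoms) == 0L) {
    pm_abort("structure must contain at least one atom", "petminer_format_error")
  }
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z))) {
    pm_abort("structure coordinates must be finite", "petminer_format_error")
  }
  resno <- unique(atoms$auth_seq_id)
  if (any(diff(resno) <= 0L)) {
    pm_abort("residue numbering must be strictly increasing",
             "petminer_format_error")
  }
  structure(list(id = id, atoms = atoms[needed]), class = "pm_structure")
}

#' @export
print.pm_structure <- function(x, ...) {
  cat("<pm_structure> ", x$id, ": ", length(unique(x$atoms$auth_seq_id)),
      " residues, ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Residue-level summary of a structure model
#'
#' @param x A `pm_structure` as returned by [read_structure()].
#' @param ... Unused.
#' @return Tibble with one row per residue: `auth_seq_id`, `res_name`,
#'   `n_atoms`, `confidence`.
#' @export
tidy.pm_structure <- function(x, ...) {
  x$atoms |>
    group_by(.data$auth_seq_id, .data$res_name) |>
    summarise(n_atoms = n(),
              confidence = .data$confidence[1L], .groups = "drop") |>
    arrange(.data$auth_seq_id)
}

#' Read a single-chain protein structure from a PDB-format file
#'
#' Reads ATOM records (first model, one chain), mapping the B-factor column
#' to per-residue confidence (e.g. pLDDT for predicted models). Waters and
#' heteroatoms are dropped; for alternate locations the highest-occupancy
#' conformer is kept (ties resolved towards altloc `"A"`). Residues carrying
#' insertion codes are rejected: author numbering must be strictly
#' increasing so that residue positions are unambiguous.
#'
#' @param path Path to a PDB-format coordinate file.
#' @param chain Chain identifier; default: the first chain in the file.
#' @param id Model id; defaults to the file name without extension.
#' @return A `pm_structure`.
#' @export
read_structure <- function(path, chain = NULL, id = NULL) {
  pm_assert_file(path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) pm_abort(paste0("cannot parse PDB file: ",
                                        conditionMessage(e)),
                                 "petminer_format_error"))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid != "HOH", , drop = FALSE]
  if (nrow(at) == 0L) {
    pm_abort("no ATOM records in file", "petminer_format_error")
  }
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) {
    pm_abort(paste0("no ATOM records for chain ", chain),
             "petminer_format_error")
  }
  ins <- !is.na(at$insert) & nzchar(at$insert)
  if (any(ins)) {
    pm_abort("insertion codes are not supported", "petminer_format_error")
  }
  # altloc resolution: keep highest occupancy per (residue, atom name);
  # ties go to the alphabetically first altloc (i.e. 'A').
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$resno, at$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$resno, at$eleno), , drop = FALSE]
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  new_structure(id, tibble(
    auth_seq_id = as.integer(at$resno),
    res_name = at$resid,
    atom_name = at$elety,
    element = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                     substr(gsub("[0-9]", "", at$elety), 1L, 1L), at$elesy),
    x = at$x, y = at$y, z = at$z,
    confidence = as.numeric(at$b)
  ))
}

# Calpha coordinate matrix (residues x 3) with auth_seq_id rownames
ca_coords <- function(s) {
  ca <- s$atoms[s$atoms$atom_name == "CA", , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- as.character(ca$auth_seq_id)
  m
}

# one-letter sequence from residue names (unknown -> X)
structure_sequence <- function(s) {
  res <- tidy.pm_structure(s)
  paste(aa_three_to_one(res$res_name), collapse = "")
}

aa_three_to_one <- function(res_name) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  out <- unname(tab[toupper(res_name)])
  out[is.na(out)] <- "X"
  out
}
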