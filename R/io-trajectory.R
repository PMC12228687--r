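# Plain-text MD trajectories.
#
# A `pm_trajectory` is a list with:
#   atoms  - tibble: atom_name, res_name, auth_seq_id, element, mass (Da)
#   coords - numeric array [A, 3, F] in Angstrom
#   dt_ps  - frame spacing in picoseconds (> 0)
# Supported on-disk formats are multi-frame XYZ (atom-count line, comment
# line, then "name x y z" rows) and multi-model PDB; binary trajectory
# formats are out of scope.

atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, X = 12.011)

element_mass <- function(element) {
  m <- atomic_masses[toupper(element)]
  m[is.na(m)] <- atomic_masses[["X"]]
  unname(m)
}

new_trajectory <- function(atoms, coords, dt_ps) {
  atoms <- as_tibble(atoms)
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2L] == 3L,
            dim(coords)[1L] == nrow(atoms))
  if (dim(coords)[3L] < 1L) {
    pm_abort("trajectory needs at least one frame", "petminer_format_error")
  }
  if (!all(is.finite(coords))) {
    pm_abort("trajectory coordinates must be finite", "petminer_format_error")
  }
  if (!is.numeric(dt_ps) || dt_ps <= 0) {
    pm_abort("dt_ps must be positive", "petminer_format_error")
  }
  if (!"mass" %in% names(atoms)) {
    atoms$mass <- element_mass(if ("element" %in% names(atoms)) atoms$element
                               else atoms$atom_name)
  }
  structure(list(atoms = atoms, coords = coords, dt_ps = dt_ps),
            class = "pm_trajectory")
}

#' @export
print.pm_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("<pm_trajectory> ", d[1L], " atoms x ", d[3L], " frames, dt = ",
      x$dt_ps, " ps\n", sep = "")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3L]

# frame as an A x 3 matrix
traj_frame <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' Read a multi-frame XYZ trajectory
#'
#' XYZ text format: per frame an atom-count line, a comment line, then one
#' `name x y z` row per atom. All frames must have the same atom count and
#' order.
#'
#' @param path Path to an XYZ file.
#' @param dt_ps Frame spacing in picoseconds.
#' @param atoms Optional atom metadata tibble (`atom_name`, `res_name`,
#'   `auth_seq_id`, `element`); defaults are derived from the atom-name
#'   column (one pseudo-residue per atom).
#' @return A `pm_trajectory`.
#' @export
read_xyz_trajectory <- function(path, dt_ps, atoms = NULL) {
  pm_assert_file(path)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (!length(lines)) {
    pm_abort("empty XYZ file", "petminer_format_error")
  }
  pos <- 1L
  frames <- list()
  names_ref <- NULL
  while (pos <= length(lines)) {
    a <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(a) || a < 1L) {
      pm_abort(paste0("bad atom-count line at line ", pos),
               "petminer_format_error")
    }
    if (pos + 1L + a > length(lines)) {
      pm_abort("truncated XYZ frame", "petminer_format_error")
    }
    body <- lines[(pos + 2L):(pos + 1L + a)]
    toks <- strsplit(trimws(body), "\\s+")
    if (any(lengths(toks) < 4L)) {
      pm_abort("XYZ atom row needs: name x y z", "petminer_format_error")
    }
    nm <- vapply(toks, `[[`, character(1L), 1L)
    xyz <- matrix(suppressWarnings(as.numeric(
      unlist(lapply(toks, function(t) t[2:4])))), ncol = 3L, byrow = TRUE)
    if (!all(is.finite(xyz))) {
      pm_abort("non-numeric XYZ coordinate", "petminer_format_error")
    }
    if (is.null(names_ref)) names_ref <- nm
    else if (!identical(nm, names_ref)) {
      pm_abort("atom names differ between frames", "petminer_format_error")
    }
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + a
  }
  coords <- array(unlist(frames),
                  dim = c(length(names_ref), 3L, length(frames)))
  if (is.null(atoms)) {
    atoms <- tibble(atom_name = names_ref, res_name = "UNK",
                    auth_seq_id = seq_along(names_ref),
                    element = substr(gsub("[0-9]", "", names_ref), 1L, 1L))
  }
  new_trajectory(atoms, coords, dt_ps)
}

#' Write a multi-frame XYZ trajectory
#' @param traj A `pm_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  a <- nrow(traj$atoms)
  f <- n_frames(traj)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(f)) {
    writeLines(as.character(a), con)
    writeLines(sprintf("frame %d t= %.6g ps", i, (i - 1) * traj$dt_ps), con)
    m <- traj_frame(traj, i)
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$atoms$atom_name,
                       m[, 1L], m[, 2L], m[, 3L]), con)
  }
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL block becomes one frame; atom metadata comes from the first
#' model.
#'
#' @inheritParams read_xyz_trajectory
#' @param path Path to a multi-model PDB file.
#' @return A `pm_trajectory`.
#' @export
read_pdb_trajectory <- function(path, dt_ps) {
  pm_assert_file(path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) pm_abort(paste0("cannot parse PDB file: ",
                                        conditionMessage(e)),
                                 "petminer_format_error"))
  at <- pdb$atom
  keep <- at$type == "ATOM" & at$resid != "HOH"
  xyz <- pdb$xyz[, rep(keep, each = 3L), drop = FALSE]
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) {
    pm_abort("no ATOM records in file", "petminer_format_error")
  }
  f <- nrow(xyz)
  coords <- array(0, dim = c(nrow(at), 3L, f))
  for (i in seq_len(f)) {
    coords[, , i] <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
  }
  atoms <- tibble(
    atom_name = at$elety, res_name = at$resid,
    auth_seq_id = as.integer(at$resno),
    element = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                     substr(gsub("[0-9]", "", at$elety), 1L, 1L), at$elesy))
  new_trajectory(atoms, coords, dt_ps)
}
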