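# Catalytic-triad detection and conservation. Serine hydrolases (PET
# hydrolases among them) carry a Ser-His-Asp charge-relay triad; candidates
# whose triad is not conserved through the alignment to the reference are
# screened out. Geometric cutoffs follow canonical Ser-His-Asp
# hydrogen-bond geometry (heavy-atom contacts <= 4 A by default).

his_ring_n <- c("NE2", "ND1")
asp_od <- c("OD1", "OD2")

#' Detect a Ser-His-Asp catalytic triad in a structure
#'
#' Scans all (Ser, His, Asp) triples and returns the one minimising the
#' Ser:OG to His ring-nitrogen distance, subject to both triad contacts
#' (Ser:OG - His:NE2/ND1, and His:NE2/ND1 - Asp:OD1/OD2) being within
#' `contact_max`. Residues lacking the needed side-chain atoms cannot
#' qualify. When no triple qualifies an empty result is returned (no
#' error): a missing triad is a legitimate screening outcome.
#'
#' @param s A `pm_structure`.
#' @param contact_max Heavy-atom contact cutoff in Angstrom (default 4.0).
#' @param seq_distance_min Minimum sequence separation (in author
#'   numbering) between any two triad residues (default 1).
#' @return Tibble with columns `residue` (`"S"`, `"H"`, `"D"`) and
#'   `auth_seq_id`; zero rows when no triad is found.
#' @export
detect_triad <- function(s, contact_max = 4.0, seq_distance_min = 1) {
  at <- s$atoms
  ser_og <- at[at$res_name == "SER" & at$atom_name == "OG", , drop = FALSE]
  his_n <- at[at$res_name == "HIS" & at$atom_name %in% his_ring_n, ,
              drop = FALSE]
  asp_o <- at[at$res_name == "ASP" & at$atom_name %in% asp_od, ,
              drop = FALSE]
  empty <- tibble(residue = character(), auth_seq_id = integer())
  if (nrow(ser_og) == 0L || nrow(his_n) == 0L || nrow(asp_o) == 0L) {
    return(empty)
  }
  xyz <- function(df) as.matrix(df[, c("x", "y", "z")])
  d_sh <- pm_cross_dist(xyz(ser_og), xyz(his_n))   # ser atoms x his atoms
  d_ha <- pm_cross_dist(xyz(his_n), xyz(asp_o))    # his atoms x asp atoms
  best <- NULL
  for (hres in unique(his_n$auth_seq_id)) {
    hi <- which(his_n$auth_seq_id == hres)
    for (sres in unique(ser_og$auth_seq_id)) {
      if (abs(sres - hres) < seq_distance_min) next
      si <- which(ser_og$auth_seq_id == sres)
      sh <- min(d_sh[si, hi])
      if (sh > contact_max) next
      for (ares in unique(asp_o$auth_seq_id)) {
        if (abs(ares - hres) < seq_distance_min ||
            abs(ares - sres) < seq_distance_min) next
        ai <- which(asp_o$auth_seq_id == ares)
        ha <- min(d_ha[hi, ai])
        if (ha > contact_max) next
        if (is.null(best) || sh < best$sh) {
          best <- list(s = sres, h = hres, d = ares, sh = sh)
        }
      }
    }
  }
  if (is.null(best)) return(empty)
  tibble(residue = c("S", "H", "D"),
         auth_seq_id = as.integer(c(best$s, best$h, best$d)))
}

pm_cross_dist <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, rep(1, nrow(b))) + outer(rep(1, nrow(a)), b2) -
    2 * a %*% t(b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Check triad conservation through an alignment
#'
#' Maps each reference triad position through the residue correspondence
#' and requires all three to align to residues of identical one-letter
#' type in the candidate.
#'
#' @param alignment A `pm_alignment` of reference (`a`) vs candidate (`b`)
#'   sequences.
#' @param ref_triad Tibble from [detect_triad()] (`residue`,
#'   `auth_seq_id`), positions interpreted as 1-based positions in
#'   `ref_seq`.
#' @param ref_seq,cand_seq Sequences (strings or one-row record tibbles).
#' @return List with `matched` (logical scalar) and `detail`, a tibble with
#'   one row per triad residue: `residue`, `ref_pos`, `cand_pos` (`NA` when
#'   the position aligns to a gap), `cand_residue`, `identity_ok`.
#' @export
check_triad <- function(alignment, ref_triad, ref_seq, cand_seq) {
  sa <- pm_seq_string(ref_seq)
  sb <- pm_seq_string(cand_seq)
  if (nrow(ref_triad) != 3L) {
    pm_abort("ref_triad must have exactly three residues",
             "petminer_format_error")
  }
  if (any(ref_triad$auth_seq_id < 1L | ref_triad$auth_seq_id > nchar(sa))) {
    pm_abort("triad position outside the reference sequence",
             "petminer_format_error")
  }
  detail <- ref_triad |>
    mutate(
      ref_pos = .data$auth_seq_id,
      cand_pos = vapply(.data$auth_seq_id, function(p) {
        hit <- alignment$pairs$j[alignment$pairs$i == p]
        if (length(hit)) hit[1L] else NA_integer_
      }, integer(1L)),
      cand_residue = ifelse(is.na(.data$cand_pos), NA_character_,
                            substring(sb, .data$cand_pos, .data$cand_pos)),
      identity_ok = !is.na(.data$cand_pos) &
        .data$cand_residue == .data$residue
    ) |>
    select("residue", "ref_pos", "cand_pos", "cand_residue", "identity_ok")
  list(matched = all(detail$identity_ok), detail = detail)
}
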