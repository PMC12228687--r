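# TM-score of a candidate structure against a reference, over a
# sequence-derived residue correspondence. The score uses the standard
# length-normalised definition
#   TM = (1 / L_target) * sum_i 1 / (1 + (d_i / d0)^2),
#   d0 = 1.24 * (L_target - 15)^(1/3) - 1.8, clamped to >= 0.5 A,
# after a single Kabsch fit of the aligned Calpha pairs (no iterative
# aligned-subset refinement; see the methods vignette for the divergence
# from full structure-alignment tools). Screening retains candidates with
# TM-score >= 0.5 against the reference fold.

tm_d0 <- function(l_target) {
  x <- l_target - 15
  d0 <- 1.24 * sign(x) * abs(x)^(1 / 3) - 1.8
  max(d0, 0.5)
}

tm_from_distances <- function(d, l_target, d0) {
  sum(1 / (1 + (d / d0)^2)) / l_target
}

#' TM-score between two structures over an alignment
#'
#' @param alignment A `pm_alignment` between the sequences of `a` and `b`
#'   (positions index residues in order).
#' @param a,b `pm_structure` models; both need Calpha atoms for the aligned
#'   residues.
#' @param target Which structure's length normalises the score: `"b"`
#'   (default, the reference) or `"a"`.
#' @param superpose Superpose aligned Calpha pairs by [kabsch_superpose()]
#'   before measuring distances (default `TRUE`); with `FALSE` the
#'   coordinates are compared in their current frames.
#' @return A `pm_tmscore`: list with `tm`, `l_target`, `d0`, `n_aligned`
#'   and the per-pair distances `distances` (Angstrom).
#' @export
tm_score <- function(alignment, a, b, target = c("b", "a"),
                     superpose = TRUE) {
  target <- match.arg(target)
  ca_a <- ca_coords(a)
  ca_b <- ca_coords(b)
  pairs <- alignment$pairs
  ok <- pairs$i <= nrow(ca_a) & pairs$j <= nrow(ca_b)
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    pm_abort("no aligned residue pairs with Calpha coordinates",
             "petminer_format_error")
  }
  p <- ca_a[pairs$i, , drop = FALSE]
  q <- ca_b[pairs$j, , drop = FALSE]
  if (superpose) {
    sup <- kabsch_superpose(p, q)
    p <- apply_superposition(sup, p)
  }
  d <- sqrt(rowSums((p - q)^2))
  l_target <- if (target == "b") nrow(ca_b) else nrow(ca_a)
  d0 <- tm_d0(l_target)
  structure(list(tm = tm_from_distances(d, l_target, d0),
                 l_target = l_target, d0 = d0,
                 n_aligned = nrow(pairs), distances = d),
            class = "pm_tmscore")
}

#' @export
print.pm_tmscore <- function(x, ...) {
  cat("<pm_tmscore> TM = ", format(x$tm, digits = 4), " (L_target = ",
      x$l_target, ", d0 = ", format(x$d0, digits = 3), " A, ",
      x$n_aligned, " aligned pairs)\n", sep = "")
  invisible(x)
}

#' @describeIn tm_score One-row summary of a TM-score result.
#' @param x A `pm_tmscore`.
#' @param ... Unused.
#' @export
glance.pm_tmscore <- function(x, ...) {
  tibble(tm = x$tm, l_target = x$l_target, d0 = x$d0,
         n_aligned = x$n_aligned)
}
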