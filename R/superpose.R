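#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `sum_i |R p_i + t - q_i|^2` over paired coordinates. A reflection in the
#' optimal orthogonal solution is corrected to a proper rotation
#' (determinant +1) by a sign flip on the smallest singular direction.
#'
#' @param p,q Numeric matrices `n x 3` of paired coordinates (Angstrom);
#'   `p` is the moving set, `q` the target. `n >= 3` and `p` must not be
#'   collinear.
#' @return A `pm_superposition`: list with `rotation` (3x3), `translation`
#'   (length 3) and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (nrow(p) < 3L || nrow(q) != nrow(p) || ncol(p) != 3L || ncol(q) != 3L) {
    pm_abort("need >= 3 coordinate pairs (n x 3 matrices)",
             "petminer_format_error")
  }
  pc <- colMeans(p); qc <- colMeans(q)
  pp <- sweep(p, 2L, pc); qq <- sweep(q, 2L, qc)
  sv_p <- svd(pp)$d
  if (sv_p[2L] <= 1e-8 * max(sv_p[1L], 1)) {
    pm_abort("degenerate (collinear) coordinate set", "petminer_format_error")
  }
  h <- crossprod(pp, qq)              # sum p_i q_i^T
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- qc - as.vector(r %*% pc)
  fitted <- pp %*% t(r)               # rows (R p_i) centered
  rmsd <- sqrt(mean(rowSums((fitted - qq)^2)))
  structure(list(rotation = r, translation = t_vec, rmsd = rmsd),
            class = "pm_superposition")
}

#' @export
print.pm_superposition <- function(x, ...) {
  cat("<pm_superposition> rmsd ", format(x$rmsd, digits = 6), " A\n",
      sep = "")
  invisible(x)
}

#' Write a superposition as delimited text
#'
#' Four tab-separated rows: three rotation rows, then the translation.
#'
#' @param sup A `pm_superposition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_superposition <- function(sup, path) {
  m <- rbind(sup$rotation, sup$translation)
  utils::write.table(cbind(row = c("r1", "r2", "r3", "t"),
                           as.data.frame(m)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("row", "x", "y", "z"))
  invisible(path)
}

# apply a superposition to an n x 3 coordinate matrix
apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2L, sup$translation, `+`)
}
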