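# Trajectory-derived stability observables: radius of gyration, RMSF,
# hydrogen-bond occupancy / autocorrelation / lifetime, and salt-bridge
# counts.
#
# The hydrogen-bond lifetime statistic is implemented exactly as defined:
#   C(t) = <h(t0) h(t0 + t)> / <h(t0)^2>,   tau = integral_0^T C(t) dt,
# with h(t) the binary bond-occupancy indicator, the average running over
# all valid time origins, and the integral taken as a left-rectangle sum
# over the dt-spaced discrete curve. No mean subtraction is applied, so
# tau grows with the analysis window for persistent bonds; the window
# length is recorded with every result so values remain comparable.

#' Hydrogen-bond geometric criteria
#'
#' Defaults follow common MD-analysis convention: donor-acceptor heavy-atom
#' distance at most 3.5 A, and (when a donor hydrogen is available) a
#' D-H...A angle of at least 150 degrees. Without a hydrogen the criterion
#' is distance-only.
#'
#' @param distance_max Donor-acceptor heavy-atom cutoff (Angstrom).
#' @param angle_min Minimum D-H...A angle (degrees, in (0, 180]).
#' @return A `pm_hbond_criteria` list.
#' @export
hbond_criteria <- function(distance_max = 3.5, angle_min = 150) {
  stopifnot(distance_max > 0, angle_min > 0, angle_min <= 180)
  structure(list(distance_max = distance_max, angle_min = angle_min),
            class = "pm_hbond_criteria")
}

#' Mass-weighted radius of gyration of one frame
#'
#' @param frame Numeric `A x 3` coordinate matrix (Angstrom).
#' @param masses Atomic masses (Da), all positive; default: unit masses.
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(frame, masses = rep(1, nrow(frame))) {
  frame <- as.matrix(frame)
  if (nrow(frame) < 1L) {
    pm_abort("frame needs at least one atom", "petminer_format_error")
  }
  if (any(masses <= 0) || sum(masses) <= 0) {
    pm_abort("masses must be positive", "petminer_format_error")
  }
  com <- colSums(frame * masses) / sum(masses)
  dev <- sweep(frame, 2L, com)
  sqrt(sum(masses * rowSums(dev^2)) / sum(masses))
}

#' Radius-of-gyration series over a trajectory
#' @param traj A `pm_trajectory`.
#' @return Tibble with `frame`, `time_ps`, `rg`.
#' @export
rg_series <- function(traj) {
  f <- n_frames(traj)
  rg <- vapply(seq_len(f), function(i) {
    radius_of_gyration(traj_frame(traj, i), traj$atoms$mass)
  }, double(1L))
  tibble(frame = seq_len(f), time_ps = (seq_len(f) - 1) * traj$dt_ps,
         rg = rg)
}

#' Per-residue root-mean-square fluctuation
#'
#' Removes global rigid-body motion by superposing every frame onto the
#' mean structure with [kabsch_superpose()] (the mean and the fits are
#' iterated twice), then reports, per selected atom,
#' `sqrt(mean_t |r_i(t) - rbar_i|^2)`.
#'
#' @param traj A `pm_trajectory` with at least 2 frames.
#' @param selection Atom-name selection (default `"CA"`) or integer atom
#'   indices.
#' @return Tibble with `auth_seq_id`, `res_name`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, selection = "CA") {
  f <- n_frames(traj)
  if (f < 2L) pm_abort("RMSF needs at least 2 frames",
                       "petminer_format_error")
  idx <- if (is.numeric(selection)) as.integer(selection) else
    which(traj$atoms$atom_name %in% selection)
  if (length(idx) == 0L) {
    pm_abort("empty atom selection", "petminer_format_error")
  }
  frames <- lapply(seq_len(f), function(i) {
    matrix(traj$coords[idx, , i], ncol = 3L)
  })
  fit_all <- function(ref) {
    lapply(frames, function(fr) {
      apply_superposition(kabsch_superpose(fr, ref), fr)
    })
  }
  aligned <- fit_all(frames[[1L]])
  for (it in 1:2) {
    ref <- Reduce(`+`, aligned) / f
    aligned <- fit_all(ref)
  }
  ref <- Reduce(`+`, aligned) / f
  msd <- Reduce(`+`, lapply(aligned, function(a) rowSums((a - ref)^2))) / f
  tibble(auth_seq_id = traj$atoms$auth_seq_id[idx],
         res_name = traj$atoms$res_name[idx],
         rmsf = sqrt(msd))
}

#' Detect hydrogen-bond occupancy series in a trajectory
#'
#' Evaluates the geometric criteria per frame for every donor-acceptor
#' pair and returns one binary occupancy series per pair that is bonded in
#' at least one frame.
#'
#' @param traj A `pm_trajectory`.
#' @param donors Integer vector of donor heavy-atom indices, or a tibble
#'   with columns `donor` and optionally `hydrogen` (atom index of the
#'   bonded hydrogen, `NA` for distance-only evaluation).
#' @param acceptors Integer vector of acceptor atom indices.
#' @param criteria A [hbond_criteria()].
#' @return Tibble with one row per bonded pair: `donor`, `acceptor`
#'   (atom labels `RES<seq>:<name>`), `donor_idx`, `acceptor_idx`,
#'   `dt_ps`, `occupancy` (fraction of frames), and `h` (list column of
#'   binary integer vectors of length F).
#' @export
detect_hbond_series <- function(traj, donors, acceptors,
                                criteria = hbond_criteria()) {
  if (is.numeric(donors)) {
    donors <- tibble(donor = as.integer(donors), hydrogen = NA_integer_)
  }
  if (!"hydrogen" %in% names(donors)) donors$hydrogen <- NA_integer_
  acceptors <- as.integer(acceptors)
  a_tot <- nrow(traj$atoms)
  if (any(c(donors$donor, acceptors) < 1L) ||
      any(c(donors$donor, acceptors) > a_tot)) {
    pm_abort("donor/acceptor atom index out of range",
             "petminer_format_error")
  }
  lab <- function(i) paste0(traj$atoms$res_name[i],
                            traj$atoms$auth_seq_id[i], ":",
                            traj$atoms$atom_name[i])
  f <- n_frames(traj)
  out <- list()
  for (di in seq_len(nrow(donors))) {
    d <- donors$donor[di]
    hyd <- donors$hydrogen[di]
    dc <- t(traj$coords[d, , , drop = TRUE])       # F x 3
    if (f == 1L) dc <- matrix(traj$coords[d, , 1L], nrow = 1L)
    for (a in acceptors) {
      if (a == d) next
      ac <- t(traj$coords[a, , , drop = TRUE])
      if (f == 1L) ac <- matrix(traj$coords[a, , 1L], nrow = 1L)
      dist_ok <- sqrt(rowSums((dc - ac)^2)) <= criteria$distance_max
      h <- dist_ok
      if (!is.na(hyd)) {
        hc <- t(traj$coords[hyd, , , drop = TRUE])
        if (f == 1L) hc <- matrix(traj$coords[hyd, , 1L], nrow = 1L)
        v1 <- dc - hc     # H -> D
        v2 <- ac - hc     # H -> A
        cosang <- rowSums(v1 * v2) /
          (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
        cosang <- pmin(1, pmax(-1, cosang))
        h <- h & (acos(cosang) * 180 / pi >= criteria$angle_min)
      }
      if (any(h)) {
        out[[length(out) + 1L]] <- tibble(
          donor = lab(d), acceptor = lab(a),
          donor_idx = d, acceptor_idx = a, dt_ps = traj$dt_ps,
          occupancy = mean(h), h = list(as.integer(h)))
      }
    }
  }
  if (!length(out)) {
    return(tibble(donor = character(), acceptor = character(),
                  donor_idx = integer(), acceptor_idx = integer(),
                  dt_ps = double(), occupancy = double(), h = list()))
  }
  dplyr::bind_rows(out)
}

#' Occupancy autocorrelation of a hydrogen bond
#'
#' `C(t) = <h(t0) h(t0 + t)> / <h^2>`: the numerator averages over all
#' valid time origins for each lag (`F - lag` terms); the denominator is
#' the full-series mean of `h^2`, which for a binary indicator equals the
#' occupancy fraction. `C(0) = 1` for any series that is not all zero.
#'
#' @param h Binary occupancy vector, or a one-row tibble from
#'   [detect_hbond_series()].
#' @param dt_ps Frame spacing (ps); taken from the series row when given.
#' @param max_lag Largest lag evaluated, in frames (default `F - 1`).
#' @return A tibble (class `pm_autocorr`) with `lag` (frames), `lag_ps`
#'   and `c`; attributes `dt_ps` and `norm` (the `<h^2>` constant).
#' @export
hbond_autocorrelation <- function(h, dt_ps = NULL, max_lag = NULL) {
  if (is.data.frame(h)) {
    stopifnot(nrow(h) == 1L)
    dt_ps <- h$dt_ps[1L]
    h <- h$h[[1L]]
  }
  if (is.null(dt_ps)) {
    pm_abort("dt_ps required when h is a bare vector",
             "petminer_format_error")
  }
  h <- as.numeric(h)
  f <- length(h)
  if (!all(h %in% c(0, 1))) {
    pm_abort("occupancy series must be binary", "petminer_format_error")
  }
  if (all(h == 0)) {
    pm_abort("autocorrelation undefined for an all-zero series",
             "petminer_format_error")
  }
  if (is.null(max_lag)) max_lag <- f - 1L
  max_lag <- min(as.integer(max_lag), f - 1L)
  # raw lagged sums via FFT-based autocorrelation, O(F log F)
  npad <- stats::nextn(2L * f, 2L)
  hp <- c(h, rep(0, npad - f))
  raw <- Re(stats::fft(Mod(stats::fft(hp))^2, inverse = TRUE)) / npad
  lags <- 0:max_lag
  num <- raw[lags + 1L] / (f - lags)
  cc <- num / mean(h)
  structure(tibble(lag = lags, lag_ps = lags * dt_ps, c = cc),
            dt_ps = dt_ps, norm = mean(h),
            class = c("pm_autocorr", class(tibble())))
}

#' Hydrogen-bond lifetime from an autocorrelation curve
#'
#' Integrates `C(t)` over the analysis window: the default left-rectangle
#' rule gives `tau = sum_t C(t) * dt` (lag 0 included); a trapezoid option
#' differs by O(dt).
#'
#' @param curve A `pm_autocorr` from [hbond_autocorrelation()].
#' @param rule Integration rule, `"left"` (default) or `"trapezoid"`.
#' @return One-row tibble: `tau_ps`, `window_ps`, `dt_ps`, `rule`.
#' @export
hbond_lifetime <- function(curve, rule = c("left", "trapezoid")) {
  rule <- match.arg(rule)
  dt <- attr(curve, "dt_ps")
  stopifnot(!is.null(dt), nrow(curve) >= 1L)
  tau <- if (rule == "left") sum(curve$c) * dt else {
    if (nrow(curve) == 1L) curve$c[1L] * dt else
      sum((curve$c[-1L] + curve$c[-nrow(curve)]) / 2) * dt
  }
  tibble(tau_ps = tau, window_ps = nrow(curve) * dt, dt_ps = dt,
         rule = rule)
}

#' Lifetimes for every bond in a series table
#'
#' Convenience wrapper: autocorrelation + lifetime per row of
#' [detect_hbond_series()] output.
#'
#' @param series Tibble from [detect_hbond_series()].
#' @param max_lag,rule Passed through to the per-bond computation.
#' @return `series` without the `h` column, plus `tau_ps` and `window_ps`.
#' @export
hbond_lifetimes <- function(series, max_lag = NULL,
                            rule = c("left", "trapezoid")) {
  rule <- match.arg(rule)
  res <- lapply(seq_len(nrow(series)), function(i) {
    cur <- hbond_autocorrelation(series[i, ], max_lag = max_lag)
    hbond_lifetime(cur, rule)
  })
  dplyr::bind_cols(series |> select(-"h"), dplyr::bind_rows(res))
}

#' Plot hydrogen-bond autocorrelation curves
#' @param object A `pm_autocorr`.
#' @param ... Unused.
#' @export
autoplot.pm_autocorr <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$lag_ps, y = .data$c)) +
    geom_line() +
    labs(x = "lag (ps)", y = "C(t)") +
    theme_minimal()
}

#' Count salt bridges in one frame
#'
#' A salt bridge is a residue pair with any basic-nitrogen to
#' acidic-oxygen distance within the cutoff; each residue pair is counted
#' once regardless of how many atom contacts it makes.
#'
#' @param frame Numeric `A x 3` coordinate matrix.
#' @param basic_group_atoms Tibble with `res` (residue id) and `atom`
#'   (row index into `frame`) for basic-group nitrogens (Lys NZ;
#'   Arg NH1/NH2/NE; His ring N when treated as charged).
#' @param acidic_group_atoms Same shape, for acidic-group oxygens
#'   (Asp OD1/OD2; Glu OE1/OE2).
#' @param cutoff Distance cutoff in Angstrom (default 4.0).
#' @return Integer count of bridged residue pairs.
#' @export
salt_bridge_count <- function(frame, basic_group_atoms, acidic_group_atoms,
                              cutoff = 4.0) {
  if (nrow(basic_group_atoms) == 0L || nrow(acidic_group_atoms) == 0L) {
    return(0L)
  }
  frame <- as.matrix(frame)
  d <- pm_cross_dist(frame[basic_group_atoms$atom, , drop = FALSE],
                     frame[acidic_group_atoms$atom, , drop = FALSE])
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(0L)
  pairs <- unique(paste(basic_group_atoms$res[hit[, 1L]],
                        acidic_group_atoms$res[hit[, 2L]], sep = "\r"))
  length(pairs)
}

#' Charged side-chain group atoms of a structure or trajectory
#'
#' @param atoms Atom tibble (`res_name`, `auth_seq_id`, `atom_name`), e.g.
#'   `traj$atoms` or `structure$atoms`.
#' @param include_his Treat His ring nitrogens as basic (default FALSE).
#' @return List with `basic` and `acidic` tibbles (`res`, `atom`) suitable
#'   for [salt_bridge_count()].
#' @export
charged_groups <- function(atoms, include_his = FALSE) {
  basic_sel <- (atoms$res_name == "LYS" & atoms$atom_name == "NZ") |
    (atoms$res_name == "ARG" & atoms$atom_name %in% c("NH1", "NH2", "NE"))
  if (include_his) {
    basic_sel <- basic_sel |
      (atoms$res_name == "HIS" & atoms$atom_name %in% c("ND1", "NE2"))
  }
  acidic_sel <- (atoms$res_name == "ASP" & atoms$atom_name %in%
                   c("OD1", "OD2")) |
    (atoms$res_name == "GLU" & atoms$atom_name %in% c("OE1", "OE2"))
  list(basic = tibble(res = atoms$auth_seq_id[basic_sel],
                      atom = which(basic_sel)),
       acidic = tibble(res = atoms$auth_seq_id[acidic_sel],
                       atom = which(acidic_sel)))
}
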