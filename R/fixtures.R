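# Seeded synthetic-fixture generators with planted ground truth. These
# emulate the statistical shape of the pipeline's inputs (embedding-space
# cluster structure, triad geometry, bond-occupancy kinetics, thermal
# fluctuation amplitudes) so every module is testable without downloads;
# they are not physical models. Identical seed and parameters give
# identical output.

#' Planted Gaussian clusters in embedding space
#'
#' `k` isotropic Gaussian components in `d` dimensions. Component means
#' are placed on coordinate axes at multiples of `separation`, so the
#' ratio `separation / spread` controls separability. All members of
#' component 1 are flagged as validated positives and annotated with the
#' first EC number; other components cycle through distinct EC numbers.
#'
#' @param k Number of components.
#' @param n_per Members per component.
#' @param d Embedding dimension.
#' @param separation Distance scale between component means.
#' @param spread Within-component standard deviation (per axis).
#' @param seed Integer seed.
#' @param ec_palette EC numbers assigned per component (recycled).
#' @return List with `embeddings` (tibble `id` + `e1..ed`), `annotations`
#'   (tibble `id`, `ec_numbers`, `validated_positive`) and `truth`
#'   (tibble `id`, `component`).
#' @export
make_gaussian_embedding_clusters <- function(k, n_per, d, separation,
                                             spread, seed,
                                             ec_palette = c(
                                               "3.1.1.101", "3.1.1.74",
                                               "3.5.2.6", "2.7.11.1",
                                               "1.1.1.1", "4.2.1.1")) {
  stopifnot(k >= 1, n_per >= 1, d >= 1, separation >= 0, spread > 0)
  n <- k * n_per
  with_seed(seed, {
    means <- matrix(0, nrow = k, ncol = d)
    for (j in seq_len(k)) {
      axis <- ((j - 1L) %% d) + 1L
      means[j, axis] <- separation * ceiling(j / d)
    }
    comp <- rep(seq_len(k), each = n_per)
    x <- means[comp, , drop = FALSE] +
      matrix(rnorm(n * d, sd = spread), nrow = n)
    ids <- sprintf("prot%04d", seq_len(n))
    emb <- as_tibble(as.data.frame(x), .name_repair = ~sprintf(
      "e%d", seq_len(d)))
    emb <- dplyr::bind_cols(tibble(id = ids), emb)
    ecs <- rep(ec_palette, length.out = k)
    ann <- tibble(id = ids,
                  ec_numbers = as.list(ecs[comp]),
                  validated_positive = comp == 1L)
    list(embeddings = emb, annotations = ann,
         truth = tibble(id = ids, component = comp))
  })
}

#' Toy helical structure with an optionally planted catalytic triad
#'
#' Ideal alpha-helix Calpha trace (radius 2.3 A, rise 1.5 A per residue,
#' 100 degrees per residue). When `triad` is given, the residues at those
#' (1-based) positions become Ser/His/Asp carrying side-chain pseudo-atoms
#' engineered into 3.0 A triad contacts near the trace centroid; all other
#' residues draw from non-Ser/His/Asp amino acids so the planted triad is
#' the only one. The side-chain pseudo-atom placement is geometric, not
#' stereochemical: this is a detector fixture, not a protein model.
#'
#' @param n_res Number of residues.
#' @param triad Integer vector `c(ser, his, asp)` of planted positions, or
#'   `NULL` for no triad.
#' @param seed Integer seed (residue identities).
#' @param confidence Per-residue confidence written to the model
#'   (default 90).
#' @return List with `structure` (a `pm_structure`) and `record` (one-row
#'   sequence tibble consistent with the residue names).
#' @export
make_toy_structure <- function(n_res, triad = NULL, seed = 1,
                               confidence = 90) {
  stopifnot(n_res >= 3)
  if (!is.null(triad)) {
    stopifnot(length(triad) == 3L, !anyDuplicated(triad),
              all(triad >= 1), all(triad <= n_res))
  }
  aa3 <- c("ALA", "GLY", "LEU", "VAL", "ILE", "PHE", "THR", "LYS", "GLU",
           "ASN", "GLN", "ARG", "TRP", "TYR", "MET", "PRO", "CYS")
  with_seed(seed, {
    res_names <- sample(aa3, n_res, replace = TRUE)
    if (!is.null(triad)) {
      res_names[triad[1L]] <- "SER"
      res_names[triad[2L]] <- "HIS"
      res_names[triad[3L]] <- "ASP"
    }
    ang <- (seq_len(n_res) - 1) * 100 * pi / 180
    ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), (seq_len(n_res) - 1) * 1.5)
    centroid <- colMeans(ca)
    rows <- lapply(seq_len(n_res), function(r) {
      at <- tibble(auth_seq_id = r, res_name = res_names[r],
                   atom_name = "CA", element = "C",
                   x = ca[r, 1L], y = ca[r, 2L], z = ca[r, 3L],
                   confidence = confidence)
      if (!is.null(triad) && r %in% triad) {
        side <- switch(res_names[r],
          SER = tibble(atom_name = "OG", element = "O",
                       x = centroid[1L], y = centroid[2L], z = centroid[3L]),
          HIS = tibble(atom_name = c("NE2", "ND1"), element = "N",
                       x = centroid[1L] + c(3, 3),
                       y = centroid[2L] + c(0, 1.4),
                       z = centroid[3L]),
          ASP = tibble(atom_name = c("OD1", "OD2"), element = "O",
                       x = centroid[1L] + c(6, 6),
                       y = centroid[2L] + c(0, 1.4),
                       z = centroid[3L]))
        side <- side |>
          mutate(auth_seq_id = r, res_name = res_names[r],
                 confidence = confidence)
        at <- dplyr::bind_rows(at, side)
      }
      at
    })
    s <- new_structure(paste0("toy", n_res), dplyr::bind_rows(rows))
    seq1 <- paste(aa_three_to_one(res_names), collapse = "")
    list(structure = s,
         record = tibble(id = s$id, description = "synthetic helix fixture",
                         sequence = seq1))
  })
}

#' Two-state telegraph occupancy series
#'
#' Stationary binary Markov chain (on/off) started from its stationary
#' distribution; the analytic occupancy `p`, the per-step correlation
#' eigenvalue `lambda = 1 - p_on_to_off - p_off_to_on` and the correlation
#' time `tau_c` are recorded so the lifetime estimator can be checked
#' against its closed-form expectation.
#'
#' @param p_on_to_off,p_off_to_on Per-step transition probabilities in
#'   `[0, 1)`; at least one must be positive.
#' @param n_frames Series length.
#' @param dt_ps Frame spacing (ps).
#' @param seed Integer seed.
#' @return List with `h` (integer vector), `dt_ps`, `p`, `lambda`,
#'   `tau_c_ps`.
#' @export
make_telegraph_occupancy <- function(p_on_to_off, p_off_to_on, n_frames,
                                     dt_ps, seed) {
  stopifnot(p_on_to_off >= 0, p_on_to_off < 1,
            p_off_to_on >= 0, p_off_to_on < 1,
            p_on_to_off + p_off_to_on > 0, n_frames >= 1, dt_ps > 0)
  p <- p_off_to_on / (p_on_to_off + p_off_to_on)
  lambda <- 1 - p_on_to_off - p_off_to_on
  with_seed(seed, {
    h <- integer(n_frames)
    u <- runif(n_frames)
    h[1L] <- as.integer(u[1L] < p)
    for (t in seq_len(n_frames - 1L)) {
      h[t + 1L] <- if (h[t] == 1L) {
        as.integer(u[t + 1L] >= p_on_to_off)
      } else {
        as.integer(u[t + 1L] < p_off_to_on)
      }
    }
    list(h = h, dt_ps = dt_ps, p = p, lambda = lambda,
         tau_c_ps = if (lambda > 0) -dt_ps / log(lambda) else 0)
  })
}

#' Closed-form expected lifetime of a telegraph bond
#'
#' Expectation of the as-implemented estimator (left-rectangle sum of the
#' unsubtracted autocorrelation over `n_lags` dt-spaced lags) for a
#' stationary telegraph process:
#' `E[tau] = dt * (n_lags * p + (1 - p) * (1 - lambda^n_lags) / (1 - lambda))`.
#'
#' @param p Stationary occupancy.
#' @param lambda Per-step correlation eigenvalue.
#' @param n_lags Number of lags summed (window / dt).
#' @param dt_ps Frame spacing (ps).
#' @return Expected lifetime in ps.
#' @export
telegraph_expected_tau <- function(p, lambda, n_lags, dt_ps) {
  geo <- if (abs(1 - lambda) < 1e-12) n_lags else
    (1 - lambda^n_lags) / (1 - lambda)
  dt_ps * (n_lags * p + (1 - p) * geo)
}

#' Harmonic (isotropic Gaussian) trajectory around a reference structure
#'
#' Frames are the reference coordinates plus independent isotropic
#' Gaussian displacements (per-axis standard deviation set per residue),
#' optionally composed with a random global rigid motion per frame --
#' the oracle fixture for [rmsf()], whose superposition step must remove
#' the rigid motion.
#'
#' @param ref A `pm_structure` reference.
#' @param per_residue_sigma Per-axis displacement sd (Angstrom): scalar or
#'   one value per residue.
#' @param n_frames Number of frames.
#' @param dt_ps Frame spacing (ps).
#' @param seed Integer seed.
#' @param rigid_motion Add a random global rotation + translation per
#'   frame (default FALSE).
#' @return A `pm_trajectory`.
#' @export
make_harmonic_trajectory <- function(ref, per_residue_sigma, n_frames,
                                     dt_ps, seed, rigid_motion = FALSE) {
  stopifnot(inherits(ref, "pm_structure"), all(per_residue_sigma >= 0),
            n_frames >= 1, dt_ps > 0)
  atoms <- ref$atoms
  res_ids <- unique(atoms$auth_seq_id)
  sigma <- rep(per_residue_sigma, length.out = length(res_ids))
  atom_sigma <- sigma[match(atoms$auth_seq_id, res_ids)]
  base <- as.matrix(atoms[, c("x", "y", "z")])
  a <- nrow(base)
  with_seed(seed, {
    coords <- array(0, dim = c(a, 3L, n_frames))
    # displacements are drawn first so the same seed yields the same
    # internal motion with and without the rigid-motion overlay
    for (i in seq_len(n_frames)) {
      coords[, , i] <- base + matrix(rnorm(a * 3L, sd = atom_sigma),
                                     nrow = a)
    }
    if (rigid_motion) {
      for (i in seq_len(n_frames)) {
        rot <- random_rotation()
        shift <- runif(3L, -5, 5)
        coords[, , i] <- sweep(coords[, , i] %*% t(rot), 2L, shift, `+`)
      }
    }
    new_trajectory(tibble(atom_name = atoms$atom_name,
                          res_name = atoms$res_name,
                          auth_seq_id = atoms$auth_seq_id,
                          element = atoms$element),
                   coords, dt_ps)
  })
}

# uniform-ish random proper rotation via QR of a Gaussian matrix
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9L), 3L))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Candidate-property table with a known screening outcome
#'
#' Constructs `n` candidate records where chosen fractions fail exactly
#' one cascade stage each (values placed strictly on the failing side of
#' the threshold) and the remainder pass everything. The per-stage
#' survivor sets expected from the construction ship with the fixture.
#'
#' @param n Number of candidates.
#' @param fail_fractions Named numeric vector with entries among
#'   `tm`, `solubility`, `plddt`, `tmscore`, `triad`; fractions must sum
#'   to at most 1.
#' @param seed Integer seed.
#' @param config A [screening_config()]; default query Tm 50 C, query
#'   solubility 0.5, `top_k = n`.
#' @return List with `records` (candidate tibble), `expected` (list:
#'   `survivors` named list of id sets per stage, `ranked` id vector) and
#'   `config`.
#' @export
make_candidate_table <- function(n,
                                 fail_fractions = c(tm = 0.2,
                                                    solubility = 0.1,
                                                    plddt = 0.1,
                                                    tmscore = 0.1,
                                                    triad = 0.1),
                                 seed = 1,
                                 config = screening_config(
                                   query_tm = 50, query_solubility = 0.5,
                                   top_k = n)) {
  kinds <- c("tm", "solubility", "plddt", "tmscore", "triad")
  ff <- setNames(rep(0, length(kinds)), kinds)
  ff[names(fail_fractions)] <- fail_fractions
  stopifnot(sum(ff) <= 1 + 1e-12)
  counts <- floor(ff * n)
  n_pass <- n - sum(counts)
  fates <- c(rep(names(counts), counts), rep("pass", n_pass))
  with_seed(seed, {
    fate <- sample(fates)
    ids <- sprintf("cand%03d", seq_len(n))
    tm <- config$query_tm + runif(n, 5, 30)
    sol <- config$query_solubility + runif(n, 0.1, 0.4)
    plddt <- runif(n, config$plddt_min + 5, 98)
    tms <- runif(n, config$tm_min + 0.1, 0.95)
    triad <- rep(TRUE, n)
    tm[fate == "tm"] <- config$query_tm - runif(sum(fate == "tm"), 0, 10)
    sol[fate == "solubility"] <-
      config$query_solubility - runif(sum(fate == "solubility"), 0, 0.3)
    plddt[fate == "plddt"] <-
      config$plddt_min - runif(sum(fate == "plddt"), 0.5, 10)
    tms[fate == "tmscore"] <-
      config$tm_min - runif(sum(fate == "tmscore"), 0.05, 0.3)
    triad[fate == "triad"] <- FALSE
    records <- tibble(id = ids, predicted_tm = tm,
                      predicted_solubility = sol, plddt_mean = plddt,
                      tm_score_vs_ref = tms, triad_ok = triad)
    ok_after <- list(
      tm_filter = fate != "tm",
      solubility_filter = !fate %in% c("tm", "solubility"),
      plddt_filter = !fate %in% c("tm", "solubility", "plddt"),
      tmscore_filter = !fate %in% c("tm", "solubility", "plddt", "tmscore"),
      triad_filter = fate == "pass")
    survivors <- lapply(ok_after, function(sel) ids[sel])
    pass_rec <- records[fate == "pass", , drop = FALSE]
    ranked <- utils::head(
      pass_rec$id[order(-pass_rec$predicted_tm, pass_rec$id)],
      config$top_k)
    survivors$ranked_top_k <- ranked
    list(records = records,
         expected = list(survivors = survivors, ranked = ranked),
         config = config)
  })
}
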