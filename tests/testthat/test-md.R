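test_that("radius of gyration matches hand values and the direct loop", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1.0)
  set.seed(12)
  frame <- matrix(rnorm(30), ncol = 3)
  masses <- runif(10, 1, 16)
  expect_equal(radius_of_gyration(frame, masses),
               oracle_rg(frame, masses))
  expect_error(radius_of_gyration(frame, rep(0, 10)),
               class = "petminer_format_error")
})

test_that("Rg is rigid-motion invariant to 1e-9", {
  set.seed(13)
  frame <- matrix(rnorm(60), ncol = 3)
  masses <- runif(20, 1, 16)
  rot <- petminer:::random_rotation()
  moved <- sweep(frame %*% t(rot), 2L, c(10, -4, 2), `+`)
  expect_equal(radius_of_gyration(moved, masses),
               radius_of_gyration(frame, masses), tolerance = 1e-9)
})

test_that("RMSF is zero on a static trajectory and scales linearly", {
  toy <- make_toy_structure(20, seed = 1)
  static <- make_harmonic_trajectory(toy$structure, 0, 10, 10, seed = 2)
  expect_true(all(rmsf(static)$rmsf < 1e-12))
  t1 <- make_harmonic_trajectory(toy$structure, 0.4, 800, 10, seed = 3)
  t2 <- make_harmonic_trajectory(toy$structure, 0.8, 800, 10, seed = 3)
  r1 <- mean(rmsf(t1)$rmsf)
  r2 <- mean(rmsf(t2)$rmsf)
  expect_equal(r2 / r1, 2, tolerance = 0.05)
})

test_that("per-residue amplitude pattern shows up in the RMSF profile", {
  toy <- make_toy_structure(30, seed = 5)
  sigma <- rep(c(0.2, 0.8), length.out = 30)
  traj <- make_harmonic_trajectory(toy$structure, sigma, 600, 10, seed = 6)
  prof <- rmsf(traj)
  expect_gt(stats::cor(prof$rmsf, sigma), 0.9)
})

test_that("global rigid motion per frame does not change RMSF", {
  toy <- make_toy_structure(20, seed = 7)
  plain <- make_harmonic_trajectory(toy$structure, 0.5, 400, 10, seed = 8)
  moving <- make_harmonic_trajectory(toy$structure, 0.5, 400, 10, seed = 8,
                                     rigid_motion = TRUE)
  expect_equal(rmsf(moving)$rmsf, rmsf(plain)$rmsf, tolerance = 1e-6)
})

test_that("hydrogen-bond series follow the geometric criteria per frame", {
  atoms <- tibble::tibble(atom_name = c("N", "H", "O"),
                          res_name = c("ALA", "ALA", "GLY"),
                          auth_seq_id = c(1L, 1L, 2L),
                          element = c("N", "H", "O"))
  mk <- function(d) {
    coords <- array(0, dim = c(3, 3, length(d)))
    for (i in seq_along(d)) {
      coords[2, , i] <- c(1.0, 0, 0)       # H on the N-O axis
      coords[3, , i] <- c(d[i], 0, 0)
    }
    petminer:::new_trajectory(atoms, coords, 10)
  }
  donors <- tibble::tibble(donor = 1L, hydrogen = 2L)
  # fixed 3.0 A, angle 180: always bonded
  s1 <- detect_hbond_series(mk(rep(3, 5)), donors, 3L)
  expect_equal(s1$h[[1L]], rep(1L, 5))
  expect_equal(s1$occupancy, 1)
  # fixed 4.5 A: no series emitted
  expect_equal(nrow(detect_hbond_series(mk(rep(4.5, 5)), donors, 3L)), 0L)
  # oscillating across the cutoff: h matches the per-frame evaluation
  d <- c(3.0, 3.6, 3.4, 4.0, 3.5)
  s3 <- detect_hbond_series(mk(d), donors, 3L)
  expect_equal(s3$h[[1L]], as.integer(d <= 3.5))
  # angle criterion: bent D-H...A below 150 degrees fails even when close
  bent <- mk(rep(3, 2))
  bent$coords[2, , ] <- c(0.5, 1.2, 0)     # push H off-axis
  expect_equal(nrow(detect_hbond_series(bent, donors, 3L)), 0L)
  # distance-only when no hydrogen given
  expect_equal(nrow(detect_hbond_series(bent, 1L, 3L)), 1L)
})

test_that("autocorrelation reproduces enumerated values", {
  alt <- c(1, 0, 1, 0, 1, 0)
  cur <- hbond_autocorrelation(alt, dt_ps = 10)
  expect_equal(cur$c[1:3], c(1, 0, 1))
  short <- hbond_autocorrelation(c(1, 1, 0, 0), dt_ps = 10)
  expect_equal(short$c[2L], (1 / 3) / (1 / 2))
  ones <- hbond_autocorrelation(rep(1, 7), dt_ps = 10)
  expect_true(all(abs(ones$c - 1) < 1e-12))
  expect_error(hbond_autocorrelation(rep(0, 5), dt_ps = 10),
               class = "petminer_format_error")
  expect_error(hbond_autocorrelation(c(1, 2, 0), dt_ps = 10),
               class = "petminer_format_error")
})

test_that("autocorrelation matches the brute-force double loop", {
  set.seed(17)
  for (rep in 1:20) {
    f <- sample(2:8, 1L)
    h <- sample(c(0L, 1L), f, replace = TRUE)
    if (all(h == 0L)) h[1L] <- 1L
    cur <- hbond_autocorrelation(h, dt_ps = 10)
    expect_equal(cur$c, oracle_autocorr(h), tolerance = 1e-12)
  }
})

test_that("lifetimes integrate the curve over the recorded window", {
  ones <- hbond_autocorrelation(rep(1, 12), dt_ps = 10)
  lt <- hbond_lifetime(ones)
  expect_equal(lt$tau_ps, 12 * 10)          # tau = F * dt for C == 1
  expect_equal(lt$window_ps, 120)
  alt <- hbond_autocorrelation(c(1, 0, 1, 0, 1, 0), dt_ps = 10,
                               max_lag = 2)
  expect_equal(hbond_lifetime(alt)$tau_ps, 20)
  # trapezoid differs by O(dt) and is smaller here
  expect_lt(hbond_lifetime(alt, rule = "trapezoid")$tau_ps, 20)
})

test_that("leading on-frames never decrease tau at fixed window", {
  base <- c(0, 1, 1, 0, 0, 1, 0, 0)
  tau_of <- function(h) hbond_lifetime(
    hbond_autocorrelation(h, dt_ps = 10, max_lag = 3))$tau_ps
  h2 <- base; h2[1L] <- 1
  expect_gte(tau_of(h2), tau_of(base))
})

test_that("telegraph lifetimes match the closed-form expectation", {
  settings <- list(c(0.2, 0.1), c(0.05, 0.05), c(0.02, 0.08))
  for (si in seq_along(settings)) {
    st <- settings[[si]]
    taus <- vapply(1:5, function(r) {
      tel <- make_telegraph_occupancy(st[1L], st[2L], 20000, 10,
                                      seed = 100 * si + r)
      cur <- hbond_autocorrelation(tel$h, dt_ps = 10, max_lag = 1000)
      hbond_lifetime(cur)$tau_ps
    }, double(1L))
    tel0 <- make_telegraph_occupancy(st[1L], st[2L], 20000, 10, seed = 1)
    expected <- telegraph_expected_tau(tel0$p, tel0$lambda, 1001, 10)
    se <- stats::sd(taus) / sqrt(length(taus))
    expect_lt(abs(mean(taus) - expected), 3 * se + 1e-9)
  }
})

test_that("salt bridges count residue pairs once within the cutoff", {
  frame <- rbind(c(0, 0, 0),     # LYS NZ
                 c(3, 0, 0),     # GLU OE1
                 c(3.5, 0.5, 0), # GLU OE2 (same residue)
                 c(10, 0, 0))    # ASP OD1, far away
  basic <- tibble::tibble(res = 1L, atom = 1L)
  acidic <- tibble::tibble(res = c(2L, 2L, 3L), atom = c(2L, 3L, 4L))
  expect_equal(salt_bridge_count(frame, basic, acidic), 1L)
  far <- frame; far[2, 1] <- 5; far[3, 1] <- 5.5
  expect_equal(salt_bridge_count(far, basic, acidic), 0L)
  # both Arg nitrogens near one Asp still count a single bridge
  frame2 <- rbind(c(0, 0, 0), c(1.3, 0, 0), c(2.5, 0, 0))
  basic2 <- tibble::tibble(res = 1L, atom = c(1L, 2L))
  acidic2 <- tibble::tibble(res = 5L, atom = 3L)
  expect_equal(salt_bridge_count(frame2, basic2, acidic2), 1L)
})

test_that("charged group selection follows side-chain conventions", {
  atoms <- tibble::tibble(
    atom_name = c("NZ", "NH1", "NE2", "OD1", "OE2", "CA"),
    res_name = c("LYS", "ARG", "HIS", "ASP", "GLU", "GLY"),
    auth_seq_id = 1:6, element = c("N", "N", "N", "O", "O", "C"))
  gr <- charged_groups(atoms)
  expect_equal(gr$basic$res, c(1L, 2L))
  expect_equal(gr$acidic$res, c(4L, 5L))
  gr_his <- charged_groups(atoms, include_his = TRUE)
  expect_true(3L %in% gr_his$basic$res)
})
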