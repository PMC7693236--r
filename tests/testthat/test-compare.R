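mk_prof <- function(w, edges = seq(0, 5 * length(w), 5), sumw2 = w) {
  p <- build_profile(numeric(0), edges = edges)
  p$w <- as.numeric(w); p$sumw2 <- as.numeric(sumw2)
  p$counts <- as.numeric(w)
  p
}

test_that("chi-square kernel reproduces the closed-form two-histogram case", {
  n <- mk_prof(c(10, 20, 30)); m <- mk_prof(c(20, 10, 30))
  cs <- chi2_profiles(n, m, normalize = "shape")
  expect_equal(cs$chi2, 20 / 3, tolerance = 1e-12)
  expect_equal(cs$ndf, 2L)
  expect_equal(cs$p_chi2, exp(-cs$chi2 / 2), tolerance = 1e-12)
  expect_equal(cs$p_chi2, 0.03567399, tolerance = 1e-6)

  # identity
  cs0 <- chi2_profiles(n, n, normalize = "shape")
  expect_equal(cs0$chi2, 0)
  expect_equal(cs0$p_chi2, 1)
})

test_that("shape-mode statistic reduces exactly to sum (n-m)^2/(n+m) at equal totals", {
  set.seed(13)
  for (i in 1:20) {
    n <- rpois(8, 40) + 1
    m <- sample(n)                       # equal totals by construction
    cs <- chi2_profiles(mk_prof(n), mk_prof(m), normalize = "shape")
    expect_equal(cs$chi2, sum((n - m)^2 / (n + m)), tolerance = 1e-10)
  }
})

test_that("chi-square is invariant under common rescaling and monotone in systematics", {
  n <- mk_prof(c(30, 60, 90, 50)); m <- mk_prof(c(40, 55, 80, 60))
  a <- chi2_profiles(n, m, normalize = "shape")
  n2 <- mk_prof(3 * c(30, 60, 90, 50), sumw2 = 9 * c(30, 60, 90, 50))
  m2 <- mk_prof(3 * c(40, 55, 80, 60), sumw2 = 9 * c(40, 55, 80, 60))
  b <- chi2_profiles(n2, m2, normalize = "shape")
  expect_equal(a$chi2, b$chi2, tolerance = 1e-10)

  s_small <- rep(1e-4, 4); s_big <- rep(1e-2, 4)
  c1 <- chi2_profiles(n, m, sigma_sys = s_small, normalize = "shape")
  c2 <- chi2_profiles(n, m, sigma_sys = s_big, normalize = "shape")
  expect_lt(c2$chi2, c1$chi2)
  expect_gte(c2$p_chi2, c1$p_chi2)
})

test_that("chi-square p-values are uniform under the null", {
  set.seed(14)
  edges <- seq(0, 60, 5)
  ps <- replicate(400, {
    z1 <- rnorm(2000, 30, 10); z2 <- rnorm(2000, 30, 10)
    cs <- chi2_profiles(build_profile(z1, edges = edges),
                        build_profile(z2, edges = edges),
                        normalize = "shape")
    cs$p_chi2
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("undefined comparisons are reported invalid", {
  n <- mk_prof(c(0, 0, 5)); m <- mk_prof(c(0, 0, 7))
  cs <- chi2_profiles(n, m, normalize = "shape")
  expect_false(cs$valid)
  expect_error(chi2_profiles(n, mk_prof(c(1, 2), edges = seq(0, 10, 5))),
               "binning")
})

test_that("KS cross-check matches a textbook implementation and is calibrated", {
  z <- rnorm(500)
  expect_equal(ks_profiles(z, z), 1, tolerance = 1e-9)

  set.seed(15)
  a <- rnorm(1000); b <- rnorm(1000) + 5
  p <- ks_profiles(a, b)
  expect_lt(p, 1e-6)
  # independent asymptotic oracle: D via sorted merge, Kolmogorov tail
  ec <- function(x, q) mean(x <= q)
  grid <- sort(c(a, b))
  D <- max(abs(vapply(grid, function(q) ec(a, q) - ec(b, q), 0)))
  ne <- 1000 * 1000 / 2000
  lam <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  k <- 1:100
  p_orc <- 2 * sum((-1)^(k - 1) * exp(-2 * lam^2 * k^2))
  expect_equal(ks_profiles(a, b[1:900]), ks_profiles(a, b[1:900]))  # pure
  expect_equal(p, max(p_orc, 0), tolerance = 1e-6)

  ps <- replicate(200, ks_profiles(rnorm(300), rnorm(300)))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_true(is.na(ks_profiles(numeric(0), rnorm(10))))
})

test_that("positioning systematic vanishes at zero sigma and scales linearly", {
  set.seed(16)
  plan <- plan_table(1L, 0, 0, 200, 1000)
  # synthetic RS-like track set with a steep longitudinal edge
  n <- 4000
  z_em <- runif(n, -65, -50)            # sharp edge at -50
  dv <- c(0.75, 0.43, 0.5); dv <- dv / sqrt(sum(dv^2))
  pt <- cbind(0, 0, z_em) + 500 * matrix(dv, n, 3, byrow = TRUE)
  mk_tracks <- function() {
    track_table(pt[, 1], pt[, 2], pt[, 3], -dv[1], -dv[2], -dv[3],
                t = seq_len(n) * 1e-5, pb_id = 1L, fraction_id = "F")
  }
  tr <- mk_tracks()
  edges <- seq(-80, -20, 5)
  pose0 <- detector_pose(diag(3), c(0, 0, 0), sigma_xyz = c(0, 0, 0))
  b0 <- positioning_systematic(tr, tr, plan, pose0, edges, K = 20, seed = 2)
  expect_equal(b0$sigma_rs, rep(0, length(edges) - 1))
  expect_equal(b0$dz_eff, 0)

  pose1 <- detector_pose(diag(3), c(0, 0, 0), sigma_xyz = rep(1.0, 3))
  pose2 <- detector_pose(diag(3), c(0, 0, 0), sigma_xyz = rep(2.0, 3))
  b1 <- positioning_systematic(tr, tr, plan, pose1, edges, K = 150, seed = 2)
  b2 <- positioning_systematic(tr, tr, plan, pose2, edges, K = 150, seed = 2)
  expect_equal(b2$dz_eff / b1$dz_eff, 2, tolerance = 0.35)
  hot <- which.max(b1$sigma_rs)
  expect_equal(b2$sigma_rs[hot] / b1$sigma_rs[hot], 2, tolerance = 0.5)

  # finite-difference check at the steep edge: sigma ~ |dP/dz| * dz_eff
  base <- build_profile(compute_pca(tr, plan)$s_beam, edges = edges)
  P <- base$w / sum(base$w)
  grad <- abs(diff(P)) / 5
  pred <- grad[hot - 1] * b1$dz_eff / sqrt(2)   # per-session jitter
  expect_equal(b1$sigma_rs[hot], pred, tolerance = 0.5)

  expect_warning(
    bz <- positioning_systematic(tr[0, ], tr, plan, pose1, edges, K = 10),
    "no RS tracks")
  expect_equal(bz$dz_eff, 0)
})

test_that("comparing a fraction with itself yields no flags and p = 1", {
  cfg <- tiny_scenario(seed = 31L)
  sim <- simulate_fraction(cfg, "F1", 311)
  cc <- compare_config(min_entries = 50, sys_trials = 20)
  rep <- compare_fractions(sim$tracks, sim$tracks, cfg$plan,
                           phantom = scenario_phantom(cfg, 1), config = cc)
  expect_equal(rep$n_flagged, 0L)
  expect_true(all(rep$results$p_chi2 > 0.999))
  expect_true(all(rep$results$p_ks > 0.999))
  expect_equal(rep$band$mean_shift, 0, tolerance = 1e-9)
  expect_equal(rep$n_tested, nrow(rep$results))
})

test_that("gross changes are flagged consistently by chi-square and KS", {
  cfg <- tiny_scenario(seed = 32L)
  ph <- scenario_phantom(cfg, 1)
  s1 <- simulate_fraction(cfg, "F1", 321, cavity_fill = 1)
  s2 <- simulate_fraction(cfg, "F2", 322, cavity_fill = 0)
  cc <- compare_config(min_entries = 50, sys_trials = 30)
  rep <- compare_fractions(s1$tracks, s2$tracks, cfg$plan, phantom = ph,
                           config = cc)
  expect_gt(rep$n_flagged, 5 * rep$expected_null_flags)
  hard <- rep$results[rep$results$p_chi2 < 1e-3, ]
  expect_gte(mean(hard$p_ks < 0.05), 0.9)
  expect_gt(nrow(rep$flagged_pca_cloud), 0)
})
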