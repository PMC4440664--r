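test_that("the population generator matches its Poisson moments", {
  lay <- line_layout(K = 2, spacing = 300)
  mask <- build_mask(lay$detectors, buffer = 500, spacing = 50)
  area_ha <- nrow(mask) * attr(mask, "cell_area") / 1e4
  D <- 3
  set.seed(51)
  counts <- replicate(300, nrow(sim_population(D, mask, "per_ha")))
  mu <- D * area_ha
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 300))
  pts <- sim_population(D, mask, "per_ha")
  sp <- attr(mask, "spacing") / 2
  expect_true(all(pts[, 1] >= min(mask[, 1]) - sp &
                    pts[, 1] <= max(mask[, 1]) + sp))
  expect_equal(nrow(sim_population(0, mask, "per_ha")), 0)
})

test_that("detection thinning reproduces the detection probabilities", {
  lay <- line_layout(K = 3, spacing = 400)
  dfn <- detfn_halfnormal(sigma = 350)
  x <- c(150, 230)
  p_true <- halfnormal_p(distances(lay$detectors, x)[, 1], 350)
  set.seed(52)
  pts <- matrix(rep(x, each = 3000), ncol = 2)
  sd1 <- sim_detections(pts, lay, dfn)
  # empirical per-detector frequency among all 3000 animals
  freq <- colSums(sd1$capture$omega[, , 1]) / 3000
  for (k in 1:3) {
    expect_lt(abs(freq[k] - p_true[k]),
              3 * sqrt(p_true[k] * (1 - p_true[k]) / 3000))
  }
  # certain detection with one detector: everyone is detected
  one <- survey_layout(detector_array(0, 0))
  sd2 <- sim_detections(matrix(0.01, 10, 2), one, detfn_halfnormal(1e6))
  expect_equal(sd2$capture$n, 10)
})

test_that("multi-catch simulation detains at most once per occasion", {
  lay <- line_layout(K = 3, spacing = 200, type = "multicatch", S = 4L)
  set.seed(53)
  pts <- cbind(runif(400, -200, 600), runif(400, -200, 200))
  sd1 <- sim_detections(pts, lay, detfn_halfnormal(250))
  percocc <- apply(sd1$capture$omega > 0, c(1, 3), sum)
  expect_true(all(percocc <= 1))
})

test_that("observation noise follows the stated error models", {
  lay <- line_layout(K = 2, spacing = 100)
  set.seed(54)
  x <- matrix(rep(c(40, 90), 800), ncol = 2, byrow = TRUE)
  cap <- capture_data(array(1L, c(800, 2, 1)))
  # near-infinite concentration: observed bearings equal true bearings
  o1 <- sim_observations(cap, x, list(obs_bearing(1e9)), lay)
  b_true <- bearings(lay$detectors, x[1, ])[, 1]
  expect_equal(unname(colMeans(o1$bearing[, , 1])), b_true,
               tolerance = 1e-3)
  # gamma distances are unbiased with CV 1/sqrt(alpha)
  o2 <- sim_observations(cap, x, list(obs_distance(9.77)), lay)
  d_true <- distances(lay$detectors, x[1, ])[, 1]
  for (k in 1:2) {
    est <- o2$distance[, k, 1]
    expect_lt(abs(mean(est) - d_true[k]),
              3 * d_true[k] / sqrt(9.77) / sqrt(800))
  }
  # arrival-time differences at equal distances have SD sqrt(2) * sigma_t
  layE <- survey_layout(detector_array(c(-50, 50), c(0, 0)),
                        durations = 600)
  xE <- matrix(rep(c(0, 120), 800), ncol = 2, byrow = TRUE)
  o3 <- sim_observations(cap, xE, list(obs_toa(0.002)), layE)
  dt <- o3$toa[, 1, 1] - o3$toa[, 2, 1]
  expect_equal(mean(dt), 0, tolerance = 3 * sqrt(2) * 0.002 / sqrt(800))
  expect_lt(abs(sd(dt) - sqrt(2) * 0.002), 0.0004)
})

test_that("signal-strength simulation ties detection to the threshold", {
  f <- design_frog()
  set.seed(55)
  dat <- sim_survey(f)
  ss <- dat$obs[[1]]$ss
  om <- dat$capture[[1]]$omega
  expect_true(all(is.na(ss) == (om == 0)))
  expect_true(all(ss >= f$detection$cutoff, na.rm = TRUE))
})

test_that("mean simulated sample size matches the rate lambda", {
  sv_design <- list(layout = line_layout(K = 3, spacing = 500),
                    mask = build_mask(line_layout(3, 500)$detectors,
                                      buffer = 1570, spacing = 150),
                    detection = detfn_halfnormal(400),
                    observation = list(),
                    pars = c(D = 30, sigma = 400), D_units = "per_km2",
                    n_sessions = 1L)
  om <- array(c(1L, 0L, 0L), c(1, 3, 1))
  m <- unisecr_model(capture_data(om), sv_design$layout, sv_design$mask,
                     sv_design$detection, D_units = "per_km2")
  lam <- lambda_rate(m, sv_design$pars)
  set.seed(56)
  ns <- replicate(150, sim_survey(sv_design)$capture[[1]]$n)
  expect_lt(abs(mean(ns) - lam), 3 * sqrt(lam / 150))
})

test_that("detected locations are distributed as D(x) p.(x)", {
  lay <- line_layout(K = 3, spacing = 500)
  mask <- build_mask(lay$detectors, buffer = 1570, spacing = 150)
  dfn <- detfn_halfnormal(400)
  design <- list(layout = lay, mask = mask, detection = dfn,
                 observation = list(), pars = c(D = 60, sigma = 400),
                 D_units = "per_km2", n_sessions = 1L)
  set.seed(57)
  locs <- do.call(rbind, lapply(1:40, function(i)
    sim_survey(design)$locations[[1]]))
  # coarse quadrants with boundaries on cell edges (so the discrete
  # expected masses match the continuous regions)
  cx <- 455; cy <- 5
  quad <- 1 + (locs[, 1] > cx) + 2 * (locs[, 2] > cy)
  pd <- p_dot_total(mask, dfn, lay, design$pars)
  mquad <- 1 + (mask[, 1] > cx) + 2 * (mask[, 2] > cy)
  expected <- tapply(pd, mquad, sum) / sum(pd)
  test <- chisq.test(tabulate(quad, 4), p = expected[as.character(1:4)])
  expect_gt(test$p.value, 1e-3)
})

test_that("studies are reproducible and paired across variants", {
  design <- list(layout = line_layout(K = 3, spacing = 500),
                 mask = build_mask(line_layout(3, 500)$detectors,
                                   buffer = 1570, spacing = 200),
                 detection = detfn_halfnormal(400),
                 observation = list(obs_bearing(20)),
                 pars = c(D = 30, sigma = 400, kappa = 20),
                 D_units = "per_km2", n_sessions = 1L)
  st1 <- run_study(design, variants = list(a = list(), b = list()),
                   n_sims = 3, seed = 99)
  st2 <- run_study(design, variants = list(a = list(), b = list()),
                   n_sims = 3, seed = 99)
  expect_identical(st1$per_variant$a$D, st2$per_variant$a$D)
  expect_identical(st1$per_variant$a$D, st1$per_variant$b$D)
  expect_identical(st1$per_variant$a$n, st1$per_variant$b$n)
})

test_that("von Mises deviates have the right mean direction and spread", {
  set.seed(58)
  th <- rvonmises(4000, mu = 1.2, kappa = 5)
  C <- mean(cos(th)); S <- mean(sin(th))
  expect_equal(atan2(S, C), 1.2, tolerance = 0.05)
  R <- sqrt(C^2 + S^2)
  A5 <- besselI(5, 1) / besselI(5, 0)   # theoretical resultant length
  expect_equal(R, A5, tolerance = 0.02)
  expect_true(all(th >= 0 & th < 2 * pi))
})
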