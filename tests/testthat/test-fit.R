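test_that("the optimum dominates the generating values on simulated data", {
  sv <- small_bearing_survey(seed = 21)
  m <- unisecr_model(sv$data$capture[[1]], sv$layout, sv$mask, sv$detection,
                     observation = sv$observation, obs = sv$data$obs[[1]],
                     D_units = "per_km2")
  fit <- fit_unisecr(m, start = sv$pars, n_starts = 1, seed = 1)
  expect_gte(fit$logLik, full_loglik(m, sv$pars) - 1e-6)
  expect_true(fit$convergence$converged)
  # covariance is symmetric PSD; CVs follow the delta method for log links
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  est <- fit$estimates
  free <- !est$fixed
  expect_equal(est$cv[free], est$se[free] / abs(est$estimate[free]))
  # AIC bookkeeping
  expect_equal(fit$AIC, 2 * fit$npar - 2 * fit$logLik)
  expect_equal(unname(coef(fit)["D"]), est$estimate[est$par == "D"])
  ci <- confint(fit)
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))
})

test_that("co-located detectors without location data are refused", {
  lay <- survey_layout(detector_array(c(0, 0), c(0, 0)))
  mask <- build_mask(lay$detectors, buffer = 1000, spacing = 100)
  om <- array(c(1L, 0L), c(1, 2, 1))
  expect_error(
    unisecr_model(capture_data(om), lay, mask,
                  detfn_halfnormal_g0(sigma = 300, per_detector = TRUE)),
    "single location")
  # the same geometry is accepted once distance observations are modelled
  obs <- supplementary_data(capture_data(om),
                            distance = matrix(c(350, NA), 1))
  expect_s3_class(
    unisecr_model(capture_data(om), lay, mask,
                  detfn_halfnormal_g0(sigma = 300, per_detector = TRUE),
                  observation = list(obs_distance(10)), obs = obs),
    "unisecr_model")
})

test_that("fixing parameters removes them from optimisation", {
  sv <- small_bearing_survey(seed = 22)
  m <- unisecr_model(sv$data$capture[[1]], sv$layout, sv$mask, sv$detection,
                     observation = sv$observation, obs = sv$data$obs[[1]],
                     D_units = "per_km2")
  fit <- fit_unisecr(m, start = sv$pars, fixed = list(kappa = 20),
                     n_starts = 1, seed = 1)
  expect_true(fit$estimates$fixed[fit$estimates$par == "kappa"])
  expect_equal(fit$estimates$estimate[fit$estimates$par == "kappa"], 20)
  expect_equal(fit$npar, 2)
  expect_error(fit_unisecr(m, fixed = list(bogus = 1)), "unknown")
})

test_that("model comparison ranks by AIC and guards the data identity", {
  sv <- small_bearing_survey(seed = 23)
  cap <- sv$data$capture[[1]]
  obs <- sv$data$obs[[1]]
  m1 <- unisecr_model(cap, sv$layout, sv$mask, sv$detection,
                      observation = sv$observation, obs = obs,
                      D_units = "per_km2")
  fit1 <- fit_unisecr(m1, start = sv$pars, n_starts = 1, seed = 1)
  tab <- compare_models(a = fit1, b = fit1)
  expect_equal(tab$dAIC, c(0, 0))
  sv2 <- small_bearing_survey(seed = 24)
  m2 <- unisecr_model(sv2$data$capture[[1]], sv$layout, sv$mask,
                      sv$detection, observation = sv$observation,
                      obs = sv2$data$obs[[1]], D_units = "per_km2")
  fit2 <- fit_unisecr(m2, start = sv$pars, n_starts = 1, seed = 1)
  expect_error(compare_models(fit1, fit2), "same data")
})

test_that("a superfluous g(0) parameter costs about two AIC units", {
  # null simulations: truth has g(0) = 1, the richer model estimates it
  set.seed(31)
  lay <- line_layout(K = 3, spacing = 500)
  mask <- build_mask(lay$detectors, buffer = 1570, spacing = 200)
  design <- list(layout = lay, mask = mask,
                 detection = detfn_halfnormal(sigma = 400),
                 observation = list(obs_bearing(20)),
                 pars = c(D = 30, sigma = 400, kappa = 20),
                 D_units = "per_km2", n_sessions = 1L)
  daic <- replicate(12, suppressWarnings({
    dat <- sim_survey(design)
    m0 <- unisecr_model(dat$capture, lay, mask, detfn_halfnormal(),
                        observation = design$observation, obs = dat$obs,
                        D_units = "per_km2")
    f0 <- fit_unisecr(m0, start = design$pars, n_starts = 1, seed = 1,
                      hessian = FALSE)
    m1 <- unisecr_model(dat$capture, lay, mask,
                        detfn_halfnormal_g0(g0 = 0.9),
                        observation = design$observation, obs = dat$obs,
                        D_units = "per_km2")
    f1 <- fit_unisecr(m1, start = c(design$pars, g0 = 0.9), n_starts = 1,
                      seed = 1, hessian = FALSE)
    f1$AIC - f0$AIC
  }))
  expect_gt(median(daic), 0)
  expect_lt(median(daic), 2.5)
})

test_that("predict and plot expose the fitted detection structure", {
  sv <- small_bearing_survey(seed = 25)
  m <- unisecr_model(sv$data$capture[[1]], sv$layout, sv$mask, sv$detection,
                     observation = sv$observation, obs = sv$data$obs[[1]],
                     D_units = "per_km2")
  fit <- fit_unisecr(m, start = sv$pars, n_starts = 1, seed = 1)
  p <- predict(fit, newdata = c(0, 500, 2000), type = "detection")
  expect_equal(p, halfnormal_p(c(0, 500, 2000), coef(fit)[["sigma"]]))
  pd <- predict(fit, newdata = rbind(c(430, 150)), type = "pdot")
  expect_true(pd > 0 && pd < 1)
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
  unlink(tmp)
  s <- summary(fit)
  expect_s3_class(s, "summary.unisecr_fit")
  expect_output(print(s), "Wald")
})
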