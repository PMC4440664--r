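dets2 <- detector_array(c(0, 800), c(0, 0))

test_that("bearing log-likelihood has the von Mises form and symmetries", {
  x <- c(300, 400)
  b <- bearings(dets2, x)[, 1]
  # uniform limit
  expect_equal(bearing_loglik(c(b[1], NA), x, dets2, kappa = 0),
               log(1 / (2 * pi)))
  # density at the true bearing with kappa = 1: I0(1) enters the constant
  expect_equal(bearing_loglik(c(b[1], NA), x, dets2, kappa = 1),
               1 - log(2 * pi * besselI(1, 0)), tolerance = 1e-12)
  # symmetric in the sign of the error; periodic in 2*pi
  eps <- 0.21
  expect_equal(bearing_loglik(c(b[1] + eps, NA), x, dets2, 4),
               bearing_loglik(c(b[1] - eps, NA), x, dets2, 4))
  expect_equal(bearing_loglik(c(b[1] + eps + 2 * pi, b[2]), x, dets2, 4),
               bearing_loglik(c(b[1] + eps, b[2]), x, dets2, 4))
  expect_error(bearing_loglik(c(b[1], b[2]), x, dets2, 4,
                              omega = c(1, 0)), "did not detect")
  # normalisation: the density integrates to 1 over the circle
  intg <- integrate(function(y) sapply(y, function(yy)
    exp(bearing_loglik(c(yy, NA), x, dets2, 2.5))), 0, 2 * pi)
  expect_equal(intg$value, 1, tolerance = 1e-6)
})

test_that("arrival-time log-likelihood conditions away the emission time", {
  x <- c(300, 400)
  d <- distances(dets2, x)[, 1]
  st <- 0.002; slope <- 1 / 330
  # one microphone: no information
  expect_equal(toa_loglik(c(0.1, NA), x, dets2, st, slope), 0)
  # two microphones with equal residuals
  y <- 7 + slope * d
  expect_equal(toa_loglik(y, x, dets2, st, slope),
               -0.5 * log(2 * pi * st^2), tolerance = 1e-12)
  # shift invariance (incidental emission time eliminated)
  y2 <- y + c(0.013, -0.004)
  expect_equal(toa_loglik(y2 + 5, x, dets2, st, slope),
               toa_loglik(y2, x, dets2, st, slope))
  expect_error(toa_loglik(y, x, dets2, 0, slope), "sigma_toa")
})

test_that("conditional TOA likelihood equals the marginal random-effect form", {
  # Independent normal arrival times with a flat random effect for the
  # emission time, integrated out numerically, should reproduce the
  # conditional-on-mean form up to a constant free of location and scale.
  dets3 <- detector_array(c(0, 6, 3), c(0, 0, 5))
  st <- 0.0015; slope <- 1 / 330
  set.seed(9)
  marginal <- function(y, x) {
    d <- distances(dets3, x)[, 1]
    f <- function(b0) sapply(b0, function(b) {
      prod(dnorm(y, b + slope * d, st))
    })
    b0_hat <- mean(y - slope * d)
    log(integrate(f, b0_hat - 0.1, b0_hat + 0.1, rel.tol = 1e-10)$value)
  }
  diffs <- replicate(10, {
    x <- runif(2, -10, 15)
    d <- distances(dets3, x)[, 1]
    t0 <- runif(1, 0, 60)
    y <- t0 + slope * d + rnorm(3, 0, st)
    marginal(y, x) - toa_loglik(y, x, dets3, st, slope)
  })
  # constant = log(1/sqrt(m)) here; only constancy matters
  expect_lt(diff(range(diffs)) / abs(mean(diffs)), 1e-6)
})

test_that("signal-strength log-likelihood is the truncated normal", {
  x <- c(300, 400)
  d <- distances(dets2, x)[1, 1]
  # mean at the cutoff, observation at the cutoff
  beta1 <- (150 - 160) / d
  expect_equal(ss_loglik(c(150, NA), x, dets2, 160, beta1, 5, 150),
               dnorm(0, log = TRUE) - log(5) - log(0.5), tolerance = 1e-12)
  # worked arithmetic case: d = 100, mu = 150, y = 155
  o <- detector_array(c(0, 1e6), c(0, 0))
  expect_equal(ss_loglik(c(155, NA), c(100, 0), o, 160, -0.1, 5, 150),
               dnorm(1, log = TRUE) - log(5) - log(0.5), tolerance = 1e-12)
  expect_error(ss_loglik(c(149, NA), c(100, 0), o, 160, -0.1, 5, 150),
               "cutoff")
  # normalisation over [c, Inf)
  intg <- integrate(function(y) sapply(y, function(yy)
    exp(ss_loglik(c(yy, NA), c(100, 0), o, 160, -0.1, 5, 150))), 150, Inf)
  expect_equal(intg$value, 1, tolerance = 1e-6)
})

test_that("distance log-likelihood is unbiased gamma with CV 1/sqrt(alpha)", {
  x <- c(300, 400)
  d <- distances(dets2, x)[1, 1]
  # shape 1 reduces to the exponential with mean d
  y <- 420
  expect_equal(distance_loglik(c(y, NA), x, dets2, alpha = 1),
               log(1 / d) - y / d, tolerance = 1e-12)
  # implied distribution: mean d, CV 1/sqrt(alpha)
  a <- 9.77
  mean_imp <- integrate(function(y) y * dgamma(y, a, rate = a / d),
                        0, Inf)$value
  var_imp <- integrate(function(y) (y - d)^2 * dgamma(y, a, rate = a / d),
                       0, Inf)$value
  expect_equal(mean_imp, d, tolerance = 1e-6)
  expect_equal(sqrt(var_imp) / mean_imp, 1 / sqrt(a), tolerance = 1e-6)
  # and the package density integrates to 1
  intg <- integrate(function(y) sapply(y, function(yy)
    exp(distance_loglik(c(yy, NA), x, dets2, a))), 0, Inf)
  expect_equal(intg$value, 1, tolerance = 1e-6)
  expect_error(distance_loglik(c(-5, NA), x, dets2, 2), "> 0")
})

test_that("joint supplementary likelihood adds independent components", {
  x <- c(300, 400)
  b <- bearings(dets2, x)[, 1]
  d <- distances(dets2, x)[, 1]
  obs <- list(bearing = c(b[1] + 0.1, b[2] - 0.05),
              toa = c(2 + d[1] / 330, NA),
              distance = c(d[1] * 1.2, d[2] * 0.9))
  models <- list(obs_bearing(8), obs_toa(0.002), obs_distance(5))
  joint <- joint_supplementary_loglik(obs, x, models, dets2)
  expect_equal(joint,
               bearing_loglik(obs$bearing, x, dets2, 8) +
                 0 +  # single-mic TOA carries no information
                 distance_loglik(obs$distance, x, dets2, 5))
  expect_equal(joint_supplementary_loglik(obs["bearing"], x,
                                          list(obs_bearing(8)), dets2),
               bearing_loglik(obs$bearing, x, dets2, 8))
  expect_error(joint_supplementary_loglik(obs, x,
                                          list(obs_bearing(8), obs_bearing(2)),
                                          dets2), "duplicate")
  # exact-location mode: unity at Y = X, zero elsewhere
  expect_equal(joint_supplementary_loglik(list(exact = x), x,
                                          list(obs_exact()), dets2), 0)
  expect_equal(joint_supplementary_loglik(list(exact = x + 5), x,
                                          list(obs_exact()), dets2), -Inf)
})
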