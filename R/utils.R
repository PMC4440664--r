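# Internal helpers: link functions, stable log-sum-exp, small utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

link_apply <- function(value, link) {
  switch(link,
    log = log(value),
    logit = stats::qlogis(value),
    identity = value,
    stop("unknown link: ", link)
  )
}

link_invert <- function(value, link) {
  switch(link,
    log = exp(value),
    logit = stats::plogis(value),
    identity = value,
    stop("unknown link: ", link)
  )
}

# d(inverse link)/d(transformed), evaluated at the transformed value.
link_deriv <- function(trans_value, link) {
  switch(link,
    log = exp(trans_value),
    logit = stats::dlogis(trans_value),
    identity = rep_len(1, length(trans_value)),
    stop("unknown link: ", link)
  )
}

# Row-wise log(sum(exp(x))) with max-shift stabilisation; rows all -Inf give -Inf.
row_logsumexp <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  idx <- max.col(x, ties.method = "first")
  mx <- x[cbind(seq_len(nrow(x)), idx)]
  out <- mx + log(rowSums(exp(x - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Density-unit conversion factors: user units -> animals per square metre.
D_UNIT_FACTORS <- c(per_m2 = 1, per_ha = 1e-4, per_km2 = 1e-6)

d_unit_factor <- function(units) {
  units <- match.arg(units, names(D_UNIT_FACTORS))
  D_UNIT_FACTORS[[units]]
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
  invisible(x)
}

# Weak data fingerprint used to refuse AIC comparisons across different data.
data_fingerprint <- function(model) {
  sums <- vapply(model$sessions, function(s) {
    o <- s$capture$omega
    sum(o) + 0.7 * sum(o * seq_along(o)) + dim(o)[1] * 1e3 + dim(o)[2] * 11 + dim(o)[3]
  }, numeric(1))
  signif(sum(sums) + length(sums) * pi, 12)
}
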