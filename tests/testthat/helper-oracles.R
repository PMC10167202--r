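# Independent numerical oracles used across the suite.

# central finite differences of a vector-valued function, independent of
# the package's analytic Jacobian
fd_jacobian <- function(f, x, h = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), n)
  for (j in seq_len(n)) {
    hj <- if (x[j] != 0) h * abs(x[j]) else h  # relative step, stays positive
    xp <- x; xp[j] <- xp[j] + hj
    xm <- x; xm[j] <- xm[j] - hj
    J[, j] <- (f(xp) - f(xm)) / (2 * hj)
  }
  J
}

# full (x1, x2, D) derivative vector of a variant, built from the exported
# rhs_* functions only
variant_rhs <- function(set, variant) {
  switch(variant,
    base = function(s) c(rhs_base(s[1:2], set$params),
                         gompertz_rate(s[3], set$tumor$mu, set$tumor$sigma)),
    model1 = function(s) rhs_model1(s, set$params, set$tumor, set$scenario),
    model2 = function(s) rhs_model2(s, set$params, set$tumor, set$g31, set$g32),
    model3 = function(s) rhs_model3(s, set$params, set$tumor,
                                    set$r11, set$r12, set$r21, set$r22))
}

# Compare an analytic Jacobian against its finite-difference estimate.
# Each cell-row entry is judged relative to the row's term scale
# (production ~ removal ~ beta_i * x_i at a fixed point, bounded by the
# worst 1/(1-sigma) modulation): the D-column derivative of a row is a
# combination of terms of that scale, so at a fixed point its true value
# sits on a cancellation and can only be certified to term_scale * tol.
max_jacobian_err <- function(J, fd, set, ss) {
  S <- c(set$params$beta1 * ss$x1bar, set$params$beta2 * ss$x2bar) /
    (1 - set$tumor$sigma)
  err <- 0
  for (r in 1:2) {
    err <- max(err, abs(J[r, 1:2] - fd[r, 1:2]) /
                 pmax(abs(fd[r, 1:2]), 1e-9 * S[r]))
    err <- max(err, abs(J[r, 3] - fd[r, 3]) / S[r])
  }
  max(err, abs(J[3, 3] - fd[3, 3]) / max(abs(fd[3, 3]), 1e-12))
}

variant_spec <- function(set, variant) {
  switch(variant,
    base = model_spec("base"),
    model1 = model_spec("model1", scenario = set$scenario),
    model2 = model_spec("model2", g31 = set$g31, g32 = set$g32),
    model3 = model_spec("model3", r11 = set$r11, r12 = set$r12,
                        r21 = set$r21, r22 = set$r22))
}

table3 <- default_params()
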