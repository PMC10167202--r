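#' Tumor modulation forms of the model-1 scenarios
#'
#' In the first coupling variant each production/removal constant is
#' either left alone, multiplied by `(1 - D)` (suppressed as the tumor
#' grows), or divided by `(1 - D)` (amplified). The nine scenarios are a
#' fixed lookup, encoded as data rather than as nine functions so the
#' table has a single source of truth:
#'
#' | scenario | alpha1 | alpha2 | beta1 | beta2 |
#' |---|---|---|---|---|
#' | 0 | original | original | original | original |
#' | 1 | inverse | multiplicative | inverse | multiplicative |
#' | 2 | multiplicative | inverse | multiplicative | inverse |
#' | 3 | inverse | multiplicative | multiplicative | inverse |
#' | 4 | multiplicative | inverse | inverse | multiplicative |
#' | 5 | inverse | original | original | original |
#' | 6 | original | original | multiplicative | original |
#' | 7 | original | inverse | original | original |
#' | 8 | original | original | original | multiplicative |
#'
#' @param scenario integer in 0..8
#' @return named character vector of forms for `alpha1, alpha2, beta1, beta2`
#' @export
scenario_forms <- function(scenario) {
  stopifnot(length(scenario) == 1L, scenario %in% 0:8)
  f <- .scenario_table[[as.character(as.integer(scenario))]]
  stats::setNames(f, c("alpha1", "alpha2", "beta1", "beta2"))
}

# "o" original, "m" multiplicative gamma*(1-D), "i" inverse gamma/(1-D)
.scenario_table <- list(
  "0" = c("original", "original", "original", "original"),
  "1" = c("inverse", "multiplicative", "inverse", "multiplicative"),
  "2" = c("multiplicative", "inverse", "multiplicative", "inverse"),
  "3" = c("inverse", "multiplicative", "multiplicative", "inverse"),
  "4" = c("multiplicative", "inverse", "inverse", "multiplicative"),
  "5" = c("inverse", "original", "original", "original"),
  "6" = c("original", "original", "multiplicative", "original"),
  "7" = c("original", "inverse", "original", "original"),
  "8" = c("original", "original", "original", "multiplicative")
)

# value and d/dD of one modulated rate constant at burden D
.modulate <- function(value, form, D) {
  switch(form,
    original       = c(value, 0),
    multiplicative = c(value * (1 - D), -value),
    inverse        = c(value / (1 - D), value / (1 - D)^2),
    stop("unknown modulation form: ", form))
}

## -- unified coefficient view ----------------------------------------------
## Every variant's cell equations have the shape
##   dx1/dt = A1(D) * x1^G11(D) * x2^G21(D) - B1(D) * x1
##   dx2/dt = A2(D) * x1^G12(D) * x2^G22(D) - B2(D) * x2
## so the RHS, the closed-form steady state, and the analytic Jacobian can
## all be computed from one evaluation of the coefficients and their
## D-derivatives.
model_coefficients <- function(spec, params, tumor, D) {
  p <- params
  co <- list(A1 = p$alpha1, A2 = p$alpha2, B1 = p$beta1, B2 = p$beta2,
             G11 = p$g11, G21 = p$g21, G12 = p$g12, G22 = p$g22,
             dA1 = 0, dA2 = 0, dB1 = 0, dB2 = 0,
             dG11 = 0, dG21 = 0, dG12 = 0, dG22 = 0)
  switch(spec$variant,
    base = co,
    model1 = {
      if (D >= 1) stop("model 1 requires D < 1 (rate modulation divides by 1 - D)",
                       call. = FALSE)
      if (D < 0) stop("D must be nonnegative", call. = FALSE)
      f <- scenario_forms(spec$scenario)
      a1 <- .modulate(p$alpha1, f[["alpha1"]], D)
      a2 <- .modulate(p$alpha2, f[["alpha2"]], D)
      b1 <- .modulate(p$beta1, f[["beta1"]], D)
      b2 <- .modulate(p$beta2, f[["beta2"]], D)
      co[c("A1", "A2", "B1", "B2")] <- list(a1[1], a2[1], b1[1], b2[1])
      co[c("dA1", "dA2", "dB1", "dB2")] <- list(a1[2], a2[2], b1[2], b2[2])
      co
    },
    model2 = {
      if (D < 0) stop("D must be nonnegative", call. = FALSE)
      if (D == 0 && (spec$g31 < 0 || spec$g32 < 0))
        stop("D = 0 with a negative tumor paracrine exponent is undefined; ",
             "start the tumor burden at D0 > 0", call. = FALSE)
      co$A1 <- p$alpha1 * D^spec$g31
      co$A2 <- p$alpha2 * D^spec$g32
      co$dA1 <- if (spec$g31 == 0) 0 else p$alpha1 * spec$g31 * D^(spec$g31 - 1)
      co$dA2 <- if (spec$g32 == 0) 0 else p$alpha2 * spec$g32 * D^(spec$g32 - 1)
      co
    },
    model3 = {
      s <- tumor$sigma
      u <- D / s
      den <- 1 + spec$r12 * u
      if (den == 0) stop("1 + r12*D/sigma is zero: model-3 exponent undefined",
                         call. = FALSE)
      co$G11 <- p$g11 * (1 + spec$r11 * u)
      co$G21 <- p$g21 * (1 + spec$r21 * u)
      co$G12 <- p$g12 / den
      co$G22 <- p$g22 - spec$r22 * u
      co$dG11 <- p$g11 * spec$r11 / s
      co$dG21 <- p$g21 * spec$r21 / s
      co$dG12 <- -p$g12 * spec$r12 / s / den^2
      co$dG22 <- -spec$r22 / s
      co
    },
    stop("unknown variant: ", spec$variant))
}

.check_cells <- function(x1, x2) {
  if (!is.finite(x1) || !is.finite(x2) || x1 <= 0 || x2 <= 0)
    stop("cell numbers must be strictly positive (fractional powers of ",
         "nonpositive numbers are undefined)", call. = FALSE)
}

.cell_rates <- function(co, x1, x2) {
  c(co$A1 * x1^co$G11 * x2^co$G21 - co$B1 * x1,
    co$A2 * x1^co$G12 * x2^co$G22 - co$B2 * x2)
}

#' Gompertz tumor growth rate
#'
#' `dD/dt = mu * D * log10(sigma / D)` for the normalized tumor burden
#' `D`. The logarithm is base 10: the tumor row of the system Jacobian
#' is then `-mu / ln(10)` at the fixed point `D = sigma`. `D = 0` is a
#' removable singularity (`D * log -> 0`) and is defined as rate 0,
#' making extinction an (unstable) fixed point. The rate is positive for
#' `0 < D < sigma`, zero at `D = sigma`, negative beyond.
#'
#' @param D normalized tumor burden (>= 0)
#' @param mu proliferation rate (day^-1)
#' @param sigma asymptotic normalized burden
#' @return dD/dt
#' @examples
#' gompertz_rate(0.05, 0.005, 0.05)       # 0 at the asymptote
#' gompertz_rate(0.005, 0.005, 0.05)      # mu * D at one decade below
#' @export
gompertz_rate <- function(D, mu, sigma) {
  if (any(D < 0)) stop("D must be nonnegative", call. = FALSE)
  ifelse(D == 0, 0, mu * D * log10(sigma / D))
}

#' Tumor-free cell dynamics
#'
#' The power-law osteoclast/osteoblast rates
#' `dx1/dt = alpha1*x1^g11*x2^g21 - beta1*x1`,
#' `dx2/dt = alpha2*x1^g12*x2^g22 - beta2*x2`.
#'
#' @param state numeric `c(x1, x2)`, both strictly positive
#' @param params [remodeling_params()]
#' @return numeric `c(dx1, dx2)` (per day)
#' @export
rhs_base <- function(state, params) {
  .check_cells(state[[1]], state[[2]])
  co <- model_coefficients(list(variant = "base"), params, NULL, 0)
  .cell_rates(co, state[[1]], state[[2]])
}

#' Model 1: tumor-modulated production/removal rates
#'
#' Applies the scenario's `(1 - D)` modulation (see [scenario_forms()])
#' to the four rate constants, then evaluates the power-law cell rates;
#' the tumor burden follows [gompertz_rate()].
#'
#' @param state numeric `c(x1, x2, D)`
#' @param params [remodeling_params()]
#' @param tumor [tumor_params()]
#' @param scenario integer 0-8
#' @return numeric `c(dx1, dx2, dD)`
#' @export
rhs_model1 <- function(state, params, tumor, scenario) {
  .check_cells(state[[1]], state[[2]])
  spec <- list(variant = "model1", scenario = as.integer(scenario))
  co <- model_coefficients(spec, params, tumor, state[[3]])
  c(.cell_rates(co, state[[1]], state[[2]]),
    gompertz_rate(state[[3]], tumor$mu, tumor$sigma))
}

#' Model 2: tumor paracrine power-law factor
#'
#' `dx1/dt = alpha1*x1^g11*x2^g21*D^g31 - beta1*x1` and analogously for
#' `x2` with `g32`; the tumor burden follows [gompertz_rate()]. With a
#' negative tumor exponent the production term diverges as `D -> 0`, so
#' the burden must start strictly positive.
#'
#' @inheritParams rhs_model1
#' @param g31,g32 tumor paracrine exponents
#' @return numeric `c(dx1, dx2, dD)`
#' @export
rhs_model2 <- function(state, params, tumor, g31, g32) {
  .check_cells(state[[1]], state[[2]])
  spec <- list(variant = "model2", g31 = g31, g32 = g32)
  co <- model_coefficients(spec, params, tumor, state[[3]])
  c(.cell_rates(co, state[[1]], state[[2]]),
    gompertz_rate(state[[3]], tumor$mu, tumor$sigma))
}

#' Model 3: tumor-dependent autocrine/paracrine exponents
#'
#' The cell equations keep the tumor-free rate constants but the
#' exponents become functions of the relative burden `D/sigma`:
#' `g11*(1+r11*D/sigma)`, `g21*(1+r21*D/sigma)`, `g12/(1+r12*D/sigma)`,
#' `g22 - r22*D/sigma`. At `D = 0` all four reduce to the unmodified
#' exponents.
#'
#' @inheritParams rhs_model1
#' @param r11,r12,r21,r22 exponent-modification constants
#' @return numeric `c(dx1, dx2, dD)`
#' @export
rhs_model3 <- function(state, params, tumor, r11, r12, r21, r22) {
  .check_cells(state[[1]], state[[2]])
  spec <- list(variant = "model3", r11 = r11, r12 = r12, r21 = r21, r22 = r22)
  co <- model_coefficients(spec, params, tumor, state[[3]])
  c(.cell_rates(co, state[[1]], state[[2]]),
    gompertz_rate(state[[3]], tumor$mu, tumor$sigma))
}

#' Bone mass rate of change
#'
#' Only cells in excess of the nontrivial steady state resorb or form
#' bone: with the half-rectification `y_i = max(x_i - xbar_i, 0)`
#' (equivalently `2*y_i = (x_i - xbar_i) + |x_i - xbar_i|`), the bone
#' mass percentage changes as `dz/dt = -k1*y1 + k2*y2`.
#'
#' @param state numeric `c(x1, x2, ...)`; only the first two are used
#' @param steady a [steady_state()] object (the reference `xbar`)
#' @param params [remodeling_params()] (for `k1`, `k2`)
#' @return dz/dt in percent of initial bone mass per day
#' @export
bone_mass_rate <- function(state, steady, params) {
  y1 <- max(state[[1]] - steady$x1bar, 0)
  y2 <- max(state[[2]] - steady$x2bar, 0)
  -params$k1 * y1 + params$k2 * y2
}

# deSolve-style derivative function over y = (x1, x2, D, z).
# `steady` supplies the bone-mass reference; closing over coefficients is
# not possible because they depend on D.
make_rhs <- function(spec, params, tumor, steady) {
  force(spec); force(params); force(tumor); force(steady)
  function(t, y, parms) {
    .check_cells(y[[1]], y[[2]])
    co <- model_coefficients(spec, params, tumor, y[[3]])
    r <- .cell_rates(co, y[[1]], y[[2]])
    list(c(r[1], r[2],
           gompertz_rate(y[[3]], tumor$mu, tumor$sigma),
           bone_mass_rate(y, steady, params)))
  }
}
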