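## Closed-form nontrivial steady states.
##
## All variants share the algebraic core: a power-law pair
##   A1 * x1^e11 * x2^e21 = B1 * x1
##   A2 * x1^e12 * x2^e22 = B2 * x2
## has the unique positive fixed point
##   x1 = R1^((1-e22)/g) * R2^(e21/g),  x2 = R1^(e12/g) * R2^((1-e11)/g)
## with R_i = B_i/A_i and g = e12*e21 - (1-e11)*(1-e22).

.powerlaw_fixed_point <- function(R1, R2, e11, e21, e12, e22) {
  g <- e12 * e21 - (1 - e11) * (1 - e22)
  if (!is.finite(g) || abs(g) < .Machine$double.eps * 16)
    stop("coupling determinant is zero: nontrivial steady state undefined",
         call. = FALSE)
  if (!is.finite(R1) || !is.finite(R2) || R1 <= 0 || R2 <= 0)
    stop("removal/production ratios must be positive", call. = FALSE)
  l1 <- log(R1); l2 <- log(R2)
  c(x1 = exp(((1 - e22) * l1 + e21 * l2) / g),
    x2 = exp((e12 * l1 + (1 - e11) * l2) / g))
}

.new_steady <- function(x, sigma, source) {
  structure(list(x1bar = unname(x[1]), x2bar = unname(x[2]),
                 Dbar = sigma, source = source),
            class = "steady_state")
}

#' Nontrivial steady state of the tumor-free model
#'
#' Closed form
#' `x1bar = (beta1/alpha1)^((1-g22)/gamma) * (beta2/alpha2)^(g21/gamma)`,
#' `x2bar = (beta1/alpha1)^(g12/gamma) * (beta2/alpha2)^((1-g11)/gamma)`
#' with `gamma` from [gamma_coupling()]. Powers are computed as
#' `exp(e * log(ratio))` on strictly positive ratios.
#'
#' @param params [remodeling_params()]
#' @return a `steady_state` object with fields `x1bar`, `x2bar`, `Dbar`
#'   (`NA` here: no tumor), and `source`
#' @examples
#' base_steady_state(default_params()$params)  # (1.1586, 231.7238)
#' @export
base_steady_state <- function(params) {
  x <- .powerlaw_fixed_point(params$beta1 / params$alpha1,
                             params$beta2 / params$alpha2,
                             params$g11, params$g21, params$g12, params$g22)
  .new_steady(x, NA_real_, "closed-form/base")
}

#' Model-1 steady state (tumor-modulated rates)
#'
#' At the tumor fixed point `Dbar = sigma` the scenario's modulated
#' constants are just numbers, so the base closed form applies with the
#' modulated ratios `beta_hat/alpha_hat` evaluated at `D = sigma`. For
#' scenarios 0-2 the `(1 - sigma)` factors cancel in the ratios and the
#' steady state equals the tumor-free one; the other scenarios pick up
#' the `(1 - sigma)` powers of the scenario table.
#'
#' @param params [remodeling_params()]
#' @param sigma asymptotic tumor burden in (0, 1)
#' @param scenario integer 0-8
#' @return a `steady_state` object with `Dbar = sigma`
#' @export
model1_steady_state <- function(params, sigma, scenario) {
  stopifnot(sigma > 0, sigma < 1)
  spec <- list(variant = "model1", scenario = as.integer(scenario))
  co <- model_coefficients(spec, params, NULL, sigma)
  x <- .powerlaw_fixed_point(co$B1 / co$A1, co$B2 / co$A2,
                             co$G11, co$G21, co$G12, co$G22)
  .new_steady(x, sigma, sprintf("closed-form/scenario-%d", spec$scenario))
}

#' Model-2 steady state (tumor paracrine factor)
#'
#' By default evaluates the published closed form: the tumor-free steady
#' state times `sigma^((g31 - g31*g22 - g21*g32)/gamma)` for the
#' osteoclasts and `sigma^((g32*g11 - g31*g12 - g32)/gamma)` for the
#' osteoblasts. This is the reference point used by the stability-region
#' analysis and reproduces the published worked examples.
#'
#' Note, however, that the sign of the `g31` terms in that osteoclast
#' exponent is inconsistent with the model-2 differential equations: the
#' algebraic fixed point of the ODE has osteoclast exponent
#' `(g31*g22 - g31 - g21*g32)/gamma`. `consistent = TRUE` returns that
#' fixed point instead (it satisfies the RHS-residual and root-finding
#' checks); see the methods vignette for the full analysis.
#'
#' @param params [remodeling_params()]
#' @param sigma asymptotic tumor burden in (0, 1)
#' @param g31,g32 tumor paracrine exponents
#' @param consistent if `TRUE`, return the algebraic fixed point of the
#'   ODE instead of the published closed form
#' @return a `steady_state` object with `Dbar = sigma`
#' @export
model2_steady_state <- function(params, sigma, g31, g32, consistent = FALSE) {
  stopifnot(sigma > 0, sigma < 1)
  g <- gamma_coupling(params)
  if (abs(g) < .Machine$double.eps * 16)
    stop("coupling determinant is zero: nontrivial steady state undefined",
         call. = FALSE)
  if (consistent) {
    # absorb D^g3i into the production rates at D = sigma
    x <- .powerlaw_fixed_point(params$beta1 / (params$alpha1 * sigma^g31),
                               params$beta2 / (params$alpha2 * sigma^g32),
                               params$g11, params$g21, params$g12, params$g22)
    return(.new_steady(x, sigma, "closed-form/model2-consistent"))
  }
  b <- base_steady_state(params)
  e1 <- (g31 - g31 * params$g22 - params$g21 * g32) / g
  e2 <- (g32 * params$g11 - g31 * params$g12 - g32) / g
  .new_steady(c(b$x1bar * sigma^e1, b$x2bar * sigma^e2), sigma,
              "closed-form/model2")
}

#' Model-3 steady state (tumor-dependent exponents)
#'
#' At `D = sigma` the effective exponents are `g11*(1+r11)`,
#' `g21*(1+r21)`, `g12/(1+r12)`, `g22 - r22`, and the base closed form
#' applies with those exponents; the coupling determinant becomes
#' `Lambda = (g12/(1+r12))*(g21*(1+r21)) - (1 - g11*(1+r11))*(1 - g22 + r22)`,
#' which must be nonzero.
#'
#' @param params [remodeling_params()]
#' @param sigma asymptotic tumor burden in (0, 1)
#' @param r11,r12,r21,r22 exponent-modification constants
#' @return a `steady_state` object with `Dbar = sigma`
#' @export
model3_steady_state <- function(params, sigma, r11, r12, r21, r22) {
  stopifnot(sigma > 0, sigma < 1)
  spec <- list(variant = "model3", r11 = r11, r12 = r12, r21 = r21, r22 = r22)
  co <- model_coefficients(spec, params, list(sigma = sigma), sigma)
  x <- .powerlaw_fixed_point(co$B1 / co$A1, co$B2 / co$A2,
                             co$G11, co$G21, co$G12, co$G22)
  .new_steady(x, sigma, "closed-form/model3-lambda")
}

#' Steady state of any model variant
#'
#' Dispatches to the closed form matching `spec$variant`.
#'
#' @param spec [model_spec()]
#' @param params [remodeling_params()]
#' @param tumor [tumor_params()] (ignored for the base variant)
#' @param ... passed on (e.g. `consistent` for model 2)
#' @return a `steady_state` object
#' @export
steady_state <- function(spec, params, tumor = NULL, ...) {
  switch(spec$variant,
    base = base_steady_state(params),
    model1 = model1_steady_state(params, tumor$sigma, spec$scenario),
    model2 = model2_steady_state(params, tumor$sigma, spec$g31, spec$g32, ...),
    model3 = model3_steady_state(params, tumor$sigma,
                                 spec$r11, spec$r12, spec$r21, spec$r22),
    stop("unknown variant: ", spec$variant))
}

#' Root-finding certification of a steady state
#'
#' Solves the two cell equations at fixed `D = sigma` numerically, in
#' log coordinates (which confines the search to the positive orthant
#' and excludes the trivial fixed point at the origin). Used in the test
#' suite as an oracle that is independent of the closed forms.
#'
#' @param spec [model_spec()]
#' @param params [remodeling_params()]
#' @param tumor [tumor_params()] (for `sigma`; may be `NULL` for base)
#' @param guess numeric `c(x1, x2)` starting point, positive
#' @return a `steady_state` object with `source = "oracle"`
#' @export
steady_state_oracle <- function(spec, params, tumor = NULL,
                                guess = c(1, 100)) {
  stopifnot(all(guess > 0))
  sigma <- if (is.null(tumor)) NA_real_ else tumor$sigma
  D <- if (identical(spec$variant, "base")) 0 else sigma
  co <- model_coefficients(spec, params, tumor, D)
  fn <- function(u) .cell_rates(co, exp(u[1]), exp(u[2]))
  sol <- tryCatch(suppressWarnings(pracma::fsolve(fn, log(guess), tol = 1e-12)),
                  error = function(e) NULL)
  # accept only if the rates vanish relative to the removal terms: on the
  # spurious descent toward the trivial point (0, 0) the absolute rates go
  # to zero but their ratio to beta_i * x_i does not
  ok <- !is.null(sol) && all(is.finite(sol$x)) && {
    x <- exp(sol$x)
    r <- fn(sol$x)
    max(abs(r[1]) / (co$B1 * x[1]), abs(r[2]) / (co$B2 * x[2])) < 1e-8
  }
  if (!ok) stop("steady-state oracle did not converge", call. = FALSE)
  .new_steady(exp(sol$x), sigma, "oracle")
}

#' Residual of the cell equations at a steady state
#'
#' Maximum relative magnitude of the two cell rates at
#' `(x1bar, x2bar, Dbar)`, each scaled by its removal term. Zero (to
#' rounding) certifies a fixed point.
#'
#' @param steady a `steady_state` object
#' @param spec [model_spec()]
#' @param params [remodeling_params()]
#' @param tumor [tumor_params()] or `NULL` for base
#' @return numeric scalar
#' @export
steady_state_residual <- function(steady, spec, params, tumor = NULL) {
  D <- if (identical(spec$variant, "base")) 0 else steady$Dbar
  co <- model_coefficients(spec, params, tumor, D)
  r <- .cell_rates(co, steady$x1bar, steady$x2bar)
  max(abs(r[1]) / (co$B1 * steady$x1bar), abs(r[2]) / (co$B2 * steady$x2bar))
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Nontrivial steady state [%s]\n", x$source))
  cat(sprintf("  x1bar = %.4f osteoclasts, x2bar = %.4f osteoblasts",
              x$x1bar, x$x2bar))
  if (is.finite(x$Dbar)) cat(sprintf(", Dbar = %g", x$Dbar))
  cat("\n")
  invisible(x)
}
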