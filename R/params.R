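#' Osteoclast-osteoblast remodeling parameters
#'
#' Bundles the eight constants of the power-law bone remodeling model
#' together with the bone resorption/formation activities. Production
#' rates `alpha1`, `alpha2` and removal rates `beta1`, `beta2` are in
#' day^-1 units on the cell scale; the exponents `g11`, `g21`, `g12`,
#' `g22` encode autocrine (`gii`) and paracrine (`gij`) regulation and
#' are dimensionless; `k1` and `k2` are the normalized activities of
#' bone resorption and formation in percent per cell per day.
#'
#' The coupling determinant `gamma = g12*g21 - (1-g11)*(1-g22)` must be
#' nonzero for a nontrivial steady state to exist; this is checked when
#' a steady state is requested, not here.
#'
#' @param alpha1,alpha2 osteoclast / osteoblast production rates (> 0)
#' @param beta1,beta2 osteoclast / osteoblast removal rates (> 0)
#' @param g11,g21,g12,g22 autocrine/paracrine power-law exponents
#' @param k1,k2 bone resorption / formation activities (> 0, %/cell/day)
#' @return an object of class `remodeling_params`
#' @seealso [default_params()] for the canonical physiological set
#' @export
remodeling_params <- function(alpha1, alpha2, beta1, beta2,
                              g11, g21, g12, g22, k1, k2) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2,
            g11 = g11, g21 = g21, g12 = g12, g22 = g22, k1 = k1, k2 = k2)
  stopifnot(vapply(p, function(x) is.numeric(x) && length(x) == 1L, logical(1)))
  bad <- validate_remodeling(p)
  if (length(bad)) stop("invalid remodeling parameters: ",
                        paste(bad, collapse = "; "), call. = FALSE)
  structure(p, class = "remodeling_params")
}

#' Tumor growth parameters
#'
#' Parameters of the Gompertz tumor-burden equation
#' `dD/dt = mu * D * log10(sigma / D)`, where `D` is the tumor cell
#' count normalized by its carrying limit. `sigma` is the asymptotic
#' normalized burden (the value `D` saturates at) and must lie strictly
#' inside (0, 1) because the rate-modulation factors divide by `1 - D`.
#'
#' The initial burden `D0` defaults to `0.005 * sigma`, a small positive
#' fraction of the asymptote: the Gompertz form requires `D0 > 0`, and
#' the burden then grows monotonically toward `sigma`.
#'
#' @param mu tumor proliferation rate (day^-1, >= 0); default 0.005
#' @param sigma scaling constant / asymptotic normalized burden, in (0, 1)
#' @param D0 initial normalized burden, in (0, sigma]
#' @return an object of class `tumor_params`
#' @export
tumor_params <- function(sigma, mu = 0.005, D0 = 0.005 * sigma) {
  p <- list(mu = mu, sigma = sigma, D0 = D0)
  stopifnot(vapply(p, function(x) is.numeric(x) && length(x) == 1L, logical(1)))
  bad <- validate_tumor(p)
  if (length(bad)) stop("invalid tumor parameters: ",
                        paste(bad, collapse = "; "), call. = FALSE)
  structure(p, class = "tumor_params")
}

#' Model-variant selector
#'
#' Chooses which tumor coupling is in force and carries its constants:
#' * `"base"` - the tumor-free power-law model;
#' * `"model1"` - tumor-modulated production/removal rates, one of nine
#'   `scenario`s (0 keeps all four rates unmodified; see
#'   [scenario_forms()]);
#' * `"model2"` - tumor paracrine power-law factors `D^g31`, `D^g32` on
#'   the production terms;
#' * `"model3"` - tumor-dependent exponents
#'   `g11*(1+r11*D/sigma)`, `g21*(1+r21*D/sigma)`,
#'   `g12/(1+r12*D/sigma)`, `g22 - r22*D/sigma`.
#'
#' @param variant one of `"base"`, `"model1"`, `"model2"`, `"model3"`
#' @param scenario integer 0-8, model 1 only
#' @param g31,g32 tumor paracrine exponents, model 2 only
#' @param r11,r12,r21,r22 exponent-modification constants, model 3 only
#' @return an object of class `model_spec`
#' @export
model_spec <- function(variant = c("base", "model1", "model2", "model3"),
                       scenario = 0L, g31 = 0, g32 = 0,
                       r11 = 0, r12 = 0, r21 = 0, r22 = 0) {
  variant <- match.arg(variant)
  s <- list(variant = variant, scenario = as.integer(scenario),
            g31 = g31, g32 = g32,
            r11 = r11, r12 = r12, r21 = r21, r22 = r22)
  bad <- validate_spec(s)
  if (length(bad)) stop("invalid model spec: ",
                        paste(bad, collapse = "; "), call. = FALSE)
  structure(s, class = "model_spec")
}

#' Canonical physiological parameter set
#'
#' The physiological bone remodeling constants used throughout:
#' alpha1 = 3, alpha2 = 4, beta1 = 0.2, beta2 = 0.02, g11 = 1.1,
#' g21 = -0.5, g12 = 1, g22 = 0, k1 = 0.093, k2 = 0.0008, and tumor
#' proliferation rate mu = 0.005/day. With these exponents the coupling
#' determinant is `gamma = -0.4` and the tumor-free nontrivial steady
#' state is (1.1586, 231.7238) cells.
#'
#' `sigma` (and `D0`) are deliberately not bundled here: the asymptotic
#' tumor burden is a run-level setting swept over
#' 0.05, 0.10, 0.20, 0.40, 0.80, 0.99 in the analyses this package
#' supports. Construct one with [tumor_params()].
#'
#' @return list with elements `params` ([remodeling_params()]) and
#'   `mu` (the canonical tumor proliferation rate)
#' @examples
#' p <- default_params()
#' gamma_coupling(p$params)  # -0.4
#' @export
default_params <- function() {
  list(params = remodeling_params(alpha1 = 3, alpha2 = 4,
                                  beta1 = 0.2, beta2 = 0.02,
                                  g11 = 1.1, g21 = -0.5, g12 = 1, g22 = 0,
                                  k1 = 0.093, k2 = 0.0008),
       mu = 0.005)
}

#' Coupling determinant of the power-law exponents
#'
#' `gamma = g12*g21 - (1-g11)*(1-g22)`, the determinant that must be
#' nonzero for the closed-form nontrivial steady state to exist.
#'
#' @param params a [remodeling_params()] object (or list with the g's)
#' @return numeric scalar
#' @export
gamma_coupling <- function(params) {
  params$g12 * params$g21 - (1 - params$g11) * (1 - params$g22)
}

## -- validation ------------------------------------------------------------

validate_remodeling <- function(p) {
  v <- character()
  for (f in c("alpha1", "alpha2", "beta1", "beta2", "k1", "k2")) {
    x <- p[[f]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      v <- c(v, paste0(f, " must be a positive finite number"))
  }
  for (f in c("g11", "g21", "g12", "g22")) {
    x <- p[[f]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      v <- c(v, paste0(f, " must be a finite number"))
  }
  v
}

validate_tumor <- function(p) {
  v <- character()
  num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num(p$mu) || p$mu < 0) v <- c(v, "mu must be >= 0")
  if (!num(p$sigma) || p$sigma <= 0 || p$sigma >= 1)
    v <- c(v, "sigma must be < 1 and > 0")
  if (!num(p$D0) || p$D0 <= 0)
    v <- c(v, "D0 must be > 0")
  else if (num(p$sigma) && p$sigma > 0 && p$sigma < 1 && p$D0 > p$sigma)
    v <- c(v, "D0 must be <= sigma")
  v
}

validate_spec <- function(s) {
  v <- character()
  if (!s$variant %in% c("base", "model1", "model2", "model3"))
    v <- c(v, "variant must be base/model1/model2/model3")
  if (identical(s$variant, "model1") &&
      (!is.finite(s$scenario) || !s$scenario %in% 0:8))
    v <- c(v, "scenario must be an integer in 0..8")
  num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("g31", "g32", "r11", "r12", "r21", "r22"))
    if (!num(s[[f]])) v <- c(v, paste0(f, " must be a finite number"))
  if (identical(s$variant, "model3") && num(s$r12) && s$r12 <= -1)
    v <- c(v, "r12 must be > -1 (1 + r12*D/sigma must stay nonzero on (0, sigma])")
  v
}

#' Validate a full model setup without raising
#'
#' Collects every invariant violation of a (parameters, tumor, model
#' spec) triple into a character vector, one message per broken rule.
#' Unlike the constructors this function never raises: it accepts plain
#' lists with the right field names (or the corresponding objects) and
#' tolerates any finite or non-finite numeric content, so it can be used
#' to pre-flight raw configuration input. An empty character vector
#' means the setup is valid. A zero coupling determinant `gamma` (which
#' would make the steady state undefined) is reported here as well.
#'
#' @param params remodeling parameters (object or named list)
#' @param tumor tumor parameters (object or named list)
#' @param spec model spec (object or named list); optional
#' @return character vector of violations (empty if valid)
#' @examples
#' p <- default_params()$params
#' validate_setup(p, list(mu = 0.005, sigma = 0.05, D0 = 1e-4))  # character(0)
#' validate_setup(p, list(mu = 0.005, sigma = 1.0, D0 = 1e-4))
#' @export
validate_setup <- function(params, tumor = NULL, spec = NULL) {
  v <- validate_remodeling(as.list(params))
  if (!length(v)) {
    g <- gamma_coupling(params)
    if (is.finite(g) && abs(g) < .Machine$double.eps * 16)
      v <- c(v, "gamma is zero: g12*g21 == (1-g11)*(1-g22), steady state undefined")
  }
  if (!is.null(tumor)) v <- c(v, validate_tumor(as.list(tumor)))
  if (!is.null(spec)) v <- c(v, validate_spec(as.list(spec)))
  v
}

#' @export
print.remodeling_params <- function(x, ...) {
  cat("Bone remodeling parameters\n")
  cat(sprintf("  production alpha = (%g, %g)/day, removal beta = (%g, %g)/day\n",
              x$alpha1, x$alpha2, x$beta1, x$beta2))
  cat(sprintf("  exponents g11=%g g21=%g g12=%g g22=%g (gamma=%g)\n",
              x$g11, x$g21, x$g12, x$g22, gamma_coupling(x)))
  cat(sprintf("  bone activities k1=%g k2=%g %%/cell/day\n", x$k1, x$k2))
  invisible(x)
}

#' @export
print.tumor_params <- function(x, ...) {
  cat(sprintf("Gompertz tumor: mu=%g/day, sigma=%g, D0=%g\n",
              x$mu, x$sigma, x$D0))
  invisible(x)
}

#' @export
print.model_spec <- function(x, ...) {
  extra <- switch(x$variant,
    base   = "",
    model1 = sprintf(" (scenario %d)", x$scenario),
    model2 = sprintf(" (g31=%g, g32=%g)", x$g31, x$g32),
    model3 = sprintf(" (r11=%g, r12=%g, r21=%g, r22=%g)",
                     x$r11, x$r12, x$r21, x$r22))
  cat(sprintf("Model variant: %s%s\n", x$variant, extra))
  invisible(x)
}
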