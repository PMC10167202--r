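## Linear stability of the three-state system (x1, x2, D).
##
## The Jacobian is block triangular: the tumor equation depends only on D,
## so its row is (0, 0, J33) with J33 = -mu/ln(10) at D = sigma, and the
## eigenvalues are those of the 2x2 cell block plus -mu/ln(10) exactly.
## Entries are derived analytically from the implemented right-hand sides
## (coefficients and their D-derivatives), not transcribed from printed
## formulas, and are cross-checked against finite differences in the tests.

jacobian_point <- function(spec, params, tumor, x1, x2, D) {
  .check_cells(x1, x2)
  co <- model_coefficients(spec, params, tumor, D)
  P1 <- co$A1 * x1^co$G11 * x2^co$G21
  P2 <- co$A2 * x1^co$G12 * x2^co$G22
  J <- matrix(0, 3, 3,
              dimnames = list(c("x1", "x2", "D"), c("x1", "x2", "D")))
  J[1, 1] <- co$G11 * P1 / x1 - co$B1
  J[1, 2] <- co$G21 * P1 / x2
  J[1, 3] <- co$dA1 * P1 / co$A1 +
    P1 * (co$dG11 * log(x1) + co$dG21 * log(x2)) - co$dB1 * x1
  J[2, 1] <- co$G12 * P2 / x1
  J[2, 2] <- co$G22 * P2 / x2 - co$B2
  J[2, 3] <- co$dA2 * P2 / co$A2 +
    P2 * (co$dG12 * log(x1) + co$dG22 * log(x2)) - co$dB2 * x2
  mu <- if (is.null(tumor)) 0 else tumor$mu
  sigma <- if (is.null(tumor)) D else tumor$sigma
  J[3, 3] <- if (D == 0) NA_real_ else
    mu * log10(sigma / D) - mu / log(10)
  J
}

#' System Jacobian at the nontrivial steady state
#'
#' Analytic 3x3 Jacobian of the `(x1, x2, D)` dynamics evaluated at
#' `(x1bar, x2bar, sigma)`. The third row is `(0, 0, -mu/ln(10))`
#' exactly, so `-mu/ln(10)` is always an eigenvalue; the other two are
#' the eigenvalues of the cell block. For the base variant a zero-mu,
#' `D`-free system is used (the Jacobian reduces to the cell block plus
#' a zero tumor row).
#'
#' @param spec [model_spec()]
#' @param params [remodeling_params()]
#' @param tumor [tumor_params()] (may be `NULL` for the base variant)
#' @param steady optional precomputed [steady_state()]; defaults to the
#'   variant's closed form (for model 2 the published one, which is the
#'   reference point of the published stability analysis)
#' @return 3x3 numeric matrix
#' @export
jacobian_at_steady <- function(spec, params, tumor = NULL, steady = NULL) {
  if (is.null(steady)) steady <- steady_state(spec, params, tumor)
  D <- if (identical(spec$variant, "base")) {
    if (is.null(tumor)) 1 else tumor$sigma  # any D: base cells ignore it
  } else steady$Dbar
  jacobian_point(spec, params, tumor, steady$x1bar, steady$x2bar, D)
}

#' Characteristic-polynomial invariants of a 3x3 matrix
#'
#' Coefficients `(a1, a2, a3)` of
#' `lambda^3 + a1*lambda^2 + a2*lambda + a3`:
#' `a1 = -tr(J)`, `a2` = sum of the principal 2x2 minors,
#' `a3 = -det(J)`. Computed from the matrix itself.
#'
#' @param J 3x3 numeric matrix
#' @return named numeric vector `c(a1, a2, a3)`
#' @export
characteristic_invariants <- function(J) {
  stopifnot(is.matrix(J), all(dim(J) == c(3, 3)))
  m12 <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  m13 <- J[1, 1] * J[3, 3] - J[1, 3] * J[3, 1]
  m23 <- J[2, 2] * J[3, 3] - J[2, 3] * J[3, 2]
  c(a1 = -(J[1, 1] + J[2, 2] + J[3, 3]),
    a2 = m12 + m13 + m23,
    a3 = -det(J))
}

#' Routh-Hurwitz stability test for a cubic
#'
#' For `lambda^3 + a1*lambda^2 + a2*lambda + a3` all roots have negative
#' real part iff `a1 > 0`, `a3 > 0` and `a1*a2 - a3 > 0`.
#'
#' @param a1 first coefficient, or a length-3 vector `c(a1, a2, a3)`
#' @param a2,a3 remaining coefficients when `a1` is scalar
#' @return logical
#' @examples
#' routh_hurwitz(6, 11, 6)   # roots -1, -2, -3: TRUE
#' routh_hurwitz(1, 1, 2)    # a1*a2 - a3 = -1: FALSE
#' @export
routh_hurwitz <- function(a1, a2 = NULL, a3 = NULL) {
  if (length(a1) == 3 && is.null(a2)) {
    a3 <- a1[[3]]; a2 <- a1[[2]]; a1 <- a1[[1]]
  }
  isTRUE(a1 > 0 && a3 > 0 && a1 * a2 - a3 > 0)
}

#' Eigenvalue taxonomy of a steady state
#'
#' Maps the three eigenvalues to the qualitative regimes of the model:
#' * `"unstable"` - some real part exceeds `tol` (growing solutions);
#' * `"center_like"` - some real part is within `tol` of zero and the
#'   rest are negative (sustained oscillation, as in the physiological
#'   limit cycle);
#' * `"stable_spiral"` - all real parts below `-tol`, some imaginary
#'   part beyond `tol` (damped oscillation);
#' * `"stable_node"` - all real parts below `-tol`, no imaginary parts
#'   (monotone decay).
#'
#' Ties at class boundaries are resolved toward the marginal class
#' (`"center_like"`), never silently toward stability.
#'
#' @param eigs complex vector of eigenvalues
#' @param tol zero tolerance for real/imaginary parts
#' @return character scalar
#' @export
classify_eigenvalues <- function(eigs, tol = 1e-9) {
  re <- Re(eigs); im <- Im(eigs)
  if (any(re > tol)) return("unstable")
  if (any(abs(re) <= tol)) return("center_like")
  if (any(abs(im) > tol)) return("stable_spiral")
  "stable_node"
}

#' Full stability report at the nontrivial steady state
#'
#' Computes the analytic Jacobian, its eigenvalues, the
#' characteristic-polynomial invariants, the Routh-Hurwitz verdict, and
#' the eigenvalue class. The zero tolerance defaults to
#' `1e-9 * max(1, ||J||_inf)`: the limit-cycle case of the physiological
#' model is structurally exact (the cell block has zero trace) but
#' floating-point fuzzy.
#'
#' @param spec [model_spec()]
#' @param params [remodeling_params()]
#' @param tumor [tumor_params()] (may be `NULL` for the base variant)
#' @param steady optional precomputed steady state
#' @param tol zero tolerance; default scales with the Jacobian norm
#' @return an object of class `stability_report`: list with `jacobian`,
#'   `eigenvalues`, `invariants`, `routh_hurwitz_stable`, `eig_class`,
#'   `tol`, `steady`
#' @export
stability_report <- function(spec, params, tumor = NULL, steady = NULL,
                             tol = NULL) {
  if (is.null(steady)) steady <- steady_state(spec, params, tumor)
  J <- jacobian_at_steady(spec, params, tumor, steady)
  if (is.null(tol)) tol <- 1e-9 * max(1, norm(J, "I"))
  ev <- eigen(J, only.values = TRUE)$values
  ev <- as.complex(ev)
  inv <- characteristic_invariants(J)
  structure(list(jacobian = J,
                 eigenvalues = ev,
                 invariants = inv,
                 routh_hurwitz_stable = routh_hurwitz(inv),
                 eig_class = classify_eigenvalues(ev, tol),
                 tol = tol,
                 steady = steady),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability at (x1bar, x2bar) = (%.4f, %.4f)\n",
              x$steady$x1bar, x$steady$x2bar))
  cat(sprintf("  invariants a1=%.6g a2=%.6g a3=%.6g; Routh-Hurwitz stable: %s\n",
              x$invariants[1], x$invariants[2], x$invariants[3],
              x$routh_hurwitz_stable))
  cat("  eigenvalues:",
      paste(sprintf("%.5g%+.5gi", Re(x$eigenvalues), Im(x$eigenvalues)),
            collapse = ", "), "\n")
  cat(sprintf("  class: %s (tol %.3g)\n", x$eig_class, x$tol))
  invisible(x)
}

#' Stability-region scan over coupling parameters
#'
#' Classifies the steady state on a finite grid of coupling constants
#' and tumor asymptotes and returns one row per grid point, suitable for
#' region plotting. For `variant = "model2"` the grid is
#' `g31 x g32 x sigma`; for `variant = "model3"` it is
#' `r11 x r12 x r22 x sigma` at fixed `r21` slices. Grid points whose
#' steady state is undefined are recorded with class `"undefined"`, not
#' dropped, so the row count always equals the product of the grid
#' sizes.
#'
#' @param params [remodeling_params()]
#' @param variant `"model2"` or `"model3"`
#' @param sigma numeric vector of tumor asymptotes
#' @param g31,g32 numeric grids (model 2)
#' @param r11,r12,r21,r22 numeric grids (model 3; `r21` is the slice axis)
#' @param mu tumor proliferation rate
#' @param tol zero tolerance for the eigenvalue classes; scans default
#'   to a coarser 1e-6 than single-point reports
#' @return data.frame with the coupling columns, `sigma`, invariants
#'   `a1 a2 a3`, eigenvalue parts `re1 im1 re2 im2 re3 im3`, and `class`
#' @export
stability_region_scan <- function(params, variant = c("model2", "model3"),
                                  sigma, g31 = 0, g32 = 0,
                                  r11 = 0, r12 = 0, r21 = 0, r22 = 0,
                                  mu = 0.005, tol = 1e-6) {
  variant <- match.arg(variant)
  grid <- if (variant == "model2") {
    expand.grid(g31 = g31, g32 = g32, sigma = sigma,
                KEEP.OUT.ATTRS = FALSE)
  } else {
    expand.grid(r11 = r11, r12 = r12, r21 = r21, r22 = r22, sigma = sigma,
                KEEP.OUT.ATTRS = FALSE)
  }
  n <- nrow(grid)
  out <- cbind(grid,
               a1 = NA_real_, a2 = NA_real_, a3 = NA_real_,
               re1 = NA_real_, im1 = NA_real_, re2 = NA_real_,
               im2 = NA_real_, re3 = NA_real_, im3 = NA_real_,
               class = rep("undefined", n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    row <- grid[i, ]
    spec <- if (variant == "model2") {
      list(variant = "model2", g31 = row$g31, g32 = row$g32)
    } else {
      list(variant = "model3", r11 = row$r11, r12 = row$r12,
           r21 = row$r21, r22 = row$r22)
    }
    tum <- list(mu = mu, sigma = row$sigma, D0 = 0.005 * row$sigma)
    rep_i <- tryCatch(stability_report(spec, params, tum, tol = tol),
                      error = function(e) NULL)
    if (is.null(rep_i)) next
    ev <- rep_i$eigenvalues[order(-Re(rep_i$eigenvalues))]
    out[i, c("a1", "a2", "a3")] <- rep_i$invariants
    out[i, c("re1", "im1", "re2", "im2", "re3", "im3")] <-
      c(rbind(Re(ev), Im(ev)))
    out[i, "class"] <- rep_i$eig_class
  }
  out
}
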