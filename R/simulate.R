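#' Integrate a model variant through time
#'
#' Adaptive stiff-capable integration (lsoda) of the four-state system
#' `(x1, x2, D, z)`: osteoclasts, osteoblasts, normalized tumor burden,
#' and bone mass percentage. Bone mass accumulates via
#' [bone_mass_rate()] against the variant's own nontrivial steady state
#' at `Dbar = sigma`, held constant over the run (`reference = "base"`
#' switches to the tumor-free steady state instead; for model 2 the
#' dynamically consistent fixed point is used, since the bone-mass rule
#' compares cells against the attractor of the trajectory).
#'
#' The solver operates on the open positive orthant: fractional powers
#' of nonpositive cell numbers are meaningless, so if an output point
#' leaves it the run is retried once with 100-fold tighter tolerances
#' and then aborted with a diagnostic (no silent clamping). The aborted
#' condition carries the partial trajectory in its `partial` field.
#'
#' @param spec [model_spec()]
#' @param params [remodeling_params()]
#' @param tumor [tumor_params()]
#' @param init optional `c(x1, x2)` initial cells; defaults to the
#'   tumor-free steady state perturbed by +10 osteoclasts
#' @param t_end final time (days)
#' @param dt_out output grid spacing (days)
#' @param z0 initial bone mass (percent)
#' @param rtol,atol solver tolerances
#' @param reference `"variant"` (default) or `"base"`: which steady
#'   state anchors the bone-mass rule
#' @return a `remodeling_trajectory`: data.frame with columns
#'   `time, x1, x2, D, z` and attributes `spec`, `params`, `tumor`,
#'   `steady`, `solver`
#' @examples
#' d <- default_params()
#' tr <- simulate_remodeling(model_spec("base"), d$params,
#'                           tumor_params(sigma = 0.05), t_end = 300)
#' range(tr$x1)
#' @export
simulate_remodeling <- function(spec, params, tumor, init = NULL,
                                t_end = 1000, dt_out = 1, z0 = 100,
                                rtol = 1e-8, atol = 1e-10,
                                reference = c("variant", "base")) {
  reference <- match.arg(reference)
  steady <- if (reference == "base") base_steady_state(params)
            else if (identical(spec$variant, "model2"))
              steady_state(spec, params, tumor, consistent = TRUE)
            else steady_state(spec, params, tumor)
  if (is.null(init)) {
    b <- base_steady_state(params)
    init <- c(b$x1bar + 10, b$x2bar)
  }
  stopifnot(all(init > 0), tumor$D0 > 0, tumor$D0 <= tumor$sigma)
  y0 <- c(x1 = init[[1]], x2 = init[[2]], D = tumor$D0, z = z0)
  times <- seq(0, t_end, by = dt_out)
  rhs <- make_rhs(spec, params, tumor, steady)

  attempt <- function(rt, at) {
    out <- tryCatch(
      suppressWarnings(
        deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                     rtol = rt, atol = at)),
      error = function(e) NULL)
    if (is.null(out))
      return(list(out = matrix(numeric(), 0, 5,
                               dimnames = list(NULL, c("time", names(y0)))),
                  ok = FALSE))
    ok <- nrow(out) == length(times) &&
      all(is.finite(out[, c("x1", "x2")])) &&
      all(out[, "x1"] > 0) && all(out[, "x2"] > 0)
    list(out = out, ok = ok)
  }
  res <- attempt(rtol, atol)
  used <- c(rtol, atol)
  if (!res$ok) {
    used <- c(rtol / 100, atol / 100)
    res <- attempt(used[1], used[2])
  }
  if (!res$ok) {
    cond <- structure(
      class = c("osteodyn_aborted_run", "error", "condition"),
      list(message = paste0("integration left the positive orthant (or failed)",
                            " even with tightened tolerances"),
           call = sys.call(-1), partial = as.data.frame(res$out)))
    stop(cond)
  }
  traj <- as.data.frame(res$out)
  names(traj)[1] <- "time"
  structure(traj,
            spec = spec, params = params, tumor = tumor, steady = steady,
            solver = list(method = "lsoda", rtol = used[1], atol = used[2]),
            class = c("remodeling_trajectory", "data.frame"))
}

# local maxima with quadratic refinement through the three bracketing points
find_peaks <- function(time, x) {
  n <- length(x)
  if (n < 3) return(data.frame(time = numeric(), value = numeric()))
  i <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(i)) return(data.frame(time = numeric(), value = numeric()))
  a <- x[i - 1]; b <- x[i]; c <- x[i + 1]
  den <- a - 2 * b + c
  off <- ifelse(den == 0, 0, 0.5 * (a - c) / den)
  dt <- time[i + 1] - time[i]
  data.frame(time = time[i] + off * dt,
             value = b - 0.25 * (a - c) * off)
}

#' Diagnose the qualitative regime of a trajectory
#'
#' Assigns one of the trajectory verdicts by explicit numeric rules,
#' applied in order:
#' * `"converged"` - the last 10% of samples stay within `tol`
#'   (relative) of the steady state; the convergence time is the first
#'   time from which this holds through the end;
#' * `"sustained_oscillation"` - at least 5 osteoclast peaks and the
#'   last 5 peak amplitudes differ by less than 2%; period and amplitude
#'   estimates are attached;
#' * `"divergent"` - `x1` or `x2` exceeds 100 times its initial value;
#' * `"collapsed"` - both cell counts end below `1e-3` of the steady
#'   state;
#' * `"undetermined"` - none of the rules fire.
#'
#' @param traj a `remodeling_trajectory` (or data.frame with
#'   `time, x1, x2`)
#' @param steady reference [steady_state()]; defaults to the
#'   trajectory's own
#' @param tol relative convergence tolerance (default 1%)
#' @return an object of class `trajectory_diagnosis`: list with
#'   `verdict` and, when applicable, `convergence_time`, `period`,
#'   `amplitude`
#' @export
diagnose_trajectory <- function(traj, steady = attr(traj, "steady"),
                                tol = 0.01) {
  stopifnot(!is.null(steady))
  n <- nrow(traj)
  rel <- pmax(abs(traj$x1 - steady$x1bar) / steady$x1bar,
              abs(traj$x2 - steady$x2bar) / steady$x2bar)
  tail_i <- seq.int(ceiling(0.9 * n), n)
  if (all(rel[tail_i] <= tol)) {
    ok <- rev(cumprod(rev(rel <= tol))) > 0  # longest compliant tail
    return(structure(list(verdict = "converged",
                          convergence_time = traj$time[which(ok)[1]]),
                     class = "trajectory_diagnosis"))
  }
  pk <- find_peaks(traj$time, traj$x1)
  if (nrow(pk) >= 5) {
    last5 <- utils::tail(pk$value, 5)
    if (max(abs(diff(last5)) / last5[-length(last5)]) < 0.02) {
      per <- mean(diff(utils::tail(pk$time, 5)))
      return(structure(list(verdict = "sustained_oscillation",
                            period = per,
                            amplitude = mean(last5)),
                       class = "trajectory_diagnosis"))
    }
  }
  if (max(traj$x1) > 100 * traj$x1[1] || max(traj$x2) > 100 * traj$x2[1])
    return(structure(list(verdict = "divergent"),
                     class = "trajectory_diagnosis"))
  if (traj$x1[n] < 1e-3 * steady$x1bar && traj$x2[n] < 1e-3 * steady$x2bar)
    return(structure(list(verdict = "collapsed"),
                     class = "trajectory_diagnosis"))
  structure(list(verdict = "undetermined",
                 final = c(x1 = traj$x1[n], x2 = traj$x2[n]),
                 max_rel_deviation = max(rel[tail_i])),
            class = "trajectory_diagnosis")
}

#' @export
print.trajectory_diagnosis <- function(x, ...) {
  cat("Trajectory verdict:", x$verdict, "\n")
  if (!is.null(x$convergence_time))
    cat(sprintf("  converged from t = %g days\n", x$convergence_time))
  if (!is.null(x$period))
    cat(sprintf("  period ~ %.1f days, peak amplitude ~ %.3f\n",
                x$period, x$amplitude))
  invisible(x)
}

#' Four-panel trajectory plot
#'
#' Osteoclasts, osteoblasts, bone mass over time, and the
#' osteoclast-osteoblast phase portrait.
#'
#' @param x a `remodeling_trajectory`
#' @param ... ignored
#' @export
plot.remodeling_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$x1, type = "l", xlab = "time (days)",
                 ylab = "osteoclasts", main = "x1(t)")
  graphics::plot(x$time, x$x2, type = "l", xlab = "time (days)",
                 ylab = "osteoblasts", main = "x2(t)")
  graphics::plot(x$time, x$z, type = "l", xlab = "time (days)",
                 ylab = "bone mass (%)", main = "z(t)")
  graphics::plot(x$x1, x$x2, type = "l", xlab = "osteoclasts",
                 ylab = "osteoblasts", main = "phase portrait")
  invisible(x)
}
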