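#' State populations from a trajectory ensemble
#'
#' `P_k(t)` is the fraction of trajectories whose active state is `k` at
#' time `t`. Accepts a list of `sh_trajectory` records, the output of
#' [propagate_ensemble()], or a `synthetic_ensemble` (for which active
#' states follow analytically from the hop times: upper state before the
#' S2 -> S1 hop, S1 until the S1 -> S0 hop, S0 afterwards).
#'
#' @param x ensemble object (see above).
#' @param grid time grid in fs; defaults to the recorded frame times
#'   (trajectories) or a 5 fs grid over the production window (synthetic).
#' @param states number of states (inferred when possible).
#' @return a `population_curves` data frame: `time_fs` plus one column per
#'   state label; populations sum to one on every row. Attribute
#'   `n_trajectories`.
#' @export
populations_from_ensemble <- function(x, grid = NULL, states = NULL) {
  if (inherits(x, "synthetic_ensemble")) {
    tr <- x$trajectories
    if (nrow(tr) == 0) stop("empty ensemble")
    if (is.null(grid)) grid <- seq(0, x$total_time_fs, by = 5)
    t21 <- tr$t21_fs
    t10 <- ifelse(is.na(tr$t10_fs), Inf, tr$t10_fs)
    n <- nrow(tr)
    p2 <- vapply(grid, function(t) sum(t21 > t), numeric(1)) / n
    p0 <- vapply(grid, function(t) sum(t10 <= t), numeric(1)) / n
    p1 <- 1 - p2 - p0
    out <- data.frame(time_fs = grid, S0 = p0, S1 = p1, upper = p2)
  } else {
    if (!is.null(x$active) && is.list(x$active)) {
      actives <- x$active
      tgrid <- x$time
    } else {
      actives <- lapply(x, function(tr) tr$active)
      tgrid <- x[[1]]$time
    }
    n <- length(actives)
    if (n == 0) stop("empty ensemble")
    if (is.null(states))
      states <- max(vapply(actives, max, integer(1)))
    len <- max(lengths(actives))
    # trajectories that exited early keep their final state afterwards
    A <- vapply(actives, function(a) c(a, rep(a[length(a)], len - length(a))),
                integer(len))
    counts <- vapply(seq_len(states), function(k) rowSums(A == k),
                     numeric(len))
    P <- counts / n
    if (!is.null(grid)) {
      idx <- vapply(grid, function(t) which.min(abs(tgrid - t)), integer(1))
      P <- P[idx, , drop = FALSE]
      tgrid <- grid
    }
    out <- data.frame(time_fs = tgrid[seq_len(nrow(P))], P)
    names(out)[-1] <- paste0("S", seq_len(states) - 1L)
  }
  stopifnot(all(abs(rowSums(out[, -1]) - 1) < 1e-9))
  attr(out, "n_trajectories") <- n
  class(out) <- c("population_curves", class(out))
  out
}

# sequential-feed population of an S1 channel fed by exp(-t/tau2) decay,
# with the analytic tau -> tau2 limiting form
seq_feed <- function(t, tau, tau2) {
  if (abs(tau - tau2) < 1e-6 * tau2) {
    (t / tau) * exp(-t / tau)
  } else {
    tau / (tau - tau2) * (exp(-t / tau) - exp(-t / tau2))
  }
}

#' Fit the sequential kinetic model to population curves
#'
#' The upper-state pool (every state above S1, summed) decays as
#' `exp(-t / tau2)`; the S1 population follows the sequential-feed
#' bi-exponential closed form
#' `sum_i w_i tau_i / (tau_i - tau2) (exp(-t/tau_i) - exp(-t/tau2))`
#' with `w_2 = 1 - w_1` (degenerate `tau_i -> tau2` handled by the analytic
#' limit `(t/tau) exp(-t/tau)`). Both curves are fitted jointly by
#' Levenberg-Marquardt least squares with unit weights; initial guesses
#' `tau2 = 100 fs, tau1 = 1 ps, tau1' = 20 ps, w = 0.3`.
#'
#' Alternatively (`mode = "independent"`) the S1 curve alone is fitted with
#' a plain bi-exponential from its maximum onward.
#'
#' @param curves a `population_curves` data frame; the S1 column must be
#'   named `S1`, upper states are all columns beyond `S1` (or a column
#'   named `upper`).
#' @param mode `"sequential"` (default) or `"independent"`.
#' @param start optional named list overriding the initial guesses
#'   (`tau2` fs, `tau1` fs, `tau1p` fs, `w`).
#' @return a `kinetic_fit` object: `tau2_fs`, `tau1_ps`, `tau1_prime_ps`,
#'   `weight_fast`, `tau1_avg_ps`, standard errors, `residual_norm`, and
#'   `tau1_prime_identifiable`.
#' @export
fit_sequential_kinetics <- function(curves, mode = c("sequential", "independent"),
                                    start = list()) {
  mode <- match.arg(mode)
  cn <- names(curves)
  if (!"S1" %in% cn) stop("curves must contain an S1 column")
  t <- curves$time_fs
  s1 <- curves$S1
  upcols <- setdiff(cn, c("time_fs", "S0", "S1"))
  if (length(upcols) == 0) stop("curves must contain upper-state populations")
  up <- rowSums(curves[, upcols, drop = FALSE])
  s0 <- list(tau2 = 100, tau1 = 1000, tau1p = 20000, w = 0.3)
  s0[names(start)] <- start

  if (mode == "sequential") {
    resid_fun <- function(p)
      c(exp(-t / p["tau2"]), p["w"] * seq_feed(t, p["tau1"], p["tau2"]) +
          (1 - p["w"]) * seq_feed(t, p["tau1p"], p["tau2"])) - c(up, s1)
    par0 <- unlist(s0)
    lower <- c(tau2 = 1, tau1 = 1, tau1p = 1, w = 0)
    upper <- c(tau2 = Inf, tau1 = Inf, tau1p = Inf, w = 1)
  } else {
    i0 <- which.max(s1)
    tt <- t[i0:length(t)] - t[i0]
    yy <- s1[i0:length(t)] / s1[i0]
    resid_fun <- function(p)
      p["w"] * exp(-tt / p["tau1"]) + (1 - p["w"]) * exp(-tt / p["tau1p"]) - yy
    par0 <- unlist(s0[c("tau1", "tau1p", "w")])
    lower <- c(tau1 = 1, tau1p = 1, w = 0)
    upper <- c(tau1 = Inf, tau1p = Inf, w = 1)
  }
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  if (!fit$info %in% 1:4)
    stop("kinetic fit did not converge: ", fit$message,
         " (last iterate: ", paste(signif(fit$par, 4), collapse = ", "), ")")
  cf <- fit$par
  # standard errors from the local quadratic approximation; degenerate
  # directions (e.g. an unidentifiable slow component) come out NA
  dof <- length(resid_fun(cf)) - length(cf)
  s2 <- fit$deviance / max(dof, 1)
  covm <- tryCatch(solve(fit$hessian) * s2, error = function(e) NULL)
  se <- if (is.null(covm) || any(diag(covm) < 0)) {
    setNames(rep(NA_real_, length(cf)), names(cf))
  } else {
    sqrt(diag(covm))
  }
  tau2 <- if (mode == "sequential") unname(cf["tau2"]) else NA_real_
  tau1 <- unname(cf["tau1"]) / 1000
  tau1p <- unname(cf["tau1p"]) / 1000
  w <- unname(cf["w"])
  identifiable <- is.finite(se["tau1p"]) &&
    (1 - w) > 1e-3 && abs(tau1p - tau1) / tau1p > 1e-3
  structure(list(
    tau2_fs = tau2, tau1_ps = tau1, tau1_prime_ps = tau1p, weight_fast = w,
    tau1_avg_ps = w * tau1 + (1 - w) * tau1p,
    se = list(tau2_fs = unname(se["tau2"]), tau1_ps = unname(se["tau1"]) / 1000,
              tau1_prime_ps = unname(se["tau1p"]) / 1000,
              weight_fast = unname(se["w"])),
    residual_norm = sqrt(fit$deviance),
    tau1_prime_identifiable = identifiable,
    mode = mode, fit = fit), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Sequential kinetic fit (", x$mode, ")\n", sep = "")
  if (is.finite(x$tau2_fs))
    cat(sprintf("  tau2      = %.0f fs\n", x$tau2_fs))
  cat(sprintf("  tau1      = %.1f ps (%.1f%%)\n", x$tau1_ps,
              100 * x$weight_fast))
  cat(sprintf("  tau1'     = %.1f ps (%.1f%%)%s\n", x$tau1_prime_ps,
              100 * (1 - x$weight_fast),
              if (!x$tau1_prime_identifiable) "  [unidentifiable]" else ""))
  cat(sprintf("  tau1_avg  = %.1f ps\n", x$tau1_avg_ps))
  invisible(x)
}

#' Weighted-average S1 lifetime
#'
#' `w * tau1 + (1 - w) * tau1'`, reported to 0.1 ps.
#'
#' @param weight_fast weight of the fast component, in `[0, 1]`.
#' @param tau1,tau1_prime lifetimes in ps.
#' @return weighted average in ps, rounded to one decimal.
#' @export
weighted_average_lifetime <- function(weight_fast, tau1, tau1_prime) {
  stopifnot(weight_fast >= 0, weight_fast <= 1, tau1 > 0, tau1_prime > 0)
  round(weight_fast * tau1 + (1 - weight_fast) * tau1_prime, 1)
}

#' Lifetime ratio
#'
#' Plain quotient rounded to two decimals (e.g. the s-trans / s-cis lifetime
#' ratio compared against the experimental S*/S1 ratio).
#'
#' @param numerator,denominator lifetimes (ps).
#' @return unitless ratio, two decimals.
#' @export
lifetime_ratio <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  round(numerator / denominator, 2)
}

#' Convert between photon energy (eV) and wavelength (nm)
#'
#' `lambda[nm] = 1239.8419 / E[eV]`; the function is its own inverse.
#'
#' @param x energy in eV or wavelength in nm (positive).
#' @return the converted value.
#' @export
ev_nm_convert <- function(x) {
  if (any(x <= 0)) stop("input must be positive")
  .const$evnm / x
}

#' @rdname ev_nm_convert
#' @export
ev_to_nm <- ev_nm_convert

#' @rdname ev_nm_convert
#' @export
nm_to_ev <- ev_nm_convert

#' Analytic population curves of the sequential kinetic model
#'
#' Convenience generator of noise-free `population_curves` from given
#' parameters (used for fit validation and reporting).
#'
#' @param tau2_fs,tau1_ps,tau1_prime_ps,weight_fast model parameters.
#' @param grid_fs time grid (fs).
#' @return a `population_curves` data frame with columns `S0`, `S1`, `upper`.
#' @export
sequential_population_curves <- function(tau2_fs, tau1_ps, tau1_prime_ps,
                                         weight_fast,
                                         grid_fs = seq(0, 15000, by = 5)) {
  up <- exp(-grid_fs / tau2_fs)
  s1 <- weight_fast * seq_feed(grid_fs, tau1_ps * 1000, tau2_fs) +
    (1 - weight_fast) * seq_feed(grid_fs, tau1_prime_ps * 1000, tau2_fs)
  out <- data.frame(time_fs = grid_fs, S0 = 1 - up - s1, S1 = s1, upper = up)
  attr(out, "n_trajectories") <- Inf
  class(out) <- c("population_curves", class(out))
  out
}
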