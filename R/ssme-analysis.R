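#' Extract the peak current of the activating phase
#'
#' Finds the sample of largest absolute current after onset of the A phase,
#' preserving its sign (transport currents may be positive or negative
#' depending on the direction of net charge movement).
#'
#' @param trace a `"current_trace"` (or data frame with `time_s`,
#'   `current_nA`, `phase`).
#' @return List with `peak_nA`, `time_s`, and `index`.
#' @export
peak_current <- function(trace) {
  idx <- which(trace$phase == "A")
  if (!length(idx)) stop("trace has no A phase", call. = FALSE)
  k <- idx[which.max(abs(trace$current_nA[idx]))]
  list(peak_nA = trace$current_nA[k], time_s = trace$time_s[k], index = k)
}

#' Fit the decay of a transient current
#'
#' Fits the current decay from its peak with a mono- or bi-exponential
#' `I(t) = sum_i A_i exp(-t / tau_i)` by nonlinear least squares
#' (Levenberg-Marquardt). The observed rate constant is `k_obs = 1/tau` of
#' the dominant (largest-|A|) component. Bi-exponential fits are initialized
#' from log-spaced time-constant guesses around the mono-exponential
#' solution and the best residual norm wins.
#'
#' @param trace a `"current_trace"`; the fit window starts at the A-phase
#'   peak (or the global absolute maximum if no phase labels are present).
#' @param n_components 1 or 2.
#' @return Object of class `"exp_fit"`: `amplitudes_nA`, `tau_s` (ordered
#'   fast to slow), `k_obs` (1/tau of the dominant component), `residual_norm`,
#'   `fitted`, `converged`.
#' @export
fit_decay <- function(trace, n_components = 1) {
  stopifnot(n_components %in% 1:2)
  if ("phase" %in% names(trace) && any(trace$phase == "A")) {
    pk <- peak_current(trace)
    i0 <- pk$index
    win <- which(trace$phase == "A" & seq_len(nrow(trace)) >= i0)
  } else {
    i0 <- which.max(abs(trace$current_nA))
    win <- seq(i0, nrow(trace))
  }
  t <- trace$time_s[win] - trace$time_s[win[1]]
  y <- trace$current_nA[win]
  if (length(t) < 10) stop("need at least 10 samples after the peak", call. = FALSE)

  sgn <- sign(y[1]); if (sgn == 0) sgn <- 1
  tau0 <- max(t[max(which(abs(y) > abs(y[1]) / exp(1)))], t[2])
  fits <- list()
  if (n_components == 1) {
    starts <- list(c(A1 = y[1], tau1 = tau0))
    form <- y ~ A1 * exp(-t / tau1)
  } else {
    starts <- lapply(c(0.2, 1, 5), function(f) {
      c(A1 = y[1] / 2, tau1 = tau0 * f / 4, A2 = y[1] / 2, tau2 = tau0 * f)
    })
    form <- y ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2)
  }
  dat <- data.frame(t = t, y = y)
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = as.list(st),
                        lower = c(-Inf, 1e-8)[rep(1:2, length(st) / 2)],
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1]] <- f
  }
  if (!length(fits)) {
    stop("exponential fit did not converge; residual data returned in message",
         call. = FALSE)
  }
  rn <- vapply(fits, function(f) sqrt(sum(residuals(f)^2)), numeric(1))
  best <- fits[[which.min(rn)]]
  cf <- coef(best)
  taus <- cf[grep("^tau", names(cf))]
  amps <- cf[grep("^A", names(cf))]
  o <- order(taus)            # fast -> slow
  taus <- unname(taus[o]); amps <- unname(amps[o])
  dom <- which.max(abs(amps))
  structure(
    list(amplitudes_nA = amps, tau_s = taus, k_obs = 1 / taus[dom],
         residual_norm = min(rn),
         fitted = data.frame(t = t + trace$time_s[win[1]],
                             y = fitted(best)),
         converged = TRUE),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("Exponential decay fit:\n")
  for (i in seq_along(x$tau_s)) {
    cat(sprintf("  A%d = %.4g nA, tau%d = %.4g s (k = %.4g 1/s)\n",
                i, x$amplitudes_nA[i], i, x$tau_s[i], 1 / x$tau_s[i]))
  }
  cat(sprintf("  k_obs = %.4g 1/s, residual norm = %.3g\n",
              x$k_obs, x$residual_norm))
  invisible(x)
}

#' Apparent pKa fit of peak currents versus pH
#'
#' Fits normalized peak currents with a single-site titration curve:
#' acidic deactivation (pH <= 8): `I(pH) = I_max / (1 + 10^(pK - pH))`;
#' alkaline deactivation (pH >= 7.5): `I(pH) = I_max / (1 + 10^(pH - pK))`.
#' `I_max` and `pK` are fitted jointly on the unnormalized peaks, so the
#' reported normalized curve needs no iteration.
#'
#' @param pH numeric vector of pH values.
#' @param current peak currents (any consistent unit).
#' @param mode `"acidic"` or `"alkaline"`; points outside the printed
#'   equation domain (pH <= 8 acidic, pH >= 7.5 alkaline) are dropped with a
#'   message.
#' @return Object of class `"pka_fit"`: `I_max`, `pK`, `mode`,
#'   `residual_norm`, `se` (Jacobian-based standard errors), `data`.
#' @export
pka_fit <- function(pH, current, mode = c("acidic", "alkaline")) {
  mode <- match.arg(mode)
  keep <- if (mode == "acidic") pH <= 8 else pH >= 7.5
  if (any(!keep)) {
    message(sum(!keep), " point(s) outside the ", mode, " fit domain dropped")
  }
  pH <- pH[keep]; current <- current[keep]
  if (length(pH) < 3) stop("need at least 3 points in the fit domain", call. = FALSE)
  s <- if (mode == "acidic") 1 else -1
  ## monotone-direction sanity check: acidic curves rise with pH
  slope <- coef(stats::lm(current ~ pH))[2]
  if (s * slope < 0) {
    stop("data trend is inconsistent with ", mode,
         " deactivation; check the mode", call. = FALSE)
  }
  dat <- data.frame(pH = pH, y = current)
  start <- list(I_max = max(abs(current)) * sign(current[which.max(abs(current))]),
                pK = median(pH))
  f <- minpack.lm::nlsLM(y ~ I_max / (1 + 10^(s * (pK - pH))), data = dat,
                         start = start,
                         control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(f)
  se <- tryCatch(sqrt(diag(vcov(f))), error = function(e) rep(NA_real_, 2))
  if (cf[["pK"]] < min(pH) - 1 || cf[["pK"]] > max(pH) + 1) {
    warning("fitted pK lies outside the sampled pH range +/- 1", call. = FALSE)
  }
  structure(
    list(I_max = cf[["I_max"]], pK = cf[["pK"]], mode = mode,
         residual_norm = sqrt(sum(residuals(f)^2)),
         se = setNames(se, c("I_max", "pK")),
         data = data.frame(pH = pH, current = current,
                           normalized = current / cf[["I_max"]])),
    class = "pka_fit"
  )
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf("%s deactivation fit: pK = %.3f (SE %.3f), I_max = %.4g (SE %.3g)\n",
              x$mode, x$pK, x$se["pK"], x$I_max, x$se["I_max"]))
  invisible(x)
}

#' Observed rate constant of the induced-fit binding scheme
#'
#' For the two-step scheme P + S <-> PS <-> P*S with rapid binding
#' (dissociation constant `K_D`) followed by a conformational change
#' (`k_plus` forward, `k_minus` back), the observed relaxation rate is
#' hyperbolic in substrate concentration:
#' `k_obs = k_minus + k_plus * gal / (gal + K_D)`.
#'
#' @param gal substrate concentration (mM), >= 0.
#' @param K_D dissociation constant (mM).
#' @param k_plus,k_minus conformational rate constants (1/s).
#' @return `k_obs` in 1/s.
#' @examples
#' kobs_model(50, K_D = 15.1, k_plus = 70.6, k_minus = 23.8) # ~78 1/s
#' @export
kobs_model <- function(gal, K_D, k_plus, k_minus) {
  if (K_D <= 0 || k_plus <= 0 || k_minus <= 0) {
    stop("K_D, k_plus and k_minus must be positive", call. = FALSE)
  }
  if (any(gal < 0)) stop("gal must be non-negative", call. = FALSE)
  k_minus + k_plus * gal / (gal + K_D)
}

#' Fit the induced-fit model to k_obs versus concentration
#'
#' Nonlinear least squares of [kobs_model()] against observed rate constants
#' at several substrate concentrations.
#'
#' @param concs substrate concentrations (mM); at least 4 distinct values
#'   are required, spanning both sides of the fitted `K_D` for good
#'   identifiability.
#' @param kobs_values observed rates (1/s).
#' @param weights optional fitting weights.
#' @return Object of class `"induced_fit"`: `K_D`, `k_plus`, `k_minus`,
#'   `se`, `covariance`, `residual_norm`.
#' @export
fit_induced_fit <- function(concs, kobs_values, weights = NULL) {
  if (length(unique(concs)) < 4) {
    stop("need at least 4 distinct concentrations for identifiability",
         call. = FALSE)
  }
  dat <- data.frame(x = concs, y = kobs_values)
  if (is.null(weights)) weights <- rep(1, length(concs))
  ## the model is linear in (k_minus, k_plus) at fixed K_D: profile K_D on
  ## a log grid with weighted linear solves to get a robust start
  kd_grid <- exp(seq(log(min(concs[concs > 0]) / 10), log(max(concs) * 10),
                     length.out = 80))
  prof <- vapply(kd_grid, function(kd) {
    Xd <- cbind(1, concs / (concs + kd))
    cf <- tryCatch(stats::lm.wfit(Xd, kobs_values, weights)$coefficients,
                   error = function(e) c(NA, NA))
    if (any(is.na(cf)) || any(cf <= 0)) return(Inf)
    sum(weights * (kobs_values - Xd %*% cf)^2)
  }, numeric(1))
  kd0 <- kd_grid[which.min(prof)]
  X0 <- cbind(1, concs / (concs + kd0))
  cf0 <- stats::lm.wfit(X0, kobs_values, weights)$coefficients
  start <- list(K_D = kd0, k_plus = max(cf0[2], 1e-6),
                k_minus = max(cf0[1], 1e-6))
  f <- tryCatch(
    minpack.lm::nlsLM(y ~ k_minus + k_plus * x / (x + K_D), data = dat,
                      start = start, weights = weights,
                      lower = c(1e-9, 1e-9, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (!is.null(f)) {
    cf <- coef(f)
    V <- tryCatch(vcov(f), error = function(e) matrix(NA_real_, 3, 3))
    rss <- sqrt(sum(residuals(f)^2))
  } else {
    ## LM polish can fail on flat profiles; refine the profiled solve instead
    profile_rss <- function(kd) {
      Xd <- cbind(1, concs / (concs + kd))
      cfk <- stats::lm.wfit(Xd, kobs_values, weights)$coefficients
      sum(weights * (kobs_values - Xd %*% cfk)^2)
    }
    kd_hat <- stats::optimize(profile_rss, kd0 * c(0.5, 2))$minimum
    Xh <- cbind(1, concs / (concs + kd_hat))
    cfh <- stats::lm.wfit(Xh, kobs_values, weights)$coefficients
    cf <- c(K_D = kd_hat, k_plus = unname(cfh[2]), k_minus = unname(cfh[1]))
    ## Jacobian-based covariance at the optimum
    J <- cbind(-cfh[2] * concs / (concs + kd_hat)^2,
               concs / (concs + kd_hat), rep(1, length(concs)))
    res <- kobs_values - Xh %*% cfh
    s2 <- sum(weights * res^2) / (length(concs) - 3)
    V <- tryCatch(s2 * solve(t(J * weights) %*% J),
                  error = function(e) matrix(NA_real_, 3, 3))
    rss <- sqrt(sum(res^2))
  }
  if (cf[["K_D"]] > 2 * max(concs)) {
    warning("fitted K_D far above the sampled concentrations; ",
            "design poorly identifies the plateau", call. = FALSE)
  }
  structure(
    list(K_D = unname(cf[["K_D"]]), k_plus = unname(cf[["k_plus"]]),
         k_minus = unname(cf[["k_minus"]]),
         se = sqrt(abs(diag(V))), covariance = V,
         residual_norm = rss),
    class = "induced_fit"
  )
}

#' @export
print.induced_fit <- function(x, ...) {
  cat(sprintf("Induced-fit: K_D = %.3g mM, k+ = %.3g 1/s, k- = %.3g 1/s\n",
              x$K_D, x$k_plus, x$k_minus))
  invisible(x)
}

#' Ratio of substrate to proton chemical-potential differences
#'
#' `ln(gal_in/gal_out) / ln([H]_out/[H]_in)`; RT cancels. At the reversal
#' point of a coupled n H+ : m substrate transporter this ratio equals n/m.
#'
#' @param cond a [solution_condition()] with all four concentrations > 0 and
#'   `pH_in != pH_out`.
#' @return Dimensionless ratio.
#' @export
chemical_potential_ratio <- function(cond) {
  if (cond$gal_in <= 0 || cond$gal_out <= 0) {
    stop("galactonate concentrations must be positive", call. = FALSE)
  }
  if (cond$pH_in == cond$pH_out) {
    stop("pH_in equals pH_out: proton chemical-potential difference is zero",
         call. = FALSE)
  }
  log(cond$gal_in / cond$gal_out) / log(10^(cond$pH_in - cond$pH_out))
}

#' Integrate transported charge over a trace window
#'
#' Trapezoidal integral of the current over the A phase (default) or an
#' explicit time window; with current in nA and time in s the result is in
#' nC. An optional baseline (e.g. the mean current over the late NA phase)
#' is subtracted first.
#'
#' @param trace a `"current_trace"`.
#' @param window `"A"` or a numeric `c(t0, t1)` in seconds.
#' @param baseline scalar baseline current to subtract (default:
#'   `"auto"` = mean of the last 0.2 s of the NA phase preceding A, or 0 if
#'   absent); or a number.
#' @return Charge in nC.
#' @export
integrate_charge <- function(trace, window = "A", baseline = "auto") {
  if (identical(window, "A")) {
    idx <- which(trace$phase == "A")
    if (!length(idx)) stop("trace has no A phase", call. = FALSE)
  } else {
    idx <- which(trace$time_s >= window[1] & trace$time_s <= window[2])
  }
  b <- 0
  if (identical(baseline, "auto")) {
    if ("phase" %in% names(trace) && any(trace$phase == "NA")) {
      pre <- which(trace$phase == "NA" & seq_len(nrow(trace)) < min(idx))
      if (length(pre)) {
        t_end <- trace$time_s[max(pre)]
        sel <- pre[trace$time_s[pre] >= t_end - 0.2]
        b <- mean(trace$current_nA[sel])
      }
    }
  } else {
    b <- baseline
  }
  pracma::trapz(trace$time_s[idx], trace$current_nA[idx] - b)
}

#' Subtract a negative-control trace
#'
#' Point-wise subtraction of a control recording (e.g. empty liposomes) to
#' remove solution-exchange artifacts. Grids must match unless
#' `resample = TRUE`, in which case the control is linearly interpolated
#' onto the trace grid.
#'
#' @param trace,control_trace `"current_trace"` objects.
#' @param resample interpolate the control onto the trace grid.
#' @param control_id identifier stored in the result's attributes.
#' @return Corrected `"current_trace"`.
#' @export
subtract_control <- function(trace, control_trace, resample = FALSE,
                             control_id = "control") {
  same_grid <- nrow(trace) == nrow(control_trace) &&
    isTRUE(all.equal(trace$time_s, control_trace$time_s))
  if (!same_grid && !resample) {
    stop("time grids differ; set resample = TRUE to interpolate the control",
         call. = FALSE)
  }
  ctl <- if (same_grid) control_trace$current_nA else {
    stats::approx(control_trace$time_s, control_trace$current_nA,
                  xout = trace$time_s, rule = 2)$y
  }
  out <- trace
  out$current_nA <- trace$current_nA - ctl
  attr(out, "control_id") <- control_id
  out
}

#' Transport stoichiometry from a reversal assay
#'
#' Given transported charges measured across a range of substrate-to-proton
#' chemical-potential ratios, locates the zero crossing by piecewise-linear
#' interpolation between the two bracketing points. For an n H+ : m
#' substrate symporter the crossing sits at ratio n/m.
#'
#' @param ratios chemical-potential ratios (see
#'   [chemical_potential_ratio()]).
#' @param charges transported charges (nC) at each ratio; must change sign
#'   across the sampled range.
#' @return Object of class `"stoichiometry_result"`: `n_over_m`, `bracket`
#'   (the two bracketing ratios), `points`.
#' @export
stoichiometry_from_reversal <- function(ratios, charges) {
  o <- order(ratios)
  ratios <- ratios[o]; charges <- charges[o]
  s <- sign(charges)
  cross <- which(s[-1] * s[-length(s)] < 0 | s[-length(s)] == 0)
  if (any(charges == 0)) {
    i <- which(charges == 0)[1]
    return(structure(list(n_over_m = ratios[i],
                          bracket = ratios[c(i, i)],
                          points = data.frame(ratio = ratios, charge = charges)),
                     class = "stoichiometry_result"))
  }
  if (!length(cross)) {
    stop("no reversal in sampled range: charges do not change sign",
         call. = FALSE)
  }
  i <- cross[1]
  x0 <- ratios[i] - charges[i] * (ratios[i + 1] - ratios[i]) /
    (charges[i + 1] - charges[i])
  structure(
    list(n_over_m = x0, bracket = ratios[c(i, i + 1)],
         points = data.frame(ratio = ratios, charge = charges)),
    class = "stoichiometry_result"
  )
}

#' @export
print.stoichiometry_result <- function(x, ...) {
  cat(sprintf("Reversal-assay stoichiometry: n/m = %.3f (bracket %.3g..%.3g)\n",
              x$n_over_m, x$bracket[1], x$bracket[2]))
  invisible(x)
}

#' Simulate the reversal assay and estimate the stoichiometry
#'
#' Runs the solution-exchange reversal protocol on the kinetic cycle:
#' internal solution pH 7.3 with 0.5 mM galactonate; external activating
#' solutions at pH 7.6 with galactonate chosen so the chemical-potential
#' ratio spans the requested range; phases NA, A, NA of 2, 3 and 3 s. The
#' A-phase current is integrated to charge at each ratio and the
#' zero-crossing returned via [stoichiometry_from_reversal()].
#'
#' @param model a `"state_cycle_model"` (default [build_dgot_cycle()]).
#' @param ratios chemical-potential ratios to sample (default 0..4).
#' @param pH_in,pH_out,gal_in protocol solution parameters.
#' @param readout an [ssme_readout()].
#' @param dt sampling interval, s.
#' @return A `"stoichiometry_result"` with the simulated charge-vs-ratio
#'   points attached.
#' @export
reversal_assay <- function(model = build_dgot_cycle(),
                           ratios = seq(0, 4, by = 0.5),
                           pH_in = 7.3, pH_out = 7.6, gal_in = 0.5,
                           readout = ssme_readout(), dt = 2e-3) {
  lhr <- log(10^(-pH_out) / 10^(-pH_in))  # ln([H]_out/[H]_in)
  charges <- vapply(ratios, function(r) {
    gal_out <- gal_in * exp(-r * lhr)
    na_cond <- solution_condition(pH_in, pH_in, gal_in, gal_in)
    a_cond  <- solution_condition(pH_in, pH_out, gal_in, gal_out)
    phases <- list(protocol_phase("NA", 2, na_cond),
                   protocol_phase("A", 3, a_cond),
                   protocol_phase("NA", 3, na_cond))
    tr <- simulate_ssme_protocol(model, phases, readout, dt)
    integrate_charge(tr)
  }, numeric(1))
  stoichiometry_from_reversal(ratios, charges)
}

#' Compare current decay times across lipid-to-protein ratios
#'
#' Transport currents decay faster at higher LPR (fewer transporters charge
#' the same liposome capacitance more slowly... i.e. the discharge is
#' turnover-limited), whereas pre-steady-state currents are LPR-independent.
#' Fits a mono-exponential decay per group and reports whether the decay
#' time falls monotonically with LPR.
#'
#' @param traces list of `"current_trace"` objects.
#' @param lpr numeric LPR per trace.
#' @param tol relative spread below which the decay times are called
#'   LPR-independent (default 0.1).
#' @return List with `tau_by_lpr` (data frame), `verdict` in
#'   `c("monotone_decreasing", "independent", "non_monotone")`.
#' @export
lpr_decay_comparison <- function(traces, lpr, tol = 0.1) {
  if (length(unique(lpr)) < 2) {
    stop("need at least two LPR groups", call. = FALSE)
  }
  tau <- vapply(traces, function(tr) {
    f <- fit_decay(tr, 1)
    f$tau_s[which.max(abs(f$amplitudes_nA))]
  }, numeric(1))
  agg <- aggregate(tau, list(lpr = lpr), mean)
  names(agg)[2] <- "tau_s"
  agg <- agg[order(agg$lpr), ]
  spread <- diff(range(agg$tau_s)) / mean(agg$tau_s)
  verdict <- if (spread < tol) "independent"
  else if (all(diff(agg$tau_s) < 0)) "monotone_decreasing"
  else "non_monotone"
  list(tau_by_lpr = agg, verdict = verdict)
}

#' @importFrom stats aggregate approx fitted lm residuals vcov
NULL
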