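#' Well-tempered metadynamics parameters
#'
#' Defaults follow common practice for dihedral collective variables:
#' Gaussian height 1.2 kJ/mol, sigma 0.35 rad, bias factor 15, one
#' deposition every 500 integration steps.
#'
#' @param height initial Gaussian height w0 (kJ/mol).
#' @param sigma Gaussian width (CV units, e.g. rad).
#' @param bias_factor well-tempering factor gamma (> 1); deposited heights
#'   are tempered by `exp(-V/((gamma-1) kT))`.
#' @param stride deposition stride (steps).
#' @param grid_size bias grid resolution.
#' @return Object of class `"metad_params"`.
#' @export
metad_params <- function(height = 1.2, sigma = 0.35, bias_factor = 15,
                         stride = 500, grid_size = 400) {
  if (bias_factor <= 1) stop("bias factor must exceed 1", call. = FALSE)
  if (sigma <= 0 || height <= 0) stop("height and sigma must be positive",
                                      call. = FALSE)
  structure(list(height = height, sigma = sigma, bias_factor = bias_factor,
                 stride = as.integer(stride), grid_size = as.integer(grid_size)),
            class = "metad_params")
}

#' Well-tempered metadynamics on a 1D toy potential
#'
#' Overdamped Langevin dynamics under `U + V_bias`, with a Gaussian
#' deposited every `stride` steps at tempered height
#' `w0 * exp(-V(s,t) / ((gamma - 1) kT))`. Periodic CVs wrap on the
#' potential's domain; non-periodic domains use reflecting walls. The run
#' records, at every saved frame, the instantaneous bias `V(s_t, t)` and
#' the time-dependent offset `c(t)` needed for reweighting.
#'
#' @param potential a 1D [potential_spec].
#' @param metad a [metad_params()].
#' @param langevin a [langevin_params()].
#' @return Object of class `"wtmtd_run"`: `cv` (saved CV values),
#'   `v_frame`, `c_frame`, `grid`, `bias_grid` (final bias), deposition
#'   history (`dep_center`, `dep_height`, `dep_time`), `kT`, `gamma`, `dt`.
#' @export
wtmtd_simulate <- function(potential, metad = metad_params(),
                           langevin = langevin_params()) {
  stopifnot(inherits(potential, "potential_spec"), potential$dim == 1)
  curv <- .max_curvature(potential)
  if (langevin$dt * curv / langevin$friction > 0.5) {
    stop("unstable dt for this potential; reduce dt", call. = FALSE)
  }
  x0 <- langevin$x0
  if (is.null(x0)) x0 <- potential$minima[1]
  set.seed(langevin$seed)
  res <- .wtmtd_cpp(potential$kind_id, potential$params, as.numeric(x0),
                    langevin$n_steps, langevin$dt, langevin$kT,
                    langevin$friction, langevin$stride,
                    metad$height, metad$sigma, metad$bias_factor,
                    metad$stride,
                    potential$domain[1], potential$domain[2],
                    metad$grid_size, potential$periodic)
  structure(c(res, list(kT = langevin$kT, gamma = metad$bias_factor,
                        dt = langevin$dt * langevin$stride,
                        potential = potential)),
            class = "wtmtd_run")
}

#' @export
print.wtmtd_run <- function(x, ...) {
  cat(sprintf("WT-MTD run: %d frames, %d Gaussians deposited, gamma %g\n",
              length(x$cv), length(x$dep_center), x$gamma))
  invisible(x)
}

#' Free-energy profile by time-dependent metadynamics reweighting
#'
#' Reconstructs the unbiased distribution from a well-tempered
#' metadynamics run by weighting every frame with
#' `exp((V(s_t, t) - c(t)) / kT)`, where `c(t)` is the time-dependent bias
#' offset computed from the bias potential at deposition times, then
#' returns `F = -kT log p` shifted to a zero minimum. Grid regions never
#' sampled are `NA` and flagged.
#'
#' @param run a `"wtmtd_run"`.
#' @param grid evaluation grid for the profile (default: the run's bias
#'   grid).
#' @param equil_frac fraction of initial frames discarded (default 0.1,
#'   before the bias has grown anywhere).
#' @return Object of class `"free_energy_profile"`: data frame `cv`,
#'   `F_kJ_mol`, plus attributes `method = "WTMTD"`, `unsampled`.
#' @export
wtmtd_reweight <- function(run, grid = NULL, equil_frac = 0.1) {
  stopifnot(inherits(run, "wtmtd_run"))
  if (is.null(grid)) grid <- run$grid
  n <- length(run$cv)
  use <- seq(max(1, floor(n * equil_frac)), n)
  s <- run$cv[use]
  logw <- (run$v_frame[use] - run$c_frame[use]) / run$kT
  logw <- logw - max(logw)
  w <- exp(logw)
  edges <- c(grid - (grid[2] - grid[1]) / 2, grid[length(grid)] +
               (grid[2] - grid[1]) / 2)
  idx <- findInterval(s, edges, rightmost.closed = TRUE)
  ok <- idx >= 1 & idx <= length(grid)
  H <- vapply(seq_along(grid), function(b) sum(w[ok][idx[ok] == b]), numeric(1))
  if (isTRUE(run$potential$periodic)) {
    ## first and last grid node are the same physical point: each boundary
    ## bin only collects half a bin width of samples, so merge them
    tot <- H[1] + H[length(H)]
    H[1] <- H[length(H)] <- tot
  }
  Fv <- -run$kT * log(H / sum(H))
  unsampled <- !is.finite(Fv)
  Fv[unsampled] <- NA
  Fv <- Fv - min(Fv, na.rm = TRUE)
  structure(data.frame(cv = grid, F_kJ_mol = Fv),
            method = "WTMTD", unsampled = unsampled, kT = run$kT,
            class = c("free_energy_profile", "data.frame"))
}

#' Free-energy estimate from the final metadynamics bias
#'
#' The converged well-tempered bias satisfies
#' `F(s) = -(gamma/(gamma-1)) V_bias(s)` up to a constant; this internal
#' cross-check estimator complements [wtmtd_reweight()].
#'
#' @param run a `"wtmtd_run"`.
#' @return `"free_energy_profile"` data frame (`cv`, `F_kJ_mol`, min 0).
#' @export
wtmtd_bias_fes <- function(run) {
  Fv <- -(run$gamma / (run$gamma - 1)) * run$bias_grid
  Fv <- Fv - min(Fv)
  structure(data.frame(cv = run$grid, F_kJ_mol = Fv),
            method = "WTMTD_bias", kT = run$kT,
            class = c("free_energy_profile", "data.frame"))
}

#' @export
plot.free_energy_profile <- function(x, ...) {
  plot(x$cv, x$F_kJ_mol, type = "l", xlab = "collective variable",
       ylab = "free energy (kJ/mol)", ...)
  invisible(x)
}

#' Difference-of-distances proton-transfer collective variable
#'
#' `d(donor, proton) - d(proton, acceptor)`: negative when the proton
#' rests on the donor, positive after transfer to the acceptor.
#'
#' @param positions numeric matrix (atoms x 3) or a single frame of a
#'   trajectory.
#' @param donor,proton,acceptor row indices of the three sites (distinct).
#' @return CV value (Angstrom); vectorized over the first dimension if
#'   `positions` is a 3D array (frames x atoms x 3).
#' @export
difference_of_distances_cv <- function(positions, donor, proton, acceptor) {
  if (length(unique(c(donor, proton, acceptor))) != 3) {
    stop("donor, proton and acceptor must be three distinct sites", call. = FALSE)
  }
  one <- function(P) {
    d1 <- sqrt(sum((P[donor, ] - P[proton, ])^2))
    d2 <- sqrt(sum((P[proton, ] - P[acceptor, ])^2))
    if (d1 == 0 && d2 == 0) stop("coincident sites", call. = FALSE)
    d1 - d2
  }
  if (length(dim(positions)) == 3) {
    vapply(seq_len(dim(positions)[1]),
           function(f) one(matrix(positions[f, , ], ncol = 3)), numeric(1))
  } else {
    one(as.matrix(positions))
  }
}

#' Mean constraint force at a fixed collective-variable value
#'
#' Blue-moon sampling window: the CV is held at `cv_value` and the
#' constraint force is sampled; its post-equilibration mean estimates the
#' free-energy derivative `dF/ds` at the constraint. For a 1D potential
#' the exact mean force is `dU/ds`; the sampler adds zero-mean fluctuations
#' (orthogonal-bath noise) and an optional decaying equilibration
#' transient, which the discard fraction must remove. The standard error
#' is computed by block averaging (5 blocks) to respect correlation.
#'
#' @param potential a 1D [potential_spec].
#' @param cv_value constrained CV value.
#' @param n_samples constraint-force samples per window.
#' @param noise_sd SD of the force fluctuations (kJ/mol per CV unit).
#' @param discard_frac fraction of initial samples discarded (default 0.25).
#' @param transient initial transient amplitude added to the force,
#'   decaying over the discarded span (default 0 = stationary).
#' @param seed RNG seed.
#' @return Object of class `"ti_window"`: `cv`, `mean_force`, `sd_force`,
#'   `se_force`, `n_used`, `discard_frac`.
#' @export
blue_moon_mean_force <- function(potential, cv_value, n_samples = 2000,
                                 noise_sd = 0, discard_frac = 0.25,
                                 transient = 0, seed = 1) {
  stopifnot(inherits(potential, "potential_spec"), potential$dim == 1)
  if (discard_frac < 0 || discard_frac >= 1) {
    stop("discard_frac must be in [0, 1)", call. = FALSE)
  }
  set.seed(seed)
  f0 <- potential$grad(cv_value)
  f <- rep(f0, n_samples)
  if (noise_sd > 0) f <- f + rnorm(n_samples, sd = noise_sd)
  if (transient != 0) {
    tau <- max(1, floor(n_samples * discard_frac / 6))
    f <- f + transient * exp(-(seq_len(n_samples) - 1) / tau)
  }
  keep <- seq(floor(n_samples * discard_frac) + 1, n_samples)
  if (!length(keep)) stop("all samples discarded", call. = FALSE)
  fk <- f[keep]
  nb <- 5
  bs <- floor(length(fk) / nb)
  se <- if (bs >= 2) {
    bm <- vapply(seq_len(nb), function(b) mean(fk[((b - 1) * bs + 1):(b * bs)]),
                 numeric(1))
    sd(bm) / sqrt(nb)
  } else sd(fk) / sqrt(length(fk))
  structure(list(cv = cv_value, mean_force = mean(fk), sd_force = sd(fk),
                 se_force = se, n_used = length(fk),
                 discard_frac = discard_frac),
            class = "ti_window")
}

#' Thermodynamic integration of mean constraint forces
#'
#' Cumulative trapezoid integration of the window mean forces along the CV
#' gives the free-energy profile; the per-point uncertainty is propagated
#' from the window standard errors through the trapezoid weights. Windows
#' are sorted by CV (with a warning if unordered). The kinetic correction
#' term is omitted (negligible when the constraint geometry barely
#' fluctuates).
#'
#' @param windows list of `"ti_window"` objects (>= 2).
#' @return `"free_energy_profile"` data frame: `cv`, `F_kJ_mol` (min 0),
#'   `se_kJ_mol`, `mean_force`; attribute `method = "TI"`.
#' @export
ti_integrate <- function(windows) {
  if (length(windows) < 2) stop("need at least two windows", call. = FALSE)
  cv <- vapply(windows, `[[`, numeric(1), "cv")
  f <- vapply(windows, `[[`, numeric(1), "mean_force")
  se <- vapply(windows, function(w) {
    if (is.null(w$se_force) || is.na(w$se_force)) 0 else w$se_force
  }, numeric(1))
  if (is.unsorted(cv)) {
    warning("windows were not ordered in CV; sorting", call. = FALSE)
    o <- order(cv)
    cv <- cv[o]; f <- f[o]; se <- se[o]
  }
  F_ <- pracma::cumtrapz(cv, f)[, 1]
  ## error propagation: F_k = sum_j w_jk f_j with trapezoid weights
  n <- length(cv)
  varF <- numeric(n)
  h <- diff(cv)
  w <- numeric(n)
  for (k in 2:n) {
    w[] <- 0
    w[1] <- h[1] / 2
    if (k > 2) w[2:(k - 1)] <- (h[1:(k - 2)] + h[2:(k - 1)]) / 2
    w[k] <- h[k - 1] / 2
    varF[k] <- sum((w[1:k] * se[1:k])^2)
  }
  shift <- min(F_)
  structure(data.frame(cv = cv, F_kJ_mol = F_ - shift,
                       se_kJ_mol = sqrt(varF), mean_force = f),
            method = "TI",
            class = c("free_energy_profile", "data.frame"))
}
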