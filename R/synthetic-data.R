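#' Toy potential specifications
#'
#' Analytic low-dimensional potentials used as stand-ins for molecular free
#' energy landscapes: a harmonic well, a symmetric double well, a periodic
#' dihedral-like potential with minima near -70 and +70 degrees, a 2D
#' three-well landscape with unequal well depths, and tabulated 1D
#' potentials. Each spec carries the energy function, its gradient, the
#' domain, and an encoding used by the compiled samplers. Energies in
#' kJ/mol, coordinates dimensionless (or radians for the periodic kind).
#'
#' @param kappa harmonic force constant (kJ/mol per unit^2).
#' @param x0 harmonic minimum location.
#' @return An object of class `"potential_spec"` with elements `kind`, `dim`,
#'   `U(x)`, `grad(x)`, `domain`, `periodic`, `minima`.
#' @examples
#' pot <- double_well_1d(barrier = 10)
#' pot$U(c(-1, 0, 1)) # two minima at 0, barrier at x = 0
#' @name potential_spec
NULL

.potential <- function(kind, kind_id, dim, params, U, grad, domain,
                       periodic = FALSE, minima = NULL) {
  structure(list(kind = kind, kind_id = kind_id, dim = dim, params = params,
                 U = U, grad = grad, domain = domain, periodic = periodic,
                 minima = minima),
            class = "potential_spec")
}

#' @rdname potential_spec
#' @export
harmonic_1d <- function(kappa = 1, x0 = 0) {
  .potential("harmonic", 1L, 1L, c(kappa, x0),
             U = function(x) 0.5 * kappa * (x - x0)^2,
             grad = function(x) kappa * (x - x0),
             domain = x0 + c(-1, 1) * 6 / sqrt(kappa),
             minima = x0)
}

#' @rdname potential_spec
#' @param barrier barrier height (kJ/mol) between the wells.
#' @param xm location of the minima (at `+/- xm` for the double well).
#' @export
double_well_1d <- function(barrier = 10, xm = 1) {
  .potential("double_well_1d", 2L, 1L, c(barrier, xm),
             U = function(x) barrier * ((x / xm)^2 - 1)^2,
             grad = function(x) 4 * barrier * x * ((x / xm)^2 - 1) / xm^2,
             domain = c(-2.5, 2.5) * xm,
             minima = c(-xm, xm))
}

#' @rdname potential_spec
#' @param terms matrix with columns `A`, `n`, `phi`: cosine series
#'   `U = sum A * (1 + cos(n * theta - phi))`. The default places minima at
#'   about -70 and +70 degrees with inequivalent barriers through 0 and 180
#'   degrees, scaled so the lower (cis) barrier equals `barrier` kJ/mol.
#' @export
periodic_dihedral <- function(barrier = 8, terms = NULL) {
  if (is.null(terms)) {
    b <- barrier / 0.8661     # cis barrier of a*cos + b*cos2 with a = -1.368b
    a <- -4 * cos(70 * pi / 180) * b
    terms <- cbind(A = c(a, b), n = c(1, 2), phi = c(0, 0))
  }
  U <- function(x) {
    rowSums(sapply(seq_len(nrow(terms)), function(k) {
      terms[k, "A"] * (1 + cos(terms[k, "n"] * x - terms[k, "phi"]))
    }) |> matrix(nrow = length(x)))
  }
  grad <- function(x) {
    rowSums(sapply(seq_len(nrow(terms)), function(k) {
      -terms[k, "A"] * terms[k, "n"] * sin(terms[k, "n"] * x - terms[k, "phi"])
    }) |> matrix(nrow = length(x)))
  }
  .potential("periodic_dihedral", 3L, 1L, as.numeric(t(terms)),
             U = U, grad = grad, domain = c(-pi, pi), periodic = TRUE,
             minima = c(-70, 70) * pi / 180)
}

#' @rdname potential_spec
#' @param wells 3 x 4 matrix (x, y, depth kJ/mol, sigma) of Gaussian wells;
#'   the default has unequal depths so the three basins have distinct
#'   Boltzmann weights.
#' @param kconf quadratic confinement constant (kJ/mol per unit^2).
#' @export
three_well_2d <- function(wells = NULL, kconf = 2) {
  if (is.null(wells)) {
    wells <- cbind(x = c(-1, 1, 0), y = c(0, 0, 1.6),
                   depth = c(26, 24.5, 22.5), sigma = c(0.45, 0.45, 0.45))
  }
  U <- function(x) {
    x <- matrix(x, ncol = 2)
    u <- 0.5 * kconf * (x[, 1]^2 + x[, 2]^2)
    for (w in seq_len(nrow(wells))) {
      u <- u - wells[w, "depth"] *
        exp(-((x[, 1] - wells[w, "x"])^2 + (x[, 2] - wells[w, "y"])^2) /
              (2 * wells[w, "sigma"]^2))
    }
    u
  }
  grad <- function(x) {
    x <- matrix(x, ncol = 2)
    g <- kconf * x
    for (w in seq_len(nrow(wells))) {
      s2 <- wells[w, "sigma"]^2
      dx <- x[, 1] - wells[w, "x"]; dy <- x[, 2] - wells[w, "y"]
      e <- wells[w, "depth"] * exp(-(dx^2 + dy^2) / (2 * s2)) / s2
      g[, 1] <- g[, 1] + e * dx
      g[, 2] <- g[, 2] + e * dy
    }
    g
  }
  .potential("three_well_2d", 4L, 2L,
             c(as.numeric(t(wells[, c("x", "y", "depth", "sigma")])), kconf),
             U = U, grad = grad,
             domain = c(-3, 3), minima = wells[, c("x", "y"), drop = FALSE])
}

#' @rdname potential_spec
#' @param x,Ux uniform grid and tabulated energies for a custom 1D
#'   potential (linearly interpolated forces).
#' @export
tabulated_1d <- function(x, Ux) {
  if (length(x) != length(Ux) || length(x) < 4) {
    stop("x and Ux must have equal length >= 4", call. = FALSE)
  }
  dx <- diff(x)
  if (max(abs(dx - dx[1])) > 1e-8 * dx[1]) {
    stop("tabulated grid must be uniform", call. = FALSE)
  }
  Ufun <- stats::approxfun(x, Ux, rule = 2)
  gfun <- stats::approxfun(head(x, -1) + dx[1] / 2, diff(Ux) / dx[1], rule = 2)
  .potential("tabulated", 5L, 1L, c(x[1], dx[1], length(x), Ux),
             U = Ufun, grad = gfun, domain = range(x),
             minima = x[which.min(Ux)])
}

#' @export
print.potential_spec <- function(x, ...) {
  cat(sprintf("potential_spec: %s (%dD)%s\n", x$kind, x$dim,
              if (x$periodic) ", periodic" else ""))
  invisible(x)
}

#' Overdamped Langevin sampling parameters
#'
#' @param kT thermal energy (kJ/mol); the default 2.579 is RT at 310.15 K.
#' @param friction friction coefficient (1/time unit).
#' @param dt integration time step.
#' @param n_steps number of Euler-Maruyama steps.
#' @param seed RNG seed (every sampler is a pure function of parameters and
#'   seed).
#' @param stride save every `stride`-th step.
#' @param x0 start position (default: first minimum of the potential).
#' @return Object of class `"langevin_params"`.
#' @export
langevin_params <- function(kT = 2.579, friction = 1, dt = 0.005,
                            n_steps = 1e5, seed = 1, stride = 1L, x0 = NULL) {
  stopifnot(kT > 0, friction > 0, dt > 0, n_steps >= 1, stride >= 1)
  structure(list(kT = kT, friction = friction, dt = dt,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 stride = as.integer(stride), x0 = x0),
            class = "langevin_params")
}

.max_curvature <- function(potential) {
  d <- potential$domain
  if (potential$dim == 1) {
    xs <- seq(d[1], d[2], length.out = 400)
    h <- (d[2] - d[1]) / 2000
    max(abs((potential$U(xs + h) - 2 * potential$U(xs) + potential$U(xs - h)) / h^2))
  } else {
    xs <- as.matrix(expand.grid(seq(d[1], d[2], length.out = 40),
                                seq(d[1], d[2], length.out = 40)))
    h <- (d[2] - d[1]) / 400
    cxx <- abs((potential$U(cbind(xs[, 1] + h, xs[, 2])) - 2 * potential$U(xs) +
                  potential$U(cbind(xs[, 1] - h, xs[, 2]))) / h^2)
    cyy <- abs((potential$U(cbind(xs[, 1], xs[, 2] + h)) - 2 * potential$U(xs) +
                  potential$U(cbind(xs[, 1], xs[, 2] - h))) / h^2)
    max(cxx, cyy)
  }
}

#' Sample a toy potential with overdamped Langevin dynamics
#'
#' Euler-Maruyama integration of position Langevin dynamics
#' `dx = -grad U / friction * dt + sqrt(2 kT dt / friction) * eta`. The
#' long-run histogram converges to the Boltzmann distribution
#' `exp(-U/kT)`. Periodic CVs are wrapped to `[-pi, pi)`.
#'
#' @param potential a [potential_spec].
#' @param params a [langevin_params()].
#' @return Matrix (saved frames x dim) of class `"cv_trajectory"` with
#'   attributes `dt` (time between saved frames) and `potential`.
#' @export
langevin_sample <- function(potential, params = langevin_params()) {
  stopifnot(inherits(potential, "potential_spec"),
            inherits(params, "langevin_params"))
  curv <- .max_curvature(potential)
  if (params$dt * curv / params$friction > 0.5) {
    stop(sprintf(
      "unstable dt: dt * max curvature / friction = %.3g > 0.5; reduce dt",
      params$dt * curv / params$friction), call. = FALSE)
  }
  x0 <- params$x0
  if (is.null(x0)) {
    x0 <- if (is.matrix(potential$minima)) potential$minima[1, ]
          else potential$minima[1]
  }
  set.seed(params$seed)
  out <- .langevin_cpp(potential$kind_id, potential$params, potential$dim,
                       as.numeric(x0), params$n_steps, params$dt, params$kT,
                       params$friction, params$stride)
  structure(out, dt = params$dt * params$stride, potential = potential,
            kT = params$kT, class = c("cv_trajectory", class(out)))
}

#' Boltzmann free-energy profile by quadrature
#'
#' Independent numerical reference: bins the Boltzmann density
#' `exp(-U/kT)` of a 1D potential on a grid and returns the min-shifted
#' free energy, for comparison with sampled or reweighted estimates.
#'
#' @param potential a 1D [potential_spec].
#' @param kT thermal energy (kJ/mol).
#' @param grid evaluation grid (default 512 points over the domain).
#' @return data frame with `x`, `F` (kJ/mol, min 0), `p` (normalized density).
#' @export
boltzmann_profile <- function(potential, kT = 2.579, grid = NULL) {
  stopifnot(potential$dim == 1)
  if (is.null(grid)) {
    grid <- seq(potential$domain[1], potential$domain[2], length.out = 512)
  }
  u <- potential$U(grid)
  p <- exp(-(u - min(u)) / kT)
  p <- p / pracma::trapz(grid, p)
  data.frame(x = grid, F = u - min(u), p = p)
}

#' Boltzmann basin weights of a multi-well potential
#'
#' Quadrature of `exp(-U/kT)` over a dense grid, assigning every grid node
#' to its nearest potential minimum; returns the normalized basin weights.
#' Used as the independent truth for macrostate stationary probabilities.
#'
#' @param potential a [potential_spec] with a `minima` matrix/vector.
#' @param kT thermal energy (kJ/mol).
#' @param n_grid nodes per axis.
#' @return Named numeric vector of basin probabilities (sums to 1).
#' @export
basin_weights <- function(potential, kT = 2.579, n_grid = 301) {
  d <- potential$domain
  if (potential$dim == 1) {
    xs <- seq(d[1], d[2], length.out = n_grid)
    w <- exp(-(potential$U(xs) - min(potential$U(xs))) / kT)
    mins <- potential$minima
    assign <- apply(abs(outer(xs, mins, "-")), 1, which.min)
  } else {
    g <- seq(d[1], d[2], length.out = n_grid)
    xs <- as.matrix(expand.grid(x = g, y = g))
    u <- potential$U(xs)
    w <- exp(-(u - min(u)) / kT)
    mins <- potential$minima
    d2 <- sapply(seq_len(nrow(mins)), function(k) {
      (xs[, 1] - mins[k, 1])^2 + (xs[, 2] - mins[k, 2])^2
    })
    assign <- max.col(-d2)
  }
  tot <- tapply(w, assign, sum)
  out <- as.numeric(tot / sum(tot))
  names(out) <- paste0("basin", seq_along(out))
  out
}

#' Lift a low-dimensional CV trajectory into a noisy feature space
#'
#' Emulates high-dimensional distance featurization of molecular
#' trajectories: the CVs are mapped through a fixed random affine map into
#' `dim` coordinates and isotropic Gaussian noise is added. The slow
#' dynamics live in a known linear subspace (the returned mixing matrix),
#' which downstream dimension-reduction must recover.
#'
#' @param cv_traj matrix (frames x d) of CV values.
#' @param dim target dimensionality (>= 2, >= d).
#' @param mixing_seed seed for the random mixing matrix.
#' @param noise_sd isotropic noise standard deviation.
#' @param noise_seed seed for the additive noise.
#' @return Matrix (frames x dim) with attributes `mixing` (dim x d map) and
#'   `offset`.
#' @export
lift_to_features <- function(cv_traj, dim = 50, mixing_seed = 11,
                             noise_sd = 0.1, noise_seed = 12) {
  cv_traj <- as.matrix(cv_traj)
  d <- ncol(cv_traj)
  if (dim < max(2, d)) stop("dim must be >= max(2, ncol(cv_traj))", call. = FALSE)
  set.seed(mixing_seed)
  W <- matrix(rnorm(dim * d), dim, d)
  W <- qr.Q(qr(W))[, seq_len(d), drop = FALSE]   # orthonormal columns
  offset <- rnorm(dim)
  X <- cv_traj %*% t(W)
  X <- sweep(X, 2, offset, "+")
  if (noise_sd > 0) {
    set.seed(noise_seed)
    X <- X + matrix(rnorm(length(X), sd = noise_sd), nrow(X), ncol(X))
  }
  attr(X, "mixing") <- W
  attr(X, "offset") <- offset
  for (a in c("dt", "potential", "kT")) {
    if (!is.null(attr(cv_traj, a))) attr(X, a) <- attr(cv_traj, a)
  }
  X
}

#' Simulated SSME dataset with known truth
#'
#' Simulates replicate SSME recordings from the kinetic cycle under a
#' protocol and adds additive Gaussian current noise; the generating
#' parameters are returned alongside for recovery tests. Deterministic
#' under `seed`.
#'
#' @param model a `"state_cycle_model"`.
#' @param phases list of [protocol_phase()]s.
#' @param noise_sd additive current noise SD (nA).
#' @param n_replicates replicate traces to draw.
#' @param seed RNG seed.
#' @param readout an [ssme_readout()].
#' @param dt sampling interval (s).
#' @return List with `traces` (list of `"current_trace"`), `clean` (the
#'   noiseless trace) and `truth` (generator record).
#' @export
gen_ssme_dataset <- function(model, phases, noise_sd = 0.02,
                             n_replicates = 3, seed = 1,
                             readout = ssme_readout(), dt = 1e-3) {
  clean <- simulate_ssme_protocol(model, phases, readout, dt)
  set.seed(seed)
  traces <- lapply(seq_len(n_replicates), function(i) {
    tr <- clean
    tr$current_nA <- tr$current_nA + rnorm(nrow(tr), sd = noise_sd)
    tr
  })
  list(traces = traces, clean = clean,
       truth = list(rate_params = model$rate_params, noise_sd = noise_sd,
                    seed = seed, readout = unclass(readout)))
}

#' Synthetic k_obs-versus-concentration dataset
#'
#' Draws observed rate constants from the induced-fit hyperbola
#' [kobs_model()] with multiplicative Gaussian noise:
#' `k_obs * (1 + noise_frac * eta)`.
#'
#' @param K_D,k_plus,k_minus generating truth (mM, 1/s, 1/s).
#' @param concs substrate concentrations (mM).
#' @param noise_frac relative noise level (e.g. 0.05).
#' @param n_sensors independent measurements per concentration (default 3,
#'   matching the usual per-condition sensor count).
#' @param seed RNG seed.
#' @return data frame `gal_mM`, `kobs` (one row per concentration and
#'   sensor); truth in attributes.
#' @export
gen_kobs_dataset <- function(K_D = 15.1, k_plus = 70.6, k_minus = 23.8,
                             concs = c(2, 5, 10, 20, 40, 80, 160),
                             noise_frac = 0.05, n_sensors = 3, seed = 1) {
  set.seed(seed)
  gal <- rep(concs, each = n_sensors)
  k <- kobs_model(gal, K_D, k_plus, k_minus)
  k <- k * (1 + noise_frac * rnorm(length(k)))
  structure(data.frame(gal_mM = gal, kobs = k),
            truth = c(K_D = K_D, k_plus = k_plus, k_minus = k_minus))
}

#' Synthetic peak-current-versus-pH dataset
#'
#' Draws normalized peak currents from a single-site titration curve with
#' multiplicative Gaussian noise.
#'
#' @param pK,I_max generating truth.
#' @param mode `"acidic"` or `"alkaline"` deactivation.
#' @param pH sampled pH values.
#' @param noise_frac relative noise (e.g. 0.03).
#' @param seed RNG seed.
#' @return data frame `pH`, `current`; truth in attributes.
#' @export
gen_pka_dataset <- function(pK = 6, I_max = 1, mode = c("acidic", "alkaline"),
                            pH = seq(4.5, 8, by = 0.5), noise_frac = 0.03,
                            seed = 1) {
  mode <- match.arg(mode)
  s <- if (mode == "acidic") 1 else -1
  set.seed(seed)
  y <- I_max / (1 + 10^(s * (pK - pH)))
  y <- y * (1 + noise_frac * rnorm(length(y)))
  structure(data.frame(pH = pH, current = y),
            truth = c(pK = pK, I_max = I_max), mode = mode)
}

#' Toy solvated configurations in a periodic box
#'
#' Places `n_waters` water-like particles in an orthorhombic box by seeded
#' uniform sampling with minimum-distance rejection, optionally together
#' with fixed solute charge sites, and generates frames by jittering the
#' base positions. A scripted water column (cylinder along z) can be
#' switched on for chosen frames to mimic open-gate hydration.
#'
#' @param n_waters number of water particles.
#' @param box numeric(3) box lengths (Angstrom).
#' @param solute optional data frame with `x`, `y`, `z`, `charge` (and
#'   optionally `name`, `resid`, `resname`) of solute sites.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param jitter_sd per-frame Gaussian displacement SD (Angstrom).
#' @param min_dist minimum inter-particle distance (Angstrom).
#' @param column optional list(`center` = c(x, y), `radius`, `z_range`,
#'   `n`, `frames`): adds `n` extra column waters in the cylinder for the
#'   listed frames only.
#' @return An [md_trajectory()].
#' @export
gen_toy_solvated_frames <- function(n_waters, box = c(30, 30, 30),
                                    solute = NULL, n_frames = 10, seed = 1,
                                    jitter_sd = 0.3, min_dist = 2.6,
                                    column = NULL) {
  vol <- prod(box)
  if (n_waters / vol > 0.04) {
    stop("infeasible packing: requested density exceeds liquid water",
         call. = FALSE)
  }
  set.seed(seed)
  pos <- matrix(NA_real_, n_waters, 3)
  fixed <- if (!is.null(solute)) as.matrix(solute[, c("x", "y", "z")]) else
    matrix(numeric(0), 0, 3)
  placed <- fixed
  tries <- 0
  i <- 1
  while (i <= n_waters) {
    cand <- runif(3) * box
    ok <- TRUE
    if (nrow(placed)) {
      d <- sweep(placed, 2, cand)
      d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")  # min image
      ok <- min(sqrt(rowSums(d^2))) >= min_dist
    }
    if (ok) {
      pos[i, ] <- cand
      placed <- rbind(placed, cand)
      i <- i + 1
      tries <- 0
    } else {
      tries <- tries + 1
      if (tries > 5000) stop("infeasible packing: rejection sampling stalled",
                             call. = FALSE)
    }
  }
  n_col <- if (is.null(column)) 0L else column$n
  n_solute <- nrow(fixed)
  n_atoms <- n_solute + n_waters + n_col
  coords <- array(NA_real_, c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames)) {
    w <- pos + matrix(rnorm(n_waters * 3, sd = jitter_sd), n_waters, 3)
    w <- sweep(w, 2, box, function(a, b) a %% b)
    col_xyz <- matrix(NA_real_, n_col, 3)
    if (n_col > 0 && f %in% column$frames) {
      ang <- runif(n_col) * 2 * pi
      rad <- sqrt(runif(n_col)) * column$radius
      col_xyz <- cbind(column$center[1] + rad * cos(ang),
                       column$center[2] + rad * sin(ang),
                       runif(n_col, column$z_range[1], column$z_range[2]))
    } else if (n_col > 0) {
      ## column absent this frame: park far outside the region of interest
      col_xyz <- cbind(runif(n_col) * box[1], runif(n_col) * box[2],
                       rep(box[3] * 0.999, n_col))
    }
    coords[f, , ] <- rbind(fixed, w, col_xyz)
  }
  ann <- data.frame(
    resid = seq_len(n_atoms),
    resname = c(rep("LIG", n_solute), rep("SOL", n_waters + n_col)),
    name = c(if (n_solute > 0) {
      if (!is.null(solute$name)) as.character(solute$name)
      else paste0("Q", seq_len(n_solute))
    }, rep("OW", n_waters + n_col)),
    is_water = c(rep(FALSE, n_solute), rep(TRUE, n_waters + n_col)),
    is_sidechain = FALSE,
    charge = c(if (n_solute > 0) solute$charge, rep(0, n_waters + n_col)),
    stringsAsFactors = FALSE
  )
  md_trajectory(coords, box = box, atoms = ann)
}
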