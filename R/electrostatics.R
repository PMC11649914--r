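## Coulomb prefactor e^2/(4 pi eps0 kT) in Angstrom at T Kelvin: the
## vacuum Bjerrum length. Potentials are reported in kT/e.
.bjerrum_A <- function(temperature = 310.15) 1.66947e5 / temperature

#' Point-charge configuration in a periodic box
#'
#' @param positions numeric matrix (N x 3), Angstrom.
#' @param charges numeric(N), elementary charges.
#' @param box numeric(3) orthorhombic box lengths (Angstrom).
#' @return Object of class `"charge_configuration"` (records the net
#'   charge; non-neutral systems are handled with a uniform neutralizing
#'   background by the grid operator).
#' @export
charge_configuration <- function(positions, charges, box) {
  positions <- as.matrix(positions)
  if (nrow(positions) != length(charges)) {
    stop("positions and charges disagree in length", call. = FALSE)
  }
  if (length(positions) && !all(is.finite(positions))) {
    stop("positions must be finite", call. = FALSE)
  }
  stopifnot(length(box) == 3, all(box > 0))
  structure(list(positions = positions, charges = charges, box = box,
                 net_charge = sum(charges)),
            class = "charge_configuration")
}

#' Gaussian-smeared Ewald electrostatic potential on a grid
#'
#' Evaluates the reciprocal-space (smooth particle mesh Ewald) potential of
#' Gaussian-smeared point charges on a regular grid: each charge is
#' replaced by a Gaussian of inverse width `beta`, and the periodic Coulomb
#' potential of the smeared density is computed exactly via the k-space sum
#' `phi(r) = (4 pi f_c / V) sum_k exp(-k^2/(4 beta^2))/k^2 S(k) e^{ikr}`
#' with the structure factor evaluated at the exact charge positions. The
#' k = 0 term is dropped, which both applies a uniform neutralizing
#' background for non-neutral systems and fixes the zero-mean convention.
#' Values are in kT/e at `temperature`.
#'
#' @param config a [charge_configuration()].
#' @param dims grid points per axis, numeric(3) or scalar (>= 8).
#' @param beta inverse Gaussian smearing width in 1/nm (default 20).
#' @param temperature K (for the kT/e scale).
#' @return Object of class `"potential_grid"`: `values` (3D array),
#'   `spacing` (numeric(3)), `origin`, `beta`, `box`, `units`.
#' @export
smeared_potential_grid <- function(config, dims = 32, beta = 20,
                                   temperature = 310.15) {
  stopifnot(inherits(config, "charge_configuration"))
  if (length(dims) == 1) dims <- rep(dims, 3)
  if (any(dims < 8)) stop("grid must have at least 8 points per axis", call. = FALSE)
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  beta_A <- beta / 10                     # nm^-1 -> A^-1
  box <- config$box
  k_nyq <- pi * min(dims / box)
  if (nrow(config$positions) && exp(-k_nyq^2 / (4 * beta_A^2)) > 0.01) {
    warning("grid too coarse to resolve the smearing width: increase dims ",
            "(need spacing well below 1/beta)", call. = FALSE)
  }
  if (abs(config$net_charge) > 1e-9 && nrow(config$positions)) {
    warning("non-neutral configuration: uniform neutralizing background applied",
            call. = FALSE)
  }
  ## FFT frequencies per axis (wrapped), k = 2 pi n / L
  kfreq <- lapply(1:3, function(a) {
    n <- dims[a]
    idx <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1))
    2 * pi * idx / box[a]
  })
  S <- array(0 + 0i, dims)
  if (nrow(config$positions)) {
    for (j in seq_len(nrow(config$positions))) {
      ex <- exp(-1i * kfreq[[1]] * config$positions[j, 1])
      ey <- exp(-1i * kfreq[[2]] * config$positions[j, 2])
      ez <- exp(-1i * kfreq[[3]] * config$positions[j, 3])
      S <- S + config$charges[j] * outer(outer(ex, ey), ez)
    }
  }
  K2 <- outer(outer(kfreq[[1]]^2, kfreq[[2]]^2, "+"), kfreq[[3]]^2, "+")
  G <- exp(-K2 / (4 * beta_A^2)) / K2
  G[1, 1, 1] <- 0
  f_c <- .bjerrum_A(temperature)
  vals <- Re(fft(S * G, inverse = TRUE)) * 4 * pi * f_c / prod(box)
  structure(list(values = vals, spacing = box / dims, origin = c(0, 0, 0),
                 beta = beta, box = box, units = "kT/e",
                 temperature = temperature),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf("potential_grid: %s nodes, spacing %s A, beta %g 1/nm, %s\n",
              paste(dim(x$values), collapse = " x "),
              paste(signif(x$spacing, 3), collapse = "/"), x$beta, x$units))
  invisible(x)
}

#' Convert a potential from kT/e to millivolt
#'
#' @param x numeric values in kT/e.
#' @param temperature K.
#' @return Values in mV (kT/e = 26.73 mV at 310.15 K).
#' @export
kTe_to_mV <- function(x, temperature = 310.15) {
  x * 1000 * 1.380649e-23 * temperature / 1.602177e-19
}

#' Average potential in a sphere around a site
#'
#' Mean of grid-node values within `radius` of a center (minimum-image
#' under the grid's periodic box), e.g. a 3 Angstrom sphere around the
#' center of geometry of a carboxyl group. With a list of per-frame grids
#' and a matrix of per-frame centers, returns the time series.
#'
#' @param grid a `"potential_grid"` or list of them.
#' @param center numeric(3), or matrix (frames x 3) matching a grid list.
#' @param radius sphere radius (Angstrom), at least one grid spacing.
#' @return Scalar or numeric vector (kT/e).
#' @export
region_average_potential <- function(grid, center, radius) {
  if (inherits(grid, "potential_grid")) {
    grid <- list(grid)
    center <- matrix(center, 1)
  } else {
    center <- as.matrix(center)
  }
  if (radius < max(grid[[1]]$spacing)) {
    stop("radius must be at least one grid spacing", call. = FALSE)
  }
  vapply(seq_along(grid), function(f) {
    g <- grid[[f]]
    d <- dim(g$values)
    if (any(center[f, ] < 0) || any(center[f, ] > g$box)) {
      stop("sphere center outside the grid box", call. = FALSE)
    }
    nodes <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * g$spacing[a])
    dist1 <- function(a) {
      dd <- nodes[[a]] - center[f, a]
      dd - round(dd / g$box[a]) * g$box[a]
    }
    D2 <- outer(outer(dist1(1)^2, dist1(2)^2, "+"), dist1(3)^2, "+")
    sel <- D2 <= radius^2
    mean(g$values[sel])
  }, numeric(1))
}

#' Hydration-gated average of a potential time series
#'
#' Averages a per-frame regional potential over the frames whose regional
#' water occupancy exceeds a threshold, discarding dehydrated frames in
#' which the short-range environment is not comparable.
#'
#' @param potential_series per-frame potential values.
#' @param occupancy_series aligned per-frame water occupancy of the same
#'   region.
#' @param threshold occupancy threshold (frames with occupancy strictly
#'   greater are kept; 0 keeps every frame with any occupancy >= 0).
#' @return Mean potential over hydrated frames; the number of frames used
#'   is in attribute `n_hydrated`.
#' @export
hydration_gated_average <- function(potential_series, occupancy_series,
                                    threshold = 0.5) {
  if (length(potential_series) != length(occupancy_series)) {
    stop("series are not aligned", call. = FALSE)
  }
  keep <- if (threshold <= 0) rep(TRUE, length(potential_series))
          else occupancy_series > threshold
  if (!any(keep)) stop("zero hydrated frames above the threshold", call. = FALSE)
  structure(mean(potential_series[keep]), n_hydrated = sum(keep))
}

#' @importFrom stats fft
NULL
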