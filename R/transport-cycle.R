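#' @useDynLib symportkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef median nls optim qnorm quantile rnorm runif sd setNames var
#' @importFrom utils head modifyList read.csv tail write.csv
NULL

## Gas constant, J mol^-1 K^-1
.R_GAS <- 8.314

#' Solution condition on the two membrane faces
#'
#' Bundles the proton and substrate (galactonate) activities facing the
#' intracellular ("in") and extracellular ("out") sides of the transporter,
#' the only thermodynamic driving forces in a solid-supported membrane
#' experiment (no applied voltage).
#'
#' @param pH_in,pH_out pH on the inner / outer face, in [0, 14].
#' @param gal_in,gal_out galactonate concentration (mM), non-negative.
#' @param temperature absolute temperature (K).
#' @return An object of class `"solution_condition"`.
#' @examples
#' cond <- solution_condition(pH_in = 7.3, pH_out = 7.6,
#'                            gal_in = 0.5, gal_out = 2)
#' delta_g(cond) # J/mol for 2 H+ : 1 galactonate moved in
#' @export
solution_condition <- function(pH_in, pH_out, gal_in, gal_out,
                               temperature = 310.15) {
  for (p in c(pH_in, pH_out)) {
    if (!is.finite(p) || p < 0 || p > 14) {
      stop("pH values must lie in [0, 14]", call. = FALSE)
    }
  }
  if (gal_in < 0 || gal_out < 0) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  structure(
    list(pH_in = pH_in, pH_out = pH_out,
         gal_in = gal_in, gal_out = gal_out,
         temperature = temperature),
    class = "solution_condition"
  )
}

#' @export
print.solution_condition <- function(x, ...) {
  cat(sprintf("solution condition: pH %.2f (in) / %.2f (out), galactonate %g / %g mM, T = %.2f K\n",
              x$pH_in, x$pH_out, x$gal_in, x$gal_out, x$temperature))
  invisible(x)
}

#' Free energy of one coupled transport event
#'
#' Computes `dG = n * dmu_H + m * dmu_gal` for moving `n` protons and `m`
#' galactonate anions from the outer to the inner face, with
#' `dmu_H = RT ln([H]_in / [H]_out)` and analogously for galactonate.
#' Negative values drive net influx.
#'
#' @param cond a [solution_condition()].
#' @param n,m transported protons and galactonate per cycle (default 2 and 1).
#' @return Free energy in J/mol (can be `-Inf`/`Inf` at zero concentrations).
#' @export
delta_g <- function(cond, n = 2, m = 1) {
  RT <- .R_GAS * cond$temperature
  dmu_h <- RT * log(10^(-cond$pH_in) / 10^(-cond$pH_out))
  dmu_g <- RT * log(cond$gal_in / cond$gal_out)
  n * dmu_h + m * dmu_g
}

#' Default base rate constants for the eight-state cycle
#'
#' Rates the experiments constrain directly are taken from the induced-fit
#' analysis of wild-type pre-steady-state currents (outer substrate step:
#' K_D = 15.1 mM; conformational step k+ = 70.6, k- = 23.8 s^-1). The
#' remaining rates are free parameters chosen so that (i) empty-carrier
#' return is the slowest forward step at reference conditions and (ii) the
#' peak-current pH dependence is bell-shaped with a maximum near pH 7.5.
#' Units: first-order rates s^-1; `kon_g_*` per M per s; `kon_h_out` per M^2
#' per s (both protons bind in one step); `kon_h1`/`kon_h2` per M per s.
#'
#' @return Named list of rate constants.
#' @export
dgot_default_rates <- function() {
  list(
    kon_h_out = 1e17,  koff_h_out = 2.512,      # outer pair, pK ~8.3 per site
    kon_g_out = 1e5,   koff_g_out = 1510,       # K_D = 15.1 mM
    k_occl_f  = 70.6,  k_occl_b   = 23.8,       # induced-fit step
    k_trans_f = 300,   k_trans_b  = 100,        # translocation
    koff_h1   = 1000,  kon_h1     = 1e10,       # inner release, pKa 7.0
    koff_g_in = 1510,  kon_g_in   = 1e5,        # inner substrate, K_D 15.1 mM
    koff_h2   = 1000,  kon_h2     = 1e10,       # second inner release
    k_ret_f   = 12,    k_ret_b    = 30          # empty-carrier return
  )
}

.CYCLE_RATE_NAMES <- names(dgot_default_rates())

#' Build the eight-state alternating-access transport cycle
#'
#' Constructs the 2 H+ : 1 galactonate kinetic cycle: (1) outward-facing apo,
#' (2) doubly protonated, (3) galactonate bound, (4) occluded, (5)
#' inward-facing loaded, (6) first proton released, (7) galactonate released,
#' (8) inward-facing apo; 8 -> 1 is the empty-carrier reorientation. Ligand
#' binding steps face "out", release steps face "in"; one elementary charge
#' moves inward per completed cycle (2 H+ plus one anion).
#'
#' @param rate_params named list of base rate constants; see
#'   [dgot_default_rates()] for names, units and defaults. A partial list
#'   overrides the defaults.
#' @param charges optional numeric(8) of per-transition forward charge
#'   displacements (elementary charges, must sum to +1). The default places
#'   a small displacement on the two conformational steps (0.1 each) and
#'   the remainder on the inner-facing release steps (0.3, 0.2, 0.3),
#'   i.e. most of the +1 cargo charge crosses the membrane field while the
#'   loaded carrier opens inward and discharges; ion-binding steps from the
#'   aqueous phases are treated as electroneutral. This split reproduces
#'   the two experimental signatures that constrain it: positive transport
#'   currents on an outward-gal jump and a bell-shaped peak-current pH
#'   dependence.
#' @param n_protons protons transported per cycle (default 2). With
#'   `n_protons = 1` the cycle binds and releases a single proton (the
#'   second inner release step becomes a plain conformational step); the
#'   substrate is then treated as electroneutral so one elementary charge
#'   still crosses per loop, mimicking 1 H+ : 1 neutral-substrate coupling.
#' @return An object of class `"state_cycle_model"` with elements `states`
#'   and `transitions` (data frame: from, to, k_f, k_b, ligand, count,
#'   charge).
#' @examples
#' mod <- build_dgot_cycle()
#' sum(mod$transitions$charge) # +1 per completed cycle
#' @export
build_dgot_cycle <- function(rate_params = list(), charges = NULL,
                             n_protons = 2) {
  if (!n_protons %in% 1:2) stop("n_protons must be 1 or 2", call. = FALSE)
  rp <- modifyList(dgot_default_rates(), rate_params)
  missing <- setdiff(.CYCLE_RATE_NAMES, names(rp))
  if (length(missing)) {
    stop("missing rate constants: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- names(rp)[!vapply(rp, function(v) is.finite(v) && v > 0, logical(1))]
  if (length(bad)) {
    stop("rate constants must be positive and finite: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(charges)) charges <- c(0, 0, 0.1, 0.1, 0.3, 0.2, 0.3, 0)
  if (length(charges) != 8 || abs(sum(charges) - 1) > 1e-12) {
    stop("charge displacements must be length 8 and sum to +1", call. = FALSE)
  }
  ## with a single proton, step 7 degrades to a plain conformational step;
  ## proton on/off rates would leave it frozen, so it reuses the
  ## translocation defaults
  tr <- data.frame(
    from   = 1:8,
    to     = c(2:8, 1),
    k_f    = c(rp$kon_h_out, rp$kon_g_out, rp$k_occl_f, rp$k_trans_f,
               rp$koff_h1, rp$koff_g_in,
               if (n_protons == 2) rp$koff_h2 else rp$k_trans_f, rp$k_ret_f),
    k_b    = c(rp$koff_h_out, rp$koff_g_out, rp$k_occl_b, rp$k_trans_b,
               rp$kon_h1, rp$kon_g_in,
               if (n_protons == 2) rp$kon_h2 else rp$k_trans_b, rp$k_ret_b),
    ligand = c("H_out", "gal_out", "none", "none", "H_in", "gal_in",
               if (n_protons == 2) "H_in" else "none", "none"),
    count  = c(n_protons, 1, 0, 0, 1, 1, n_protons - 1, 0),
    charge = charges,
    stringsAsFactors = FALSE
  )
  model <- structure(
    list(states = 1:8, transitions = tr, rate_params = rp,
         haldane_step = 8L, n_protons = n_protons),
    class = "state_cycle_model"
  )
  validate_cycle(model)
  model
}

#' Validate cycle topology and stoichiometry
#'
#' Checks that the transitions form a single closed 1 -> 2 -> ... -> 8 -> 1
#' loop, that two protons bind outside and two are released inside per loop,
#' that one galactonate binds outside and is released inside, and that the
#' charge displacements sum to +1.
#'
#' @param model a `"state_cycle_model"`.
#' @return The model, invisibly; errors on violation.
#' @export
validate_cycle <- function(model) {
  tr <- model$transitions
  if (nrow(tr) != 8 || !all(tr$from == 1:8) || !all(tr$to == c(2:8, 1))) {
    stop("cycle topology must be the single closed loop 1->2->...->8->1",
         call. = FALSE)
  }
  n_p <- if (is.null(model$n_protons)) 2 else model$n_protons
  n_h_out  <- sum(tr$count[tr$ligand == "H_out"])
  n_h_in   <- sum(tr$count[tr$ligand == "H_in"])
  n_g_out  <- sum(tr$count[tr$ligand == "gal_out"])
  n_g_in   <- sum(tr$count[tr$ligand == "gal_in"])
  if (n_h_out != n_p || n_h_in != n_p) {
    stop("cycle must bind ", n_p, " H+ outside and release ", n_p,
         " H+ inside per loop", call. = FALSE)
  }
  if (n_g_out != 1 || n_g_in != 1) {
    stop("cycle must bind 1 galactonate outside and release 1 inside",
         call. = FALSE)
  }
  if (abs(sum(tr$charge) - 1) > 1e-12) {
    stop("net charge displacement per loop must be +1 elementary charge",
         call. = FALSE)
  }
  invisible(model)
}

#' @export
print.state_cycle_model <- function(x, ...) {
  cat("Eight-state 2 H+ : 1 galactonate transport cycle\n")
  cat(sprintf("  Haldane-balanced on step %d -> %d\n",
              x$haldane_step, x$transitions$to[x$haldane_step]))
  print(x$transitions, row.names = FALSE)
  invisible(x)
}

#' Pseudo-first-order rates and generator matrix under given conditions
#'
#' Multiplies every ligand-dependent rate by the facing concentration (to the
#' power of its ligand count) and rescales the backward rate of the
#' empty-carrier return step so that the product of forward/backward rates
#' around the loop equals `exp(-dG/RT)` exactly (generalized Haldane
#' relation, `dG = 2 dmu_H + dmu_gal`). Binding transitions (`H_out`,
#' `gal_out`) are concentration-dependent in the forward direction, release
#' transitions (`H_in`, `gal_in`) in the backward (rebinding) direction.
#'
#' @param model a `"state_cycle_model"`.
#' @param cond a [solution_condition()].
#' @return An object of class `"cycle_rates"`: `rate_matrix` (8 x 8
#'   generator, columns sum to zero), `rates` (per-transition effective
#'   `k_f`, `k_b`), `delta_g` (J/mol), `loop_product`, `cond`.
#' @export
apply_solution_conditions <- function(model, cond) {
  validate_cycle(model)
  if (!inherits(cond, "solution_condition")) {
    stop("cond must be a solution_condition", call. = FALSE)
  }
  tr <- model$transitions
  conc <- c(H_out   = 10^(-cond$pH_out),
            H_in    = 10^(-cond$pH_in),
            gal_out = cond$gal_out / 1000,
            gal_in  = cond$gal_in / 1000)
  kf <- tr$k_f
  kb <- tr$k_b
  for (i in seq_len(nrow(tr))) {
    lig <- tr$ligand[i]
    if (lig %in% c("H_out", "gal_out")) {
      kf[i] <- kf[i] * conc[[lig]]^tr$count[i]
    } else if (lig %in% c("H_in", "gal_in")) {
      kb[i] <- kb[i] * conc[[lig]]^tr$count[i]
    }
  }
  dG <- delta_g(cond, n = if (is.null(model$n_protons)) 2 else model$n_protons)
  RT <- .R_GAS * cond$temperature
  target <- exp(-dG / RT)
  prod_now <- prod(kf / kb)
  hs <- model$haldane_step
  if (is.finite(target) && target > 0 && is.finite(prod_now) && prod_now > 0) {
    ## rescale the designated backward rate so the loop product is exact
    kb[hs] <- kb[hs] * (prod_now / target)
  }
  K <- matrix(0, 8, 8)
  for (i in seq_len(nrow(tr))) {
    K[tr$to[i], tr$from[i]] <- K[tr$to[i], tr$from[i]] + kf[i]
    K[tr$from[i], tr$to[i]] <- K[tr$from[i], tr$to[i]] + kb[i]
  }
  diag(K) <- -colSums(K)
  rates <- data.frame(from = tr$from, to = tr$to, k_f = kf, k_b = kb,
                      charge = tr$charge)
  structure(
    list(rate_matrix = K, rates = rates, delta_g = dG,
         loop_product = prod(kf / kb), cond = cond),
    class = "cycle_rates"
  )
}

## stationary distribution of a generator matrix (columns sum to zero),
## scale-invariant so vanishing rate sets still solve cleanly
.stationary <- function(K) {
  s <- max(abs(K))
  if (s == 0) return(rep(1 / nrow(K), nrow(K)))
  ## null vector from the SVD (robust to extreme rate magnitudes)
  v <- svd(K / s)$v[, nrow(K)]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  v / sum(v)
}

## strong connectivity of the off-diagonal rate graph
.irreducible_states <- function(K) {
  A <- (K > 0) & !diag(TRUE, nrow(K))
  R <- diag(TRUE, nrow(K)) | A
  for (i in seq_len(nrow(K))) R <- R | (R %*% R > 0)
  which(!(apply(R & t(R), 1, all)))
}

#' Steady-state transport flux
#'
#' Solves the master-equation steady state (null space of the generator,
#' normalized to total probability 1) and returns the net cycle flux, i.e.
#' completed transport events per second per transporter. Positive flux means
#' influx of 2 H+ and 1 galactonate. Flux is zero exactly at `dG = 0`.
#'
#' @param model a `"state_cycle_model"`.
#' @param cond a [solution_condition()].
#' @return Signed flux (cycles/s) with attributes `occupancy` (stationary
#'   state probabilities) and `transition_flux` (per-step net fluxes, equal
#'   at steady state).
#' @export
steady_state_flux <- function(model, cond) {
  cr <- apply_solution_conditions(model, cond)
  K <- cr$rate_matrix
  bad <- .irreducible_states(K)
  if (length(bad)) {
    stop("rate matrix is reducible; states not connected to the cycle: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ## null space via least squares with the normalization row appended
  p <- .stationary(K)
  r <- cr$rates
  J <- r$k_f * p[r$from] - r$k_b * p[r$to]
  flux <- mean(J)
  attr(flux, "occupancy") <- p
  attr(flux, "transition_flux") <- J
  flux
}

#' SSME sensor readout model
#'
#' The solid-supported membrane sensor records transporter turnover through
#' capacitive coupling: sustained currents decay with the coupling RC
#' constant. Modelled as a first-order high-pass filter (time constant
#' `coupling_tau`) followed by a first-order rise-time low-pass
#' (`rise_time`), scaled by `gain`. The transfer function is a modelling
#' choice of this package, not a measured instrument response.
#'
#' @param coupling_tau high-pass (capacitive coupling) time constant, s (default 0.3 s, well below the A-phase duration so that integrated charge tracks steady-state turnover).
#' @param gain output current per unit charge-weighted turnover (nA s).
#' @param rise_time instrument rise time, s (default 10 ms).
#' @return Object of class `"ssme_readout"`.
#' @export
ssme_readout <- function(coupling_tau = 0.3, gain = 1, rise_time = 0.01) {
  if (coupling_tau <= 0 || gain <= 0 || rise_time <= 0) {
    stop("readout parameters must be positive", call. = FALSE)
  }
  structure(list(coupling_tau = coupling_tau, gain = gain,
                 rise_time = rise_time), class = "ssme_readout")
}

#' One phase of a solution-exchange protocol
#'
#' @param label phase label: `"R"` (resting), `"NA"` (non-activating) or
#'   `"A"` (activating).
#' @param duration phase duration, s (> 0).
#' @param condition the [solution_condition()] flowing during the phase.
#' @return Object of class `"protocol_phase"`.
#' @export
protocol_phase <- function(label, duration, condition) {
  label <- match.arg(label, c("R", "NA", "A"))
  if (duration <= 0) stop("phase duration must be positive", call. = FALSE)
  if (!inherits(condition, "solution_condition")) {
    stop("condition must be a solution_condition", call. = FALSE)
  }
  structure(list(label = label, duration = duration, condition = condition),
            class = "protocol_phase")
}

#' Simulate an SSME recording from the kinetic cycle
#'
#' Propagates the master equation through a sequence of solution-exchange
#' phases with an error-controlled stiff integrator (`deSolve::lsoda`),
#' forming the instantaneous turnover current as the charge-weighted sum of
#' net transition fluxes, then passes it through the capacitive readout
#' model. The state starts at the steady state of the first phase.
#'
#' @param model a `"state_cycle_model"`.
#' @param phases list of [protocol_phase()] objects.
#' @param readout an [ssme_readout()].
#' @param dt output sampling interval, s; must resolve the readout time
#'   constants.
#' @return A `"current_trace"`: data frame with columns `time_s`,
#'   `current_nA`, `phase`, plus attributes `turnover_nA` (pre-filter
#'   current) and `occupancy` (final state probabilities).
#' @export
simulate_ssme_protocol <- function(model, phases, readout = ssme_readout(),
                                   dt = 1e-3) {
  if (!length(phases)) stop("at least one protocol phase required", call. = FALSE)
  if (dt > min(readout$coupling_tau, readout$rise_time) / 2) {
    stop("dt too large for the readout time constants; decrease dt",
         call. = FALSE)
  }
  cr1 <- apply_solution_conditions(model, phases[[1]]$condition)
  p0 <- .stationary(cr1$rate_matrix)

  turnover <- function(p, r) {
    readout$gain * sum(r$charge * (r$k_f * p[r$from] - r$k_b * p[r$to]))
  }
  ## high-pass state z tracks the low-pass of the turnover current
  y <- c(p0, z = turnover(p0, cr1$rates), w = 0)
  t_abs <- 0
  out_t <- out_i <- out_turn <- numeric(0)
  out_ph <- character(0)
  for (ph in phases) {
    cr <- apply_solution_conditions(model, ph$condition)
    r <- cr$rates
    K <- cr$rate_matrix
    deriv <- function(t, y, parms) {
      p <- y[1:8]
      it <- turnover(p, r)
      ihp <- it - y[9]
      list(c(K %*% p,
             ihp / readout$coupling_tau,
             (ihp - y[10]) / readout$rise_time))
    }
    times <- seq(0, ph$duration, by = dt)
    sol <- deSolve::lsoda(y, times, deriv, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    p_mat <- sol[, 2:9, drop = FALSE]
    it <- apply(p_mat, 1, turnover, r = r)
    n <- nrow(sol)
    keep <- if (length(out_t)) 2:n else 1:n  # avoid duplicated boundary sample
    out_t <- c(out_t, t_abs + sol[keep, 1])
    out_i <- c(out_i, sol[keep, "w"])
    out_turn <- c(out_turn, it[keep])
    out_ph <- c(out_ph, rep(ph$label, length(keep)))
    y <- sol[n, -1]
    t_abs <- t_abs + ph$duration
  }
  trace <- data.frame(time_s = out_t, current_nA = out_i, phase = out_ph,
                      stringsAsFactors = FALSE)
  class(trace) <- c("current_trace", "data.frame")
  attr(trace, "turnover_nA") <- out_turn
  attr(trace, "occupancy") <- y[1:8] / sum(y[1:8])
  trace
}

#' @export
plot.current_trace <- function(x, ...) {
  plot(x$time_s, x$current_nA, type = "l", xlab = "time (s)",
       ylab = "current (nA)", ...)
  bounds <- x$time_s[c(1, which(diff(as.integer(factor(x$phase))) != 0) + 1)]
  abline(v = bounds, lty = 3, col = "grey50")
  invisible(x)
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("SSME current trace: %d samples, %.3g s, phases: %s\n",
              nrow(x), max(x$time_s) - min(x$time_s),
              paste(rle(x$phase)$values, collapse = " -> ")))
  invisible(x)
}
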