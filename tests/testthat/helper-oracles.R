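## Independent oracles and fixture builders used across the test files.

erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

## Direct Ewald sum (real + reciprocal at splitting alpha) for the potential
## of beta-smeared charges: total periodic point potential minus the
## short-range erfc(beta r)/r part, in kT/e at 310.15 K. Independent of the
## FFT-grid implementation.
smeared_ewald_oracle <- function(r, pos, q, box, beta_A,
                                 alpha = 0.6, nimg = 3, kmax = 30) {
  f_c <- 1.66947e5 / 310.15
  real <- 0; corr <- 0
  for (j in seq_along(q)) {
    for (ix in -nimg:nimg) for (iy in -nimg:nimg) for (iz in -nimg:nimg) {
      rv <- pos[j, ] + c(ix, iy, iz) * box - r
      d <- sqrt(sum(rv^2))
      if (d > 1e-9) {
        real <- real + q[j] * erfc(alpha * d) / d
        corr <- corr + q[j] * erfc(beta_A * d) / d
      }
    }
  }
  rec <- 0
  for (nx in -kmax:kmax) for (ny in -kmax:kmax) for (nz in -kmax:kmax) {
    if (nx == 0 && ny == 0 && nz == 0) next
    k <- 2 * pi * c(nx, ny, nz) / box
    k2 <- sum(k^2)
    if (k2 > 160) next
    Sk <- sum(q * exp(-1i * as.numeric(pos %*% k)))
    rec <- rec + Re(exp(-k2 / (4 * alpha^2)) / k2 * Sk * exp(1i * sum(k * r)))
  }
  f_c * (real + 4 * pi / prod(box) * rec - corr)
}

## Slowest relaxation time of overdamped diffusion in a 2D potential from a
## fine-grid discretized Smoluchowski rate matrix (independent of MSM code).
smoluchowski_slowest_time <- function(potential, kT = 2.579, friction = 1,
                                      ng = 41, lim = c(-3, 3)) {
  D <- kT / friction
  g <- seq(lim[1], lim[2], length.out = ng)
  h <- g[2] - g[1]
  U <- matrix(potential$U(as.matrix(expand.grid(g, g))), ng)
  n <- ng * ng
  id <- function(i, j) (j - 1) * ng + i
  K <- matrix(0, n, n)
  ii <- expand.grid(i = 1:ng, j = 1:ng)
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    i2 <- ii$i + sh[1]; j2 <- ii$j + sh[2]
    ok <- i2 >= 1 & i2 <= ng & j2 >= 1 & j2 <= ng
    from <- id(ii$i[ok], ii$j[ok]); to <- id(i2[ok], j2[ok])
    rate <- (D / h^2) *
      exp(-(U[cbind(i2[ok], j2[ok])] - U[cbind(ii$i[ok], ii$j[ok])]) / (2 * kT))
    K[cbind(to, from)] <- K[cbind(to, from)] + rate
  }
  diag(K) <- -colSums(K)
  pivec <- exp(-(as.numeric(U) - min(U)) / kT)
  pivec <- pivec / sum(pivec)
  S <- diag(1 / sqrt(pivec)) %*% K %*% diag(sqrt(pivec))
  S <- (S + t(S)) / 2
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  -1 / ev[2]
}

## Minimal trajectory fixture: explicit coordinates, optional box
make_traj <- function(coord_list, box = NULL, atoms = NULL) {
  n_frames <- length(coord_list)
  n_atoms <- nrow(coord_list[[1]])
  coords <- array(NA_real_, c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- coord_list[[f]]
  md_trajectory(coords, box = box, atoms = atoms)
}

## brute-force minimum-image distance over all 27 periodic images
brute_min_image_dist <- function(a, b, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- sqrt(sum((a - (b + c(ix, iy, iz) * box))^2))
    best <- min(best, d)
  }
  best
}

## greedy Daura clustering oracle on an explicit distance matrix
daura_oracle <- function(D, cutoff) {
  remaining <- seq_len(nrow(D))
  out <- list()
  while (length(remaining)) {
    nb <- vapply(remaining, function(i) sum(D[i, remaining] <= cutoff),
                 integer(1))
    ci <- remaining[which.max(nb)]
    members <- remaining[D[ci, remaining] <= cutoff]
    out[[length(out) + 1]] <- sort(members)
    remaining <- setdiff(remaining, members)
  }
  out[order(vapply(out, length, integer(1)), decreasing = TRUE)]
}

## reference NA/A/NA reversal-protocol phases for a given ratio
reversal_phases <- function(ratio, pH_in = 7.3, pH_out = 7.6, gal_in = 0.5) {
  lhr <- log(10^(-pH_out) / 10^(-pH_in))
  gal_out <- gal_in * exp(-ratio * lhr)
  na <- solution_condition(pH_in, pH_in, gal_in, gal_in)
  a <- solution_condition(pH_in, pH_out, gal_in, gal_out)
  list(protocol_phase("NA", 2, na), protocol_phase("A", 3, a),
       protocol_phase("NA", 3, na))
}
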