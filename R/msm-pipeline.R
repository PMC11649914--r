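#' Cross-domain distance featurization
#'
#' Builds the feature matrix used for conformational analysis of two-domain
#' transporters: every `stride`-th Calpha of the first domain's helices
#' paired with every `stride`-th Calpha of the second domain's, one feature
#' per cross-domain pair, per-frame Euclidean distance (minimum image if
#' the trajectory is periodic).
#'
#' @param traj an [md_trajectory()].
#' @param domainA_resids,domainB_resids residue ids of the two domains.
#' @param stride take every `stride`-th matching atom (default 5).
#' @param atom_name atom name to select (default `"CA"`).
#' @return Matrix (frames x nA*nB) with column labels `"rA-rB"`; selected
#'   residue ids in attributes `selA`, `selB`.
#' @export
featurize_interdomain_distances <- function(traj, domainA_resids,
                                            domainB_resids, stride = 5,
                                            atom_name = "CA") {
  ia <- select_atoms(traj, resid = domainA_resids, name = atom_name)
  ib <- select_atoms(traj, resid = domainB_resids, name = atom_name)
  if (!length(ia)) stop("domain A selection is empty", call. = FALSE)
  if (!length(ib)) stop("domain B selection is empty", call. = FALSE)
  ia <- ia[seq(1, length(ia), by = stride)]
  ib <- ib[seq(1, length(ib), by = stride)]
  n <- dim(traj$coords)[1]
  X <- matrix(NA_real_, n, length(ia) * length(ib))
  for (f in seq_len(n)) {
    A <- matrix(traj$coords[f, ia, ], ncol = 3)
    B <- matrix(traj$coords[f, ib, ], ncol = 3)
    k <- 1
    for (i in seq_len(nrow(A))) {
      d <- .min_image(sweep(B, 2, A[i, ]), traj$box)
      X[f, k:(k + nrow(B) - 1)] <- sqrt(rowSums(d^2))
      k <- k + nrow(B)
    }
  }
  colnames(X) <- as.vector(t(outer(traj$atoms$resid[ia], traj$atoms$resid[ib],
                                   paste, sep = "-")))
  attr(X, "selA") <- ia; attr(X, "selB") <- ib
  X
}

#' Time-lagged independent component analysis
#'
#' Solves the symmetrized generalized eigenproblem of the time-lagged
#' covariance against the instantaneous covariance to find the slowest
#' linearly decorrelating coordinates. Features are mean-centered
#' internally; the instantaneous covariance receives a small diagonal
#' shrinkage so rank-deficient (e.g. lifted or padded) feature sets stay
#' solvable.
#'
#' @param X feature matrix (frames x features).
#' @param lag lag time in frames (`0 < lag < nrow(X)`).
#' @param shrinkage diagonal regularization added to the covariance
#'   (relative to its trace; default 1e-10).
#' @param n_components number of components kept (default 2).
#' @return Object of class `"tica_model"`: `eigenvalues` (descending),
#'   `components` (features x n, orthonormal in the covariance metric),
#'   `means`, `lag`, `timescales` (frames, `-lag/log(lambda)`).
#' @export
tica_fit <- function(X, lag, shrinkage = 1e-10, n_components = 2) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (lag <= 0 || lag >= n) stop("need 0 < lag < nrow(X)", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  X0 <- Xc[1:(n - lag), , drop = FALSE]
  Xt <- Xc[(1 + lag):n, , drop = FALSE]
  m <- nrow(X0)
  C0 <- (crossprod(X0) + crossprod(Xt)) / (2 * m)
  Ct <- (crossprod(X0, Xt) + crossprod(Xt, X0)) / (2 * m)
  tr <- sum(diag(C0))
  C0 <- C0 + diag(shrinkage * max(tr, 1), ncol(C0))
  e0 <- eigen(C0, symmetric = TRUE)
  keep <- e0$values > max(e0$values) * 1e-12
  if (!any(keep)) stop("singular covariance; increase shrinkage", call. = FALSE)
  W <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), sum(keep))
  M <- t(W) %*% Ct %*% W
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  comp <- W %*% em$vectors
  lam <- em$values
  nc <- min(n_components, length(lam))
  ts <- rep(NA_real_, length(lam))
  sel <- lam > 0 & lam < 1
  ts[sel] <- -lag / log(lam[sel])
  structure(list(eigenvalues = lam, components = comp[, seq_len(nc), drop = FALSE],
                 all_components = comp, means = mu, lag = lag,
                 timescales = ts),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("tICA model: lag %d frames, leading eigenvalues %s\n", x$lag,
              paste(signif(head(x$eigenvalues, 4), 3), collapse = ", ")))
  invisible(x)
}

#' Project features onto tICA components
#'
#' @param object a `"tica_model"`.
#' @param newdata feature matrix on the same feature set.
#' @param ... unused.
#' @return Matrix (frames x n_components).
#' @export
predict.tica_model <- function(object, newdata, ...) {
  sweep(as.matrix(newdata), 2, object$means) %*% object$components
}

#' Discretize projected coordinates into microstates
#'
#' Seeded k-means clustering of the tICA-projected coordinates.
#'
#' @param Y projected coordinates (frames x d).
#' @param k number of microstates (>= 2).
#' @param seed RNG seed.
#' @param max_fit centers are fitted on at most this many frames (a seeded
#'   subsample) and all frames are then assigned to the nearest center;
#'   keeps the clustering cost bounded on long trajectories.
#' @return Integer vector of per-frame microstate assignments with the
#'   fitted `kmeans` object in attribute `kmeans`.
#' @export
cluster_microstates <- function(Y, k, seed = 1, max_fit = 50000) {
  Y <- as.matrix(Y)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > nrow(Y)) stop("k exceeds the number of frames", call. = FALSE)
  set.seed(seed)
  fit_idx <- if (nrow(Y) > max_fit) sort(sample.int(nrow(Y), max_fit))
             else seq_len(nrow(Y))
  km <- suppressWarnings(kmeans(Y[fit_idx, , drop = FALSE], centers = k,
                                nstart = 5, iter.max = 200))
  ## assign every frame to its nearest center
  cn2 <- rowSums(km$centers^2)
  assign <- integer(nrow(Y))
  step <- 20000
  for (s in seq(1, nrow(Y), by = step)) {
    rows <- s:min(s + step - 1, nrow(Y))
    D <- outer(rowSums(Y[rows, , drop = FALSE]^2), cn2, "+") -
      2 * Y[rows, , drop = FALSE] %*% t(km$centers)
    assign[rows] <- max.col(-D)
  }
  structure(assign, kmeans = km)
}

## transition count matrix at a lag (sliding window) over a list of dtrajs
.count_matrix <- function(dtrajs, lag, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  if (is.null(n_states)) n_states <- max(unlist(dtrajs))
  C <- matrix(0, n_states, n_states)
  for (d in dtrajs) {
    if (length(d) <= lag) next
    from <- d[1:(length(d) - lag)]
    to <- d[(1 + lag):length(d)]
    for (k in seq_along(from)) C[from[k], to[k]] <- C[from[k], to[k]] + 1
  }
  C
}

## largest strongly connected set of the directed graph C > 0
.largest_connected_set <- function(C) {
  A <- (C > 0) | diag(TRUE, nrow(C))
  R <- A
  for (i in seq_len(ceiling(log2(nrow(C))) + 1)) R <- (R %*% R) > 0
  mutual <- R & t(R)
  comp <- match(apply(mutual, 1, paste, collapse = ""),
                unique(apply(mutual, 1, paste, collapse = "")))
  sizes <- tapply(rowSums(C) + colSums(C), comp, sum)
  which(comp == as.integer(names(sizes)[which.max(sizes)]))
}

#' Maximum-likelihood reversible Markov state model
#'
#' Estimates the transition matrix at a lag time under the detailed-balance
#' constraint by the standard iterative fixed point on the symmetric flux
#' variables `x_ij`, restricted to the largest strongly connected set of
#' the transition counts. The stationary distribution is read off the
#' converged fluxes.
#'
#' @param dtrajs integer vector or list of vectors of microstate
#'   assignments.
#' @param lag lag time in frames.
#' @param tol convergence tolerance on the flux update (default 1e-12).
#' @param max_iter iteration cap.
#' @return Object of class `"msm_model"`: `T` (row-stochastic), `pi`,
#'   `lag`, `active_set` (original state labels), `counts`.
#' @export
estimate_reversible_msm <- function(dtrajs, lag, tol = 1e-12,
                                    max_iter = 10000) {
  C_full <- .count_matrix(dtrajs, lag)
  act <- .largest_connected_set(C_full)
  if (length(act) < nrow(C_full)) {
    message("restricting to largest connected set: ", length(act), " of ",
            nrow(C_full), " states")
  }
  C <- C_full[act, act, drop = FALSE]
  n <- nrow(C)
  Cs <- C + t(C)
  ci <- rowSums(C)
  x <- Cs / sum(Cs)               # init: symmetrized counts
  for (it in seq_len(max_iter)) {
    xi <- rowSums(x)
    denom <- outer(ci / xi, ci / xi, "+")
    x_new <- Cs / denom
    x_new[Cs == 0] <- 0
    delta <- max(abs(x_new - x))
    x <- x_new / sum(x_new)
    if (delta < tol) break
  }
  xi <- rowSums(x)
  T_ <- x / xi
  pi_ <- xi / sum(xi)
  structure(list(T = T_, pi = pi_, lag = lag, active_set = act, counts = C),
            class = "msm_model")
}

#' @export
print.msm_model <- function(x, ...) {
  cat(sprintf("Reversible MSM: %d states, lag %d frames\n",
              nrow(x$T), x$lag))
  ev <- sort(Re(eigen(x$T, only.values = TRUE)$values), decreasing = TRUE)
  cat("  slowest implied timescales (frames): ",
      paste(signif(-x$lag / log(pmax(pmin(ev[2:min(4, length(ev))], 1 - 1e-15),
                                     1e-15)), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Implied relaxation timescales across lag times
#'
#' Estimates a reversible MSM at each lag and reports
#' `t_i(tau) = -tau / log(lambda_i(tau))` for the dominant non-stationary
#' eigenvalues. Markovianity shows as a plateau: the verdict flags the
#' first lag after which the slowest timescale changes by less than
#' `tol_rel` between successive lags.
#'
#' @param dtrajs microstate assignments (vector or list).
#' @param lags increasing vector of lag times (frames).
#' @param n_its number of timescales reported (default 3).
#' @param tol_rel relative plateau tolerance (default 0.1).
#' @return List: `timescales` (data frame lag x t1..tn; `NA` where the
#'   eigenvalue is non-positive), `converged_lag` (smallest plateau lag or
#'   `NA`), `plateau` (logical verdict).
#' @export
implied_timescales <- function(dtrajs, lags, n_its = 3, tol_rel = 0.1) {
  rows <- lapply(lags, function(l) {
    m <- estimate_reversible_msm(dtrajs, l)
    ev <- sort(Re(eigen(m$T, only.values = TRUE)$values), decreasing = TRUE)
    its <- vapply(seq_len(n_its), function(i) {
      lam <- if (i + 1 <= length(ev)) ev[i + 1] else NA_real_
      if (is.na(lam) || lam <= 0 || lam >= 1) NA_real_ else -l / log(lam)
    }, numeric(1))
    its
  })
  ts <- do.call(rbind, rows)
  colnames(ts) <- paste0("t", seq_len(n_its))
  out <- data.frame(lag = lags, ts)
  t1 <- out$t1
  plateau_at <- NA_integer_
  for (i in seq_along(lags)[-1]) {
    if (!is.na(t1[i]) && !is.na(t1[i - 1]) &&
        abs(t1[i] - t1[i - 1]) / t1[i - 1] < tol_rel) {
      plateau_at <- lags[i - 1]
      break
    }
  }
  list(timescales = out, converged_lag = plateau_at,
       plateau = !is.na(plateau_at))
}

#' PCCA+ metastable coarse-graining
#'
#' Perron-cluster cluster analysis on the dominant eigenvectors of a
#' reversible MSM: the top `n_macrostates` right eigenvectors span a
#' simplex whose vertices are located by successive farthest-row selection;
#' the linear map onto barycentric coordinates yields fuzzy memberships
#' (clipped to [0, 1] and row-normalized). Macrostate stationary
#' probabilities are the membership-weighted sums of the microstate
#' distribution.
#'
#' @param msm an `"msm_model"`.
#' @param n_macrostates number of metastable states (default 3).
#' @return Object of class `"pcca_result"`: `memberships` (micro x macro,
#'   rows sum to 1), `assignment` (crisp argmax), `macro_pi`.
#' @export
pcca_coarse_grain <- function(msm, n_macrostates = 3) {
  n <- nrow(msm$T)
  if (n_macrostates > n) stop("more macrostates than microstates", call. = FALSE)
  ## reversible T is similar to a symmetric matrix: real spectrum guaranteed
  s <- sqrt(msm$pi)
  A <- diag(s) %*% msm$T %*% diag(1 / s)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  o <- order(e$values, decreasing = TRUE)
  evec <- e$vectors[, o[seq_len(n_macrostates)], drop = FALSE]
  X <- diag(1 / s) %*% evec          # right eigenvectors of T
  X[, 1] <- 1                         # first eigenvector is constant
  ## inner simplex: farthest-row vertex search with Gram-Schmidt deflation
  idx <- integer(n_macrostates)
  Y <- X
  idx[1] <- which.max(rowSums(Y^2))
  Y <- sweep(Y, 2, Y[idx[1], ])
  for (k in seq_len(n_macrostates)[-1]) {
    idx[k] <- which.max(rowSums(Y^2))
    v <- Y[idx[k], ]
    v <- v / sqrt(sum(v^2))
    Y <- Y - (Y %*% v) %*% t(v)
  }
  Ainv <- tryCatch(solve(X[idx, , drop = FALSE]),
                   error = function(e) stop("degenerate eigenvector simplex; ",
                                            "try fewer macrostates", call. = FALSE))
  chi <- X %*% Ainv
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  macro_pi <- as.numeric(t(chi) %*% msm$pi)
  structure(list(memberships = chi,
                 assignment = max.col(chi),
                 macro_pi = macro_pi / sum(macro_pi)),
            class = "pcca_result")
}

#' @export
print.pcca_result <- function(x, ...) {
  cat(sprintf("PCCA+ coarse-graining: %d macrostates, stationary probabilities %s\n",
              ncol(x$memberships),
              paste(signif(x$macro_pi, 3), collapse = ", ")))
  invisible(x)
}

#' Chapman-Kolmogorov test
#'
#' Compares set-occupation probabilities predicted by powering the MSM
#' transition matrix, `T(tau)^k`, with those re-estimated directly from
#' the data at lag `k*tau`, for each PCCA metastable set. Small deviations
#' indicate Markovian behavior at the chosen lag.
#'
#' @param msm an `"msm_model"`.
#' @param dtrajs the microstate assignments the model was estimated from.
#' @param n_sets number of metastable sets (default 3).
#' @param steps multiples of the lag to test (default 1:5).
#' @return List: `curves` (data frame set, k, predicted, estimated),
#'   `max_dev` (largest absolute deviation).
#' @export
ck_test <- function(msm, dtrajs, n_sets = 3, steps = 1:5) {
  pcca <- pcca_coarse_grain(msm, n_sets)
  sets <- lapply(seq_len(n_sets), function(m) which(pcca$assignment == m))
  Tk <- diag(nrow(msm$T))
  rows <- list()
  usable <- integer(0)
  for (k in sort(unique(steps))) {
    Tk <- if (k == 1) msm$T else Tk %*% msm$T
    C <- .count_matrix(dtrajs, k * msm$lag)
    C <- C[msm$active_set, msm$active_set, drop = FALSE]
    if (sum(C) == 0) next
    usable <- c(usable, k)
    T_est <- C / pmax(rowSums(C), 1)
    for (m in seq_len(n_sets)) {
      A <- sets[[m]]
      w <- msm$pi * (seq_len(nrow(msm$T)) %in% A)
      w <- w / sum(w)
      rows[[length(rows) + 1]] <- data.frame(
        set = m, k = k,
        predicted = sum((w %*% Tk)[1, A]),
        estimated = sum((w %*% T_est)[1, A]))
    }
  }
  if (!length(rows)) {
    stop("insufficient data at any multiple of the lag; usable k: none",
         call. = FALSE)
  }
  curves <- do.call(rbind, rows)
  list(curves = curves, max_dev = max(abs(curves$predicted - curves$estimated)),
       usable_k = usable)
}

#' MSM-reweighted free-energy surface
#'
#' Histograms projected coordinates with per-frame weights
#' `pi(state) / count(state)` so that each microstate contributes its
#' stationary probability regardless of how often it was sampled, and
#' returns `F = -kT log(weighted histogram)`, shifted to a zero minimum.
#' Bins never visited are `NA`, not zero.
#'
#' @param Y projected coordinates (frames x 2).
#' @param msm an `"msm_model"`.
#' @param dtraj per-frame microstate assignment aligned with `Y`.
#' @param bins bins per axis (default 60).
#' @param kT energy scale of the output (default 2.579 kJ/mol).
#' @return Object of class `"free_energy_surface"`: `x`, `y` (bin centers),
#'   `F` (matrix, kJ/mol, min 0), `weights`.
#' @export
weighted_fes <- function(Y, msm, dtraj, bins = 60, kT = 2.579) {
  Y <- as.matrix(Y)
  keep <- dtraj %in% msm$active_set
  Y <- Y[keep, , drop = FALSE]
  st <- match(dtraj[keep], msm$active_set)
  cnt <- tabulate(st, nbins = nrow(msm$T))
  w <- msm$pi[st] / cnt[st]
  bx <- seq(min(Y[, 1]), max(Y[, 1]), length.out = bins + 1)
  by <- seq(min(Y[, 2]), max(Y[, 2]), length.out = bins + 1)
  ix <- pmin(findInterval(Y[, 1], bx, rightmost.closed = TRUE), bins)
  iy <- pmin(findInterval(Y[, 2], by, rightmost.closed = TRUE), bins)
  H <- matrix(0, bins, bins)
  for (k in seq_along(w)) H[ix[k], iy[k]] <- H[ix[k], iy[k]] + w[k]
  F_ <- -kT * log(H / sum(H))
  F_[!is.finite(F_)] <- NA
  F_ <- F_ - min(F_, na.rm = TRUE)
  structure(list(x = (bx[-1] + bx[-(bins + 1)]) / 2,
                 y = (by[-1] + by[-(bins + 1)]) / 2,
                 F = F_, weights = w, kT = kT),
            class = "free_energy_surface")
}

#' Frames nearest a target region in projected space
#'
#' Deterministically returns the indices of the frames closest (Euclidean,
#' ties broken by frame index) to a target point in tICA space — used to
#' seed new simulations from sparsely sampled transition regions.
#'
#' @param Y projected coordinates (frames x d).
#' @param target numeric(d) target point (e.g. the centroid of the sampled
#'   region, `colMeans(Y)`).
#' @param n number of frames to return.
#' @return Integer frame indices, nearest first.
#' @export
adaptive_seed_selection <- function(Y, target, n = 10) {
  Y <- as.matrix(Y)
  if (!nrow(Y)) stop("no frames", call. = FALSE)
  d2 <- colSums((t(Y) - target)^2)
  head(order(d2, seq_len(nrow(Y))), n)
}

#' @importFrom stats kmeans
NULL
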