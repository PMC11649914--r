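#' Trajectory container
#'
#' Frames of annotated particle coordinates in an orthorhombic periodic box.
#' Coordinates are in Angstrom; annotations carry residue ids/names, atom
#' names, and water / side-chain flags used by the analysis operators.
#'
#' @param coords numeric array `(n_frames, n_atoms, 3)`.
#' @param box numeric(3) box lengths (Angstrom); `NULL` for non-periodic.
#' @param atoms data frame with columns `resid`, `resname`, `name`,
#'   `is_water`, `is_sidechain` (missing flag columns are filled with
#'   `FALSE`), optionally `charge`.
#' @param time_ns optional per-frame times (ns).
#' @return Object of class `"md_trajectory"`.
#' @export
md_trajectory <- function(coords, box = NULL, atoms = NULL, time_ns = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  n_atoms <- dim(coords)[2]
  if (is.null(atoms)) {
    atoms <- data.frame(resid = seq_len(n_atoms), resname = "UNK",
                        name = "X", stringsAsFactors = FALSE)
  }
  if (nrow(atoms) != n_atoms) stop("atoms table does not match coords", call. = FALSE)
  for (fl in c("is_water", "is_sidechain")) {
    if (is.null(atoms[[fl]])) atoms[[fl]] <- FALSE
  }
  if (!is.null(box)) stopifnot(length(box) == 3, all(box > 0))
  structure(list(coords = coords, box = box, atoms = atoms,
                 time_ns = time_ns),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames, %d atoms%s\n",
              dim(x$coords)[1], dim(x$coords)[2],
              if (!is.null(x$box)) sprintf(", box %s A",
                                           paste(signif(x$box, 4), collapse = " x "))
              else ""))
  invisible(x)
}

#' Select atom indices by annotation
#'
#' @param traj an [md_trajectory()].
#' @param resid,resname,name optional filters (vectors allowed).
#' @param water,sidechain optional logical filters.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(traj, resid = NULL, resname = NULL, name = NULL,
                         water = NULL, sidechain = NULL) {
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(water)) keep <- keep & a$is_water == water
  if (!is.null(sidechain)) keep <- keep & a$is_sidechain == sidechain
  which(keep)
}

## minimum-image displacement(s) in an orthorhombic box (box NULL = none)
.min_image <- function(d, box) {
  if (is.null(box)) return(d)
  d <- as.matrix(d)
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

#' Center-of-mass gate distance
#'
#' Per-frame Euclidean distance between the (unweighted) centers of mass of
#' two atom selections, with the minimum-image convention applied to the
#' COM difference vector. This is the standard gating order parameter, e.g.
#' the distance between Calpha centroids of the TM1 and TM7 tips for the
#' extracellular gate.
#'
#' @param traj an [md_trajectory()].
#' @param selA,selB integer atom indices (see [select_atoms()]).
#' @return Object of class `"gate_metric"`: data frame `frame`, `value_A`
#'   with attribute `metric = "COM_distance"`.
#' @export
com_gate_distance <- function(traj, selA, selB) {
  if (!length(selA)) stop("selection A is empty", call. = FALSE)
  if (!length(selB)) stop("selection B is empty", call. = FALSE)
  n <- dim(traj$coords)[1]
  v <- vapply(seq_len(n), function(f) {
    ca <- colMeans(matrix(traj$coords[f, selA, ], ncol = 3))
    cb <- colMeans(matrix(traj$coords[f, selB, ], ncol = 3))
    sqrt(sum(.min_image(matrix(ca - cb, 1), traj$box)^2))
  }, numeric(1))
  structure(data.frame(frame = seq_len(n), value_A = v),
            metric = "COM_distance", class = c("gate_metric", "data.frame"))
}

#' Minimum side-chain distance between two residues
#'
#' Per-frame minimum over all pairs of side-chain atoms (atoms flagged
#' `is_sidechain`, i.e. Cbeta and beyond) of the two residues, e.g. the
#' F137-W373 aromatic-lock distance.
#'
#' @param traj an [md_trajectory()].
#' @param resA,resB residue ids.
#' @return `"gate_metric"` data frame (`frame`, `value_A`).
#' @export
min_sidechain_distance <- function(traj, resA, resB) {
  ia <- select_atoms(traj, resid = resA, sidechain = TRUE)
  ib <- select_atoms(traj, resid = resB, sidechain = TRUE)
  if (!length(ia)) stop("residue ", resA, " has no side-chain atoms", call. = FALSE)
  if (!length(ib)) stop("residue ", resB, " has no side-chain atoms", call. = FALSE)
  n <- dim(traj$coords)[1]
  v <- vapply(seq_len(n), function(f) {
    A <- matrix(traj$coords[f, ia, ], ncol = 3)
    B <- matrix(traj$coords[f, ib, ], ncol = 3)
    dmin <- Inf
    for (i in seq_len(nrow(A))) {
      d <- .min_image(sweep(B, 2, A[i, ]), traj$box)
      dmin <- min(dmin, sqrt(min(rowSums(d^2))))
    }
    dmin
  }, numeric(1))
  structure(data.frame(frame = seq_len(n), value_A = v),
            metric = "min_sidechain_distance",
            class = c("gate_metric", "data.frame"))
}

#' Classify gate states from a distance series
#'
#' Three-way labelling of a gating distance: closed below `closed_max`,
#' open above `open_min`, intermediate in between (defaults 13 and 15
#' Angstrom for the extracellular-gate COM distance; use e.g. 12.5 or 8
#' Angstrom single thresholds for aromatic-lock metrics).
#'
#' @param series a `"gate_metric"` or numeric vector (Angstrom).
#' @param closed_max,open_min thresholds, `closed_max < open_min`.
#' @return Factor with levels closed, intermediate, open.
#' @export
classify_gate <- function(series, closed_max = 13, open_min = 15) {
  if (closed_max >= open_min) {
    stop("closed_max must be smaller than open_min", call. = FALSE)
  }
  v <- if (is.data.frame(series)) series$value_A else series
  factor(ifelse(v < closed_max, "closed",
                ifelse(v > open_min, "open", "intermediate")),
         levels = c("closed", "intermediate", "open"))
}

#' Water count profile along the pore axis
#'
#' Mean and SD, over (optionally filtered) frames, of the number of water
#' molecules in consecutive half-open sections `[z, z + bin)` along the
#' pore axis.
#'
#' @param traj an [md_trajectory()] with water flags.
#' @param axis_range numeric(2) range along the axis (Angstrom).
#' @param bin section width (Angstrom, default 2).
#' @param frame_filter optional logical/integer frame subset (e.g. frames
#'   with a closed aromatic lock).
#' @param axis `"x"`, `"y"` or `"z"` (default `"z"`).
#' @return Object of class `"hydration_profile"`: data frame `z_lo`, `z_hi`,
#'   `mean_count`, `sd_count`, with per-frame counts in attribute `counts`.
#' @export
hydration_profile <- function(traj, axis_range, bin = 2, frame_filter = NULL,
                              axis = "z") {
  ax <- match(axis, c("x", "y", "z"))
  wi <- select_atoms(traj, water = TRUE)
  if (!length(wi)) stop("trajectory has no water-flagged particles", call. = FALSE)
  frames <- seq_len(dim(traj$coords)[1])
  if (!is.null(frame_filter)) frames <- frames[frame_filter]
  if (!length(frames)) stop("frame filter selects zero frames", call. = FALSE)
  edges <- seq(axis_range[1], axis_range[2], by = bin)
  nb <- length(edges) - 1
  counts <- matrix(0L, length(frames), nb)
  for (k in seq_along(frames)) {
    z <- traj$coords[frames[k], wi, ax]
    idx <- floor((z - axis_range[1]) / bin) + 1
    ok <- z >= edges[1] & z < edges[length(edges)] & idx >= 1 & idx <= nb
    counts[k, ] <- tabulate(idx[ok], nbins = nb)
  }
  structure(
    data.frame(z_lo = edges[-length(edges)], z_hi = edges[-1],
               mean_count = colMeans(counts),
               sd_count = apply(counts, 2, sd)),
    counts = counts, frames = frames,
    class = c("hydration_profile", "data.frame")
  )
}

#' Water-occupancy map
#'
#' Fraction of frames in which each node of a regular grid spanning the box
#' is occupied by water, a node counting as occupied in a frame iff any
#' water particle lies within half a grid spacing (Euclidean) of it. Export
#' at an iso-level (e.g. 0.1) via [write_opendx()].
#'
#' @param traj an [md_trajectory()] with a periodic box.
#' @param spacing grid spacing (Angstrom).
#' @return Object of class `"occupancy_grid"`: list with `fraction` (3D
#'   array), `origin`, `spacing`.
#' @export
water_occupancy_map <- function(traj, spacing = 1) {
  if (is.null(traj$box)) stop("occupancy map requires a periodic box", call. = FALSE)
  wi <- select_atoms(traj, water = TRUE)
  if (!length(wi)) stop("trajectory has no water-flagged particles", call. = FALSE)
  dims <- pmax(round(traj$box / spacing), 1)
  n_frames <- dim(traj$coords)[1]
  occ <- array(0, dims)
  for (f in seq_len(n_frames)) {
    xyz <- matrix(traj$coords[f, wi, ], ncol = 3)
    node <- round(sweep(xyz, 2, spacing, "/"))
    near <- sweep(node, 2, spacing, "*") - xyz
    ok <- sqrt(rowSums(near^2)) <= spacing / 2
    node <- sweep(node[ok, , drop = FALSE], 2, dims, function(a, b) a %% b) + 1
    if (nrow(node)) {
      idx <- unique(node[, 1] + dims[1] * (node[, 2] - 1) +
                      dims[1] * dims[2] * (node[, 3] - 1))
      occ[idx] <- occ[idx] + 1
    }
  }
  structure(list(fraction = occ / n_frames,
                 origin = c(0, 0, 0), spacing = spacing),
            class = "occupancy_grid")
}

#' Residue-ligand contact fraction
#'
#' Fraction of frames in which the minimum distance between a residue's
#' side chain and the closest atom of a ligand selection (typically the
#' substrate's oxygen atoms) is at or below a cutoff (default 2 Angstrom).
#'
#' @param traj an [md_trajectory()].
#' @param residue residue id whose side chain is probed.
#' @param ligand_sel integer atom indices of the ligand atoms.
#' @param cutoff contact cutoff (Angstrom).
#' @return Fraction in [0, 1]; per-frame minimum distances in attribute
#'   `min_dist`.
#' @export
contact_fraction <- function(traj, residue, ligand_sel, cutoff = 2) {
  ir <- select_atoms(traj, resid = residue, sidechain = TRUE)
  if (!length(ir)) stop("residue ", residue, " has no side-chain atoms", call. = FALSE)
  if (!length(ligand_sel)) stop("ligand selection is empty", call. = FALSE)
  n <- dim(traj$coords)[1]
  dmin <- vapply(seq_len(n), function(f) {
    A <- matrix(traj$coords[f, ir, ], ncol = 3)
    B <- matrix(traj$coords[f, ligand_sel, ], ncol = 3)
    m <- Inf
    for (i in seq_len(nrow(A))) {
      d <- .min_image(sweep(B, 2, A[i, ]), traj$box)
      m <- min(m, sqrt(min(rowSums(d^2))))
    }
    m
  }, numeric(1))
  structure(mean(dmin <= cutoff), min_dist = dmin)
}

#' Block-distribution overlap convergence check
#'
#' Splits a scalar series into non-overlapping blocks, histograms each
#' block on common bins, and reports the overlap coefficient
#' `sum(min(p_block, p_total))` of every block distribution with the total
#' distribution. A sampled observable is called converged when all blocks
#' overlap the total by at least `threshold`.
#'
#' @param series numeric series (e.g. a gating distance over time).
#' @param block_len block length in samples (e.g. the equivalent of 10 ns).
#' @param n_bins histogram bins (default 30).
#' @param threshold convergence threshold on the overlap (default 0.8).
#' @return List with `overlap` (per block), `converged` (logical verdict),
#'   `threshold`.
#' @export
block_overlap_convergence <- function(series, block_len, n_bins = 30,
                                      threshold = 0.8) {
  n <- length(series)
  n_blocks <- floor(n / block_len)
  if (n_blocks < 2) stop("series shorter than two blocks", call. = FALSE)
  use <- series[seq_len(n_blocks * block_len)]
  breaks <- seq(min(use), max(use), length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-9; breaks[n_bins + 1] <- breaks[n_bins + 1] + 1e-9
  p_tot <- hist(use, breaks = breaks, plot = FALSE)$counts
  p_tot <- p_tot / sum(p_tot)
  ov <- vapply(seq_len(n_blocks), function(b) {
    blk <- use[((b - 1) * block_len + 1):(b * block_len)]
    p <- hist(blk, breaks = breaks, plot = FALSE)$counts
    p <- p / sum(p)
    sum(pmin(p, p_tot))
  }, numeric(1))
  list(overlap = ov, converged = all(ov >= threshold), threshold = threshold)
}

## Kabsch superposition RMSD between two coordinate sets (rows = atoms)
.rmsd_kabsch <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((A %*% R - B)^2)))
}

#' Gromos (Daura) conformational clustering
#'
#' Iterative neighbor-count clustering on pairwise RMSD after optimal
#' superposition: the frame with the most neighbors within the cutoff
#' becomes the centroid of the first cluster, the cluster is removed, and
#' the procedure repeats. Clusters are returned in order of decreasing
#' size; the centroids are the representative snapshots.
#'
#' @param traj an [md_trajectory()].
#' @param selection integer atom indices used for superposition and RMSD.
#' @param cutoff RMSD cutoff (Angstrom).
#' @return Object of class `"gromos_clusters"`: list of clusters, each with
#'   `members` (frame indices) and `centroid`; pairwise RMSD matrix in
#'   attribute `rmsd`.
#' @export
cluster_gromos <- function(traj, selection, cutoff) {
  if (!length(selection)) stop("empty selection", call. = FALSE)
  n <- dim(traj$coords)[1]
  if (n < 1) stop("no frames", call. = FALSE)
  X <- lapply(seq_len(n), function(f) matrix(traj$coords[f, selection, ], ncol = 3))
  D <- matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- .rmsd_kabsch(X[[i]], X[[j]])
    }
  }
  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining)) {
    nb <- vapply(remaining, function(i) sum(D[i, remaining] <= cutoff), integer(1))
    c_idx <- remaining[which.max(nb)]       # ties: first (lowest frame index)
    members <- remaining[D[c_idx, remaining] <= cutoff]
    clusters[[length(clusters) + 1]] <- list(members = members,
                                             centroid = c_idx)
    remaining <- setdiff(remaining, members)
  }
  o <- order(vapply(clusters, function(cl) length(cl$members), integer(1)),
             decreasing = TRUE)
  structure(clusters[o], rmsd = D, class = "gromos_clusters")
}

#' @export
print.gromos_clusters <- function(x, ...) {
  sizes <- vapply(x, function(cl) length(cl$members), integer(1))
  cat(sprintf("gromos clustering: %d clusters, sizes %s\n",
              length(x), paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Read a (multi-frame) PDB file as a trajectory
#'
#' Uses bio3d to parse the PDB; water and side-chain flags are derived from
#' residue/atom names (waters: HOH/SOL/WAT/TIP3; side chain: atoms other
#' than the backbone set N, CA, C, O, OXT and backbone hydrogens, i.e.
#' Cbeta and beyond).
#'
#' @param path PDB file path.
#' @param box numeric(3) box lengths (Angstrom), or `NULL`.
#' @return An [md_trajectory()].
#' @export
read_trajectory_pdb <- function(path, box = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) / 3
  coords <- array(NA_real_, c(n_frames, n_atoms, 3))
  for (f in seq_len(n_frames)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  a <- pdb$atom
  backbone <- c("N", "CA", "C", "O", "OXT", "H", "HA", "HN")
  atoms <- data.frame(
    resid = a$resno, resname = a$resid, name = a$elety,
    is_water = a$resid %in% c("HOH", "SOL", "WAT", "TIP3"),
    is_sidechain = !(a$elety %in% backbone) &
      !(a$resid %in% c("HOH", "SOL", "WAT", "TIP3")),
    stringsAsFactors = FALSE
  )
  md_trajectory(coords, box = box, atoms = atoms)
}

#' Write a trajectory as a multi-frame PDB file
#'
#' @param traj an [md_trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  n_frames <- dim(traj$coords)[1]
  xyz <- t(vapply(seq_len(n_frames), function(f) {
    as.numeric(t(matrix(traj$coords[f, , ], ncol = 3)))
  }, numeric(dim(traj$coords)[2] * 3)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = traj$atoms$resid, resid = traj$atoms$resname,
                   elety = traj$atoms$name)
  invisible(path)
}

#' Write a 3D scalar grid in OpenDX text format
#'
#' @param grid an `"occupancy_grid"` or `"potential_grid"` (list with 3D
#'   array `fraction` or `values`, `origin`, `spacing`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_opendx <- function(grid, path) {
  vals <- if (!is.null(grid$values)) grid$values else grid$fraction
  d <- dim(vals)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0 0", grid$spacing),
    sprintf("delta 0 %g 0", grid$spacing),
    sprintf("delta 0 0 %g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals))
  ), con)
  ## OpenDX order: z fastest
  v <- as.numeric(aperm(vals, c(3, 2, 1)))
  idx <- seq(1, length(v), by = 3)
  lines <- vapply(idx, function(i) {
    paste(format(v[i:min(i + 2, length(v))], scientific = TRUE), collapse = " ")
  }, character(1))
  writeLines(lines, con)
  writeLines("object \"density\" class field", con)
  invisible(path)
}

#' @importFrom graphics abline hist
NULL
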