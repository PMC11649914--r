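test_that("COM gate distance matches constructions and the 27-image oracle", {
  ## two single particles 7 A apart
  tr <- make_traj(list(rbind(c(0, 0, 0), c(7, 0, 0))))
  d <- com_gate_distance(tr, 1, 2)
  expect_equal(d$value_A, 7)
  ## symmetric 4-particle construction: distance of midpoints
  P <- rbind(c(0, 0, 0), c(2, 0, 0), c(10, 1, 0), c(10, -1, 0))
  tr2 <- make_traj(list(P))
  expect_equal(com_gate_distance(tr2, 1:2, 3:4)$value_A, 9)
  ## periodic wrap: verified against brute force over 27 images
  box <- c(10, 12, 14)
  set.seed(8)
  P3 <- matrix(runif(6 * 3) * 20 - 5, ncol = 3)
  tr3 <- make_traj(list(P3), box = box)
  for (pair in list(c(1, 2), c(3, 6), c(4, 5))) {
    got <- com_gate_distance(tr3, pair[1], pair[2])$value_A
    expect_equal(got, brute_min_image_dist(P3[pair[1], ], P3[pair[2], ], box),
                 tolerance = 1e-10)
  }
  expect_error(com_gate_distance(tr, integer(0), 2), "empty")
})

test_that("minimum side-chain distance equals the exhaustive pair minimum", {
  atoms <- data.frame(resid = rep(c(1, 2), each = 3), resname = "PHE",
                      name = c("CB", "CG", "CD", "CB", "CG", "CD"),
                      is_water = FALSE, is_sidechain = TRUE)
  set.seed(5)
  frames <- lapply(1:4, function(f) matrix(runif(18) * 10, ncol = 3))
  tr <- make_traj(frames, atoms = atoms)
  got <- min_sidechain_distance(tr, 1, 2)$value_A
  want <- vapply(frames, function(P) {
    min(as.matrix(dist(P))[1:3, 4:6])
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-10)
  ## identical positions give zero
  same <- make_traj(list(rbind(c(1, 1, 1), c(1, 1, 1))),
                    atoms = data.frame(resid = c(1, 2), resname = "X",
                                       name = "CB", is_water = FALSE,
                                       is_sidechain = TRUE))
  expect_equal(min_sidechain_distance(same, 1, 2)$value_A, 0)
  expect_error(min_sidechain_distance(tr, 1, 99), "side-chain")
})

test_that("gate classification uses the published thresholds", {
  lab <- classify_gate(c(12, 16, 14))
  expect_equal(as.character(lab), c("closed", "open", "intermediate"))
  ## configurable single-residue lock thresholds
  lab2 <- classify_gate(c(7, 9), closed_max = 8, open_min = 8.0001)
  expect_equal(as.character(lab2), c("closed", "open"))
  expect_error(classify_gate(1, closed_max = 15, open_min = 13), "smaller")
})

test_that("hydration profile counts waters per 2 A section with conservation", {
  ## 10 waters all in one section: mean 10, sd 0
  P <- cbind(runif(10) * 5, runif(10) * 5, runif(10, 0, 2 - 1e-9))
  atoms <- data.frame(resid = 1:10, resname = "SOL", name = "OW",
                      is_water = TRUE, is_sidechain = FALSE)
  tr <- make_traj(list(P, P), atoms = atoms)
  hp <- hydration_profile(tr, axis_range = c(0, 10), bin = 2)
  expect_equal(hp$mean_count[1], 10)
  expect_equal(hp$sd_count[1], 0)
  expect_equal(sum(hp$mean_count), 10)
  ## random frames: per-bin counts equal brute-force recount, totals conserved
  set.seed(9)
  frames <- lapply(1:6, function(f) cbind(runif(20) * 8, runif(20) * 8,
                                          runif(20) * 10))
  atoms2 <- data.frame(resid = 1:20, resname = "SOL", name = "OW",
                       is_water = TRUE, is_sidechain = FALSE)
  tr2 <- make_traj(frames, atoms = atoms2)
  hp2 <- hydration_profile(tr2, axis_range = c(0, 10), bin = 2)
  counts <- attr(hp2, "counts")
  for (f in 1:6) {
    z <- frames[[f]][, 3]
    brute <- vapply(seq(0, 8, by = 2), function(lo) sum(z >= lo & z < lo + 2),
                    numeric(1))
    expect_equal(counts[f, ], brute, ignore_attr = TRUE)
    expect_equal(sum(counts[f, ]), sum(z >= 0 & z < 10))
  }
  expect_error(hydration_profile(tr2, c(0, 10), frame_filter = rep(FALSE, 6)),
               "zero frames")
})

test_that("water occupancy map reports per-node frame fractions", {
  atoms <- data.frame(resid = 1, resname = "SOL", name = "OW",
                      is_water = TRUE, is_sidechain = FALSE)
  ## stationary water: its node fraction is 1
  still <- make_traj(rep(list(matrix(c(5, 5, 5), 1)), 4), box = c(10, 10, 10),
                     atoms = atoms)
  m <- water_occupancy_map(still, spacing = 1)
  expect_equal(m$fraction[6, 6, 6], 1)
  expect_equal(sum(m$fraction), 1)
  ## present at the node in half the frames
  half <- make_traj(list(matrix(c(5, 5, 5), 1), matrix(c(2, 2, 2), 1),
                         matrix(c(5, 5, 5), 1), matrix(c(2, 2, 2), 1)),
                    box = c(10, 10, 10), atoms = atoms)
  m2 <- water_occupancy_map(half, spacing = 1)
  expect_equal(m2$fraction[6, 6, 6], 0.5)
  expect_equal(m2$fraction[3, 3, 3], 0.5)
  ## random frames cross-checked by an oracle recount
  set.seed(3)
  atoms3 <- data.frame(resid = 1:5, resname = "SOL", name = "OW",
                       is_water = TRUE, is_sidechain = FALSE)
  frames <- lapply(1:5, function(f) matrix(runif(15) * 10, ncol = 3))
  tr3 <- make_traj(frames, box = c(10, 10, 10), atoms = atoms3)
  m3 <- water_occupancy_map(tr3, spacing = 1)
  dims <- dim(m3$fraction)
  oracle <- array(0, dims)
  for (f in 1:5) {
    hit <- array(FALSE, dims)
    for (w in 1:5) {
      node <- round(frames[[f]][w, ])
      if (sqrt(sum((node - frames[[f]][w, ])^2)) <= 0.5) {
        node <- node %% dims + 1
        hit[node[1], node[2], node[3]] <- TRUE
      }
    }
    oracle <- oracle + hit
  }
  expect_equal(m3$fraction, oracle / 5)
})

test_that("contact fraction counts frames within the cutoff", {
  atoms <- data.frame(resid = c(1, 2), resname = c("ARG", "GAL"),
                      name = c("CZ", "O1"), is_water = FALSE,
                      is_sidechain = c(TRUE, FALSE))
  close_f <- rbind(c(0, 0, 0), c(1, 0, 0))
  far_f <- rbind(c(0, 0, 0), c(6, 0, 0))
  expect_equal(as.numeric(contact_fraction(
    make_traj(list(close_f, close_f), atoms = atoms), 1, 2)), 1)
  expect_equal(as.numeric(contact_fraction(
    make_traj(list(far_f, far_f), atoms = atoms), 1, 2)), 0)
  expect_equal(as.numeric(contact_fraction(
    make_traj(list(close_f, far_f, close_f, far_f), atoms = atoms), 1, 2)),
    0.5)
})

test_that("block-overlap convergence flags stationary vs two-regime series", {
  set.seed(12)
  stationary <- rnorm(5000)
  res <- block_overlap_convergence(stationary, block_len = 1000)
  expect_true(res$converged)
  expect_true(all(res$overlap > 0.9))
  two_regime <- c(rnorm(1000, mean = -4), rnorm(4000, mean = 0))
  res2 <- block_overlap_convergence(two_regime, block_len = 1000)
  expect_false(res2$converged)
  expect_lt(res2$overlap[1], 0.5)
  ## single-value series: overlap exactly 1
  res3 <- block_overlap_convergence(rep(1, 400), block_len = 100)
  expect_equal(res3$overlap, rep(1, 4))
  expect_error(block_overlap_convergence(1:50, block_len = 40), "two blocks")
})

test_that("gromos clustering reproduces the greedy oracle partition", {
  set.seed(31)
  ## three tight bundles of distinct conformations (superposition removes
  ## rigid-body placement, so the bundles differ in shape, not position)
  sizes <- c(6, 4, 2)
  frames <- list()
  for (b in 1:3) {
    shape <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3)) * b
    for (k in seq_len(sizes[b])) {
      frames[[length(frames) + 1]] <- shape + matrix(rnorm(12, sd = 0.05), 4)
    }
  }
  tr <- make_traj(frames)
  cl <- cluster_gromos(tr, 1:4, cutoff = 1)
  expect_length(cl, 3)
  expect_equal(vapply(cl, function(x) length(x$members), integer(1)),
               c(6, 4, 2))
  expect_setequal(cl[[1]]$members, 1:6)
  expect_setequal(cl[[3]]$members, 11:12)
  ## partition is disjoint and exhaustive
  all_members <- sort(unlist(lapply(cl, `[[`, "members")))
  expect_equal(all_members, 1:12)
  ## identical frames collapse to one cluster
  tr_same <- make_traj(rep(list(frames[[1]]), 5))
  expect_length(cluster_gromos(tr_same, 1:4, cutoff = 0.1), 1)
  ## random instance equals the exhaustive greedy oracle on the same RMSDs
  set.seed(77)
  rnd <- lapply(1:12, function(f) matrix(rnorm(12, sd = 2), 4))
  trr <- make_traj(rnd)
  cutoff <- 2.2
  got <- cluster_gromos(trr, 1:4, cutoff)
  D <- attr(got, "rmsd")
  want <- daura_oracle(D, cutoff)
  expect_equal(lapply(got, function(x) sort(x$members)), want)
  expect_error(cluster_gromos(trr, integer(0), 1), "empty")
})

test_that("trajectory PDB round trip preserves coordinates and annotations", {
  traj <- gen_toy_solvated_frames(8, box = c(15, 15, 15), n_frames = 3,
                                  seed = 6,
                                  solute = data.frame(x = 7, y = 7, z = 7,
                                                      charge = -1))
  path <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, path)
  back <- read_trajectory_pdb(path, box = c(15, 15, 15))
  expect_equal(dim(back$coords), dim(traj$coords))
  expect_equal(back$coords, traj$coords, tolerance = 1e-3) # PDB precision
  expect_equal(sum(back$atoms$is_water), 8)
  unlink(path)
})

test_that("OpenDX export writes a well-formed text grid", {
  traj <- gen_toy_solvated_frames(5, box = c(10, 10, 10), n_frames = 2,
                                  seed = 1)
  m <- water_occupancy_map(traj, spacing = 2)
  path <- tempfile(fileext = ".dx")
  write_opendx(m, path)
  lines <- readLines(path)
  expect_match(lines[1], "gridpositions counts 5 5 5")
  expect_match(lines[7], "items 125")
  unlink(path)
})
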