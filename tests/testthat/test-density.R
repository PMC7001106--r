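# Occupancy density maps: deposition, conservation, normalization; site
# detection: connectivity, ordering, thresholds.

static_traj <- function(coords_list, particles = NULL, box = c(4, 4, 2)) {
  n <- nrow(coords_list[[1]])
  if (is.null(particles)) {
    particles <- data.frame(id = seq_len(n), role = "lipid_head",
                            species = "PIP2", residue_label = "", chain = "")
  }
  sys <- membrane_system(particles, coords_list[[1]], box)
  frames <- lapply(seq_along(coords_list), function(i)
    traj_frame((i - 1) * 0.1, coords_list[[i]], box))
  trajectory(sys, frames)
}

test_that("a static particle occupies a single voxel with mass one", {
  co <- matrix(c(1.23, 2.31, 0.5), 1)
  traj <- static_traj(rep(list(co), 100))
  map <- occupancy_density(traj, role = "lipid_head", spacing = 0.1)
  expect_equal(max(map$values), 1.0)
  expect_equal(sum(map$values > 0), 1)
  expect_equal(sum(map$values), 1.0)
})

test_that("a particle alternating between two voxels splits its mass 0.5/0.5", {
  a <- matrix(c(1.05, 1.05, 0.5), 1)
  b <- matrix(c(2.55, 1.05, 0.5), 1)
  traj <- static_traj(rep(list(a, b), 50))
  map <- occupancy_density(traj, spacing = 0.1)
  occupied <- sort(map$values[map$values > 0])
  expect_equal(occupied, c(0.5, 0.5))
  expect_equal(sum(map$values), 1.0)
})

test_that("grid mass equals the mean selected particle count per frame", {
  set.seed(23)
  n <- 7
  frames <- lapply(1:50, function(i)
    cbind(stats::runif(n) * 4, stats::runif(n) * 4, stats::runif(n) * 2))
  particles <- data.frame(id = 1:n, role = "lipid_head",
                          species = sample(c("PIP2", "PS"), n, replace = TRUE),
                          residue_label = "", chain = "")
  traj <- static_traj(frames, particles)
  # brute-force per-frame tally of the selection
  n_pip2 <- sum(particles$species == "PIP2")
  map <- occupancy_density(traj, species = "PIP2", spacing = 0.13)
  expect_equal(sum(map$values), n_pip2, tolerance = 1e-9)
  raw <- occupancy_density(traj, species = "PIP2", spacing = 0.13,
                           normalization = "raw_counts")
  expect_equal(sum(raw$values), n_pip2 * 50)
})

test_that("density mass is conserved in expectation under frame subsampling", {
  set.seed(31)
  n <- 5
  frames <- lapply(1:60, function(i)
    cbind(stats::runif(n) * 4, stats::runif(n) * 4, stats::runif(n) * 2))
  traj <- static_traj(frames)
  full <- occupancy_density(traj, spacing = 0.1)
  sub <- trajectory(traj$system, traj$frames[seq(1, 60, by = 3)])
  sub_map <- occupancy_density(sub, spacing = 0.1)
  expect_equal(sum(sub_map$values), sum(full$values), tolerance = 1e-9)
})

test_that("bad selections and parameters are rejected", {
  traj <- static_traj(rep(list(matrix(c(1, 1, 0.5), 1)), 3))
  expect_error(occupancy_density(traj, species = "GM3"), "empty selection")
  expect_error(occupancy_density(traj, spacing = 0), "spacing")
  map <- occupancy_density(traj)
  expect_error(detect_sites(map, threshold = 0), "threshold")
  expect_error(detect_sites(map, threshold = 1.5), "threshold")
})

test_that("a single Gaussian blob yields one site at its mode", {
  set.seed(7)
  vals <- array(0, dim = c(20, 20, 3))
  for (i in 1:20) for (j in 1:20) {
    vals[i, j, 2] <- exp(-((i - 10.5)^2 + (j - 6.5)^2) / 8)
  }
  map <- memsite:::new_density_map(c(0, 0, 0), 0.1, vals, 1L, "per_frame_mean")
  sites <- detect_sites(map, threshold = 0.5)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$x, 1.0, tolerance = 0.05)   # mode between voxels 10, 11
  expect_equal(sites$y, 0.6, tolerance = 0.05)
})

test_that("a uniform map at threshold 1 forms one 6-connected component", {
  vals <- array(1, dim = c(3, 4, 2))
  map <- memsite:::new_density_map(c(0, 0, 0), 0.1, vals, 1L, "per_frame_mean")
  sites <- detect_sites(map, threshold = 1.0)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$n_voxels, 24)
})

test_that("diagonal voxels are separate components (6-connectivity)", {
  vals <- array(0, dim = c(4, 4, 1))
  vals[1, 1, 1] <- 1; vals[2, 2, 1] <- 0.9   # touch only at a corner
  vals[4, 4, 1] <- 0.8
  map <- memsite:::new_density_map(c(0, 0, 0), 0.1, vals, 1L, "per_frame_mean")
  sites <- detect_sites(map, threshold = 0.5)
  expect_equal(nrow(sites), 3)
  # deterministic ordering: by peak descending
  expect_equal(sites$peak, c(1, 0.9, 0.8))
})

test_that("the absolute peak floor suppresses diffuse noise densities", {
  set.seed(3)
  n <- 6
  frames <- lapply(1:40, function(i)
    cbind(stats::runif(n) * 4, stats::runif(n) * 4, 0.5))
  traj <- static_traj(frames)
  map <- occupancy_density(traj, spacing = 0.1)
  expect_equal(nrow(detect_sites(map, threshold = 0.5, min_peak = 0.5)), 0)
  expect_gt(nrow(detect_sites(map, threshold = 0.5)), 0)
})
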