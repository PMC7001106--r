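# Brownian-dynamics surrogate: frozen limit, Einstein relation,
# equipartition in a harmonic trap, Boltzmann occupancy of a planted well,
# composition conservation and seed determinism.

free_system <- function(n, box = c(40, 40, 6), seed = 1) {
  set.seed(seed)
  particles <- data.frame(id = seq_len(n), role = "lipid_head",
                          species = "POPC", residue_label = "", chain = "")
  membrane_system(particles,
                  cbind(stats::runif(n) * box[1], stats::runif(n) * box[2],
                        box[3] / 2), box)
}

test_that("zero diffusion leaves every frame at the start configuration", {
  sys <- free_system(10)
  traj <- simulate_dynamics(sys, params = dynamics_params(
    D = 0, n_steps = 50L, save_every = 10L, seed = 4))
  for (f in traj$frames) expect_equal(f$coordinates, sys$coordinates)
})

test_that("free diffusion follows the Einstein relation MSD = 4 D t", {
  sys <- free_system(500, seed = 8)
  D <- 0.1
  traj <- simulate_dynamics(sys, params = dynamics_params(
    D = D, dt = 0.01, n_steps = 10000L, save_every = 500L, seed = 22))
  msd <- ensemble_msd(traj)
  late <- msd[msd$time >= 20, ]
  ratios <- late$msd / (4 * D * late$time)
  expect_lt(abs(mean(ratios) - 1), 0.10)   # Einstein relation on average
  expect_true(all(abs(ratios - 1) < 0.25)) # no frame wildly off
})

test_that("a harmonic trap equilibrates to variance kT/k (equipartition)", {
  sys <- free_system(1)
  sys$coordinates[1, 1:2] <- c(20, 20)
  k <- 50
  bias <- bias_spec("umbrella", axis = c(1, 0), center = 0, k = k,
                    origin = c(20, 20), particle_ids = 1L)
  lat <- bias_spec("lateral_restraint", axis = c(1, 0), k = k,
                   origin = c(20, 20), particle_ids = 1L)
  traj <- simulate_dynamics(sys, biases = list(bias, lat),
                            params = dynamics_params(
                              D = 0.1, dt = 0.002, n_steps = 60000L,
                              save_every = 5L, seed = 13))
  x <- t(vapply(traj$frames, function(f) f$coordinates[1, 1:2], numeric(2)))
  x <- x[-(1:500), ]                    # discard equilibration
  target <- kT(310) / k
  expect_equal(stats::var(x[, 1]), target, tolerance = 0.10)
  expect_equal(stats::var(x[, 2]), target, tolerance = 0.10)
})

test_that("unbiased sampling of a planted well matches Boltzmann occupancy", {
  # occupancy ratio between the core (r < sigma) and a bulk shell must match
  # the quadrature of exp(-U/kT) over the same regions
  depth <- 5; sigma <- 0.4
  box <- c(8, 8, 6)
  n <- 30
  sys <- free_system(n, box = box, seed = 3)
  well <- site_well(anchor = c(4, 4), depth = depth, sigma = sigma)
  traj <- simulate_dynamics(sys, potentials = list(well),
                            params = dynamics_params(
                              D = 0.1, dt = 0.005, n_steps = 60000L,
                              save_every = 10L, seed = 17))
  r_all <- unlist(lapply(traj$frames[-(1:2000)], function(f) {
    d <- min_image_displacement(f$coordinates, c(4, 4, 0), box)[, 1:2]
    sqrt(rowSums(d^2))
  }))
  shell <- c(1.5, 2.0)
  obs <- sum(r_all < sigma) / sum(r_all >= shell[1] & r_all < shell[2])
  boltz <- function(lo, hi) {
    stats::integrate(function(r)
      2 * pi * r * exp(depth * exp(-r^2 / (2 * sigma^2)) / kT(310)),
      lo, hi, rel.tol = 1e-10)$value
  }
  expected <- boltz(0, sigma) / boltz(shell[1], shell[2])
  expect_equal(obs, expected, tolerance = 0.15)
})

test_that("composition is conserved and identical seeds reproduce bit-identically", {
  spec <- bilayer_spec(lipids_per_leaflet = 30)
  sys <- build_bilayer(spec, seed = 6)
  pots <- list(site_well(c(6, 6), 10, 0.4, species = "PIP2"))
  run <- function() simulate_dynamics(sys, pots, params = dynamics_params(
    n_steps = 400L, save_every = 40L, seed = 99))
  t1 <- run(); t2 <- run()
  expect_identical(coord_array(t1), coord_array(t2))
  expect_identical(t1$system$particles$species, sys$particles$species)
  # a different seed diverges
  t3 <- simulate_dynamics(sys, pots, params = dynamics_params(
    n_steps = 400L, save_every = 40L, seed = 100))
  expect_false(identical(coord_array(t1), coord_array(t3)))
})

test_that("anchors and protein particles never move", {
  site <- make_planted_site_system(20, 0.3, species = "PIP2")
  bl <- build_bilayer(bilayer_spec(lipids_per_leaflet = 10), seed = 1)
  sys <- merge_systems(site$anchor_system, bl)
  traj <- simulate_dynamics(sys, site$potentials, params = dynamics_params(
    n_steps = 200L, save_every = 50L, seed = 2))
  fixed <- sys$particles$role %in% c("protein", "site_anchor")
  for (f in traj$frames) {
    expect_equal(f$coordinates[fixed, ], sys$coordinates[fixed, ])
  }
})

test_that("unstable step sizes are rejected at construction", {
  expect_error(dynamics_params(D = 1, dt = 0.1, min_sigma = 0.3),
               "unstable")
})
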