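# Window ladder generation and the umbrella sampler's statistical behaviour.

test_that("default window ladder matches the reference protocol", {
  spec <- umbrella_spec()
  centers <- generate_windows(spec)
  expect_length(centers, 38)
  expect_equal(centers[1], -0.7)
  expect_equal(centers[38], 3.0)
  expect_equal(unique(round(diff(centers), 10)), 0.1)
  expect_equal(generate_windows(umbrella_spec(n_windows = 2)), c(-0.7, 3.0))
  expect_error(umbrella_spec(n_windows = 1), "at least 2")
  expect_error(umbrella_spec(k = 0), "force constant")
})

flat_umbrella <- function(spec, seed = 5, dt = 0.002) {
  site <- make_test_well(0)            # wall only; windows >= 0 never feel it
  rc <- reaction_coordinate(anchor_ids = 1L, axis = c(1, 0))
  run_umbrella_sampling(site$anchor_system, list(), rc, spec,
                        params = dynamics_params(dt = dt, save_every = 1L),
                        seed = seed)
}

test_that("the stiff-spring limit pins samples at the window centres", {
  spec <- umbrella_spec(n_windows = 5, range = c(0, 2), k = 1e6,
                        steps_per_window = 2000L, burn_in_fraction = 0.25)
  uset <- flat_umbrella(spec, dt = 5e-6)
  for (w in uset$windows) {
    expect_lt(stats::sd(w$samples), 0.01)
    expect_equal(mean(w$samples), w$center, tolerance = 0.01)
  }
})

test_that("on a flat landscape each window samples variance kT/k", {
  spec <- umbrella_spec(steps_per_window = 20000L)
  uset <- flat_umbrella(spec)
  vars <- vapply(uset$windows, function(w) stats::var(w$samples), numeric(1))
  target <- kT(310) / spec$k           # 0.005155 nm^2 at k = 500
  expect_equal(target, 0.005155, tolerance = 1e-4)
  expect_equal(mean(vars), target, tolerance = 0.10)
  expect_true(all(abs(vars / target - 1) < 0.4))
})

test_that("windows in a planted well are pulled toward the minimum and overlap", {
  site <- make_test_well(37)
  rc <- reaction_coordinate(anchor_ids = 1L, axis = c(1, 0))
  spec <- umbrella_spec(steps_per_window = 6000L)
  uset <- run_umbrella_sampling(site$anchor_system, site$potentials, rc, spec,
                                seed = 3)
  expect_length(uset$windows, 38)
  # restoring-force sanity: the window mean sits between the window centre
  # and the unbiased minimum (s = 0) wherever the well force is felt
  for (w in uset$windows) {
    if (abs(w$center) <= 0.6 && abs(w$center) > 0.05) {
      m <- mean(w$samples)
      expect_true((m - 0) * (m - w$center) <= 1e-6)
    }
  }
  expect_true(all(window_overlap(uset) >= 0.05))
})

test_that("identical seeds give identical window samples", {
  spec <- umbrella_spec(n_windows = 6, steps_per_window = 1000L)
  u1 <- flat_umbrella(spec, seed = 42)
  u2 <- flat_umbrella(spec, seed = 42)
  expect_identical(u1$windows, u2$windows)
})

test_that("the finite lateral-restraint mode also samples the ladder", {
  site <- make_test_well(10)
  rc <- reaction_coordinate(anchor_ids = 1L, axis = c(1, 0))
  spec <- umbrella_spec(n_windows = 8, range = c(0, 1.4),
                        steps_per_window = 3000L, lateral_mode = "restraint")
  uset <- run_umbrella_sampling(site$anchor_system, site$potentials, rc, spec,
                                seed = 11)
  expect_length(uset$windows, 8)
  expect_true(all(is.finite(unlist(lapply(uset$windows, `[[`, "samples")))))
})
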