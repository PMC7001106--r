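# WHAM reconstruction against analytic oracles, well-depth extraction, ddG
# arithmetic, convergence checkpoints and bootstrap errors.

test_that("WHAM recovers a quadratic landscape from exact window samples", {
  a <- 20                                   # kJ/mol/nm^2 landscape curvature
  centers <- seq(-1, 1, by = 0.1)
  uset <- oracle_harmonic_umbrella(a, k = 500, centers, n_per_window = 4000,
                                   seed = 31)
  pmf <- wham(uset, bin_width = 0.05, bulk_interval = c(-0.1, 0.1))
  # analytic profile, referenced the same way as the estimate
  g_true <- 0.5 * a * pmf$s^2
  bulk <- pmf$s >= -0.1 & pmf$s <= 0.1
  g_true <- g_true - mean(g_true[bulk])
  inner <- abs(pmf$s) <= 0.9               # edges of the ladder are undersampled
  expect_lt(max(abs(pmf$G[inner] - g_true[inner])), 0.5)
})

test_that("WHAM equals direct Boltzmann inversion on one densely sampled window", {
  # single window, known bias: unbiasing by WHAM must match reweighting the
  # histogram by exp(+beta w) and inverting
  set.seed(77)
  k <- 30; cc <- 0.4; a <- 10
  kbt <- KBT310
  n <- 2e5
  s <- stats::rnorm(n, mean = k * cc / (a + k), sd = sqrt(kbt / (a + k)))
  uset <- list(windows = list(list(center = cc, k = k, samples = s)), kT = kbt)
  pmf <- wham(uset, bin_width = 0.02, bulk_interval = c(0.0, 0.2))
  h <- hist(s, breaks = pmf$breaks, plot = FALSE)
  keep <- h$counts >= 25                   # the profile's own bin filter
  g_direct <- (-kbt * log(h$counts) - 0.5 * k * (h$mids - cc)^2)[keep]
  expect_equal(h$mids[keep], pmf$s)        # same occupied bins
  # profiles agree up to their additive reference: anchor both at bin 1
  expect_lt(max(abs((pmf$G - pmf$G[1]) - (g_direct - g_direct[1]))), 0.1)
})

test_that("a flat landscape reconstructs to |G| below 1 kJ/mol", {
  uset <- oracle_harmonic_umbrella(a = 0, k = 500,
                                   centers = seq(0, 2, by = 0.1),
                                   n_per_window = 3000, seed = 8)
  pmf <- wham(uset, bulk_interval = c(1.5, 2.0))
  inner <- pmf$s >= 0 & pmf$s <= 2
  expect_lt(max(abs(pmf$G[inner])), 1)
})

test_that("well depth is min(G) relative to the bulk mean", {
  prof <- structure(list(s = seq(0.05, 0.55, by = 0.1),
                         G = c(0, -5, -10, -3, 0, 0),
                         error = rep(NA_real_, 6), bin_width = 0.1,
                         bulk_interval = c(0.4, 0.6), kT = KBT310),
                    class = "pmf_profile")
  expect_equal(well_depth(prof), -10)
  flat <- prof; flat$G <- rep(0, 6)
  expect_equal(well_depth(flat), 0)
  expect_error(well_depth(prof, bulk_interval = c(5, 6)), "outside")
  # ddG arithmetic on printed depths: -37 vs -20 gives +17; -37 vs -28 gives +9
  mk <- function(depth) {
    p <- prof; p$G <- c(0, depth / 2, depth, depth / 2, 0, 0); p
  }
  expect_equal(ddg_from_pmfs(mk(-37), mk(-20)), 17)
  expect_equal(ddg_from_pmfs(mk(-37), mk(-28)), 9)
  expect_equal(ddg_from_pmfs(mk(-20), mk(-20)), 0)
})

test_that("non-overlapping ladders fail with the gap location", {
  set.seed(4)
  kbt <- KBT310
  mk <- function(cc) list(center = cc, k = 5000,
                          samples = stats::rnorm(500, cc, sqrt(kbt / 5000)))
  uset <- list(windows = list(mk(0), mk(2)), kT = kbt)
  expect_error(wham(uset, bin_width = 0.05, bulk_interval = c(1.9, 2.1),
                    max_iter = 200),
               "overlap|converge")
})

test_that("convergence checkpoints: identical halves deviate by zero", {
  set.seed(91)
  centers <- seq(0, 1, by = 0.1)
  kbt <- KBT310
  half <- lapply(centers, function(cc)
    stats::rnorm(1000, cc, sqrt(kbt / 400)))
  uset <- list(windows = lapply(seq_along(centers), function(i)
    list(center = centers[i], k = 400,
         samples = rep(half[[i]], 2))),    # second half repeats the first
    kT = kbt)
  conv <- convergence_by_duration(uset, checkpoints = c(1000, 2000),
                                  bulk_interval = c(0.8, 1.0))
  expect_equal(conv$max_deviation, 0, tolerance = 1e-9)
  # unsorted checkpoint lists are sorted internally
  conv2 <- convergence_by_duration(uset, checkpoints = c(2000, 1000),
                                   bulk_interval = c(0.8, 1.0))
  expect_equal(conv2$checkpoints, c(1000, 2000))
  expect_error(convergence_by_duration(uset, checkpoints = 5000,
                                       bulk_interval = c(0.8, 1.0)),
               "exceeds")
})

test_that("deviation between checkpoints shrinks as sampling grows", {
  site <- make_test_well(15)
  rc <- reaction_coordinate(1L, c(1, 0))
  spec <- umbrella_spec(n_windows = 16, range = c(-0.3, 1.8),
                        steps_per_window = 12000L)
  uset <- run_umbrella_sampling(site$anchor_system, site$potentials, rc, spec,
                                seed = 5)
  conv <- convergence_by_duration(uset, checkpoints = c(300, 3000, 9000),
                                  bulk_interval = c(1.4, 1.8))
  expect_lt(conv$max_deviation[2], conv$max_deviation[1])
})

test_that("bootstrap depth error is zero for zero-variance samples", {
  kbt <- KBT310
  centers <- seq(0, 1, by = 0.25)
  uset <- list(windows = lapply(centers, function(cc)
    list(center = cc, k = 400, samples = rep(cc, 200))), kT = kbt)
  expect_identical(bootstrap_well_depth_error(uset, n_boot = 4, seed = 2), 0)
})

test_that("bootstrap error tracks the seed-to-seed depth scatter", {
  site <- make_test_well(10)
  rc <- reaction_coordinate(1L, c(1, 0))
  spec <- umbrella_spec(n_windows = 16, range = c(-0.3, 1.8),
                        steps_per_window = 5000L)
  run_depth <- function(seed) {
    uset <- run_umbrella_sampling(site$anchor_system, site$potentials, rc,
                                  spec, seed = seed)
    well_depth(wham(uset, bulk_interval = c(1.4, 1.8)))
  }
  depths <- vapply(1:6, run_depth, numeric(1))
  sd_repeat <- stats::sd(depths)
  uset1 <- run_umbrella_sampling(site$anchor_system, site$potentials, rc,
                                 spec, seed = 1)
  sd_boot <- bootstrap_well_depth_error(uset1, n_boot = 8, seed = 3,
                                        bulk_interval = c(1.4, 1.8))
  expect_gt(sd_boot, sd_repeat / 3)
  expect_lt(sd_boot, sd_repeat * 3)
})
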