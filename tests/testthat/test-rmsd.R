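# Kabsch superposition and superposition-based ligand RMSD series.

test_that("identical coordinate sets give identity transform and zero RMSD", {
  set.seed(2)
  x <- matrix(stats::runif(15, 0, 5), 5)
  sp <- superpose(x, x)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sp$translation, c(0, 0, 0), tolerance = 1e-10)
})

test_that("a known rigid motion is recovered exactly", {
  set.seed(6)
  x <- matrix(stats::runif(24, 0, 5), 8)
  for (rep in 1:5) {
    m <- random_rigid_motion()
    y <- apply_rigid(x, m)
    sp <- superpose(x, y)
    expect_equal(sp$rmsd, 0, tolerance = 1e-9)
    expect_equal(sp$apply(y), x, tolerance = 1e-9)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  }
})

test_that("fit RMSD is invariant under rigid pre-transformation of the mobile set", {
  set.seed(14)
  ref <- matrix(stats::runif(30, 0, 5), 10)
  mob <- ref + matrix(stats::rnorm(30, sd = 0.1), 10)
  base <- superpose(ref, mob)$rmsd
  for (rep in 1:8) {
    m <- random_rigid_motion()
    expect_equal(superpose(ref, apply_rigid(mob, m))$rmsd, base,
                 tolerance = 1e-9)
  }
})

test_that("superposition matches an independent reference implementation", {
  set.seed(27)
  ref <- matrix(stats::runif(30, 0, 5), 10)
  mob <- ref + matrix(stats::rnorm(30, sd = 0.15), 10)
  ours <- superpose(ref, mob)
  # bio3d's least-squares fit as the independent oracle
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(ref)),
                                            mobile = as.vector(t(mob))))
  theirs <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) -
                                 ref)^2)))
  expect_equal(ours$rmsd, theirs, tolerance = 1e-6)
})

test_that("degenerate fit sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))  # collinear points
  expect_error(superpose(line, line + 0.1), "collinear")
  expect_error(superpose(matrix(1:6, 2), matrix(1:6, 2)), "3 fit particles")
})

test_that("zero-drift fixtures give identically-zero RMSD series", {
  tr <- make_geometry_fixtures("ligand_pose", n_frames = 40, drift = 0)
  roles <- attr(tr, "pose_roles")
  ser <- ligand_rmsd_series(tr, roles$copies, roles$fit)
  expect_lt(max(as.matrix(ser[, -1])), 1e-10)
  expect_true(all(ser[1, -1] == 0))    # reference frame exactly zero
})

test_that("a scripted rigid displacement appears as a step in the series", {
  tr <- make_geometry_fixtures("ligand_pose", n_frames = 100, drift = 0.2)
  roles <- attr(tr, "pose_roles")
  ser <- ligand_rmsd_series(tr, roles$copies, roles$fit)
  expect_equal(ser$copy_1, rep(0, 100))              # multiplier 0: no drift
  # copy 3 drifts rigidly by 0.2 nm from the half-way frame on
  expect_equal(ser$copy_3[1:50], rep(0, 50))
  expect_equal(ser$copy_3[51:100], rep(0.2, 50), tolerance = 1e-9)
  expect_equal(ser$copy_4[51:100], rep(0.4, 50), tolerance = 1e-9)
  expect_equal(ser[1, -1], data.frame(copy_1 = 0, copy_2 = 0, copy_3 = 0,
                                      copy_4 = 0))   # reference frame: exact 0
})

test_that("jittered copies show heterogeneous stability like mixed binding", {
  tr <- make_geometry_fixtures("ligand_pose", n_frames = 80, drift = 0.3,
                               jitter = 0.02, seed = 5)
  roles <- attr(tr, "pose_roles")
  ser <- ligand_rmsd_series(tr, roles$copies, roles$fit)
  maxes <- apply(as.matrix(ser[, -1]), 2, max)
  expect_gt(max(maxes), 2 * min(maxes))
  # missing ligand particles are an error
  expect_error(ligand_rmsd_series(tr, list(c(999L)), roles$fit), "missing")
  expect_error(ligand_rmsd_series(tr, roles$copies, roles$fit,
                                  reference_frame = 500), "does not exist")
})
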