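# Geometric hydrogen-bond detection and per-residue count series.

test_that("criterion construction validates its thresholds", {
  expect_error(hbond_criterion(max_distance = 0), "max_distance")
  expect_error(hbond_criterion(max_angle = 0), "max_angle")
  expect_error(hbond_criterion(max_angle = 120), "max_angle")
})

test_that("collinear donors bond at 0.28 nm but not at 0.50 nm", {
  box <- c(5, 5, 5)
  co <- rbind(c(1.0, 1.0, 1.0),   # donor
              c(1.1, 1.0, 1.0),   # hydrogen on the D-A axis
              c(1.28, 1.0, 1.0))  # acceptor: d(D,A) = 0.28, deviation 0
  bonds <- detect_hbonds(co, donors = 1, hydrogens = 2, acceptors = 3, box)
  expect_equal(nrow(bonds), 1)
  expect_equal(bonds$distance, 0.28)
  expect_lt(bonds$deviation, 1e-6)
  co2 <- co; co2[3, 1] <- 1.50    # same geometry at 0.50 nm
  expect_equal(nrow(detect_hbonds(co2, 1, 2, 3, box)), 0)
  # bent beyond 30 degrees fails even at short range
  co3 <- co
  co3[2, ] <- c(1.0 + 0.1 * cos(pi / 3), 1.0 + 0.1 * sin(pi / 3), 1.0)
  expect_equal(nrow(detect_hbonds(co3, 1, 2, 3, box)), 0)
})

test_that("hydrogens without donor parents are rejected", {
  co <- matrix(stats::runif(12), 4)
  expect_error(detect_hbonds(co, donors = c(1, 2), hydrogens = 3,
                             acceptors = 4, box = c(5, 5, 5)),
               "parallel|parent")
})

test_that("detection matches brute force over all donor-acceptor pairs", {
  # independent oracle: explicit distance and angle evaluation per pair
  set.seed(44)
  box <- c(6, 6, 6)
  crit <- hbond_criterion()
  for (rep in 1:10) {
    nd <- 3; na_ <- 2
    D <- matrix(stats::runif(3 * nd, 1, 3), nd)
    H <- D + matrix(stats::rnorm(3 * nd, sd = 0.06), nd)
    A <- matrix(stats::runif(3 * na_, 1, 3), na_)
    co <- rbind(D, H, A)
    bonds <- detect_hbonds(co, donors = 1:nd, hydrogens = nd + (1:nd),
                           acceptors = 2 * nd + (1:na_), box, crit)
    brute <- 0
    for (i in 1:nd) for (j in 1:na_) {
      d_vec <- D[i, ] - A[j, ]
      dist <- sqrt(sum(d_vec^2))
      hd <- D[i, ] - H[i, ]; ha <- A[j, ] - H[i, ]
      ang <- acos(min(1, max(-1, sum(hd * ha) /
                               sqrt(sum(hd^2) * sum(ha^2))))) * 180 / pi
      if (dist <= crit$max_distance && (180 - ang) <= crit$max_angle) {
        brute <- brute + 1
      }
    }
    expect_equal(nrow(bonds), brute)
  }
})

test_that("detection is invariant under global rotation and translation", {
  set.seed(9)
  box <- c(50, 50, 50)                     # large box: wrapping plays no role
  D <- matrix(stats::runif(9, 20, 22), 3)
  H <- D + matrix(stats::rnorm(9, sd = 0.06), 3)
  A <- matrix(stats::runif(6, 20, 22), 2)
  co <- rbind(D, H, A)
  n0 <- nrow(detect_hbonds(co, 1:3, 4:6, 7:8, box))
  for (rep in 1:5) {
    m <- random_rigid_motion()
    m$t <- stats::runif(3, -2, 2)          # stay within the box
    co2 <- apply_rigid(co, m) + 0
    n1 <- nrow(detect_hbonds(co2, 1:3, 4:6, 7:8, box))
    expect_equal(n1, n0)
  }
})

test_that("the hbond fixture contains exactly two bonds by construction", {
  tr <- make_geometry_fixtures("hbond")
  roles <- attr(tr, "hbond_roles")
  bonds <- detect_hbonds(tr$frames[[1]]$coordinates, roles$donors,
                         roles$hydrogens, roles$acceptors,
                         tr$frames[[1]]$box)
  expect_equal(nrow(bonds), 2)
  # regeneration with the same seed is bit-identical
  tr2 <- make_geometry_fixtures("hbond")
  expect_identical(tr$frames[[1]]$coordinates, tr2$frames[[1]]$coordinates)
})

test_that("per-residue series step when a scripted bond breaks", {
  tr <- make_geometry_fixtures("hbond")
  roles <- attr(tr, "hbond_roles")
  sys <- tr$system
  frames <- lapply(1:100, function(f) {
    co <- tr$frames[[1]]$coordinates
    if (f >= 50) co[7, 1] <- co[7, 1] + 1.0   # pull acceptor A1 away
    traj_frame((f - 1) * 0.1, co, sys$box)
  })
  traj2 <- trajectory(sys, frames)
  ser <- hbond_series(traj2, sys$particles$id[roles$donors],
                      sys$particles$id[roles$hydrogens],
                      sys$particles$id[roles$acceptors])
  expect_equal(unname(ser[["R504"]][1:49]), rep(1L, 49))
  expect_equal(unname(ser[["R504"]][50:100]), rep(0L, 51))
  expect_equal(unname(ser[["K572"]]), rep(1L, 100))  # untouched bond persists
  # TSV export round-trips
  path <- tempfile(fileext = ".tsv")
  hbond_series(traj2, sys$particles$id[roles$donors],
               sys$particles$id[roles$hydrogens],
               sys$particles$id[roles$acceptors], path = path)
  back <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
  expect_equal(back[["R504"]], ser[["R504"]])
})

test_that("an empty residue set warns and returns an empty table", {
  tr <- make_geometry_fixtures("hbond")
  roles <- attr(tr, "hbond_roles")
  expect_warning(
    out <- hbond_series(tr, roles$donors, roles$hydrogens, roles$acceptors,
                        residues = character(0)),
    "empty residue set")
  expect_equal(names(out), "time")
})
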