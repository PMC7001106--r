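# Distance-to-site traces and dual-cutoff contact statistics.

anchor_system <- function(lipid_xy, box = c(6, 6, 2), anchor_xy = c(3, 3)) {
  particles <- data.frame(
    id = 1:2, role = c("site_anchor", "lipid_head"),
    species = c("ANCHOR", "PIP2"), residue_label = c("S505", ""),
    chain = "A")
  membrane_system(particles, rbind(c(anchor_xy, 1), c(lipid_xy, 1)), box)
}

test_that("a lipid at the anchor gives an identically-zero distance series", {
  sys <- anchor_system(c(3, 3))
  frames <- lapply(1:5, function(i) traj_frame(i - 1, sys$coordinates, sys$box))
  traj <- trajectory(sys, frames)
  ser <- distance_to_site_series(traj, species = "PIP2")
  expect_equal(ser$distance, rep(0, 5))
})

test_that("site distances use the minimum image", {
  # anchor at the origin corner, lipid at (L - 0.5, 0): true distance 0.5 nm
  box <- c(6, 6, 2)
  sys <- anchor_system(c(5.5, 0), box = box, anchor_xy = c(0, 0))
  traj <- trajectory(sys, list(traj_frame(0, sys$coordinates, box),
                               traj_frame(1, sys$coordinates, box)))
  ser <- distance_to_site_series(traj, species = "PIP2")
  expect_equal(ser$distance, rep(0.5, 2))
})

test_that("empty lipid selections are an error", {
  sys <- anchor_system(c(3, 3))
  traj <- trajectory(sys, list(traj_frame(0, sys$coordinates, sys$box)))
  expect_error(distance_to_site_series(traj, species = "CHOL"),
               "empty lipid selection")
})

test_that("dual-cutoff events match the scripted pattern", {
  # 10 ns inside, 5 ns outside, 5 ns inside at dt = 1 ns -> events 10 and 5
  d <- c(rep(0.3, 10), rep(1.5, 5), rep(0.3, 5))
  ev <- contact_events(d, dt = 1, on_cutoff = 0.55, off_cutoff = 1.0)
  expect_equal(ev, c(10, 5))
  expect_equal(mean(ev), 7.5)
  # always inside: one full-length event; never inside: none
  expect_equal(contact_events(rep(0.1, 20), 1), 20)
  expect_equal(length(contact_events(rep(2, 20), 1)), 0)
  # the buffer zone keeps an open event alive but cannot open one
  d2 <- c(rep(0.3, 3), rep(0.7, 4), rep(0.3, 3), rep(1.5, 2))
  expect_equal(contact_events(d2, 1), 10)
  expect_equal(length(contact_events(rep(0.7, 10), 1)), 0)
  expect_error(contact_events(d, 1, on_cutoff = 1.0, off_cutoff = 0.5),
               "off_cutoff")
})

test_that("dual-cutoff durations agree with the brute-force state machine", {
  set.seed(12)
  for (rep in 1:25) {
    d <- stats::runif(200, 0, 2)
    ev <- contact_events(d, dt = 0.5, on_cutoff = 0.55, off_cutoff = 1.0)
    expect_equal(ev, oracle_dual_cutoff(d, 0.5, 0.55, 1.0))
  }
})

test_that("total contact time is monotone non-decreasing in off_cutoff", {
  set.seed(19)
  for (rep in 1:10) {
    d <- stats::runif(300, 0, 2)
    offs <- c(0.6, 0.8, 1.0, 1.4, 1.8)
    tot <- vapply(offs, function(off)
      sum(contact_events(d, 1, on_cutoff = 0.55, off_cutoff = off)),
      numeric(1))
    expect_true(all(diff(tot) >= 0))
  }
})

test_that("per-residue tables aggregate events over lipid molecules", {
  # two residues; lipid 1 oscillates near R1, lipid 2 sits on R2 throughout
  box <- c(8, 8, 2)
  particles <- data.frame(
    id = 1:4,
    role = c("protein", "protein", "lipid_head", "lipid_head"),
    species = c("PROT", "PROT", "PIP2", "PIP2"),
    residue_label = c("R504", "K572", "", ""), chain = "A")
  base <- rbind(c(2, 2, 1), c(6, 6, 1), c(2, 2.3, 1), c(6, 6.3, 1))
  nf <- 12
  frames <- lapply(seq_len(nf), function(i) {
    co <- base
    if (i > 4 && i <= 8) co[3, 2] <- 4.0    # lipid 1 leaves R504 for 4 frames
    traj_frame((i - 1) * 1.0, co, box)
  })
  sys <- membrane_system(particles, base, box)
  traj <- trajectory(sys, frames)
  tab <- residue_contact_durations(traj, "PIP2", on_cutoff = 0.55,
                                   off_cutoff = 1.0)
  r1 <- tab[tab$residue == "R504", ]
  r2 <- tab[tab$residue == "K572", ]
  expect_equal(r1$n_events, 2)
  expect_equal(sort(c(r1$mean_duration * r1$n_events)), 8)  # 4 + 4 ns
  expect_equal(r2$n_events, 1)
  expect_equal(r2$max_duration, 12)
  expect_equal(r2$occupancy, 1)
  expect_true(all(tab$mean_duration <= tab$max_duration))
  expect_true(all(tab$occupancy >= 0 & tab$occupancy <= 1))
})

test_that("contact reports scale mean durations onto [0, 1]", {
  tab <- data.frame(residue = c("A", "B", "C"), species = "PIP2",
                    mean_duration = c(0, 5, 10), max_duration = c(0, 6, 12),
                    n_events = c(0L, 2L, 3L), occupancy = c(0, 0.4, 0.9))
  class(tab) <- c("residue_contact_table", class(tab))
  rep1 <- contact_table_report(tab)
  expect_equal(rep1$scale, c(0, 0.5, 1.0))
  tab$mean_duration <- c(4, 4, 4)
  expect_equal(contact_table_report(tab)$scale, c(1, 1, 1))
  tab$mean_duration <- c(0, 0, 0)
  expect_equal(contact_table_report(tab)$scale, c(0, 0, 0))
  # TSV round trip
  path <- tempfile(fileext = ".tsv")
  tab$mean_duration <- c(0, 5, 10)
  contact_table_report(tab, path)
  back <- read_contact_table(path)
  expect_equal(back$scale, c(0, 0.5, 1.0))
  expect_equal(back$residue, c("A", "B", "C"))
})
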