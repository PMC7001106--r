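# Independent oracles used across the suite.  These deliberately avoid the
# package's own evaluation paths: energies are written out from the model
# definitions, integrals use stats::integrate, and exact window samples are
# drawn from the known Gaussian window densities.

KBT310 <- 0.0083145 * 310

# energy of a radial Gaussian well + harmonic core wall along the axis
# through the anchor, written independently of the package's evaluators.
oracle_axis_energy <- function(s, depth, sigma, core_radius = 1.5,
                               wall_k = 200) {
  u <- -depth * exp(-s^2 / (2 * sigma^2))
  # anchor sits on the wall rim: wall is felt for s < 0
  r <- core_radius + s
  u + ifelse(r < core_radius, 0.5 * wall_k * (r - core_radius)^2, 0)
}

# flat-bottom confinement used by the alchemical bound-state definition
oracle_confinement <- function(s, half_width = 1, k = 500) {
  ex <- pmax(abs(s) - half_width, 0)
  0.5 * k * ex^2
}

# quadrature ddG for the planted transformation depth_a -> depth_b under the
# confined 1D Hamiltonian (the truth the MBAR estimate must approach)
oracle_quadrature_ddg <- function(depth_a, depth_b, sigma = 0.3,
                                  temperature = 310) {
  kbt <- 0.0083145 * temperature
  z <- function(depth) {
    stats::integrate(function(s) {
      exp(-(oracle_axis_energy(s, depth, sigma) + oracle_confinement(s)) / kbt)
    }, -6, 6, rel.tol = 1e-10)$value
  }
  -kbt * log(z(depth_b) / z(depth_a))
}

# exact umbrella samples for a quadratic landscape G(s) = a/2 s^2 under bias
# k/2 (s - c)^2: the biased density is Gaussian with precision a + k and mean
# k c / (a + k).  Returns a hand-built umbrella set.
oracle_harmonic_umbrella <- function(a, k, centers, n_per_window,
                                     temperature = 310, seed = 1) {
  set.seed(seed)
  kbt <- 0.0083145 * temperature
  prec <- (a + k) / kbt
  windows <- lapply(centers, function(cc) {
    mu <- k * cc / (a + k)
    list(center = cc, k = k,
         samples = stats::rnorm(n_per_window, mean = mu, sd = sqrt(1 / prec)))
  })
  list(windows = windows, kT = kbt)
}

# hand-built alchemical samples for two harmonic states U_k = kappa_k/2 s^2,
# drawn exactly from their Boltzmann distributions (independent samples)
oracle_harmonic_alchemy <- function(kappas, n_per_state, temperature = 310,
                                    seed = 1) {
  set.seed(seed)
  kbt <- 0.0083145 * temperature
  s_all <- unlist(lapply(kappas, function(kap) {
    stats::rnorm(n_per_state, sd = sqrt(kbt / kap))
  }))
  u <- t(vapply(kappas, function(kap) 0.5 * kap * s_all^2 / kbt,
                numeric(length(s_all))))
  structure(list(lambda = seq(0, 1, length.out = length(kappas)), u = u,
                 N_k = rep(n_per_state, length(kappas)), kT = kbt,
                 samples = s_all),
            class = "alchemical_samples")
}

# brute-force dual-cutoff state machine, written independently (explicit
# per-sample walk with a boolean state)
oracle_dual_cutoff <- function(d, dt, on, off) {
  state <- FALSE
  durs <- c()
  cur <- 0
  for (i in seq_along(d)) {
    if (!state && d[i] < on) {
      state <- TRUE
      cur <- 0
    }
    if (state) {
      cur <- cur + dt
      if (d[i] > off) {
        state <- FALSE
        durs <- c(durs, cur - dt)  # the closing sample is already outside
      }
    }
  }
  if (state) durs <- c(durs, cur)
  durs
}

# random rigid motion: proper rotation from QR + random translation
random_rigid_motion <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = stats::rnorm(3, sd = 2))
}

apply_rigid <- function(x, motion) {
  sweep(as.matrix(x) %*% motion$R, 2, motion$t, `+`)
}

# small planted single-well system reused across free-energy tests
make_test_well <- function(depth, sigma = 0.3) {
  make_planted_site_system(depth, sigma, species = "TAGGED",
                           four_fold = FALSE, box = c(12, 12, 6))
}
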