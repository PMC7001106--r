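# Overdamped (Brownian) dynamics in the membrane plane, the desk-scale
# surrogate for coarse-grained membrane MD.  Update rule:
#   x <- x + (D / k_B T) F dt + sqrt(2 D dt) eta,   eta ~ N(0, 1) per axis.
# Lipids are mutually non-interacting (ideal-dilute surrogate); protein and
# site_anchor particles never move.

#' Brownian dynamics parameters
#'
#' @param D Lateral diffusion coefficient (nm^2/ns). A free surrogate
#'   parameter, not a physical claim; default 0.1 gives fast desk-scale
#'   mixing.
#' @param dt Time step (ns).
#' @param temperature Temperature (K), default 310.
#' @param n_steps Number of integration steps.
#' @param save_every Store every `save_every`-th step (step 0 is always
#'   stored).
#' @param seed Integer RNG seed; identical seed + configuration gives a
#'   bit-identical trajectory.
#' @param min_sigma Width of the narrowest planted well the run will see
#'   (nm); construction fails unless the per-step RMS displacement
#'   `sqrt(2 D dt)` is below `min_sigma / 3` (stability check).
#' @return Object of class `dynamics_params`.
#' @export
dynamics_params <- function(D = 0.1, dt = 0.01, temperature = 310,
                            n_steps = 1000L, save_every = 10L, seed = 1L,
                            min_sigma = 0.3) {
  stopifnot(D >= 0, dt > 0, temperature > 0, n_steps >= 1, save_every >= 1)
  rms <- sqrt(2 * D * dt)
  if (rms >= min_sigma / 3) {
    stop("unstable dynamics: per-step RMS displacement ", signif(rms, 3),
         " nm exceeds min_sigma/3 = ", signif(min_sigma / 3, 3),
         " nm; reduce D*dt")
  }
  structure(list(D = D, dt = dt, temperature = temperature,
                 n_steps = as.integer(n_steps),
                 save_every = as.integer(save_every), seed = as.integer(seed),
                 min_sigma = min_sigma),
            class = "dynamics_params")
}

#' Simulate Brownian dynamics of a membrane system
#'
#' Mobile particles (`lipid_head`, `lipid_tail`, `ligand`) diffuse in the
#' membrane plane under the planted potentials and biases; `protein` and
#' `site_anchor` particles are immobile.  Positions are wrapped into the
#' periodic box.  The initial configuration is stored as frame 1 at time 0.
#'
#' @param system A [membrane_system()] providing particles and start
#'   coordinates.
#' @param potentials List of potential objects ([site_well()],
#'   [protein_wall()]); may be empty for free diffusion.
#' @param biases List of [bias_spec()] objects (may be empty).
#' @param params A [dynamics_params()].
#' @return A [trajectory()] with `1 + floor(n_steps / save_every)` frames.
#' @export
simulate_dynamics <- function(system, potentials = list(), biases = list(),
                              params = dynamics_params()) {
  stopifnot(inherits(system, "membrane_system"),
            inherits(params, "dynamics_params"))
  set.seed(params$seed)
  p <- system$particles
  mobile <- p$role %in% c("lipid_head", "lipid_tail", "ligand")
  x <- system$coordinates
  box <- system$box
  sp_m <- p$species[mobile]
  id_m <- p$id[mobile]
  xm <- x[mobile, , drop = FALSE]
  beta_D_dt <- params$D / kT(params$temperature) * params$dt
  noise_sd <- sqrt(2 * params$D * params$dt)
  n_save <- params$n_steps %/% params$save_every
  frames <- vector("list", 1 + n_save)
  frames[[1]] <- traj_frame(0, x, box)
  k <- 1L
  nm <- sum(mobile)
  for (step in seq_len(params$n_steps)) {
    if (nm > 0 && (length(potentials) || length(biases))) {
      ef <- eval_forces(xm, sp_m, id_m, potentials, biases, box)
      if (any(!is.finite(ef$forces))) {
        stop("simulation aborted: non-finite force at step ", step,
             " (particle at a singular point)")
      }
      xm[, 1:2] <- xm[, 1:2] + beta_D_dt * ef$forces
    }
    if (nm > 0 && params$D > 0) {
      xm[, 1:2] <- xm[, 1:2] + matrix(stats::rnorm(2 * nm, sd = noise_sd), nm, 2)
    }
    if (step %% params$save_every == 0) {
      xm <- wrap_positions(xm, box, system$periodic)
      k <- k + 1L
      xw <- x
      xw[mobile, ] <- xm
      frames[[k]] <- traj_frame(step * params$dt, xw, box)
    }
  }
  trajectory(system, frames[seq_len(k)])
}

#' Ensemble mean-squared displacement
#'
#' MSD(t) averaged over all mobile particles, computed on unwrapped
#' coordinates, relative to the first frame.  For free lateral diffusion the
#' Einstein relation gives `MSD(t) = 4 D t`.
#'
#' @param traj A [trajectory()].
#' @return `data.frame` with columns `time` (ns) and `msd` (nm^2).
#' @export
ensemble_msd <- function(traj) {
  tr <- unwrap_trajectory(traj)
  mobile <- tr$system$particles$role %in% c("lipid_head", "lipid_tail", "ligand")
  x0 <- tr$frames[[1]]$coordinates[mobile, 1:2, drop = FALSE]
  msd <- vapply(tr$frames, function(f) {
    d <- f$coordinates[mobile, 1:2, drop = FALSE] - x0
    mean(rowSums(d^2))
  }, numeric(1))
  data.frame(time = tr$times, msd = msd)
}

#' Deterministic fixtures for the geometric analyses
#'
#' * `kind = "hbond"`: a single frame with three donor/hydrogen pairs and two
#'   acceptors placed so that exactly two pairs satisfy the default geometric
#'   hydrogen-bond criterion (one collinear at 0.28 nm, one at 20 degrees
#'   deviation and 0.30 nm; the third donor sits 0.5 nm away). The donor
#'   metadata is attached as attribute `hbond_roles`.
#' * `kind = "ligand_pose"`: a trajectory of a rigid 4-particle protein core
#'   plus four 3-particle ligand copies; copies drift by a scripted rigid
#'   displacement (`drift` nm, applied from half-time on, scaled 0/0.5/1/2
#'   across copies) with optional positional jitter. Metadata in attribute
#'   `pose_roles`.
#'
#' @param kind `"hbond"` or `"ligand_pose"`.
#' @param n_frames Frames for the ligand-pose trajectory.
#' @param drift Rigid drift amplitude (nm); 0 gives an identically-zero RMSD
#'   series.
#' @param jitter SD of per-frame Gaussian jitter on ligand particles (nm).
#' @param seed RNG seed (fixture regeneration is deterministic).
#' @return A [trajectory()] with fixture metadata attributes.
#' @export
make_geometry_fixtures <- function(kind = c("hbond", "ligand_pose"),
                                   n_frames = 100L, drift = 0.2,
                                   jitter = 0, seed = 1L) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  box <- c(8, 8, 8)
  if (kind == "hbond") {
    # donors D1..D3 (with hydrogens H1..H3) on "protein" residues, acceptors
    # A1..A2 on the lipid head group
    d_ha <- 0.10                       # D-H bond length
    coords <- rbind(
      c(2.00, 2.00, 2.00),             # D1
      c(2.00 + d_ha, 2.00, 2.00),      # H1 pointing at A1 (collinear)
      c(3.00, 3.00, 2.00),             # D2
      c(3.00 + d_ha * cos(0.15), 3.00 + d_ha * sin(0.15), 2.00),  # H2, ~8.6 deg off
      c(5.00, 5.00, 2.00),             # D3 (too far from both acceptors)
      c(5.00 + d_ha, 5.00, 2.00),      # H3
      c(2.28, 2.00, 2.00),             # A1: 0.28 nm from D1, collinear
      c(3.30, 3.00, 2.00)              # A2: 0.30 nm from D2, small deviation
    )
    particles <- data.frame(
      id = 1:8,
      role = c(rep("protein", 6), "lipid_head", "lipid_head"),
      species = c(rep("PROT", 6), "PIP2", "PIP2"),
      residue_label = c("R504", "R504", "K572", "K572", "K595", "K595",
                        "PIP2-1", "PIP2-1"),
      chain = "A", stringsAsFactors = FALSE)
    sys <- membrane_system(particles, coords, box)
    tr <- trajectory(sys, list(traj_frame(0, coords, box)))
    attr(tr, "hbond_roles") <- list(donors = c(1L, 3L, 5L),
                                    hydrogens = c(2L, 4L, 6L),
                                    acceptors = c(7L, 8L))
    return(tr)
  }
  # ligand_pose: rigid protein tetrahedron + 4 triangular ligand copies
  prot <- rbind(c(3, 3, 3), c(5, 3, 3), c(4, 5, 3), c(4, 4, 5))
  lig0 <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(0, 0.3, 0))
  centers <- rbind(c(2.5, 2.5, 4), c(5.5, 2.5, 4), c(5.5, 5.5, 4), c(2.5, 5.5, 4))
  lig <- do.call(rbind, lapply(1:4, function(i) sweep(lig0, 2, centers[i, ], `+`)))
  particles <- data.frame(
    id = seq_len(4 + 12),
    role = c(rep("protein", 4), rep("ligand", 12)),
    species = c(rep("PROT", 4), rep("CHOL", 12)),
    residue_label = c(rep("CORE", 4), rep(paste0("CHOL", 1:4), each = 3)),
    chain = "A", stringsAsFactors = FALSE)
  base <- rbind(prot, lig)
  scale <- c(0, 0.5, 1, 2)             # per-copy drift multiplier
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    co <- base
    if (f > n_frames / 2 && drift != 0) {
      for (i in 1:4) {
        rows <- 4 + (3 * (i - 1) + 1):(3 * i)
        co[rows, ] <- co[rows, ] +
          matrix(drift * scale[i] * dirs[i, ], 3, 3, byrow = TRUE)
      }
    }
    if (jitter > 0) {
      co[5:16, ] <- co[5:16, ] + matrix(stats::rnorm(36, sd = jitter), 12, 3)
    }
    frames[[f]] <- traj_frame((f - 1) * 0.1, co, box)
  }
  sys <- membrane_system(particles, base, box)
  tr <- trajectory(sys, frames)
  attr(tr, "pose_roles") <- list(
    fit = 1:4,
    copies = lapply(1:4, function(i) 4L + (3L * (i - 1L) + 1L):(3L * i)))
  tr
}
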