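# Domain containers: a membrane system (particle table + coordinates + box),
# single frames, and multi-frame trajectories.

PARTICLE_ROLES <- c("protein", "lipid_head", "lipid_tail", "ligand", "site_anchor")

#' Construct a membrane system
#'
#' A membrane system couples a particle table (identity, role, species,
#' residue label, chain) with a coordinate snapshot and a periodic box.
#' Roles follow the surrogate-model convention: `protein` and `site_anchor`
#' particles are immobile in synthetic dynamics, everything else diffuses.
#'
#' @param particles `data.frame` with columns `id` (unique integers), `role`
#'   (one of `r paste(PARTICLE_ROLES, collapse = ", ")`), `species` (string
#'   tag, e.g. `"PIP2"`), `residue_label` (e.g. `"R504"`), `chain`.
#'   Missing `residue_label`/`chain` columns are filled with `""`.
#' @param coordinates n x 3 numeric matrix of positions (nm), one row per
#'   particle, in the particle-table order.
#' @param box Orthorhombic box edges (nm), 3-vector.
#' @param periodic Logical 3-vector of periodic axes (default x, y periodic).
#' @return An object of class `membrane_system`.
#' @export
membrane_system <- function(particles, coordinates, box,
                            periodic = c(TRUE, TRUE, FALSE)) {
  stopifnot(is.data.frame(particles))
  for (col in c("id", "role", "species")) {
    if (!col %in% names(particles)) stop("particle table lacks column '", col, "'")
  }
  if (!"residue_label" %in% names(particles)) particles$residue_label <- ""
  if (!"chain" %in% names(particles)) particles$chain <- ""
  particles$id <- as.integer(particles$id)
  if (anyDuplicated(particles$id)) stop("particle ids must be unique")
  bad <- setdiff(unique(particles$role), PARTICLE_ROLES)
  if (length(bad)) stop("unknown particle role(s): ", paste(bad, collapse = ", "))
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) != nrow(particles) || ncol(coordinates) != 3) {
    stop("coordinates must be an n x 3 matrix matching the particle table")
  }
  box <- as.numeric(box)
  if (length(box) != 3 || any(box <= 0)) stop("box edges must be 3 positive numbers")
  structure(
    list(particles = particles, coordinates = unname(coordinates),
         box = box, periodic = periodic),
    class = "membrane_system"
  )
}

#' @export
print.membrane_system <- function(x, ...) {
  cat("membrane_system:", nrow(x$particles), "particles, box",
      paste(signif(x$box, 4), collapse = " x "), "nm\n")
  print(table(role = x$particles$role))
  invisible(x)
}

#' Construct a single trajectory frame
#'
#' @param time Frame time in ns.
#' @param coordinates n x 3 matrix (nm).
#' @param box Box edges (nm).
#' @return Object of class `traj_frame`.
#' @export
traj_frame <- function(time, coordinates, box) {
  coordinates <- as.matrix(coordinates)
  stopifnot(ncol(coordinates) == 3, length(box) == 3, all(box > 0),
            is.finite(time))
  structure(list(time = time, coordinates = unname(coordinates),
                 box = as.numeric(box)),
            class = "traj_frame")
}

#' Construct a trajectory
#'
#' Frames must share the particle table of `system`, have strictly increasing,
#' uniformly spaced times, and a consistent particle count.
#'
#' @param system A [membrane_system()].
#' @param frames List of [traj_frame()] objects.
#' @return Object of class `trajectory` with elements `system`, `frames`,
#'   `times` and `dt` (ns between stored frames; `NA` for a single frame).
#' @export
trajectory <- function(system, frames) {
  stopifnot(inherits(system, "membrane_system"), length(frames) >= 1)
  np <- nrow(system$particles)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!inherits(f, "traj_frame")) stop("frame ", i, " is not a traj_frame")
    if (nrow(f$coordinates) != np) {
      stop("frame ", i, ": coordinate count ", nrow(f$coordinates),
           " does not match particle count ", np)
    }
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (length(times) > 1) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("frame times must be strictly increasing")
    if (max(dts) - min(dts) > 1e-6 * max(dts)) {
      stop("frame times must be uniformly spaced")
    }
    dt <- mean(dts)
  } else {
    dt <- NA_real_
  }
  structure(list(system = system, frames = frames, times = times, dt = dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$frames), "frames,",
      nrow(x$system$particles), "particles, dt =", signif(x$dt, 4), "ns\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract the coordinate array of a trajectory
#'
#' @param traj A [trajectory()].
#' @return A 3D array `[particle, xyz, frame]` of positions (nm).
#' @export
coord_array <- function(traj) {
  np <- nrow(traj$system$particles)
  nf <- length(traj$frames)
  arr <- array(NA_real_, dim = c(np, 3, nf))
  for (i in seq_len(nf)) arr[, , i] <- traj$frames[[i]]$coordinates
  arr
}

#' Unwrap a trajectory across periodic boundaries
#'
#' Rebuilds continuous coordinates by accumulating minimum-image displacements
#' between consecutive frames (valid while no particle moves more than half a
#' box edge per stored frame). Needed for diffusion analysis (MSD).
#'
#' @param traj A [trajectory()].
#' @return A trajectory whose coordinates are continuous (not wrapped).
#' @export
unwrap_trajectory <- function(traj) {
  frames <- traj$frames
  if (length(frames) < 2) return(traj)
  per <- traj$system$periodic
  out <- frames
  prev_wrapped <- frames[[1]]$coordinates
  prev_unwrapped <- prev_wrapped
  for (i in 2:length(frames)) {
    cur <- frames[[i]]$coordinates
    step <- min_image_displacement(cur, prev_wrapped, frames[[i]]$box, per)
    prev_unwrapped <- prev_unwrapped + step
    out[[i]]$coordinates <- prev_unwrapped
    prev_wrapped <- cur
  }
  trajectory(traj$system, out)
}
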