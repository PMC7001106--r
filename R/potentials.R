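# Planted site potentials and biases.  Energies kJ/mol, lengths nm.  Wells are
# radial Gaussians in the membrane plane; the protein footprint is a soft
# harmonic wall that keeps lipids outside a core radius; biases are harmonic
# in a signed in-plane coordinate.

#' A planted Gaussian binding-site well
#'
#' `U(r) = -depth * exp(-r^2 / (2 sigma^2))`, with `r` the in-plane
#' minimum-image distance to the anchor, acting only on particles whose
#' species is in `species` (NULL = all mobile particles).
#'
#' @param anchor In-plane site centre, 2-vector (nm).
#' @param depth Well depth D0 >= 0 (kJ/mol); the magnitude of attraction, so
#'   the potential minimum is `-depth`.
#' @param sigma Well width (nm), > 0.
#' @param species Character vector of affected species tags, or NULL for all.
#' @return Object of class `site_well`.
#' @export
site_well <- function(anchor, depth, sigma, species = NULL) {
  if (depth < 0) stop("well depth must be >= 0 (magnitude of attraction)")
  if (sigma <= 0) stop("well width sigma must be > 0")
  structure(list(kind = "site_well", anchor = as.numeric(anchor)[1:2],
                 depth = depth, sigma = sigma, species = species),
            class = c("site_well", "memsite_potential"))
}

#' Soft protein-core repulsion
#'
#' Harmonic wall for in-plane distances below `radius` from `center`:
#' `U = k/2 (r - radius)^2` for `r < radius`, 0 outside.  Models the protein
#' footprint so lipids cannot cross the pore axis.
#'
#' @param center In-plane centre, 2-vector (nm).
#' @param radius Core radius (nm).
#' @param k Wall stiffness (kJ/mol/nm^2).
#' @param species Affected species, or NULL for all.
#' @return Object of class `protein_wall`.
#' @export
protein_wall <- function(center, radius, k = 200, species = NULL) {
  stopifnot(radius > 0, k >= 0)
  structure(list(kind = "protein_wall", center = as.numeric(center)[1:2],
                 radius = radius, k = k, species = species),
            class = c("protein_wall", "memsite_potential"))
}

#' A harmonic bias on a signed in-plane coordinate
#'
#' For `kind = "umbrella"` the biased coordinate is the projection of the
#' minimum-image displacement from `origin` onto `axis`
#' (`s = disp . axis`) and `U = k/2 (s - center)^2`.  For
#' `kind = "lateral_restraint"` the coordinate is the off-axis component
#' (`t = disp . perp(axis)`) and `U = k/2 t^2`.  Biases act on the particle
#' ids in `particle_ids`.
#'
#' @param kind `"umbrella"`, `"lateral_restraint"` or `"none"`.
#' @param axis Unit 2-vector in the membrane plane.
#' @param center Window centre s_i (nm); ignored for lateral restraints.
#' @param k Force constant (kJ/mol/nm^2), >= 0.
#' @param origin In-plane reference point (the site-anchor COM), 2-vector.
#' @param particle_ids Integer ids of biased particles.
#' @return Object of class `bias_spec`.
#' @export
bias_spec <- function(kind = c("umbrella", "lateral_restraint", "none"),
                      axis = c(1, 0), center = 0, k = 500,
                      origin = c(0, 0), particle_ids = integer()) {
  kind <- match.arg(kind)
  if (k < 0) stop("bias force constant must be >= 0")
  axis <- as.numeric(axis)[1:2]
  na <- sqrt(sum(axis^2))
  if (na == 0) stop("bias axis must be a nonzero vector")
  structure(list(kind = kind, axis = axis / na, center = center, k = k,
                 origin = as.numeric(origin)[1:2],
                 particle_ids = as.integer(particle_ids)),
            class = "bias_spec")
}

#' Four symmetry-related planted wells plus a protein core
#'
#' Builds the tetramer-mimetic arrangement: a soft protein wall at the box
#' centre and, when `four_fold = TRUE`, four wells of equal depth related by
#' 90-degree rotation about the centre, sitting at the wall rim (the synthetic
#' analogue of one site per channel subunit).  Each well carries a
#' `site_anchor` particle so reaction coordinates and distance traces can
#' reference it.
#'
#' @param depth Well depth (kJ/mol), >= 0.
#' @param sigma Well width (nm), > 0.
#' @param species Affected species tag(s) (default `"PIP2"`).
#' @param four_fold If TRUE place 4 wells at 90-degree spacing; else one well.
#' @param box Box edges (nm).
#' @param core_radius Protein core radius (nm); wells sit on this rim.
#' @param wall_k Wall stiffness (kJ/mol/nm^2).
#' @param leaflet_z Plane height for the anchors (nm).
#' @return List with `anchors` (data.frame id/x/y), `potentials` (list of
#'   potential objects) and `anchor_system` (a [membrane_system()] of the
#'   anchor + protein-centre particles that can be merged into a bilayer).
#' @export
make_planted_site_system <- function(depth, sigma, species = "PIP2",
                                     four_fold = TRUE, box = c(12, 12, 6),
                                     core_radius = 1.5, wall_k = 200,
                                     leaflet_z = box[3] * 0.25) {
  if (depth < 0) stop("well depth must be >= 0")
  if (sigma <= 0) stop("well width sigma must be > 0")
  ctr <- box[1:2] / 2
  angles <- if (four_fold) c(0, 90, 180, 270) * pi / 180 else 0
  anchors <- t(vapply(angles, function(a)
    ctr + core_radius * c(cos(a), sin(a)), numeric(2)))
  pots <- list(protein_wall(ctr, core_radius, wall_k))
  if (depth > 0) {
    for (i in seq_len(nrow(anchors))) {
      pots[[length(pots) + 1]] <- site_well(anchors[i, ], depth, sigma, species)
    }
  }
  particles <- data.frame(
    id = seq_len(nrow(anchors) + 1),
    role = c(rep("site_anchor", nrow(anchors)), "protein"),
    species = c(rep("ANCHOR", nrow(anchors)), "PROT"),
    residue_label = c(paste0("S", 500 + seq_len(nrow(anchors))), "CORE"),
    chain = c(LETTERS[seq_len(nrow(anchors))], "A"),
    stringsAsFactors = FALSE)
  coords <- rbind(cbind(anchors, leaflet_z), c(ctr, leaflet_z))
  list(anchors = data.frame(id = seq_len(nrow(anchors)),
                            x = anchors[, 1], y = anchors[, 2]),
       potentials = pots,
       anchor_system = membrane_system(particles, coords, box))
}

#' Merge the particle tables and coordinates of two systems
#'
#' Used to embed the planted-site anchors/protein into a built bilayer; ids of
#' the second system are shifted to stay unique.
#'
#' @param a,b [membrane_system()] objects sharing a box.
#' @return A combined [membrane_system()].
#' @export
merge_systems <- function(a, b) {
  stopifnot(all(abs(a$box - b$box) < 1e-9))
  pb <- b$particles
  pb$id <- pb$id + max(a$particles$id)
  membrane_system(rbind(a$particles, pb), rbind(a$coordinates, b$coordinates),
                  a$box, a$periodic)
}

# --- vectorized energy/force evaluation -----------------------------------

# species_mask: logical vector of which rows a potential acts on
pot_mask <- function(pot, species) {
  if (is.null(pot$species)) rep(TRUE, length(species))
  else species %in% pot$species
}

# Evaluate total potential energy and in-plane forces (n x 2) for coordinates
# x (n x 3), species tags, and a list of potentials + biases.  Periodic in
# x, y via the box.
eval_forces <- function(x, species, ids, potentials, biases, box) {
  n <- nrow(x)
  f <- matrix(0, n, 2)
  e <- 0
  for (pot in potentials) {
    m <- pot_mask(pot, species)
    if (!any(m)) next
    if (pot$kind == "site_well") {
      d <- min_image_displacement(x[m, , drop = FALSE],
                                  c(pot$anchor, 0), box)[, 1:2, drop = FALSE]
      r2 <- rowSums(d^2)
      g <- exp(-r2 / (2 * pot$sigma^2))
      e <- e + sum(-pot$depth * g)
      # F = -dU/dx = -depth * g * d / sigma^2  (attractive toward anchor)
      f[m, ] <- f[m, ] - (pot$depth / pot$sigma^2) * g * d
    } else if (pot$kind == "protein_wall") {
      d <- min_image_displacement(x[m, , drop = FALSE],
                                  c(pot$center, 0), box)[, 1:2, drop = FALSE]
      r <- sqrt(rowSums(d^2))
      inside <- r < pot$radius & r > 1e-12
      if (any(inside)) {
        dr <- r[inside] - pot$radius
        e <- e + sum(0.5 * pot$k * dr^2)
        fi <- -pot$k * dr / r[inside]          # positive: pushes outward
        idx <- which(m)[inside]
        f[idx, ] <- f[idx, ] + fi * d[inside, , drop = FALSE]
      }
    } else {
      stop("unknown potential kind: ", pot$kind)
    }
  }
  for (b in biases) {
    if (b$kind == "none" || b$k == 0) next
    m <- ids %in% b$particle_ids
    if (!any(m)) next
    d <- min_image_displacement(x[m, , drop = FALSE],
                                c(b$origin, 0), box)[, 1:2, drop = FALSE]
    if (b$kind == "umbrella") {
      s <- d %*% b$axis
      e <- e + sum(0.5 * b$k * (s - b$center)^2)
      f[m, ] <- f[m, ] - (b$k * as.numeric(s - b$center)) %o% b$axis
    } else {                                   # lateral_restraint
      perp <- c(-b$axis[2], b$axis[1])
      t_ <- d %*% perp
      e <- e + sum(0.5 * b$k * t_^2)
      f[m, ] <- f[m, ] - (b$k * as.numeric(t_)) %o% perp
    }
  }
  list(energy = e, forces = f)
}

# Potential energy of the plain (unbiased) potential set along the line
# origin + s*axis in the membrane plane; vectorized over s.  Used by the 1D
# umbrella/alchemical samplers and the quadrature oracles.
potential_on_axis <- function(s, potentials, origin, axis, box) {
  x <- cbind(origin[1] + s * axis[1], origin[2] + s * axis[2], 0)
  u <- numeric(length(s))
  for (pot in potentials) {
    if (pot$kind == "site_well") {
      d <- min_image_displacement(x, c(pot$anchor, 0), box)[, 1:2, drop = FALSE]
      u <- u - pot$depth * exp(-rowSums(d^2) / (2 * pot$sigma^2))
    } else if (pot$kind == "protein_wall") {
      d <- min_image_displacement(x, c(pot$center, 0), box)[, 1:2, drop = FALSE]
      r <- sqrt(rowSums(d^2))
      dr <- pmin(r - pot$radius, 0)
      u <- u + 0.5 * pot$k * dr^2
    }
  }
  u
}

# d/ds of potential_on_axis, vectorized over s (analytic).
potential_grad_on_axis <- function(s, potentials, origin, axis, box) {
  x <- cbind(origin[1] + s * axis[1], origin[2] + s * axis[2], 0)
  g <- numeric(length(s))
  for (pot in potentials) {
    if (pot$kind == "site_well") {
      d <- min_image_displacement(x, c(pot$anchor, 0), box)[, 1:2, drop = FALSE]
      gau <- exp(-rowSums(d^2) / (2 * pot$sigma^2))
      # dU/ds = depth/sigma^2 * exp(...) * (d . axis)
      g <- g + (pot$depth / pot$sigma^2) * gau * (d %*% axis)[, 1]
    } else if (pot$kind == "protein_wall") {
      d <- min_image_displacement(x, c(pot$center, 0), box)[, 1:2, drop = FALSE]
      r <- sqrt(rowSums(d^2))
      inside <- r < pot$radius & r > 1e-12
      if (any(inside)) {
        g[inside] <- g[inside] +
          pot$k * (r[inside] - pot$radius) / r[inside] *
          (d[inside, , drop = FALSE] %*% axis)[, 1]
      }
    }
  }
  g
}
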