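# Mixed-bilayer construction.  The default composition is the in-vivo mimetic
# mixture used for the channel simulations this package re-analyses:
# outer leaflet PC:PE:SM:GM3:CHOL = 40:10:15:10:25,
# inner leaflet PC:PE:PS:PIP2:CHOL = 10:40:15:10:25,
# which gives an overall PIP2 mole fraction of 5%.

#' Per-leaflet composition of the in-vivo mimetic bilayer
#'
#' @return Named list with `outer` and `inner` mole-fraction vectors.
#' @export
mimetic_composition <- function() {
  list(
    outer = c(PC = 0.40, PE = 0.10, SM = 0.15, GM3 = 0.10, CHOL = 0.25),
    inner = c(PC = 0.10, PE = 0.40, PS = 0.15, PIP2 = 0.10, CHOL = 0.25)
  )
}

#' Specify a bilayer
#'
#' @param leaflets Named list mapping leaflet name to a named vector of
#'   species mole fractions (each leaflet must sum to 1 within 1e-9, all
#'   fractions >= 0). Default: the in-vivo mimetic composition.
#' @param lipids_per_leaflet Number of lipids per leaflet.
#' @param box Box edges (nm); z spans both leaflet planes.
#' @param leaflet_z Named numeric of leaflet plane heights (nm).
#' @return Object of class `bilayer_spec`.
#' @export
bilayer_spec <- function(leaflets = mimetic_composition(),
                         lipids_per_leaflet = 200,
                         box = c(12, 12, 6),
                         leaflet_z = NULL) {
  stopifnot(is.list(leaflets), length(leaflets) >= 1, lipids_per_leaflet >= 1)
  for (nm in names(leaflets)) {
    fr <- leaflets[[nm]]
    if (is.null(names(fr)) || any(names(fr) == "")) {
      stop("leaflet '", nm, "': species fractions must be named")
    }
    if (any(fr < 0)) stop("leaflet '", nm, "': negative mole fraction")
    if (abs(sum(fr) - 1) > 1e-9) {
      stop("leaflet '", nm, "': fractions sum to ", sum(fr), ", not 1")
    }
  }
  if (is.null(leaflet_z)) {
    zs <- seq(box[3] * 0.75, box[3] * 0.25, length.out = length(leaflets))
    leaflet_z <- stats::setNames(zs, names(leaflets))
  }
  structure(list(leaflets = leaflets,
                 lipids_per_leaflet = as.integer(lipids_per_leaflet),
                 box = as.numeric(box), leaflet_z = leaflet_z),
            class = "bilayer_spec")
}

#' Largest-remainder apportionment of species counts
#'
#' Rounds `fractions * total` to integers summing to `total`: floor first,
#' then distribute the remaining lipids by descending fractional remainder,
#' ties broken by species name order (deterministic builds).
#'
#' @param fractions Named mole fractions summing to 1.
#' @param total Integer total count.
#' @return Named integer vector summing to `total`.
#' @export
largest_remainder_counts <- function(fractions, total) {
  stopifnot(abs(sum(fractions) - 1) <= 1e-9, total >= 0)
  raw <- fractions * total
  base <- floor(raw)
  rem <- raw - base
  short <- as.integer(round(total - sum(base)))
  ord <- order(-rem, names(fractions))
  counts <- base
  if (short > 0) counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  stats::setNames(as.integer(counts), names(fractions))
}

#' Build a membrane system from a bilayer specification
#'
#' Species counts per leaflet follow largest-remainder rounding of
#' `fraction * lipids_per_leaflet`; lipid head particles are placed uniformly
#' at random in the leaflet plane, rejecting placements closer than
#' `min_spacing` to an already-placed lipid of the same leaflet.
#'
#' @param spec A [bilayer_spec()].
#' @param seed Integer RNG seed (placement is deterministic given the seed).
#' @param min_spacing Minimum in-plane spacing between lipids (nm).
#' @return A [membrane_system()] of `lipid_head` particles.
#' @export
build_bilayer <- function(spec, seed = 1, min_spacing = 0.45) {
  stopifnot(inherits(spec, "bilayer_spec"))
  set.seed(as.integer(seed))
  rows <- list(); coords <- list(); id0 <- 0L
  for (nm in names(spec$leaflets)) {
    counts <- largest_remainder_counts(spec$leaflets[[nm]],
                                       spec$lipids_per_leaflet)
    n <- sum(counts)
    species <- rep(names(counts), counts)
    xy <- place_nonoverlapping(n, spec$box[1:2], min_spacing)
    rows[[nm]] <- data.frame(
      id = id0 + seq_len(n), role = "lipid_head", species = species,
      residue_label = "", chain = nm, stringsAsFactors = FALSE)
    coords[[nm]] <- cbind(xy, spec$leaflet_z[[nm]])
    id0 <- id0 + n
  }
  membrane_system(do.call(rbind, rows), do.call(rbind, coords), spec$box)
}

place_nonoverlapping <- function(n, box_xy, min_spacing, max_tries = 2000L) {
  pts <- matrix(NA_real_, n, 2)
  if (n * pi * (min_spacing / 2)^2 > 0.7 * prod(box_xy)) {
    stop("cannot place ", n, " lipids at spacing ", min_spacing,
         " in a ", box_xy[1], " x ", box_xy[2], " nm leaflet")
  }
  for (i in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      p <- stats::runif(2) * box_xy
      if (i == 1) break
      d <- sweep(pts[seq_len(i - 1), , drop = FALSE], 2, p)
      for (ax in 1:2) d[, ax] <- d[, ax] - box_xy[ax] * round(d[, ax] / box_xy[ax])
      if (min(rowSums(d^2)) >= min_spacing^2) break
      if (try == max_tries) stop("placement failed after ", max_tries, " tries")
    }
    pts[i, ] <- p
  }
  pts
}

#' Overall mole fraction of a species across all leaflets
#'
#' @param system A [membrane_system()] (or the output of [build_bilayer()]).
#' @param species Species tag, e.g. `"PIP2"`.
#' @return Fraction of lipid-head particles with that species tag.
#' @export
overall_mole_fraction <- function(system, species) {
  p <- system$particles
  lip <- p$role == "lipid_head"
  if (!any(lip)) stop("system contains no lipid_head particles")
  mean(p$species[lip] == species)
}
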