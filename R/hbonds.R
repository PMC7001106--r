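# Geometric hydrogen-bond detection.  Criterion: donor-acceptor distance
# <= max_distance AND deviation of the D-H...A angle from linearity
# <= max_angle (0 degrees = perfectly linear; this convention avoids the
# "minimum 150 degrees" ambiguity).  Both thresholds are configurable; the
# defaults 0.35 nm / 30 degrees are the standard geometric convention.

#' Geometric hydrogen-bond criterion
#'
#' @param max_distance Donor-acceptor distance cutoff (nm), > 0.
#'   Default 0.35.
#' @param max_angle Maximum deviation of D-H...A from linearity (degrees),
#'   in (0, 90]. Default 30.
#' @return Object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_distance = 0.35, max_angle = 30) {
  if (max_distance <= 0) stop("max_distance must be > 0")
  if (max_angle <= 0 || max_angle > 90) stop("max_angle must be in (0, 90]")
  structure(list(max_distance = max_distance, max_angle = max_angle),
            class = "hbond_criterion")
}

#' Detect hydrogen bonds in one frame
#'
#' Exhaustive search over all donor x acceptor pairs using minimum-image
#' distances.  `donors` and `hydrogens` are parallel vectors: `hydrogens[i]`
#' is the hydrogen bonded to `donors[i]` (a donor with several hydrogens
#' appears once per hydrogen).
#'
#' @param coordinates n x 3 matrix (nm).
#' @param donors,hydrogens Parallel integer row indices of donor heavy atoms
#'   and their hydrogens.
#' @param acceptors Integer row indices of acceptor atoms.
#' @param box Box edges (nm).
#' @param criterion An [hbond_criterion()].
#' @param periodic Periodic axes. Default x, y.
#' @return `data.frame` with one row per bond: `donor`, `hydrogen`,
#'   `acceptor`, `distance` (nm), `deviation` (degrees).
#' @export
detect_hbonds <- function(coordinates, donors, hydrogens, acceptors, box,
                          criterion = hbond_criterion(),
                          periodic = c(TRUE, TRUE, FALSE)) {
  if (length(donors) != length(hydrogens)) {
    stop("input error: every hydrogen needs its donor parent ",
         "(donors and hydrogens must be parallel vectors)")
  }
  co <- as.matrix(coordinates)
  out <- list()
  for (i in seq_along(donors)) {
    d <- donors[i]; h <- hydrogens[i]
    for (a in acceptors) {
      if (a == d) next
      da <- min_image_distance(co[d, ], co[a, ], box, periodic)
      if (da > criterion$max_distance) next
      hd <- min_image_displacement(co[d, ], co[h, ], box, periodic)
      ha <- min_image_displacement(co[a, ], co[h, ], box, periodic)
      cosang <- sum(hd * ha) / (sqrt(sum(hd^2)) * sqrt(sum(ha^2)))
      cosang <- min(1, max(-1, cosang))
      dev <- 180 - acos(cosang) * 180 / pi
      if (dev <= criterion$max_angle) {
        out[[length(out) + 1]] <- data.frame(donor = d, hydrogen = h,
                                             acceptor = a, distance = da,
                                             deviation = dev)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      deviation = numeric()))
  }
  do.call(rbind, out)
}

#' Per-residue hydrogen-bond count time series
#'
#' Counts, for every frame and every residue in `residues`, the hydrogen
#' bonds between that residue's donors and the selected lipid head-group
#' acceptors — the count-versus-time traces used to watch a bound head
#' group's contacts fluctuate.
#'
#' @param traj A [trajectory()].
#' @param donors,hydrogens Parallel particle-id vectors (donor heavy atoms
#'   on the protein side and their hydrogens).
#' @param acceptors Particle ids of the lipid head-group acceptors.
#' @param residues Residue labels to report; default: all residues owning a
#'   donor. An empty set returns an empty table with a warning.
#' @param criterion An [hbond_criterion()].
#' @param path Optional TSV output (one column per residue).
#' @return `data.frame` with `time` and one integer column per residue.
#' @export
hbond_series <- function(traj, donors, hydrogens, acceptors, residues = NULL,
                         criterion = hbond_criterion(), path = NULL) {
  p <- traj$system$particles
  if (length(donors) != length(hydrogens)) {
    stop("input error: donors and hydrogens must be parallel vectors")
  }
  d_rows <- match(donors, p$id)
  h_rows <- match(hydrogens, p$id)
  a_rows <- match(acceptors, p$id)
  if (anyNA(c(d_rows, h_rows, a_rows))) stop("unknown particle id in selection")
  res_of_donor <- p$residue_label[d_rows]
  if (is.null(residues)) residues <- unique(res_of_donor)
  if (!length(residues)) {
    warning("empty residue set: returning an empty hydrogen-bond table")
    return(data.frame(time = traj$times))
  }
  box <- traj$frames[[1]]$box
  counts <- matrix(0L, length(traj$frames), length(residues),
                   dimnames = list(NULL, residues))
  for (f in seq_along(traj$frames)) {
    bonds <- detect_hbonds(traj$frames[[f]]$coordinates, d_rows, h_rows,
                           a_rows, box, criterion, traj$system$periodic)
    if (nrow(bonds)) {
      res <- res_of_donor[match(bonds$donor, d_rows)]
      tab <- table(factor(res, levels = residues))
      counts[f, ] <- as.integer(tab)
    }
  }
  out <- data.frame(time = traj$times, counts, check.names = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
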