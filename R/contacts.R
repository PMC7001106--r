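# Distance-to-site traces and per-residue contact-duration statistics with
# dual-cutoff event detection (an event opens when the distance drops below
# on_cutoff and closes only when it exceeds off_cutoff, suppressing rattling).

#' Distance-to-site time series for each lipid molecule
#'
#' For every frame, the minimum-image distance (projected into the membrane
#' plane) between the centre of mass of each lipid molecule's head-group
#' particles and the centre of mass of the site-anchor particles — the
#' distance-versus-time trace used to watch lipids find their site.
#'
#' @param traj A [trajectory()].
#' @param species Lipid species tag selecting the head-group particles.
#' @param anchor_ids Ids of the `site_anchor` particles defining the site COM;
#'   default: all site_anchor particles in the system.
#' @param group_by Particle-table column that distinguishes lipid molecules
#'   (default `"id"`: one particle per head group).
#' @param site_of `"com"` (default): one site defined by the COM of all
#'   anchor particles (the convention when the anchors are the two serine
#'   side chains of a single site).  `"eventual"`: each anchor particle is a
#'   separate site and every lipid is measured against the site it is
#'   nearest at the final frame — the convention for watching each molecule
#'   approach the site it eventually occupies on a multi-site tetramer.
#' @return `data.frame` with columns `time`, `molecule`, `distance` (nm)
#'   (and `site` in `"eventual"` mode).
#' @export
distance_to_site_series <- function(traj, species, anchor_ids = NULL,
                                    group_by = "id",
                                    site_of = c("com", "eventual")) {
  site_of <- match.arg(site_of)
  p <- traj$system$particles
  if (is.null(anchor_ids)) anchor_ids <- p$id[p$role == "site_anchor"]
  if (!length(anchor_ids)) stop("no site_anchor particles to measure from")
  a_rows <- match(anchor_ids, p$id)
  lip <- which(p$role %in% c("lipid_head", "ligand") & p$species %in% species)
  if (!length(lip)) stop("empty lipid selection for species ",
                         paste(species, collapse = ","))
  mol <- p[[group_by]][lip]
  mols <- unique(mol)
  box <- traj$frames[[1]]$box
  per <- traj$system$periodic
  mol_com <- function(co, m) {
    rows <- lip[mol == m]
    colMeans(co[rows, , drop = FALSE])
  }
  if (site_of == "eventual") {
    last <- traj$frames[[length(traj$frames)]]$coordinates
    site_idx <- vapply(mols, function(m) {
      d <- vapply(a_rows, function(a)
        min_image_distance(mol_com(last, m), last[a, ], box, per,
                           plane = TRUE), numeric(1))
      which.min(d)
    }, integer(1))
  } else {
    site_idx <- NULL
  }
  res <- vector("list", length(traj$frames))
  for (i in seq_along(traj$frames)) {
    co <- traj$frames[[i]]$coordinates
    if (site_of == "com") {
      a_com <- colMeans(co[a_rows, , drop = FALSE])
      d <- vapply(mols, function(m)
        min_image_distance(mol_com(co, m), a_com, box, per, plane = TRUE),
        numeric(1))
      res[[i]] <- data.frame(time = traj$times[i], molecule = mols,
                             distance = d)
    } else {
      d <- vapply(seq_along(mols), function(j)
        min_image_distance(mol_com(co, mols[j]), co[a_rows[site_idx[j]], ],
                           box, per, plane = TRUE), numeric(1))
      res[[i]] <- data.frame(time = traj$times[i], molecule = mols,
                             site = anchor_ids[site_idx], distance = d)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Dual-cutoff contact events on a distance series
#'
#' State machine over one distance series: a contact opens when
#' `d < on_cutoff` and closes when `d > off_cutoff`.  A contact still open at
#' the end of the series is counted with its (censored) duration.
#'
#' @param distance Numeric distance series (nm).
#' @param dt Time between samples (ns).
#' @param on_cutoff,off_cutoff Cutoffs (nm), `off_cutoff >= on_cutoff > 0`.
#' @return Numeric vector of event durations (ns); each sample in contact
#'   contributes `dt`.
#' @export
contact_events <- function(distance, dt, on_cutoff = 0.55, off_cutoff = 1.0) {
  if (!(off_cutoff >= on_cutoff && on_cutoff > 0)) {
    stop("need off_cutoff >= on_cutoff > 0")
  }
  in_contact <- FALSE
  durations <- numeric()
  len <- 0L
  for (d in distance) {
    if (!in_contact) {
      if (d < on_cutoff) {
        in_contact <- TRUE
        len <- 1L
      }
    } else {
      if (d > off_cutoff) {
        in_contact <- FALSE
        durations <- c(durations, len * dt)
        len <- 0L
      } else {
        len <- len + 1L
      }
    }
  }
  if (in_contact) durations <- c(durations, len * dt)
  durations
}

#' Per-residue contact durations with a lipid species
#'
#' For each (residue, lipid molecule) pair the per-frame distance is the
#' minimum over all particle pairs between the residue's particles and the
#' lipid's head-group particles (particle-to-particle, not COM).  Dual-cutoff
#' events are aggregated per residue over all lipid molecules of the species.
#'
#' @param traj A [trajectory()].
#' @param species Lipid species tag.
#' @param on_cutoff,off_cutoff Contact cutoffs (nm); defaults 0.55 / 1.0, the
#'   conventional dual-cutoff scale for coarse bead models.
#' @param residue_roles Roles whose particles define residues (default
#'   protein and site_anchor).
#' @param per_chain If TRUE, residues on different chains are reported
#'   separately; if FALSE (default) statistics are pooled over chains
#'   (chain-averaged reporting).
#' @return `data.frame` (class `residue_contact_table`) with columns
#'   `residue`, `species`, `mean_duration`, `max_duration`, `n_events`,
#'   `occupancy` plus attribute `total_time` (ns).
#' @export
residue_contact_durations <- function(traj, species, on_cutoff = 0.55,
                                      off_cutoff = 1.0,
                                      residue_roles = c("protein", "site_anchor"),
                                      per_chain = FALSE) {
  if (!(off_cutoff >= on_cutoff && on_cutoff > 0)) {
    stop("need off_cutoff >= on_cutoff > 0")
  }
  p <- traj$system$particles
  res_rows <- which(p$role %in% residue_roles & p$residue_label != "")
  if (!length(res_rows)) stop("no residue particles in the trajectory")
  res_key <- if (per_chain) paste(p$residue_label[res_rows], p$chain[res_rows])
             else p$residue_label[res_rows]
  lip_rows <- which(p$role %in% c("lipid_head", "ligand") & p$species %in% species)
  if (!length(lip_rows)) stop("no lipids of species ", paste(species, collapse = ","))
  lip_mol <- p$id[lip_rows]
  nf <- length(traj$frames)
  dt <- if (nf > 1) traj$dt else 1
  total_time <- nf * dt
  box <- traj$frames[[1]]$box
  arr <- coord_array(traj)
  keys <- unique(res_key)
  out <- vector("list", length(keys))
  for (ki in seq_along(keys)) {
    rr <- res_rows[res_key == keys[ki]]
    durs <- numeric()
    time_on <- 0
    for (lm in unique(lip_mol)) {
      lr <- lip_rows[lip_mol == lm]
      # min over residue-particle x lipid-particle distances, per frame
      dmin <- rep(Inf, nf)
      for (a in rr) for (b in lr) {
        d <- arr[a, , ] - arr[b, , ]
        if (nf == 1) d <- matrix(d, ncol = 1)
        for (ax in which(traj$system$periodic)) {
          d[ax, ] <- d[ax, ] - box[ax] * round(d[ax, ] / box[ax])
        }
        dmin <- pmin(dmin, sqrt(colSums(d^2)))
      }
      ev <- contact_events(dmin, dt, on_cutoff, off_cutoff)
      durs <- c(durs, ev)
      time_on <- time_on + sum(ev)
    }
    out[[ki]] <- data.frame(
      residue = keys[ki], species = paste(species, collapse = ","),
      mean_duration = if (length(durs)) mean(durs) else 0,
      max_duration = if (length(durs)) max(durs) else 0,
      n_events = length(durs),
      occupancy = min(1, time_on / total_time),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  attr(tab, "total_time") <- total_time
  class(tab) <- c("residue_contact_table", class(tab))
  tab
}

#' Write a contact table with colour-scale values
#'
#' Adds a `scale` column mapping mean durations linearly onto `[0, 1]` with
#' the maximum mean mapped to 1 (the white-to-red colouring convention); when
#' all means are equal and positive every value is 1, and an all-zero table
#' maps to 0.  Written as TSV with a deterministic column order.
#'
#' @param table A `residue_contact_table`.
#' @param path Optional TSV output path.
#' @return The table with the added `scale` column (invisibly if written).
#' @export
contact_table_report <- function(table, path = NULL) {
  if (!nrow(table)) stop("contact table is empty")
  mx <- max(table$mean_duration)
  table$scale <- if (mx > 0) table$mean_duration / mx else 0
  cols <- c("residue", "species", "mean_duration", "max_duration",
            "n_events", "occupancy", "scale")
  table <- as.data.frame(table)[, cols]
  if (!is.null(path)) {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(table))
  }
  table
}

#' Read a contact table written by [contact_table_report()]
#' @param path TSV path.
#' @return `data.frame` with the report columns.
#' @export
read_contact_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
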