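# Plain-text multi-frame trajectory store.  Header with the particle table,
# then one block per frame.  Text so tests (and humans) can diff it.

#' Write a trajectory to the plain-text store
#'
#' Format: a header (`memsite-traj 1`, particle count, frame count), the
#' particle table as TSV, then per frame a `frame` line (`time` ns and box
#' edges nm) followed by one `x y z` row per particle at 1e-5 nm precision.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"), length(traj$frames) >= 1)
  con <- file(path, "w")
  on.exit(close(con))
  p <- traj$system$particles
  writeLines(c("memsite-traj 1",
               sprintf("n_particles %d", nrow(p)),
               sprintf("n_frames %d", length(traj$frames)),
               sprintf("periodic %s", paste(as.integer(traj$system$periodic),
                                            collapse = " ")),
               "particles id role species residue_label chain"), con)
  writeLines(sprintf("%d\t%s\t%s\t%s\t%s", p$id, p$role, p$species,
                     p$residue_label, p$chain), con)
  for (f in traj$frames) {
    writeLines(sprintf("frame %.6f %.5f %.5f %.5f", f$time,
                       f$box[1], f$box[2], f$box[3]), con)
    writeLines(sprintf("%.5f %.5f %.5f", f$coordinates[, 1],
                       f$coordinates[, 2], f$coordinates[, 3]), con)
  }
  invisible(path)
}

#' Read a trajectory from the plain-text store
#'
#' Validates the header, frame/particle counts and time spacing; `dt` is
#' inferred from the stored frame times.
#'
#' @param path Path written by [write_trajectory()].
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != "memsite-traj 1") {
    stop("format error: ", path, " is not a memsite trajectory store")
  }
  np <- as.integer(sub("n_particles ", "", lines[2]))
  nf <- as.integer(sub("n_frames ", "", lines[3]))
  periodic <- as.logical(as.integer(strsplit(sub("periodic ", "", lines[4]),
                                             " ")[[1]]))
  if (is.na(np) || is.na(nf)) stop("format error: bad header in ", path)
  ptab_lines <- lines[6:(5 + np)]
  parts <- do.call(rbind, strsplit(ptab_lines, "\t"))
  particles <- data.frame(id = as.integer(parts[, 1]), role = parts[, 2],
                          species = parts[, 3], residue_label = parts[, 4],
                          chain = if (ncol(parts) >= 5) parts[, 5] else "",
                          stringsAsFactors = FALSE)
  pos <- 5 + np
  frames <- vector("list", nf)
  for (i in seq_len(nf)) {
    hdr <- lines[pos + 1]
    if (is.na(hdr) || !startsWith(hdr, "frame ")) {
      stop("format error in ", path, ": expected frame header at line ",
           pos + 1, " (frame/particle count mismatch?)")
    }
    h <- as.numeric(strsplit(sub("frame ", "", hdr), " ")[[1]])
    block <- lines[(pos + 2):(pos + 1 + np)]
    if (length(block) != np || anyNA(block)) {
      stop("format error in ", path, ": frame ", i, " has fewer than ",
           np, " coordinate rows")
    }
    co <- matrix(as.numeric(unlist(strsplit(block, " "))), ncol = 3, byrow = TRUE)
    if (anyNA(co)) stop("format error in ", path, ": non-numeric coordinate in frame ", i)
    frames[[i]] <- traj_frame(h[1], co, h[2:4])
    pos <- pos + 1 + np
  }
  if (pos != length(lines)) {
    stop("format error in ", path, ": trailing content after last frame ",
         "(frame/particle count mismatch)")
  }
  sys <- membrane_system(particles, frames[[1]]$coordinates, frames[[1]]$box,
                         periodic)
  trajectory(sys, frames)
}
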