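# OpenDX volumetric grid I/O for occupancy density maps, following the
# convention of VMD's Volmap output: regular grid, three values per data line,
# the LAST grid index (z) varying fastest.

#' Write a density map in OpenDX grid format
#'
#' The grid is serialized in the standard OpenDX order: the z index varies
#' fastest, then y, then x.  Values are written with 6 significant digits, so
#' a write/read round trip reproduces origin, spacing and values to that
#' precision.
#'
#' @param map A [density_map] as returned by [occupancy_density()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  dims <- dim(map$values)
  if (length(dims) != 3 || prod(dims) == 0) stop("refusing to write an empty grid")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# memsite occupancy density (normalization: %s, n_frames: %d)",
                     map$normalization, map$n_frames), con)
  writeLines(sprintf("object 1 class gridpositions counts %d %d %d",
                     dims[1], dims[2], dims[3]), con)
  writeLines(sprintf("origin %.6g %.6g %.6g",
                     map$origin[1], map$origin[2], map$origin[3]), con)
  writeLines(sprintf("delta %.6g 0 0", map$spacing), con)
  writeLines(sprintf("delta 0 %.6g 0", map$spacing), con)
  writeLines(sprintf("delta 0 0 %.6g", map$spacing), con)
  writeLines(sprintf("object 2 class gridconnections counts %d %d %d",
                     dims[1], dims[2], dims[3]), con)
  writeLines(sprintf("object 3 class array type double rank 0 items %d data follows",
                     prod(dims)), con)
  # z fastest, then y, then x: aperm so the flattened (column-major) order is z,y,x
  vals <- as.vector(aperm(map$values, c(3, 2, 1)))
  n <- length(vals)
  pad <- c(vals, rep(NA_real_, (3 - n %% 3) %% 3))
  m <- matrix(pad, nrow = 3)
  lines <- apply(m, 2, function(v) paste(sprintf("%.6g", v[!is.na(v)]), collapse = " "))
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  writeLines('object "density" class field', con)
  invisible(path)
}

#' Read an OpenDX density map written by [write_density_map()]
#'
#' @param path Path to a `.dx` file.
#' @return A `density_map` object (origin, spacing, values grid).
#' @export
read_density_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  if (is.na(gp)) stop("parse error: no gridpositions object in ", path)
  counts <- as.integer(strsplit(trimws(sub(".*counts", "", gp)), "\\s+")[[1]])
  orig_line <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", orig_line)), "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dmat <- unname(t(vapply(deltas, function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1]]),
    numeric(3))))
  spacing <- dmat[1, 1]
  start <- grep("data follows", lines)[1]
  end_attr <- grep('^attribute|^object "', lines)
  end_attr <- end_attr[end_attr > start]
  end <- if (length(end_attr)) min(end_attr) - 1 else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[(start + 1):end]), "\\s+")))
  if (length(vals) != prod(counts)) {
    stop("parse error: expected ", prod(counts), " values, got ", length(vals))
  }
  arr_zyx <- array(vals, dim = rev(counts))       # z fastest on disk
  values <- aperm(arr_zyx, c(3, 2, 1))
  new_density_map(origin = origin, spacing = spacing, values = values,
                  n_frames = NA_integer_, normalization = "per_frame_mean")
}
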