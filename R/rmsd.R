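# Least-squares rigid-body superposition (Kabsch, via SVD) and
# superposition-based ligand RMSD time series: fit the protein to a reference
# frame, carry the ligand along, and measure each ligand copy's deviation
# from its reference pose (no fitting on the ligand itself).

#' Optimal rigid superposition of two coordinate sets
#'
#' Returns the proper rotation `R` (det = +1) and translation minimizing the
#' RMSD of `mobile[fit, ]` onto `reference[fit, ]`.  The transform maps
#' mobile coordinates as `x %*% R + t(translation)` applied row-wise.
#'
#' @param reference,mobile n x 3 coordinate matrices (nm).
#' @param fit Row indices used for the fit (default: all rows). Needs >= 3
#'   non-collinear points.
#' @return List with `rotation` (3 x 3), `translation` (3-vector),
#'   `rmsd` (fit RMSD, nm) and `apply` (a function transforming any n x 3
#'   matrix).
#' @export
superpose <- function(reference, mobile, fit = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  stopifnot(ncol(reference) == 3, ncol(mobile) == 3,
            nrow(reference) == nrow(mobile))
  if (is.null(fit)) fit <- seq_len(nrow(reference))
  if (length(fit) < 3) stop("need >= 3 fit particles for superposition")
  A <- mobile[fit, , drop = FALSE]
  B <- reference[fit, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinearity check: rank of the fit-point scatter
  svA <- svd(A0)
  if (svA$d[2] < 1e-10 * max(svA$d[1], 1e-300)) {
    stop("degenerate fit set: fit particles are collinear")
  }
  sv <- svd(crossprod(A0, B0))          # A0^T B0 = U D V^T
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  trans <- cb - as.numeric(ca %*% R)
  fitted <- A %*% R + matrix(trans, nrow(A), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = trans, rmsd = rmsd,
       apply = function(x) as.matrix(x) %*% R +
         matrix(trans, nrow(x), 3, byrow = TRUE))
}

#' Root-mean-square deviation of two coordinate sets (no fitting)
#'
#' @param a,b n x 3 matrices (nm).
#' @return RMSD in nm.
#' @export
rmsd_raw <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

#' Ligand RMSD time series after protein superposition
#'
#' For every frame: superpose the protein fit selection onto the reference
#' frame, apply the same transform to the whole frame, and compute each
#' ligand copy's RMSD against its reference pose.  The ligand never enters
#' the fit, so a stably bound copy gives a flat low trace and a loosely bound
#' one drifts — the per-copy stability fingerprint.
#'
#' @param traj A [trajectory()].
#' @param copies List of particle-id vectors, one per ligand copy.
#' @param fit_ids Particle ids of the protein fit selection.
#' @param reference_frame Index of the reference frame. Default 1.
#' @return `data.frame` with `time` and one column `copy_<i>` per ligand
#'   copy (RMSD, nm); the reference-frame row is exactly 0.
#' @export
ligand_rmsd_series <- function(traj, copies, fit_ids, reference_frame = 1L) {
  nf <- length(traj$frames)
  if (reference_frame < 1 || reference_frame > nf) {
    stop("reference frame ", reference_frame, " does not exist (", nf, " frames)")
  }
  p <- traj$system$particles
  fit_rows <- match(fit_ids, p$id)
  if (anyNA(fit_rows)) stop("unknown particle id in fit selection")
  copy_rows <- lapply(copies, function(ids) {
    r <- match(ids, p$id)
    if (anyNA(r)) stop("missing ligand copy particle id(s): ",
                       paste(ids[is.na(r)], collapse = ", "))
    r
  })
  ref <- traj$frames[[reference_frame]]$coordinates
  out <- matrix(NA_real_, nf, length(copies),
                dimnames = list(NULL, paste0("copy_", seq_along(copies))))
  for (f in seq_len(nf)) {
    if (f == reference_frame) {          # identical coordinates by definition
      out[f, ] <- 0
      next
    }
    co <- traj$frames[[f]]$coordinates
    sp <- superpose(ref, co, fit_rows)
    moved <- sp$apply(co)
    for (ci in seq_along(copy_rows)) {
      out[f, ci] <- rmsd_raw(moved[copy_rows[[ci]], , drop = FALSE],
                             ref[copy_rows[[ci]], , drop = FALSE])
    }
  }
  data.frame(time = traj$times, out)
}
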