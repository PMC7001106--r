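# Weighted histogram analysis method: self-consistent combination of biased
# umbrella-window histograms into one unbiased free-energy profile.
# Implemented in log space (logsumexp) so deep wells and stiff biases do not
# underflow.

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Reconstruct a PMF from umbrella windows by WHAM
#'
#' Iterates the standard WHAM equations on a shared bin grid until the
#' largest change in any window free-energy offset is below `tol` (kJ/mol).
#' The profile is reported as `G(s) = -kT ln P(s)` and zeroed so that its
#' mean over the bulk interval is exactly 0.
#'
#' @param uset An `umbrella_set` from [run_umbrella_sampling()] (or built by
#'   hand from external window samples: a list of `windows`, each with
#'   `center`, `k`, `samples`, plus `kT`).
#' @param bin_width Histogram bin width (nm). Default 0.05.
#' @param tol Convergence tolerance on window offsets (kJ/mol). Default 1e-8.
#' @param max_iter Iteration cap. Default 1e5.
#' @param bulk_interval Interval (nm) over which the profile is defined to be
#'   zero. Default `c(2.5, 3.0)`, the outermost 0.5 nm of the default ladder.
#' @param min_count Bins with fewer pooled samples are dropped from the
#'   profile (default 25): bins reached only by a single window's far tail
#'   otherwise contribute wildly noisy `-kT log n` values at the profile
#'   edges.
#' @param n_boot If > 0, per-bin errors from this many block-bootstrap
#'   resamples of the window series.
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `pmf_profile`: `data.frame`-like list with bin
#'   centres `s`, free energy `G` (kJ/mol), per-bin `error` (NA when
#'   `n_boot = 0`), plus convergence metadata.
#' @export
wham <- function(uset, bin_width = 0.05, tol = 1e-8, max_iter = 1e5,
                 bulk_interval = c(2.5, 3.0), n_boot = 0, seed = 1L,
                 min_count = 25L) {
  stopifnot(length(uset$windows) >= 1, bin_width > 0)
  prof <- wham_core(uset$windows, uset$kT, bin_width, tol, max_iter,
                    bulk_interval, min_count = min_count)
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    boots <- matrix(NA_real_, n_boot, length(prof$s))
    for (b in seq_len(n_boot)) {
      res <- resample_windows(uset$windows)
      pb <- wham_core(res, uset$kT, bin_width, tol, max_iter, bulk_interval,
                      breaks = prof$breaks, min_count = min_count)
      boots[b, ] <- pb$G[match(round(prof$s, 10), round(pb$s, 10))]
    }
    prof$error <- apply(boots, 2, stats::sd, na.rm = TRUE)
  }
  prof
}

# Core WHAM solve on a fixed or data-derived bin grid.
wham_core <- function(windows, kbt, bin_width, tol, max_iter, bulk_interval,
                      breaks = NULL, min_count = 1L) {
  all_s <- unlist(lapply(windows, `[[`, "samples"))
  all_s <- all_s[is.finite(all_s)]
  if (!length(all_s)) stop("no finite samples in umbrella set")
  if (is.null(breaks)) {
    lo <- floor(min(all_s) / bin_width) * bin_width
    hi <- ceiling(max(all_s) / bin_width) * bin_width
    breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  }
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  K <- length(windows)
  M <- length(mids)
  H <- matrix(0, K, M)           # per-window histograms
  N <- numeric(K)
  for (i in seq_len(K)) {
    s <- windows[[i]]$samples
    s <- s[is.finite(s) & s >= breaks[1] & s <= breaks[length(breaks)]]
    H[i, ] <- tabulate(findInterval(s, breaks, rightmost.closed = TRUE),
                       nbins = M)
    N[i] <- length(s)
  }
  Ht <- colSums(H)
  centers <- vapply(windows, `[[`, numeric(1), "center")
  kk <- vapply(windows, `[[`, numeric(1), "k")
  # ladder connectivity: windows must be linked through shared occupied bins,
  # otherwise the relative offsets across the gap are undetermined
  if (K > 1) {
    occ_w <- H > 0
    comp <- integer(K); comp[1] <- 1L
    frontier <- 1L
    while (length(frontier)) {
      nxt <- integer()
      for (i in frontier) {
        linked <- which(comp == 0L &
                          (occ_w %*% occ_w[i, ])[, 1] > 0)
        comp[linked] <- 1L
        nxt <- c(nxt, linked)
      }
      frontier <- nxt
    }
    if (any(comp == 0L)) {
      ord <- order(centers)
      in_comp <- comp[ord] == 1L
      edge <- which(diff(in_comp) != 0)[1]
      stop("WHAM convergence failure: non-overlapping window histograms; ",
           "gap between window centres ", signif(centers[ord][edge], 3),
           " and ", signif(centers[ord][edge + 1], 3), " nm")
    }
  }
  # reduced bias energies  beta * w_i(x_m)
  bw <- outer(seq_len(K), seq_len(M), function(i, m)
    0.5 * kk[i] * (mids[m] - centers[i])^2 / kbt)
  lf <- numeric(K)               # beta * f_i, window offsets
  occ <- Ht > 0
  logHt <- ifelse(occ, log(Ht), -Inf)
  logN <- log(N)
  iter <- 0L
  resid <- Inf
  repeat {
    iter <- iter + 1L
    # log P_m = log H_m - logsumexp_i(log N_i + lf_i - bw_im)
    denom <- logsumexp_rows(t(logN + lf - bw))     # length M
    logP <- logHt - denom
    lf_new <- -logsumexp_rows(sweep(-bw, 2, logP, `+`))
    lf_new <- lf_new - lf_new[1]
    resid <- max(abs(lf_new - lf)) * kbt
    lf <- lf_new
    if (resid < tol || iter >= max_iter) break
  }
  if (resid >= tol) {
    ov <- vapply(seq_len(K - 1), function(i) {
      r <- range(windows[[i + 1]]$samples)
      mean(windows[[i]]$samples >= r[1] & windows[[i]]$samples <= r[2])
    }, numeric(1))
    gap <- which.min(ov)
    stop("WHAM did not converge in ", max_iter, " iterations (residual ",
         signif(resid, 3), " kJ/mol); weakest window overlap between centres ",
         signif(centers[gap], 3), " and ", signif(centers[gap + 1], 3), " nm")
  }
  G <- ifelse(occ, -kbt * logP, NA_real_)
  keep <- occ & Ht >= min_count
  if (!any(keep)) stop("no bin retains min_count = ", min_count, " samples")
  s <- mids[keep]; G <- G[keep]
  bulk <- s >= bulk_interval[1] & s <= bulk_interval[2]
  if (!any(bulk)) {
    stop("bulk interval [", bulk_interval[1], ", ", bulk_interval[2],
         "] nm contains no sampled bins")
  }
  G <- G - mean(G[bulk])
  structure(list(s = s, G = G, error = rep(NA_real_, length(s)),
                 counts = Ht[keep],
                 bin_width = bin_width, bulk_interval = bulk_interval,
                 breaks = breaks, iterations = iter, residual = resid,
                 kT = kbt),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat("pmf_profile:", length(x$s), "bins over [", signif(min(x$s), 3), ",",
      signif(max(x$s), 3), "] nm; min G =", signif(min(x$G), 4),
      "kJ/mol;", x$iterations, "WHAM iterations\n")
  invisible(x)
}

# block resampling of each window's (autocorrelated) series
resample_windows <- function(windows) {
  lapply(windows, function(w) {
    s <- w$samples
    n <- length(s)
    bl <- max(1L, block_length(s))
    nb <- ceiling(n / bl)
    starts <- sample.int(max(1L, n - bl + 1L), nb, replace = TRUE)
    idx <- as.vector(outer(0:(bl - 1L), starts, `+`))[seq_len(n)]
    w$samples <- s[idx]
    w
  })
}

# block length from the integrated autocorrelation time of the series
block_length <- function(s, max_lag = min(1000L, length(s) %/% 2L)) {
  if (length(s) < 10 || stats::sd(s) == 0) return(1L)
  ac <- stats::acf(s, lag.max = max_lag, plot = FALSE)$acf[-1]
  pos <- which(ac <= 0.05)
  cut <- if (length(pos)) pos[1] else max_lag
  tau <- 1 + 2 * sum(ac[seq_len(cut)])
  max(1L, as.integer(ceiling(2 * tau)))
}

#' Well depth of a PMF
#'
#' `min(G) - mean(G over the bulk interval)`; for a bulk-zeroed profile this
#' is simply `min(G)`.  More negative means stronger binding.
#'
#' @param pmf A `pmf_profile`.
#' @param bulk_interval Bulk interval (nm); default: the profile's own.
#' @return Well depth in kJ/mol.
#' @export
well_depth <- function(pmf, bulk_interval = NULL) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (is.null(bulk_interval)) bulk_interval <- pmf$bulk_interval
  bulk <- pmf$s >= bulk_interval[1] & pmf$s <= bulk_interval[2]
  if (!any(bulk)) {
    stop("bulk interval [", bulk_interval[1], ", ", bulk_interval[2],
         "] nm lies outside the profile")
  }
  min(pmf$G) - mean(pmf$G[bulk])
}

#' Relative binding free energy from two PMFs
#'
#' For the conversion of the bound lipid from species A to species B,
#' `ddG = well_depth(B) - well_depth(A)`; positive means B binds more
#' weakly.
#'
#' @param pmf_a,pmf_b `pmf_profile` objects sharing the bulk convention.
#' @return ddG in kJ/mol.
#' @export
ddg_from_pmfs <- function(pmf_a, pmf_b) {
  well_depth(pmf_b) - well_depth(pmf_a)
}

#' PMF convergence as a function of sampling duration
#'
#' Recomputes the PMF on truncated prefixes of every window's series and
#' reports the largest absolute free-energy change between successive
#' checkpoints (on bins present in both profiles).
#'
#' @param uset An `umbrella_set`.
#' @param checkpoints Sample counts (per window) at which to evaluate;
#'   sorted internally.
#' @param ... Passed to [wham()].
#' @return List with `profiles` (one `pmf_profile` per checkpoint),
#'   `checkpoints`, and `max_deviation` (kJ/mol, between successive
#'   checkpoints).
#' @export
convergence_by_duration <- function(uset, checkpoints, ...) {
  n_avail <- min(vapply(uset$windows, function(w) length(w$samples), numeric(1)))
  checkpoints <- sort(unique(as.integer(checkpoints)))
  if (any(checkpoints > n_avail)) {
    stop("checkpoint ", max(checkpoints), " exceeds available samples (",
         n_avail, ")")
  }
  if (any(checkpoints < 1)) stop("checkpoints must be >= 1")
  profiles <- lapply(checkpoints, function(n) {
    trunc <- uset
    trunc$windows <- lapply(uset$windows, function(w) {
      w$samples <- w$samples[seq_len(n)]
      w
    })
    wham(trunc, ...)
  })
  dev <- rep(NA_real_, max(0, length(profiles) - 1))
  for (i in seq_along(dev)) {
    a <- profiles[[i]]; b <- profiles[[i + 1]]
    # compare only bins both checkpoints sample adequately, so the deviation
    # reflects the profile and not newly reached, barely occupied edge bins
    common <- intersect(round(a$s, 10), round(b$s, 10))
    ia <- match(common, round(a$s, 10)); ib <- match(common, round(b$s, 10))
    ok <- a$counts[ia] >= 10 & b$counts[ib] >= 10
    dev[i] <- max(abs(a$G[ia][ok] - b$G[ib][ok]))
  }
  list(profiles = profiles, checkpoints = checkpoints,
       max_deviation = dev)
}

#' Bootstrap error of the PMF well depth
#'
#' Standard deviation of the well depth over block-bootstrap resamples of
#' each window's series; the block length is set per window from its
#' integrated autocorrelation time (so correlated samples are not treated as
#' independent).
#'
#' @param uset An `umbrella_set`.
#' @param n_boot Number of bootstrap resamples (>= 2). Default 20.
#' @param seed RNG seed.
#' @param ... Passed to [wham()].
#' @return Bootstrap SD of the well depth (kJ/mol).
#' @export
bootstrap_well_depth_error <- function(uset, n_boot = 20L, seed = 1L, ...) {
  if (n_boot < 2) stop("need n_boot >= 2")
  # degenerate case: zero-variance windows cannot produce resampling scatter
  if (all(vapply(uset$windows,
                 function(w) stats::sd(w$samples) == 0, logical(1)))) {
    return(0)
  }
  set.seed(as.integer(seed))
  depths <- vapply(seq_len(n_boot), function(b) {
    res <- uset
    res$windows <- resample_windows(uset$windows)
    well_depth(wham(res, ...))
  }, numeric(1))
  stats::sd(depths)
}
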