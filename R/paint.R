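# DNA-PAINT post-processing: fiducial tracking, LOESS drift estimation and
# correction, 2D histogram rendering, radial cross-correlation and
# trans-synaptic 1D profiles.  The module's contract starts at localization
# tables (frame, x_nm, y_nm); spot localization itself is upstream.

#' Identify fiducial markers in a localization table
#'
#' Greedy nearest-neighbour linking: localizations are linked frame by frame
#' to the track whose last position is within \code{link_radius_nm}; tracks
#' observed in at least \code{persistence_frac} of all frames are fiducials
#' (transient binding events last only a few frames and never qualify).
#'
#' @param locs localization data.frame (frame, x_nm, y_nm)
#' @param persistence_frac minimum fraction of frames a fiducial must appear
#'   in (default 0.5)
#' @param link_radius_nm linking radius (default 100)
#' @param max_gap_frames tracks unmatched for this many frames are closed
#'   (default 50)
#' @return list of fiducial tracks, each a data.frame (frame, x_nm, y_nm)
#' @export
identify_fiducials <- function(locs, persistence_frac = 0.5,
                               link_radius_nm = 100, max_gap_frames = 50L) {
  validate_localizations(locs)
  if (nrow(locs) == 0L) stop("no fiducials: empty localization table")
  locs <- locs[order(locs$frame), ]
  total_frames <- max(locs$frame) + 1L

  # active track state: last position, last frame, row indices
  tx <- numeric(0); ty <- numeric(0); tlast <- integer(0)
  rows <- list()
  closed <- list()
  for (f in sort(unique(locs$frame))) {
    idx <- which(locs$frame == f)
    px <- locs$x_nm[idx]; py <- locs$y_nm[idx]
    used <- rep(FALSE, length(idx))
    if (length(tx)) {
      # close stale tracks first
      stale <- which(f - tlast > max_gap_frames)
      if (length(stale)) {
        closed <- c(closed, rows[stale])
        keep <- setdiff(seq_along(tx), stale)
        tx <- tx[keep]; ty <- ty[keep]; tlast <- tlast[keep]
        rows <- rows[keep]
      }
    }
    if (length(tx)) {
      for (t in seq_along(tx)) {
        d <- sqrt((px - tx[t])^2 + (py - ty[t])^2)
        d[used] <- Inf
        j <- which.min(d)
        if (length(j) && is.finite(d[j]) && d[j] <= link_radius_nm) {
          used[j] <- TRUE
          tx[t] <- px[j]; ty[t] <- py[j]; tlast[t] <- f
          rows[[t]] <- c(rows[[t]], idx[j])
        }
      }
    }
    for (j in which(!used)) {   # new tracks
      tx <- c(tx, px[j]); ty <- c(ty, py[j]); tlast <- c(tlast, f)
      rows[[length(rows) + 1L]] <- idx[j]
    }
  }
  all_tracks <- c(closed, rows)
  tracks <- lapply(all_tracks, function(r) {
    locs[r, c("frame", "x_nm", "y_nm")]
  })
  n_frames <- vapply(tracks, nrow, integer(1))
  fid <- tracks[n_frames >= persistence_frac * total_frames]
  if (length(fid) == 0L) {
    stop("no fiducials: no track persists in >= ",
         round(100 * persistence_frac), "% of frames")
  }
  fid
}

#' Estimate the drift trajectory from fiducial tracks by LOESS
#'
#' For each fiducial, the x- and y-coordinates are smoothed separately as a
#' function of frame with locally weighted regression (tricube weights,
#' degree 1, span \code{span}); each smooth curve is centered by subtracting
#' its value at the reference frame, the centered curves are averaged over
#' fiducials, and the average is interpolated to every frame.  Tracks
#' covering fewer than 10 frames are excluded with a warning.
#'
#' @param tracks list of fiducial tracks from \code{\link{identify_fiducials}}
#' @param span LOESS span as a fraction of frames (default 0.1)
#' @param frames total number of frames (default: up to the last frame seen)
#' @param reference_frame frame at which the trajectory is zero (default 0)
#' @return data.frame of class \code{drift_trajectory}: frame, dx, dy
#' @export
estimate_drift_loess <- function(tracks, span = 0.1, frames = NULL,
                                 reference_frame = 0L) {
  keep <- vapply(tracks, nrow, integer(1)) >= 10L
  if (any(!keep)) {
    warning(sum(!keep), " track(s) covering < 10 frames excluded")
  }
  tracks <- tracks[keep]
  if (length(tracks) == 0L) stop("no usable fiducial tracks")
  if (is.null(frames)) {
    frames <- max(vapply(tracks, function(t) max(t$frame), numeric(1))) + 1L
  }
  grid <- seq_len(frames) - 1L
  smooth_one <- function(tr, col) {
    d <- data.frame(f = tr$frame, y = tr[[col]])
    fit <- loess(y ~ f, data = d, span = span, degree = 1,
                 family = "gaussian")
    # smooth at observed frames, then linear interpolation to the full
    # grid (constant extrapolation beyond the track's coverage)
    approx(d$f, predict(fit), xout = grid, rule = 2)$y
  }
  dx <- matrix(0, frames, length(tracks))
  dy <- matrix(0, frames, length(tracks))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    sx <- smooth_one(tr, "x_nm")
    sy <- smooth_one(tr, "y_nm")
    ref <- which(grid == reference_frame)
    dx[, i] <- sx - sx[ref]
    dy[, i] <- sy - sy[ref]
  }
  out <- data.frame(frame = grid, dx = rowMeans(dx), dy = rowMeans(dy))
  class(out) <- c("drift_trajectory", "data.frame")
  out
}

#' Apply (or undo) a drift correction to a localization table
#'
#' Shifts the localization at frame f by -(dx_f, dy_f).  The same
#' trajectory aligns tables from different imaging rounds that share
#' fiducials.
#'
#' @param locs localization data.frame
#' @param trajectory a \code{drift_trajectory} (frame, dx, dy), defined for
#'   every frame present in \code{locs}
#' @return corrected localization table
#' @export
correct_drift <- function(locs, trajectory) {
  validate_localizations(locs)
  idx <- match(locs$frame, trajectory$frame)
  if (anyNA(idx)) {
    stop("trajectory does not cover frame(s): ",
         paste(head(unique(locs$frame[is.na(idx)])), collapse = ", "))
  }
  locs$x_nm <- locs$x_nm - trajectory$dx[idx]
  locs$y_nm <- locs$y_nm - trajectory$dy[idx]
  locs
}

#' Negate a drift trajectory
#' @param trajectory a \code{drift_trajectory}
#' @return the trajectory with dx, dy negated
#' @export
negate_trajectory <- function(trajectory) {
  trajectory$dx <- -trajectory$dx
  trajectory$dy <- -trajectory$dy
  trajectory
}

#' Render a super-resolution image from localizations
#'
#' 2D histogram of the (x, y) coordinates with square bins of
#' \code{bin_nm} (default 5.4 nm), followed by Gaussian smoothing with SD
#' \code{smooth_sigma_bins} bins.  The raw histogram conserves the
#' localization count exactly; smoothing can lose a small fraction of mass
#' at the image border, which is reported.
#'
#' @param locs localization data.frame
#' @param bin_nm bin size in nm (default 5.4)
#' @param smooth_sigma_bins Gaussian SD in bins (default 1; 0 disables)
#' @param extent optional list(x = c(min, max), y = c(min, max)) in nm;
#'   default spans the data plus a 3-sigma margin
#' @return list of class \code{sr_image}: image (matrix, rows = y),
#'   bin_nm, x0_nm, y0_nm (origin of the first bin), n (localizations
#'   binned), mass_fraction (smoothed mass / n)
#' @export
render_histogram <- function(locs, bin_nm = 5.4, smooth_sigma_bins = 1,
                             extent = NULL) {
  validate_localizations(locs)
  if (nrow(locs) == 0L) stop("cannot render an empty localization table")
  pad <- 3 * max(smooth_sigma_bins, 1) * bin_nm
  if (is.null(extent)) {
    extent <- list(x = range(locs$x_nm) + c(-pad, pad),
                   y = range(locs$y_nm) + c(-pad, pad))
  }
  nx <- max(1L, ceiling(diff(extent$x) / bin_nm))
  ny <- max(1L, ceiling(diff(extent$y) / bin_nm))
  ix <- floor((locs$x_nm - extent$x[1]) / bin_nm) + 1L
  iy <- floor((locs$y_nm - extent$y[1]) / bin_nm) + 1L
  ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  img <- matrix(0, ny, nx)
  counts <- table(factor((ix[ok] - 1L) * ny + iy[ok],
                         levels = seq_len(nx * ny)))
  img[] <- as.numeric(counts)
  n <- sum(ok)
  if (smooth_sigma_bins > 0) img <- gaussian_smooth(img, smooth_sigma_bins)
  structure(list(image = img, bin_nm = bin_nm,
                 x0_nm = extent$x[1], y0_nm = extent$y[1], n = n,
                 mass_fraction = sum(img) / n),
            class = "sr_image")
}

#' Normalized radial cross-correlation between two rendered channels
#'
#' The pair cross-correlation C(r) = <A(x) B(x + r)> / (<A> <B>) is
#' computed for all displacements by FFT with zero padding (overlap-area
#' edge correction), averaged over displacement angle in annuli of width
#' \code{bin_r_nm}, so that the no-correlation baseline is 1.  The decay
#' length is the smallest r at which C(r) - 1 has fallen below
#' (C(0) - 1) / e (or below half, with \code{decay = "half"}); for an
#' isotropic Gaussian structure of SD sigma the 1/e decay length is
#' 2 sigma.
#'
#' @param a,b \code{sr_image}s on the same geometry (same bin size and
#'   extent)
#' @param max_r_nm largest radial shift evaluated (default a quarter of the
#'   smaller image side)
#' @param bin_r_nm radial bin width (default: the rendering bin size)
#' @param decay "e" (1/e, default) or "half"
#' @return list of class \code{radial_corr}: r_nm, corr, decay_length_nm,
#'   baseline
#' @export
radial_cross_correlation <- function(a, b, max_r_nm = NULL, bin_r_nm = NULL,
                                     decay = c("e", "half")) {
  decay <- match.arg(decay)
  stopifnot(inherits(a, "sr_image"), inherits(b, "sr_image"))
  if (a$bin_nm != b$bin_nm ||
      !identical(dim(a$image), dim(b$image))) {
    stop("images must share geometry (bin size and extent)")
  }
  A <- a$image; B <- b$image
  if (sum(A) <= 0 || sum(B) <= 0) stop("empty image")
  bin <- a$bin_nm
  if (is.null(bin_r_nm)) bin_r_nm <- bin
  nr <- nrow(A); nc <- ncol(A)
  if (is.null(max_r_nm)) max_r_nm <- min(nr, nc) / 4 * bin

  # zero padding against wrap-around, at FFT-friendly sizes
  pr <- stats::nextn(2L * nr, c(2, 3, 5))
  pc <- stats::nextn(2L * nc, c(2, 3, 5))
  pad <- function(m) { z <- matrix(0, pr, pc); z[1:nr, 1:nc] <- m; z }
  FA <- stats::fft(pad(A)); FB <- stats::fft(pad(B))
  FW <- stats::fft(pad(matrix(1, nr, nc)))
  cc <- Re(stats::fft(Conj(FA) * FB, inverse = TRUE)) / (pr * pc)
  ww <- Re(stats::fft(Conj(FW) * FW, inverse = TRUE)) / (pr * pc)

  # displacement grid (fftshift convention)
  sy <- c(0:(pr / 2 - 1), -(pr / 2):-1)
  sx <- c(0:(pc / 2 - 1), -(pc / 2):-1)
  rr <- sqrt(outer(sy^2, sx^2, "+")) * bin
  valid <- ww > 0.5   # at least one overlapping pixel pair
  corr2d <- matrix(NA_real_, pr, pc)
  corr2d[valid] <- (cc[valid] / ww[valid]) / (mean(A) * mean(B))

  keep <- valid & rr <= max_r_nm
  rbin <- floor(rr[keep] / bin_r_nm)
  vals <- rowsum(corr2d[keep], rbin)
  cnts <- rowsum(rep(1, sum(keep)), rbin)
  r_nm <- (as.numeric(rownames(vals)) + 0.5) * bin_r_nm
  curve <- vals[, 1] / cnts[, 1]
  ord <- order(r_nm)
  r_nm <- r_nm[ord]; curve <- curve[ord]
  # C(0) from the zero-displacement bin
  c0 <- curve[1]
  target <- if (decay == "e") (c0 - 1) / exp(1) else (c0 - 1) / 2
  below <- which(curve - 1 < target)
  decay_len <- if (length(below)) r_nm[below[1]] else NA_real_
  structure(list(r_nm = r_nm, corr = curve, decay_length_nm = decay_len,
                 baseline = 1, c0 = c0, decay = decay),
            class = "radial_corr")
}

#' Trans-synaptic 1D profiles of localization channels
#'
#' Projects the localizations of each channel inside an oriented box onto
#' the box axis, and reports the per-channel 1D histogram, the median
#' position along the axis, and the Gaussian-fit FWHM
#' (2 sqrt(2 ln 2) sigma-hat).  Channels with fewer than
#' \code{min_locs} localizations in the box omit the FWHM but still report
#' the median.
#'
#' @param locs_by_channel named list of localization tables
#' @param center box centre (x_nm, y_nm)
#' @param axis_angle trans-synaptic axis angle in radians
#' @param length_nm box extent along the axis
#' @param width_nm box extent across the axis
#' @param bin_nm histogram bin width (default 10)
#' @param min_locs minimum localizations for a FWHM fit (default 20)
#' @return list per channel: histogram (data.frame position_nm, count),
#'   median_nm, fwhm_nm (NA if omitted), n
#' @export
transsynaptic_profile <- function(locs_by_channel, center, axis_angle = 0,
                                  length_nm = 600, width_nm = 300,
                                  bin_nm = 10, min_locs = 20L) {
  u <- c(cos(axis_angle), sin(axis_angle))
  v <- c(-u[2], u[1])
  breaks <- seq(-length_nm / 2, length_nm / 2 + bin_nm, by = bin_nm) -
    bin_nm / 2
  lapply(locs_by_channel, function(locs) {
    validate_localizations(locs)
    rx <- locs$x_nm - center[1]
    ry <- locs$y_nm - center[2]
    along <- rx * u[1] + ry * u[2]
    across <- rx * v[1] + ry * v[2]
    inbox <- abs(along) <= length_nm / 2 & abs(across) <= width_nm / 2
    al <- along[inbox]
    h <- hist(al, breaks = breaks, plot = FALSE)
    fwhm <- NA_real_
    if (length(al) >= min_locs) {
      fit <- tryCatch(fit_gaussian_profile(h$mids, h$counts),
                      error = function(e) NULL)
      if (!is.null(fit)) fwhm <- fit$fwhm
    }
    list(histogram = data.frame(position_nm = h$mids, count = h$counts),
         median_nm = if (length(al)) median(al) else NA_real_,
         fwhm_nm = fwhm, n = length(al))
  })
}
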