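# Flat-field illumination correction and round-to-round rigid registration.
#
# Illumination inhomogeneity in spinning-disk confocal data is
# multiplicative (laser beam profile), so each plane is divided by a
# per-channel, per-plate illumination profile estimated from the morphological
# background of many fields.  Inter-round lateral drift is rigid at the
# integer-pixel level and is estimated on the reference (MAP2) channel by the
# peak of the normalized spatial cross-correlation function.

#' Morphological background of a grayscale plane
#'
#' Opening (erosion then dilation) with a disc structuring element removes
#' structures smaller than the disc, leaving the smooth background.  The
#' result is pixelwise less than or equal to the input (anti-extensivity) and
#' idempotent.
#'
#' @param image numeric matrix
#' @param disk_radius disc radius in pixels (default 100)
#' @return background image, same size
#' @export
estimate_background <- function(image, disk_radius = 100) {
  if (disk_radius >= min(dim(image)) / 2) {
    stop("disk_radius must be smaller than half the image size")
  }
  lo <- min(image)
  hi <- max(image)
  if (hi - lo <= 0) return(image)   # opening is the identity on constants
  # EBImage grayscale morphology expects values in [0, 1]
  sc <- (image - lo) / (hi - lo)
  op <- EBImage::opening(sc, disc_brush(disk_radius))
  matrix(as.numeric(EBImage::imageData(op)), nrow(image), ncol(image)) *
    (hi - lo) + lo
}

#' Estimate a per-channel illumination profile
#'
#' Pixelwise mean of background images from the same channel (and plate),
#' rescaled to spatial mean 1 so that correction preserves average
#' intensity.  Profiles vary between experiments and should be estimated
#' per plate.
#'
#' Because the illumination field is a smooth optical property, the averaged
#' background is Gaussian-smoothed (SD \code{smooth_sigma_px}) before
#' normalization; this stabilizes profiles estimated from few fields and
#' removes isolated zero-count pixels.  Set \code{smooth_sigma_px = 0} to
#' disable.
#'
#' @param backgrounds list of background images (same channel, same plate)
#' @param smooth_sigma_px Gaussian SD of the profile smoothing (default 10)
#' @return list of class \code{illumination_profile}: field (matrix, mean 1),
#'   n (number of fields averaged)
#' @export
estimate_illumination_profile <- function(backgrounds, smooth_sigma_px = 10) {
  if (!is.list(backgrounds)) backgrounds <- list(backgrounds)
  stopifnot(length(backgrounds) >= 1L)
  d <- dim(backgrounds[[1]])
  ok <- vapply(backgrounds, function(b) identical(dim(b), d), logical(1))
  if (!all(ok)) stop("all background images must have the same size")
  avg <- Reduce(`+`, backgrounds) / length(backgrounds)
  if (smooth_sigma_px > 0) avg <- gaussian_smooth(avg, smooth_sigma_px)
  m <- mean(avg)
  if (m <= 0) stop("average background has non-positive mean")
  field <- avg / m
  if (any(field <= 0)) stop("illumination profile must be strictly positive")
  structure(list(field = field, n = length(backgrounds)),
            class = "illumination_profile")
}

#' Flat-field correct a plane
#'
#' Pixelwise division by the illumination profile.  Because the profile has
#' spatial mean 1, the average intensity of the plane is approximately
#' preserved.
#'
#' @param image numeric matrix
#' @param profile an \code{illumination_profile} or a positive matrix
#' @return corrected image
#' @export
flat_field_correct <- function(image, profile) {
  field <- if (inherits(profile, "illumination_profile")) profile$field
  else profile
  if (!identical(dim(image), dim(field))) {
    stop("image and illumination profile dimensions differ")
  }
  if (any(field <= 0)) stop("illumination profile must be strictly positive")
  image / field
}

#' Estimate integer rigid drift between two planes
#'
#' Returns the integer shift (dx, dy) maximizing the normalized
#' cross-correlation between \code{reference} and \code{moving} over the
#' search window \code{[-max_shift, max_shift]^2}; the convention is that
#' \code{moving} equals \code{reference} translated by (dx, dy)
#' (content moved +dx along x = columns, +dy along y = rows).  For each
#' candidate shift the Pearson correlation is computed over the overlap
#' region only (zero-padded borders do not bias the estimate).  Exact ties
#' are broken by smallest |dx| + |dy|, then lexicographically by (dx, dy).
#'
#' The cross terms are computed with FFTs and the overlap moments with
#' integral images, so the estimator is exactly the exhaustive search at any
#' image size.
#'
#' @param reference,moving numeric matrices of the same size
#' @param max_shift search radius in pixels (default 50)
#' @param subpixel if TRUE, refine the integer peak by parabolic
#'   interpolation of the correlation surface (off by default; downstream
#'   registration uses integer shifts)
#' @return list of class \code{rigid_shift}: dx, dy, ncc (peak correlation);
#'   with \code{subpixel}, also dx_sub, dy_sub
#' @export
estimate_xy_drift <- function(reference, moving, max_shift = 50,
                              subpixel = FALSE) {
  stopifnot(identical(dim(reference), dim(moving)))
  if (sd(reference) == 0 || sd(moving) == 0) {
    stop("blank (zero-variance) input: round cannot be registered")
  }
  nr <- nrow(reference); nc <- ncol(reference)
  max_shift <- as.integer(min(max_shift, nr - 2L, nc - 2L))
  stopifnot(max_shift >= 0L)

  # cross term sum_x ref(x) * mov(x + s) for all s, via zero-padded FFT
  pr <- nr + max_shift * 2L; pc <- nc + max_shift * 2L
  A <- matrix(0, pr, pc); A[1:nr, 1:nc] <- reference
  B <- matrix(0, pr, pc); B[1:nr, 1:nc] <- moving
  cc <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE)) /
    (pr * pc)
  # cc[1 + ((sy) mod pr), 1 + ((sx) mod pc)] = sum ref(x) mov(x + s)

  # integral images for overlap moments
  ii <- function(m) {
    z <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
    z[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
    z
  }
  Sr <- ii(reference); Sr2 <- ii(reference^2)
  Sm <- ii(moving); Sm2 <- ii(moving^2)
  rect <- function(S, r0, r1, c0, c1) {
    S[r1 + 1L, c1 + 1L] - S[r0, c1 + 1L] - S[r1 + 1L, c0] + S[r0, c0]
  }

  shifts <- expand.grid(dx = -max_shift:max_shift, dy = -max_shift:max_shift)
  ncc <- numeric(nrow(shifts))
  for (i in seq_len(nrow(shifts))) {
    sx <- shifts$dx[i]; sy <- shifts$dy[i]
    # overlap in reference coordinates: mov(x + s) defined for x + s in frame
    r0 <- max(1L, 1L - sy); r1 <- min(nr, nr - sy)
    c0 <- max(1L, 1L - sx); c1 <- min(nc, nc - sx)
    n <- (r1 - r0 + 1L) * (c1 - c0 + 1L)
    if (n < 4L) { ncc[i] <- -Inf; next }
    cross <- cc[1L + ((sy) %% pr), 1L + ((sx) %% pc)]
    sa <- rect(Sr, r0, r1, c0, c1); sa2 <- rect(Sr2, r0, r1, c0, c1)
    sb <- rect(Sm, r0 + sy, r1 + sy, c0 + sx, c1 + sx)
    sb2 <- rect(Sm2, r0 + sy, r1 + sy, c0 + sx, c1 + sx)
    va <- sa2 - sa^2 / n
    vb <- sb2 - sb^2 / n
    if (va <= 1e-12 || vb <= 1e-12) { ncc[i] <- -Inf; next }
    ncc[i] <- (cross - sa * sb / n) / sqrt(va * vb)
  }
  # peak with tie-breaks: highest ncc, then smallest |dx|+|dy|, then (dx, dy)
  r <- round(ncc, 9)
  ord <- order(-r, abs(shifts$dx) + abs(shifts$dy), shifts$dx, shifts$dy)
  best <- ord[1]
  out <- list(dx = shifts$dx[best], dy = shifts$dy[best], ncc = ncc[best])
  if (subpixel) {
    para <- function(ym, y0, yp) {
      d <- ym - 2 * y0 + yp
      if (d >= 0) 0 else 0.5 * (ym - yp) / d
    }
    at <- function(dx, dy) {
      j <- which(shifts$dx == dx & shifts$dy == dy)
      if (length(j)) ncc[j] else NA_real_
    }
    dxs <- out$dx; dys <- out$dy
    xm <- at(dxs - 1, dys); xp <- at(dxs + 1, dys)
    ym <- at(dxs, dys - 1); yp <- at(dxs, dys + 1)
    out$dx_sub <- dxs + if (is.finite(xm) && is.finite(xp))
      para(xm, out$ncc, xp) else 0
    out$dy_sub <- dys + if (is.finite(ym) && is.finite(yp))
      para(ym, out$ncc, yp) else 0
  }
  class(out) <- "rigid_shift"
  out
}

#' Register all rounds of an image set to a reference round
#'
#' Estimates per-round drift on the reference channel (which must be present
#' in every round) against the first round, then translates every plane of
#' each round by the negated estimate.  Out-of-frame pixels are zero-filled
#' and flagged in per-round validity masks, which downstream measurement
#' stages exclude.
#'
#' @param x an \code{image_set}
#' @param reference_channel channel used for registration (default "MAP2")
#' @param max_shift search radius in pixels
#' @return list: images (aligned \code{image_set} with \code{masks}),
#'   shifts (data.frame round, dx, dy, ncc)
#' @export
register_rounds <- function(x, reference_channel = "MAP2", max_shift = 50) {
  stopifnot(inherits(x, "image_set"))
  rounds <- sort(unique(x$info$round[!is.na(x$info$round)]))
  ref_idx <- which(x$info$channel == reference_channel)
  if (length(ref_idx) == 0L) {
    stop("reference channel '", reference_channel, "' not present")
  }
  have <- x$info$round[ref_idx]
  if (!all(rounds %in% have)) {
    stop("reference channel '", reference_channel,
         "' missing from round(s): ",
         paste(setdiff(rounds, have), collapse = ", "))
  }
  ref_round <- rounds[1]
  ref_img <- get_plane(x, reference_channel, ref_round)

  shifts <- data.frame(round = rounds, dx = 0L, dy = 0L, ncc = 1)
  planes <- x$planes
  masks <- stats::setNames(
    lapply(rounds, function(r) matrix(TRUE, nrow(ref_img), ncol(ref_img))),
    as.character(rounds))
  for (r in rounds) {
    if (r == ref_round) next
    mov <- get_plane(x, reference_channel, r)
    est <- estimate_xy_drift(ref_img, mov, max_shift = max_shift)
    shifts[shifts$round == r, c("dx", "dy", "ncc")] <-
      list(est$dx, est$dy, est$ncc)
    idx <- which(x$info$round == r)
    for (i in idx) {
      sh <- shift_image(planes[[i]], -est$dx, -est$dy)
      planes[[i]] <- sh$image
      masks[[as.character(r)]] <- sh$mask
    }
  }
  aligned <- image_set(planes, x$info, pixel_size_nm = x$pixel_size_nm,
                       well = x$well, masks = masks)
  list(images = aligned, shifts = shifts)
}

#' Flat-field correct every plane of an image set
#'
#' Applies \code{\link{flat_field_correct}} channel-wise, using one profile
#' per channel.
#'
#' @param x an \code{image_set}
#' @param profiles named list of \code{illumination_profile} (or matrices),
#'   one per channel; channels without a profile pass through unchanged
#' @return corrected \code{image_set}
#' @export
flat_field_correct_set <- function(x, profiles) {
  stopifnot(inherits(x, "image_set"))
  planes <- x$planes
  for (i in seq_along(planes)) {
    cname <- x$info$channel[i]
    if (!is.null(profiles[[cname]])) {
      planes[[i]] <- flat_field_correct(planes[[i]], profiles[[cname]])
    }
  }
  image_set(planes, x$info, pixel_size_nm = x$pixel_size_nm, well = x$well,
            masks = x$masks)
}
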