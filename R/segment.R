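# Per-channel punctae segmentation and synapse identification.
#
# The segmentation recipe: percentile contrast stretch, adaptive 5x5 Wiener
# denoising, white top-hat enhancement with an 8 px disc, object-count-
# maximizing thresholding, watershed splitting of touching punctae, and
# measurement of area / integrated intensity / intensity-weighted centroid
# on the corrected (un-enhanced) image.  Synapses are synapse-marker
# (synapsin-I) punctae larger than 0.42 um^2 whose centroid lies outside the
# nuclear mask; punctae of other channels are attached to synapses by
# weighted-centroid distance < 1 um.

#' Enhance punctae in a corrected plane
#'
#' Three steps: (1) saturate the lowest and highest \code{saturation_frac}
#' of pixel intensities and rescale to the full range of a
#' \code{bit_depth}-bit image (integer gray levels, as \code{imadjust}-style
#' contrast adjustment produces); (2) adaptive Wiener denoising in
#' \code{wiener_size} x \code{wiener_size} windows (local mean/variance
#' shrinkage with the noise floor estimated as the mean local variance),
#' (3) white top-hat with a disc of radius \code{tophat_radius}, which
#' removes structures larger than the disc (dendrite shafts, nuclei, the
#' smooth diffuse background) and leaves compact punctae on a near-zero
#' background; the result is rounded to gray levels.  The final
#' quantization matters: the Wiener-flattened, top-hatted background
#' fluctuates well below half a gray level and rounds to exactly zero, so
#' the threshold scan ranges over punctae intensities rather than the
#' noise floor.
#'
#' @param image corrected grayscale plane
#' @param saturation_frac fraction saturated at each tail (default 0.01)
#' @param wiener_size Wiener window side in pixels (default 5)
#' @param tophat_radius top-hat disc radius in pixels (default 8)
#' @param bit_depth gray-level depth of the stretched image (default 8)
#' @return enhanced image in gray levels, non-negative, same size
#' @export
enhance_punctae <- function(image, saturation_frac = 0.01, wiener_size = 5L,
                            tophat_radius = 8L, bit_depth = 8L) {
  qs <- quantile(image, c(saturation_frac, 1 - saturation_frac), names = FALSE)
  if (qs[2] <= qs[1]) stop("image has no contrast to stretch")
  levels <- 2^bit_depth - 1
  x <- pmin(pmax(image, qs[1]), qs[2])
  x <- (x - qs[1]) / (qs[2] - qs[1])
  x <- wiener_filter(x, wiener_size)
  th <- EBImage::whiteTopHat(x, disc_brush(tophat_radius))
  out <- matrix(as.numeric(EBImage::imageData(th)), nrow(image), ncol(image))
  pmax(round(out * levels), 0)
}

#' Adaptive Wiener denoising (local mean/variance shrinkage)
#'
#' For each pixel, with local mean m and local variance v over the window
#' and noise floor nu = mean(v) over the image:
#' out = m + max(v - nu, 0) / max(v, nu) * (x - m).
#' Flat regions collapse to their local mean; high-variance structure is
#' preserved.
#'
#' @param image numeric matrix
#' @param size window side (odd integer, default 5)
#' @return filtered matrix
#' @export
wiener_filter <- function(image, size = 5L) {
  size <- as.integer(size)
  stopifnot(size >= 3L, size %% 2L == 1L)
  box <- matrix(1 / size^2, size, size)
  m <- EBImage::filter2(image, box, boundary = "replicate")
  m2 <- EBImage::filter2(image^2, box, boundary = "replicate")
  m <- matrix(as.numeric(m), nrow(image), ncol(image))
  m2 <- matrix(as.numeric(m2), nrow(image), ncol(image))
  v <- pmax(m2 - m^2, 0)
  nu <- mean(v)
  gain <- ifelse(pmax(v, nu) > 0, pmax(v - nu, 0) / pmax(v, nu), 0)
  m + gain * (image - m)
}

#' Object-count-maximizing threshold
#'
#' Scans candidate thresholds (quantile-spaced over the nonzero pixel
#' intensities, so the choice is invariant to monotone rescaling) and for
#' each counts the 8-connected foreground components with at least
#' \code{min_object_px} pixels.  The threshold producing the maximum object
#' count is returned; exact ties are broken by the lowest such threshold
#' (the most inclusive segmentation).
#'
#' @param image enhanced (non-negative) plane
#' @param n_levels number of quantile-spaced candidates (default 100)
#' @param min_object_px minimum component area counted (default 2)
#' @return list: threshold, n_objects, candidates (data.frame threshold,
#'   n_objects)
#' @export
optimal_object_threshold <- function(image, n_levels = 100L,
                                     min_object_px = 2L) {
  nz <- image[image > 0]
  if (length(nz) == 0L) stop("no objects: image has no positive pixels")
  cand <- unique(quantile(nz, seq(0, 1, length.out = n_levels),
                          names = FALSE))
  counts <- integer(length(cand))
  for (i in seq_along(cand)) {
    lab <- label_components(image >= cand[i], connectivity = 8L)
    if (max(lab) == 0L) { counts[i] <- 0L; next }
    areas <- tabulate(lab[lab > 0L])
    counts[i] <- sum(areas >= min_object_px)
  }
  best <- which(counts == max(counts))[1]   # candidates ascending -> lowest
  list(threshold = cand[best], n_objects = counts[best],
       candidates = data.frame(threshold = cand, n_objects = counts))
}

#' Split touching punctae by watershed
#'
#' Watershed transform on the negated Euclidean distance transform of the
#' mask, with catchment basins grown from local maxima of the distance map
#' (detected within an \code{ext}-pixel neighbourhood, i.e. minimum seed
#' separation); every foreground pixel receives exactly one label, so
#' foreground area is conserved.
#'
#' @param mask logical or 0/1 matrix
#' @param min_seed_sep minimum separation of watershed seeds in pixels
#'   (default 3)
#' @param tolerance minimum distance-map height separating two objects
#'   (default 0.5 px)
#' @return integer label matrix
#' @export
split_touching <- function(mask, min_seed_sep = 3L, tolerance = 0.5) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  if (sum(m) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- EBImage::distmap(m)
  ws <- EBImage::watershed(dm, tolerance = tolerance, ext = min_seed_sep)
  matrix(as.integer(EBImage::imageData(ws)), nrow(mask), ncol(mask))
}

#' Segment one channel into a punctae set
#'
#' Composition enhance -> threshold -> watershed split -> measure.  Area,
#' integrated intensity and intensity-weighted centroid are measured on the
#' corrected image passed in, not on the enhanced image (the top-hat
#' distorts intensities).
#'
#' @param image flat-field-corrected, registered plane
#' @param pixel_size_nm physical pixel size
#' @param channel channel name carried into the output
#' @param mask optional logical matrix of valid pixels (from registration);
#'   pixels outside are excluded before segmentation
#' @param saturation_frac,wiener_size,tophat_radius see
#'   \code{\link{enhance_punctae}}
#' @param n_levels,min_object_px see \code{\link{optimal_object_threshold}}
#' @param min_seed_sep,tolerance see \code{\link{split_touching}}
#' @return object of class \code{puncta_set}: labels (integer matrix),
#'   measurements (data.frame id, area_px, area_um2, integrated, mean, x, y),
#'   channel, pixel_size_nm, threshold
#' @export
segment_channel <- function(image, pixel_size_nm, channel = "channel",
                            mask = NULL,
                            saturation_frac = 0.01, wiener_size = 5L,
                            tophat_radius = 8L, n_levels = 100L,
                            min_object_px = 2L, min_seed_sep = 3L,
                            tolerance = 0.5) {
  stopifnot(pixel_size_nm > 0)
  work <- image
  if (!is.null(mask)) work[!mask] <- 0
  empty <- function() {
    structure(list(
      labels = matrix(0L, nrow(image), ncol(image)),
      measurements = data.frame(id = integer(), area_px = integer(),
                                area_um2 = numeric(), integrated = numeric(),
                                mean = numeric(), x = numeric(),
                                y = numeric()),
      channel = channel, pixel_size_nm = pixel_size_nm,
      threshold = NA_real_), class = "puncta_set")
  }
  enh <- tryCatch(
    enhance_punctae(work, saturation_frac, wiener_size, tophat_radius),
    error = function(e) NULL)
  if (is.null(enh) || all(enh <= 0)) return(empty())
  thr <- optimal_object_threshold(enh, n_levels, min_object_px)
  bin <- enh >= thr$threshold
  lab <- split_touching(bin, min_seed_sep, tolerance)
  if (max(lab) > 0L) {   # drop fragments below the scan's area floor
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= min_object_px)
    lab[!(lab %in% keep)] <- 0L
    lab[lab > 0L] <- match(lab[lab > 0L], keep)
  }
  meas <- label_measurements(lab, work)
  meas$area_um2 <- meas$area_px * (pixel_size_nm / 1000)^2
  meas$mean <- ifelse(meas$area_px > 0, meas$integrated / meas$area_px, 0)
  meas <- meas[, c("id", "area_px", "area_um2", "integrated", "mean",
                   "x", "y")]
  structure(list(labels = lab, measurements = meas, channel = channel,
                 pixel_size_nm = pixel_size_nm, threshold = thr$threshold),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("puncta_set '%s': %d punctae, threshold %.4g, %.0f nm/px\n",
              x$channel, nrow(x$measurements), x$threshold,
              x$pixel_size_nm))
  invisible(x)
}

#' Nuclear mask from the nuclear (DAPI) channel
#'
#' Global Otsu threshold, hole filling, removal of objects smaller than
#' \code{min_area_um2}, and a 1 px dilation.  A blank channel yields an
#' empty mask with a warning.
#'
#' @param image nuclear-channel plane
#' @param pixel_size_nm physical pixel size
#' @param min_area_um2 minimum nucleus area kept (default 20)
#' @param dilate_px dilation radius in pixels (default 1)
#' @return logical matrix, TRUE inside nuclei
#' @export
nuclear_mask <- function(image, pixel_size_nm, min_area_um2 = 20,
                         dilate_px = 1L) {
  lo <- min(image); hi <- max(image)
  if (hi - lo <= 0) {
    warning("blank nuclear channel: returning empty mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  sc <- (image - lo) / (hi - lo)
  th <- EBImage::otsu(EBImage::Image(sc))
  m <- sc > th
  m <- EBImage::fillHull(EBImage::bwlabel(m)) > 0
  m <- matrix(as.logical(m), nrow(image), ncol(image))
  lab <- label_components(m, connectivity = 8L)
  if (max(lab) > 0L) {
    min_px <- min_area_um2 / (pixel_size_nm / 1000)^2
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= min_px)
    m <- matrix(lab %in% keep, nrow(image), ncol(image))
  }
  if (any(m) && dilate_px > 0L) {
    d <- EBImage::dilate(matrix(as.numeric(m), nrow(m), ncol(m)),
                         disc_brush(dilate_px))
    m <- matrix(as.numeric(EBImage::imageData(d)) > 0, nrow(m), ncol(m))
  }
  m
}

#' Identify synapses among synapse-marker punctae
#'
#' A punctum is a synapse if its area is strictly larger than
#' \code{min_area_um2} (default 0.42) and its intensity-weighted centroid
#' lies outside the nuclear mask (intranuclear synapsin punctae are mostly
#' not synapses).
#'
#' @param puncta a \code{puncta_set} of the synapse-marker channel
#' @param nuclear_mask logical matrix (TRUE inside nuclei), or NULL to skip
#'   nuclear exclusion
#' @param min_area_um2 strict area gate in um^2 (default 0.42)
#' @return object of class \code{synapse_set}: synapses (data.frame
#'   synapse_id, punctum_id, x, y, area_px, area_um2, integrated, mean,
#'   in_nucleus), plus the marker \code{puncta_set}
#' @export
detect_synapses <- function(puncta, nuclear_mask = NULL,
                            min_area_um2 = 0.42) {
  stopifnot(inherits(puncta, "puncta_set"))
  m <- puncta$measurements
  in_nuc <- rep(FALSE, nrow(m))
  if (!is.null(nuclear_mask) && nrow(m) > 0L) {
    rr <- pmin(pmax(round(m$y) + 1L, 1L), nrow(nuclear_mask))
    cc <- pmin(pmax(round(m$x) + 1L, 1L), ncol(nuclear_mask))
    in_nuc <- nuclear_mask[cbind(rr, cc)]
  }
  keep <- m$area_um2 > min_area_um2 & !in_nuc
  syn <- m[keep, , drop = FALSE]
  out <- data.frame(synapse_id = seq_len(nrow(syn)),
                    punctum_id = syn$id, x = syn$x, y = syn$y,
                    area_px = syn$area_px, area_um2 = syn$area_um2,
                    integrated = syn$integrated, mean = syn$mean)
  rownames(out) <- NULL
  structure(list(synapses = out, marker = puncta,
                 min_area_um2 = min_area_um2), class = "synapse_set")
}

#' @export
print.synapse_set <- function(x, ...) {
  cat(sprintf("synapse_set: %d synapses (marker '%s', area > %.2f um^2)\n",
              nrow(x$synapses), x$marker$channel, x$min_area_um2))
  invisible(x)
}

#' Colocalize channel punctae with synapses
#'
#' Assigns punctae of one channel to synapses by intensity-weighted centroid
#' distance.  Candidate pairs with distance strictly below
#' \code{max_dist_um} are matched greedily in order of increasing distance
#' (ties: lower synapse id, then lower punctum id), so each synapse receives
#' its nearest available punctum and each punctum is assigned to at most one
#' synapse.
#'
#' @param synapses a \code{synapse_set}
#' @param puncta a \code{puncta_set} of the channel being attached
#' @param max_dist_um strict distance gate in micrometres (default 1.0)
#' @return data.frame: synapse_id, punctum_id (NA when absent), distance_um
#' @export
colocalize <- function(synapses, puncta, max_dist_um = 1.0) {
  stopifnot(inherits(synapses, "synapse_set"), inherits(puncta, "puncta_set"))
  if (synapses$marker$pixel_size_nm != puncta$pixel_size_nm) {
    stop("pixel size mismatch between synapse set and puncta set")
  }
  px_um <- puncta$pixel_size_nm / 1000
  s <- synapses$synapses
  p <- puncta$measurements
  out <- data.frame(synapse_id = s$synapse_id,
                    punctum_id = rep(NA_integer_, nrow(s)),
                    distance_um = rep(NA_real_, nrow(s)))
  if (nrow(s) == 0L || nrow(p) == 0L) return(out)
  dx <- outer(s$x, p$x, "-"); dy <- outer(s$y, p$y, "-")
  d_um <- sqrt(dx^2 + dy^2) * px_um
  cand <- which(d_um < max_dist_um, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(out)
  cd <- data.frame(si = cand[, 1], pi = cand[, 2],
                   d = d_um[cand])
  cd <- cd[order(cd$d, cd$si, cd$pi), ]
  s_free <- rep(TRUE, nrow(s)); p_free <- rep(TRUE, nrow(p))
  for (i in seq_len(nrow(cd))) {
    si <- cd$si[i]; pi <- cd$pi[i]
    if (s_free[si] && p_free[pi]) {
      out$punctum_id[si] <- p$id[pi]
      out$distance_um[si] <- cd$d[i]
      s_free[si] <- FALSE; p_free[pi] <- FALSE
    }
  }
  out
}
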