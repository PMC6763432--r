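# Shared low-level helpers: brushes, connected components, coordinate
# conventions, small numerical utilities.
#
# Coordinate convention used throughout the package: images are base R
# matrices with rows = y and columns = x; pixel (x, y) in 0-based continuous
# coordinates has its centre at matrix element [y + 1, x + 1].  Intervals are
# half-open; physical units (nm, um) are explicit in argument and column
# names.

#' Disc-shaped structuring element
#'
#' @param radius_px disc radius in pixels (integer >= 1)
#' @return binary matrix usable as an EBImage brush
#' @keywords internal
disc_brush <- function(radius_px) {
  radius_px <- as.integer(round(radius_px))
  stopifnot(radius_px >= 1L)
  EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
}

#' Label connected components of a binary mask
#'
#' 8-connectivity (edge or corner adjacency) by default, matching the
#' diagonal boundaries produced by watershed splitting.  Built on
#' \code{EBImage::bwlabel} (4-connected) plus a union-find merge of
#' diagonally adjacent labels.
#'
#' @param mask logical or 0/1 matrix
#' @param connectivity 4 or 8
#' @return integer matrix of labels, 0 = background, labels contiguous from 1
#' @keywords internal
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab == 0L || connectivity == 4L) return(lab)

  # collect label pairs adjacent along the two diagonals
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # down-left diagonal
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(pairs) == 0L) return(lab)

  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pairs <- unique(pairs)
  for (k in seq_len(nrow(pairs))) {
    ri <- find(pairs[k, 1L]); rj <- find(pairs[k, 2L])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relabel <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relabel[lab[lab > 0L]]
  out
}

#' Per-label pixel statistics
#'
#' Area, integrated intensity and intensity-weighted centroid of every label,
#' measured on \code{values} (typically the corrected, un-enhanced image).
#' Centroids are 0-based (x = column, y = row).
#'
#' @param labels integer label matrix
#' @param values numeric matrix of the same size
#' @return data.frame: id, area_px, integrated, x, y
#' @keywords internal
label_measurements <- function(labels, values) {
  stopifnot(identical(dim(labels), dim(values)))
  idx <- which(labels > 0L)
  if (length(idx) == 0L) {
    return(data.frame(id = integer(), area_px = integer(),
                      integrated = numeric(), x = numeric(), y = numeric()))
  }
  lab <- labels[idx]
  val <- values[idx]
  nr <- nrow(labels)
  ycoord <- (idx - 1L) %% nr          # 0-based row
  xcoord <- (idx - 1L) %/% nr         # 0-based column
  ids <- sort(unique(lab))
  area <- as.integer(rowsum(rep(1L, length(lab)), lab)[, 1])
  tot <- rowsum(val, lab)[, 1]
  # weighted centroid; fall back to unweighted if a label has no mass
  w <- val
  wsum <- rowsum(w, lab)[, 1]
  bad <- wsum <= 0
  if (any(bad)) {
    badids <- ids[bad]
    w[lab %in% badids] <- 1
    wsum <- rowsum(w, lab)[, 1]
  }
  cx <- rowsum(w * xcoord, lab)[, 1] / wsum
  cy <- rowsum(w * ycoord, lab)[, 1] / wsum
  data.frame(id = ids, area_px = area, integrated = as.numeric(tot),
             x = as.numeric(cx), y = as.numeric(cy))
}

#' Draw correlated multivariate normal deviates
#'
#' Cholesky-based sampler used by the generators; rejects non-PSD
#' correlation matrices with a diagnostic rather than silently repairing
#' them.
#'
#' @param n number of draws
#' @param R correlation matrix (symmetric, unit diagonal, PSD)
#' @return n x ncol(R) matrix of standard normal deviates with correlation R
#' @keywords internal
rmvnorm_corr <- function(n, R) {
  check_correlation_matrix(R)
  k <- ncol(R)
  ev <- eigen(R, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  A <- ev$vectors %*% diag(sqrt(lam), k)
  Z <- matrix(rnorm(n * k), n, k)
  Z %*% t(A)
}

#' Validate a correlation matrix
#' @keywords internal
check_correlation_matrix <- function(R, tol = 1e-8) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    stop("correlation matrix must be square")
  }
  if (max(abs(R - t(R))) > tol) {
    stop("correlation matrix must be symmetric")
  }
  if (max(abs(diag(R) - 1)) > tol) {
    stop("correlation matrix must have unit diagonal")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop(sprintf(
      "correlation matrix is not positive semi-definite (min eigenvalue %.3g)",
      min(ev)))
  }
  invisible(TRUE)
}

#' Integer-pixel image translation with zero fill
#'
#' Shifts image content by (dx, dy) pixels: output(x, y) = input(x - dx,
#' y - dy).  Pixels shifted in from outside the frame are zero.
#'
#' @param img numeric matrix
#' @param dx,dy integer shifts (x = columns, y = rows)
#' @return list(image, mask) where mask marks valid (in-frame) pixels
#' @keywords internal
shift_image <- function(img, dx, dy) {
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  msk <- matrix(FALSE, nr, nc)
  if (abs(dx) < nc && abs(dy) < nr) {
    src_r <- max(1L, 1L - dy):min(nr, nr - dy)
    src_c <- max(1L, 1L - dx):min(nc, nc - dx)
    out[src_r + dy, src_c + dx] <- img[src_r, src_c]
    msk[src_r + dy, src_c + dx] <- TRUE
  }
  list(image = out, mask = msk)
}

#' Fit a Gaussian to a 1D profile
#'
#' Nonlinear least squares fit of amplitude * exp(-(x - mu)^2 / (2 sigma^2))
#' + baseline, with moment-based starting values; falls back to
#' baseline-subtracted weighted moments if the fit does not converge.
#'
#' @param x positions (bin centres)
#' @param y profile values (counts or intensities)
#' @return list(mu, sigma, fwhm, amplitude, baseline, method)
#' @keywords internal
fit_gaussian_profile <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  base0 <- min(y)
  yb <- pmax(y - base0, 0)
  if (sum(yb) <= 0) stop("profile has no mass above baseline")
  mu0 <- sum(x * yb) / sum(yb)
  s0 <- sqrt(max(sum((x - mu0)^2 * yb) / sum(yb), diff(range(x))^2 / 1e6))
  a0 <- max(y) - base0
  fit <- tryCatch(
    nls(y ~ a * exp(-(x - mu)^2 / (2 * s^2)) + b,
        start = list(a = a0, mu = mu0, s = s0, b = base0),
        control = nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    sigma <- abs(unname(cf["s"]))
    return(list(mu = unname(cf["mu"]), sigma = sigma,
                fwhm = 2 * sqrt(2 * log(2)) * sigma,
                amplitude = unname(cf["a"]), baseline = unname(cf["b"]),
                method = "nls"))
  }
  list(mu = mu0, sigma = s0, fwhm = 2 * sqrt(2 * log(2)) * s0,
       amplitude = a0, baseline = base0, method = "moments")
}

#' Gaussian smoothing of a matrix (separable convolution, replicated edges)
#' @keywords internal
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(m, n, side) {
    if (side == "rows") rbind(m[rep(1, n), , drop = FALSE], m,
                              m[rep(nrow(m), n), , drop = FALSE])
    else cbind(m[, rep(1, n), drop = FALSE], m,
               m[, rep(ncol(m), n), drop = FALSE])
  }
  m <- pad(img, r, "rows")
  m <- apply(m, 2, function(col) stats::filter(col, k, sides = 2))
  m <- m[(r + 1):(r + nrow(img)), , drop = FALSE]
  m <- pad(m, r, "cols")
  m <- t(apply(m, 1, function(row) stats::filter(row, k, sides = 2)))
  m[, (r + 1):(r + ncol(img)), drop = FALSE]
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
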