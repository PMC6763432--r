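# Synthetic multiplexed confocal data with known ground truth.
#
# The generator emulates the structure of sequential multiplexed imaging of
# dissociated neuronal culture: dendrite-localized synaptic punctae with
# correlated lognormal per-channel intensities and sub-type mixtures, a
# reference (MAP2-like) dendrite channel re-imaged every round, a nuclear
# (DAPI-like) channel, multiplicative illumination inhomogeneity, integer
# per-round stage drift, and Poisson + Gaussian camera noise.  All planted
# quantities are returned as ground truth so every downstream stage can be
# scored.

#' Default channel registry for the confocal simulator
#'
#' Eight synaptic targets, one dendritic reference channel (MAP2, present in
#' every imaging round for registration), one non-synaptic cytoskeletal
#' channel (Tuj-1), and one nuclear channel (DAPI).
#'
#' @return data.frame with columns channel, role
#'   (synaptic/non_synaptic/nuclear/reference) and round
#' @export
default_channels <- function() {
  data.frame(
    channel = c("synapsin", "PSD95", "bassoon", "Homer1", "SHANK3",
                "VGLUT1", "NR2B", "ARPC2", "Tuj1", "DAPI", "MAP2"),
    role = c(rep("synaptic", 8), "non_synaptic", "nuclear", "reference"),
    round = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 1L, 1L, NA_integer_),
    stringsAsFactors = FALSE
  )
}

#' Default inter-channel intensity correlation matrix
#'
#' Block structure motivated by the biology of excitatory synapses:
#' pre-synaptic vesicle/active-zone proteins (synapsin, bassoon, VGLUT1)
#' correlate strongly with one another, as do post-synaptic density proteins
#' (PSD-95, Homer-1, SHANK3, ARPC2); pre/post cross-correlations are
#' moderate, and the NMDA receptor subunit NR2B correlates mildly with both
#' compartments.
#'
#' @param channels character vector of synaptic channel names
#' @return symmetric PSD correlation matrix with unit diagonal
#' @export
default_correlation <- function(channels = c("synapsin", "PSD95", "bassoon",
                                             "Homer1", "SHANK3", "VGLUT1",
                                             "NR2B", "ARPC2")) {
  pre <- intersect(channels, c("synapsin", "bassoon", "VGLUT1"))
  post <- intersect(channels, c("PSD95", "Homer1", "SHANK3", "ARPC2"))
  k <- length(channels)
  R <- matrix(0.25, k, k, dimnames = list(channels, channels))
  R[pre, pre] <- 0.6
  R[post, post] <- 0.6
  if ("NR2B" %in% channels) {
    R["NR2B", ] <- 0.35
    R[, "NR2B"] <- 0.35
  }
  diag(R) <- 1
  check_correlation_matrix(R)
  R
}

#' Configuration for the confocal simulator
#'
#' All distributional choices are generator conventions (no public raw data
#' exist to match); defaults describe a realistic 63x confocal field of
#' dissociated hippocampal culture at DIV21 density.
#'
#' @param image_size image side in pixels (square images)
#' @param pixel_size_nm physical pixel size (default 187 nm)
#' @param channels channel registry, see \code{\link{default_channels}}
#' @param n_synapses number of planted synapses
#' @param correlation inter-channel intensity correlation matrix over the
#'   synaptic channels (symmetric, unit diagonal, PSD)
#' @param meanlog,sdlog lognormal parameters of the per-channel integrated
#'   intensities (recycled across synaptic channels)
#' @param suppressed_meanlog lognormal log-mean for channels suppressed in a
#'   sub-type (near background)
#' @param subtypes list of sub-type definitions: each a list(name, fraction,
#'   suppressed = character vector of channel names); fractions must sum to 1
#' @param punctum_sigma_px range of the Gaussian punctum width (PSF
#'   surrogate), drawn uniformly per synapse
#' @param illumination list(enabled, amplitude, width_frac): multiplicative
#'   Gaussian vignette, normalized to spatial mean 1
#' @param drift list(enabled, max_px): per-round integer stage shift drawn
#'   uniformly in [-max_px, max_px]; the first round is the reference (0, 0)
#' @param noise list(enabled, gain, read_sd, background): Poisson shot noise
#'   at the given gain on top of a constant background, plus Gaussian read
#'   noise
#' @param nuclei list(n, axis_px = c(min, max), intensity): elliptical nuclei
#'   rendered in the nuclear channel
#' @param n_decoys number of intranuclear decoy punctae added to the
#'   synapse-marker channel (these are not synapses and must be removed by
#'   the nuclear-exclusion rule)
#' @param n_dendrites number of piecewise-linear dendrite backbones
#' @param min_separation_px hard-core minimum distance between planted
#'   synapses (default 26 px, about 4.9 um at 187 nm pixels, so that planted
#'   punctae are individually resolvable and ground-truth matching at the
#'   1 um radius is unambiguous; real cultures also contain closer pairs,
#'   which no diffraction-limited pipeline can separate)
#' @param seed RNG seed
#' @return object of class \code{sim_config}
#' @export
sim_config <- function(image_size = 512L,
                       pixel_size_nm = 187,
                       channels = default_channels(),
                       n_synapses = 200L,
                       correlation = NULL,
                       meanlog = log(150000),
                       sdlog = 0.3,
                       suppressed_meanlog = log(25),
                       subtypes = list(
                         list(name = "full", fraction = 0.8,
                              suppressed = character(0)),
                         list(name = "sparse", fraction = 0.2,
                              suppressed = c("PSD95", "Homer1", "SHANK3"))),
                       punctum_sigma_px = c(2.0, 2.8),
                       illumination = list(enabled = TRUE, amplitude = 0.4,
                                           width_frac = 0.6),
                       drift = list(enabled = TRUE, max_px = 8L),
                       noise = list(enabled = TRUE, gain = 1, read_sd = 1,
                                    background = 50),
                       nuclei = list(n = 4L, axis_px = c(25, 45),
                                     intensity = 300),
                       n_decoys = 20L,
                       n_dendrites = 30L,
                       min_separation_px = 26,
                       seed = 1L) {
  stopifnot(image_size >= 64L, pixel_size_nm > 0, n_synapses >= 0L)
  syn_ch <- channels$channel[channels$role == "synaptic"]
  if (is.null(correlation)) correlation <- default_correlation(syn_ch)
  if (!identical(sort(rownames(correlation)), sort(syn_ch))) {
    stop("correlation matrix must be indexed by the synaptic channel names")
  }
  check_correlation_matrix(correlation)
  fr <- vapply(subtypes, function(s) s$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-8) stop("sub-type mixing fractions must sum to 1")
  for (s in subtypes) {
    if (!all(s$suppressed %in% syn_ch)) {
      stop("sub-type suppresses unknown channel(s): ",
           paste(setdiff(s$suppressed, syn_ch), collapse = ", "))
    }
  }
  meanlog <- rep_len(meanlog, length(syn_ch))
  sdlog <- rep_len(sdlog, length(syn_ch))
  names(meanlog) <- names(sdlog) <- syn_ch
  structure(list(
    image_size = as.integer(image_size), pixel_size_nm = pixel_size_nm,
    channels = channels, n_synapses = as.integer(n_synapses),
    correlation = correlation[syn_ch, syn_ch, drop = FALSE],
    meanlog = meanlog, sdlog = sdlog,
    suppressed_meanlog = suppressed_meanlog, subtypes = subtypes,
    punctum_sigma_px = punctum_sigma_px, illumination = illumination,
    drift = drift, noise = noise, nuclei = nuclei,
    n_decoys = as.integer(n_decoys), n_dendrites = as.integer(n_dendrites),
    min_separation_px = min_separation_px,
    seed = as.integer(seed)), class = "sim_config")
}

# render 2D Gaussian punctae additively onto an image; each punctum
# contributes exactly `integrated` total intensity within its 4-sigma window
render_gaussians <- function(img, x, y, sigma, integrated) {
  n <- length(x)
  if (n == 0L) return(img)
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_len(n)) {
    r <- ceiling(4 * sigma[i])
    cx <- x[i]; cy <- y[i]
    c0 <- max(0L, floor(cx) - r); c1 <- min(nc - 1L, floor(cx) + r)
    r0 <- max(0L, floor(cy) - r); r1 <- min(nr - 1L, floor(cy) + r)
    if (c0 > c1 || r0 > r1) next
    gx <- exp(-((c0:c1) - cx)^2 / (2 * sigma[i]^2))
    gy <- exp(-((r0:r1) - cy)^2 / (2 * sigma[i]^2))
    patch <- gy %o% gx
    patch <- patch * (integrated[i] / sum(patch))
    img[(r0:r1) + 1L, (c0:c1) + 1L] <- img[(r0:r1) + 1L, (c0:c1) + 1L] + patch
  }
  img
}

# piecewise-linear dendrite backbones spanning the field
make_dendrites <- function(size, n) {
  lapply(seq_len(n), function(i) {
    horizontal <- runif(1) < 0.5
    if (horizontal) {
      xs <- c(0, sort(runif(2, 0.2, 0.8)) * size, size - 1)
      ys <- runif(4, 0.1, 0.9) * size
    } else {
      ys <- c(0, sort(runif(2, 0.2, 0.8)) * size, size - 1)
      xs <- runif(4, 0.1, 0.9) * size
    }
    cbind(x = xs, y = ys)
  })
}

# sample points along polylines (uniform in arc length), with jitter and a
# hard-core minimum separation (closer pairs are unresolvable at confocal
# resolution and would make ground-truth matching ambiguous); falls back to
# unconstrained placement once the attempt budget is exhausted
sample_on_dendrites <- function(dendrites, n, jitter_px, margin, size,
                                min_sep_px = 0, avoid = NULL,
                                avoid_margin = 0L) {
  # synapses live on dendrites, not somata: positions inside (dilated)
  # avoid regions -- nuclei -- are rejected
  blocked <- function(px, py) {
    if (is.null(avoid)) return(rep(FALSE, length(px)))
    rr <- pmin(pmax(round(py) + 1L, 1L), nrow(avoid))
    cc <- pmin(pmax(round(px) + 1L, 1L), ncol(avoid))
    out <- avoid[cbind(rr, cc)]
    if (avoid_margin > 0L) {
      for (dy in -avoid_margin:avoid_margin) for (dx in -avoid_margin:avoid_margin) {
        r2 <- pmin(pmax(rr + dy, 1L), nrow(avoid))
        c2 <- pmin(pmax(cc + dx, 1L), ncol(avoid))
        out <- out | avoid[cbind(r2, c2)]
      }
    }
    out
  }
  segs <- do.call(rbind, lapply(seq_along(dendrites), function(d) {
    p <- dendrites[[d]]
    cbind(x0 = p[-nrow(p), 1], y0 = p[-nrow(p), 2],
          x1 = p[-1, 1], y1 = p[-1, 2])
  }))
  len <- sqrt((segs[, "x1"] - segs[, "x0"])^2 + (segs[, "y1"] - segs[, "y0"])^2)
  out <- matrix(NA_real_, 0, 2)
  budget <- 2000L * n
  sep <- min_sep_px
  while (nrow(out) < n && budget > 0L) {
    m <- 4L * (n - nrow(out)) + 16L
    budget <- budget - m
    if (budget < 400L * n) sep <- 0.95 * sep   # relax near jamming
    si <- sample.int(nrow(segs), m, replace = TRUE, prob = len)
    t <- runif(m)
    px <- segs[si, "x0"] + t * (segs[si, "x1"] - segs[si, "x0"]) +
      rnorm(m, 0, jitter_px)
    py <- segs[si, "y0"] + t * (segs[si, "y1"] - segs[si, "y0"]) +
      rnorm(m, 0, jitter_px)
    ok <- px >= margin & px <= size - 1 - margin &
      py >= margin & py <= size - 1 - margin & !blocked(px, py)
    for (i in which(ok)) {
      if (sep > 0 && nrow(out) > 0L) {
        if (min((out[, 1] - px[i])^2 + (out[, 2] - py[i])^2) < sep^2) next
      }
      out <- rbind(out, c(px[i], py[i]))
      if (nrow(out) == n) break
    }
  }
  while (nrow(out) < n) {   # budget exhausted: fill unconstrained
    si <- sample.int(nrow(segs), 1L, prob = len)
    t <- runif(1)
    px <- segs[si, "x0"] + t * (segs[si, "x1"] - segs[si, "x0"])
    py <- segs[si, "y0"] + t * (segs[si, "y1"] - segs[si, "y0"])
    if (px >= margin && px <= size - 1 - margin &&
        py >= margin && py <= size - 1 - margin && !blocked(px, py)) {
      out <- rbind(out, c(px, py))
    }
  }
  out[seq_len(n), , drop = FALSE]
}

# render dendrite backbones as tubes with Gaussian cross-section
render_dendrites <- function(img, dendrites, width_sigma = 1.5,
                             intensity_per_px = 60) {
  for (p in dendrites) {
    for (s in seq_len(nrow(p) - 1L)) {
      L <- sqrt(sum((p[s + 1L, ] - p[s, ])^2))
      npts <- max(2L, ceiling(L / 0.5))
      t <- seq(0, 1, length.out = npts)
      xs <- p[s, 1] + t * (p[s + 1L, 1] - p[s, 1])
      ys <- p[s, 2] + t * (p[s + 1L, 2] - p[s, 2])
      img <- render_gaussians(img, xs, ys, rep(width_sigma, npts),
                              rep(intensity_per_px * L / npts, npts))
    }
  }
  img
}

# elliptical nuclei; returns list(mask, params)
make_nuclei <- function(size, n, axis_px) {
  mask <- matrix(FALSE, size, size)
  params <- data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
                       b = numeric(0), theta = numeric(0))
  if (n == 0L) return(list(mask = mask, params = params))
  xs <- runif(n, 0.15, 0.85) * size
  ys <- runif(n, 0.15, 0.85) * size
  as <- runif(n, axis_px[1], axis_px[2])
  bs <- runif(n, axis_px[1], axis_px[2])
  th <- runif(n, 0, pi)
  xg <- matrix(rep(0:(size - 1), each = size), size, size)   # x = col
  yg <- matrix(rep(0:(size - 1), times = size), size, size)  # y = row
  for (i in seq_len(n)) {
    u <- (xg - xs[i]) * cos(th[i]) + (yg - ys[i]) * sin(th[i])
    v <- -(xg - xs[i]) * sin(th[i]) + (yg - ys[i]) * cos(th[i])
    mask <- mask | (u^2 / as[i]^2 + v^2 / bs[i]^2 <= 1)
  }
  list(mask = mask,
       params = data.frame(x = xs, y = ys, a = as, b = bs, theta = th))
}

# multiplicative illumination field: centred Gaussian vignette, mean 1
make_illumination <- function(size, amplitude, width_frac) {
  cx <- (size - 1) / 2 + runif(1, -0.1, 0.1) * size
  cy <- (size - 1) / 2 + runif(1, -0.1, 0.1) * size
  w <- width_frac * size
  xg <- matrix(rep(0:(size - 1), each = size), size, size)
  yg <- matrix(rep(0:(size - 1), times = size), size, size)
  f <- 1 + amplitude * exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * w^2))
  f / mean(f)
}

#' Simulate a multiplexed confocal image set with ground truth
#'
#' Generates one grayscale plane per channel per round.  Synaptic punctae are
#' rendered as isotropic 2D Gaussians at positions sampled along dendrite
#' backbones, with per-channel integrated intensities drawn from a
#' multivariate lognormal with the configured correlation matrix; channels
#' suppressed in a sub-type are drawn near background.  The reference channel
#' is rendered in every round so that per-round drift can be estimated.
#' Planes are multiplied by the illumination field, shifted by the round's
#' drift, and corrupted by Poisson + Gaussian noise (if enabled).
#'
#' @param config a \code{\link{sim_config}}
#' @return list with elements \code{images} (an \code{image_set}, see
#'   \code{\link{image_set}}) and \code{truth} (synapse table, decoy table,
#'   illumination field, per-round drift, nuclear mask, dendrites)
#' @export
simulate_confocal_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  size <- config$image_size
  ch <- config$channels
  syn_ch <- ch$channel[ch$role == "synaptic"]
  marker <- syn_ch[1]   # first synaptic channel is the synapse marker
  rounds <- sort(unique(ch$round[!is.na(ch$round)]))
  if (length(rounds) == 0L) rounds <- 1L

  # --- ground truth -------------------------------------------------------
  n <- config$n_synapses
  dend <- make_dendrites(size, config$n_dendrites)
  nuc <- make_nuclei(size, config$nuclei$n, config$nuclei$axis_px)
  sig <- runif(n, config$punctum_sigma_px[1], config$punctum_sigma_px[2])
  margin <- ceiling(2 * max(config$punctum_sigma_px, 1)) + 8
  pos <- if (n > 0)
    sample_on_dendrites(dend, n, 2, margin, size,
                        min_sep_px = config$min_separation_px %||% 0,
                        avoid = nuc$mask, avoid_margin = 3L) else
    matrix(numeric(0), 0, 2)

  fr <- vapply(config$subtypes, function(s) s$fraction, numeric(1))
  subtype <- if (n > 0)
    sample(vapply(config$subtypes, function(s) s$name, character(1)),
           n, replace = TRUE, prob = fr) else character(0)

  Z <- if (n > 0) rmvnorm_corr(n, config$correlation) else
    matrix(numeric(0), 0, length(syn_ch))
  intens <- exp(sweep(sweep(Z, 2, config$sdlog[syn_ch], "*"),
                      2, config$meanlog[syn_ch], "+"))
  colnames(intens) <- syn_ch
  for (s in config$subtypes) {
    if (length(s$suppressed) == 0L) next
    rows <- which(subtype == s$name)
    if (length(rows) == 0L) next
    for (cc in s$suppressed) {
      intens[rows, cc] <- exp(rnorm(length(rows), config$suppressed_meanlog,
                                    0.3))
    }
  }
  synapses <- data.frame(synapse = seq_len(n),
                         x = pos[, 1], y = pos[, 2],
                         sigma_px = sig, radius_px = 2 * sig,
                         subtype = subtype)
  synapses <- cbind(synapses, as.data.frame(intens))

  # intranuclear decoy punctae in the synapse-marker channel
  nd <- config$n_decoys
  decoys <- data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0))
  if (nd > 0L && any(nuc$mask)) {
    inside <- which(nuc$mask)
    nr <- nrow(nuc$mask)
    cand <- sample(inside, min(50L * nd, length(inside)))
    cx <- (cand - 1L) %/% nr; cy <- (cand - 1L) %% nr
    sep <- config$min_separation_px %||% 0
    keep <- integer(0)
    for (i in seq_along(cand)) {   # hard-core thinning, same spacing rule
      if (length(keep) &&
          min((cx[keep] - cx[i])^2 + (cy[keep] - cy[i])^2) < sep^2) next
      keep <- c(keep, i)
      if (length(keep) == nd) break
    }
    decoys <- data.frame(x = cx[keep], y = cy[keep],
                         intensity = exp(rnorm(length(keep),
                                               config$meanlog[marker],
                                               config$sdlog[marker])))
  }

  illum <- if (isTRUE(config$illumination$enabled))
    make_illumination(size, config$illumination$amplitude,
                      config$illumination$width_frac)
  else matrix(1, size, size)

  drift <- data.frame(round = rounds, dx = 0L, dy = 0L)
  if (isTRUE(config$drift$enabled) && length(rounds) > 1L) {
    m <- config$drift$max_px
    drift$dx[-1] <- sample(seq(-m, m), length(rounds) - 1L, replace = TRUE)
    drift$dy[-1] <- sample(seq(-m, m), length(rounds) - 1L, replace = TRUE)
  }

  # --- clean per-channel content -----------------------------------------
  clean <- list()
  for (i in seq_len(nrow(ch))) {
    cname <- ch$channel[i]
    if (ch$role[i] == "synaptic") {
      img <- render_gaussians(matrix(0, size, size), synapses$x, synapses$y,
                              synapses$sigma_px, intens[, cname])
      if (cname == marker && nrow(decoys) > 0L) {
        img <- render_gaussians(img, decoys$x, decoys$y,
                                rep(1.5, nrow(decoys)), decoys$intensity)
      }
    } else if (ch$role[i] == "nuclear") {
      img <- matrix(0, size, size)
      img[nuc$mask] <- config$nuclei$intensity
      img <- gaussian_smooth(img, 2)
    } else { # reference / non_synaptic: dendritic cytoskeleton
      img <- render_dendrites(matrix(0, size, size), dend)
    }
    clean[[cname]] <- img
  }

  # --- assemble planes per (channel, round) ------------------------------
  planes <- list()
  info <- data.frame(channel = character(0), round = integer(0),
                     role = character(0))
  add_plane <- function(cname, rnd, role) {
    # stage drift moves the sample content; the diffuse background fills the
    # whole frame and, like the fluorescence, is modulated by illumination
    d <- drift[drift$round == rnd, ]
    img <- shift_image(clean[[cname]], d$dx, d$dy)$image
    if (isTRUE(config$noise$enabled)) {
      g <- config$noise$gain
      img <- (img + config$noise$background) * illum
      img <- rpois(length(img), pmax(img, 0) * g) / g
      img <- img + rnorm(length(img), 0, config$noise$read_sd)
      img <- matrix(pmax(img, 0), size, size)   # unsigned camera counts
    } else {
      img <- img * illum
    }
    planes[[length(planes) + 1L]] <<- img
    info[nrow(info) + 1L, ] <<- list(cname, rnd, role)
  }
  for (i in seq_len(nrow(ch))) {
    if (ch$role[i] == "reference") {
      for (rnd in rounds) add_plane(ch$channel[i], rnd, "reference")
    } else {
      add_plane(ch$channel[i], ch$round[i], ch$role[i])
    }
  }

  images <- image_set(planes, info, pixel_size_nm = config$pixel_size_nm,
                      well = "well01")
  truth <- list(synapses = synapses, decoys = decoys, illumination = illum,
                drift = drift, nuclear_mask = nuc$mask,
                nuclei = nuc$params, dendrites = dend,
                marker_channel = marker)
  list(images = images, truth = truth)
}

#' Simulate single-synapse feature tables directly (no image rendering)
#'
#' Draws per-synapse feature vectors from the same latent intensity model as
#' \code{\link{simulate_confocal_dataset}} -- correlated lognormal integrated
#' intensities with optional sub-type suppression -- organized into wells,
#' images and culture batches, with optional multiplicative treatment
#' effects, well-level random effects and measurement noise.  This is the
#' light-weight substrate for testing the statistical stages (well
#' summaries, correlation networks, treatment comparisons, embedding,
#' clustering) at realistic sample sizes.
#'
#' @param channels synaptic channel names
#' @param correlation correlation matrix over channels
#' @param meanlog,sdlog lognormal parameters (recycled)
#' @param n_per_image synapses per image
#' @param images_per_well images per well
#' @param wells data.frame(well, batch, treatment); defaults to 6 untreated
#'   wells in 3 batches
#' @param effects named numeric vector of multiplicative treatment effects on
#'   intensity (e.g. c(PSD95 = 1.3)); applied to wells with
#'   treatment != "untreated"
#' @param well_sd log-scale SD of the per-well random effect
#' @param noise_sd log-scale SD of per-synapse measurement noise added on top
#'   of the latent correlated draw
#' @param subtypes optional sub-type list as in \code{\link{sim_config}}
#' @param suppressed_meanlog log-mean of suppressed channels
#' @param seed RNG seed
#' @return data.frame with columns synapse_id, image_id, well_id, batch_id,
#'   treatment, subtype, and per channel \code{<ch>_intensity},
#'   \code{<ch>_area_um2}, \code{<ch>_mean}
#' @export
simulate_synapse_table <- function(channels = c("synapsin", "PSD95",
                                                "bassoon", "Homer1"),
                                   correlation = NULL,
                                   meanlog = log(800), sdlog = 0.5,
                                   n_per_image = 100L, images_per_well = 3L,
                                   wells = NULL,
                                   effects = NULL,
                                   well_sd = 0.05, noise_sd = 0.1,
                                   subtypes = NULL,
                                   suppressed_meanlog = log(25),
                                   seed = 1L) {
  set.seed(seed)
  if (is.null(wells)) {
    wells <- data.frame(well = sprintf("w%02d", 1:6),
                        batch = rep(sprintf("b%d", 1:3), each = 2),
                        treatment = "untreated")
  }
  k <- length(channels)
  if (is.null(correlation)) {
    correlation <- matrix(0.4, k, k, dimnames = list(channels, channels))
    diag(correlation) <- 1
  }
  check_correlation_matrix(correlation)
  meanlog <- rep_len(meanlog, k); names(meanlog) <- channels
  sdlog <- rep_len(sdlog, k); names(sdlog) <- channels

  rows <- list()
  sid <- 0L
  for (w in seq_len(nrow(wells))) {
    weff <- rnorm(k, 0, well_sd)   # per-well log-scale random effect
    names(weff) <- channels
    treated <- wells$treatment[w] != "untreated"
    for (im in seq_len(images_per_well)) {
      n <- n_per_image
      Z <- rmvnorm_corr(n, correlation)
      logI <- sweep(sweep(Z, 2, sdlog, "*"), 2, meanlog + weff, "+")
      if (treated && !is.null(effects)) {
        for (cc in intersect(names(effects), channels)) {
          logI[, match(cc, channels)] <-
            logI[, match(cc, channels)] + log(effects[[cc]])
        }
      }
      logI <- logI + matrix(rnorm(n * k, 0, noise_sd), n, k)
      I <- exp(logI)
      colnames(I) <- channels
      subtype <- rep("full", n)
      if (!is.null(subtypes)) {
        fr <- vapply(subtypes, function(s) s$fraction, numeric(1))
        subtype <- sample(vapply(subtypes, function(s) s$name, character(1)),
                          n, replace = TRUE, prob = fr)
        for (s in subtypes) {
          if (length(s$suppressed) == 0L) next
          r <- which(subtype == s$name)
          for (cc in intersect(s$suppressed, channels)) {
            I[r, cc] <- exp(rnorm(length(r), suppressed_meanlog, 0.3))
          }
        }
      }
      # punctum area loosely tied to intensity (bigger synapses are brighter)
      A <- 0.3 * (I / exp(meanlog[col(I)]))^0.4 *
        exp(matrix(rnorm(n * k, 0, 0.2), n, k)) + 0.15
      colnames(A) <- channels
      df <- data.frame(synapse_id = sid + seq_len(n),
                       image_id = sprintf("%s_img%d", wells$well[w], im),
                       well_id = wells$well[w], batch_id = wells$batch[w],
                       treatment = wells$treatment[w], subtype = subtype)
      for (cc in channels) {
        df[[paste0(cc, "_intensity")]] <- I[, cc]
        df[[paste0(cc, "_area_um2")]] <- A[, cc]
        df[[paste0(cc, "_mean")]] <- I[, cc] / A[, cc]
      }
      sid <- sid + n
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
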