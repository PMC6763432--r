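# Synthetic single-molecule localization (PAINT-style) data with ground
# truth: transient binding events at docking sites, persistent fiducial
# emitters, Gaussian localization noise and smooth sample drift.

#' Docking-site geometry helpers for the PAINT simulator
#'
#' \code{paint_filament_sites} places sites along a line segment with a
#' Gaussian cross-section (a filament bundle); \code{paint_cluster_sites}
#' draws an isotropic Gaussian cluster (a protein nanocluster);
#' \code{paint_synapse_pair_sites} builds an apposed pre/post-synaptic pair:
#' two Gaussian clusters of lateral extent \code{extent_nm} (SD =
#' extent_nm / 2, so the radial-correlation decay length of either channel
#' is approximately extent_nm), separated by \code{separation_nm} along the
#' trans-synaptic axis.
#'
#' @param p0,p1 filament endpoints, nm (length-2 vectors)
#' @param n_sites number of docking sites
#' @param cross_sigma_nm Gaussian cross-section SD of the filament
#' @return data.frame: x_nm, y_nm
#' @export
paint_filament_sites <- function(p0, p1, n_sites = 200L,
                                 cross_sigma_nm = 20) {
  t <- runif(n_sites)
  ax <- p1 - p0
  L <- sqrt(sum(ax^2))
  u <- ax / L
  perp <- c(-u[2], u[1])
  off <- rnorm(n_sites, 0, cross_sigma_nm)
  data.frame(x_nm = p0[1] + t * ax[1] + off * perp[1],
             y_nm = p0[2] + t * ax[2] + off * perp[2])
}

#' @rdname paint_filament_sites
#' @param center cluster centre, nm
#' @param sigma_nm cluster SD, nm
#' @export
paint_cluster_sites <- function(center, sigma_nm = 100, n_sites = 100L) {
  data.frame(x_nm = rnorm(n_sites, center[1], sigma_nm),
             y_nm = rnorm(n_sites, center[2], sigma_nm))
}

#' @rdname paint_filament_sites
#' @param axis_angle trans-synaptic axis angle, radians
#' @param separation_nm pre/post centre separation along the axis
#' @param extent_nm lateral extent (structure scale) of each compartment
#' @param n_per_side sites per compartment
#' @return for \code{paint_synapse_pair_sites}, a list of two site tables
#'   (pre, post)
#' @export
paint_synapse_pair_sites <- function(center, axis_angle = 0,
                                     separation_nm = 150, extent_nm = 200,
                                     n_per_side = 100L) {
  u <- c(cos(axis_angle), sin(axis_angle))
  s <- separation_nm / 2
  sigma <- extent_nm / 2
  list(pre = paint_cluster_sites(center - s * u, sigma, n_per_side),
       post = paint_cluster_sites(center + s * u, sigma, n_per_side))
}

#' Configuration for the PAINT localization simulator
#'
#' @param frames number of movie frames (> 0)
#' @param sites docking-site table (x_nm, y_nm), possibly empty
#' @param site_rate per-frame binding probability of each docking site;
#'   transient events last a single frame (fast probe dissociation)
#' @param sigma_loc_nm localization precision SD in nm (default 10)
#' @param fiducials fiducial position table (x_nm, y_nm)
#' @param fiducial_rate per-frame detection probability of a fiducial
#'   (default 0.98, so fiducials appear in well over 95% of frames)
#' @param drift list describing the true drift: mode "none", "linear"
#'   (rate_nm_per_frame, length-2), or "random_walk" (step_nm, smoothed by a
#'   running mean over smooth_frames); anchored at (0, 0) in frame 0
#' @param seed RNG seed
#' @return object of class \code{paint_config}
#' @export
paint_config <- function(frames = 5000L, sites = NULL, site_rate = 0.02,
                         sigma_loc_nm = 10,
                         fiducials = data.frame(x_nm = 0, y_nm = 0),
                         fiducial_rate = 0.98,
                         drift = list(mode = "random_walk", step_nm = 0.5,
                                      smooth_frames = 200L),
                         seed = 1L) {
  if (frames <= 0L) stop("frame count must be positive")
  if (is.null(sites)) sites <- data.frame(x_nm = numeric(0),
                                          y_nm = numeric(0))
  structure(list(frames = as.integer(frames), sites = sites,
                 site_rate = site_rate, sigma_loc_nm = sigma_loc_nm,
                 fiducials = fiducials, fiducial_rate = fiducial_rate,
                 drift = drift, seed = as.integer(seed)),
            class = "paint_config")
}

# true drift trajectory (nm per frame), (0, 0) at frame 0
make_drift_trajectory <- function(frames, drift) {
  f <- seq_len(frames) - 1L
  traj <- switch(drift$mode %||% "none",
    none = cbind(dx = numeric(frames), dy = numeric(frames)),
    linear = cbind(dx = f * drift$rate_nm_per_frame[1],
                   dy = f * drift$rate_nm_per_frame[2]),
    random_walk = {
      w <- max(3L, as.integer(drift$smooth_frames %||% 200L))
      sm <- function(v) {
        k <- rep(1 / w, w)
        out <- stats::filter(c(rep(v[1], w), v, rep(v[length(v)], w)),
                             k, sides = 2)
        out[(w + 1):(w + length(v))]
      }
      dx <- sm(cumsum(rnorm(frames, 0, drift$step_nm)))
      dy <- sm(cumsum(rnorm(frames, 0, drift$step_nm)))
      cbind(dx = dx - dx[1], dy = dy - dy[1])
    },
    stop("unknown drift mode: ", drift$mode))
  data.frame(frame = f, dx = traj[, "dx"], dy = traj[, "dy"])
}

#' Simulate a PAINT localization stream with ground truth
#'
#' Per frame, each docking site produces a localization with probability
#' \code{site_rate} (Poisson-thinned binding); each fiducial produces one
#' with probability \code{fiducial_rate}.  Every localization is displaced
#' by Gaussian noise of SD \code{sigma_loc_nm} and by the cumulative drift
#' of its frame.  The exact drift trajectory, site table and fiducial
#' positions are returned as ground truth.
#'
#' @param config a \code{\link{paint_config}}
#' @return list: locs (data.frame frame, x_nm, y_nm, kind, source_id),
#'   truth (drift data.frame, sites, fiducials, sigma_loc_nm)
#' @export
simulate_localization_dataset <- function(config = paint_config()) {
  stopifnot(inherits(config, "paint_config"))
  set.seed(config$seed)
  frames <- config$frames
  traj <- make_drift_trajectory(frames, config$drift)

  emit <- function(tab, rate, kind) {
    if (nrow(tab) == 0L) {
      return(data.frame(frame = integer(0), x_nm = numeric(0),
                        y_nm = numeric(0), kind = character(0),
                        source_id = integer(0)))
    }
    rate <- rep_len(rate, nrow(tab))
    out <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
      on <- which(runif(frames) < rate[i]) - 1L
      if (length(on) == 0L) next
      out[[i]] <- data.frame(
        frame = on,
        x_nm = tab$x_nm[i] + rnorm(length(on), 0, config$sigma_loc_nm) +
          traj$dx[on + 1L],
        y_nm = tab$y_nm[i] + rnorm(length(on), 0, config$sigma_loc_nm) +
          traj$dy[on + 1L],
        kind = kind, source_id = i)
    }
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  }
  locs <- rbind(emit(config$sites, config$site_rate, "site"),
                emit(config$fiducials, config$fiducial_rate, "fiducial"))
  if (is.null(locs)) {
    locs <- data.frame(frame = integer(0), x_nm = numeric(0),
                       y_nm = numeric(0), kind = character(0),
                       source_id = integer(0))
  }
  locs <- locs[order(locs$frame, locs$kind, locs$source_id), ]
  rownames(locs) <- NULL
  list(locs = locs,
       truth = list(drift = traj, sites = config$sites,
                    fiducials = config$fiducials,
                    sigma_loc_nm = config$sigma_loc_nm))
}
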