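# Correlation networks, treatment comparisons and the replicate-centered
# correlation difference test.

#' Pairwise intensity correlations and the correlation network
#'
#' Computes the Pearson correlation between every pair of channel
#' intensities within each group (culture batch by default), averages the
#' per-group coefficients, and draws a network edge wherever the mean
#' correlation is strictly greater than \code{threshold}.  Pairs whose
#' correlation is undefined in a group (zero variance) skip that group with
#' a warning.
#'
#' @param tab a \code{synapse_table}
#' @param channels channel names; default every channel with an
#'   \code{_intensity} column
#' @param by grouping column (default "batch_id")
#' @param feature "intensity" (integrated, default) or "mean"
#' @param threshold edge threshold on the mean correlation (strict >,
#'   default 0.35)
#' @return object of class \code{correlation_network}: channels, matrix
#'   (mean Pearson r), per_group (3D array), edges (data.frame a, b, r),
#'   threshold
#' @export
pairwise_correlations <- function(tab, channels = NULL, by = "batch_id",
                                  feature = c("intensity", "mean"),
                                  threshold = 0.35) {
  feature <- match.arg(feature)
  suffix <- paste0("_", feature)
  if (is.null(channels)) {
    channels <- sub("_intensity$", "",
                    grep("_intensity$", names(tab), value = TRUE))
  }
  cols <- paste0(channels, suffix)
  stopifnot(all(cols %in% names(tab)), by %in% names(tab))
  groups <- unique(tab[[by]])
  k <- length(channels)
  per_group <- array(NA_real_, dim = c(k, k, length(groups)),
                     dimnames = list(channels, channels, groups))
  for (g in seq_along(groups)) {
    sub <- tab[tab[[by]] == groups[g], cols, drop = FALSE]
    if (nrow(sub) < 3L) {
      warning("group '", groups[g], "' has < 3 synapses; skipped")
      next
    }
    sds <- vapply(sub, sd, numeric(1))
    if (any(sds == 0)) {
      warning("zero-variance channel(s) in group '", groups[g],
              "': ", paste(channels[sds == 0], collapse = ", "),
              "; group skipped for the affected pairs")
    }
    cm <- suppressWarnings(cor(as.matrix(sub)))
    dimnames(cm) <- list(channels, channels)
    per_group[, , g] <- cm
  }
  avg <- apply(per_group, c(1, 2), mean, na.rm = TRUE)
  diag(avg) <- 1
  pairs <- t(combn(channels, 2))
  r <- avg[pairs]
  edges <- data.frame(a = pairs[, 1], b = pairs[, 2], r = r)
  edges <- edges[!is.na(edges$r) & edges$r > threshold, ]
  rownames(edges) <- NULL
  structure(list(channels = channels, matrix = avg, per_group = per_group,
                 edges = edges, threshold = threshold, feature = feature),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network: %d channels, %d edges (r > %.2f)\n",
              length(x$channels), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Compare treated and untreated groups on well-level features
#'
#' For each feature, well values are expressed relative to the mean of the
#' untreated group, compared by a two-tailed two-sample Student's t-test
#' (pooled variance by default, Welch by flag), with 95% confidence
#' intervals of the relative group means.
#'
#' @param well_tab well-level table from \code{\link{summarize_wells}}
#' @param features feature columns to compare; default all numeric features
#' @param untreated,treated the two treatment labels
#' @param var_equal pooled-variance Student's t (default TRUE)
#' @param conf_level confidence level (default 0.95)
#' @return data.frame of class \code{group_comparison}: feature, mean and CI
#'   of the relative means per group, t, df, p_value, n wells per group
#' @export
compare_groups <- function(well_tab, features = NULL,
                           untreated = "untreated", treated = "treated",
                           var_equal = TRUE, conf_level = 0.95) {
  stopifnot("treatment" %in% names(well_tab))
  if (is.null(features)) {
    numcols <- names(well_tab)[vapply(well_tab, is.numeric, logical(1))]
    features <- setdiff(numcols, c("n_images", "n_synapses"))
  }
  g0 <- well_tab[well_tab$treatment == untreated, , drop = FALSE]
  g1 <- well_tab[well_tab$treatment == treated, , drop = FALSE]
  if (nrow(g0) < 2L || nrow(g1) < 2L) {
    stop("each group needs at least 2 wells (got ", nrow(g0), " untreated, ",
         nrow(g1), " treated)")
  }
  ci_half <- function(x) {
    qt(1 - (1 - conf_level) / 2, length(x) - 1) * sd(x) / sqrt(length(x))
  }
  rows <- lapply(features, function(f) {
    ref <- mean(g0[[f]])
    x0 <- g0[[f]] / ref
    x1 <- g1[[f]] / ref
    tt <- t.test(x1, x0, var.equal = var_equal, conf.level = conf_level)
    data.frame(feature = f,
               untreated_mean = mean(g0[[f]]), treated_mean = mean(g1[[f]]),
               rel_untreated = mean(x0), rel_treated = mean(x1),
               rel_untreated_ci = ci_half(x0), rel_treated_ci = ci_half(x1),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value,
               n_untreated = nrow(g0), n_treated = nrow(g1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Per-well pairwise correlations
#'
#' Long-format per-well Pearson correlations for every channel pair, the
#' substrate of \code{\link{correlation_difference_test}}.
#'
#' @inheritParams pairwise_correlations
#' @return data.frame: well_id, batch_id, treatment, a, b, r, n
#' @export
per_well_correlations <- function(tab, channels = NULL,
                                  feature = c("intensity", "mean")) {
  feature <- match.arg(feature)
  suffix <- paste0("_", feature)
  if (is.null(channels)) {
    channels <- sub("_intensity$", "",
                    grep("_intensity$", names(tab), value = TRUE))
  }
  cols <- paste0(channels, suffix)
  wells <- unique(tab[, intersect(c("well_id", "batch_id", "treatment"),
                                  names(tab)), drop = FALSE])
  pairs <- t(combn(channels, 2))
  rows <- list()
  for (w in seq_len(nrow(wells))) {
    sub <- tab[tab$well_id == wells$well_id[w], cols, drop = FALSE]
    cm <- suppressWarnings(cor(as.matrix(sub)))
    dimnames(cm) <- list(channels, channels)
    rows[[w]] <- data.frame(wells[w, , drop = FALSE],
                            a = pairs[, 1], b = pairs[, 2],
                            r = cm[pairs], n = nrow(sub),
                            row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replicate-centered test of correlation differences
#'
#' Within each biological replicate (batch), the replicate's untreated mean
#' correlation is subtracted from every well's correlation for each channel
#' pair; the centered differences of treated wells are then compared with
#' those of untreated wells by a two-tailed Student's t-test, pair by pair.
#' Centering removes batch-level offsets, so untreated differences average
#' exactly zero within each replicate by construction.
#'
#' @param well_r per-well correlation table from
#'   \code{\link{per_well_correlations}}
#' @param untreated,treated treatment labels
#' @param var_equal pooled-variance Student's t (default TRUE)
#' @param conf_level confidence level (default 0.95)
#' @return data.frame: a, b, mean_diff_untreated, mean_diff_treated, delta,
#'   ci, t, df, p_value
#' @export
correlation_difference_test <- function(well_r, untreated = "untreated",
                                        treated = "treated",
                                        var_equal = TRUE,
                                        conf_level = 0.95) {
  need <- c("well_id", "batch_id", "treatment", "a", "b", "r")
  stopifnot(all(need %in% names(well_r)))
  for (b in unique(well_r$batch_id)) {
    if (!any(well_r$treatment[well_r$batch_id == b] == untreated)) {
      stop("replicate '", b, "' has no untreated wells; cannot center")
    }
  }
  key <- paste(well_r$a, well_r$b, sep = "|")
  rows <- list()
  for (k in unique(key)) {
    sub <- well_r[key == k, , drop = FALSE]
    # center on the replicate's untreated mean r
    for (b in unique(sub$batch_id)) {
      ref <- mean(sub$r[sub$batch_id == b & sub$treatment == untreated],
                  na.rm = TRUE)
      sub$r[sub$batch_id == b] <- sub$r[sub$batch_id == b] - ref
    }
    d0 <- sub$r[sub$treatment == untreated]
    d1 <- sub$r[sub$treatment == treated]
    if (length(d0) < 2L || length(d1) < 2L) next
    tt <- t.test(d1, d0, var.equal = var_equal, conf.level = conf_level)
    rows[[k]] <- data.frame(a = sub$a[1], b = sub$b[1],
                            mean_diff_untreated = mean(d0),
                            mean_diff_treated = mean(d1),
                            delta = mean(d1) - mean(d0),
                            ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
                            t = unname(tt$statistic),
                            df = unname(tt$parameter),
                            p_value = tt$p.value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
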