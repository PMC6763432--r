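# Single-synapse feature tables and well-level summaries.

#' Build the single-synapse feature table
#'
#' One row per synapse.  For each synaptic channel the integrated intensity
#' and area of the colocalized punctum are recorded, with zero assigned to
#' both when no colocalized punctum was detected; mean intensity is
#' integrated / area (0 where area is 0).  For non-synaptic channels (MAP2,
#' Tuj-1) the intensity is the average of the corrected image within the
#' synapse-marker punctum, and no area is measured.
#'
#' @param synapses a \code{synapse_set}
#' @param assignments named list of colocalization tables (one per synaptic
#'   channel, from \code{\link{colocalize}}); the marker channel itself may
#'   be omitted (its punctae are the synapses)
#' @param puncta_sets named list of \code{puncta_set}s for the synaptic
#'   channels in \code{assignments}
#' @param images named list of corrected planes for non-synaptic channels
#'   (mean intensity within the marker punctum)
#' @param image_id,well_id,batch_id,treatment grouping labels stored on
#'   every row
#' @return data.frame of class \code{synapse_table}
#' @export
extract_features <- function(synapses, assignments = list(),
                             puncta_sets = list(), images = list(),
                             image_id = "img1", well_id = "well01",
                             batch_id = "b1", treatment = "untreated") {
  stopifnot(inherits(synapses, "synapse_set"))
  s <- synapses$synapses
  marker <- synapses$marker
  out <- data.frame(synapse_id = s$synapse_id,
                    image_id = image_id, well_id = well_id,
                    batch_id = batch_id, treatment = treatment,
                    x = s$x, y = s$y)
  # the marker channel's own features come from the synapse punctae
  out[[paste0(marker$channel, "_intensity")]] <- s$integrated
  out[[paste0(marker$channel, "_area_um2")]] <- s$area_um2
  out[[paste0(marker$channel, "_mean")]] <- s$mean

  for (ch in names(assignments)) {
    asn <- assignments[[ch]]
    ps <- puncta_sets[[ch]]
    if (is.null(ps)) stop("no puncta_set supplied for channel '", ch, "'")
    m <- ps$measurements
    idx <- match(asn$punctum_id, m$id)
    if (any(!is.na(asn$punctum_id) & is.na(idx))) {
      stop("assignment references punctum id(s) absent from channel '",
           ch, "'")
    }
    intens <- ifelse(is.na(idx), 0, m$integrated[idx])
    area <- ifelse(is.na(idx), 0, m$area_um2[idx])
    out[[paste0(ch, "_intensity")]] <- intens
    out[[paste0(ch, "_area_um2")]] <- area
    out[[paste0(ch, "_mean")]] <- ifelse(area > 0, intens /
                                           ifelse(is.na(idx), 1,
                                                  m$area_px[idx]), 0)
  }
  # non-synaptic channels: mean corrected intensity within the marker punctum
  if (length(images)) {
    lab <- marker$labels
    for (ch in names(images)) {
      img <- images[[ch]]
      stopifnot(identical(dim(img), dim(lab)))
      idx <- which(lab > 0L)
      vals <- rep(NA_real_, nrow(s))
      if (length(idx)) {
        sums <- rowsum(img[idx], lab[idx])
        cnts <- rowsum(rep(1, length(idx)), lab[idx])
        ids <- as.integer(rownames(sums))
        mm <- match(s$punctum_id, ids)
        vals <- ifelse(is.na(mm), 0, sums[mm, 1] / cnts[mm, 1])
      }
      out[[paste0(ch, "_mean")]] <- vals
    }
  }
  class(out) <- c("synapse_table", "data.frame")
  out
}

#' Two-stage well summaries of a synapse table
#'
#' First averages every numeric feature over the synapses of each image,
#' then averages the image means within each well (unweighted, so images
#' with many synapses do not dominate).  Empty wells are excluded with a
#' warning.
#'
#' @param tab a \code{synapse_table} (or any data.frame with image_id,
#'   well_id and numeric feature columns)
#' @param features character vector of feature columns; default all numeric
#'   columns except coordinates and ids
#' @return data.frame with one row per well: well_id, batch_id, treatment,
#'   n_images, n_synapses and the per-well feature means
#' @export
summarize_wells <- function(tab, features = NULL) {
  stopifnot(all(c("image_id", "well_id") %in% names(tab)))
  if (is.null(features)) {
    numcols <- names(tab)[vapply(tab, is.numeric, logical(1))]
    features <- setdiff(numcols, c("synapse_id", "x", "y"))
  }
  meta <- unique(tab[, intersect(c("well_id", "batch_id", "treatment"),
                                 names(tab)), drop = FALSE])
  if (anyDuplicated(meta$well_id)) {
    stop("inconsistent batch/treatment labels within a well")
  }
  img_means <- aggregate(tab[features],
                         by = list(well_id = tab$well_id,
                                   image_id = tab$image_id),
                         FUN = mean)
  n_syn <- aggregate(list(n_synapses = tab$synapse_id),
                     by = list(well_id = tab$well_id), FUN = length)
  well_means <- aggregate(img_means[features],
                          by = list(well_id = img_means$well_id),
                          FUN = mean)
  n_img <- aggregate(list(n_images = img_means$image_id),
                     by = list(well_id = img_means$well_id), FUN = length)
  out <- merge(merge(merge(meta, well_means, by = "well_id"),
                     n_img, by = "well_id"),
               n_syn, by = "well_id")
  out[order(out$well_id), ]
}
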