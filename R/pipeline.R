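# End-to-end confocal profiling pipeline: configuration, stage dispatch,
# artifact persistence and provenance.

PIPELINE_STAGES <- c("acquire", "flatfield", "register", "segment",
                     "features", "stats")

#' Pipeline run configuration
#'
#' Assembles and validates the configuration of
#' \code{\link{run_pipeline}}.  Unknown stage names are rejected before any
#' computation.
#'
#' @param stages ordered subset of acquire, flatfield, register, segment,
#'   features, stats
#' @param out_dir artifact directory
#' @param simulate a \code{\link{sim_config}} (used by the acquire stage
#'   when no manifest is given)
#' @param manifest optional manifest CSV path: load images instead of
#'   simulating
#' @param reference_channel registration reference (default "MAP2")
#' @param marker_channel synapse-defining channel (default "synapsin")
#' @param background_disk_radius opening disc radius for the illumination
#'   background (default 100 px)
#' @param min_synapse_area_um2 synapse area gate (default 0.42)
#' @param coloc_max_dist_um colocalization gate (default 1.0)
#' @param network_threshold correlation network edge threshold (default
#'   0.35)
#' @param seed RNG seed
#' @return object of class \code{run_config}
#' @export
run_config <- function(stages = PIPELINE_STAGES,
                       out_dir = tempfile("prismr_run_"),
                       simulate = sim_config(),
                       manifest = NULL,
                       reference_channel = "MAP2",
                       marker_channel = "synapsin",
                       background_disk_radius = 100,
                       min_synapse_area_um2 = 0.42,
                       coloc_max_dist_um = 1.0,
                       network_threshold = 0.35,
                       seed = 1L) {
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown)) {
    stop("unknown pipeline stage(s): ", paste(unknown, collapse = ", "))
  }
  structure(list(stages = stages, out_dir = out_dir, simulate = simulate,
                 manifest = manifest,
                 reference_channel = reference_channel,
                 marker_channel = marker_channel,
                 background_disk_radius = background_disk_radius,
                 min_synapse_area_um2 = min_synapse_area_um2,
                 coloc_max_dist_um = coloc_max_dist_um,
                 network_threshold = network_threshold,
                 seed = as.integer(seed)), class = "run_config")
}

#' Run the confocal profiling pipeline
#'
#' Executes the configured stages in order -- acquire (simulate or load),
#' flat-field correction, round registration, segmentation and synapse
#' calling, feature extraction, statistics -- persisting every intermediate
#' (shift table, label images, synapse table, well summaries, correlation
#' network) under \code{out_dir} together with a machine-readable
#' provenance log of versions, parameters and seeds.  A stage failure
#' aborts with the stage name.
#'
#' @param config a \code{\link{run_config}}
#' @return (invisibly) list with the in-memory artifacts: images, truth,
#'   shifts, puncta, synapses, synapse_table, well_table, network, paths
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  state <- list(paths = list())
  stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(invisible())
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  stage("acquire", function() {
    if (!is.null(config$manifest)) {
      state$images <<- read_image_set(config$manifest)
    } else {
      sim <- simulate_confocal_dataset(config$simulate)
      state$images <<- sim$images
      state$truth <<- sim$truth
      write.csv(sim$truth$synapses,
                file.path(config$out_dir, "truth_synapses.csv"),
                row.names = FALSE)
    }
  })

  stage("flatfield", function() {
    x <- state$images
    channels <- unique(x$info$channel)
    profiles <- list()
    for (ch in channels) {
      idx <- which(x$info$channel == ch)
      bgs <- lapply(x$planes[idx], estimate_background,
                    disk_radius = config$background_disk_radius)
      profiles[[ch]] <- estimate_illumination_profile(bgs)
    }
    state$images <<- flat_field_correct_set(x, profiles)
    state$profiles <<- profiles
  })

  stage("register", function() {
    reg <- register_rounds(state$images, config$reference_channel)
    state$images <<- reg$images
    state$shifts <<- reg$shifts
    p <- file.path(config$out_dir, "shifts.csv")
    write.csv(reg$shifts, p, row.names = FALSE)
    state$paths$shifts <<- p
  })

  stage("segment", function() {
    x <- state$images
    info <- x$info
    px <- x$pixel_size_nm
    mask_for <- function(i) {
      r <- info$round[i]
      if (!is.null(x$masks) && !is.na(r)) x$masks[[as.character(r)]]
      else NULL
    }
    puncta <- list()
    for (i in which(info$role == "synaptic")) {
      ch <- info$channel[i]
      puncta[[ch]] <- segment_channel(x$planes[[i]], px, channel = ch,
                                      mask = mask_for(i))
    }
    nuc <- NULL
    inuc <- which(info$role == "nuclear")
    if (length(inuc)) {
      nuc <- nuclear_mask(x$planes[[inuc[1]]], px)
    }
    marker <- config$marker_channel
    if (is.null(puncta[[marker]])) {
      stop("marker channel '", marker, "' was not segmented")
    }
    syn <- detect_synapses(puncta[[marker]], nuc,
                           min_area_um2 = config$min_synapse_area_um2)
    state$puncta <<- puncta
    state$nuclear <<- nuc
    state$synapses <<- syn
  })

  stage("features", function() {
    x <- state$images
    info <- x$info
    marker <- config$marker_channel
    others <- setdiff(names(state$puncta), marker)
    assignments <- lapply(others, function(ch) {
      colocalize(state$synapses, state$puncta[[ch]],
                 max_dist_um = config$coloc_max_dist_um)
    })
    names(assignments) <- others
    images <- list()
    for (i in which(info$role %in% c("non_synaptic", "reference"))) {
      ch <- info$channel[i]
      if (is.null(images[[ch]])) images[[ch]] <- x$planes[[i]]
    }
    tab <- extract_features(state$synapses, assignments,
                            state$puncta[others], images,
                            image_id = "img1", well_id = x$well)
    state$synapse_table <<- tab
    p <- file.path(config$out_dir, "synapse_table.csv")
    write.csv(tab, p, row.names = FALSE)
    state$paths$synapse_table <<- p
  })

  stage("stats", function() {
    tab <- state$synapse_table
    well <- summarize_wells(tab)
    net <- pairwise_correlations(tab, by = "well_id",
                                 threshold = config$network_threshold)
    write.csv(well, file.path(config$out_dir, "well_table.csv"),
              row.names = FALSE)
    write.csv(net$edges, file.path(config$out_dir, "network_edges.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(net$matrix),
              file.path(config$out_dir, "correlation_matrix.csv"))
    state$well_table <<- well
    state$network <<- net
  })

  provenance <- list(
    package = "prismr",
    version = as.character(packageVersion("prismr")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    stages = config$stages,
    parameters = list(
      reference_channel = config$reference_channel,
      marker_channel = config$marker_channel,
      background_disk_radius = config$background_disk_radius,
      min_synapse_area_um2 = config$min_synapse_area_um2,
      coloc_max_dist_um = config$coloc_max_dist_um,
      network_threshold = config$network_threshold))
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  state$out_dir <- config$out_dir
  invisible(state)
}
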