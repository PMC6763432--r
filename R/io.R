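# Image-set container and file I/O (TIFF planes + CSV manifests/tables).

#' Multi-channel, multi-round image set
#'
#' A light container for the unit of confocal processing: a list of
#' grayscale planes (base R matrices, rows = y, columns = x) with parallel
#' per-plane metadata (channel, round, role), a physical pixel size and a
#' well identifier.  Optional per-round validity masks (from registration)
#' travel with the set.
#'
#' @param planes list of numeric matrices, all the same size
#' @param info data.frame with one row per plane: channel, round, role
#' @param pixel_size_nm physical pixel size in nm
#' @param well well identifier
#' @param masks optional named list of logical matrices, one per round
#' @return object of class \code{image_set}
#' @export
image_set <- function(planes, info, pixel_size_nm, well = "well01",
                      masks = NULL) {
  stopifnot(is.list(planes), nrow(info) == length(planes),
            all(c("channel", "round", "role") %in% names(info)),
            pixel_size_nm > 0)
  if (length(planes) > 0) {
    d <- dim(planes[[1]])
    ok <- vapply(planes, function(p) identical(dim(p), d), logical(1))
    if (!all(ok)) stop("all planes in an image set must have the same size")
  }
  structure(list(planes = planes, info = info,
                 pixel_size_nm = pixel_size_nm, well = well, masks = masks),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  d <- if (length(x$planes)) paste(dim(x$planes[[1]]), collapse = " x ") else "0 x 0"
  cat(sprintf("image_set: %d plane(s), %s px, %.0f nm/px, well %s\n",
              length(x$planes), d, x$pixel_size_nm, x$well))
  if (nrow(x$info)) print(x$info, row.names = FALSE)
  invisible(x)
}

#' Fetch a plane from an image set
#'
#' @param x an \code{image_set}
#' @param channel channel name
#' @param round imaging round (needed only if the channel appears in several
#'   rounds, e.g. the registration reference)
#' @return numeric matrix
#' @export
get_plane <- function(x, channel, round = NULL) {
  stopifnot(inherits(x, "image_set"))
  i <- which(x$info$channel == channel &
               (is.null(round) | x$info$round %in% round))
  if (length(i) == 0L) stop("no plane for channel '", channel, "'")
  if (length(i) > 1L) {
    stop("channel '", channel, "' appears in several rounds; specify `round`")
  }
  x$planes[[i]]
}

#' Write an image set to a directory (TIFF planes + CSV manifest)
#'
#' Planes are written as 32-bit float grayscale TIFF, one file per
#' channel/round; a \code{manifest.csv} records file, channel, round, role,
#' well and pixel size.
#'
#' @param x an \code{image_set}
#' @param dir output directory (created if absent)
#' @return invisibly, the manifest data.frame
#' @export
write_image_set <- function(x, dir) {
  stopifnot(inherits(x, "image_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_r%s.tif", x$info$channel,
                   ifelse(is.na(x$info$round), "NA", x$info$round))
  for (i in seq_along(x$planes)) {
    p <- x$planes[[i]]
    tiff::writeTIFF(p / max(max(p), 1), file.path(dir, files[i]),
                    bits.per.sample = 32L)
  }
  # store the scale so the round trip is exact
  manifest <- data.frame(file = files, channel = x$info$channel,
                         round = x$info$round, role = x$info$role,
                         well = x$well, pixel_size_nm = x$pixel_size_nm,
                         scale = vapply(x$planes,
                                        function(p) max(max(p), 1), numeric(1)))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read an image set from a manifest
#'
#' @param manifest path to a manifest CSV (columns file, channel, round,
#'   role, well, pixel_size_nm and optional scale), or a data.frame of the
#'   same shape; file paths are resolved relative to the manifest location
#' @param dir base directory when \code{manifest} is a data.frame
#' @return an \code{image_set}
#' @export
read_image_set <- function(manifest, dir = ".") {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("file", "channel", "round", "role", "well", "pixel_size_nm")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (length(unique(manifest$pixel_size_nm)) != 1L) {
    stop("mixed pixel sizes in one image set: ",
         paste(unique(manifest$pixel_size_nm), collapse = ", "))
  }
  if (length(unique(manifest$well)) != 1L) {
    stop("a manifest must describe a single well")
  }
  paths <- file.path(dir, manifest$file)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing image file(s): ", paste(manifest$file[missing],
                                          collapse = ", "))
  }
  planes <- lapply(seq_along(paths), function(i) {
    m <- tiff::readTIFF(paths[i])
    if (length(dim(m)) == 3L) m <- m[, , 1]
    sc <- if ("scale" %in% names(manifest)) manifest$scale[i] else 1
    m * sc
  })
  d <- dim(planes[[1]])
  ok <- vapply(planes, function(p) identical(dim(p), d), logical(1))
  if (!all(ok)) {
    stop("image dimension mismatch within well: ",
         paste(manifest$file[!ok], collapse = ", "))
  }
  image_set(planes,
            manifest[, c("channel", "round", "role")],
            pixel_size_nm = manifest$pixel_size_nm[1],
            well = manifest$well[1])
}

#' Read / write single-molecule localization tables
#'
#' Localization CSVs have columns \code{frame}, \code{x_nm}, \code{y_nm} and
#' optionally \code{intensity} and \code{channel}.
#'
#' @param path CSV path
#' @return data.frame with validated columns
#' @export
read_localizations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "x_nm", "y_nm")
  if (!all(need %in% names(df))) {
    stop("localization table must have columns: ",
         paste(need, collapse = ", "))
  }
  validate_localizations(df)
  df
}

#' @rdname read_localizations
#' @param locs localization data.frame
#' @export
write_localizations <- function(locs, path) {
  validate_localizations(locs)
  write.csv(locs, path, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
validate_localizations <- function(locs) {
  stopifnot(is.data.frame(locs))
  if (nrow(locs)) {
    if (any(locs$frame < 0)) stop("frame indices must be non-negative")
    if (!all(is.finite(locs$x_nm)) || !all(is.finite(locs$y_nm))) {
      stop("localization coordinates must be finite")
    }
  }
  invisible(TRUE)
}
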