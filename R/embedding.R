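# Feature normalization, t-SNE embedding, density maps and hierarchical
# clustering of single-synapse profiles.

#' Normalize features for embedding / clustering
#'
#' Each feature is log-transformed as log(x + 1) (the pseudocount makes the
#' transform defined at the zeros produced by the absent-punctum rule), then
#' divided by its standard deviation and shifted to minimum zero, so every
#' output column has SD 1 and minimum 0.  Zero-variance features are dropped
#' with a warning.
#'
#' @param tab a \code{synapse_table} (or data.frame)
#' @param features feature columns; default all channel intensity columns
#'   plus synaptic-channel area columns
#' @param pseudocount added before the log (default 1)
#' @return numeric matrix, one row per synapse, columns named by feature
#' @export
normalize_for_embedding <- function(tab, features = NULL, pseudocount = 1) {
  if (is.null(features)) {
    features <- c(grep("_intensity$", names(tab), value = TRUE),
                  grep("_area_um2$", names(tab), value = TRUE))
  }
  stopifnot(all(features %in% names(tab)))
  X <- as.matrix(tab[, features, drop = FALSE])
  if (any(X < 0)) stop("features must be non-negative before log transform")
  X <- log(X + pseudocount)
  sds <- apply(X, 2, sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning("dropping zero-variance feature(s): ",
            paste(features[drop], collapse = ", "))
    X <- X[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  X <- sweep(X, 2, sds, "/")
  sweep(X, 2, apply(X, 2, min), "-")
}

#' t-SNE embedding of normalized synapse profiles
#'
#' Wrapper around exact-gradient t-SNE (\code{Rtsne} with theta = 0) with
#' PCA initialization, the defaults used throughout the package: perplexity
#' 40, 5000 iterations.  When the table is larger than \code{subsample},
#' that many synapses are drawn at random (seeded) first.
#'
#' @param X normalized matrix from \code{\link{normalize_for_embedding}}
#' @param perplexity t-SNE perplexity (default 40)
#' @param n_iter gradient iterations (default 5000)
#' @param init "pca" (default) or a numeric n x 2 matrix of starting
#'   coordinates
#' @param subsample maximum number of synapses embedded (default 10000)
#' @param seed RNG seed for subsampling and the embedding
#' @param theta Barnes-Hut accuracy parameter; 0 = exact method (default)
#' @return list: coords (n x 2 matrix), index (rows of X retained),
#'   perplexity
#' @export
embed_tsne <- function(X, perplexity = 40, n_iter = 5000, init = "pca",
                       subsample = 10000, seed = 1, theta = 0) {
  X <- as.matrix(X)
  set.seed(seed)
  idx <- seq_len(nrow(X))
  if (nrow(X) > subsample) idx <- sort(sample(idx, subsample))
  Xs <- X[idx, , drop = FALSE]
  n <- nrow(Xs)
  if (n <= 3 * perplexity) {
    stop("need n > 3 * perplexity synapses (n = ", n,
         ", perplexity = ", perplexity, ")")
  }
  Y0 <- NULL
  if (is.matrix(init)) {
    Y0 <- init
  } else if (identical(init, "pca")) {
    pc <- prcomp(Xs, center = TRUE, scale. = FALSE)
    Y0 <- pc$x[, 1:2, drop = FALSE]
    Y0 <- Y0 / sd(Y0[, 1]) * 1e-4   # small-variance start, PCA directions
  }
  fit <- Rtsne::Rtsne(Xs, dims = 2, perplexity = perplexity, theta = theta,
                      max_iter = n_iter, Y_init = Y0, pca = FALSE,
                      check_duplicates = FALSE, verbose = FALSE)
  list(coords = fit$Y, index = idx, perplexity = perplexity)
}

#' Kernel density map of an embedding with candidate sub-type modes
#'
#' 2D Gaussian kernel density estimate of the embedding coordinates on a
#' regular grid (bandwidth by Scott's rule unless given), with grid local
#' maxima above a density quantile reported as candidate sub-type centres.
#' Mode stability is probed by re-estimating at 1.5x the bandwidth: if the
#' mode count changes, the result is flagged low-confidence (as for
#' featureless/uniform point clouds).
#'
#' @param coords n x 2 matrix of embedding coordinates
#' @param bandwidth numeric of length 2 or NULL (Scott's rule)
#' @param gridsize grid points per axis (default 101)
#' @param min_quantile density quantile (over positive grid densities) a
#'   local maximum must exceed (default 0.75)
#' @return list: x, y (grid axes), density (matrix, integrates to ~1),
#'   modes (data.frame x, y, density), bandwidth, low_confidence
#' @export
density_regions <- function(coords, bandwidth = NULL, gridsize = 101L,
                            min_quantile = 0.75) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 10L) stop("need at least 10 points for a density map")
  scott <- function(v) sd(v) * n^(-1 / 6)
  if (is.null(bandwidth)) {
    bandwidth <- c(scott(coords[, 1]), scott(coords[, 2]))
  }
  kde <- function(bw) {
    KernSmooth::bkde2D(coords, bandwidth = bw,
                       gridsize = c(gridsize, gridsize))
  }
  find_modes <- function(est) {
    z <- est$fhat
    thr <- quantile(z[z > 0], min_quantile)
    nr <- nrow(z); nc <- ncol(z)
    zp <- matrix(-Inf, nr + 2L, nc + 2L)
    zp[2:(nr + 1L), 2:(nc + 1L)] <- z
    ismax <- matrix(TRUE, nr, nc)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ismax <- ismax & (z >= zp[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj])
    }
    idx <- which(ismax & z > thr, arr.ind = TRUE)
    data.frame(x = est$x1[idx[, 1]], y = est$x2[idx[, 2]],
               density = z[idx])
  }
  est <- kde(bandwidth)
  modes <- find_modes(est)
  modes <- modes[order(-modes$density), ]
  rownames(modes) <- NULL
  modes2 <- find_modes(kde(1.5 * bandwidth))
  dx <- mean(diff(est$x1)); dy <- mean(diff(est$x2))
  list(x = est$x1, y = est$x2, density = est$fhat,
       integral = sum(est$fhat) * dx * dy,
       modes = modes, bandwidth = bandwidth,
       low_confidence = nrow(modes) != nrow(modes2))
}

#' Hierarchical clustering of synapse profiles
#'
#' Agglomerative clustering with Euclidean distance and Ward's linkage, over
#' synapses (rows) and over features (columns), as used for clustered
#' heatmaps of single-synapse profiles.  Linkage heights are non-decreasing
#' (Ward monotonicity).
#'
#' @param X normalized matrix from \code{\link{normalize_for_embedding}}
#' @param cluster_synapses,cluster_features compute the respective linkage
#' @return list: synapse_hclust, feature_hclust (hclust objects or NULL),
#'   synapse_order, feature_order, data (X reordered)
#' @export
cluster_profiles <- function(X, cluster_synapses = TRUE,
                             cluster_features = TRUE) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("profile matrix contains non-finite values")
  hs <- hf <- NULL
  so <- seq_len(nrow(X)); fo <- seq_len(ncol(X))
  if (cluster_synapses && nrow(X) > 2L) {
    hs <- hclust(dist(X), method = "ward.D2")
    so <- hs$order
  }
  if (cluster_features && ncol(X) > 2L) {
    hf <- hclust(dist(t(X)), method = "ward.D2")
    fo <- hf$order
  }
  list(synapse_hclust = hs, feature_hclust = hf,
       synapse_order = so, feature_order = fo,
       data = X[so, fo, drop = FALSE])
}
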