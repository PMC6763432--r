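# Shared fixtures, memoised so expensive simulations run once per session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, make) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- make()
  .fixture_env[[name]]
}

# default-condition confocal simulation (the acceptance surface)
fixture_confocal <- function() {
  memo("confocal", function() simulate_confocal_dataset(sim_config(seed = 7L)))
}

# synapsin segmentation + nuclear mask + synapse set on the default sim
fixture_segmented <- function() {
  memo("segmented", function() {
    sim <- fixture_confocal()
    img <- get_plane(sim$images, "synapsin")
    ps <- segment_channel(img, sim$images$pixel_size_nm, "synapsin")
    nuc <- nuclear_mask(get_plane(sim$images, "DAPI"),
                        sim$images$pixel_size_nm)
    syn <- detect_synapses(ps, nuc)
    list(sim = sim, puncta = ps, nuclear = nuc, synapses = syn)
  })
}

# small, fast confocal configuration for pipeline/io tests
small_sim_config <- function(seed = 3L) {
  sim_config(image_size = 192L, n_synapses = 25L, n_dendrites = 8L,
             n_decoys = 5L, min_separation_px = 16,
             nuclei = list(n = 2L, axis_px = c(18, 26), intensity = 300),
             seed = seed)
}

# independent connected-component counter (label propagation on matrix
# shifts), used as the oracle for the object-count threshold scan
oracle_count_objects <- function(mask, min_px = 2L) {
  if (!any(mask)) return(0L)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  shift_mat <- function(m, dr, dc, fill = 0L) {
    out <- matrix(fill, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    nb <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      s <- shift_mat(lab, dr, dc)
      upd <- mask & s > 0L & (nb == 0L | s < nb)
      nb[upd] <- s[upd]
    }
    new <- ifelse(mask & nb > 0L & nb < lab, nb, lab)
    if (identical(new, lab)) break
    lab <- new
  }
  sizes <- table(lab[lab > 0L])
  sum(sizes >= min_px)
}

# independent exhaustive threshold search (the oracle for
# optimal_object_threshold)
oracle_object_threshold <- function(img, n_levels = 100L, min_px = 2L) {
  nz <- img[img > 0]
  cand <- unique(quantile(nz, seq(0, 1, length.out = n_levels),
                          names = FALSE))
  counts <- vapply(cand, function(t) oracle_count_objects(img >= t, min_px),
                   integer(1))
  list(threshold = cand[which.max(counts)], n_objects = max(counts))
}

# random punctae image for threshold-scan tests
random_punctae_image <- function(size = 128L, n = 25L, seed = 1L) {
  set.seed(seed)
  img <- matrix(0, size, size)
  x <- runif(n, 8, size - 9)
  y <- runif(n, 8, size - 9)
  amp <- exp(rnorm(n, log(80), 0.5))
  for (i in seq_len(n)) {
    r <- 6L
    cx <- round(x[i]); cy <- round(y[i])
    gx <- exp(-((cx - r):(cx + r) - x[i])^2 / (2 * 1.6^2))
    gy <- exp(-((cy - r):(cy + r) - y[i])^2 / (2 * 1.6^2))
    img[(cy - r):(cy + r) + 1L, (cx - r):(cx + r) + 1L] <-
      img[(cy - r):(cy + r) + 1L, (cx - r):(cx + r) + 1L] + amp[i] * gy %o% gx
  }
  round(img)
}

# dendrite-like structured plane for drift tests (signal-to-noise set by
# amplitude / noise sd)
structured_plane <- function(size = 128L, seed = 1L, amplitude = 50,
                             noise_sd = 10) {
  set.seed(seed)
  img <- matrix(0, size, size)
  for (k in 1:6) {
    x0 <- runif(1, 0, size - 1); y0 <- runif(1, 0, size - 1)
    ang <- runif(1, 0, pi)
    t <- seq(-size, size, by = 0.5)
    xs <- x0 + t * cos(ang); ys <- y0 + t * sin(ang)
    ok <- xs >= 1 & xs <= size - 2 & ys >= 1 & ys <= size - 2
    for (i in which(ok)) {
      img[round(ys[i]) + 1L, round(xs[i]) + 1L] <-
        img[round(ys[i]) + 1L, round(xs[i]) + 1L] + amplitude
    }
  }
  img <- prismr:::gaussian_smooth(img, 1.5)
  img + matrix(rnorm(size^2, 0, noise_sd), size, size)
}

# brute-force NCC drift search (oracle for estimate_xy_drift)
oracle_xy_drift <- function(reference, moving, max_shift) {
  best <- NULL
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    nr <- nrow(reference); nc <- ncol(reference)
    r0 <- max(1, 1 - dy):min(nr, nr - dy)
    c0 <- max(1, 1 - dx):min(nc, nc - dx)
    a <- reference[r0, c0]
    b <- moving[r0 + dy, c0 + dx]
    if (sd(a) == 0 || sd(b) == 0) next
    v <- cor(as.vector(a), as.vector(b))
    key <- c(round(v, 9), -(abs(dx) + abs(dy)), -dx, -dy)
    if (is.null(best) ||
        key[1] > best$key[1] ||
        (key[1] == best$key[1] && key[2] > best$key[2]) ||
        (key[1] == best$key[1] && key[2] == best$key[2] &&
         key[3] > best$key[3]) ||
        (key[1] == best$key[1] && key[2] == best$key[2] &&
         key[3] == best$key[3] && key[4] > best$key[4])) {
      best <- list(dx = dx, dy = dy, key = key)
    }
  }
  best
}

# brute-force complementarity region enumeration (oracle for
# find_cross_hyb_regions at max_mismatch = 0)
oracle_regions <- function(probe, dock, min_len = 4L) {
  p <- strsplit(toupper(probe), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  d <- strsplit(toupper(dock), "")[[1]]
  n <- length(p); m <- length(d)
  out <- list()
  for (i in seq_len(n)) for (j in seq_len(m)) {
    # probe[i] pairs with dock[j] (antiparallel): extend i up, j down
    k <- 0L
    while (i + k <= n && j - k >= 1 && p[i + k] == comp[[d[j - k]]]) {
      k <- k + 1L
    }
    if (k >= min_len) {
      # maximality: no extension at the left/right ends
      left_ext <- i > 1 && j < m && p[i - 1] == comp[[d[j + 1]]]
      if (!left_ext) {
        out[[length(out) + 1L]] <- c(probe_start = i - 1L,
                                     probe_end = i + k - 1L,
                                     dock_start = j - k, dock_end = j,
                                     length = k)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(probe_start = integer(0), probe_end = integer(0),
                      dock_start = integer(0), dock_end = integer(0),
                      length = integer(0)))
  }
  df <- unique(as.data.frame(do.call(rbind, out)))
  df[order(df$probe_start, df$dock_start), , drop = FALSE]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
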