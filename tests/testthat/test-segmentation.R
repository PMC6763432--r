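# Punctae enhancement, object-count thresholding, watershed splitting,
# synapse identification and colocalization.

test_that("enhancement zeroes the background and keeps punctum positions", {
  set.seed(1)
  img <- random_punctae_image(128, n = 15, seed = 1) * 10 + 20 +
    matrix(rnorm(128^2, 0, 0.5), 128, 128)
  enh <- enhance_punctae(img)
  expect_true(all(enh >= 0))
  expect_gt(mean(enh == 0), 0.7)   # background almost everywhere exactly 0
  # the brightest enhanced pixel sits on a planted punctum
  peak <- which(enh == max(enh), arr.ind = TRUE)[1, ]
  expect_gt(img[peak[1], peak[2]], quantile(img, 0.99))

  expect_error(enhance_punctae(matrix(7, 32, 32)), "contrast")
})

test_that("structures larger than the top-hat disc are suppressed", {
  img <- matrix(20, 128, 128)
  img[40:70, 20:110] <- 120          # 31-px-wide bar
  img <- img + 100 * exp(-(outer((0:127 - 100)^2, (0:127 - 60)^2, "+")) /
                           (2 * 1.5^2))   # compact punctum
  enh <- enhance_punctae(img)
  bar_peak <- max(enh[50:60, 50:80])
  punctum_peak <- max(enh[95:105, 55:65])
  expect_gt(punctum_peak, 3 * bar_peak)
})

test_that("object-count threshold separates merging Gaussians and ties at the lowest level", {
  # two Gaussians whose tails merge below some level
  xg <- outer(rep(1, 64), 0:63); yg <- outer(0:63, rep(1, 64))
  two <- 100 * exp(-((xg - 24)^2 + (yg - 32)^2) / (2 * 3^2)) +
    100 * exp(-((xg - 40)^2 + (yg - 32)^2) / (2 * 3^2))
  two <- round(two)
  res <- optimal_object_threshold(two)
  lab <- prismr:::label_components(two >= res$threshold)
  areas <- tabulate(lab[lab > 0])
  expect_equal(sum(areas >= 2), 2L)

  # single punctum: every level yields one object; tie rule returns lowest
  one <- round(100 * exp(-((xg - 32)^2 + (yg - 32)^2) / (2 * 3^2)))
  res1 <- optimal_object_threshold(one)
  expect_equal(res1$threshold, min(one[one > 0]))
  expect_equal(res1$n_objects, 1L)

  expect_error(optimal_object_threshold(matrix(0, 8, 8)), "no objects")
})

test_that("threshold choice is invariant to rescaling of the enhanced image", {
  # pure gain changes (detector gain) leave the quantile-spaced candidate
  # set, and hence the chosen threshold, proportionally unchanged; an
  # additive offset would alter which pixels count as nonzero, so it is
  # not part of the contract
  img <- random_punctae_image(96, n = 12, seed = 3)
  a <- optimal_object_threshold(img)
  b <- optimal_object_threshold(img * 4)
  expect_equal(b$threshold, a$threshold * 4, tolerance = 1e-9)
  expect_equal(b$n_objects, a$n_objects)
})

test_that("threshold scan equals the independent exhaustive oracle", {
  for (seed in 1:5) {
    img <- random_punctae_image(96, n = 14, seed = seed)
    got <- optimal_object_threshold(img)
    orc <- oracle_object_threshold(img)
    expect_equal(got$threshold, orc$threshold, info = paste("seed", seed))
    expect_equal(got$n_objects, orc$n_objects, info = paste("seed", seed))
  }
})

test_that("watershed splits touching discs and conserves foreground area", {
  xg <- outer(rep(1, 40), 0:39); yg <- outer(0:39, rep(1, 40))
  mask <- ((xg - 16)^2 + (yg - 20)^2 <= 25) |
    ((xg - 24)^2 + (yg - 20)^2 <= 25)
  lab <- split_touching(mask)
  expect_equal(max(lab), 2L)
  expect_equal(sum(lab > 0), sum(mask))          # area conservation
  # split near the waist: the two centres carry different labels
  expect_true(lab[21, 17] != lab[21, 25])

  single <- (xg - 20)^2 + (yg - 20)^2 <= 36
  lab1 <- split_touching(single)
  expect_equal(max(lab1), 1L)
  expect_equal(lab1 > 0, single)

  empty <- split_touching(matrix(FALSE, 16, 16))
  expect_equal(max(empty), 0L)
})

test_that("well-separated synthetic punctae are recovered with sub-pixel centroids", {
  set.seed(5)
  size <- 256L
  n <- 50L
  gx <- round(seq(20, 236, length.out = 8))
  grid <- expand.grid(x = gx, y = gx)
  pick <- grid[sample(nrow(grid), n), ]
  img <- matrix(50, size, size)
  for (i in seq_len(n)) {
    r <- 8L
    cx <- pick$x[i]; cy <- pick$y[i]
    g <- 3000 * exp(-((cx - r):(cx + r) - cx)^2 / (2 * 2.2^2))
    img[(cy - r):(cy + r) + 1L, (cx - r):(cx + r) + 1L] <-
      img[(cy - r):(cy + r) + 1L, (cx - r):(cx + r) + 1L] +
      (exp(-((cy - r):(cy + r) - cy)^2 / (2 * 2.2^2)) %o% g)
  }
  img <- img + matrix(rnorm(size^2, 0, 2), size, size)
  ps <- segment_channel(img, 187, "test")
  expect_equal(nrow(ps$measurements), n)
  d <- sqrt(outer(ps$measurements$x, pick$x, "-")^2 +
              outer(ps$measurements$y, pick$y, "-")^2)
  expect_lt(max(apply(d, 2, min)), 1)

  empty <- segment_channel(matrix(0, 64, 64), 187, "blank")
  expect_equal(nrow(empty$measurements), 0L)
})

test_that("puncta measurements satisfy the unit and intensity contracts", {
  seg <- fixture_segmented()
  m <- seg$puncta$measurements
  expect_true(all(m$area_um2 == m$area_px * (187 / 1000)^2))
  expect_true(all(abs(m$mean - m$integrated / m$area_px) < 1e-9))
  # labels contiguous, each labeled pixel in exactly one punctum
  lab <- seg$puncta$labels
  expect_equal(sort(unique(lab[lab > 0])), seq_len(max(lab)))
})

test_that("nuclear mask recovers planted nuclei and captures decoys", {
  seg <- fixture_segmented()
  truth <- seg$sim$truth$nuclear_mask
  est <- seg$nuclear
  jaccard <- sum(est & truth) / sum(est | truth)
  expect_gt(jaccard, 0.9)
  dec <- seg$sim$truth$decoys
  inside <- est[cbind(round(dec$y) + 1L, round(dec$x) + 1L)]
  expect_gt(mean(inside), 0.9)

  expect_warning(m <- nuclear_mask(matrix(3, 64, 64), 187), "blank")
  expect_false(any(m))
})

test_that("the synapse area gate is strict at 0.42 um^2 and excludes nuclei", {
  # at 187 nm pixels: 12 px = 0.4196 um^2 excluded, 13 px = 0.4546 included
  expect_lt(12 * 0.187^2, 0.42)
  expect_gt(13 * 0.187^2, 0.42)
  lab <- matrix(0L, 64, 64)
  lab[10, 1:12] <- 1L              # 12-px punctum
  lab[30, 1:13] <- 2L              # 13-px punctum
  vals <- matrix(1, 64, 64)
  meas <- prismr:::label_measurements(lab, vals)
  meas$area_um2 <- meas$area_px * (187 / 1000)^2
  meas$mean <- meas$integrated / meas$area_px
  ps <- structure(list(labels = lab, measurements = meas[, c(
    "id", "area_px", "area_um2", "integrated", "mean", "x", "y")],
    channel = "synapsin", pixel_size_nm = 187, threshold = 1),
    class = "puncta_set")
  syn <- detect_synapses(ps, NULL)
  expect_equal(syn$synapses$punctum_id, 2L)

  # a punctum of exactly 0.42 um^2 is excluded (strict inequality)
  meas2 <- meas
  meas2$area_um2[1] <- 0.42
  ps2 <- ps; ps2$measurements <- meas2[, names(ps$measurements)]
  expect_false(1L %in% detect_synapses(ps2, NULL)$synapses$punctum_id)

  # intranuclear decoys are removed in the default simulation
  seg <- fixture_segmented()
  dec <- seg$sim$truth$decoys
  det <- seg$synapses$synapses
  if (nrow(dec) > 0 && nrow(det) > 0) {
    d <- sqrt(outer(det$x, dec$x, "-")^2 + outer(det$y, dec$y, "-")^2)
    expect_equal(sum(apply(d, 2, min) < 3), 0L)
  }
})

test_that("colocalization is strict, tie-broken by synapse id, and matches brute force", {
  mkps <- function(df, px = 187) {
    structure(list(labels = matrix(0L, 4, 4),
                   measurements = data.frame(
                     id = seq_len(nrow(df)), area_px = 10L, area_um2 = 0.5,
                     integrated = 100, mean = 10, x = df$x, y = df$y),
                   channel = "c", pixel_size_nm = px, threshold = 1),
              class = "puncta_set")
  }
  mksyn <- function(df, px = 187) {
    ps <- mkps(df, px)
    m <- ps$measurements
    structure(list(synapses = data.frame(
      synapse_id = seq_len(nrow(df)), punctum_id = m$id, x = m$x, y = m$y,
      area_px = m$area_px, area_um2 = m$area_um2,
      integrated = m$integrated, mean = m$mean),
      marker = ps, min_area_um2 = 0.42), class = "synapse_set")
  }
  # 1000 nm pixels make the distance arithmetic exact at the boundary
  syn <- mksyn(data.frame(x = c(0, 50), y = c(0, 0)), px = 1000)
  # punctum at 0.8 um assigned; punctum at exactly 1.0 um absent
  pq <- mkps(data.frame(x = c(0.8, 51.0), y = c(0, 0)), px = 1000)
  asn <- colocalize(syn, pq, max_dist_um = 1.0)
  expect_equal(asn$punctum_id, c(1L, NA_integer_))
  expect_equal(asn$distance_um[1], 0.8, tolerance = 1e-9)

  # equidistant punctum goes to the lower synapse id
  syn2 <- mksyn(data.frame(x = c(0, 10), y = c(0, 0)))
  pq2 <- mkps(data.frame(x = 5, y = 0))
  asn2 <- colocalize(syn2, pq2, max_dist_um = 2)
  expect_equal(asn2$punctum_id, c(1L, NA_integer_))

  expect_error(colocalize(syn, mkps(data.frame(x = 1, y = 1), px = 100)),
               "pixel size")

  # brute-force greedy matching oracle on random points
  set.seed(9)
  s <- data.frame(x = runif(100, 0, 500), y = runif(100, 0, 500))
  p <- data.frame(x = runif(100, 0, 500), y = runif(100, 0, 500))
  syn3 <- mksyn(s); pq3 <- mkps(p)
  got <- colocalize(syn3, pq3, max_dist_um = 1.0)
  # oracle: sort candidate pairs by (distance, synapse id, punctum id)
  d_um <- sqrt(outer(s$x, p$x, "-")^2 + outer(s$y, p$y, "-")^2) * 0.187
  cand <- which(d_um < 1.0, arr.ind = TRUE)
  ord <- order(d_um[cand], cand[, 1], cand[, 2])
  sfree <- rep(TRUE, 100); pfree <- rep(TRUE, 100)
  want <- rep(NA_integer_, 100)
  for (k in ord) {
    si <- cand[k, 1]; pi <- cand[k, 2]
    if (sfree[si] && pfree[pi]) {
      want[si] <- pi; sfree[si] <- FALSE; pfree[pi] <- FALSE
    }
  }
  expect_equal(got$punctum_id, want)
})
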