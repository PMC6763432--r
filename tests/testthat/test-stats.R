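# Correlation networks, treatment comparison, correlation difference test.

test_that("correlation matrix has unit diagonal and strict edge threshold", {
  tab <- simulate_synapse_table(n_per_image = 200L, seed = 1L)
  net <- pairwise_correlations(tab, by = "batch_id")
  expect_true(all(diag(net$matrix) == 1))
  expect_true(all(net$matrix == t(net$matrix)))
  pairs_above <- sum(net$matrix[upper.tri(net$matrix)] > net$threshold)
  expect_equal(nrow(net$edges), pairs_above)
})

test_that("planted correlations are estimated within tolerance and edges match the plant", {
  ch <- c("a", "b", "c", "d")
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.70
  R[3, 4] <- R[4, 3] <- 0.50
  R[1, 3] <- R[3, 1] <- 0.10
  dimnames(R) <- list(ch, ch)
  wells <- data.frame(well = sprintf("w%d", 1:3),
                      batch = sprintf("b%d", 1:3), treatment = "untreated")
  tab <- simulate_synapse_table(channels = ch, correlation = R,
                                n_per_image = 1700L, images_per_well = 1L,
                                wells = wells, well_sd = 0, noise_sd = 0,
                                seed = 2L)
  net <- pairwise_correlations(tab, by = "batch_id")
  expect_lt(abs(net$matrix["a", "b"] - 0.70), 0.05)
  got_edges <- paste(net$edges$a, net$edges$b)
  want <- c("a b", "c d")   # exactly the pairs with planted r > 0.35
  expect_setequal(got_edges, want)
})

test_that("zero-variance channels skip their group with a warning", {
  tab <- simulate_synapse_table(n_per_image = 50L, seed = 3L)
  tab$synapsin_intensity[tab$batch_id == "b1"] <- 5
  expect_warning(net <- pairwise_correlations(tab, by = "batch_id"),
                 "zero-variance")
  expect_false(anyNA(net$matrix))   # other batches still contribute
})

test_that("group comparison matches the closed-form Student t on a toy set", {
  wt <- data.frame(well_id = sprintf("w%d", 1:6),
                   batch_id = "b1",
                   treatment = rep(c("untreated", "treated"), each = 3),
                   f = c(10, 12, 11, 14, 15, 16))
  out <- compare_groups(wt, features = "f")
  x0 <- c(10, 12, 11) / 11; x1 <- c(14, 15, 16) / 11
  sp <- sqrt((2 * var(x1) + 2 * var(x0)) / 4)
  t_hand <- (mean(x1) - mean(x0)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$df, 4)
  expect_equal(out$rel_treated, 15 / 11, tolerance = 1e-12)
  # CI contains the point estimate
  expect_lt(out$rel_treated - out$rel_treated_ci, out$rel_treated)
})

test_that("identical groups give relative mean 1 and t = 0", {
  wt <- data.frame(well_id = sprintf("w%d", 1:4), batch_id = "b1",
                   treatment = rep(c("untreated", "treated"), each = 2),
                   f = c(5, 7, 5, 7))
  out <- compare_groups(wt, features = "f")
  expect_equal(out$rel_treated, 1)
  expect_equal(out$t, 0)
  expect_equal(out$p_value, 1)

  expect_error(compare_groups(wt[1:2, ], features = "f"), "2 wells")
})

test_that("treatment effects are detected on exactly the planted channels", {
  wells <- data.frame(well = sprintf("w%02d", 1:12),
                      batch = rep(sprintf("b%d", 1:3), each = 4),
                      treatment = rep(c("untreated", "treated"), 6))
  tab <- simulate_synapse_table(
    channels = c("synapsin", "PSD95", "bassoon", "Homer1", "SHANK3"),
    wells = wells, effects = c(PSD95 = 1.3, Homer1 = 1.3),
    n_per_image = 80L, seed = 5L)
  wt <- summarize_wells(tab)
  out <- compare_groups(wt,
                        features = grep("_intensity$", names(wt),
                                        value = TRUE))
  sig <- out$feature[out$p_value < 0.05]
  expect_setequal(sig, c("PSD95_intensity", "Homer1_intensity"))
  expect_equal(out$rel_treated[out$feature == "PSD95_intensity"], 1.3,
               tolerance = 0.1)
})

test_that("correlation differences are centred exactly within replicates", {
  wells <- data.frame(well = sprintf("w%02d", 1:8),
                      batch = rep(c("b1", "b2"), each = 4),
                      treatment = rep(c("untreated", "treated"), 4))
  tab <- simulate_synapse_table(channels = c("a", "b", "c"), wells = wells,
                                n_per_image = 120L, seed = 6L)
  wr <- per_well_correlations(tab)
  out <- correlation_difference_test(wr)
  expect_true(all(abs(out$mean_diff_untreated) < 1e-12))

  # treated identical to untreated: no pair flagged strongly
  expect_gt(min(out$p_value), 0.01)

  wr2 <- wr[wr$treatment == "treated", ]
  expect_error(correlation_difference_test(wr2), "no untreated")
})

test_that("a planted correlation increase is flagged for the right pair", {
  wells <- data.frame(well = sprintf("w%02d", 1:12),
                      batch = rep(sprintf("b%d", 1:3), each = 4),
                      treatment = rep(c("untreated", "treated"), 6))
  ch <- c("a", "b", "c")
  rows <- list()
  for (w in seq_len(nrow(wells))) {
    r_ab <- if (wells$treatment[w] == "treated") 0.6 else 0.3
    R <- diag(3); R[1, 2] <- R[2, 1] <- r_ab
    dimnames(R) <- list(ch, ch)
    rows[[w]] <- simulate_synapse_table(
      channels = ch, correlation = R, n_per_image = 400L,
      images_per_well = 1L, wells = wells[w, , drop = FALSE],
      well_sd = 0, noise_sd = 0, seed = 100L + w)
  }
  tab <- do.call(rbind, rows)
  out <- correlation_difference_test(per_well_correlations(tab))
  key <- paste(out$a, out$b)
  expect_lt(out$p_value[key == "a b"], 0.05)
  expect_equal(out$delta[key == "a b"], 0.3, tolerance = 0.1)
  # unplanted pairs show no systematic shift
  expect_lt(max(abs(out$delta[key != "a b"])), 0.1)
  expect_equal(key[which.min(out$p_value)], "a b")
})
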