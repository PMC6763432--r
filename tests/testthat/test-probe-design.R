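# LNA imaging-probe design: anchor, cross-hybridization regions, cost
# function, exhaustive optimizer.

test_that("the 3' anchor appends two adenines and validates the alphabet", {
  expect_equal(append_anchor("CTAGATGTAT"), "CTAGATGTATAA")
  expect_equal(nchar(append_anchor(paste(rep("A", 11), collapse = ""))), 13L)
  expect_error(append_anchor("CUAGA"), "invalid character")
  expect_error(append_anchor(""), "empty")
})

test_that("cross-hybridization regions match a planted complement and its offsets", {
  # docking strand containing the reverse complement of probe[0:8)
  probe <- "ATCGATCGTTTTT"
  dock <- c(d1 = paste0("GG", "CGATCGAT", "G"))  # revcomp(ATCGATCG)
  rg <- find_cross_hyb_regions(probe, dock, min_len = 4L)
  r8 <- rg[rg$length == 8L, ]
  expect_equal(nrow(r8), 1L)
  expect_equal(r8$probe_start, 0L)
  expect_equal(r8$probe_end, 8L)
  expect_equal(r8$dock_start, 2L)
  expect_equal(r8$dock_end, 10L)

  # no complementarity >= 4 nt anywhere
  none <- find_cross_hyb_regions("AAAAAAAAAA", c(d = "CCCCCCCC"))
  expect_equal(nrow(none), 0L)

  expect_equal(nrow(find_cross_hyb_regions("ACGTACGT",
                                           setNames(character(0),
                                                    character(0)))), 0L)
})

test_that("region finding equals brute-force enumeration on random pairs", {
  set.seed(11)
  for (i in 1:20) {
    probe <- random_dna(13)
    dock <- random_dna(11)
    got <- find_cross_hyb_regions(probe, c(d = dock), min_len = 4L)
    got <- got[order(got$probe_start, got$dock_start),
               c("probe_start", "probe_end", "dock_start", "dock_end",
                 "length")]
    rownames(got) <- NULL
    want <- oracle_regions(probe, dock, min_len = 4L)
    rownames(want) <- NULL
    expect_equal(got, want, info = paste("pair", i))
  }
})

test_that("the cognate strand's intended duplex is excluded", {
  probe_core <- "ATACATCTAGT"
  probe <- append_anchor(probe_core)
  panel <- demo_docking_panel()
  with_cog <- find_cross_hyb_regions(probe, panel, cognate = "p2")
  without <- find_cross_hyb_regions(probe, panel)
  # excluding the cognate removes exactly one region (the longest on p2)
  expect_equal(nrow(without) - nrow(with_cog), 1L)
  lost <- setdiff(paste(without$docking_id, without$probe_start,
                        without$length),
                  paste(with_cog$docking_id, with_cog$probe_start,
                        with_cog$length))
  expect_match(lost, "^p2 ")
})

test_that("scheme cost follows the power-law form and its monotonicities", {
  r <- data.frame(docking_id = "d", probe_start = 3L, probe_end = 9L,
                  dock_start = 0L, dock_end = 6L, length = 6L)
  # one region of length 6 with 2 LNAs inside: 6^1 * 2^2 = 24
  expect_equal(scheme_cost(c(4L, 5L, 0L), r, 13L)$cost, 24)
  # no LNA inside any region: zero cost
  expect_equal(scheme_cost(c(0L, 1L, 2L), r, 13L)$cost, 0)
  # moving an LNA out of the region never increases the cost
  inside <- scheme_cost(c(4L, 5L, 6L), r, 13L)$cost
  partly <- scheme_cost(c(4L, 5L, 12L), r, 13L)$cost
  expect_gte(inside, partly)
  # strictly increasing in the number of occupying LNAs
  expect_gt(scheme_cost(c(4L, 5L), r, 13L)$cost,
            scheme_cost(c(4L), r, 13L)$cost)
  # assigned cost is the max over strands (permutation invariant)
  r2 <- rbind(r, data.frame(docking_id = "e", probe_start = 0L,
                            probe_end = 4L, dock_start = 0L, dock_end = 4L,
                            length = 4L))
  a <- scheme_cost(c(1L, 4L), r2, 13L)
  b <- scheme_cost(c(1L, 4L), r2[2:1, ], 13L)
  expect_equal(a$cost, b$cost)
  expect_equal(a$cost, max(a$per_strand))

  expect_error(scheme_cost(c(0L, 20L), r, 13L), "outside")
  expect_error(scheme_cost(c(1L, 1L), r, 13L), "distinct")
})

test_that("the optimizer is exhaustive, tie-broken lexicographically, and avoids regions when possible", {
  # empty region list: all schemes cost 0, positions {0,1,2} by tie rule
  sc <- design_lna_scheme("ACGTACGTACG", setNames(character(0),
                                                  character(0)))
  expect_equal(sc$positions, c(0L, 1L, 2L))
  expect_equal(sc$cost, 0)
  expect_equal(sc$n_schemes, choose(13, 3))

  expect_error(design_lna_scheme("ACG", c(d = "ACGT"), n_lna = 9L),
               "exceeds")
})

test_that("the optimizer matches an independent brute-force enumerator", {
  set.seed(12)
  for (panel_i in 1:10) {
    probe <- random_dna(11)
    docking <- setNames(replicate(4, random_dna(11)),
                        sprintf("d%d", 1:4))
    got <- design_lna_scheme(probe, docking, n_lna = 3L)
    # independent brute force over all position triples
    seqa <- append_anchor(probe)
    L <- nchar(seqa)
    regions <- find_cross_hyb_regions(seqa, docking, min_len = 4L)
    best_cost <- Inf; best_set <- NULL
    for (i in 0:(L - 3)) for (j in (i + 1):(L - 2)) for (k in (j + 1):(L - 1)) {
      cost <- 0
      if (nrow(regions)) {
        per <- tapply(seq_len(nrow(regions)), regions$docking_id,
                      function(idx) {
          sum(vapply(idx, function(q) {
            nin <- sum(c(i, j, k) >= regions$probe_start[q] &
                         c(i, j, k) < regions$probe_end[q])
            regions$length[q] * nin^2
          }, numeric(1)))
        })
        cost <- max(unlist(per))
      }
      if (cost < best_cost) { best_cost <- cost; best_set <- c(i, j, k) }
    }
    expect_equal(got$cost, best_cost, info = paste("panel", panel_i))
    expect_equal(got$positions, best_set, info = paste("panel", panel_i))
  }
})
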