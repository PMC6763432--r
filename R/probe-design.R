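# LNA imaging-probe substitution design.
#
# High-affinity LNA imaging probes are derived from the DNA-PAINT probe
# sequences by (1) appending two adenines at the 3' end and (2) replacing
# three DNA nucleotides with LNA nucleotides.  Because LNA raises duplex
# melting temperature, substitutions falling inside regions of partial
# complementarity with non-cognate docking strands would strengthen
# crosstalk; the optimizer therefore enumerates every substitution scheme
# and picks the one with minimal cross-hybridization cost.

VALID_BASES <- c("A", "C", "G", "T")

check_dna <- function(seq) {
  s <- toupper(seq)
  chars <- strsplit(s, "")[[1]]
  if (length(chars) == 0L) stop("empty sequence")
  bad <- setdiff(unique(chars), VALID_BASES)
  if (length(bad)) {
    stop("invalid character(s) in sequence: ", paste(bad, collapse = ", "))
  }
  s
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Append the 3' adenine anchor to a probe core sequence
#'
#' Imaging probes carry two extra adenines at the 3' end to maximize
#' hybridization with the cognate docking strand.
#'
#' @param seq probe core sequence, 5'->3', over A/C/G/T
#' @return the anchored sequence (seq + "AA")
#' @export
append_anchor <- function(seq) {
  paste0(check_dna(seq), "AA")
}

#' Find partially complementary regions between a probe and docking strands
#'
#' Enumerates every maximal ungapped stretch (length >= \code{min_len},
#' at most \code{max_mismatch} internal mismatches, flanked by matches)
#' where the probe is reverse-complementary to a docking strand.  At
#' oligonucleotide lengths of 11-13 nt this exact scan over all alignment
#' offsets is the deterministic equivalent of a short-word BLAST search.
#' The cognate strand's intended duplex (its longest complementary region)
#' is excluded; any additional unintended complementarity with the cognate
#' strand is kept.
#'
#' @param probe anchored probe sequence (5'->3')
#' @param docking named character vector of docking-strand sequences
#'   (5'->3')
#' @param cognate name of the probe's own docking strand (excluded as the
#'   intended duplex), or NULL
#' @param min_len minimum region length in nt (default 4)
#' @param max_mismatch maximum internal mismatches per region (default 0)
#' @return data.frame: docking_id, probe_start, probe_end (0-based,
#'   half-open), dock_start, dock_end, length
#' @export
find_cross_hyb_regions <- function(probe, docking, cognate = NULL,
                                   min_len = 4L, max_mismatch = 0L) {
  probe <- check_dna(probe)
  if (length(docking) == 0L) {
    return(data.frame(docking_id = character(0), probe_start = integer(0),
                      probe_end = integer(0), dock_start = integer(0),
                      dock_end = integer(0), length = integer(0)))
  }
  if (is.null(names(docking))) {
    names(docking) <- sprintf("dock%02d", seq_along(docking))
  }
  p <- strsplit(probe, "")[[1]]
  n <- length(p)
  out <- list()
  for (id in names(docking)) {
    dseq <- check_dna(docking[[id]])
    rc <- strsplit(revcomp(dseq), "")[[1]]
    m <- length(rc)
    # offset d: probe[i] aligned with rc[i + d]
    for (d in (1L - n):(m - 1L)) {
      i0 <- max(1L, 1L - d); i1 <- min(n, m - d)
      if (i1 - i0 + 1L < min_len) next
      eq <- p[i0:i1] == rc[(i0:i1) + d]
      # maximal runs with <= max_mismatch internal mismatches,
      # starting and ending on a match
      runs <- maximal_match_runs(eq, min_len, max_mismatch)
      for (rn in runs) {
        ps <- i0 + rn[1] - 1L       # 1-based probe start
        pe <- i0 + rn[2] - 1L       # 1-based probe end (inclusive)
        rs <- ps + d                # position in rc
        re <- pe + d
        out[[length(out) + 1L]] <- data.frame(
          docking_id = id,
          probe_start = ps - 1L, probe_end = pe,        # 0-based half-open
          dock_start = m - re, dock_end = m - rs + 1L,  # map rc -> docking
          length = pe - ps + 1L)
      }
    }
  }
  regions <- if (length(out)) do.call(rbind, out) else
    data.frame(docking_id = character(0), probe_start = integer(0),
               probe_end = integer(0), dock_start = integer(0),
               dock_end = integer(0), length = integer(0))
  if (!is.null(cognate) && cognate %in% regions$docking_id) {
    cg <- which(regions$docking_id == cognate)
    intended <- cg[which.max(regions$length[cg])]
    regions <- regions[-intended, , drop = FALSE]
  }
  rownames(regions) <- NULL
  regions
}

# maximal windows in a logical vector with at most `mm` FALSEs, bounded by
# TRUEs, length >= min_len; returns list of c(start, end) (1-based inclusive)
maximal_match_runs <- function(eq, min_len, mm) {
  n <- length(eq)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (!eq[i]) { i <- i + 1L; next }
    # extend from i allowing up to mm mismatches
    j <- i; miss <- 0L; best_j <- i
    while (j <= n) {
      if (!eq[j]) {
        miss <- miss + 1L
        if (miss > mm) break
      } else best_j <- j
      j <- j + 1L
    }
    if (best_j - i + 1L >= min_len) {
      runs[[length(runs) + 1L]] <- c(i, best_j)
    }
    # next candidate start: after the first mismatch inside this window
    nx <- which(!eq[i:best_j])
    i <- if (length(nx)) i + nx[1] else best_j + 1L
  }
  # drop runs contained in another run
  if (length(runs) > 1L) {
    keep <- rep(TRUE, length(runs))
    for (a in seq_along(runs)) for (b in seq_along(runs)) {
      if (a != b && keep[a] &&
          runs[[b]][1] <= runs[[a]][1] && runs[[a]][2] <= runs[[b]][2] &&
          !identical(runs[[a]], runs[[b]])) keep[a] <- FALSE
    }
    runs <- runs[keep]
  }
  runs
}

#' Cross-hybridization cost of one LNA substitution scheme
#'
#' For each docking strand d, cost_d = sum over its regions r of
#' length_r^beta * (number of LNA positions inside r)^alpha; the scheme's
#' assigned cost is the maximum of the per-strand costs.  The cost is zero
#' when no LNA falls inside any region, strictly increasing in the number
#' of LNAs within a region, and increasing with the length of occupied
#' regions; the exponents are exposed because only these monotonicities are
#' prescribed, not an exact functional form.
#'
#' @param positions 0-based LNA position set (distinct, within the probe)
#' @param regions region table from \code{\link{find_cross_hyb_regions}}
#' @param probe_length length of the probe (for bounds checking)
#' @param alpha LNA-count exponent (default 2)
#' @param beta region-length exponent (default 1)
#' @return list: cost (assigned = max), per_strand (named numeric)
#' @export
scheme_cost <- function(positions, regions, probe_length,
                        alpha = 2, beta = 1) {
  positions <- as.integer(positions)
  if (anyDuplicated(positions)) stop("LNA positions must be distinct")
  if (length(positions) &&
      (min(positions) < 0L || max(positions) >= probe_length)) {
    stop("LNA position(s) outside the probe sequence")
  }
  if (nrow(regions) == 0L) {
    return(list(cost = 0, per_strand = numeric(0)))
  }
  n_in <- vapply(seq_len(nrow(regions)), function(i) {
    sum(positions >= regions$probe_start[i] & positions < regions$probe_end[i])
  }, numeric(1))
  contrib <- regions$length^beta * n_in^alpha
  per_strand <- tapply(contrib, regions$docking_id, sum)
  per_strand <- stats::setNames(as.numeric(per_strand), names(per_strand))
  list(cost = max(per_strand), per_strand = per_strand)
}

#' Design the minimal-cost LNA substitution scheme for a probe
#'
#' Appends the 3' anchor (optional), finds the partially complementary
#' regions against the docking panel, evaluates the cost of every
#' \code{choose(L, n_lna)} position set exhaustively, and returns the
#' scheme with minimal cost; exact ties are broken by the lexicographically
#' smallest position set.
#'
#' @param probe probe core sequence (5'->3')
#' @param docking named character vector of docking-strand sequences
#' @param cognate name of the cognate docking strand (excluded as the
#'   intended duplex)
#' @param n_lna number of LNA substitutions (default 3)
#' @param add_anchor append the 3' "AA" anchor first (default TRUE)
#' @param min_len,max_mismatch see \code{\link{find_cross_hyb_regions}}
#' @param alpha,beta see \code{\link{scheme_cost}}
#' @param full_table also return the cost of every scheme
#' @return list of class \code{lna_scheme}: sequence (anchored), positions
#'   (0-based), cost, per_strand, regions, and optionally all_schemes
#' @export
design_lna_scheme <- function(probe, docking, cognate = NULL, n_lna = 3L,
                              add_anchor = TRUE, min_len = 4L,
                              max_mismatch = 0L, alpha = 2, beta = 1,
                              full_table = FALSE) {
  seq <- if (add_anchor) append_anchor(probe) else check_dna(probe)
  L <- nchar(seq)
  if (n_lna > L) stop("n_lna exceeds the probe length")
  regions <- find_cross_hyb_regions(seq, docking, cognate = cognate,
                                    min_len = min_len,
                                    max_mismatch = max_mismatch)
  sets <- combn(L, n_lna) - 1L   # 0-based; combn is lexicographic
  costs <- numeric(ncol(sets))
  for (i in seq_len(ncol(sets))) {
    costs[i] <- scheme_cost(sets[, i], regions, L, alpha, beta)$cost
  }
  best <- which.min(costs)       # first minimum = lexicographically smallest
  sc <- scheme_cost(sets[, best], regions, L, alpha, beta)
  out <- list(sequence = seq, positions = sets[, best], cost = sc$cost,
              per_strand = sc$per_strand, regions = regions,
              n_schemes = ncol(sets))
  if (full_table) {
    out$all_schemes <- data.frame(
      positions = apply(sets, 2, paste, collapse = ","), cost = costs)
  }
  class(out) <- "lna_scheme"
  out
}

#' @export
print.lna_scheme <- function(x, ...) {
  cat(sprintf("lna_scheme: %s\n  LNA at 0-based positions {%s}, cost %.4g (%d schemes searched)\n",
              x$sequence, paste(x$positions, collapse = ", "), x$cost,
              x$n_schemes))
  invisible(x)
}

#' A synthetic demonstration docking-strand panel
#'
#' Nine orthogonal 11-nt docking strands for examples and tests.  These are
#' generated sequences, not measured reagents.
#'
#' @return named character vector of sequences (5'->3')
#' @export
demo_docking_panel <- function() {
  c(p1 = "ATACATCTAGT", p2 = "TAGATGTATCT", p3 = "GTAATGAAGTC",
    p4 = "CTTCATTACGT", p5 = "ACCACCATTAG", p6 = "CTAATGGTGTC",
    p7 = "TTCGGTAAGAT", p8 = "ATCTTACCGTC", p9 = "GGAATTAGGCA")
}
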