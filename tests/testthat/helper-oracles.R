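# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: exhaustive enumeration for the segmentation DP,
# pairwise union-find for CNVR merging, and direct quadratic interval
# arithmetic for the annotation operations.

# all segmentations of 1..n as (starts, ends) pairs, cached per n
.seg_enum_cache <- new.env(parent = emptyenv())
enumerate_segmentations <- function(n) {
  key <- as.character(n)
  if (!is.null(.seg_enum_cache[[key]])) return(.seg_enum_cache[[key]])
  out <- list()
  if (n == 1L) {
    out[[1L]] <- list(starts = 1L, ends = 1L)
  } else {
    for (mask in 0:(2^(n - 1L) - 1L)) {
      cuts <- which(bitwAnd(mask, 2^(0:(n - 2L))) > 0)
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, n)
      out[[mask + 1L]] <- list(starts = starts, ends = ends)
    }
  }
  .seg_enum_cache[[key]] <- out
  out
}

# minimal penalized cost over ALL 2^(n-1) segmentations (n <= ~14)
brute_force_seg_cost <- function(x, penalty) {
  n <- length(x)
  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x^2))
  best <- Inf
  for (seg in enumerate_segmentations(n)) {
    len <- seg$ends - seg$starts + 1L
    sums <- s1[seg$ends + 1L] - s1[seg$starts]
    sse <- sum(s2[seg$ends + 1L] - s2[seg$starts] - sums^2 / len)
    cost <- sse + penalty * length(seg$starts)
    if (cost < best) best <- cost
  }
  best
}

# penalized cost of the segmentation the package returned
dp_result_cost <- function(x, segments, penalty) {
  sse <- sum(vapply(seq_len(nrow(segments)), function(k) {
    seg <- x[segments$first_probe[k]:segments$last_probe[k]]
    seg <- seg[is.finite(seg)]
    sum((seg - mean(seg))^2)
  }, numeric(1)))
  sse + penalty * nrow(segments)
}

# quadratic all-pairs union-find partition of calls under >=1 bp overlap
oracle_merge_partition <- function(calls) {
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  same <- outer(calls$chrom, calls$chrom, "==")
  ov <- outer(calls$start_bp, calls$end_bp, "<=") &
    t(outer(calls$start_bp, calls$end_bp, "<="))
  edges <- which(same & ov & upper.tri(same), arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n), find, integer(1))
  match(comp, unique(comp))
}

# quadratic gene-overlap oracle mirroring the documented rules
oracle_overlap_genes <- function(cnvrs, genes, flank) {
  recs <- list()
  for (i in seq_len(nrow(cnvrs))) {
    ov <- pmax(0, pmin(cnvrs$end_bp[i], genes$end_bp + flank) -
                 pmax(cnvrs$start_bp[i], pmax(1, genes$start_bp - flank)) + 1)
    ov[genes$chrom != cnvrs$chrom[i]] <- 0
    hit <- which(ov >= 1)
    if (length(hit)) {
      recs[[length(recs) + 1L]] <- data.frame(
        cnvr = cnvrs$name[i], feature = genes$name[hit],
        overlap = ov[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(recs)) do.call(rbind, recs) else
    data.frame(cnvr = character(), feature = character(),
               overlap = numeric(), stringsAsFactors = FALSE)
}

# brute-force union coverage of one interval by a set of intervals
oracle_union_coverage <- function(start, end, q_start, q_end) {
  covered <- rep(FALSE, end - start + 1)
  for (k in seq_along(q_start)) {
    a <- max(start, q_start[k]); b <- min(end, q_end[k])
    if (a <= b) covered[(a - start + 1):(b - start + 1)] <- TRUE
  }
  sum(covered)
}

random_calls <- function(n, n_chrom = 3, max_pos = 1e6, seed = 1) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample(1500:50000, n, replace = TRUE)
  data.frame(
    sample_id = sample(sprintf("s%02d", 1:20), n, replace = TRUE),
    chrom = sample(sprintf("chr%d", seq_len(n_chrom)), n, replace = TRUE),
    start_bp = start, end_bp = start + len - 1,
    state = sample(c("gain", "loss"), n, replace = TRUE),
    mean_log2 = rep(0.6, n), n_probes = rep(10L, n),
    stringsAsFactors = FALSE
  )
}

# small noiseless cohort shared by calling tests
noiseless_cohort <- function(seed = 1, n_samples = 10, n_loci = 8) {
  layout <- genome_layout(c(chr1 = 2e6, chr2 = 1.5e6),
                          probe_spacing_bp = 1200)
  simulate_cohort(layout, n_samples = n_samples, n_loci = n_loci,
                  noise = noise_model(0, 0), model = NULL, seed = seed,
                  size_range = c(10000, 100000))
}
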