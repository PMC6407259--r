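# ---------------------------------------------------------------------------
# Least-squares changepoint segmentation of per-sample log2-ratio profiles.
#
# The segmentation objective is
#     sum_segments sum_probes (x - segment mean)^2  +  penalty * (#segments)
# minimised exactly by dynamic programming over all contiguous partitions.
# ---------------------------------------------------------------------------

#' Segmentation configuration
#'
#' @param penalty cost per additional segment in squared-log2 units, or
#'   `NULL` to select it per profile by BIC over [penalty_candidates()].
#' @param max_segments optional hard cap on the number of segments.
#' @param min_probes_per_segment minimum probes per segment (default 1).
#' @param band optional maximum segment length in probes; bounds the DP work
#'   to O(n * band) on long chromosomes. `NULL` runs the exact unbanded DP.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(penalty = NULL, max_segments = NULL,
                                min_probes_per_segment = 1L, band = NULL) {
  if (!is.null(penalty) && penalty < 0) stop("penalty must be >= 0")
  if (min_probes_per_segment < 1) stop("min_probes_per_segment must be >= 1")
  if (!is.null(max_segments) && max_segments < 1) {
    stop("max_segments must be >= 1")
  }
  structure(list(penalty = penalty, max_segments = max_segments,
                 min_probes_per_segment = as.integer(min_probes_per_segment),
                 band = if (is.null(band)) NULL else as.integer(band)),
            class = "segmentation_config")
}

#' Normalise a sample's log2-ratio profile to a zero diploid baseline
#'
#' Subtracts the median over autosomal probes so that the diploid state sits
#' at log2 ratio 0, removing per-sample baseline shifts (dye/loading
#' differences).
#'
#' @param values numeric log2 ratios for one sample.
#' @param autosomal logical mask of values to take the median over
#'   (default: all).
#' @return Recentred numeric vector.
#' @export
normalize_profile <- function(values, autosomal = NULL) {
  if (is.null(autosomal)) autosomal <- rep(TRUE, length(values))
  ref <- values[autosomal & is.finite(values)]
  if (length(ref) == 0L) stop("profile has no finite autosomal values")
  values - median(ref)
}

#' Re-baseline the sex chromosome for hemizygous samples
#'
#' Male samples carry one copy of the X chromosome; against a female (two-X)
#' reference their chrX probes sit near log2 ratio -1.  Subtracting the
#' per-sample chrX median puts the hemizygous single-copy state at 0 so that
#' genuine chrX CNVs deviate from the recentred baseline.  Female samples
#' are returned unchanged.
#'
#' @param values numeric chrX log2 ratios for one sample.
#' @param sample_sex `"male"` or `"female"`.
#' @return Recentred numeric vector.
#' @export
shift_chrx_baseline <- function(values, sample_sex) {
  if (!is.character(sample_sex) || length(sample_sex) != 1L ||
      !sample_sex %in% c("male", "female")) {
    stop("`sample_sex` must be \"male\" or \"female\"")
  }
  if (sample_sex == "female") return(values)
  ref <- values[is.finite(values)]
  if (length(ref) == 0L) stop("profile has no finite values")
  values - median(ref)
}

#' Default penalty candidates for a profile
#'
#' Candidates scale with the profile's noise variance (estimated robustly
#' from lag-1 differences, `(mad(diff(x)) / sqrt(2))^2`, floored at 1e-8 so
#' noise-free profiles keep a strictly positive penalty) times `log(n)`,
#' the per-parameter cost of a BIC-type criterion.
#'
#' @param values numeric profile.
#' @param multipliers numeric multipliers of `sigma2 * log(n)`.
#' @return Numeric vector of candidate penalties.
#' @export
penalty_candidates <- function(values, multipliers = c(0.5, 1, 2, 4)) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 2L) return(1e-8 * multipliers)
  sigma2 <- max((mad(diff(x)) / sqrt(2))^2, 1e-8)
  sigma2 * log(n) * multipliers
}

# constrained DP used only when max_segments is set: O(n^2 * K), pure R
dp_segment_kmax <- function(x, penalty, kmax, min_len = 1L) {
  n <- length(x)
  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x^2))
  sse <- function(i, j) { # x[i..j], 1-based
    len <- j - i + 1L
    s2[j + 1L] - s2[i] - (s1[j + 1L] - s1[i])^2 / len
  }
  kmax <- min(kmax, floor(n / min_len))
  cost <- matrix(Inf, kmax, n)
  back <- matrix(NA_integer_, kmax, n)
  for (j in seq_len(n)) if (j >= min_len) cost[1L, j] <- sse(1L, j)
  if (kmax >= 2L) {
    for (k in 2:kmax) {
      for (j in seq_len(n)) {
        if (j < k * min_len) next
        for (i in seq((k - 1L) * min_len, j - min_len)) {
          c0 <- cost[k - 1L, i] + sse(i + 1L, j)
          if (c0 < cost[k, j]) { cost[k, j] <- c0; back[k, j] <- i }
        }
      }
    }
  }
  tot <- cost[, n] + penalty * seq_len(kmax)
  kbest <- which.min(tot)
  ends <- integer(kbest); j <- n
  for (k in kbest:1) { ends[k] <- j; j <- if (k > 1) back[k, j] else 0L }
  starts <- c(1L, head(ends, -1L) + 1L)
  starts
}

#' Segment one log2-ratio profile into constant-mean pieces
#'
#' Exact penalized least-squares dynamic programming: returns the partition
#' minimising the within-segment sum of squares plus `penalty` per segment.
#' Missing (non-finite) values are dropped before optimisation; the returned
#' segments still tile the full probe index range (dropped probes are
#' attached to the segment of the preceding finite probe).
#'
#' @param values numeric log2 ratios, in genomic order.
#' @param positions probe positions in bp (same length); `NULL` uses the
#'   probe index as position.
#' @param config a [segmentation_config()].
#' @return data.frame with columns `first_probe`, `last_probe` (1-based
#'   inclusive indices into `values`), `start_bp`, `end_bp`, `n_probes`
#'   (finite probes in the segment) and `mean_log2`, tiling the profile.
#' @examples
#' segment_profile(c(rep(0, 10), rep(1, 10)), config = segmentation_config(penalty = 0.5))
#' @export
segment_profile <- function(values, positions = NULL,
                            config = segmentation_config()) {
  stopifnot(inherits(config, "segmentation_config"))
  n_all <- length(values)
  if (n_all == 0L) stop("empty profile")
  if (is.null(positions)) positions <- seq_len(n_all)
  stopifnot(length(positions) == n_all, !is.unsorted(positions))
  ok <- which(is.finite(values))
  if (length(ok) == 0L) stop("profile has no finite values")
  x <- values[ok]

  penalty <- config$penalty
  if (is.null(penalty)) {
    penalty <- select_penalty(x, penalty_candidates(x), config = config)
  }

  starts_f <- dp_segment_cpp(x, penalty,
                             min_len = config$min_probes_per_segment,
                             band = if (is.null(config$band)) 0L
                                    else config$band)
  if (!is.null(config$max_segments) &&
      length(starts_f) > config$max_segments) {
    starts_f <- dp_segment_kmax(x, penalty, config$max_segments,
                                min_len = config$min_probes_per_segment)
  }
  ends_f <- c(starts_f[-1L] - 1L, length(x))

  # map back to original indices; extend so segments tile 1..n_all
  first <- ok[starts_f]
  last <- ok[ends_f]
  first[1L] <- 1L
  if (length(first) > 1L) first[-1L] <- last[-length(last)] + 1L
  last <- c(first[-1L] - 1L, n_all)

  means <- vapply(seq_along(starts_f), function(k) {
    mean(x[starts_f[k]:ends_f[k]])
  }, numeric(1))
  data.frame(
    first_probe = first, last_probe = last,
    start_bp = positions[first], end_bp = positions[last],
    n_probes = ends_f - starts_f + 1L,
    mean_log2 = means
  )
}

#' Select a segmentation penalty by a BIC-type criterion
#'
#' Each candidate penalty induces a segmentation; the candidate minimising
#' `n * log(SSE / n) + (2k - 1) * log(n)` is chosen, where `2k - 1` counts
#' the free parameters of a k-segment model (k means + k - 1 breakpoints)
#' and SSE is floored at `n * 1e-12`.  Ties break toward the segmentation
#' with fewer segments, then toward the larger penalty.
#'
#' @param values numeric profile (finite values).
#' @param candidates numeric vector of candidate penalties.
#' @param config base [segmentation_config()] supplying `min_probes` / `band`.
#' @return The chosen penalty (one of `candidates`).
#' @export
select_penalty <- function(values, candidates = penalty_candidates(values),
                           config = segmentation_config()) {
  if (length(candidates) < 1L) stop("need at least one candidate penalty")
  x <- values[is.finite(values)]
  n <- length(x)
  stats <- vapply(candidates, function(pen) {
    starts <- dp_segment_cpp(x, pen,
                             min_len = config$min_probes_per_segment,
                             band = if (is.null(config$band)) 0L
                                    else config$band)
    ends <- c(starts[-1L] - 1L, n)
    sse <- sum(vapply(seq_along(starts), function(k) {
      seg <- x[starts[k]:ends[k]]
      sum((seg - mean(seg))^2)
    }, numeric(1)))
    k <- length(starts)
    c(bic = n * log(max(sse / n, 1e-12)) + (2 * k - 1) * log(n), k = k)
  }, numeric(2))
  ord <- order(stats["bic", ], stats["k", ], -candidates)
  candidates[ord[1L]]
}

#' Segment every sample of a signal matrix
#'
#' Applies per-sample baseline normalisation ([normalize_profile()], median
#' over autosomal probes), hemizygous-chrX re-baselining for male samples
#' ([shift_chrx_baseline()]), then segments each (sample, chromosome)
#' profile independently with [segment_profile()].
#'
#' @param sm a [signal_matrix()].
#' @param config a [segmentation_config()].
#' @param sex named character vector ("male"/"female") per sample; default
#'   all male.
#' @param sex_chromosome chromosome name with sex-linked baseline, or `NA`.
#' @return data.frame of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_probes`, `mean_log2`, `first_probe`, `last_probe` (indices
#'   within the chromosome's probe order).
#' @export
segment_signal <- function(sm, config = segmentation_config(), sex = NULL,
                           sex_chromosome = NA_character_) {
  stopifnot(inherits(sm, "signal_matrix"))
  if (is.null(sex)) sex <- setNames(rep("male", length(sm$samples)),
                                    sm$samples)
  if (!all(sm$samples %in% names(sex))) stop("`sex` must cover every sample")
  autosomal <- if (is.na(sex_chromosome)) rep(TRUE, nrow(sm$probes))
               else sm$probes$chrom != sex_chromosome
  chroms <- unique(sm$probes$chrom)
  out <- vector("list", length(sm$samples) * length(chroms))
  k <- 0L
  for (s in sm$samples) {
    v <- normalize_profile(sm$values[, s], autosomal)
    for (ch in chroms) {
      idx <- which(sm$probes$chrom == ch)
      vi <- v[idx]
      if (!is.na(sex_chromosome) && ch == sex_chromosome) {
        vi <- shift_chrx_baseline(vi, unname(sex[s]))
      }
      seg <- segment_profile(vi, sm$probes$pos[idx], config)
      k <- k + 1L
      out[[k]] <- data.frame(sample_id = s, chrom = ch, seg,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[, c("sample_id", "chrom", "start_bp", "end_bp", "n_probes",
                 "mean_log2", "first_probe", "last_probe")]
  rownames(res) <- NULL
  res
}
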