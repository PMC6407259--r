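# ---------------------------------------------------------------------------
# CNV calling from segmentations and CNVR construction across samples.
#
# Calling rule ("0.5_5"): a segment is a CNV when its mean log2 ratio is at
# least 0.5 in absolute value across at least 5 consecutive probes.  Calls
# shorter than/equal to 1 kb or longer than/equal to 5 Mb are filtered out
# as likely false positives (strict inequalities retained).
# ---------------------------------------------------------------------------

#' CNV calling configuration
#'
#' @param log2_threshold absolute segment-mean cutoff (default 0.5).
#' @param min_probes minimum consecutive probes (default 5).
#' @param min_length_bp exclusive lower length bound (default 1,000).
#' @param max_length_bp exclusive upper length bound (default 5,000,000).
#' @return An object of class `calling_config`.
#' @export
calling_config <- function(log2_threshold = 0.5, min_probes = 5L,
                           min_length_bp = 1000, max_length_bp = 5e6) {
  if (log2_threshold <= 0) stop("log2_threshold must be > 0")
  if (min_probes < 1) stop("min_probes must be >= 1")
  if (min_length_bp >= max_length_bp) {
    stop("min_length_bp must be smaller than max_length_bp")
  }
  structure(list(log2_threshold = log2_threshold,
                 min_probes = as.integer(min_probes),
                 min_length_bp = min_length_bp,
                 max_length_bp = max_length_bp),
            class = "calling_config")
}

interval_length_bp <- function(start_bp, end_bp) end_bp - start_bp + 1

#' Call CNVs from a segmentation table
#'
#' Emits one call per segment whose mean log2 ratio is at least
#' `log2_threshold` in absolute value over at least `min_probes` probes.
#' Consecutive qualifying segments of the same state within a (sample,
#' chromosome) profile are merged into a single call (probe-weighted mean).
#' Length filtering is a separate step ([filter_cnvs()]).
#'
#' @param segments segmentation table from [segment_signal()] (columns
#'   `sample_id`, `chrom`, `start_bp`, `end_bp`, `n_probes`, `mean_log2`,
#'   and `first_probe`/`last_probe`).
#' @param config a [calling_config()].
#' @return data.frame of calls: `sample_id`, `chrom`, `start_bp`, `end_bp`,
#'   `state` ("gain"/"loss"), `mean_log2`, `n_probes`.
#' @export
call_cnvs <- function(segments, config = calling_config()) {
  stopifnot(is.data.frame(segments), inherits(config, "calling_config"))
  empty <- data.frame(sample_id = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      state = character(), mean_log2 = numeric(),
                      n_probes = integer(), stringsAsFactors = FALSE)
  if (nrow(segments) == 0L) return(empty)
  qual <- abs(segments$mean_log2) >= config$log2_threshold &
    segments$n_probes >= config$min_probes
  if (!any(qual)) return(empty)
  seg <- segments
  seg$state <- ifelse(seg$mean_log2 >= config$log2_threshold, "gain",
               ifelse(seg$mean_log2 <= -config$log2_threshold, "loss", NA))
  seg$qual <- qual
  ord <- order(seg$sample_id, chrom_rank(seg$chrom), seg$start_bp)
  seg <- seg[ord, , drop = FALSE]
  # run-length grouping of consecutive qualifying same-state segments
  key <- paste(seg$sample_id, seg$chrom)
  new_run <- c(TRUE, key[-1L] != key[-nrow(seg)] |
                 !seg$qual[-1L] | !seg$qual[-nrow(seg)] |
                 seg$state[-1L] != seg$state[-nrow(seg)])
  new_run[is.na(new_run)] <- TRUE
  run <- cumsum(new_run)
  keep <- seg$qual
  run <- run[keep]
  seg <- seg[keep, , drop = FALSE]
  out <- do.call(rbind, lapply(split(seq_len(nrow(seg)), run), function(i) {
    data.frame(sample_id = seg$sample_id[i[1L]], chrom = seg$chrom[i[1L]],
               start_bp = min(seg$start_bp[i]), end_bp = max(seg$end_bp[i]),
               state = seg$state[i[1L]],
               mean_log2 = sum(seg$mean_log2[i] * seg$n_probes[i]) /
                 sum(seg$n_probes[i]),
               n_probes = sum(seg$n_probes[i]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Filter CNV calls on length
#'
#' Retains calls with `min_length_bp < length < max_length_bp` (strict at
#' both bounds; length = end - start + 1).
#'
#' @param calls data.frame from [call_cnvs()].
#' @param config a [calling_config()].
#' @return Filtered data.frame.
#' @export
filter_cnvs <- function(calls, config = calling_config()) {
  stopifnot(is.data.frame(calls))
  if (nrow(calls) == 0L) return(calls)
  len <- interval_length_bp(calls$start_bp, calls$end_bp)
  out <- calls[len > config$min_length_bp & len < config$max_length_bp, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate overlapping CNV calls across samples into CNV regions
#'
#' CNVRs are the connected components of calls under >= 1 bp overlap on the
#' same chromosome (book-ended calls, `end + 1 == start`, stay separate).
#' Each CNVR spans the union hull of its member calls and is classified
#' `loss`, `gain`, or `both` when members of both states are present.
#' Identifiers are assigned in genomic order.  Chromosomes whose names do
#' not parse as placed sequence (e.g. "chrUn") are flagged `placed = FALSE`
#' and are excluded from association downstream.
#'
#' @param calls data.frame of filtered calls across all samples.
#' @return An object of class `cnvr_set`: list with `cnvrs` (`cnvr_id`,
#'   `chrom`, `start_bp`, `end_bp`, `state`, `n_samples`, `n_calls`,
#'   `placed`) and `calls` (the input with a `cnvr_id` column).
#' @export
merge_to_cnvrs <- function(calls) {
  stopifnot(is.data.frame(calls))
  if (nrow(calls) == 0L) {
    cnvrs <- data.frame(cnvr_id = character(), chrom = character(),
                        start_bp = numeric(), end_bp = numeric(),
                        state = character(), n_samples = integer(),
                        n_calls = integer(), placed = logical(),
                        stringsAsFactors = FALSE)
    calls$cnvr_id <- character(0)
    return(structure(list(cnvrs = cnvrs, calls = calls), class = "cnvr_set"))
  }
  calls <- calls[order(chrom_rank(calls$chrom), calls$start_bp,
                       calls$end_bp), , drop = FALSE]
  rownames(calls) <- NULL
  calls$cnvr_id <- NA_character_
  pieces <- list()
  next_id <- 1L
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    ir <- IRanges::IRanges(start = calls$start_bp[idx],
                           end = calls$end_bp[idx])
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red, minoverlap = 1L)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    ids <- sprintf("CNVR%04d", next_id + seq_len(length(red)) - 1L)
    next_id <- next_id + length(red)
    calls$cnvr_id[idx] <- ids[grp]
    st <- vapply(seq_along(red), function(g) {
      states <- unique(calls$state[idx[grp == g]])
      if (length(states) > 1L) "both" else states
    }, character(1))
    pieces[[length(pieces) + 1L]] <- data.frame(
      cnvr_id = ids, chrom = ch,
      start_bp = IRanges::start(red), end_bp = IRanges::end(red),
      state = st,
      n_samples = vapply(seq_along(red), function(g) {
        length(unique(calls$sample_id[idx[grp == g]]))
      }, integer(1)),
      n_calls = as.integer(table(factor(grp, levels = seq_along(red)))),
      stringsAsFactors = FALSE
    )
  }
  cnvrs <- do.call(rbind, pieces)
  cnvrs$placed <- chrom_rank(cnvrs$chrom) < 2e6
  rownames(cnvrs) <- NULL
  structure(list(cnvrs = cnvrs, calls = calls), class = "cnvr_set")
}

#' @export
print.cnvr_set <- function(x, ...) {
  st <- table(factor(x$cnvrs$state, levels = c("loss", "gain", "both")))
  cat("cnvr_set:", nrow(x$cnvrs), "CNVRs (",
      st[["loss"]], "loss,", st[["gain"]], "gain,", st[["both"]],
      "both ) from", nrow(x$calls), "calls\n")
  invisible(x)
}

#' Summarise calls and CNV regions
#'
#' @param calls filtered call table.
#' @param cnvr_set a `cnvr_set` from [merge_to_cnvrs()].
#' @param layout optional [genome_layout()]; enables the genome-fraction
#'   denominator (sum of placed chromosome lengths).
#' @return An object of class `cnv_summary`: per-chromosome call count and
#'   mean length, mean events per sample, CNVR counts by state, total CNVR
#'   length and genome fraction.
#' @export
summarize_cnvs <- function(calls, cnvr_set, layout = NULL) {
  stopifnot(inherits(cnvr_set, "cnvr_set"))
  cnvrs <- cnvr_set$cnvrs
  len <- if (nrow(calls)) interval_length_bp(calls$start_bp, calls$end_bp)
         else numeric(0)
  per_chrom <- if (nrow(calls)) {
    agg <- split(len, calls$chrom)
    data.frame(chrom = names(agg),
               n_calls = vapply(agg, length, integer(1)),
               mean_length_bp = vapply(agg, mean, numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(chrom = character(), n_calls = integer(),
               mean_length_bp = numeric(), stringsAsFactors = FALSE)
  }
  state_counts <- table(factor(cnvrs$state, levels = c("loss", "gain", "both")))
  cnvr_bp <- if (nrow(cnvrs)) {
    sum(interval_length_bp(cnvrs$start_bp, cnvrs$end_bp))
  } else 0
  genome_bp <- if (!is.null(layout)) sum(layout$chromosomes) else NA_real_
  mean_events <- if (nrow(calls)) {
    mean(table(calls$sample_id))
  } else 0
  structure(list(
    n_calls = nrow(calls),
    per_chrom = per_chrom,
    mean_events_per_sample = mean_events,
    n_cnvrs = nrow(cnvrs),
    state_counts = c(loss = unname(state_counts[["loss"]]),
                     gain = unname(state_counts[["gain"]]),
                     both = unname(state_counts[["both"]])),
    total_cnvr_bp = cnvr_bp,
    genome_bp = genome_bp,
    genome_fraction = if (is.na(genome_bp)) NA_real_ else cnvr_bp / genome_bp
  ), class = "cnv_summary")
}

#' @export
print.cnv_summary <- function(x, ...) {
  cat("CNV summary:", x$n_calls, "calls (",
      format(x$mean_events_per_sample, digits = 3), "events/sample ),",
      x$n_cnvrs, "CNVRs\n")
  cat("  states: loss", x$state_counts[["loss"]],
      "| gain", x$state_counts[["gain"]],
      "| both", x$state_counts[["both"]], "\n")
  cat("  CNVR footprint:", format(x$total_cnvr_bp, big.mark = ","), "bp")
  if (!is.na(x$genome_fraction)) {
    cat(" (", format(100 * x$genome_fraction, digits = 3), "% of genome )")
  }
  cat("\n")
  invisible(x)
}
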