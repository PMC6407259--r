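# Canonical chromosome ordering: numeric suffixes in natural order, then X,
# Y, MT, then unplaced ("chrUn"-like) names alphabetically.
chrom_rank <- function(chrom) {
  nm <- unique(as.character(chrom))
  suffix <- sub("^(chr|Chr|CHR)?", "", nm)
  num <- suppressWarnings(as.numeric(suffix))
  special <- match(toupper(suffix), c("X", "Y", "MT", "M"))
  key <- ifelse(!is.na(num), num,
         ifelse(!is.na(special), 1e6 + special, 2e6))
  lev <- nm[order(key, nm)]
  match(as.character(chrom), lev)
}

probe_order <- function(chrom, pos) order(chrom_rank(chrom), pos)

#' Construct a probe-by-sample log2-ratio signal matrix
#'
#' The central container of the package: an ordered probe map (probe id,
#' chromosome, 1-based position) plus a numeric matrix of log2 ratios with
#' one row per probe and one column per sample.  Probes are sorted by
#' (chromosome, position); duplicated (chromosome, position) pairs are
#' rejected.
#'
#' @param probes data.frame with columns `probe_id`, `chrom`, `pos`.
#' @param values numeric matrix, `nrow(probes)` rows; column names are the
#'   sample identifiers.
#' @return An object of class `signal_matrix` with elements `probes`,
#'   `samples` and `values`.
#' @export
signal_matrix <- function(probes, values) {
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "chrom", "pos") %in% names(probes)))
  values <- as.matrix(values)
  if (nrow(values) != nrow(probes)) {
    stop("`values` must have one row per probe")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("`values` must have unique column (sample) names")
  }
  probes$chrom <- as.character(probes$chrom)
  probes$pos <- as.numeric(probes$pos)
  if (anyDuplicated(probes[c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) probe coordinates")
  }
  ord <- probe_order(probes$chrom, probes$pos)
  if (is.unsorted(ord) && any(ord != seq_along(ord))) {
    probes <- probes[ord, , drop = FALSE]
    values <- values[ord, , drop = FALSE]
  }
  rownames(probes) <- NULL
  rownames(values) <- probes$probe_id
  structure(list(probes = probes, samples = colnames(values), values = values),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples on", length(unique(x$probes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$values)

# probe indices falling inside a 1-based inclusive interval
probes_in_span <- function(sm, chrom, start_bp, end_bp) {
  which(sm$probes$chrom == chrom &
          sm$probes$pos >= start_bp & sm$probes$pos <= end_bp)
}
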