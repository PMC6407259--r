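# ---------------------------------------------------------------------------
# Interval annotation of CNVRs: gene content with flanks, QTL coverage with
# a confidence-interval size filter and a 50%-of-CNV coverage rule, and
# generic comparison between two CNVR sets by fractional overlap.
# All coordinates 1-based inclusive; overlap >= 1 bp counts as overlapping.
# ---------------------------------------------------------------------------

#' Annotation configuration
#'
#' @param gene_flank_bp flank added to both gene ends before testing overlap
#'   (3 kb for genome-wide gene content; 5 kb is used when reporting
#'   significant CNVRs).
#' @param qtl_max_ci_bp QTLs with confidence intervals longer than this are
#'   discarded before overlap testing (30 Mb).
#' @param qtl_min_coverage minimum fraction of the CNV length covered by the
#'   union of retained QTLs (0.5).
#' @param set_compare_min_fraction minimum fractional overlap for a region
#'   to count as supported in a set comparison (0.5).
#' @return An object of class `annotation_config`.
#' @export
annotation_config <- function(gene_flank_bp = 3000,
                              qtl_max_ci_bp = 30e6,
                              qtl_min_coverage = 0.5,
                              set_compare_min_fraction = 0.5) {
  if (gene_flank_bp < 0) stop("gene_flank_bp must be >= 0")
  if (qtl_min_coverage <= 0 || qtl_min_coverage > 1 ||
      set_compare_min_fraction <= 0 || set_compare_min_fraction > 1) {
    stop("coverage fractions must be in (0, 1]")
  }
  structure(list(gene_flank_bp = gene_flank_bp,
                 qtl_max_ci_bp = qtl_max_ci_bp,
                 qtl_min_coverage = qtl_min_coverage,
                 set_compare_min_fraction = set_compare_min_fraction),
            class = "annotation_config")
}

#' Overlap in bp between two 1-based inclusive intervals
#'
#' `max(0, min(end_a, end_b) - max(start_a, start_b) + 1)`; intervals on
#' different chromosomes overlap by 0 bp by contract.  Vectorised.
#'
#' @param start_a,end_a,start_b,end_b interval coordinates.
#' @param chrom_a,chrom_b optional chromosome names.
#' @return Non-negative overlap in bp.
#' @examples
#' interval_overlap_bp(100, 200, 200, 300)  # 1
#' interval_overlap_bp(100, 200, 201, 300)  # 0
#' @export
interval_overlap_bp <- function(start_a, end_a, start_b, end_b,
                                chrom_a = NULL, chrom_b = NULL) {
  ov <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b) + 1)
  if (!is.null(chrom_a) && !is.null(chrom_b)) {
    ov[chrom_a != chrom_b] <- 0
  }
  ov
}

as_region_df <- function(x) {
  if (inherits(x, "cnvr_set")) x <- x$cnvrs
  stopifnot(is.data.frame(x),
            all(c("chrom", "start_bp", "end_bp") %in% names(x)))
  if (!"name" %in% names(x)) {
    x$name <- if ("cnvr_id" %in% names(x)) x$cnvr_id
              else paste0("region_", seq_len(nrow(x)))
  }
  x
}

#' Annotate CNVRs with overlapping and nearest genes
#'
#' Genes are expanded by `flank_bp` on both sides; a record is emitted for
#' every (CNVR, gene) pair sharing >= 1 bp after expansion.  A CNVR with no
#' overlapping gene gets a single `relation = "nearest"` record pointing at
#' the closest gene on its chromosome (distance in bp between closest
#' unexpanded edges; ties broken toward the lexicographically smaller
#' symbol), or no record if its chromosome has no genes.
#'
#' @param cnvrs `cnvr_set` or data.frame (`chrom`, `start_bp`, `end_bp`,
#'   `cnvr_id`/`name`).
#' @param genes data.frame from [read_intervals()] (`name`, `chrom`,
#'   `start_bp`, `end_bp`).
#' @param flank_bp flank in bp (default from [annotation_config()]).
#' @return data.frame of overlap records: `cnvr_id`, `feature`,
#'   `overlap_bp`, `fraction_of_cnvr`, `relation`, `distance_bp`.
#' @export
overlap_genes <- function(cnvrs, genes,
                          flank_bp = annotation_config()$gene_flank_bp) {
  cnvrs <- as_region_df(cnvrs)
  genes <- as_region_df(genes)
  out <- list()
  for (i in seq_len(nrow(cnvrs))) {
    cv <- cnvrs[i, ]
    len <- interval_length_bp(cv$start_bp, cv$end_bp)
    g <- genes[genes$chrom == cv$chrom, , drop = FALSE]
    if (nrow(g) == 0L) next
    ov <- interval_overlap_bp(cv$start_bp, cv$end_bp,
                              pmax(1, g$start_bp - flank_bp),
                              g$end_bp + flank_bp)
    hit <- which(ov >= 1)
    if (length(hit)) {
      raw <- interval_overlap_bp(cv$start_bp, cv$end_bp,
                                 g$start_bp[hit], g$end_bp[hit])
      out[[length(out) + 1L]] <- data.frame(
        cnvr_id = cv$name, feature = g$name[hit],
        overlap_bp = ov[hit], fraction_of_cnvr = pmin(1, ov[hit] / len),
        relation = "overlapping", distance_bp = 0,
        overlap_bp_unflanked = raw,
        stringsAsFactors = FALSE
      )
    } else {
      gap <- pmax(g$start_bp - cv$end_bp, cv$start_bp - g$end_bp)
      best <- which(gap == min(gap))
      best <- best[order(g$name[best])][1L]
      out[[length(out) + 1L]] <- data.frame(
        cnvr_id = cv$name, feature = g$name[best], overlap_bp = 0,
        fraction_of_cnvr = 0, relation = "nearest",
        distance_bp = gap[best], overlap_bp_unflanked = 0,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cnvr_id = character(), feature = character(),
               overlap_bp = numeric(), fraction_of_cnvr = numeric(),
               relation = character(), distance_bp = numeric(),
               overlap_bp_unflanked = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Annotate CNVs/CNVRs with QTL coverage
#'
#' QTLs longer than `config$qtl_max_ci_bp` (overly wide confidence
#' intervals) are discarded first.  For each CNV region, the union of the
#' retained QTL intervals on its chromosome is intersected with its span; a
#' record per contributing QTL is emitted only when that union covers at
#' least `config$qtl_min_coverage` of the region's length.
#'
#' @param cnvrs `cnvr_set` or data.frame of regions (CNVs or CNVRs).
#' @param qtls data.frame from [read_intervals()] (`name` = trait label,
#'   `chrom`, `start_bp`, `end_bp`).
#' @param config an [annotation_config()].
#' @return data.frame: `cnvr_id`, `feature` (QTL trait), `overlap_bp`,
#'   `fraction_of_cnvr` (per-QTL), `union_coverage` (fraction covered by the
#'   QTL union), `relation`, `distance_bp`.
#' @export
overlap_qtls <- function(cnvrs, qtls, config = annotation_config()) {
  cnvrs <- as_region_df(cnvrs)
  qtls <- as_region_df(qtls)
  qlen <- interval_length_bp(qtls$start_bp, qtls$end_bp)
  qtls <- qtls[qlen <= config$qtl_max_ci_bp, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(cnvrs))) {
    cv <- cnvrs[i, ]
    len <- interval_length_bp(cv$start_bp, cv$end_bp)
    q <- qtls[qtls$chrom == cv$chrom, , drop = FALSE]
    if (nrow(q) == 0L) next
    ov <- interval_overlap_bp(cv$start_bp, cv$end_bp, q$start_bp, q$end_bp)
    hit <- which(ov >= 1)
    if (length(hit) == 0L) next
    clipped <- IRanges::IRanges(
      start = pmax(q$start_bp[hit], cv$start_bp),
      end = pmin(q$end_bp[hit], cv$end_bp)
    )
    covered <- sum(IRanges::width(IRanges::reduce(clipped)))
    if (covered / len < config$qtl_min_coverage) next
    out[[length(out) + 1L]] <- data.frame(
      cnvr_id = cv$name, feature = q$name[hit], overlap_bp = ov[hit],
      fraction_of_cnvr = pmin(1, ov[hit] / len),
      union_coverage = covered / len,
      relation = "overlapping", distance_bp = 0,
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cnvr_id = character(), feature = character(),
               overlap_bp = numeric(), fraction_of_cnvr = numeric(),
               union_coverage = numeric(), relation = character(),
               distance_bp = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Compare two CNVR sets by fractional overlap
#'
#' A region in `set_a` counts as supported when its overlap with the union
#' of `set_b` covers at least `min_fraction` of its own length (the usual
#' 50%-of-length support rule for cross-study CNV comparison).
#'
#' @param set_a,set_b data.frames of regions (internal coordinates).
#' @param min_fraction support threshold in (0, 1].
#' @return list with `per_region` (data.frame: `name`, `chrom`, `start_bp`,
#'   `end_bp`, `length_bp`, `overlap_bp`, `fraction`, `supported`) and
#'   `summary` (n, n_supported, count_fraction, total_bp, supported_bp,
#'   overlap_bp, bp_fraction).
#' @export
compare_cnvr_sets <- function(set_a, set_b,
                              min_fraction =
                                annotation_config()$set_compare_min_fraction) {
  set_a <- as_region_df(set_a)
  set_b <- as_region_df(set_b)
  n <- nrow(set_a)
  overlap_bp <- numeric(n)
  for (i in seq_len(n)) {
    a <- set_a[i, ]
    b <- set_b[set_b$chrom == a$chrom, , drop = FALSE]
    if (nrow(b) == 0L) next
    clipped_start <- pmax(b$start_bp, a$start_bp)
    clipped_end <- pmin(b$end_bp, a$end_bp)
    keep <- clipped_start <= clipped_end
    if (!any(keep)) next
    ir <- IRanges::IRanges(start = clipped_start[keep],
                           end = clipped_end[keep])
    overlap_bp[i] <- sum(IRanges::width(IRanges::reduce(ir)))
  }
  len <- interval_length_bp(set_a$start_bp, set_a$end_bp)
  frac <- if (n) overlap_bp / len else numeric(0)
  per_region <- data.frame(
    name = set_a$name, chrom = set_a$chrom, start_bp = set_a$start_bp,
    end_bp = set_a$end_bp, length_bp = len, overlap_bp = overlap_bp,
    fraction = frac, supported = frac >= min_fraction,
    stringsAsFactors = FALSE
  )
  rownames(per_region) <- NULL
  list(
    per_region = per_region,
    summary = list(
      n = n,
      n_supported = sum(per_region$supported),
      count_fraction = if (n) mean(per_region$supported) else NA_real_,
      total_bp = sum(len),
      supported_bp = sum(len[per_region$supported]),
      overlap_bp = sum(overlap_bp),
      bp_fraction = if (n) sum(len[per_region$supported]) / sum(len)
                    else NA_real_
    )
  )
}
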