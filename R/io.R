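# ---------------------------------------------------------------------------
# Readers/writers.  Internal coordinates are ALWAYS 1-based inclusive;
# BED files alone are 0-based half-open, converted at the boundary:
#   internal (start, end)  ->  BED (start - 1, end)
# Interval length = end - start + 1.
# Missing signal values are written as "NA".
# ---------------------------------------------------------------------------

#' Read a probe-by-sample signal matrix from TSV
#'
#' Expects a header row; the first three columns must be `probe_id`,
#' `chrom`, `pos`, followed by one numeric column per sample.  Probes are
#' validated and sorted; duplicated (chrom, pos) pairs are an error, and an
#' unsorted file is sorted with a warning.
#'
#' @param path file path.
#' @return A [signal_matrix()].
#' @export
read_signal_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 4L ||
      !identical(names(df)[1:3], c("probe_id", "chrom", "pos"))) {
    stop("signal matrix must start with columns probe_id, chrom, pos")
  }
  pos <- suppressWarnings(as.numeric(df$pos))
  if (anyNA(pos)) {
    stop("malformed position at line ", which(is.na(pos))[1L] + 1L)
  }
  vals <- as.matrix(df[, -(1:3), drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-(1:3)], is.numeric, logical(1)))[1L]
    suppressWarnings(num <- as.numeric(df[[bad + 3L]]))
    badline <- which(is.na(num) & !df[[bad + 3L]] %in% c("NA", ""))[1L]
    stop("malformed value at line ", badline + 1L, " in column ",
         names(df)[bad + 3L])
  }
  probes <- data.frame(probe_id = as.character(df$probe_id),
                       chrom = as.character(df$chrom), pos = pos,
                       stringsAsFactors = FALSE)
  if (anyDuplicated(probes[c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) probe coordinates in ", path)
  }
  ord <- probe_order(probes$chrom, probes$pos)
  if (any(ord != seq_along(ord))) {
    warning("probes not sorted by (chrom, pos); sorting")
  }
  signal_matrix(probes, vals)
}

#' Write a signal matrix to TSV
#'
#' @param sm a [signal_matrix()].
#' @param path output path.
#' @param header_lines optional `#`-prefixed provenance lines written above
#'   the column header.
#' @return Invisibly, `path`.
#' @export
write_signal_matrix <- function(sm, path, header_lines = NULL) {
  stopifnot(inherits(sm, "signal_matrix"))
  # full double precision so a write -> read round trip is bit-exact
  vals <- apply(sm$values, 2, function(v) {
    ifelse(is.finite(v), sprintf("%.17g", v), "NA")
  })
  out <- data.frame(sm$probes, vals, check.names = FALSE,
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read interval files into internal 1-based inclusive coordinates
#'
#' Three dialects:
#' \describe{
#'   \item{`bed`}{0-based half-open; columns chrom, start, end, \[name\],
#'     \[score\], \[strand\]. Start is shifted by +1 on read.}
#'   \item{`gff3`}{1-based inclusive (via \pkg{rtracklayer}); the feature
#'     name is taken from the `Name`, `gene_name`, `gene_id` or `ID`
#'     attribute, in that order.}
#'   \item{`tsv1`}{1-based inclusive TSV with header; requires columns
#'     `chrom`, `start_bp`, `end_bp` and takes the first remaining column
#'     (e.g. `symbol` or `trait`) as the feature name.}
#' }
#'
#' @param path file path.
#' @param dialect `"bed"`, `"gff3"` or `"tsv1"`.
#' @return data.frame with columns `name`, `chrom`, `start_bp`, `end_bp`,
#'   `strand` (`"+"`, `"-"` or `"*"`).
#' @export
read_intervals <- function(path, dialect = c("bed", "gff3", "tsv1")) {
  dialect <- match.arg(dialect)
  out <- switch(dialect,
    bed = {
      df <- read.delim(path, header = FALSE, sep = "\t",
                       stringsAsFactors = FALSE, comment.char = "#")
      if (ncol(df) < 3L) stop("BED needs >= 3 columns")
      data.frame(
        name = if (ncol(df) >= 4L) as.character(df[[4L]])
               else paste0("region_", seq_len(nrow(df))),
        chrom = as.character(df[[1L]]),
        start_bp = as.numeric(df[[2L]]) + 1,
        end_bp = as.numeric(df[[3L]]),
        strand = if (ncol(df) >= 6L) as.character(df[[6L]]) else "*",
        stringsAsFactors = FALSE
      )
    },
    gff3 = {
      gr <- rtracklayer::import(path, format = "gff3")
      md <- S4Vectors::mcols(gr)
      nm <- rep(NA_character_, length(gr))
      for (field in c("Name", "gene_name", "gene_id", "ID")) {
        if (field %in% names(md)) {
          v <- as.character(md[[field]])
          nm[is.na(nm) & !is.na(v)] <- v[is.na(nm) & !is.na(v)]
        }
      }
      nm[is.na(nm)] <- paste0("feature_", which(is.na(nm)))
      data.frame(
        name = nm,
        chrom = as.character(GenomeInfoDb::seqnames(gr)),
        start_bp = as.numeric(BiocGenerics::start(gr)),
        end_bp = as.numeric(BiocGenerics::end(gr)),
        strand = as.character(BiocGenerics::strand(gr)),
        stringsAsFactors = FALSE
      )
    },
    tsv1 = {
      df <- read.delim(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
      need <- c("chrom", "start_bp", "end_bp")
      if (!all(need %in% names(df))) {
        stop("tsv1 requires columns chrom, start_bp, end_bp")
      }
      namecol <- setdiff(names(df), need)[1L]
      data.frame(
        name = if (!is.na(namecol)) as.character(df[[namecol]])
               else paste0("region_", seq_len(nrow(df))),
        chrom = as.character(df$chrom),
        start_bp = as.numeric(df$start_bp),
        end_bp = as.numeric(df$end_bp),
        strand = if ("strand" %in% names(df)) as.character(df$strand)
                 else "*",
        stringsAsFactors = FALSE
      )
    }
  )
  if (any(!out$strand %in% c("+", "-", "*"))) {
    out$strand[!out$strand %in% c("+", "-")] <- "*"
  }
  if (anyNA(out$start_bp) || anyNA(out$end_bp)) {
    stop("non-numeric coordinates in ", path)
  }
  if (any(out$start_bp < 1) || any(out$end_bp < out$start_bp)) {
    stop("invalid interval coordinates (start < 1 or end < start) in ", path)
  }
  rownames(out) <- NULL
  out
}

#' Write intervals as BED (0-based half-open)
#'
#' Internal 1-based inclusive `(start_bp, end_bp)` becomes BED
#' `(start_bp - 1, end_bp)`.
#'
#' @param records data.frame with `chrom`, `start_bp`, `end_bp` and
#'   optionally `name`, `score`, `strand`.
#' @param path output path. A header-only (empty) file is written for an
#'   empty record list.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(records, path) {
  stopifnot(is.data.frame(records))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(records) == 0L) return(invisible(path))
  bed <- data.frame(
    chrom = records$chrom,
    start = format(records$start_bp - 1, scientific = FALSE, trim = TRUE),
    end = format(records$end_bp, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(records)) records$name
           else paste0("region_", seq_len(nrow(records))),
    stringsAsFactors = FALSE
  )
  if ("score" %in% names(records)) bed$score <- records$score
  if ("strand" %in% names(records)) {
    if (!"score" %in% names(records)) bed$score <- 0
    bed$strand <- records$strand
  }
  write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write the ground-truth CNVs of a simulation as BED
#'
#' BED name field is `sample_id:copy_number`.
#'
#' @param truth a `truth_set`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_truth_bed <- function(truth, path) {
  stopifnot(inherits(truth, "truth_set"))
  rec <- truth$true_cnvs
  rec$name <- paste0(rec$sample_id, ":", rec$copy_number)
  write_bed(rec, path)
}

#' Write / read a generic results table as TSV
#'
#' Column order is preserved; missing values are written as `NA`; the file
#' re-reads into the same data.frame (round trip covered by tests).
#'
#' @param results data.frame.
#' @param path file path.
#' @return `write_results_tsv`: invisibly, `path`;
#'   `read_results_tsv`: the data.frame.
#' @export
write_results_tsv <- function(results, path) {
  stopifnot(is.data.frame(results))
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_tsv
#' @export
read_results_tsv <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "#")
}

#' Read / write a long-format trait (PTA) table
#'
#' TSV with header `sample_id`, `trait`, `pta_value` and optional
#' `reliability` in `[0, 1]`.  (sample, trait) pairs must be unique.
#' `read_trait_table` returns the long table; [traits_wide()] pivots it to
#' the wide sample-by-trait layout the association functions use.
#'
#' @param path file path.
#' @return data.frame (long format).
#' @export
read_trait_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  need <- c("sample_id", "trait", "pta_value")
  if (!all(need %in% names(df))) {
    stop("trait table requires columns sample_id, trait, pta_value")
  }
  if (anyDuplicated(df[c("sample_id", "trait")])) {
    stop("duplicate (sample, trait) pairs")
  }
  if ("reliability" %in% names(df)) {
    r <- df$reliability
    if (any(is.finite(r) & (r < 0 | r > 1))) {
      stop("reliability must be in [0, 1]")
    }
  }
  df
}

#' @rdname read_trait_table
#' @param phenotypes wide data.frame (`sample_id` + one column per trait).
#' @param reliability optional wide data.frame of reliabilities.
#' @param header_lines optional `#`-prefixed provenance lines.
#' @export
write_trait_table <- function(phenotypes, path, reliability = NULL,
                              header_lines = NULL) {
  stopifnot("sample_id" %in% names(phenotypes))
  traits <- setdiff(names(phenotypes), "sample_id")
  long <- do.call(rbind, lapply(traits, function(tr) {
    data.frame(sample_id = phenotypes$sample_id, trait = tr,
               pta_value = phenotypes[[tr]], stringsAsFactors = FALSE)
  }))
  if (!is.null(reliability)) {
    rl <- do.call(rbind, lapply(traits, function(tr) reliability[[tr]]))
    long$reliability <- as.numeric(rl)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_trait_table
#' @param long long-format trait table.
#' @export
traits_wide <- function(long) {
  traits <- unique(long$trait)
  samples <- unique(long$sample_id)
  wide <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (tr in traits) {
    d <- long[long$trait == tr, ]
    wide[[tr]] <- d$pta_value[match(samples, d$sample_id)]
  }
  wide
}
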