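# ---------------------------------------------------------------------------
# Stage orchestration: simulate -> segment -> call/merge -> associate ->
# annotate, driven by one configuration (YAML-able), a single seed, with
# provenance headers on every stage output and a run report whose counts
# are internally consistent by construction.
# ---------------------------------------------------------------------------

config_hash <- function(config) {
  # hash the analysis parameters, not the output location
  h <- unclass(config)
  h$output_dir <- NULL
  s <- paste(deparse(h), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

provenance_header <- function(config) {
  c(paste0("# cghcnv ", as.character(utils::packageVersion("cghcnv"))),
    paste0("# seed=", config$seed, " config_hash=", config_hash(config)))
}

write_stage_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  )
  invisible(path)
}

read_stage_tsv <- function(path, stage, upstream) {
  if (!file.exists(path)) {
    stop(stage, ": missing input file '", path, "'; run ", upstream,
         " first", call. = FALSE)
  }
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             comment.char = "#", check.names = FALSE)
}

#' Pipeline configuration
#'
#' One object drives every stage.  The defaults describe the packaged demo
#' cohort: a 24 Mb four-chromosome genome (including chrX) at 1.2 kb probe
#' spacing (20,000 probes), 47 male samples, 30 planted CNV loci, 8 traits,
#' and one planted dosage effect on Dtr_Preg_Rate.
#'
#' @param output_dir directory for stage outputs.
#' @param seed integer seed driving every stochastic stage.
#' @param chromosomes named numeric vector of chromosome lengths.
#' @param probe_spacing_bp mean probe spacing (bp).
#' @param sex_chromosome sex chromosome name or `NA`.
#' @param n_samples,n_loci cohort size and planted locus count.
#' @param probe_sd,sample_shift_sd noise model parameters.
#' @param traits data.frame (`trait`, `block`); default: two traits from
#'   each block of the 41-trait catalogue.
#' @param effect_trait,effect_variance_explained planted dosage effect: the
#'   trait and the fraction of its variance the planted locus explains
#'   (`NA` disables the effect).
#' @param segmentation a [segmentation_config()].
#' @param calling a [calling_config()].
#' @param annotation an [annotation_config()].
#' @param genes_path,qtls_path optional interval files for [run_annotate()]
#'   (`NA` skips annotation).
#' @param genes_dialect,qtls_dialect dialects for [read_intervals()].
#' @param assoc_family Bonferroni family (`"per_trait"` or `"global"`).
#' @param assoc_use regression covariate (`"dosage"` or `"class"`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = tempfile("cghcnv_run_"),
                            seed = 1,
                            chromosomes = c(chr1 = 8e6, chr2 = 6.4e6,
                                            chr3 = 4.8e6, chrX = 4.8e6),
                            probe_spacing_bp = 1200,
                            sex_chromosome = "chrX",
                            n_samples = 47, n_loci = 30,
                            probe_sd = 0.15, sample_shift_sd = 0.05,
                            traits = NULL,
                            effect_trait = "Dtr_Preg_Rate",
                            effect_variance_explained = 0.25,
                            segmentation = segmentation_config(band = 500L),
                            calling = calling_config(),
                            annotation = annotation_config(),
                            genes_path = NA_character_,
                            qtls_path = NA_character_,
                            genes_dialect = "bed", qtls_dialect = "tsv1",
                            assoc_family = "per_trait",
                            assoc_use = "dosage") {
  if (is.null(traits)) {
    cat41 <- trait_catalogue()
    demo8 <- c("Milk", "Net_Merit",                    # production
               "Dtr_Preg_Rate", "Prod_Life",           # reproduction
               "SCS", "livability",                    # health
               "Stature", "Rump_Width")                # type
    traits <- cat41[match(demo8, cat41$trait), ]
  }
  rownames(traits) <- NULL
  structure(list(
    output_dir = output_dir, seed = seed,
    chromosomes = chromosomes, probe_spacing_bp = probe_spacing_bp,
    sex_chromosome = sex_chromosome,
    n_samples = n_samples, n_loci = n_loci,
    probe_sd = probe_sd, sample_shift_sd = sample_shift_sd,
    traits = traits,
    effect_trait = effect_trait,
    effect_variance_explained = effect_variance_explained,
    segmentation = segmentation, calling = calling, annotation = annotation,
    genes_path = genes_path, qtls_path = qtls_path,
    genes_dialect = genes_dialect, qtls_dialect = qtls_dialect,
    assoc_family = assoc_family, assoc_use = assoc_use
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config`: a `pipeline_config`;
#'   `write_pipeline_config`: invisibly, `path`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(
    output_dir = y$output_dir, seed = y$seed,
    chromosomes = unlist(y$chromosomes),
    probe_spacing_bp = y$probe_spacing_bp,
    sex_chromosome = if (is.null(y$sex_chromosome)) NA_character_
                     else y$sex_chromosome,
    n_samples = y$n_samples, n_loci = y$n_loci,
    probe_sd = y$probe_sd, sample_shift_sd = y$sample_shift_sd,
    segmentation = do.call(segmentation_config, y$segmentation %||% list()),
    calling = do.call(calling_config, y$calling %||% list()),
    annotation = do.call(annotation_config, y$annotation %||% list())
  )
  if (!is.null(y$traits)) {
    args$traits <- data.frame(trait = vapply(y$traits, `[[`, "", "trait"),
                              block = vapply(y$traits, `[[`, "", "block"),
                              stringsAsFactors = FALSE)
  }
  for (f in c("effect_trait", "effect_variance_explained", "genes_path",
              "qtls_path", "genes_dialect", "qtls_dialect", "assoc_family",
              "assoc_use")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$chromosomes <- as.list(config$chromosomes)
  y$traits <- lapply(seq_len(nrow(config$traits)), function(i) {
    list(trait = config$traits$trait[i], block = config$traits$block[i])
  })
  y$segmentation <- unclass(config$segmentation)
  y$calling <- unclass(config$calling)
  y$annotation <- unclass(config$annotation)
  yaml::write_yaml(y, path)
  invisible(path)
}

stage_paths <- function(config) {
  d <- config$output_dir
  list(probes = file.path(d, "probes.tsv"),
       signal = file.path(d, "signal.tsv"),
       truth = file.path(d, "truth.bed"),
       traits = file.path(d, "traits.tsv"),
       segments = file.path(d, "segments.tsv"),
       calls = file.path(d, "calls.tsv"),
       calls_bed = file.path(d, "calls.bed"),
       cnvrs = file.path(d, "cnvrs.tsv"),
       cnvrs_bed = file.path(d, "cnvrs.bed"),
       assoc = file.path(d, "association.tsv"),
       genes_overlap = file.path(d, "gene_overlaps.tsv"),
       qtl_overlap = file.path(d, "qtl_overlaps.tsv"))
}

config_layout <- function(config) {
  genome_layout(config$chromosomes, config$probe_spacing_bp,
                config$sex_chromosome)
}

# deterministic choice of the planted effect locus: among well-probed loci
# whose cohort shows at most 3 distinct copy states (so the 3-class mixture
# genotype can represent them), take the one with the largest dosage
# variance; fall back to the most variable well-probed locus
pick_effect_locus <- function(truth, probes, min_probes = 5L) {
  cand <- truth$loci
  np <- vapply(seq_len(nrow(cand)), function(i) {
    sum(probes$chrom == cand$chrom[i] & probes$pos >= cand$start_bp[i] &
          probes$pos <= cand$end_bp[i])
  }, integer(1))
  dv <- vapply(cand$locus_id, function(id) {
    cn <- locus_copy_numbers(truth, id)
    mean((cn - 2)^2) - mean(cn - 2)^2
  }, numeric(1))
  nstates <- vapply(cand$locus_id, function(id) {
    length(unique(locus_copy_numbers(truth, id)))
  }, integer(1))
  ok <- np >= min_probes
  if (!any(ok)) stop("no planted locus spans enough probes")
  good <- ok & nstates <= 3L
  if (any(good)) cand$locus_id[good][which.max(dv[good])]
  else cand$locus_id[ok][which.max(dv[ok])]
}

#' Run the simulation stage
#'
#' Generates the cohort (probe map, truth set, signal matrix, phenotypes)
#' and writes `probes.tsv`, `signal.tsv`, `truth.bed` and `traits.tsv` to
#' the output directory.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a stage report fragment (record counts, file paths,
#'   elapsed seconds).
#' @export
run_simulate <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- stage_paths(config)
  layout <- config_layout(config)
  model <- phenotype_model(traits = config$traits)
  effects <- NULL
  cohort <- simulate_cohort(
    layout, n_samples = config$n_samples, n_loci = config$n_loci,
    noise = noise_model(config$probe_sd, config$sample_shift_sd),
    model = model, seed = config$seed
  )
  if (!is.na(config$effect_trait) &&
      !is.na(config$effect_variance_explained)) {
    locus <- pick_effect_locus(cohort$truth, cohort$probes,
                               config$calling$min_probes)
    cohort$truth <- add_dosage_effect(
      cohort$truth, locus, config$effect_trait,
      variance_explained = config$effect_variance_explained
    )
    cohort$phenotypes <- simulate_phenotypes(
      cohort$truth$samples, cohort$truth, model, seed = config$seed
    )
  }
  write_stage_tsv(cohort$probes, p$probes, config)
  write_signal_matrix(cohort$signal, p$signal,
                      header_lines = provenance_header(config))
  write_truth_bed(cohort$truth, p$truth)
  write_trait_table(cohort$phenotypes, p$traits,
                    header_lines = provenance_header(config))
  invisible(list(stage = "simulate",
                 n_probes = nrow(cohort$probes),
                 n_samples = config$n_samples,
                 n_true_loci = nrow(cohort$truth$loci),
                 n_true_events = nrow(cohort$truth$true_cnvs),
                 effect_locus = if (nrow(cohort$truth$true_effects))
                   cohort$truth$true_effects$locus_id[1] else NA_character_,
                 files = p[c("probes", "signal", "truth", "traits")],
                 elapsed_s = proc.time()[["elapsed"]] - t0))
}

#' Run the segmentation stage
#'
#' Reads `signal.tsv`, normalises and segments every sample profile, and
#' writes `segments.tsv`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a stage report fragment.
#' @export
run_segment <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  p <- stage_paths(config)
  if (!file.exists(p$signal)) {
    stop("run_segment: missing input file '", p$signal,
         "'; run run_simulate first", call. = FALSE)
  }
  sm <- read_signal_matrix(p$signal)
  seg <- segment_signal(sm, config$segmentation,
                        sex_chromosome = config$sex_chromosome)
  write_stage_tsv(seg, p$segments, config)
  invisible(list(stage = "segment", n_segments = nrow(seg),
                 files = p["segments"],
                 elapsed_s = proc.time()[["elapsed"]] - t0))
}

#' Run the CNV calling and CNVR merging stage
#'
#' Reads `segments.tsv`, applies the 0.5_5 calling rule and the strict
#' length filters, aggregates calls into CNVRs, and writes `calls.tsv`,
#' `calls.bed`, `cnvrs.tsv` and `cnvrs.bed`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a stage report fragment (incl. CNVR state counts).
#' @export
run_call <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  p <- stage_paths(config)
  seg <- read_stage_tsv(p$segments, "run_call", "run_segment")
  calls <- filter_cnvs(call_cnvs(seg, config$calling), config$calling)
  cs <- merge_to_cnvrs(calls)
  write_stage_tsv(cs$calls, p$calls, config)
  write_stage_tsv(cs$cnvrs, p$cnvrs, config)
  bed_calls <- cs$calls
  if (nrow(bed_calls)) {
    bed_calls$name <- paste0(bed_calls$sample_id, ":", bed_calls$state)
  }
  write_bed(bed_calls, p$calls_bed)
  bed_cnvrs <- cs$cnvrs
  if (nrow(bed_cnvrs)) bed_cnvrs$name <- bed_cnvrs$cnvr_id
  write_bed(bed_cnvrs, p$cnvrs_bed)
  st <- table(factor(cs$cnvrs$state, levels = c("loss", "gain", "both")))
  invisible(list(stage = "call", n_calls = nrow(calls),
                 n_cnvrs = nrow(cs$cnvrs),
                 state_counts = c(loss = unname(st[["loss"]]),
                                  gain = unname(st[["gain"]]),
                                  both = unname(st[["both"]])),
                 files = p[c("calls", "calls_bed", "cnvrs", "cnvrs_bed")],
                 elapsed_s = proc.time()[["elapsed"]] - t0))
}

#' Run the association stage
#'
#' Reads the signal matrix, CNVR tables and trait table, runs the
#' PCA/mixture/regression association for every (CNVR, trait) pair, and
#' writes `association.tsv`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a stage report fragment (converged and significant
#'   counts).
#' @export
run_associate <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  p <- stage_paths(config)
  if (!file.exists(p$signal)) {
    stop("run_associate: missing input file '", p$signal,
         "'; run run_simulate first", call. = FALSE)
  }
  sm <- read_signal_matrix(p$signal)
  cnvrs <- read_stage_tsv(p$cnvrs, "run_associate", "run_call")
  calls <- read_stage_tsv(p$calls, "run_associate", "run_call")
  traits <- read_trait_table(p$traits)
  cs <- structure(list(cnvrs = cnvrs, calls = calls), class = "cnvr_set")
  assoc <- associate_cnvrs(sm, cs, traits_wide(traits), seed = config$seed,
                           use = config$assoc_use,
                           family = config$assoc_family)
  write_stage_tsv(as.data.frame(assoc), p$assoc, config)
  invisible(list(stage = "associate",
                 n_tested = sum(assoc$converged),
                 n_converged_cnvrs =
                   length(unique(assoc$cnvr_id[assoc$converged])),
                 n_significant_pairs = sum(assoc$significant %in% TRUE),
                 n_significant_cnvrs =
                   length(unique(assoc$cnvr_id[assoc$significant %in% TRUE])),
                 m = attr(assoc, "m"),
                 files = p["assoc"],
                 elapsed_s = proc.time()[["elapsed"]] - t0))
}

#' Run the annotation stage
#'
#' Reads `cnvrs.tsv` plus the configured gene/QTL interval files and writes
#' the overlap tables.  Skipped (with a note in the report) when no
#' annotation inputs are configured.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a stage report fragment.
#' @export
run_annotate <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  p <- stage_paths(config)
  cnvrs <- read_stage_tsv(p$cnvrs, "run_annotate", "run_call")
  out <- list(stage = "annotate", n_gene_overlaps = NA_integer_,
              n_qtl_overlaps = NA_integer_, skipped = FALSE)
  if (is.na(config$genes_path) && is.na(config$qtls_path)) {
    out$skipped <- TRUE
    out$elapsed_s <- proc.time()[["elapsed"]] - t0
    return(invisible(out))
  }
  if (!is.na(config$genes_path)) {
    genes <- read_intervals(config$genes_path, config$genes_dialect)
    go <- overlap_genes(cnvrs, genes, config$annotation$gene_flank_bp)
    write_stage_tsv(go, p$genes_overlap, config)
    out$n_gene_overlaps <- sum(go$relation == "overlapping")
  }
  if (!is.na(config$qtls_path)) {
    qtls <- read_intervals(config$qtls_path, config$qtls_dialect)
    qo <- overlap_qtls(cnvrs, qtls, config$annotation)
    write_stage_tsv(qo, p$qtl_overlap, config)
    out$n_qtl_overlaps <- nrow(qo)
  }
  out$elapsed_s <- proc.time()[["elapsed"]] - t0
  invisible(out)
}

#' Run the full pipeline
#'
#' simulate -> segment -> call/merge -> associate -> annotate, returning a
#' run report whose counts are recomputed from the stage outputs (so the
#' report's arithmetic identities hold on every run).
#'
#' @param config a [pipeline_config()].
#' @return An object of class `cghcnv_report`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list(
    simulate = run_simulate(config),
    segment = run_segment(config),
    call = run_call(config),
    associate = run_associate(config),
    annotate = run_annotate(config)
  )
  structure(list(stages = stages, seed = config$seed,
                 config_hash = config_hash(config),
                 output_dir = config$output_dir),
            class = "cghcnv_report")
}

#' @export
print.cghcnv_report <- function(x, ...) {
  s <- x$stages
  cat("cghcnv run (seed", x$seed, ", config", x$config_hash, ")\n")
  cat("  simulate:", s$simulate$n_probes, "probes x",
      s$simulate$n_samples, "samples;", s$simulate$n_true_loci,
      "planted loci (", s$simulate$n_true_events, "events )\n")
  cat("  segment: ", s$segment$n_segments, "segments\n")
  st <- s$call$state_counts
  cat("  call:    ", s$call$n_calls, "calls ->", s$call$n_cnvrs,
      "CNVRs ( loss", st[["loss"]], "+ gain", st[["gain"]], "+ both",
      st[["both"]], "=", sum(st), ")\n")
  cat("  assoc:   ", s$associate$n_converged_cnvrs, "converged CNVRs, m =",
      s$associate$m, ";", s$associate$n_significant_pairs,
      "significant pair(s),", s$associate$n_significant_cnvrs,
      "significant CNVR(s)\n")
  if (isTRUE(s$annotate$skipped)) {
    cat("  annotate: skipped (no gene/QTL inputs configured)\n")
  } else {
    cat("  annotate:", s$annotate$n_gene_overlaps, "gene overlap(s),",
        s$annotate$n_qtl_overlaps, "QTL overlap record(s)\n")
  }
  tot <- sum(vapply(s, function(z) z$elapsed_s %||% 0, numeric(1)))
  cat("  wall time:", format(tot, digits = 3), "s\n")
  invisible(x)
}

#' One replicate of the scaled-down end-to-end power study
#'
#' Simulates a 47-sample cohort on a single 3 Mb chromosome (1.2 kb probe
#' spacing), plants a handful of CNV loci of which one carries a dosage
#' effect on the first trait (default: sized to explain 25% of that trait's
#' variance), runs segmentation, calling, CNVR merging and association in
#' memory, and reports whether the effect CNVR is Bonferroni-significant
#' for the effect trait.
#'
#' @param seed integer seed for the replicate.
#' @param n_samples cohort size.
#' @param ve planted fraction of trait variance explained.
#' @param probe_sd per-probe noise SD.
#' @param n_traits number of traits simulated (first n of the catalogue).
#' @return list: `detected` (logical), `p_value`, `p_bonferroni`, `m`,
#'   `n_cnvrs`, `effect_locus` coordinates.
#' @export
power_replicate <- function(seed, n_samples = 47, ve = 0.25,
                            probe_sd = 0.15, n_traits = 8) {
  layout <- genome_layout(c(chr1 = 3e6), probe_spacing_bp = 1200)
  traits <- trait_catalogue()[seq_len(n_traits), ]
  model <- phenotype_model(traits = traits)
  samples <- sprintf("bull_%02d", seq_len(n_samples))
  probes <- simulate_probes(layout, seed = seed)
  truth <- simulate_true_cnvs(layout, samples, n_loci = 4, seed = seed,
                              size_range = c(20000, 80000),
                              carrier_rate = 0.5,
                              copy_numbers = c(1, 3),
                              copy_weights = c(0.6, 0.4),
                              state_mix = c(loss = 0, gain = 0, both = 1))
  locus <- pick_effect_locus(truth, probes)
  trait1 <- traits$trait[1]
  truth <- add_dosage_effect(truth, locus, trait1, variance_explained = ve)
  sig <- simulate_signal(probes, truth, noise_model(probe_sd), seed = seed,
                         samples = samples)
  phen <- simulate_phenotypes(samples, truth, model, seed = seed)
  seg <- segment_signal(sig, segmentation_config(band = 300L))
  calls <- filter_cnvs(call_cnvs(seg))
  cs <- merge_to_cnvrs(calls)
  assoc <- associate_cnvrs(sig, cs, phen, seed = seed)
  loc <- truth$loci[truth$loci$locus_id == locus, ]
  hit <- assoc$trait == trait1 & assoc$chrom == loc$chrom &
    assoc$start_bp <= loc$end_bp & assoc$end_bp >= loc$start_bp
  row <- assoc[hit & assoc$converged, , drop = FALSE]
  list(
    detected = nrow(row) > 0 && any(row$significant),
    p_value = if (nrow(row)) min(row$p_value) else NA_real_,
    p_bonferroni = if (nrow(row)) min(row$p_bonferroni) else NA_real_,
    m = attr(assoc, "m"),
    n_cnvrs = nrow(cs$cnvrs),
    effect_locus = loc
  )
}
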