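# ---------------------------------------------------------------------------
# Synthetic aCGH cohorts with known CNV and phenotype structure.
#
# Emission model: a probe inside a copy-number event reports an expected
# log2 ratio of log2(cn / 2) against the diploid (2-copy) reference; probes
# outside events report 0.  Male samples carry one copy of the sex
# chromosome, so their baseline there is log2(1/2) = -1 against a female
# reference.  cn = 0 would give -Inf and is emitted at a documented floor.
# ---------------------------------------------------------------------------

CN_ZERO_FLOOR_LOG2 <- -4

log2_ratio_for_cn <- function(cn) {
  out <- log2(cn / 2)
  out[cn == 0] <- CN_ZERO_FLOOR_LOG2
  out
}

#' Simulate an array probe map
#'
#' Places probes at uniform spacing along each chromosome, with optional
#' uniform positional jitter of `jitter_frac * probe_spacing_bp` around each
#' design position (jitter below 50% of the spacing preserves ordering and
#' uniqueness).
#'
#' @param layout a [genome_layout()].
#' @param seed integer seed; identical seeds give identical probe maps.
#' @param jitter_frac uniform jitter amplitude as a fraction of the spacing,
#'   in `[0, 0.45]`.
#' @return data.frame with columns `probe_id`, `chrom`, `pos`, sorted by
#'   (chromosome, position), positions unique within chromosome.
#' @examples
#' layout <- genome_layout(c(chr1 = 12000), probe_spacing_bp = 1200)
#' simulate_probes(layout, seed = 1, jitter_frac = 0)
#' @export
simulate_probes <- function(layout, seed = 1, jitter_frac = 0.25) {
  stopifnot(inherits(layout, "genome_layout"))
  if (jitter_frac < 0 || jitter_frac > 0.45) {
    stop("`jitter_frac` must be in [0, 0.45]")
  }
  sp <- layout$probe_spacing_bp
  if (any(sp > layout$chromosomes)) {
    stop("probe spacing exceeds the length of chromosome(s): ",
         paste(names(layout$chromosomes)[sp > layout$chromosomes],
               collapse = ", "))
  }
  set.seed(split_seed(seed, "probes"))
  pieces <- lapply(names(layout$chromosomes), function(ch) {
    len <- layout$chromosomes[[ch]]
    n <- max(1L, floor(len / sp))
    centre <- sp * (seq_len(n) - 0.5)
    jit <- if (jitter_frac > 0) runif(n, -jitter_frac * sp, jitter_frac * sp)
           else 0
    pos <- round(centre + jit)
    pos <- pmin(pmax(pos, 1), len)
    # rounding can tie only at very small spacings; nudge deterministically
    while (anyDuplicated(pos)) pos[duplicated(pos)] <- pos[duplicated(pos)] + 1
    data.frame(chrom = ch, pos = sort(pos), stringsAsFactors = FALSE)
  })
  probes <- do.call(rbind, pieces)
  probes <- probes[probe_order(probes$chrom, probes$pos), , drop = FALSE]
  data.frame(probe_id = sprintf("P%06d", seq_len(nrow(probes))),
             chrom = probes$chrom, pos = probes$pos,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Plant ground-truth CNV loci and per-sample events
#'
#' Draws `n_loci` non-overlapping CNV loci on the autosomes (chromosomes
#' other than `layout$sex_chromosome`), with lengths log-uniform in
#' `size_range`, then assigns each locus to a random subset of samples
#' (carrier probability `carrier_rate`) with a per-carrier copy number drawn
#' from `copy_numbers` with weights `copy_weights`.  Each locus first draws
#' a direction type from `state_mix`: at a "loss" locus carriers only take
#' copy numbers below 2, at a "gain" locus only above 2, and a "both" locus
#' mixes the two — so the downstream CNVR state proportions resemble real
#' catalogues, where loss regions outnumber gain regions about two-fold and
#' mixed regions are a small minority.
#'
#' @param layout a [genome_layout()].
#' @param samples character vector of sample identifiers.
#' @param n_loci number of distinct CNV loci to plant.
#' @param seed integer seed.
#' @param size_range length range in bp (default 3.6 kb to 2.1 Mb, the span
#'   reported for high-confidence cattle aCGH calls).
#' @param carrier_rate per-sample probability of carrying each locus; at
#'   least one carrier is always assigned.
#' @param copy_numbers,copy_weights carrier copy-number support and weights.
#' @param state_mix named probabilities for the per-locus direction type
#'   (`loss`, `gain`, `both`); sides missing from `copy_numbers` get their
#'   probability reassigned to the available ones.
#' @return An object of class `truth_set`: list with `loci` (locus_id,
#'   chrom, start_bp, end_bp), `true_cnvs` (locus_id, sample_id, chrom,
#'   start_bp, end_bp, copy_number), `true_effects` (empty until phenotype
#'   effects are attached), `samples` and `seed`.
#' @export
simulate_true_cnvs <- function(layout, samples, n_loci, seed = 1,
                               size_range = c(3600, 2111937),
                               carrier_rate = 0.3,
                               copy_numbers = c(0, 1, 3, 4),
                               copy_weights = c(0.08, 0.52, 0.32, 0.08),
                               state_mix = c(loss = 0.55, gain = 0.30,
                                             both = 0.15)) {
  stopifnot(inherits(layout, "genome_layout"), length(samples) >= 1,
            n_loci >= 0, length(copy_numbers) == length(copy_weights))
  stopifnot(all(c("loss", "gain", "both") %in% names(state_mix)))
  has_loss <- any(copy_numbers < 2)
  has_gain <- any(copy_numbers > 2)
  if (!has_loss && !has_gain) stop("copy_numbers contains no CNV states")
  if (!has_loss) state_mix <- c(loss = 0, gain = sum(state_mix[c("gain", "both")]),
                                both = 0)
  if (!has_gain) state_mix <- c(loss = sum(state_mix[c("loss", "both")]),
                                gain = 0, both = 0)
  set.seed(split_seed(seed, "truth"))
  autosomes <- setdiff(names(layout$chromosomes), layout$sex_chromosome)
  if (length(autosomes) == 0L) stop("layout has no autosomes to plant CNVs on")
  lens <- layout$chromosomes[autosomes]
  loci <- list()
  attempts <- 0L
  while (length(loci) < n_loci && attempts < n_loci * 200L) {
    attempts <- attempts + 1L
    ch <- sample(autosomes, 1L, prob = lens / sum(lens))
    size <- round(exp(runif(1, log(size_range[1]), log(size_range[2]))))
    size <- min(size, lens[[ch]] - 2)
    start <- floor(runif(1, 1, lens[[ch]] - size))
    cand <- c(ch, start, start + size - 1)
    clash <- any(vapply(loci, function(l) {
      l[1] == ch && as.numeric(l[2]) <= as.numeric(cand[3]) + 1 &&
        as.numeric(cand[2]) <= as.numeric(l[3]) + 1
    }, logical(1)))
    if (!clash) loci[[length(loci) + 1L]] <- cand
  }
  if (length(loci) < n_loci) {
    stop("could not place ", n_loci, " non-overlapping loci; genome too small")
  }
  loci_df <- data.frame(
    locus_id = sprintf("L%03d", seq_len(n_loci)),
    chrom = vapply(loci, `[`, character(1), 1),
    start_bp = as.numeric(vapply(loci, `[`, character(1), 2)),
    end_bp = as.numeric(vapply(loci, `[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
  loci_df <- loci_df[probe_order(loci_df$chrom, loci_df$start_bp), ,
                     drop = FALSE]
  loci_df$locus_id <- sprintf("L%03d", seq_len(nrow(loci_df)))
  rownames(loci_df) <- NULL

  locus_type <- sample(c("loss", "gain", "both"), nrow(loci_df),
                       replace = TRUE, prob = state_mix)
  events <- lapply(seq_len(nrow(loci_df)), function(i) {
    carrier <- runif(length(samples)) < carrier_rate
    if (!any(carrier)) carrier[sample(length(samples), 1L)] <- TRUE
    use <- switch(locus_type[i],
                  loss = copy_numbers < 2,
                  gain = copy_numbers > 2,
                  both = rep(TRUE, length(copy_numbers)))
    vals <- copy_numbers[use]
    cn <- vals[sample.int(length(vals), sum(carrier), replace = TRUE,
                          prob = copy_weights[use])]
    data.frame(locus_id = loci_df$locus_id[i],
               sample_id = samples[carrier],
               chrom = loci_df$chrom[i],
               start_bp = loci_df$start_bp[i],
               end_bp = loci_df$end_bp[i],
               copy_number = cn, stringsAsFactors = FALSE)
  })
  true_cnvs <- if (length(events)) do.call(rbind, events) else
    data.frame(locus_id = character(), sample_id = character(),
               chrom = character(), start_bp = numeric(), end_bp = numeric(),
               copy_number = numeric(), stringsAsFactors = FALSE)
  rownames(true_cnvs) <- NULL
  structure(list(loci = loci_df, true_cnvs = true_cnvs,
                 true_effects = data.frame(locus_id = character(),
                                           trait = character(),
                                           effect = numeric(),
                                           stringsAsFactors = FALSE),
                 samples = samples, seed = seed),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", nrow(x$loci), "loci,", nrow(x$true_cnvs),
      "sample-level events,", length(x$samples), "samples\n")
  if (nrow(x$true_effects)) {
    cat("  ", nrow(x$true_effects), "planted dosage effect(s)\n")
  }
  invisible(x)
}

# copy number of each sample at one locus (baseline 2 for non-carriers)
locus_copy_numbers <- function(truth, locus_id) {
  stopifnot(inherits(truth, "truth_set"))
  if (!locus_id %in% truth$loci$locus_id) {
    stop("unknown locus: ", locus_id)
  }
  cn <- setNames(rep(2, length(truth$samples)), truth$samples)
  ev <- truth$true_cnvs[truth$true_cnvs$locus_id == locus_id, ]
  cn[ev$sample_id] <- ev$copy_number
  cn
}

#' Simulate a probe-level log2-ratio signal matrix
#'
#' Builds the expected log2 ratio from the planted copy-number events
#' (`log2(cn/2)`, with copy number 0 emitted at a floor of -4), then adds i.i.d. Gaussian per-probe noise and a
#' per-sample baseline shift.  Male samples get a baseline copy number of 1
#' (expected ratio -1) on the sex chromosome, emulating a bull hybridised
#' against a female reference.
#'
#' @param probes probe map from [simulate_probes()].
#' @param true_cnvs data.frame of planted events (`sample_id`, `chrom`,
#'   `start_bp`, `end_bp`, `copy_number`), or a `truth_set`.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param samples sample identifiers (columns of the output). Defaults to
#'   the samples named in `true_cnvs`.
#' @param sex named character vector ("male"/"female") per sample; defaults
#'   to all male (a bull cohort).
#' @param sex_chromosome chromosome with sex-linked baseline, or `NA`.
#' @return A [signal_matrix()].
#' @export
simulate_signal <- function(probes, true_cnvs, noise = noise_model(),
                            seed = 1, samples = NULL, sex = NULL,
                            sex_chromosome = NA_character_) {
  if (inherits(true_cnvs, "truth_set")) {
    if (is.null(samples)) samples <- true_cnvs$samples
    true_cnvs <- true_cnvs$true_cnvs
  }
  stopifnot(is.data.frame(probes),
            all(c("chrom", "pos") %in% names(probes)))
  if (is.null(samples)) samples <- unique(true_cnvs$sample_id)
  if (length(samples) == 0L) stop("no samples to simulate")
  if (is.null(sex)) sex <- setNames(rep("male", length(samples)), samples)
  if (!all(samples %in% names(sex))) stop("`sex` must cover every sample")
  if (!all(sex %in% c("male", "female"))) {
    stop("`sex` entries must be \"male\" or \"female\"")
  }
  if (nrow(true_cnvs)) {
    bad <- setdiff(unique(true_cnvs$chrom), unique(probes$chrom))
    if (length(bad)) {
      stop("CNV on chromosome(s) absent from the probe map: ",
           paste(bad, collapse = ", "))
    }
    if (any(true_cnvs$start_bp > true_cnvs$end_bp) ||
        any(true_cnvs$start_bp < 1)) {
      stop("invalid CNV coordinates")
    }
  }
  n <- nrow(probes)
  set.seed(split_seed(seed, "signal"))
  vals <- matrix(0, nrow = n, ncol = length(samples),
                 dimnames = list(probes$probe_id, samples))
  if (!is.na(sex_chromosome)) {
    on_x <- probes$chrom == sex_chromosome
    male <- samples[sex[samples] == "male"]
    vals[on_x, male] <- log2_ratio_for_cn(1)
  }
  if (nrow(true_cnvs)) {
    for (i in seq_len(nrow(true_cnvs))) {
      ev <- true_cnvs[i, ]
      if (!ev$sample_id %in% samples) next
      idx <- which(probes$chrom == ev$chrom &
                     probes$pos >= ev$start_bp & probes$pos <= ev$end_bp)
      vals[idx, ev$sample_id] <- log2_ratio_for_cn(ev$copy_number)
    }
  }
  if (noise$probe_sd > 0) {
    vals <- vals + matrix(rnorm(n * length(samples), sd = noise$probe_sd),
                          nrow = n)
  }
  if (noise$sample_shift_sd > 0) {
    shift <- rnorm(length(samples), sd = noise$sample_shift_sd)
    vals <- sweep(vals, 2L, shift, `+`)
  }
  signal_matrix(probes, vals)
}

#' Simulate a self-to-self (noise-only) hybridisation
#'
#' The reference sample hybridised against itself carries no copy-number
#' signal; the resulting matrix is pure noise and calibrates the
#' false-positive rate of downstream calling.
#'
#' @inheritParams simulate_signal
#' @param n_samples number of replicate self-self hybridisations.
#' @return A [signal_matrix()] with samples `selfself_1`, ...
#' @export
simulate_self_self <- function(probes, noise = noise_model(), seed = 1,
                               n_samples = 1) {
  samples <- sprintf("selfself_%d", seq_len(n_samples))
  empty <- data.frame(locus_id = character(), sample_id = character(),
                      chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), copy_number = numeric(),
                      stringsAsFactors = FALSE)
  simulate_signal(probes, empty, noise = noise,
                  seed = split_seed(seed, "selfself"), samples = samples,
                  sex = setNames(rep("female", n_samples), samples),
                  sex_chromosome = NA_character_)
}

#' Attach a dosage effect to a planted locus
#'
#' @param truth a `truth_set`.
#' @param locus_id one of `truth$loci$locus_id`.
#' @param trait trait name the locus affects.
#' @param effect trait units per copy deviation from 2; mutually exclusive
#'   with `variance_explained`.
#' @param variance_explained if given, the effect size is solved from the
#'   closed-form variance partition so the locus explains this fraction of
#'   the trait's variance (see [effect_for_variance_explained()]).
#' @param residual_sd residual SD used when solving from
#'   `variance_explained`.
#' @return The `truth_set` with the effect appended to `true_effects`.
#' @export
add_dosage_effect <- function(truth, locus_id, trait, effect = NULL,
                              variance_explained = NULL, residual_sd = 1) {
  stopifnot(inherits(truth, "truth_set"))
  cn <- locus_copy_numbers(truth, locus_id)
  if (is.null(effect)) {
    if (is.null(variance_explained)) {
      stop("give either `effect` or `variance_explained`")
    }
    dv <- mean((cn - 2)^2) - mean(cn - 2)^2
    effect <- effect_for_variance_explained(variance_explained, dv,
                                            residual_sd)
  }
  truth$true_effects <- rbind(
    truth$true_effects,
    data.frame(locus_id = locus_id, trait = trait, effect = effect,
               stringsAsFactors = FALSE)
  )
  truth
}

#' Closed-form variance partition for a dosage effect
#'
#' For trait `y = beta * d + e`, with dosage deviation `d = cn - 2` of
#' variance `dosage_var` and residual variance `residual_sd^2`, the fraction
#' of trait variance explained by the locus is
#' `beta^2 * dosage_var / (beta^2 * dosage_var + residual_sd^2)`.
#' [effect_for_variance_explained()] inverts this for `beta`.
#'
#' @param beta effect per copy.
#' @param dosage_var variance of the dosage deviation across samples.
#' @param residual_sd residual standard deviation.
#' @return Fraction of variance explained in `[0, 1)`.
#' @export
expected_variance_explained <- function(beta, dosage_var, residual_sd) {
  num <- beta^2 * dosage_var
  num / (num + residual_sd^2)
}

#' @rdname expected_variance_explained
#' @param variance_explained target fraction in `[0, 1)`.
#' @export
effect_for_variance_explained <- function(variance_explained, dosage_var,
                                          residual_sd) {
  stopifnot(variance_explained >= 0, variance_explained < 1)
  if (dosage_var <= 0) stop("dosage variance must be positive")
  sqrt(variance_explained / (1 - variance_explained)) *
    residual_sd / sqrt(dosage_var)
}

#' Simulate quantitative trait (PTA) tables
#'
#' Each trait value is the sum of planted locus effects times the sample's
#' dosage deviation (`copy_number - 2`) plus a block-correlated Gaussian
#' residual (see [phenotype_model()]).
#'
#' @param samples sample identifiers.
#' @param truth a `truth_set`; its `true_effects` (possibly augmented by the
#'   `model`'s `dosage_effects`) define the genetic architecture.
#' @param model a [phenotype_model()].
#' @param seed integer seed.
#' @return data.frame with `sample_id` plus one numeric column per trait.
#' @export
simulate_phenotypes <- function(samples, truth, model = phenotype_model(),
                                seed = 1) {
  stopifnot(inherits(truth, "truth_set"), inherits(model, "phenotype_model"))
  effects <- rbind(truth$true_effects, model$dosage_effects)
  if (nrow(effects)) {
    missing <- setdiff(effects$locus_id, truth$loci$locus_id)
    if (length(missing)) {
      stop("dosage effect(s) on loci absent from the truth set: ",
           paste(missing, collapse = ", "))
    }
    bad_trait <- setdiff(effects$trait, model$traits$trait)
    if (length(bad_trait)) {
      stop("dosage effect(s) on unknown trait(s): ",
           paste(bad_trait, collapse = ", "))
    }
  }
  traits <- model$traits$trait
  k <- length(traits)
  n <- length(samples)
  set.seed(split_seed(seed, "phenotypes"))

  # block-structured residual correlation
  blk <- model$traits$block
  R <- matrix(model$between_block_cor, k, k)
  for (b in unique(blk)) {
    i <- which(blk == b)
    R[i, i] <- model$within_block_cor
  }
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop("residual correlation structure is not positive semi-definite")
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  resid <- matrix(rnorm(n * k), n, k) %*% L
  resid <- sweep(resid, 2L, model$residual_sd, `*`)

  y <- matrix(0, n, k, dimnames = list(samples, traits))
  if (nrow(effects)) {
    for (i in seq_len(nrow(effects))) {
      cn <- locus_copy_numbers(truth, effects$locus_id[i])[samples]
      y[, effects$trait[i]] <- y[, effects$trait[i]] +
        effects$effect[i] * (cn - 2)
    }
  }
  y <- y + resid
  out <- data.frame(sample_id = samples, y, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a complete aCGH cohort
#'
#' Convenience wrapper chaining [simulate_probes()], [simulate_true_cnvs()],
#' optional dosage effects, [simulate_signal()] and
#' [simulate_phenotypes()].
#'
#' @param layout a [genome_layout()].
#' @param n_samples cohort size (default 47 bulls).
#' @param n_loci number of planted CNV loci.
#' @param noise a [noise_model()].
#' @param model a [phenotype_model()]; set to `NULL` to skip phenotypes.
#' @param effects data.frame (`locus_id`, `trait`, and either `effect` or
#'   `variance_explained`) of dosage effects to plant, or `NULL`.
#' @param seed integer seed driving every stage.
#' @param ... passed to [simulate_true_cnvs()].
#' @return list with `probes`, `truth`, `signal`, `phenotypes` (or `NULL`),
#'   `layout`, `seed`.
#' @export
simulate_cohort <- function(layout, n_samples = 47, n_loci = 30,
                            noise = noise_model(), model = phenotype_model(),
                            effects = NULL, seed = 1, ...) {
  samples <- sprintf("bull_%02d", seq_len(n_samples))
  probes <- simulate_probes(layout, seed = seed)
  truth <- simulate_true_cnvs(layout, samples, n_loci, seed = seed, ...)
  if (!is.null(effects) && nrow(effects)) {
    for (i in seq_len(nrow(effects))) {
      if (!is.null(effects$effect) && !is.na(effects$effect[i])) {
        truth <- add_dosage_effect(truth, effects$locus_id[i],
                                   effects$trait[i],
                                   effect = effects$effect[i])
      } else {
        truth <- add_dosage_effect(
          truth, effects$locus_id[i], effects$trait[i],
          variance_explained = effects$variance_explained[i],
          residual_sd = if (is.null(model)) 1 else model$residual_sd[1]
        )
      }
    }
  }
  signal <- simulate_signal(probes, truth, noise = noise, seed = seed,
                            samples = samples,
                            sex_chromosome = layout$sex_chromosome)
  phen <- if (is.null(model)) NULL else
    simulate_phenotypes(samples, truth, model, seed = seed)
  list(probes = probes, truth = truth, signal = signal, phenotypes = phen,
       layout = layout, seed = seed)
}
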