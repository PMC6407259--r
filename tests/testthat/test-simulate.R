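test_that("probe maps respect spacing, ordering, uniqueness and seeds", {
  layout <- genome_layout(c(chr1 = 12000), probe_spacing_bp = 1200)
  p <- simulate_probes(layout, seed = 1, jitter_frac = 0)
  expect_equal(nrow(p), 10L)
  expect_false(is.unsorted(p$pos))
  expect_equal(anyDuplicated(p$pos), 0L)

  big <- genome_layout(c(chr1 = 2e6, chr2 = 1e6), probe_spacing_bp = 1200)
  pb <- simulate_probes(big, seed = 3)
  for (ch in c("chr1", "chr2")) {
    pos <- pb$pos[pb$chrom == ch]
    expect_false(is.unsorted(pos))
    expect_equal(anyDuplicated(pos), 0L)
    expect_lt(abs(mean(diff(pos)) - 1200) / 1200, 0.10)
  }

  expect_identical(simulate_probes(big, seed = 5), simulate_probes(big, seed = 5))
  expect_false(identical(simulate_probes(big, seed = 5),
                         simulate_probes(big, seed = 6)))

  tiny <- genome_layout(c(chr1 = 500), probe_spacing_bp = 1200)
  expect_error(simulate_probes(tiny), "spacing exceeds")
})

test_that("noise-free emission is log2(cn/2) with hemizygous chrX baseline", {
  layout <- genome_layout(c(chr1 = 60000, chrX = 60000),
                          probe_spacing_bp = 1200, sex_chromosome = "chrX")
  probes <- simulate_probes(layout, seed = 2, jitter_frac = 0)
  samples <- c("s1", "s2")
  cnvs <- data.frame(
    sample_id = c("s1", "s1"), chrom = "chr1",
    start_bp = c(1, 30001), end_bp = c(12000, 42000),
    copy_number = c(1, 3), stringsAsFactors = FALSE
  )
  sm <- simulate_signal(probes, cnvs, noise_model(0, 0), seed = 1,
                        samples = samples,
                        sex = c(s1 = "male", s2 = "female"),
                        sex_chromosome = "chrX")
  chr1 <- sm$probes$chrom == "chr1"
  in_loss <- chr1 & sm$probes$pos <= 12000
  in_gain <- chr1 & sm$probes$pos >= 30001 & sm$probes$pos <= 42000
  expect_true(all(sm$values[in_loss, "s1"] == -1))
  expect_equal(unique(sm$values[in_gain, "s1"]), log2(3 / 2))
  expect_true(all(sm$values[chr1 & !in_loss & !in_gain, "s1"] == 0))
  expect_true(all(sm$values[chr1, "s2"] == 0))
  # male chrX baseline -1 against the female reference; female stays at 0
  chrx <- sm$probes$chrom == "chrX"
  expect_true(all(sm$values[chrx, "s1"] == -1))
  expect_true(all(sm$values[chrx, "s2"] == 0))

  bad <- cnvs; bad$chrom <- "chr9"
  expect_error(simulate_signal(probes, bad, noise_model(0, 0),
                               samples = samples), "absent from the probe map")
})

test_that("copy number zero is emitted at the documented floor", {
  layout <- genome_layout(c(chr1 = 24000), probe_spacing_bp = 1200)
  probes <- simulate_probes(layout, seed = 1, jitter_frac = 0)
  cnvs <- data.frame(sample_id = "s1", chrom = "chr1", start_bp = 1,
                     end_bp = 12000, copy_number = 0,
                     stringsAsFactors = FALSE)
  sm <- simulate_signal(probes, cnvs, noise_model(0, 0), samples = "s1")
  expect_true(all(sm$values[sm$probes$pos <= 12000, "s1"] == -4))
})

test_that("null-probe noise matches the Gaussian model", {
  layout <- genome_layout(c(chr1 = 12.2e6), probe_spacing_bp = 1200)
  probes <- simulate_probes(layout, seed = 4)
  sm <- simulate_self_self(probes, noise_model(0.15, 0), seed = 11)
  n <- nrow(sm$values)
  expect_gte(n, 10000)
  expect_lt(abs(mean(sm$values)), 3 * 0.15 / sqrt(n))
  expect_lt(abs(sd(as.numeric(sm$values)) - 0.15), 0.01)
})

test_that("self-to-self simulations are seeded pure noise", {
  layout <- genome_layout(c(chr1 = 120000), probe_spacing_bp = 1200)
  probes <- simulate_probes(layout, seed = 1)
  zero <- simulate_self_self(probes, noise_model(0, 0), seed = 1)
  expect_true(all(zero$values == 0))
  a <- simulate_self_self(probes, noise_model(0.15), seed = 9)
  b <- simulate_self_self(probes, noise_model(0.15), seed = 9)
  expect_identical(a$values, b$values)
})

test_that("phenotypes follow the planted dosage model", {
  layout <- genome_layout(c(chr1 = 5e6), probe_spacing_bp = 1200)
  samples <- sprintf("s%03d", 1:500)
  truth <- simulate_true_cnvs(layout, samples, n_loci = 2, seed = 21,
                              size_range = c(20000, 60000),
                              carrier_rate = 0.5, copy_numbers = c(1, 3),
                              copy_weights = c(0.5, 0.5))
  traits <- trait_catalogue()[1:4, ]

  # noise-free limit: trait equals the dosage deviation exactly
  t0 <- add_dosage_effect(truth, "L001", traits$trait[1], effect = 1)
  m0 <- phenotype_model(traits = traits, residual_sd = 0)
  ph0 <- simulate_phenotypes(samples, t0, m0, seed = 3)
  cn <- locus_copy_numbers(t0, "L001")[samples]
  expect_equal(ph0[[traits$trait[1]]], unname(cn - 2))

  # null model: traits independent of copy number
  mnull <- phenotype_model(traits = traits, residual_sd = 1)
  phn <- simulate_phenotypes(samples, truth, mnull, seed = 4)
  slope <- coef(lm(phn[[traits$trait[2]]] ~ I(cn - 2)))[2]
  expect_lt(abs(slope), 3 / (sd(cn - 2) * sqrt(500)))

  # effect on an unknown locus is rejected
  t_bad <- truth
  t_bad$true_effects <- data.frame(locus_id = "L999", trait = traits$trait[1],
                                   effect = 1, stringsAsFactors = FALSE)
  expect_error(simulate_phenotypes(samples, t_bad, mnull), "absent from")
})

test_that("closed-form variance explained matches simulation at n = 500", {
  layout <- genome_layout(c(chr1 = 5e6), probe_spacing_bp = 1200)
  samples <- sprintf("s%03d", 1:500)
  truth <- simulate_true_cnvs(layout, samples, n_loci = 1, seed = 31,
                              size_range = c(20000, 60000),
                              carrier_rate = 0.5, copy_numbers = c(1, 3),
                              copy_weights = c(0.5, 0.5))
  truth <- add_dosage_effect(truth, "L001", "Milk",
                             variance_explained = 0.143, residual_sd = 1)
  model <- phenotype_model(traits = trait_catalogue()[1:2, ],
                           residual_sd = 1)
  cn <- locus_copy_numbers(truth, "L001")[samples]
  # average the realized squared correlation over phenotype replicates so
  # the Monte-Carlo error (sd ~ 0.027 per draw) shrinks below the band
  r2 <- vapply(1:20, function(s) {
    ph <- simulate_phenotypes(samples, truth, model, seed = 100 + s)
    cor(ph$Milk, cn - 2)^2
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.143), 0.02)
  expect_true(all(r2 > 0.05 & r2 < 0.25))

  # the closed form itself
  expect_equal(expected_variance_explained(
    effect_for_variance_explained(0.143, 0.5, 1), 0.5, 1), 0.143)
})

test_that("the planted genome fraction is recoverable from the truth set", {
  layout <- genome_layout(c(chr1 = 2e6, chr2 = 1.5e6),
                          probe_spacing_bp = 1200)
  truth <- simulate_true_cnvs(layout, c("a", "b"), n_loci = 5, seed = 8,
                              size_range = c(5000, 50000))
  frac <- sum(truth$loci$end_bp - truth$loci$start_bp + 1) /
    sum(layout$chromosomes)
  expect_gt(frac, 0)
  expect_lt(frac, 0.2)
  # loci never overlap each other (distinct CNVRs by construction)
  loci <- truth$loci[order(loci_rank <- truth$loci$start_bp), ]
  by_chrom <- split(loci, loci$chrom)
  for (d in by_chrom) {
    if (nrow(d) > 1) {
      d <- d[order(d$start_bp), ]
      expect_true(all(d$start_bp[-1] > d$end_bp[-nrow(d)]))
    }
  }
})

test_that("simulators are byte-identical under a fixed seed", {
  layout <- genome_layout(c(chr1 = 1e6), probe_spacing_bp = 1200)
  a <- simulate_cohort(layout, n_samples = 5, n_loci = 3,
                       model = phenotype_model(traits = trait_catalogue()[1:3, ]),
                       seed = 77)
  b <- simulate_cohort(layout, n_samples = 5, n_loci = 3,
                       model = phenotype_model(traits = trait_catalogue()[1:3, ]),
                       seed = 77)
  expect_identical(a$signal$values, b$signal$values)
  expect_identical(a$truth$true_cnvs, b$truth$true_cnvs)
  expect_identical(a$phenotypes, b$phenotypes)
})
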