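sim_cnvr_matrix <- function(n_probes = 20, groups = c(-1, 0, 0.585),
                            n_per = 50, sd = 0.05, seed = 1) {
  set.seed(seed)
  mu <- rep(groups, each = n_per)
  vals <- t(vapply(seq_along(mu), function(i) rnorm(n_probes, mu[i], sd),
                   numeric(n_probes)))   # samples x probes
  probes <- data.frame(probe_id = sprintf("p%02d", seq_len(n_probes)),
                       chrom = "chr1",
                       pos = seq(1000, by = 1000, length.out = n_probes),
                       stringsAsFactors = FALSE)
  rownames(vals) <- sprintf("s%03d", seq_along(mu))
  sm <- signal_matrix(probes, t(vals))
  list(sm = sm, truth_class = rep(seq_along(groups), each = n_per))
}

test_that("CNVR signal extraction handles 1-probe, rank-1 and group cases", {
  probes <- data.frame(probe_id = c("p1", "p2", "p3"), chrom = "chr1",
                       pos = c(1000, 2000, 5000), stringsAsFactors = FALSE)
  vals <- matrix(c(0.1, 0.2, 0.3,
                   -0.5, 0, 0.5,
                   1, 2, 3), nrow = 3, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b", "c")))
  sm <- signal_matrix(probes, vals)
  one <- extract_cnvr_signal(sm, list(chrom = "chr1", start_bp = 900,
                                      end_bp = 1100))
  expect_equal(one$scores, c(a = 0.1, b = 0.2, c = 0.3))
  expect_error(extract_cnvr_signal(sm, list(chrom = "chr1", start_bp = 6000,
                                            end_bp = 7000)), "no probes")

  # perfectly correlated probes: |r| with any probe row is 1
  vals2 <- rbind(c(0.1, 0.5, -0.3), 2 * c(0.1, 0.5, -0.3))
  colnames(vals2) <- c("a", "b", "c")
  sm2 <- signal_matrix(probes[1:2, ], vals2)
  sig2 <- extract_cnvr_signal(sm2, list(chrom = "chr1", start_bp = 1,
                                        end_bp = 3000))
  expect_equal(abs(cor(sig2$scores, vals2[1, ])), 1)
  # orientation: score rises with the mean probe value
  expect_gt(cor(sig2$scores, colMeans(vals2)), 0)

  # 3 dosage groups: PC1 separates at least as well as any single probe
  d <- sim_cnvr_matrix(seed = 42)
  sig <- extract_cnvr_signal(d$sm, list(chrom = "chr1", start_bp = 1,
                                        end_bp = 21000))
  fratio <- function(x, g) {
    summary(aov(x ~ factor(g)))[[1]]$`F value`[1]
  }
  f_pc <- fratio(sig$scores, d$truth_class)
  f_probes <- apply(d$sm$values, 1, fratio, g = d$truth_class)
  expect_gt(f_pc, max(f_probes))
})

test_that("mixture genotyping recovers well-separated classes", {
  d <- sim_cnvr_matrix(n_per = 50, sd = 0.05, seed = 7)
  sig <- extract_cnvr_signal(d$sm, list(chrom = "chr1", start_bp = 1,
                                        end_bp = 21000))
  gt <- genotype_cnvr(sig, seed = 1)
  expect_equal(gt$fit$n_components, 3L)
  expect_true(gt$fit$converged)
  expect_true(all(diff(gt$fit$means) > 0))
  acc <- mean(gt$assignments$genotype_class == d$truth_class)
  expect_gte(acc, 0.99)
  # posteriors are proper probabilities
  post <- as.matrix(gt$assignments[, grep("^post_", names(gt$assignments))])
  expect_equal(rowSums(post), rep(1, nrow(post)), tolerance = 1e-8)
})

test_that("degenerate and overlapping score distributions are flagged", {
  x <- setNames(rep(0.2, 20), sprintf("s%02d", 1:20))
  gt <- genotype_cnvr(x, seed = 1)
  expect_equal(gt$fit$n_components, 1L)
  expect_true(gt$fit$converged)
  expect_true(all(gt$assignments$genotype_class == 2L))

  # heavily overlapping clusters: mostly non-converged
  flags <- vapply(1:10, function(s) {
    set.seed(s)
    x <- setNames(c(rnorm(40, 0, 1), rnorm(40, 0.5, 1)),
                  sprintf("s%02d", 1:80))
    gt <- genotype_cnvr(x, seed = s)
    gt$fit$converged && gt$fit$n_components > 1
  }, logical(1))
  expect_lt(mean(flags), 0.5)
})

test_that("genotype labels are shift-invariant and negation-equivariant", {
  set.seed(11)
  x <- setNames(c(rnorm(40, -1, 0.05), rnorm(50, 0, 0.05),
                  rnorm(30, 0.585, 0.05)), sprintf("s%03d", 1:120))
  g0 <- genotype_cnvr(x, seed = 2)$assignments$genotype_class
  g_shift <- genotype_cnvr(x + 5, seed = 2)$assignments$genotype_class
  expect_equal(g_shift, g0)
  # negation reverses the ordering of classes
  g_neg <- genotype_cnvr(-x, seed = 2)$assignments$genotype_class
  expect_equal(g_neg, max(g0) + 1L - g0)
})

test_that("our EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(require(mclust, quietly = TRUE))  # Mclust needs attach
  set.seed(23)
  x <- setNames(c(rnorm(50, -1, 0.05), rnorm(50, 0, 0.05),
                  rnorm(50, 0.585, 0.05)), sprintf("s%03d", 1:150))
  ours <- genotype_cnvr(x, seed = 3)
  mc <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(sort(ours$fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  agree <- mean(ours$assignments$genotype_class ==
                  as.integer(mc$classification))
  expect_gte(agree, 0.99)
})

test_that("regression on dosage recovers planted effects and nulls", {
  set.seed(31)
  n <- 200
  dosage <- setNames(sample(1:3, n, replace = TRUE, prob = c(.3, .5, .2)),
                     sprintf("s%03d", 1:n))
  y <- setNames(2 * dosage + rnorm(n, sd = 0.5), names(dosage))
  res <- associate(dosage, y)
  expect_true(res$testable)
  expect_lt(abs(res$beta - 2), 3 * res$se)
  expect_lt(res$p_value, 1e-10)

  # noise-free: variance explained 1
  y0 <- setNames(as.numeric(dosage), names(dosage))
  expect_equal(variance_explained(y0, dosage), 1)
  expect_equal(variance_explained(-y0, dosage), 1)  # sign-invariant

  # constant dosage -> untestable
  cst <- setNames(rep(2, 20), sprintf("s%02d", 1:20))
  res0 <- associate(cst, setNames(rnorm(20), names(cst)))
  expect_false(res0$testable)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$beta, 0)
})

test_that("null p-values are calibrated and uniform", {
  set.seed(47)
  n <- 47
  ps <- replicate(1000, {
    dosage <- setNames(sample(1:3, n, replace = TRUE), sprintf("s%02d", 1:n))
    y <- setNames(rnorm(n), names(dosage))
    associate(dosage, y)$p_value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.015)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Bonferroni arithmetic and monotonicity hold", {
  expect_equal(bonferroni_correct(0.001, 297), 0.297)
  expect_equal(bonferroni_correct(1e-6, 297), 2.97e-4)
  res <- data.frame(p_value = c(0.001, 1e-6, 0.04, 0.9))
  out <- bonferroni_correct(res, 297)
  expect_equal(out$significant, c(FALSE, TRUE, FALSE, FALSE))
  for (m in c(1, 5, 297)) {
    out_m <- bonferroni_correct(res, m)
    expect_true(all(out_m$significant <= (res$p_value < 0.05)))
    expect_true(all(out_m$p_bonferroni <= 1))
  }
})

test_that("variance explained matches the OLS fit algebraically", {
  set.seed(53)
  s <- setNames(rnorm(100), sprintf("s%03d", 1:100))
  y <- setNames(0.7 * s + rnorm(100, sd = 0.8), names(s))
  ve <- variance_explained(s, y)
  fit <- lm(y ~ s)
  expect_equal(ve, summary(fit)$r.squared)
  expect_warning(variance_explained(setNames(rep(1, 10), names(s)[1:10]),
                                    y[1:10]), "constant")
})

test_that("trait clustering recovers block structure from p-values", {
  # twin columns merge first
  set.seed(61)
  p <- matrix(runif(200), 50, 4,
              dimnames = list(NULL, c("t1", "t2", "t3", "t4")))
  p[, 2] <- p[, 1]
  hc <- cluster_traits(p)
  first <- hc$merge[1, ]
  expect_true(all(first < 0) &&
                setequal(hc$labels[-first], c("t1", "t2")))

  # two anti-correlated blocks split at the top
  lg <- matrix(0, 40, 6)
  base <- runif(40, 0, 4)
  lg[, 1:3] <- base + matrix(rnorm(120, sd = 0.2), 40)
  lg[, 4:6] <- -base + 5 + matrix(rnorm(120, sd = 0.2), 40)
  p2 <- 10^(-lg)
  colnames(p2) <- paste0("tr", 1:6)
  hc2 <- cluster_traits(p2)
  cut2 <- cutree(hc2, 2)
  expect_equal(length(unique(cut2[1:3])), 1L)
  expect_equal(length(unique(cut2[4:6])), 1L)
  expect_false(cut2[1] == cut2[4])
})

test_that("4-block trait architecture is recovered by clustering", {
  skip_if_not_installed("mclust")
  blocks <- rep(c("production", "reproduction", "health", "type"),
                times = c(6, 9, 8, 18))
  aris <- vapply(1:5, function(rep) {
    set.seed(100 + rep)
    n_cnvr <- 60
    # each block has its own set of affected CNVRs
    lg <- matrix(rexp(n_cnvr * 41, 2), n_cnvr, 41)
    for (b in unique(blocks)) {
      hit <- sample(n_cnvr, 12)
      strength <- runif(12, 2, 5)
      for (j in which(blocks == b)) {
        lg[hit, j] <- lg[hit, j] + strength * runif(12, 0.6, 1.4)
      }
    }
    p <- 10^(-lg)
    colnames(p) <- paste0("trait", 1:41)
    hc <- cluster_traits(p)
    mclust::adjustedRandIndex(cutree(hc, 4), blocks)
  }, numeric(1))
  expect_gte(mean(aris), 0.8)
})

test_that("constant trait columns cluster at maximal distance", {
  set.seed(71)
  p <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "cst")))
  p[, 3] <- 0.5
  expect_warning(hc <- cluster_traits(p), "constant")
  d <- cophenetic(hc)
  expect_equal(max(as.matrix(d)["cst", c("a", "b")]), 2)
})
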