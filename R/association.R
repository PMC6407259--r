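# ---------------------------------------------------------------------------
# CNVR-trait association:
#   probe log2 ratios in a CNVR  --PCA-->  one score per sample
#   scores  --univariate Gaussian mixture (EM, BIC over 1-3 comps)-->
#   copy-number genotype classes  --OLS-->  beta, p, Bonferroni, r^2.
# ---------------------------------------------------------------------------

#' Reduce a CNVR's member probes to a one-dimensional sample score
#'
#' First principal component of the member-probe log2 ratios across samples,
#' orientation-normalised so that the score correlates positively with the
#' per-sample mean probe value (scores then rise with copy number).  With a
#' single member probe the score is that probe's values.
#'
#' @param sm a [signal_matrix()].
#' @param cnvr one CNVR row (`chrom`, `start_bp`, `end_bp`, optionally
#'   `cnvr_id`), or any list with those elements.
#' @return An object of class `cnvr_signal`: list with `cnvr_id`, `scores`
#'   (named per sample), `n_probes`, `flipped`.
#' @export
extract_cnvr_signal <- function(sm, cnvr) {
  stopifnot(inherits(sm, "signal_matrix"))
  idx <- probes_in_span(sm, cnvr$chrom, cnvr$start_bp, cnvr$end_bp)
  if (length(idx) == 0L) {
    stop("no probes fall inside CNVR span ", cnvr$chrom, ":",
         cnvr$start_bp, "-", cnvr$end_bp)
  }
  m <- t(sm$values[idx, , drop = FALSE])      # samples x probes
  m <- m[, colSums(!is.finite(m)) == 0, drop = FALSE]
  if (ncol(m) == 0L) stop("all member probes are missing")
  if (ncol(m) == 1L) {
    scores <- drop(m)
    flipped <- FALSE
  } else {
    pc <- prcomp(m, center = TRUE, scale. = FALSE)
    scores <- pc$x[, 1L]
    ref <- rowMeans(m)
    flipped <- isTRUE(cor(scores, ref) < 0)
    if (flipped) scores <- -scores
  }
  structure(list(cnvr_id = if (!is.null(cnvr$cnvr_id)) cnvr$cnvr_id
                           else NA_character_,
                 scores = setNames(as.numeric(scores), rownames(m)),
                 n_probes = ncol(m), flipped = flipped),
            class = "cnvr_signal")
}

# --- univariate Gaussian mixture fit by EM --------------------------------

em_gmm <- function(x, k, mu0, sd0, w0, max_iter, tol, sd_floor) {
  n <- length(x)
  mu <- mu0; sdv <- pmax(sd0, sd_floor); w <- w0
  ll_old <- -Inf; converged_iter <- FALSE
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], sdv[j]),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    post <- dens / tot
    nk <- colSums(post)
    w <- nk / n
    mu <- colSums(post * x) / pmax(nk, 1e-12)
    sdv <- sqrt(colSums(post * (x - rep(mu, each = n))^2) /
                  pmax(nk, 1e-12))
    sdv <- pmax(sdv, sd_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged_iter <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(mu = mu, sd = sdv, w = w, loglik = ll_old,
       em_converged = converged_iter)
}

fit_gmm_k <- function(x, k, seed, max_iter = 500L, tol = 1e-8,
                      sd_floor = 1e-3, n_restarts = 5L) {
  n <- length(x)
  s <- sd(x); if (!is.finite(s) || s < sd_floor) s <- sd_floor
  # deterministic quantile initialisation ...
  mu0 <- as.numeric(quantile(x, probs = (seq_len(k)) / (k + 1), names = FALSE))
  inits <- list(list(mu = mu0, sd = rep(s, k), w = rep(1 / k, k)))
  # ... plus seeded random restarts
  set.seed(split_seed(seed, paste0("gmm", k)))
  for (r in seq_len(n_restarts)) {
    inits[[r + 1L]] <- list(mu = sort(sample(x, k, replace = k > n)),
                            sd = rep(s, k), w = rep(1 / k, k))
  }
  best <- NULL
  for (ini in inits) {
    fit <- em_gmm(x, k, ini$mu, ini$sd, ini$w, max_iter, tol, sd_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$mu)
  best$mu <- best$mu[ord]; best$sd <- best$sd[ord]; best$w <- best$w[ord]
  best$k <- k
  best$n_par <- 3L * k - 1L
  best$bic <- -2 * best$loglik + best$n_par * log(n)
  best
}

#' Genotype a CNVR by univariate Gaussian-mixture clustering
#'
#' Fits 1-, 2- and 3-component Gaussian mixtures to the one-dimensional
#' CNVR scores by EM (deterministic quantile initialisation plus seeded
#' random restarts), selects the component count by BIC, and assigns each
#' sample its maximum-posterior class.  Classes are ordinal copy-number
#' genotypes ordered by component mean (1 = lowest signal); a 1-component
#' fit is labelled class 2 (the diploid baseline convention).  The fit is
#' flagged non-converged — and is excluded from association testing
#' downstream — when EM hits the iteration cap, any component weight falls
#' below `min_weight`, or adjacent component means are closer than
#' `mean_sep_floor` pooled standard deviations.
#'
#' @param signal a `cnvr_signal` from [extract_cnvr_signal()], or a named
#'   numeric vector of scores.
#' @param seed integer seed for the EM restarts.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param sd_floor lower bound on component standard deviations.
#' @param min_weight minimum component weight (default `2 / n`).
#' @param mean_sep_floor minimal separation of adjacent means in pooled-SD
#'   units (default 0.5).
#' @return list with `fit` (class `cghcnv_mixture`: means, sds, weights,
#'   loglik, bic, n_components, converged) and `assignments` (data.frame:
#'   `sample_id`, `genotype_class`, `expected_dosage`, posterior columns
#'   `post_1`...).
#' @export
genotype_cnvr <- function(signal, seed = 1, max_iter = 500L, tol = 1e-8,
                          sd_floor = 1e-3, min_weight = NULL,
                          mean_sep_floor = 0.5) {
  x <- if (inherits(signal, "cnvr_signal")) signal$scores else signal
  if (is.null(names(x))) names(x) <- paste0("s", seq_along(x))
  if (length(x) < 10L) stop("need >= 10 samples with scores")
  n <- length(x)
  if (is.null(min_weight)) min_weight <- 2 / n

  if (sd(x) < 1e-12) {
    # degenerate: no variation, single component, baseline genotype
    fit <- structure(list(n_components = 1L, means = mean(x), sds = sd_floor,
                          weights = 1, loglik = NA_real_, bic = NA_real_,
                          converged = TRUE, seed = seed),
                     class = "cghcnv_mixture")
    assignments <- data.frame(sample_id = names(x), genotype_class = 2L,
                              expected_dosage = 2, post_1 = 1,
                              stringsAsFactors = FALSE)
    return(list(fit = fit, assignments = assignments))
  }

  fits <- lapply(1:3, function(k) fit_gmm_k(x, k, seed, max_iter, tol,
                                            sd_floor))
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bics)]]
  k <- best$k

  pooled_sd <- sqrt(sum(best$w * best$sd^2))
  sep_ok <- k == 1L || all(diff(best$mu) >= mean_sep_floor * pooled_sd)
  weight_ok <- all(best$w >= min_weight)
  converged <- best$em_converged && sep_ok && weight_ok

  dens <- vapply(seq_len(k),
                 function(j) best$w[j] * dnorm(x, best$mu[j], best$sd[j]),
                 numeric(n))
  dens <- matrix(dens, nrow = n)
  post <- dens / pmax(rowSums(dens), 1e-300)

  # ordinal class labels: rank by component mean; single component = 2
  class_values <- if (k == 1L) 2L else seq_len(k)
  cls <- class_values[max.col(post, ties.method = "first")]
  dosage <- as.numeric(post %*% class_values)

  fit <- structure(list(n_components = k, means = best$mu, sds = best$sd,
                        weights = best$w, loglik = best$loglik,
                        bic = best$bic, converged = converged, seed = seed),
                   class = "cghcnv_mixture")
  post_df <- as.data.frame(post)
  names(post_df) <- paste0("post_", seq_len(k))
  assignments <- data.frame(sample_id = names(x),
                            genotype_class = as.integer(cls),
                            expected_dosage = dosage, post_df,
                            stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  list(fit = fit, assignments = assignments)
}

#' @export
print.cghcnv_mixture <- function(x, ...) {
  cat("Gaussian mixture:", x$n_components, "component(s),",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("  means:  ", paste(format(x$means, digits = 3), collapse = "  "), "\n")
  cat("  sds:    ", paste(format(x$sds, digits = 3), collapse = "  "), "\n")
  cat("  weights:", paste(format(x$weights, digits = 3), collapse = "  "),
      "\n")
  if (is.finite(x$bic)) cat("  BIC:", format(x$bic, digits = 6), "\n")
  invisible(x)
}

#' @export
plot.cghcnv_mixture <- function(x, scores = NULL, ...) {
  if (is.null(scores)) stop("pass the score vector used for the fit")
  hist(scores, breaks = 30, freq = FALSE, main = "CNVR score mixture",
       xlab = "one-dimensional CNVR score", ...)
  xx <- seq(min(scores), max(scores), length.out = 300)
  for (j in seq_len(x$n_components)) {
    lines(xx, x$weights[j] * dnorm(xx, x$means[j], x$sds[j]), lwd = 2,
          col = j + 1)
  }
  invisible(x)
}

#' Regress a quantitative trait on CNV genotype dosage
#'
#' Ordinary least-squares regression of the trait (PTA) on the
#' posterior-expected genotype dosage (default) or on hard genotype class
#' labels; two-sided p-value from the slope t-statistic.
#'
#' @param assignments data.frame from [genotype_cnvr()], or a named numeric
#'   dosage vector.
#' @param trait_values named numeric vector of per-sample trait values.
#' @param use character: regress on `"dosage"` (posterior-expected, default)
#'   or `"class"` (hard labels).
#' @return one-row data.frame: `n`, `beta`, `se`, `p_value`, `testable`.
#'   A constant dosage yields `beta = 0`, `p_value = 1`, `testable = FALSE`.
#' @export
associate <- function(assignments, trait_values, use = c("dosage", "class")) {
  use <- match.arg(use)
  if (is.data.frame(assignments)) {
    d <- setNames(if (use == "dosage") assignments$expected_dosage
                  else as.numeric(assignments$genotype_class),
                  assignments$sample_id)
  } else {
    d <- assignments
  }
  common <- intersect(names(d), names(trait_values))
  d <- d[common]; y <- trait_values[common]
  ok <- is.finite(d) & is.finite(y)
  d <- d[ok]; y <- y[ok]
  if (length(d) < 10L) stop("need >= 10 samples with both genotype and trait")
  if (sd(d) < 1e-12) {
    return(data.frame(n = length(d), beta = 0, se = NA_real_, p_value = 1,
                      testable = FALSE))
  }
  fit <- lm(y ~ d)
  cf <- summary(fit)$coefficients
  data.frame(n = length(d), beta = cf["d", "Estimate"],
             se = cf["d", "Std. Error"],
             p_value = cf["d", "Pr(>|t|)"], testable = TRUE)
}

#' Bonferroni correction with an explicit family size
#'
#' `p_bonferroni = min(1, m * p)`, with the significance flag at corrected
#' 0.05.  The family size is the number of tests in the chosen family
#' (by default, the number of converged CNVRs per trait), which may differ
#' from `length(p)`.
#'
#' @param results data.frame with a `p_value` column, or numeric p-values.
#' @param m family size (>= 1).
#' @param alpha significance level on the corrected scale.
#' @return `results` with `p_bonferroni` and `significant` appended (or a
#'   numeric vector when `results` is numeric).
#' @export
bonferroni_correct <- function(results, m, alpha = 0.05) {
  if (m < 1) stop("family size m must be >= 1")
  if (is.numeric(results)) return(pmin(1, m * results))
  stopifnot("p_value" %in% names(results))
  results$p_bonferroni <- pmin(1, m * results$p_value)
  results$significant <- results$p_bonferroni < alpha
  results
}

#' Variance explained as a squared correlation
#'
#' Squared Pearson correlation between the one-dimensional CNVR signal and
#' the trait values — the approximation used to report the fraction of
#' phenotypic variance (PTA variance) attributable to a CNVR.
#'
#' @param signal a `cnvr_signal` or named numeric vector of scores.
#' @param trait_values named numeric vector.
#' @return Squared correlation in `[0, 1]`; 0 with a warning when either
#'   input is constant.
#' @export
variance_explained <- function(signal, trait_values) {
  s <- if (inherits(signal, "cnvr_signal")) signal$scores else signal
  common <- intersect(names(s), names(trait_values))
  s <- s[common]; y <- trait_values[common]
  ok <- is.finite(s) & is.finite(y)
  s <- s[ok]; y <- y[ok]
  if (length(s) < 3L) stop("need >= 3 paired observations")
  if (sd(s) < 1e-12 || sd(y) < 1e-12) {
    warning("constant input; variance explained set to 0")
    return(0)
  }
  cor(s, y)^2
}

#' Associate every CNVR with every trait
#'
#' Full association pass: per CNVR, extract the one-dimensional signal,
#' genotype it by mixture clustering, regress each trait on the genotype
#' dosage, and Bonferroni-correct per trait across the converged CNVRs
#' (family size m = number of converged, testable CNVRs; configurable to a
#' global family with `family = "global"`).  Unplaced chromosomes and
#' non-converged fits are excluded from testing but reported with
#' `converged = FALSE`.
#'
#' @param sm a [signal_matrix()].
#' @param cnvr_set a `cnvr_set` from [merge_to_cnvrs()].
#' @param phenotypes data.frame with `sample_id` plus one column per trait.
#' @param seed integer seed (mixture restarts).
#' @param use regression covariate, `"dosage"` or `"class"`.
#' @param family Bonferroni family: `"per_trait"` (m = converged CNVRs) or
#'   `"global"` (m = converged CNVRs x traits).
#' @param alpha corrected significance level.
#' @return An object of class `cghcnv_assoc`: data.frame with one row per
#'   (CNVR, trait): `cnvr_id`, `chrom`, `start_bp`, `end_bp`, `trait`, `n`,
#'   `beta`, `se`, `p_value`, `converged`, `p_bonferroni`, `significant`,
#'   `variance_explained`; attribute `m` holds the family size.
#' @export
associate_cnvrs <- function(sm, cnvr_set, phenotypes, seed = 1,
                            use = c("dosage", "class"),
                            family = c("per_trait", "global"),
                            alpha = 0.05) {
  use <- match.arg(use)
  family <- match.arg(family)
  stopifnot(inherits(sm, "signal_matrix"), inherits(cnvr_set, "cnvr_set"),
            is.data.frame(phenotypes), "sample_id" %in% names(phenotypes))
  traits <- setdiff(names(phenotypes), "sample_id")
  cnvrs <- cnvr_set$cnvrs[cnvr_set$cnvrs$placed, , drop = FALSE]
  rows <- list()
  converged_ids <- character(0)
  for (i in seq_len(nrow(cnvrs))) {
    cnvr <- cnvrs[i, ]
    sig <- extract_cnvr_signal(sm, cnvr)
    gt <- genotype_cnvr(sig, seed = split_seed(seed, cnvr$cnvr_id))
    testable <- gt$fit$converged && gt$fit$n_components > 1L
    if (testable) converged_ids <- c(converged_ids, cnvr$cnvr_id)
    for (tr in traits) {
      y <- setNames(phenotypes[[tr]], phenotypes$sample_id)
      if (testable) {
        res <- associate(gt$assignments, y, use = use)
        ve <- variance_explained(sig, y)
      } else {
        res <- data.frame(n = sum(is.finite(y)), beta = NA_real_,
                          se = NA_real_, p_value = NA_real_,
                          testable = FALSE)
        ve <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cnvr_id = cnvr$cnvr_id, chrom = cnvr$chrom,
        start_bp = cnvr$start_bp, end_bp = cnvr$end_bp, trait = tr,
        n = res$n, beta = res$beta, se = res$se, p_value = res$p_value,
        converged = testable, variance_explained = ve,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cnvr_id = character(), chrom = character(),
               start_bp = numeric(), end_bp = numeric(), trait = character(),
               n = integer(), beta = numeric(), se = numeric(),
               p_value = numeric(), converged = logical(),
               variance_explained = numeric(), stringsAsFactors = FALSE)
  m <- max(1L, length(converged_ids) *
             if (family == "global") length(traits) else 1L)
  out$p_bonferroni <- pmin(1, m * out$p_value)
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni < alpha
  rownames(out) <- NULL
  structure(out, m = m, alpha = alpha, family = family,
            class = c("cghcnv_assoc", "data.frame"))
}

#' @export
print.cghcnv_assoc <- function(x, ...) {
  n_cnvr <- length(unique(x$cnvr_id))
  n_conv <- length(unique(x$cnvr_id[x$converged]))
  n_sig <- length(unique(x$cnvr_id[x$significant %in% TRUE]))
  cat("CNVR-trait association:", n_cnvr, "CNVRs x",
      length(unique(x$trait)), "traits;", n_conv, "converged;",
      n_sig, "CNVR(s) significant at corrected",
      attr(x, "alpha"), "(m =", attr(x, "m"), ")\n")
  invisible(x)
}

#' Hierarchically cluster traits on their association p-value profiles
#'
#' Transforms the CNVR x trait p-value matrix to -log10, computes pairwise
#' Pearson correlation between trait columns, and clusters traits with
#' distance `1 - r` under average linkage.  A constant trait column cannot
#' be correlated and is placed at the maximal distance (2) with a warning.
#'
#' @param p_matrix numeric matrix, CNVRs in rows, traits in columns, or a
#'   `cghcnv_assoc` object (converged rows are pivoted automatically).
#' @return An [stats::hclust] object with trait labels.
#' @export
cluster_traits <- function(p_matrix) {
  if (inherits(p_matrix, "cghcnv_assoc")) {
    d <- p_matrix[p_matrix$converged, c("cnvr_id", "trait", "p_value")]
    p_matrix <- tapply(d$p_value, list(d$cnvr_id, d$trait), mean)
  }
  p_matrix <- as.matrix(p_matrix)
  if (ncol(p_matrix) < 2L || nrow(p_matrix) < 2L) {
    stop("need >= 2 traits and >= 2 CNVRs")
  }
  lg <- -log10(pmax(p_matrix, 1e-300))
  cc <- suppressWarnings(cor(lg, use = "pairwise.complete.obs"))
  if (any(!is.finite(cc))) {
    warning("constant trait column(s); placed at maximal distance")
    cc[!is.finite(cc)] <- -1
  }
  hclust(as.dist(1 - cc), method = "average")
}

#' Manhattan-style plot of association results for one trait
#'
#' Plots -log10 p against genomic coordinate for a single trait, with the
#' Bonferroni-corrected significance threshold drawn as a horizontal line.
#'
#' @param assoc a `cghcnv_assoc` object.
#' @param trait trait name to plot.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the plotted data.frame.
#' @export
plot_manhattan <- function(assoc, trait, ...) {
  d <- assoc[assoc$trait == trait & assoc$converged, , drop = FALSE]
  if (nrow(d) == 0L) stop("no converged results for trait ", trait)
  ord <- probe_order(d$chrom, d$start_bp)
  d <- d[ord, ]
  chrom_f <- factor(d$chrom, levels = unique(d$chrom))
  offs <- c(0, cumsum(tapply(d$end_bp, chrom_f, max)))
  xpos <- d$start_bp + offs[as.integer(chrom_f)]
  plot(xpos, -log10(d$p_value), pch = 19,
       col = as.integer(chrom_f) %% 2 + 1,
       xlab = "genomic position", ylab = expression(-log[10](p)),
       main = trait, xaxt = "n", ...)
  m <- attr(assoc, "m")
  abline(h = -log10(0.05 / m), lty = 2)
  invisible(d)
}
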