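test_that("pairwise overlap arithmetic is exact, symmetric and chrom-aware", {
  expect_equal(interval_overlap_bp(100, 200, 201, 300), 0)
  expect_equal(interval_overlap_bp(100, 200, 200, 300), 1)
  expect_equal(interval_overlap_bp(100, 200, 100, 200), 101)
  # worked coordinates: CNVR661 x CYP4A11, a positive partial overlap
  ov <- interval_overlap_bp(99808706, 99846316, 99806653, 99820784)
  expect_equal(ov, 12079)
  expect_gt(ov, 0)
  expect_lt(ov, 99846316 - 99808706 + 1)
  # symmetry
  set.seed(3)
  for (i in 1:20) {
    a <- sort(sample.int(1e5, 2)); b <- sort(sample.int(1e5, 2))
    expect_equal(interval_overlap_bp(a[1], a[2], b[1], b[2]),
                 interval_overlap_bp(b[1], b[2], a[1], a[2]))
  }
  expect_equal(interval_overlap_bp(1, 100, 1, 100,
                                   chrom_a = "chr1", chrom_b = "chr2"), 0)
})

test_that("gene overlap honours flanks and falls back to nearest gene", {
  genes <- data.frame(name = "G1", chrom = "chr1", start_bp = 10000,
                      end_bp = 20000, stringsAsFactors = FALSE)
  cnvr <- data.frame(name = "R1", chrom = "chr1", start_bp = 21000,
                     end_bp = 22000, stringsAsFactors = FALSE)
  with_flank <- overlap_genes(cnvr, genes, flank_bp = 3000)
  expect_equal(with_flank$relation, "overlapping")
  expect_equal(with_flank$overlap_bp, 1001)   # expanded gene ends at 23000
  no_flank <- overlap_genes(cnvr, genes, flank_bp = 0)
  expect_equal(no_flank$relation, "nearest")
  expect_equal(no_flank$distance_bp, 1000)
  # nearest-gene ties break toward the lexicographically smaller symbol
  genes2 <- rbind(genes,
                  data.frame(name = "A9", chrom = "chr1", start_bp = 23000,
                             end_bp = 30000, stringsAsFactors = FALSE))
  tie <- overlap_genes(cnvr, genes2, flank_bp = 0)
  expect_equal(tie$feature, "A9")
})

test_that("gene overlap counts are monotone in the flank", {
  set.seed(17)
  n <- 100
  gs <- sample.int(5e5, n)
  genes <- data.frame(name = sprintf("G%03d", 1:n),
                      chrom = sample(c("chr1", "chr2"), n, TRUE),
                      start_bp = gs, end_bp = gs + sample.int(2e4, n),
                      stringsAsFactors = FALSE)
  cs <- sample.int(5e5, 30)
  cnvrs <- data.frame(name = sprintf("R%02d", 1:30),
                      chrom = sample(c("chr1", "chr2"), 30, TRUE),
                      start_bp = cs, end_bp = cs + sample.int(3e4, 30),
                      stringsAsFactors = FALSE)
  last <- -1
  for (fl in c(0, 1000, 3000, 10000)) {
    rec <- overlap_genes(cnvrs, genes, flank_bp = fl)
    n_ov <- sum(rec$relation == "overlapping")
    expect_gte(n_ov, last)
    last <- n_ov
  }
})

test_that("gene overlap records match the quadratic all-pairs oracle", {
  set.seed(19)
  n <- 200
  gs <- sample.int(1e6, n)
  genes <- data.frame(name = sprintf("G%03d", 1:n),
                      chrom = sample(sprintf("chr%d", 1:3), n, TRUE),
                      start_bp = gs, end_bp = gs + sample.int(3e4, n),
                      stringsAsFactors = FALSE)
  cs <- sample.int(1e6, 80)
  cnvrs <- data.frame(name = sprintf("R%02d", 1:80),
                      chrom = sample(sprintf("chr%d", 1:3), 80, TRUE),
                      start_bp = cs, end_bp = cs + sample.int(5e4, 80),
                      stringsAsFactors = FALSE)
  rec <- overlap_genes(cnvrs, genes, flank_bp = 3000)
  rec <- rec[rec$relation == "overlapping", ]
  orc <- oracle_overlap_genes(cnvrs, genes, flank = 3000)
  key <- function(a, b) paste(a, b)
  expect_setequal(key(rec$cnvr_id, rec$feature), key(orc$cnvr, orc$feature))
  m <- match(key(rec$cnvr_id, rec$feature), key(orc$cnvr, orc$feature))
  expect_equal(rec$overlap_bp, orc$overlap[m])
})

test_that("QTL filter and 50% union-coverage rule are enforced", {
  cnvr <- data.frame(name = "R1", chrom = "chr5", start_bp = 100001,
                     end_bp = 110000, stringsAsFactors = FALSE)
  # 31 Mb QTL is discarded regardless of overlap
  huge <- data.frame(name = "Q_huge", chrom = "chr5", start_bp = 1,
                     end_bp = 31e6, stringsAsFactors = FALSE)
  expect_equal(nrow(overlap_qtls(cnvr, huge)), 0L)
  # 4.9 kb of a 10 kb CNVR covered -> no record; 5.0 kb -> record
  q49 <- data.frame(name = "Q1", chrom = "chr5", start_bp = 100001,
                    end_bp = 104900, stringsAsFactors = FALSE)
  expect_equal(nrow(overlap_qtls(cnvr, q49)), 0L)
  q50 <- q49; q50$end_bp <- 105000
  rec <- overlap_qtls(cnvr, q50)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$union_coverage, 0.5)
  # union of two QTLs can satisfy the rule where neither alone does
  q2 <- data.frame(name = c("Qa", "Qb"), chrom = "chr5",
                   start_bp = c(100001, 103501), end_bp = c(103000, 106500),
                   stringsAsFactors = FALSE)
  rec2 <- overlap_qtls(cnvr, q2)
  expect_equal(nrow(rec2), 2L)
  expect_equal(unique(rec2$union_coverage), 0.6)
})

test_that("QTL coverage agrees with brute-force base counting", {
  set.seed(23)
  cs <- sample.int(5e5, 40)
  cnvrs <- data.frame(name = sprintf("R%02d", 1:40), chrom = "chr1",
                      start_bp = cs, end_bp = cs + sample(5000:40000, 40, TRUE),
                      stringsAsFactors = FALSE)
  qs <- sample.int(5e5, 60)
  qtls <- data.frame(name = sprintf("Q%02d", 1:60), chrom = "chr1",
                     start_bp = qs, end_bp = qs + sample(2000:80000, 60, TRUE),
                     stringsAsFactors = FALSE)
  cfg <- annotation_config()
  rec <- overlap_qtls(cnvrs, qtls, cfg)
  keep <- qtls[qtls$end_bp - qtls$start_bp + 1 <= cfg$qtl_max_ci_bp, ]
  for (i in seq_len(nrow(cnvrs))) {
    cov <- oracle_union_coverage(cnvrs$start_bp[i], cnvrs$end_bp[i],
                                 keep$start_bp, keep$end_bp)
    len <- cnvrs$end_bp[i] - cnvrs$start_bp[i] + 1
    in_rec <- cnvrs$name[i] %in% rec$cnvr_id
    expect_equal(in_rec, cov / len >= 0.5)
    if (in_rec) {
      expect_equal(unique(rec$union_coverage[rec$cnvr_id == cnvrs$name[i]]),
                   cov / len)
    }
  }
})

test_that("CNVR set comparison: identical, disjoint and jittered sets", {
  set.seed(29)
  st <- sort(sample.int(1e6, 40))
  a <- data.frame(name = sprintf("A%02d", 1:40), chrom = "chr2",
                  start_bp = st, end_bp = st + sample(5000:30000, 40, TRUE),
                  stringsAsFactors = FALSE)
  same <- compare_cnvr_sets(a, a, 0.5)
  expect_equal(same$summary$count_fraction, 1)
  expect_equal(same$summary$bp_fraction, 1)

  b <- a; b$start_bp <- b$start_bp + 5e6; b$end_bp <- b$end_bp + 5e6
  disj <- compare_cnvr_sets(a, b, 0.5)
  expect_equal(disj$summary$n_supported, 0L)
  expect_equal(disj$summary$count_fraction, 0)

  # jitter boundaries by +/-20% of length: per-region support matches a
  # direct recomputation
  len <- a$end_bp - a$start_bp + 1
  jit <- a
  jit$start_bp <- pmax(1, round(a$start_bp + 0.2 * len * runif(40, -1, 1)))
  jit$end_bp <- round(a$end_bp + 0.2 * len * runif(40, -1, 1))
  jit$end_bp <- pmax(jit$end_bp, jit$start_bp)
  res <- compare_cnvr_sets(a, jit, 0.5)
  for (i in 1:40) {
    cov <- oracle_union_coverage(a$start_bp[i], a$end_bp[i],
                                 jit$start_bp, jit$end_bp)
    expect_equal(res$per_region$overlap_bp[i], cov)
    expect_equal(res$per_region$supported[i], cov / len[i] >= 0.5)
  }
})
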