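test_that("probeset collapse keeps the highest-mean probeset per gene", {
  m <- matrix(c(5, 5, 7, 7, 3, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("P1", "P2", "P3"), c("s1", "s2")))
  data <- make_expr(m, id = "probeset")
  map <- tibble::tibble(probeset = c("P1", "P2", "P3"),
                        gene = c("G1", "G1", "G2"))
  out <- collapse_probesets(data, map)
  expect_equal(out$gene, c("G1", "G2"))
  expect_equal(out$s1[out$gene == "G1"], 7)   # P2 wins over P1
  expect_equal(out$s1[out$gene == "G2"], 3)   # single probeset: identity
})

test_that("probeset-collapse ties go to the lexicographically smaller id", {
  m <- matrix(c(4, 6, 6, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("P9", "P2"), c("s1", "s2")))
  data <- make_expr(m, id = "probeset")
  map <- tibble::tibble(probeset = c("P9", "P2"), gene = c("G", "G"))
  out <- collapse_probesets(data, map)
  # both probesets have mean 5; P2 < P9 lexicographically
  expect_equal(out$s1, 6)
  expect_equal(out$s2, 4)
})

test_that("unmapped probesets are dropped with a message; empty map errors", {
  m <- matrix(1:4, 2, dimnames = list(c("P1", "PX"), c("s1", "s2")))
  data <- make_expr(m, id = "probeset")
  map <- tibble::tibble(probeset = "P1", gene = "G1")
  expect_message(out <- collapse_probesets(data, map), "unmapped")
  expect_equal(out$gene, "G1")
  expect_error(collapse_probesets(data, map[0, ]), "empty")
})

test_that("signed fold change follows the reciprocal-sign convention", {
  expect_equal(signed_fold_change(15, 10), 1.5)
  expect_equal(signed_fold_change(10, 15), -1.5)
  expect_equal(signed_fold_change(10, 10), 1)
  expect_error(signed_fold_change(5, 0), "zero reference")
  fc <- signed_fold_change(runif(50, 0.1, 10), runif(50, 0.1, 10))
  expect_true(all(abs(fc) >= 1))
})

test_that("median-reference fold changes de-log and use the gene median", {
  m <- log2(matrix(c(
    10, 10, 10, 20,   # refs {10,10,10}, sample 20 -> +2
    8, 10, 12, 5      # refs {8,10,12} median 10, sample 5 -> -2
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("g1", "g2"), c("r1", "r2", "r3", "t1"))))
  fc <- median_reference_fold_change(make_expr(m), c("r1", "r2", "r3"))
  expect_equal(fc$t1, c(2, -2))
  expect_equal(fc$r1[1], 1)  # sample equal to median
  expect_equal(attr(fc, "reference_samples"), c("r1", "r2", "r3"))
})

test_that("zero reference medians are reported with the offending gene", {
  m <- matrix(c(0, 0, 5, 5), 2, byrow = TRUE,
              dimnames = list(c("gz", "g2"), c("r1", "t1")))
  expect_error(
    median_reference_fold_change(make_expr(m), "r1", log2_input = FALSE),
    "gz"
  )
})

test_that("discretisation thresholds are inclusive and exhaustive", {
  expect_equal(discretize_calls(c(1.5, -1.5, 1.49, -1.49, 3, 1)),
               c(1L, -1L, 0L, 0L, 1L, 0L))
  # partition: each value maps to exactly one class
  v <- signed_fold_change(runif(200, 0.1, 10), runif(200, 0.1, 10))
  calls <- discretize_calls(v)
  expect_equal(sum(calls == 1) + sum(calls == -1) + sum(calls == 0), 200)
  # monotone in the numerator
  x <- sort(runif(50, 1, 100))
  expect_true(all(diff(discretize_calls(signed_fold_change(x, 10))) >= 0))
})

test_that("replicate filter keeps unanimous genes and drops the rest", {
  calls <- tibble::tibble(
    gene = c("g1", "g2", "g3"),
    a1 = c(1L, 1L, 0L), a2 = c(1L, 0L, 0L), a3 = c(1L, 1L, 0L),
    b1 = c(-1L, 1L, 1L), b2 = c(-1L, 1L, 1L), b3 = c(-1L, 1L, 1L)
  )
  design <- tibble::tibble(
    sample = c("a1", "a2", "a3", "b1", "b2", "b3"),
    group = rep(c("A", "B"), each = 3),
    replicate = rep(1:3, 2)
  )
  out <- filter_inconsistent_replicates(calls, design)
  expect_equal(out$dropped, "g2")   # (+1, 0, +1) in condition A
  expect_equal(sort(out$calls$gene), c("g1", "g3"))
  expect_equal(out$calls$A[out$calls$gene == "g1"], 1L)
  expect_equal(out$calls$B[out$calls$gene == "g1"], -1L)
  expect_equal(dim(out$calls), c(2L, 3L))  # gene + 2 conditions
})

test_that("anova_de matches the textbook sum-of-squares oracle", {
  m <- matrix(c(1.0, 1.1, 0.9, 2.0, 2.1, 1.9), 1,
              dimnames = list("g", paste0("s", 1:6)))
  design <- tibble::tibble(sample = paste0("s", 1:6),
                           group = rep(c("ctl", "trt"), each = 3))
  out <- anova_de(make_expr(m), design)
  oracle <- oracle_anova(m[1, ], design$group)
  expect_equal(out$F, oracle$F)
  expect_equal(out$p, oracle$p)
  expect_equal(out$F, 150)  # hand value: (1.5/1) / (0.04/4)
})

test_that("anova_de handles constant and degenerate rows as documented", {
  m <- rbind(
    flat = rep(5, 6),
    equal_means = c(1, 2, 3, 1, 2, 3),
    degenerate = c(1, 1, 1, 2, 2, 2)
  )
  colnames(m) <- paste0("s", 1:6)
  design <- tibble::tibble(sample = paste0("s", 1:6),
                           group = rep(c("a", "b"), each = 3))
  out <- suppressMessages(anova_de(make_expr(m), design))
  expect_equal(out$F[1], 0)
  expect_equal(out$p[1], 1)
  expect_equal(out$F[2], 0)
  expect_equal(out$F[3], Inf)
  expect_equal(out$p[3], .Machine$double.xmin)
  expect_error(anova_de(make_expr(m[, 1:3]),
                        tibble::tibble(sample = paste0("s", 1:3),
                                       group = c("a", "a", "b"))),
               "two samples")
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:6, 2, replace = TRUE)
    v <- c(rnorm(n[1]), rnorm(n[2], mean = 0.5))
    g <- rep(c("a", "b"), n)
    m <- matrix(v, 1, dimnames = list("g", paste0("s", seq_along(v))))
    out <- anova_de(make_expr(m), tibble::tibble(sample = colnames(m), group = g))
    tt <- t.test(v ~ g, var.equal = TRUE)
    expect_equal(out$F, unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("bh_fdr reproduces hand step-up values and its invariants", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(c(0.04, 0.01)), c(0.04, 0.02))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(1)
  p <- runif(30)
  q <- bh_fdr(p)
  expect_true(all(q >= p), info = "q >= p elementwise")
  perm <- sample(30)
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_equal(q, oracle_bh(p))
})

test_that("DE calling applies inclusive fold and q thresholds", {
  de <- tibble::tibble(
    gene = c("boundary", "low_fc", "high_q"),
    fc = c(1.2, 1.19, 5.0),
    q = c(0.05, 0.001, 0.06)
  )
  out <- call_de_genes(de)
  expect_equal(out$is_de, c(TRUE, FALSE, FALSE))
  expect_true(call_de_genes(tibble::tibble(gene = "d", fc = -1.3, q = 0.01))$is_de)
})

test_that("comparative Ct quantification follows 2^-ddCt", {
  expect_equal(delta_delta_ct(20, 15, 21, 15), 2)
  expect_equal(delta_delta_ct(20, 15, 20, 15), 1)
  expect_equal(delta_delta_ct(22, 15, 20, 15), 0.25)
  expect_error(delta_delta_ct(Inf, 15, 20, 15), "finite")
})

test_that("planted DE genes are recovered with high sensitivity and low FDR", {
  stats <- vapply(1:20, function(s) {
    sim <- generate_expression_experiment(
      n_genes = 300, n_de = 30, replicates = 3,
      fold_range = c(2, 6), sigma = 0.1, seed = s
    )
    de <- suppressMessages(
      de_table(sim$data, sim$design, contrast = "high_dose", reference = "control")
    )
    called <- de$gene[de$is_de]
    planted <- sim$truth$gene[sim$truth$planted]
    c(sens = mean(planted %in% called),
      fdr = if (length(called)) mean(!called %in% planted) else 0)
  }, numeric(2))
  expect_gte(mean(stats["sens", ]), 0.9)
  expect_lte(mean(stats["fdr", ]), 0.1)
})
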