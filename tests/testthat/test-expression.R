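test_that("the variation filter keeps genes by deviating-sample fraction", {
  m <- rbind(
    flat = rep(5, 10),
    boundary = c(rep(10, 8), 16, 4),       # 2/10 deviate -> kept (inclusive)
    weak = c(rep(10, 9), 16),              # 1/10 deviates -> removed
    strong = c(rep(1, 5), rep(10, 5))
  )
  colnames(m) <- paste0("s", 1:10)
  coh <- expression_cohort(m, driver = rnorm(10))
  filt <- filter_variable_genes(coh, fold = 1.5, min_frac = 0.2)
  expect_setequal(filt$genes, c("boundary", "strong"))
  expect_equal(filt$samples, coh$samples)

  # subset of the input, and idempotent
  twice <- filter_variable_genes(filt, fold = 1.5, min_frac = 0.2)
  expect_identical(twice$genes, filt$genes)
})

test_that("zero-median genes are assessed with a pseudocount", {
  m <- rbind(
    mostly_zero = c(rep(0, 8), 50, 60),    # on-off expression: kept
    all_zero = rep(0, 10)                  # constant: removed
  )
  colnames(m) <- paste0("s", 1:10)
  coh <- expression_cohort(m, driver = rnorm(10))
  filt <- filter_variable_genes(coh)
  expect_identical(filt$genes, "mostly_zero")
})

test_that("Spearman screen matches hand-ranked correlations", {
  driver <- c(1, 2, 3, 4, 5)
  m <- rbind(
    perfect_neg = exp(-driver),            # strictly decreasing -> rho -1
    shuffled = c(2, 1, 4, 3, 5),           # sum(d^2) = 4 -> rho = 0.8
    constant = rep(3, 5)
  )
  colnames(m) <- paste0("s", 1:5)
  coh <- expression_cohort(m, driver = driver)
  res <- spearman_screen(coh, sign = "any")
  expect_equal(res$rho[res$gene == "perfect_neg"], -1)
  expect_equal(res$rho[res$gene == "shuffled"], 0.8)
  expect_true(res$constant_flag[res$gene == "constant"])
  expect_equal(res$p[res$gene == "constant"], 1)
  expect_true(all(res$p_adjusted >= res$p))
})

test_that("small-sample p-values agree with the reference exact test", {
  driver <- c(3, 1, 4, 1.5, 5, 9, 2.6)
  g <- c(2.7, 1.8, 2.8, 1.2, 8.2, 8.4, 5.9)
  coh <- expression_cohort(matrix(g, 1, dimnames = list("g1", NULL)),
                           driver = driver)
  res <- spearman_screen(coh, sign = "any")
  ref <- stats::cor.test(driver, g, method = "spearman", exact = TRUE)
  expect_equal(res$rho, unname(ref$estimate))
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
})

test_that("large-sample p-values follow the t approximation", {
  set.seed(5)
  driver <- rnorm(40)
  g <- exp(-0.5 * driver + rnorm(40))
  coh <- expression_cohort(matrix(g, 1, dimnames = list("g1", NULL)), driver)
  res <- spearman_screen(coh, sign = "any")
  rho <- unname(stats::cor(driver, g, method = "spearman"))
  tt <- rho * sqrt((40 - 2) / (1 - rho^2))
  expect_equal(res$rho, rho)
  expect_equal(res$p, 2 * stats::pt(-abs(tt), 38))
})

test_that("rho is invariant under monotone transforms of either side", {
  set.seed(9)
  driver <- rnorm(25)
  g <- exp(-driver + rnorm(25, sd = 0.5))
  coh1 <- expression_cohort(matrix(g, 1, dimnames = list("g", NULL)), driver)
  coh2 <- expression_cohort(matrix(g^3, 1, dimnames = list("g", NULL)),
                            exp(driver))
  r1 <- spearman_screen(coh1, "any")
  r2 <- spearman_screen(coh2, "any")
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$p, r2$p)
})

test_that("requested sign gates the pass verdict", {
  coh <- simulate_expression_cohort(n_genes = 100, n_samples = 100,
                                    n_planted = 10, planted_rho = -0.6,
                                    seed = 3)
  res_neg <- spearman_screen(coh, "negative")
  res_pos <- spearman_screen(coh, "positive")
  expect_true(all(res_neg$rho[res_neg$passes] < 0))
  expect_true(all(res_pos$rho[res_pos$passes] > 0))
  expect_true(sum(res_neg$passes) > 0)
  # a planted negative cohort yields no positive passes
  expect_equal(sum(res_pos$passes), 0)
})

test_that("lentiviral concordance keeps cohort-confirmed decreasing genes", {
  expr <- rbind(
    concordant = c(10, 6, 2),   # decreasing with level -1 < 0 < 1? see below
    flat = c(5, 5, 5),
    unconfirmed = c(9, 5, 1)
  )
  # columns: knock-down (-1), control (0), over-expression (1);
  # expression decreasing as the level rises = negative association
  levels <- c(-1, 0, 1)
  cohort_results <- data.frame(
    gene = c("concordant", "flat", "other"),
    passes = c(TRUE, TRUE, TRUE), stringsAsFactors = FALSE)
  out <- lentiviral_concordance(expr, levels, cohort_results)
  expect_identical(out, "concordant")

  expect_error(lentiviral_concordance(expr, c(0, 0, 1), cohort_results),
               "levels")
})

test_that("candidate-target intersection is case-normalized set semantics", {
  expect_identical(intersect_candidate_targets(c("A", "B"), c("C", "D")),
                   character(0))
  expect_identical(intersect_candidate_targets(c("a", "B", "c"),
                                               c("B", "C", "D")),
                   c("B", "C"))
  expect_identical(intersect_candidate_targets(c("PIK3R2", "pik3r2", "AKT2"),
                                               c("PIK3R2")),
                   "PIK3R2")
})

test_that("expression tables round-trip through TSV", {
  coh <- simulate_expression_cohort(20, 8, 5, -0.5, seed = 2)
  mpath <- withr::local_tempfile(fileext = ".tsv")
  dpath <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene = coh$genes, coh$values, check.names = FALSE)
  utils::write.table(df, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(sample = coh$samples, value = coh$driver),
                     dpath, sep = "\t", row.names = FALSE, quote = FALSE)
  m <- read_expression_matrix(mpath)
  d <- read_driver_vector(dpath)
  expect_equal(unname(m), unname(coh$values), tolerance = 1e-10)
  expect_equal(unname(d), coh$driver, tolerance = 1e-10)
  expect_identical(rownames(m), coh$genes)
})
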