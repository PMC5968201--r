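#' Construct an expression cohort
#'
#' A genes x samples expression matrix paired with a per-sample driver
#' vector (a miRNA's expression, or coded condition levels), the container
#' consumed by the variation filter and the correlation screen.
#'
#' @param values numeric matrix, genes in rows, samples in columns; row and
#'   column names are the gene and sample identifiers.
#' @param driver numeric vector, one value per sample.
#' @param planted optional character vector of planted gene identifiers
#'   (carried by the synthetic generator for benchmarking).
#' @return object of class `expression_cohort`.
#' @export
expression_cohort <- function(values, driver, planted = NULL) {
  values <- as.matrix(values)
  if (nrow(values) == 0 || ncol(values) == 0)
    stop("validation error: empty expression matrix", call. = FALSE)
  if (length(driver) != ncol(values))
    stop("validation error: driver length (", length(driver),
         ") != number of samples (", ncol(values), ")", call. = FALSE)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  if (any(values < 0))
    stop("validation error: negative expression values", call. = FALSE)
  structure(list(values = values, driver = as.numeric(driver),
                 genes = rownames(values), samples = colnames(values),
                 planted = planted),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("Expression cohort:", length(x$genes), "genes x",
      length(x$samples), "samples\n")
  if (!is.null(x$planted))
    cat("  (synthetic; ", length(x$planted), " planted genes)\n", sep = "")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' First column holds gene identifiers, remaining columns are samples.
#'
#' @param path TSV path.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a per-sample driver vector from a 2-column TSV (sample, value)
#'
#' @param path TSV path.
#' @return named numeric vector.
#' @export
read_driver_vector <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}

#' Read a gene list (one identifier per line)
#'
#' @param path file path.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Filter out low-variation genes
#'
#' Keeps a gene only if at least `min_frac` of its samples show at least a
#' `fold`-fold change in either direction from the gene's median (value
#' >= fold * median or value <= median / fold, boundary inclusive). Genes
#' with a zero median are assessed after adding the smallest positive value
#' of the matrix as a pseudocount, keeping the ratio rule total on
#' count-like data.
#'
#' @param cohort an [expression_cohort()].
#' @param fold fold-change threshold, > 1 (default 1.5).
#' @param min_frac minimum deviating-sample fraction, in (0, 1] (default
#'   0.2).
#' @return a new `expression_cohort` with the surviving genes; samples and
#'   driver unchanged.
#' @export
filter_variable_genes <- function(cohort, fold = 1.5, min_frac = 0.2) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (!(fold > 1)) stop("validation error: fold must be > 1", call. = FALSE)
  if (!(min_frac > 0 && min_frac <= 1))
    stop("validation error: min_frac must be in (0, 1]", call. = FALSE)
  v <- cohort$values
  pos <- v[v > 0]
  pseudo <- if (length(pos) > 0) min(pos) else 1
  med <- apply(v, 1, stats::median)
  zero <- med == 0
  vv <- v
  if (any(zero)) {
    vv[zero, ] <- v[zero, , drop = FALSE] + pseudo
    med[zero] <- med[zero] + pseudo
  }
  deviating <- (vv >= fold * med) | (vv <= med / fold)
  frac <- rowMeans(deviating)
  keep <- frac >= min_frac
  if (!any(keep)) {
    warning("no genes pass the variation filter")
  }
  out <- cohort
  out$values <- cohort$values[keep, , drop = FALSE]
  out$genes <- rownames(out$values)
  if (!is.null(out$planted)) out$planted <- intersect(out$planted, out$genes)
  out
}

# all permutations of 1..n as an n!-row matrix (used by the exact
# Spearman null at toy sample sizes only)
.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- cbind(k, matrix(rest[sub], nrow = nrow(sub)))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

.standardize <- function(v) {
  s <- stats::sd(v)
  if (s == 0) return(rep(NA_real_, length(v)))
  (v - mean(v)) / s
}

#' Genome-wide Spearman correlation screen against the driver
#'
#' Computes each gene's Spearman correlation (mid-ranks for ties) with the
#' cohort's driver, a two-sided p-value (t approximation; exact permutation
#' null when there are at most `exact_n` samples), and the
#' Bonferroni-adjusted p-value with multiplier equal to the number of genes
#' screened. A gene passes when its adjusted p-value is below `alpha` and
#' its correlation has the requested sign. Constant genes have no defined
#' correlation and are reported with `rho = NA`, `p = 1` and a flag.
#'
#' @param cohort an [expression_cohort()], normally already passed through
#'   [filter_variable_genes()].
#' @param sign `"negative"`, `"positive"` or `"any"` required sign of rho.
#' @param alpha family-wise threshold on the adjusted p-value.
#' @param exact_n largest sample count for which the exact permutation
#'   null (all n! driver permutations) replaces the t approximation.
#' @return data frame: `gene, rho, p, p_adjusted, passes, constant_flag`,
#'   in cohort gene order.
#' @export
spearman_screen <- function(cohort, sign = c("negative", "positive", "any"),
                            alpha = 0.05, exact_n = 9) {
  sign <- match.arg(sign)
  stopifnot(inherits(cohort, "expression_cohort"))
  n <- length(cohort$samples)
  if (n < 4) stop("validation error: need >= 4 samples", call. = FALSE)
  if (stats::sd(cohort$driver) == 0)
    stop("validation error: constant driver", call. = FALSE)

  rd <- rank(cohort$driver)
  gene_ranks <- t(apply(cohort$values, 1, rank))
  gene_std <- t(apply(gene_ranks, 1, .standardize))
  rd_std <- .standardize(rd)
  rho <- as.vector(gene_std %*% rd_std) / (n - 1)
  constant <- apply(cohort$values, 1, function(g) stats::sd(g) == 0)
  rho[constant] <- NA_real_

  if (n <= exact_n) {
    perms <- .all_permutations(n)
    perm_std <- matrix(rd_std[perms], nrow = nrow(perms))
    p <- vapply(seq_len(nrow(gene_std)), function(i) {
      if (constant[i]) return(1)
      null_rho <- as.vector(perm_std %*% gene_std[i, ]) / (n - 1)
      mean(abs(null_rho) >= abs(rho[i]) - 1e-12)
    }, numeric(1))
  } else {
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p[constant] <- 1
  }
  n_tested <- nrow(cohort$values)
  p_adj <- pmin(1, p * n_tested)
  sign_ok <- switch(sign,
                    negative = !is.na(rho) & rho < 0,
                    positive = !is.na(rho) & rho > 0,
                    any = !is.na(rho))
  data.frame(gene = cohort$genes, rho = rho, p = p, p_adjusted = p_adj,
             passes = sign_ok & p_adj < alpha, constant_flag = constant,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Lentiviral concordance filter
#'
#' Orients each gene's response to the miRNA across coded lentiviral
#' conditions (1 = over-expression, -1 = knock-down, 0 = control) and keeps
#' the genes whose expression decreases with the level (negative Spearman
#' association) AND that already pass the cohort correlation screen. With
#' only three coded levels this is a concordance filter, not an inference
#' procedure.
#'
#' @param expression_by_condition numeric matrix, genes in rows, one column
#'   per lentiviral sample.
#' @param levels numeric vector of condition codes per column; all of
#'   {-1, 0, 1} must be present.
#' @param cohort_results data frame from [spearman_screen()].
#' @return sorted character vector of concordant genes.
#' @export
lentiviral_concordance <- function(expression_by_condition, levels,
                                   cohort_results) {
  m <- as.matrix(expression_by_condition)
  if (length(levels) != ncol(m))
    stop("validation error: one level code per column required",
         call. = FALSE)
  if (!all(c(-1, 0, 1) %in% levels))
    stop("validation error: levels must include all of -1, 0, 1",
         call. = FALSE)
  rl <- rank(levels)
  rho <- apply(m, 1, function(g) {
    if (stats::sd(g) == 0) return(NA_real_)
    stats::cor(rank(g), rl)
  })
  concordant <- rownames(m)[!is.na(rho) & rho < 0]
  cohort_pass <- cohort_results$gene[cohort_results$passes]
  sort(intersect(concordant, cohort_pass))
}

#' Intersect predicted miRNA targets with a cancer gene list
#'
#' Case-normalized set intersection (duplicates collapse), sorted.
#'
#' @param predicted_targets character vector of predicted target genes.
#' @param cancer_genes character vector of cancer census genes.
#' @return sorted character vector of the shared genes (upper case).
#' @export
intersect_candidate_targets <- function(predicted_targets, cancer_genes) {
  a <- unique(toupper(trimws(predicted_targets)))
  b <- unique(toupper(trimws(cancer_genes)))
  sort(intersect(a, b))
}
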