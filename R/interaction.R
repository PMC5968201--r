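#' Exact Mann-Whitney rank-sum p-value
#'
#' Two-sample rank-sum test with mid-ranks for ties. When the number of
#' group labelings `choose(n + m, n)` is at most `exact_limit`, the p-value
#' is exact: every labeling of the pooled observations is enumerated, so
#' ties need no correction terms. Above the limit a normal approximation
#' with tie and continuity corrections is used. The two-sided p-value is
#' `min(1, 2 * min(one-sided p's))`.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param alternative `"two_sided"` (default), `"less"` (x shifted below y)
#'   or `"greater"`.
#' @param exact_limit largest number of labelings enumerated exactly; the
#'   default keeps all plate-scale groups (n = m = 6 gives 924) on the
#'   exact path.
#' @return the p-value.
#' @export
rank_sum_p <- function(x, y,
                       alternative = c("two_sided", "less", "greater"),
                       exact_limit = 50000) {
  alternative <- match.arg(alternative)
  if (length(x) < 1 || length(y) < 1)
    stop("validation error: empty group", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("validation error: non-finite values", call. = FALSE)
  n <- length(x)
  m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)  # mid-ranks
  w_obs <- sum(r[seq_len(n)])
  eps <- 1e-9

  if (choose(n + m, n) <= exact_limit) {
    combos <- utils::combn(n + m, n)
    w_all <- colSums(matrix(r[combos], nrow = n))
    p_greater <- mean(w_all >= w_obs - eps)
    p_less <- mean(w_all <= w_obs + eps)
  } else {
    mu <- n * (n + m + 1) / 2
    tie_tab <- table(r)
    nn <- n + m
    sigma2 <- n * m / 12 *
      ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    sigma <- sqrt(sigma2)
    p_greater <- stats::pnorm((w_obs - mu - 0.5) / sigma, lower.tail = FALSE)
    p_less <- stats::pnorm((w_obs - mu + 0.5) / sigma)
  }
  switch(alternative,
         two_sided = min(1, 2 * min(p_less, p_greater)),
         less = p_less,
         greater = p_greater)
}

#' Bonferroni-corrected per-comparison alpha
#'
#' Divides the family-wise critical value (default 0.05) by the number of
#' comparisons in the experiment. Returned at full precision: printed
#' thresholds like 0.007 (for n = 7) or 0.017 (for n = 3) are display
#' roundings and verdicts compare against the unrounded value.
#'
#' @param n_comparisons number of comparisons in the family, >= 1.
#' @param family_alpha family-wise error rate.
#' @return the per-comparison alpha.
#' @export
bonferroni_alpha <- function(n_comparisons, family_alpha = 0.05) {
  if (!is.numeric(n_comparisons) || n_comparisons < 1 ||
      n_comparisons != round(n_comparisons))
    stop("validation error: n_comparisons must be a positive integer",
         call. = FALSE)
  family_alpha / n_comparisons
}

#' Construct a four-arm combination experiment
#'
#' Holds the replicate-well signals of the untreated, miRNA-only, drug-only
#' and combination arms of one (cell line, miRNA, drug) experiment.
#'
#' @param untreated,mirna_only,drug_only,combination numeric signal vectors,
#'   each of length >= 2, all values >= 0.
#' @param cell_line,mirna,drug optional identifiers.
#' @return object of class `arm_set`.
#' @export
arm_set <- function(untreated, mirna_only, drug_only, combination,
                    cell_line = NA_character_, mirna = NA_character_,
                    drug = NA_character_) {
  arms <- list(untreated = untreated, mirna_only = mirna_only,
               drug_only = drug_only, combination = combination)
  for (nm in names(arms)) {
    a <- arms[[nm]]
    if (length(a) < 2)
      stop("validation error: arm '", nm, "' has fewer than 2 wells",
           call. = FALSE)
    if (!all(is.finite(a)) || any(a < 0))
      stop("validation error: arm '", nm, "' has negative or non-finite ",
           "signals", call. = FALSE)
  }
  structure(c(arms, list(cell_line = cell_line, mirna = mirna, drug = drug)),
            class = "arm_set")
}

#' Call a miRNA/drug true interaction
#'
#' The three-way conjunction rule: the combination arm is compared with the
#' miRNA-only, drug-only and untreated arms by two-sided exact rank-sum
#' tests. The pair is a true interaction only if all three p-values fall
#' below the Bonferroni-corrected alpha AND the combination's median signal
#' lies strictly below the medians of all three other arms (the direction
#' check, so antagonism is never labeled an interaction).
#'
#' @param arms an [arm_set()].
#' @param alpha per-comparison significance threshold, typically from
#'   [bonferroni_alpha()].
#' @return list of class `interaction_call` with the three p-values,
#'   `alpha`, `direction_ok`, `is_true_interaction`, and
#'   `relaxed_all_p05` (all three p < 0.05, the exploratory criterion).
#' @export
call_interaction <- function(arms, alpha) {
  stopifnot(inherits(arms, "arm_set"), is.numeric(alpha), alpha > 0)
  p_mirna <- rank_sum_p(arms$mirna_only, arms$combination)
  p_drug <- rank_sum_p(arms$drug_only, arms$combination)
  p_untreated <- rank_sum_p(arms$untreated, arms$combination)
  med_comb <- stats::median(arms$combination)
  direction_ok <- med_comb < min(stats::median(arms$mirna_only),
                                 stats::median(arms$drug_only),
                                 stats::median(arms$untreated))
  all_sig <- p_mirna < alpha && p_drug < alpha && p_untreated < alpha
  structure(
    list(cell_line = arms$cell_line, mirna = arms$mirna, drug = arms$drug,
         p_mirna_vs_comb = p_mirna,
         p_drug_vs_comb = p_drug,
         p_untreated_vs_comb = p_untreated,
         alpha = alpha,
         direction_ok = direction_ok,
         is_true_interaction = all_sig && direction_ok,
         relaxed_all_p05 = p_mirna < 0.05 && p_drug < 0.05 &&
           p_untreated < 0.05 && direction_ok),
    class = "interaction_call"
  )
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("Interaction call: %s + %s [%s]\n",
              ifelse(is.na(x$mirna), "miRNA", x$mirna),
              ifelse(is.na(x$drug), "drug", x$drug),
              ifelse(is.na(x$cell_line), "-", x$cell_line)))
  cat(sprintf("  p(miRNA vs comb)     = %.5f\n", x$p_mirna_vs_comb))
  cat(sprintf("  p(drug vs comb)      = %.5f\n", x$p_drug_vs_comb))
  cat(sprintf("  p(untreated vs comb) = %.5f\n", x$p_untreated_vs_comb))
  cat(sprintf("  alpha = %.5g, direction_ok = %s\n", x$alpha, x$direction_ok))
  cat(sprintf("  TRUE INTERACTION: %s\n", x$is_true_interaction))
  invisible(x)
}

#' Test a single miRNA's effect against untreated cells
#'
#' Two-sided rank-sum test of the miRNA-only arm against the untreated arm,
#' judged at the Bonferroni alpha for the experiment's miRNA comparisons.
#'
#' @param untreated,mirna_only numeric signal vectors, length >= 2 each.
#' @param alpha significance threshold.
#' @return list with `p` and `significant`.
#' @export
call_single_mirna_effect <- function(untreated, mirna_only, alpha) {
  p <- rank_sum_p(untreated, mirna_only)
  list(p = p, significant = p < alpha)
}

#' Run all interaction calls of one experiment family
#'
#' For each (miRNA, drug) pair in the design, extracts the four arms from
#' the records of the design's cell line, computes the three-way interaction
#' call at `alpha = family_alpha / n_drug_comparisons`, and the single-agent
#' miRNA tests at `alpha = family_alpha / n_mirna_comparisons`.
#'
#' @param records validated viability records (ALAMAR combination assay).
#' @param design an [experiment_design()].
#' @param family_alpha family-wise critical value (default 0.05).
#' @return list with `interactions` (one row per pair: the three p-values,
#'   alpha, direction and verdict columns) and `single_mirna` (one row per
#'   miRNA: p, alpha, significant).
#' @export
run_interaction_family <- function(records, design, family_alpha = 0.05) {
  stopifnot(inherits(design, "experiment_design"))
  validate_viability(records)
  arms_by_key <- group_arms(records, design$cell_line)
  get_arm <- function(mirna, drug, mirna_id, drug_id) {
    key <- paste(mirna, drug, sep = "|")
    a <- arms_by_key[[key]]
    if (is.null(a))
      stop("missing arm: no wells for (", design$cell_line, ", ",
           mirna_id, ", ", drug_id, ")", call. = FALSE)
    a
  }
  alpha_int <- bonferroni_alpha(design$n_drug_comparisons, family_alpha)
  alpha_mir <- bonferroni_alpha(design$n_mirna_comparisons, family_alpha)

  rows <- list()
  for (mir in design$mirnas) {
    for (drg in design$drugs) {
      arms <- arm_set(
        untreated = get_arm("NONE", "NONE", "untreated", "none"),
        mirna_only = get_arm(mir, "NONE", mir, "none"),
        drug_only = get_arm("NONE", drg, "none", drg),
        combination = get_arm(mir, drg, mir, drg),
        cell_line = design$cell_line, mirna = mir, drug = drg
      )
      cl <- call_interaction(arms, alpha_int)
      rows[[length(rows) + 1]] <- data.frame(
        cell_line = design$cell_line, mirna = mir, drug = drg,
        p_mirna_vs_comb = cl$p_mirna_vs_comb,
        p_drug_vs_comb = cl$p_drug_vs_comb,
        p_untreated_vs_comb = cl$p_untreated_vs_comb,
        alpha = cl$alpha, direction_ok = cl$direction_ok,
        is_true_interaction = cl$is_true_interaction,
        relaxed_all_p05 = cl$relaxed_all_p05,
        stringsAsFactors = FALSE)
    }
  }
  single <- lapply(design$mirnas, function(mir) {
    res <- call_single_mirna_effect(
      get_arm("NONE", "NONE", "untreated", "none"),
      get_arm(mir, "NONE", mir, "none"),
      alpha_mir)
    data.frame(cell_line = design$cell_line, mirna = mir, p = res$p,
               alpha = alpha_mir, significant = res$significant,
               stringsAsFactors = FALSE)
  })
  list(interactions = do.call(rbind, rows),
       single_mirna = do.call(rbind, single))
}
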