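# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("validation error: seed must be a single finite number",
         call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# lognormal sigma giving a multiplicative noise term with mean 1 and the
# requested coefficient of variation
.lognorm_sigma <- function(noise_cv) sqrt(log(1 + noise_cv^2))

.lognorm_noise <- function(n, noise_cv) {
  if (noise_cv == 0) return(rep(1, n))
  sigma <- .lognorm_sigma(noise_cv)
  exp(stats::rnorm(n, mean = -sigma^2 / 2, sd = sigma))
}

#' Configure a synthetic single-agent MTS screen
#'
#' @param n_mirnas number of miRNAs screened (default 38).
#' @param n_cell_lines number of cell lines (default 12).
#' @param wells_per_mirna replicate wells per miRNA per line (default 4,
#'   quadruplicates).
#' @param effect_map data frame with columns `mirna`, `cell_line`, `effect`
#'   giving multiplicative viability effects (1 = none) for planted
#'   miRNA/line combinations; `NULL` means no planted effects.
#' @param noise_cv coefficient of variation of well-level multiplicative
#'   log-normal noise.
#' @param baseline_signal expected OD of an unaffected well.
#' @return list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_mirnas = 38, n_cell_lines = 12,
                              wells_per_mirna = 4, effect_map = NULL,
                              noise_cv = 0.1, baseline_signal = 1) {
  stopifnot(n_mirnas >= 1, n_cell_lines >= 1, wells_per_mirna >= 1,
            noise_cv >= 0, baseline_signal > 0)
  if (!is.null(effect_map)) {
    stopifnot(is.data.frame(effect_map),
              all(c("mirna", "cell_line", "effect") %in% names(effect_map)))
    if (any(effect_map$effect <= 0))
      stop("validation error: effects must be > 0", call. = FALSE)
  }
  structure(list(n_mirnas = n_mirnas, n_cell_lines = n_cell_lines,
                 wells_per_mirna = wells_per_mirna, effect_map = effect_map,
                 noise_cv = noise_cv, baseline_signal = baseline_signal),
            class = "screen_sim_config")
}

#' Default synthetic screen: 38 miRNAs x 12 lines with 6 planted effects
#'
#' The default study conditions: quadruplicate wells, 10% well-level CV,
#' and six planted miRNAs acting in every cell line -- three
#' anti-proliferative (effect 0.5) and three proliferative (effect 1.5),
#' balanced so the per-line ratio median stays near 1.
#'
#' @return a `screen_sim_config` whose `effect_map` carries the planted
#'   truth; planted identifiers are `miR-01`..`miR-06`.
#' @export
default_screen_config <- function() {
  mirnas <- sprintf("miR-%02d", 1:6)
  lines <- sprintf("CL-%02d", 1:12)
  em <- expand.grid(mirna = mirnas, cell_line = lines,
                    stringsAsFactors = FALSE)
  em$effect <- ifelse(em$mirna %in% sprintf("miR-%02d", 1:3), 0.5, 1.5)
  screen_sim_config(effect_map = em)
}

#' Simulate a single-agent MTS viability screen
#'
#' Each well's signal is `baseline * effect * noise` with mean-preserving
#' multiplicative log-normal noise, so a planted effect equals the expected
#' viability ratio.
#'
#' @param config a [screen_sim_config()].
#' @param seed RNG seed; the output is a deterministic function of
#'   (config, seed).
#' @return validated viability record data frame (assay `"MTS"`); miRNA
#'   identifiers `miR-01`.. and cell lines `CL-01`...
#' @export
simulate_mts_screen <- function(config = default_screen_config(), seed = 1) {
  stopifnot(inherits(config, "screen_sim_config"))
  mirnas <- sprintf("miR-%02d", seq_len(config$n_mirnas))
  lines <- sprintf("CL-%02d", seq_len(config$n_cell_lines))
  grid <- expand.grid(well_id = seq_len(config$wells_per_mirna),
                      mirna = mirnas, cell_line = lines,
                      stringsAsFactors = FALSE)
  effect <- rep(1, nrow(grid))
  if (!is.null(config$effect_map)) {
    key <- paste(grid$mirna, grid$cell_line)
    ekey <- paste(config$effect_map$mirna, config$effect_map$cell_line)
    idx <- match(key, ekey)
    effect[!is.na(idx)] <- config$effect_map$effect[idx[!is.na(idx)]]
  }
  noise <- .with_seed(seed, .lognorm_noise(nrow(grid), config$noise_cv))
  rec <- data.frame(
    cell_line = grid$cell_line, mirna = grid$mirna, drug = NA_character_,
    dose = 0, repeat_id = 1L, well_id = grid$well_id, assay = "MTS",
    signal = config$baseline_signal * effect * noise,
    stringsAsFactors = FALSE)
  validate_viability(rec)
  rec
}

#' Simulate a dose-response titration from known 4PL truth
#'
#' Responses are the 4PL curve plus additive Gaussian noise, truncated at
#' zero.
#'
#' @param true_fit list or `dose_response_fit` with `top`, `bottom`, `ic50`,
#'   `hill` (and optionally `cell_line`, `drug`).
#' @param doses concentrations in molar, e.g. from [make_dilution_series()].
#' @param noise_sd additive noise standard deviation (response units).
#' @param seed RNG seed.
#' @param replicates wells per dose.
#' @return viability record data frame (assay `"ALAMAR"`).
#' @export
simulate_dose_response <- function(true_fit, doses, noise_sd = 0, seed = 1,
                                   replicates = 1) {
  stopifnot(all(doses > 0), noise_sd >= 0, replicates >= 1)
  for (f in c("top", "bottom", "ic50", "hill")) {
    if (is.null(true_fit[[f]]) || !is.finite(true_fit[[f]]))
      stop("validation error: true_fit missing field '", f, "'",
           call. = FALSE)
  }
  if (true_fit$ic50 <= 0)
    stop("validation error: ic50 must be > 0", call. = FALSE)
  d <- rep(doses, each = replicates)
  mu <- four_pl(d, true_fit$top, true_fit$bottom, true_fit$ic50,
                true_fit$hill)
  y <- if (noise_sd > 0) {
    .with_seed(seed, pmax(0, mu + stats::rnorm(length(mu), 0, noise_sd)))
  } else mu
  rec <- data.frame(
    cell_line = if (is.null(true_fit$cell_line) || is.na(true_fit$cell_line))
      "CL-01" else true_fit$cell_line,
    mirna = NA_character_,
    drug = if (is.null(true_fit$drug) || is.na(true_fit$drug)) "drug-01"
      else true_fit$drug,
    dose = d, repeat_id = 1L,
    well_id = seq_along(d), assay = "ALAMAR", signal = y,
    stringsAsFactors = FALSE)
  validate_viability(rec)
  rec
}

#' Configure a synthetic four-arm combination experiment
#'
#' @param mirna_effect,drug_effect,combo_effect multiplicative viability
#'   effects of the single agents and of the combination arm (all > 0;
#'   a planted interaction means `combo_effect` below both singles).
#' @param wells_per_arm replicate wells per arm (default 6: duplicates in
#'   three experiment repeats, pooled).
#' @param noise_cv well-level multiplicative log-normal CV.
#' @param baseline_signal expected untreated signal (percent reduction
#'   scale).
#' @return list of class `combo_sim_config`.
#' @export
combo_sim_config <- function(mirna_effect = 0.8, drug_effect = 0.8,
                             combo_effect = 0.4, wells_per_arm = 6,
                             noise_cv = 0.05, baseline_signal = 100) {
  if (any(c(mirna_effect, drug_effect, combo_effect) <= 0))
    stop("validation error: effects must be > 0", call. = FALSE)
  stopifnot(wells_per_arm >= 2, noise_cv >= 0, baseline_signal > 0)
  structure(list(mirna_effect = mirna_effect, drug_effect = drug_effect,
                 combo_effect = combo_effect, wells_per_arm = wells_per_arm,
                 noise_cv = noise_cv, baseline_signal = baseline_signal),
            class = "combo_sim_config")
}

#' Simulate a four-arm miRNA/drug combination experiment
#'
#' @param config a [combo_sim_config()].
#' @param seed RNG seed.
#' @return an [arm_set()] with `wells_per_arm` signals per arm.
#' @export
simulate_combination <- function(config = combo_sim_config(), seed = 1) {
  stopifnot(inherits(config, "combo_sim_config"))
  n <- config$wells_per_arm
  eff <- c(untreated = 1, mirna_only = config$mirna_effect,
           drug_only = config$drug_effect, combination = config$combo_effect)
  sig <- .with_seed(seed, {
    noise <- .lognorm_noise(4 * n, config$noise_cv)
    config$baseline_signal * rep(unname(eff), each = n) * noise
  })
  arm_set(untreated = sig[1:n],
          mirna_only = sig[(n + 1):(2 * n)],
          drug_only = sig[(2 * n + 1):(3 * n)],
          combination = sig[(3 * n + 1):(4 * n)],
          cell_line = "CL-01", mirna = "miR-01", drug = "drug-01")
}

#' Simulate an expression cohort with planted driver-correlated genes
#'
#' The driver is standard normal. Planted genes are generated through a
#' Gaussian copula calibrated so their population Spearman correlation with
#' the driver equals `planted_rho` (Pearson latent correlation
#' `2 * sin(pi * rho_s / 6)`); all other genes are independent noise. All
#' expression values are exponentiated (rank-preserving) so the matrix is
#' non-negative.
#'
#' @param n_genes total genes.
#' @param n_samples samples (driver length).
#' @param n_planted number of planted correlated genes (first rows).
#' @param planted_rho target Spearman correlation, |rho| < 1.
#' @param seed RNG seed.
#' @return an [expression_cohort()]; `$planted` names the planted genes.
#' @export
simulate_expression_cohort <- function(n_genes = 2000, n_samples = 300,
                                       n_planted = 50, planted_rho = -0.5,
                                       seed = 1) {
  if (n_genes < 1 || n_samples < 4)
    stop("validation error: need n_genes >= 1 and n_samples >= 4",
         call. = FALSE)
  if (n_planted > n_genes)
    stop("validation error: n_planted > n_genes", call. = FALSE)
  if (abs(planted_rho) >= 1)
    stop("validation error: |planted_rho| must be < 1", call. = FALSE)
  rho_p <- 2 * sin(pi * planted_rho / 6)
  sim <- .with_seed(seed, {
    z <- stats::rnorm(n_samples)
    latent <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes)
    if (n_planted > 0) {
      idx <- seq_len(n_planted)
      latent[idx, ] <- rho_p * matrix(z, nrow = n_planted, ncol = n_samples,
                                      byrow = TRUE) +
        sqrt(1 - rho_p^2) * latent[idx, , drop = FALSE]
    }
    list(z = z, latent = latent)
  })
  values <- exp(sim$latent)
  rownames(values) <- sprintf("gene_%04d", seq_len(n_genes))
  colnames(values) <- sprintf("sample_%03d", seq_len(n_samples))
  planted <- if (n_planted > 0) rownames(values)[seq_len(n_planted)] else
    character(0)
  expression_cohort(values, sim$z, planted = planted)
}
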