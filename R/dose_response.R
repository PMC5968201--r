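#' Build a serial-dilution dose series
#'
#' Descending geometric series `top_dose / factor^i`, i = 0..n_points-1,
#' matching plate-assay practice (e.g. an 8-point 5-fold series from
#' 100 uM ends at 1.28 nM). Endpoints and factor are explicit because not
#' every assay range is an integer power of one dilution factor.
#'
#' @param top_dose highest concentration (molar), > 0.
#' @param factor dilution factor between consecutive points, > 1.
#' @param n_points number of concentrations, >= 2.
#' @return numeric vector of concentrations in molar, descending.
#' @export
make_dilution_series <- function(top_dose, factor, n_points) {
  if (!is.numeric(top_dose) || top_dose <= 0)
    stop("validation error: top_dose must be > 0", call. = FALSE)
  if (!is.numeric(factor) || factor <= 1)
    stop("validation error: factor must be > 1", call. = FALSE)
  if (n_points < 2)
    stop("validation error: n_points must be >= 2", call. = FALSE)
  top_dose / factor^(seq_len(n_points) - 1)
}

#' Four-parameter logistic curve
#'
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)`. With `hill > 0`
#' the curve decreases in dose (an inhibition curve) and equals
#' `(top + bottom) / 2` exactly at `x = ic50` (relative IC50, the curve
#' midpoint).
#'
#' @param x dose (molar), > 0.
#' @param top,bottom upper and lower asymptotes (response units).
#' @param ic50 midpoint concentration (molar).
#' @param hill slope factor.
#' @return predicted response.
#' @export
four_pl <- function(x, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (x / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the 4PL inhibition model in log-dose via
#' Levenberg-Marquardt (minpack.lm) with box constraints: `bottom >= 0`,
#' `hill` in \[0.1, 10\], `ic50` within \[min(dose)/100, max(dose)*100\].
#' Starting values: top/bottom from the response extremes, ic50 at the dose
#' whose response is nearest the midpoint, hill = 1; on failure the fit is
#' restarted from hill in {0.5, 1, 2}.
#'
#' @param doses numeric vector of concentrations (molar), > 0.
#' @param responses numeric vector of viability responses, same length.
#' @param cell_line,drug optional identifiers carried into the result.
#' @return object of class `dose_response_fit`: a list with `top`, `bottom`,
#'   `ic50`, `hill`, `rss`, `converged`, `n`, plus the identifiers.
#' @export
fit_four_pl <- function(doses, responses, cell_line = NA_character_,
                        drug = NA_character_) {
  stopifnot(length(doses) == length(responses))
  if (!all(is.finite(doses)) || any(doses <= 0))
    stop("validation error: doses must be positive and finite", call. = FALSE)
  if (!all(is.finite(responses)))
    stop("validation error: responses must be finite", call. = FALSE)
  if (length(unique(doses)) < 4)
    stop("validation error: need >= 4 distinct doses", call. = FALSE)
  if (diff(range(responses)) == 0)
    stop("degenerate fit: all responses identical, no IC50 definable",
         call. = FALSE)

  ldose <- log(doses)
  top0 <- max(responses)
  bottom0 <- min(responses)
  mid <- (top0 + bottom0) / 2
  lic50_0 <- ldose[which.min(abs(responses - mid))]
  lower <- c(top = -Inf, bottom = 0, lic50 = log(min(doses)) - log(100),
             hill = 0.1)
  upper <- c(top = Inf, bottom = Inf, lic50 = log(max(doses)) + log(100),
             hill = 10)

  # fit on log(ic50) so the box constraint is symmetric on the dose scale
  model <- function(p, x) {
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + exp(p[["hill"]] * (x - p[["lic50"]])))
  }
  best <- NULL
  for (hill0 in c(1, 0.5, 2)) {
    start <- c(top = top0, bottom = max(bottom0, 0), lic50 = lic50_0,
               hill = hill0)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start,
        lower = lower, upper = upper,
        fn = function(p) responses - model(p, ldose),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ok <- fit$info %in% 1:4
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && ok && !best$converged)) {
      best <- list(par = fit$par, rss = rss, converged = ok)
    }
    if (!is.null(best) && best$converged && hill0 == 1) break
  }
  if (is.null(best)) {
    stop("fit failed: optimizer could not evaluate the model", call. = FALSE)
  }
  p <- best$par
  structure(
    list(cell_line = cell_line, drug = drug,
         top = unname(p[["top"]]), bottom = unname(p[["bottom"]]),
         ic50 = exp(unname(p[["lic50"]])), hill = unname(p[["hill"]]),
         rss = best$rss, converged = best$converged,
         n = length(doses)),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("4PL dose-response fit",
      if (!is.na(x$drug)) paste0("(", x$drug,
                                 if (!is.na(x$cell_line))
                                   paste0(" in ", x$cell_line), ")"),
      "\n")
  cat(sprintf("  top = %.4g, bottom = %.4g, hill = %.3g\n",
              x$top, x$bottom, x$hill))
  cat(sprintf("  IC50 = %.4g M (%.4g uM), rss = %.4g, converged = %s\n",
              x$ic50, x$ic50 * 1e6, x$rss, x$converged))
  invisible(x)
}

#' @export
predict.dose_response_fit <- function(object, doses, ...) {
  four_pl(doses, object$top, object$bottom, object$ic50, object$hill)
}

#' Working concentration under the 1 uM cap
#'
#' Applies the assay-design rule: the concentration carried into the
#' combination experiments is the fitted IC50, capped at 1 uM. An IC50 of
#' exactly the cap is not capped (the rule is "higher than").
#'
#' @param fit a `dose_response_fit`.
#' @param cap cap concentration in molar (default 1 uM).
#' @param override set `TRUE` to accept an unconverged fit.
#' @return list with `drug`, `cell_line`, `concentration` (molar), `capped`.
#' @export
working_concentration <- function(fit, cap = 1e-6, override = FALSE) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (!fit$converged && !override) {
    stop("unconverged fit: refusing to derive a working concentration ",
         "(set override = TRUE to force)", call. = FALSE)
  }
  capped <- fit$ic50 > cap
  list(drug = fit$drug, cell_line = fit$cell_line,
       concentration = if (capped) cap else fit$ic50,
       capped = capped)
}

#' Fit dose-response curves for every (cell line, drug) pair
#'
#' Groups ALAMAR (or any) dose-titration records by cell line and drug and
#' fits each series, returning the per-pair parameter table with working
#' concentrations.
#'
#' @param records validated viability records with dose titrations.
#' @param cap working-concentration cap in molar.
#' @return data frame: `cell_line, drug, top, bottom, ic50_molar, hill, rss,
#'   converged, working_concentration_molar, capped`.
#' @export
fit_all_dose_response <- function(records, cap = 1e-6) {
  validate_viability(records)
  sel <- !is.na(records$drug) & records$dose > 0 & is.na(records$mirna)
  sub <- records[sel, , drop = FALSE]
  if (nrow(sub) == 0) stop("no drug-titration records", call. = FALSE)
  groups <- split(sub, paste(sub$cell_line, sub$drug, sep = "\r"))
  rows <- lapply(groups, function(g) {
    fit <- fit_four_pl(g$dose, g$signal, cell_line = g$cell_line[1],
                       drug = g$drug[1])
    wc <- working_concentration(fit, cap = cap, override = TRUE)
    data.frame(cell_line = fit$cell_line, drug = fit$drug, top = fit$top,
               bottom = fit$bottom, ic50_molar = fit$ic50, hill = fit$hill,
               rss = fit$rss, converged = fit$converged,
               working_concentration_molar = wc$concentration,
               capped = wc$capped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cell_line, out$drug), , drop = FALSE]
}
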