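#' Per-miRNA viability ratios against the global transfection median
#'
#' For one cell line's MTS wells, computes each miRNA's mean signal over its
#' replicate wells and divides by the global median of all miRNA-transfected
#' wells of that line (controls and untransfected wells excluded).
#'
#' @param records validated viability record data frame.
#' @param cell_line cell line identifier.
#' @return data frame with columns `cell_line`, `mirna`, `n_wells`,
#'   `mean_signal`, `global_median`, `ratio`.
#' @export
summarize_ratios <- function(records, cell_line) {
  validate_viability(records)
  sel <- records$cell_line == cell_line &
    records$assay == "MTS" &
    !is.na(records$mirna) &
    records$mirna != "NEG_CONTROL" &
    is.na(records$drug)
  if (!any(sel)) {
    stop("no miRNA-transfected MTS wells for cell line '", cell_line, "'",
         call. = FALSE)
  }
  sub <- records[sel, , drop = FALSE]
  global_median <- stats::median(sub$signal)
  means <- tapply(sub$signal, sub$mirna, mean)
  counts <- tapply(sub$signal, sub$mirna, length)
  data.frame(
    cell_line = cell_line,
    mirna = names(means),
    n_wells = as.integer(counts),
    mean_signal = as.numeric(means),
    global_median = global_median,
    ratio = as.numeric(means) / global_median,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Call proliferative / anti-proliferative screen hits at k MADs
#'
#' Applies the robust hit rule to a cell line's ratio table: the dispersion
#' statistic is the raw median absolute deviation (no normal-consistency
#' factor) of the per-miRNA ratios, bounds are the ratio median plus/minus
#' `k` MADs, and a miRNA is called PROLIFERATIVE above the upper bound or
#' ANTI_PROLIFERATIVE below the lower one. When the MAD degenerates to zero
#' (less than half the ratios differ from the median) any ratio strictly
#' different from the median is a hit and the table carries a
#' `degenerate_flag`.
#'
#' @param ratios data frame from [summarize_ratios()] (one cell line).
#' @param k threshold multiplier; the screen's rule uses 2.
#' @return data frame of class `screen_hit_table` with columns `cell_line`,
#'   `mirna`, `ratio`, `center`, `mad`, `lower_bound`, `upper_bound`,
#'   `call`, `degenerate_flag`.
#' @export
call_hits <- function(ratios, k = 2) {
  stopifnot(is.data.frame(ratios), k > 0)
  if (length(unique(ratios$mirna)) < 2) {
    stop("insufficient data: need ratios for at least 2 distinct miRNAs",
         call. = FALSE)
  }
  center <- stats::median(ratios$ratio)
  mad_val <- stats::median(abs(ratios$ratio - center))
  degenerate <- mad_val == 0
  lower <- center - k * mad_val
  upper <- center + k * mad_val
  call <- rep("NONE", nrow(ratios))
  if (degenerate) {
    call[ratios$ratio > center] <- "PROLIFERATIVE"
    call[ratios$ratio < center] <- "ANTI_PROLIFERATIVE"
  } else {
    call[ratios$ratio > upper] <- "PROLIFERATIVE"
    call[ratios$ratio < lower] <- "ANTI_PROLIFERATIVE"
  }
  out <- data.frame(
    cell_line = ratios$cell_line,
    mirna = ratios$mirna,
    ratio = ratios$ratio,
    center = center,
    mad = mad_val,
    lower_bound = lower,
    upper_bound = upper,
    call = call,
    degenerate_flag = degenerate,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(out) <- c("screen_hit_table", "data.frame")
  out
}

#' Select candidate miRNAs recurrent across cell lines
#'
#' A miRNA is a candidate when it carries a hit call of the requested
#' direction in at least `min_cell_lines` cell lines. This recurrence filter
#' is what controls false discoveries: the per-line k = 2 MAD rule alone is
#' deliberately liberal.
#'
#' @param tables one `screen_hit_table` or a list of them (one per cell
#'   line), or a single row-bound data frame.
#' @param min_cell_lines minimum number of supporting cell lines.
#' @param direction `"any"`, `"proliferative"` or `"anti_proliferative"`.
#' @return data frame with columns `mirna`, `n_cell_lines`, sorted by
#'   support (descending) then identifier.
#' @export
select_candidates <- function(tables, min_cell_lines = 2,
                              direction = c("any", "proliferative",
                                            "anti_proliferative")) {
  direction <- match.arg(direction)
  if (is.data.frame(tables)) tables <- list(tables)
  hits <- do.call(rbind, lapply(tables, function(tb) {
    as.data.frame(tb)[, c("cell_line", "mirna", "call")]
  }))
  if (length(unique(hits$cell_line)) < min_cell_lines) {
    stop("tables cover fewer cell lines than min_cell_lines", call. = FALSE)
  }
  keep <- switch(direction,
    any = hits$call != "NONE",
    proliferative = hits$call == "PROLIFERATIVE",
    anti_proliferative = hits$call == "ANTI_PROLIFERATIVE")
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(mirna = character(0), n_cell_lines = integer(0),
                      stringsAsFactors = FALSE))
  }
  support <- tapply(hits$cell_line, hits$mirna,
                    function(x) length(unique(x)))
  out <- data.frame(mirna = names(support),
                    n_cell_lines = as.integer(support),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$n_cell_lines >= min_cell_lines, , drop = FALSE]
  out <- out[order(-out$n_cell_lines, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the MAD screen over every cell line in a record table
#'
#' Convenience wrapper: [summarize_ratios()] then [call_hits()] per cell
#' line present in the MTS records.
#'
#' @inheritParams summarize_ratios
#' @inheritParams call_hits
#' @return list of `screen_hit_table`, named by cell line.
#' @export
screen_all_lines <- function(records, k = 2) {
  lines <- unique(records$cell_line[records$assay == "MTS"])
  if (length(lines) == 0) stop("no MTS records", call. = FALSE)
  tables <- lapply(lines, function(cl) call_hits(summarize_ratios(records, cl), k = k))
  names(tables) <- lines
  tables
}

#' Write a screen hit table to TSV
#'
#' @param tables a `screen_hit_table` or list of them.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(tables, path) {
  if (is.data.frame(tables)) tables <- list(tables)
  out <- do.call(rbind, lapply(tables, as.data.frame))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
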