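# Build a validated well-record data frame from vectors, recycling
# single-valued fields.
make_records <- function(cell_line, mirna = NA_character_,
                         drug = NA_character_, dose = 0, repeat_id = 1L,
                         well_id = NULL, assay = "MTS", signal) {
  n <- length(signal)
  if (is.null(well_id)) well_id <- seq_len(n)
  data.frame(cell_line = rep_len(cell_line, n),
             mirna = rep_len(mirna, n),
             drug = rep_len(drug, n),
             dose = rep_len(dose, n),
             repeat_id = rep_len(as.integer(repeat_id), n),
             well_id = as.integer(well_id),
             assay = rep_len(assay, n),
             signal = signal,
             stringsAsFactors = FALSE)
}

# Records for one four-arm combination experiment, one well per row.
combo_records <- function(cell_line, mirna, drug, untreated, mirna_only,
                          drug_only, combination, dose = 1e-6,
                          assay = "ALAMAR") {
  rbind(
    make_records(cell_line, NA, NA, 0, assay = assay, signal = untreated),
    make_records(cell_line, mirna, NA, 0, assay = assay, signal = mirna_only),
    make_records(cell_line, NA, drug, dose, assay = assay,
                 signal = drug_only),
    make_records(cell_line, mirna, drug, dose, assay = assay,
                 signal = combination)
  )
}
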