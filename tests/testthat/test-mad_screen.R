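test_that("ratios are means over wells divided by the global median", {
  # all wells identical -> every ratio 1
  rec <- make_records("A", rep(c("m1", "m2"), each = 4), signal = rep(2, 8))
  r <- summarize_ratios(rec, "A")
  expect_equal(r$ratio, c(1, 1))

  # quadruplicates {1,1,1,1} and {3,3,3,3}: global median of 8 wells = 2
  rec <- make_records("A", rep(c("m1", "m2"), each = 4),
                      signal = c(rep(1, 4), rep(3, 4)))
  r <- summarize_ratios(rec, "A")
  expect_equal(r$ratio[r$mirna == "m1"], 0.5)
  expect_equal(r$ratio[r$mirna == "m2"], 1.5)
  expect_equal(unique(r$global_median), 2)

  # single miRNA with wells {2,4}: mean 3 over its own global median 3
  rec <- make_records("A", "m1", signal = c(2, 4))
  r <- summarize_ratios(rec, "A")
  expect_equal(r$mean_signal, 3)
  expect_equal(r$ratio, 1)
})

test_that("control and drug-treated wells are excluded from the screen", {
  rec <- rbind(
    make_records("A", rep(c("m1", "m2"), each = 4),
                 signal = c(rep(1, 4), rep(3, 4))),
    make_records("A", "NEG_CONTROL", signal = rep(100, 4)),
    make_records("A", NA, signal = rep(100, 4), well_id = 5:8)
  )
  r <- summarize_ratios(rec, "A")
  expect_setequal(r$mirna, c("m1", "m2"))
  expect_equal(unique(r$global_median), 2)
  expect_error(summarize_ratios(rec, "nope"), "no miRNA-transfected")
})

test_that("hit calling applies the median +/- k*MAD rule", {
  r <- data.frame(cell_line = "A", mirna = paste0("m", 1:6),
                  ratio = c(0.2, 0.9, 1.0, 1.0, 1.1, 1.8))
  h <- call_hits(r, k = 2)
  expect_equal(h$mad[1], 0.1)
  expect_equal(h$lower_bound[1], 0.8)
  expect_equal(h$upper_bound[1], 1.2)
  expect_equal(h$call[h$ratio == 0.2], "ANTI_PROLIFERATIVE")
  expect_equal(h$call[h$ratio == 1.8], "PROLIFERATIVE")
  expect_true(all(h$call[h$ratio %in% c(0.9, 1.0, 1.1)] == "NONE"))
  expect_false(any(h$degenerate_flag))
})

test_that("zero MAD falls back to any-deviation calls with a flag", {
  r <- data.frame(cell_line = "A", mirna = paste0("m", 1:10),
                  ratio = c(rep(1, 9), 2))
  h <- call_hits(r)
  expect_true(all(h$degenerate_flag))
  expect_equal(h$call[h$ratio == 2], "PROLIFERATIVE")
  expect_true(all(h$call[h$ratio == 1] == "NONE"))

  # fully constant ratios: degenerate but no hits at all
  r$ratio <- rep(1, 10)
  h <- call_hits(r)
  expect_true(all(h$call == "NONE"))
  expect_error(call_hits(r[1, ]), "insufficient data")
})

test_that("calls are invariant to rescaling a cell line's signals", {
  rec <- simulate_mts_screen(screen_sim_config(n_mirnas = 15,
                                               n_cell_lines = 1), seed = 42)
  h1 <- call_hits(summarize_ratios(rec, "CL-01"))
  rec$signal <- rec$signal * 7.3
  h2 <- call_hits(summarize_ratios(rec, "CL-01"))
  expect_equal(h2$ratio, h1$ratio)
  expect_equal(h2$mad, h1$mad)
  expect_identical(h2$call, h1$call)
})

test_that("the k = 3 hit set is nested in the k = 2 hit set", {
  for (seed in 1:10) {
    rec <- simulate_mts_screen(screen_sim_config(n_mirnas = 20,
                                                 n_cell_lines = 1),
                               seed = seed)
    r <- summarize_ratios(rec, "CL-01")
    hits_k2 <- with(call_hits(r, k = 2), mirna[call != "NONE"])
    hits_k3 <- with(call_hits(r, k = 3), mirna[call != "NONE"])
    expect_true(all(hits_k3 %in% hits_k2))
  }
})

test_that("the null hit fraction decreases as k grows", {
  frac <- sapply(1:3, function(k) {
    mean(sapply(1:200, function(seed) {
      rec <- simulate_mts_screen(
        screen_sim_config(n_mirnas = 20, n_cell_lines = 1), seed = seed)
      mean(call_hits(summarize_ratios(rec, "CL-01"), k = k)$call != "NONE")
    }))
  })
  expect_true(frac[1] > frac[2])
  expect_true(frac[2] > frac[3])
})

test_that("candidate selection honours the cell-line support threshold", {
  tb <- function(cl, calls) {
    structure(data.frame(cell_line = cl, mirna = names(calls),
                         call = unname(calls), stringsAsFactors = FALSE),
              class = c("screen_hit_table", "data.frame"))
  }
  tabs <- list(
    tb("A", c(m1 = "ANTI_PROLIFERATIVE", m2 = "ANTI_PROLIFERATIVE",
              m3 = "ANTI_PROLIFERATIVE")),
    tb("B", c(m1 = "ANTI_PROLIFERATIVE", m2 = "PROLIFERATIVE",
              m3 = "NONE")),
    tb("C", c(m1 = "NONE", m2 = "NONE", m3 = "NONE"))
  )
  # m1 hits in 2 of 3 lines -> selected; m3 in 1 line -> not
  sel <- select_candidates(tabs, min_cell_lines = 2,
                           direction = "anti_proliferative")
  expect_equal(sel$mirna, "m1")
  expect_equal(sel$n_cell_lines, 2)
  # m2's hits point in opposite directions: counted by "any" only
  sel_any <- select_candidates(tabs, min_cell_lines = 2, direction = "any")
  expect_setequal(sel_any$mirna, c("m1", "m2"))
  sel_pro <- select_candidates(tabs, min_cell_lines = 2,
                               direction = "proliferative")
  expect_equal(nrow(sel_pro), 0)
})

test_that("planted screen effects are recovered exactly at a fixed seed", {
  rec <- simulate_mts_screen(default_screen_config(), seed = 101)
  tabs <- screen_all_lines(rec)
  anti <- select_candidates(tabs, min_cell_lines = 6,
                            direction = "anti_proliferative")
  pro <- select_candidates(tabs, min_cell_lines = 6,
                           direction = "proliferative")
  expect_setequal(anti$mirna, sprintf("miR-%02d", 1:3))
  expect_setequal(pro$mirna, sprintf("miR-%02d", 4:6))
})
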