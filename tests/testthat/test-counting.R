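count_of <- function(counts, drug, event, month) {
  r <- counts[counts$drug_id == drug & counts$event_id == event &
                counts$month == month, ]
  if (nrow(r) == 0) 0L else r$count
}

test_that("monthly counts tally units per drug-event-month with explicit zeros", {
  h <- toy_hierarchy()
  tab <- rbind(report_row("c1", "2010-07-03"),
               report_row("c2", "2010-07-11"),
               report_row("c3", "2010-07-28"),
               report_row("c4", "2010-08-02"),
               report_row("c5", "2010-08-19"))
  rep <- validate_reports(tab, h)
  cfg <- screen_config(window_months = 3, threshold_tau = 3)
  counts <- monthly_counts(rep, cfg, h, c("2010-05", "2010-08"))
  expect_equal(counts$count[counts$month %in%
                              c("2010-06", "2010-07", "2010-08")],
               c(0L, 3L, 2L))
  expect_equal(count_of(counts, "drug x", "a1", "2010-05"), 0L)
  expect_equal(attr(counts, "n_units"), 5L)
})

test_that("the literature toggle removes literature units", {
  h <- toy_hierarchy()
  tab <- rbind(report_row("c1", "2010-07-03", literature = TRUE),
               report_row("c2", "2010-07-11"),
               report_row("c3", "2010-07-28"),
               report_row("c4", "2010-08-02"),
               report_row("c5", "2010-08-19"))
  rep <- validate_reports(tab, h)
  cfg <- screen_config(window_months = 3, include_literature = FALSE)
  counts <- monthly_counts(rep, cfg, h, c("2010-05", "2010-08"))
  expect_equal(count_of(counts, "drug x", "a1", "2010-07"), 2L)
  expect_equal(count_of(counts, "drug x", "a1", "2010-08"), 2L)
})

test_that("pooling all PTs sums units into the ALL series", {
  h <- toy_hierarchy()
  tab <- rbind(report_row("c1", "2010-07-03", pt = "a1"),
               report_row("c2", "2010-07-05", pt = "a1"),
               report_row("c3", "2010-07-09", pt = "a1"),
               report_row("c4", "2010-07-12", pt = "b1"),
               report_row("c5", "2010-07-21", pt = "b1"))
  rep <- validate_reports(tab, h)
  cfg <- screen_config(window_months = 3, event_level = "pooled_all")
  counts <- monthly_counts(rep, cfg, h, c("2010-05", "2010-08"))
  expect_equal(count_of(counts, "drug x", "ALL", "2010-07"), 5L)
})

test_that("counting conserves units and the pooled series is the PT sum", {
  h <- toy_hierarchy()
  span <- c("2010-01", "2010-12")
  for (i in 1:20) {
    set.seed(1000 + i)
    rep <- validate_reports(random_reports(h, 80), h)
    cfg <- screen_config(window_months = 6, restrict_ime_dme = FALSE)
    counts <- monthly_counts(rep, cfg, h, span)
    # conservation: PT-level counts sum to the number of counted units
    units <- unique(as.data.frame(rep)[c("case_id", "substance",
                                         "event_pt")])
    expect_equal(sum(counts$count), nrow(units))
    # pooled_all equals the elementwise PT sum per drug
    pooled <- monthly_counts(rep, screen_config(
      window_months = 6, event_level = "pooled_all",
      restrict_ime_dme = FALSE), h, span)
    for (d in unique(pooled$drug_id)) {
      pt_sum <- tapply(counts$count[counts$drug_id == d],
                       counts$month[counts$drug_id == d], sum)
      all_series <- pooled[pooled$drug_id == d, ]
      expect_equal(as.integer(pt_sum[all_series$month]),
                   all_series$count)
    }
    # literature toggle is elementwise monotone
    no_lit <- monthly_counts(rep, screen_config(
      window_months = 6, include_literature = FALSE,
      restrict_ime_dme = FALSE), h, span)
    merged <- merge(counts, no_lit,
                    by = c("drug_id", "event_id", "month"))
    expect_true(all(merged$count.y <= merged$count.x))
  }
})

test_that("grouping-level counting assigns units to their HLT", {
  h <- toy_hierarchy()
  tab <- rbind(report_row("c1", "2010-07-03", pt = "a1"),
               report_row("c2", "2010-07-05", pt = "a2"),
               report_row("c3", "2010-07-09", pt = "b1"))
  rep <- validate_reports(tab, h)
  cfg <- screen_config(window_months = 3, event_level = "grouping",
                       grouping_level = "hlt")
  counts <- monthly_counts(rep, cfg, h, c("2010-05", "2010-08"))
  expect_equal(count_of(counts, "drug x", "ha", "2010-07"), 2L)
  expect_equal(count_of(counts, "drug x", "hb", "2010-07"), 1L)
})

test_that("product-level counting drops reports without a product name", {
  h <- toy_hierarchy()
  tab <- rbind(report_row("c1", "2010-07-03"),
               report_row("c2", "2010-07-05", product = NA))
  rep <- validate_reports(tab, h)
  cfg <- screen_config(window_months = 3, drug_level = "product")
  counts <- monthly_counts(rep, cfg, h, c("2010-05", "2010-08"))
  expect_equal(attr(counts, "n_units"), 1L)
  expect_equal(unique(counts$drug_id), "brand x")
})

test_that("slice_for_month returns the window history and monitored count", {
  months <- month_seq("2010-01", "2010-07")
  series <- data.frame(month = months, count = c(0L, 3L, 2L, 1L, 4L, 0L, 7L))
  s6 <- slice_for_month(series, "2010-07", 6)
  expect_equal(s6$history, c(0L, 3L, 2L, 1L, 4L, 0L))
  expect_equal(s6$y0, 7L)
  s3 <- slice_for_month(series, "2010-07", 3)
  expect_equal(s3$history, c(1L, 4L, 0L))
  expect_equal(s3$y0, 7L)
  expect_error(slice_for_month(series, "2010-03", 6), "2009-09")
})

test_that("an undersized span is rejected", {
  h <- toy_hierarchy()
  rep <- validate_reports(report_row("c1", "2010-07-03"), h)
  expect_error(
    monthly_counts(rep, screen_config(), h, c("2010-03", "2010-08")),
    "need at least 7")
})
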