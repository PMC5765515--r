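mk_detection <- function(drug, event, month, branch = "regression",
                         event_level = "pt") {
  data.frame(drug_level = "substance", drug_id = drug,
             event_level = event_level, event_id = event, month = month,
             y0 = 6L, branch = branch, y_hat = 2, upper_bound = 4,
             threshold = 5L, level = 0.95, bound_type = "ci_mean",
             stringsAsFactors = FALSE)
}

packaged_register <- function() {
  h <- make_synthetic_hierarchy()
  list(h = h, concerns = load_concerns(uif_example("concerns.csv"), h))
}

test_that("the true-positive window spans 12 months before to 6 after the index date", {
  reg <- packaged_register()
  # immunoglobulin concern, index date 2010-08-23, embolic/thrombotic SMQ
  tp_months <- c("2009-08", "2010-08", "2011-02")
  fp_months <- c("2009-07", "2011-03")
  det <- do.call(rbind, lapply(c(tp_months, fp_months), function(m) {
    mk_detection("human normal immunoglobulin", "deep vein thrombosis", m)
  }))
  lab <- label_detections(det, reg$concerns, reg$h, screen_config())
  expect_equal(lab$label,
               c(rep("true_positive", 3), rep("false_positive", 2)))
  expect_equal(lab$concern_id[1:3], rep("C01", 3))
})

test_that("events outside the case definition are false positives", {
  reg <- packaged_register()
  det <- mk_detection("human normal immunoglobulin", "hypoglycaemia",
                      "2010-08")
  lab <- label_detections(det, reg$concerns, reg$h, screen_config())
  expect_equal(lab$label, "false_positive")
})

test_that("drugs absent from the register are out of the evaluation universe", {
  reg <- packaged_register()
  det <- mk_detection("aspirin", "deep vein thrombosis", "2010-08")
  lab <- label_detections(det, reg$concerns, reg$h, screen_config())
  expect_equal(lab$label, "out_of_universe")
})

test_that("every detection gets exactly one label", {
  reg <- packaged_register()
  set.seed(31)
  pts <- all_pts_of(reg$h)
  drugs <- c(unique(reg$concerns$substance), "aspirin", "ibuprofen")
  det <- do.call(rbind, lapply(1:40, function(i) {
    mk_detection(sample(drugs, 1), sample(pts, 1),
                 month_add("2010-01", sample.int(60, 1)),
                 branch = sample(c("regression", "heuristic"), 1))
  }))
  lab <- label_detections(det, reg$concerns, reg$h, screen_config())
  expect_true(all(lab$label %in%
                    c("true_positive", "false_positive", "out_of_universe")))
  expect_equal(nrow(lab), nrow(det))
  expect_true(all(!is.na(lab$concern_id[lab$label == "true_positive"])))
  expect_true(all(is.na(lab$concern_id[lab$label != "true_positive"])))
})

test_that("shifting all dates by the same number of months leaves labels unchanged", {
  reg <- packaged_register()
  det <- do.call(rbind, lapply(
    c("2009-07", "2009-08", "2010-08", "2011-02", "2011-03"),
    function(m) mk_detection("human normal immunoglobulin",
                             "deep vein thrombosis", m)))
  base <- label_detections(det, reg$concerns, reg$h, screen_config())
  for (k in c(-7L, 13L)) {
    det2 <- det
    det2$month <- month_add(det$month, k)
    conc2 <- reg$concerns
    # shift index dates by k months, keeping the day
    idx <- month_add(as_month(conc2$index_date), k)
    conc2$index_date <- as.Date(paste0(idx, "-",
                                       format(conc2$index_date, "%d")))
    lab2 <- label_detections(det2, conc2, reg$h, screen_config())
    expect_equal(lab2$label, base$label)
  }
})

test_that("abuse/misuse concerns define no product-level scope", {
  reg <- packaged_register()
  det <- mk_detection("loperamide", "drug abuse", "2015-04")
  lab_sub <- label_detections(det, reg$concerns, reg$h, screen_config())
  expect_equal(lab_sub$label, "true_positive")
  det_prod <- det
  det_prod$drug_level <- "product"
  lab_prod <- label_detections(det_prod, reg$concerns, reg$h,
                               screen_config(drug_level = "product"))
  expect_equal(lab_prod$label, "out_of_universe")
})

test_that("grouped event keys match concerns through their PT expansion", {
  reg <- packaged_register()
  det <- mk_detection("human normal immunoglobulin",
                      "site specific embolism and thrombosis", "2010-08",
                      event_level = "hlt")
  lab <- label_detections(det, reg$concerns, reg$h,
                          screen_config(event_level = "grouping",
                                        grouping_level = "hlt"))
  expect_equal(lab$label, "true_positive")
  det_all <- mk_detection("human normal immunoglobulin", "ALL", "2010-08",
                          event_level = "pooled_all")
  lab_all <- label_detections(det_all, reg$concerns, reg$h,
                              screen_config(event_level = "pooled_all"))
  expect_equal(lab_all$label, "true_positive")
})

test_that("PPV is the pooled TP share, per branch and overall", {
  labeled <- rbind(
    cbind(mk_detection("d", "a1", "2010-01"),
          label = c(rep("true_positive", 2), rep("false_positive", 8))[1],
          concern_id = "C01", concern_type = "QD"),
    cbind(mk_detection("d", "a1", "2010-02"),
          label = "true_positive", concern_id = "C01", concern_type = "QD"))
  labeled <- rbind(labeled,
                   do.call(rbind, lapply(1:8, function(i) {
                     cbind(mk_detection("d", "a1", "2010-03"),
                           label = "false_positive",
                           concern_id = NA_character_,
                           concern_type = NA_character_)
                   })))
  ev <- compute_ppv(labeled)
  expect_equal(ev$ppv_overall, 0.2)
  expect_equal(ev$detected_concerns, "C01")
  expect_equal(ev$detections_by_type[["QD"]], 2L)
  expect_equal(ev$first_detection_month[["C01"]], "2010-01")
})

test_that("branch PPVs bracket the overall PPV and 0/0 is undefined", {
  mixed <- rbind(
    cbind(mk_detection("d", "a1", "2010-01", branch = "regression"),
          label = "true_positive", concern_id = "C01", concern_type = "QD"),
    cbind(mk_detection("d", "a1", "2010-02", branch = "heuristic"),
          label = "false_positive", concern_id = NA_character_,
          concern_type = NA_character_))
  ev <- compute_ppv(mixed)
  expect_equal(ev$ppv_regression, 1)
  expect_equal(ev$ppv_heuristic, 0)
  expect_equal(ev$ppv_overall, 0.5)
  expect_true(ev$ppv_overall >= min(ev$ppv_regression, ev$ppv_heuristic))
  expect_true(ev$ppv_overall <= max(ev$ppv_regression, ev$ppv_heuristic))
  oou <- cbind(mk_detection("d", "a1", "2010-01"),
               label = "out_of_universe", concern_id = NA_character_,
               concern_type = NA_character_)
  ev2 <- compute_ppv(oou)
  expect_true(is.na(ev2$ppv_overall))
  expect_true(is.na(ev2$ppv_regression))
  expect_equal(ev2$n_out_of_universe, 1L)
})
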