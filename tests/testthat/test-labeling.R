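make_intensity_table <- function(labeled, unlabeled, reference = "1") {
  n <- length(labeled)
  enrichment_table("synthetic", "acetate_1_13C",
                   data.frame(position = as.character(seq_len(n)),
                              shift_ppm = 10 + seq_len(n),
                              labeled_intensity = labeled,
                              unlabeled_intensity = unlabeled),
                   reference_position = reference)
}

test_that("two-spectrum normalization yields the forced ratios", {
  # one carbon at L = 5U, everything else at L = U, reference elsewhere
  tab <- make_intensity_table(c(1, 1, 5, 1), c(1, 1, 1, 1), reference = "1")
  calls <- compute_enrichment(tab)
  expect_equal(calls$ratio, c(1, 1, 5, 1))
  expect_identical(calls$ratio[calls$position == "1"], 1)  # reference exactly 1
  expect_equal(classify_enriched(calls, 3), "3")

  # identical spectra give no enrichment anywhere
  flat <- compute_enrichment(make_intensity_table(rep(2, 5), rep(2, 5)))
  expect_equal(flat$ratio, rep(1, 5))
  expect_false(any(flat$enriched))
})

test_that("ratios are invariant to overall spectrum scaling", {
  set.seed(7)
  u <- runif(8, 0.5, 2)
  l <- u * c(1, 1, 6, 1, 1, 4, 1, 1)
  base <- compute_enrichment(make_intensity_table(l, u))
  for (k in c(0.01, 3, 250)) {
    scaled <- compute_enrichment(make_intensity_table(k * l, u))
    expect_equal(scaled$ratio, base$ratio)
  }
})

test_that("data errors name the offending position or missing reference", {
  err <- expect_error(
    compute_enrichment(make_intensity_table(c(1, 1), c(1, 0))),
    class = "pks_data_error")
  expect_match(conditionMessage(err), "position 2")
  expect_error(make_intensity_table(c(1, 1), c(1, 1), reference = "9"),
               class = "pks_data_error")
  # mixed missing intensities in intensity mode
  tab <- make_intensity_table(c(1, 1), c(1, 1))
  tab$records$labeled_intensity[2] <- NA
  expect_error(compute_enrichment(tab, mode = "intensities"),
               class = "pks_data_error")
})

test_that("classification is monotone in the threshold", {
  tabs <- read_enrichment_csv(fixture("feeding_chloroakaeolide.csv"),
                              compound = "17-chloroakaeolide", reference = "2")
  calls <- compute_enrichment(tabs$acetate_2_13C)
  thresholds <- c(1.5, 2, 3, 4.5, 6)
  sets <- lapply(thresholds, function(t) classify_enriched(calls, t))
  for (i in seq_len(length(sets) - 1L)) {
    expect_true(all(sets[[i + 1L]] %in% sets[[i]]))
  }
  expect_identical(classify_enriched(calls[0, ], 3), character(0))
})

test_that("published tables load with the expected dimensions and pass through", {
  akae <- read_enrichment_csv(fixture("feeding_chloroakaeolide.csv"),
                              compound = "17-chloroakaeolide", reference = "2")
  expect_setequal(names(akae),
                  c("acetate_1_13C", "acetate_2_13C", "propionate_1_13C"))
  for (t in akae) expect_equal(nrow(t$records), 22L)

  lorn <- read_enrichment_csv(fixture("feeding_lorneic_acid_a.csv"),
                              compound = "lorneic acid A", reference = "16")
  expect_setequal(names(lorn), c("acetate_1_13C", "propionate_1_13C"))
  for (t in lorn) expect_equal(nrow(t$records), 17L)

  # ratio pass-through keeps the printed values (reference printed as 1.00)
  calls <- compute_enrichment(akae$acetate_1_13C)
  expect_equal(calls$ratio[calls$position == "5"], 5.01)
  expect_equal(calls$ratio[calls$position == "2"], 1)

  # overlapping signals are distinct records sharing a shift
  shifts <- akae$acetate_1_13C$records
  expect_equal(shifts$shift_ppm[shifts$position == "12"],
               shifts$shift_ppm[shifts$position == "15"])
})

test_that("CSV round trips are identities and malformed rows are located", {
  tabs <- read_enrichment_csv(fixture("feeding_lorneic_acid_a.csv"),
                              compound = "lorneic acid A", reference = "16")
  path <- withr::local_tempfile(fileext = ".csv")
  write_enrichment_csv(tabs, path)
  back <- read_enrichment_csv(path, compound = "lorneic acid A", reference = "16")
  expect_equal(back, tabs)

  # synthetic intensity-mode table round trips too
  sim <- simulate_labeling(assemble(read_cluster(fixture("lorneic_cluster.txt"))),
                           config = simulation_config(seed = 5L),
                           intensity_mode = TRUE)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_enrichment_csv(sim$tables, p2)
  back2 <- read_enrichment_csv(p2, compound = "lorneic_bgc",
                               reference = sim$truth$reference)
  expect_equal(back2, sim$tables)

  bad <- withr::local_tempfile(lines = c(
    "position,shift_ppm,experiment,labeled_intensity,unlabeled_intensity,ratio",
    "1,10,acetate_1_13C,,,1.0",
    "2,11,acetate_1_13C,,,notanumber"))
  err <- expect_error(read_enrichment_csv(bad, reference = "1"),
                      class = "pks_data_error")
  expect_match(conditionMessage(err), "line 3")
})
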