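ref <- suppressWarnings(read_reference_table())

test_that("unit conversion is exact and round-trips", {
  expect_equal(um_to_mg_per_l(1000, 1000), 1000)
  # 2,4-dinitrochlorobenzene: 2.19 uM at MW 202.55 is the table's 0.443 mg/L
  expect_equal(um_to_mg_per_l(2.19, 202.55), 0.443, tolerance = 2e-3)
  expect_error(um_to_mg_per_l(0, 100), "positive")
  expect_error(um_to_mg_per_l(10, -1), "positive")
  set.seed(5)
  x <- exp(runif(20, -3, 8)); mw <- runif(20, 50, 600)
  expect_equal(mg_per_l_to_um(um_to_mg_per_l(x, mw), mw), x,
               tolerance = 1e-12)
})

test_that("GHS sub-categorization applies the inclusive 2% cutoff", {
  expect_identical(ghs_subcategory(0.06), "1A")
  expect_identical(ghs_subcategory(2.0), "1A")   # boundary inclusive
  expect_identical(ghs_subcategory(2.1), "1B")
  expect_identical(ghs_subcategory(NA), "NoCat")
  expect_identical(ghs_subcategory("NS"), "NoCat")
  expect_identical(ghs_subcategory(c(1, 3, NA)), c("1A", "1B", "NoCat"))
})

test_that("the bundled reference table parses censoring tokens and counts", {
  expect_equal(nrow(ref), 29)
  expect_equal(sum(ref$sensitizer), 22)
  expect_equal(sum(!ref$sensitizer), 7)
  # censoring markers survive as status columns, never sentinel numerics
  expect_identical(ref$llna_ec3_status[ref$chemical == "Kanamycin sulfate"], "NS")
  expect_true(is.na(ref$llna_ec3[ref$chemical == "Kanamycin sulfate"]))
  expect_identical(ref$noel_status[ref$chemical == "Benzalkonium chloride"], "ND")
  expect_identical(ref$cdv0_mgL_status[ref$chemical == "2-Hydroxyethyl acrylate"],
                   "NM")
  # a censored model-based estimate can still carry a lower bound
  benzo <- ref[ref$chemical == "Benzocaine", ]
  expect_identical(benzo$cdv0_ll_status, "NS")
  expect_equal(benzo$cdv0_ll_ci_low, 406)
  expect_true(is.na(benzo$cdv0_ll_ci_high))
})

test_that("log-scale Pearson correlations reproduce the reference statistics", {
  llna <- correlate_potency(ref, "llna_ec3")
  expect_equal(llna$n, 17)
  expect_equal(round(llna$r, 2), 0.81)
  expect_lt(llna$p_value, 1e-3)

  noel <- correlate_potency(ref, "human_noel")
  expect_equal(noel$n, 15)
  expect_equal(round(noel$r, 2), 0.74)
  expect_lt(noel$p_value, 0.01)

  # benzyl alcohol: excluded from the EC3 pairing (LLNA NS) but present in
  # the NOEL pairing (numeric NOEL)
  expect_false("Benzyl alcohol" %in% llna$chemicals)
  expect_true("Benzyl alcohol" %in% noel$chemicals)
})

test_that("Pearson r on logs is invariant to rescaling and exact on affine data", {
  r1 <- correlate_potency(ref, "llna_ec3")$r
  scaled <- ref
  scaled$cdv0_mgL <- scaled$cdv0_mgL * 1e3   # unit change
  scaled$llna_ec3 <- scaled$llna_ec3 / 7
  r2 <- correlate_potency(scaled, "llna_ec3")$r
  expect_equal(r1, r2, tolerance = 1e-12)

  # exact affine log-log relation gives r = 1
  fake <- data.frame(
    chemical = letters[1:6],
    cdv0_mgL = exp(seq(0, 5)), cdv0_mgL_status = "value",
    llna_ec3 = exp(2 + 0.7 * seq(0, 5)), llna_ec3_status = "value")
  expect_equal(correlate_potency(fake, "llna_ec3")$r, 1, tolerance = 1e-12)

  too_few <- fake[1:2, ]
  expect_error(correlate_potency(too_few, "llna_ec3"), "at least 3")
})

test_that("class separation flags diethyl maleate as the sole 1A/1B exception", {
  rep_ <- class_separation_report(ref)
  expect_equal(rep_$n_flagged, 1)
  expect_identical(rep_$violations$chemical, "Diethyl maleate")

  # perfectly separated synthetic classes: no violations
  synth <- data.frame(chemical = letters[1:6],
                      ghs = c("1A", "1A", "1A", "1B", "1B", "1B"),
                      cdv0_uM = c(1, 2, 3, 10, 20, 30))
  expect_equal(class_separation_report(synth)$n_flagged, 0)

  # single-class input: empty violation set
  one <- data.frame(chemical = letters[1:3], ghs = "1B", cdv0_uM = c(3, 1, 2))
  expect_equal(class_separation_report(one)$n_flagged, 0)
})
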