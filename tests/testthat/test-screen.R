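# a three-point control set with sample mean exactly 95 and sample SD
# exactly 12.175 (the screen's printed wild-type statistics)
wt_controls_95 <- c(95 - 12.175, 95, 95 + 12.175)

test_that("wild-type thresholds reproduce the printed screen cutoffs", {
  th <- compute_thresholds(wt_controls_95)
  expect_equal(th$wt_mean, 95)
  expect_equal(th$wt_sd, 12.175)
  # integer significance cutoffs as quoted on the screen histogram
  expect_identical(th$cutoffs, c(low = 70, high = 119))
  # moderate band edges at 1 SD
  expect_equal(th$bounds[["low1"]], 82.825)
  expect_equal(th$bounds[["high1"]], 107.175)
  expect_equal(th$bounds[["low2"]], 70.65)
  expect_equal(th$bounds[["high2"]], 119.35)
  expect_true(all(diff(th$bounds) > 0))
})

test_that("threshold computation rejects degenerate control sets", {
  expect_error(compute_thresholds(95), ">= 2")
  expect_error(compute_thresholds(c(95, 95, 95)), "degenerate")
})

test_that("hit categories follow the 1 SD / 2 SD banding with soft boundaries", {
  th <- compute_thresholds(wt_controls_95)
  cat_of <- function(x) as.character(call_hit(x, th)$category)
  expect_identical(cat_of(95), "no_change")
  expect_identical(cat_of(65), "significant_low")      # below 70.65
  expect_identical(cat_of(110), "moderate_high")       # 107.175 < 110 < 119.35
  expect_identical(cat_of(75), "moderate_low")
  expect_identical(cat_of(125), "significant_high")
  # boundary values take the less extreme category
  expect_identical(cat_of(95 + 12.175), "no_change")
  expect_identical(cat_of(95 - 12.175), "no_change")
  expect_identical(cat_of(95 + 2 * 12.175), "moderate_high")
  expect_identical(cat_of(95 - 2 * 12.175), "moderate_low")
})

test_that("the category partition is exhaustive and contiguous", {
  th <- compute_thresholds(wt_controls_95)
  xs <- seq(0, 300, by = 0.25)
  cats <- vapply(xs, function(x) as.character(call_hit(x, th)$category),
                 character(1))
  expect_true(all(cats %in% c("significant_low", "moderate_low", "no_change",
                              "moderate_high", "significant_high")))
  # walking up the axis, each category forms one contiguous block
  expect_identical(unique(cats),
                   c("significant_low", "moderate_low", "no_change",
                     "moderate_high", "significant_high"))
})

test_that("chromosome dosage ratio flags aneuploid strains", {
  ok <- karyotype(1000, 1000)
  expect_equal(ok$ratio, 1)
  expect_false(ok$flagged)

  # simulated disome XII: twice the chr12 molecules
  cfg <- assay_config()
  set.seed(5)
  n <- cfg$n_droplets
  mu <- genome_equivalents_mean(cfg)
  k12 <- sum(tabulate(sample.int(n, rpois(1, 2 * mu)), nbins = n) > 0)
  k13 <- sum(tabulate(sample.int(n, rpois(1, mu)), nbins = n) > 0)
  dis <- karyotype(target_estimate(n, k12), target_estimate(n, k13),
                   strain = "disomeXII")
  expect_equal(dis$ratio, 2, tolerance = 0.25)
  expect_true(dis$flagged)

  # the band is closed: a ratio exactly at the edge is not flagged
  expect_false(karyotype(1.25, 1)$flagged)
  expect_false(karyotype(0.8, 1)$flagged)
  expect_true(karyotype(1.2501, 1)$flagged)
  expect_error(karyotype(1000, 0), "positive")

  # scale invariance of ratio and flag
  a <- karyotype(1100, 1000)
  b <- karyotype(1100 * 3.7, 1000 * 3.7)
  expect_equal(a$ratio, b$ratio)
  expect_identical(a$flagged, b$flagged)
})

test_that("two-condition comparison matches the textbook t-test", {
  same <- compare_conditions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_identical(same$stars, "")

  shifted <- compare_conditions(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p_value, 0.01)
  expect_identical(shifted$stars, "**")

  # hand-computed pooled-variance t for an unbalanced case
  a <- c(150, 148, 152, 151)
  b <- c(120, 119, 121)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  res <- compare_conditions(a, b)
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$p_value,
               2 * pt(abs(t_manual), length(a) + length(b) - 2,
                      lower.tail = FALSE),
               tolerance = 1e-12)

  # degenerate variance with equal means: p = 1 by convention
  flat <- compare_conditions(c(95, 95), c(95, 95))
  expect_equal(flat$t, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(compare_conditions(c(95, 96), c(95, 96))$t, 0)
})

test_that("the screen pipeline calls a contracted-array mutant", {
  layout <- plate_layout_96(n_controls = 8,
                            mutant_cn = c(rep(150, 6), 40))
  counts <- simulate_plate(plate_spec(layout, seed = 17))
  scr <- screen_pipeline(counts, layout)
  low <- scr$hits[scr$hits$strain == "mut_007", ]
  expect_identical(as.character(low$category), "significant_low")
  expect_equal(low$copies_per_genome, 40, tolerance = 0.2)
  # severity-sorted: the significant hit leads the table
  expect_identical(scr$hits$strain[1], "mut_007")
  expect_identical(sum(scr$tallies), nrow(scr$hits))
})

test_that("the screen pipeline demands wild-type controls", {
  layout <- plate_layout_96(n_controls = 1, mutant_cn = c(150, 150))
  counts <- simulate_plate(plate_spec(layout, seed = 19))
  expect_error(screen_pipeline(counts, layout), "insufficient controls")
})

test_that("a control-only plate yields thresholds and an empty hit table", {
  layout <- plate_layout_96(n_controls = 6, mutant_cn = numeric(0))
  counts <- simulate_plate(plate_spec(layout, seed = 23))
  scr <- screen_pipeline(counts, layout)
  expect_identical(nrow(scr$hits), 0L)
  expect_s3_class(scr$thresholds, "screen_thresholds")
})

test_that("aneuploid strains are flagged and excluded from tallies", {
  layout <- plate_layout_96(n_controls = 8, mutant_cn = c(150, 40))
  counts <- simulate_plate(plate_spec(layout, seed = 29))
  kary <- data.frame(strain = c("mut_001", "mut_002"),
                     total_droplets = c(20000L, 20000L),
                     positives_chr12 = c(380L, 740L),
                     positives_chr13 = c(380L, 380L))
  scr <- screen_pipeline(counts, layout, karyotype_counts = kary)
  m2 <- scr$hits[scr$hits$strain == "mut_002", ]
  expect_true(m2$aneuploidy_flag)
  expect_equal(m2$chr_ratio, 2, tolerance = 0.1)
  expect_false(scr$hits$aneuploidy_flag[scr$hits$strain == "mut_001"])
  # the flagged strain is reported but not tallied
  expect_identical(scr$n_excluded_aneuploid, 1L)
  expect_identical(sum(scr$tallies), 1L)
})

test_that("null plates call significant hits at the nominal two-sided rate", {
  layout <- null_screen_layout(n_plates = 4, n_controls = 16, n_mutants = 40)
  counts <- simulate_plate(plate_spec(layout, seed = 31))
  scr <- screen_pipeline(counts, layout)
  n <- nrow(scr$hits)
  rate <- mean(grepl("significant", scr$hits$category))
  p0 <- 0.046
  expect_lt(abs(rate - p0), 3 * sqrt(p0 * (1 - p0) / n))
  # and about two thirds of true-WT strains land in the no-change band
  expect_equal(mean(scr$hits$category == "no_change"), 0.68, tolerance = 0.12)
})
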