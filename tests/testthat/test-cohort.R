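test_that("collinear data collapse all three regression lines", {
  x <- c(0, 1, 2, 3, 4)
  r <- dualRegression(x, 2 * x)
  expect_equal(r@slopeYX, 2)
  expect_equal(r@slopeXYInv, 2)
  expect_equal(r@slopeMean, 2)
  expect_equal(r@r2, 1)
})

test_that("the four-point worked example matches closed-form least squares", {
  x <- c(0, 1, 2, 3); y <- c(0, 1, 0, 1)
  r <- dualRegression(x, y)
  expect_equal(r@slopeYX, 0.2)
  expect_equal(r@r2, 0.2)
  expect_equal(r@slopeXYInv, 1.0)
  # independent route: lm() for both axis orders
  expect_equal(r@slopeYX, unname(coef(lm(y ~ x))[2]))
  expect_equal(r@slopeXYInv, 1 / unname(coef(lm(x ~ y))[2]))
  expect_equal(r@interceptYX, unname(coef(lm(y ~ x))[1]))
  # all lines pass through the centroid
  for (s in list(c(r@slopeYX, r@interceptYX),
                 c(r@slopeXYInv, r@interceptXYInv),
                 c(r@slopeMean, r@interceptMean)))
    expect_equal(s[1] * mean(x) + s[2], mean(y))
})

test_that("r2 is invariant under axis inversion and obeys the slope identity", {
  set.seed(401)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n, sd = runif(1, 0.1, 2))
    a <- dualRegression(x, y)
    b <- dualRegression(y, x)
    expect_equal(a@r2, b@r2, tolerance = 1e-12)
    # slope_yx * slope_xy (un-inverted X-on-Y slope) = r2
    expect_equal(a@slopeYX * b@slopeYX, a@r2, tolerance = 1e-12)
    # the mean slope lies between the two in absolute value
    expect_true(abs(a@slopeMean) >= min(abs(a@slopeYX), abs(a@slopeXYInv)) &&
                abs(a@slopeMean) <= max(abs(a@slopeYX), abs(a@slopeXYInv)))
  }
})

test_that("degenerate regressions are refused or flagged", {
  expect_error(dualRegression(1:2, 2:3), "at least 3")
  expect_error(dualRegression(rep(1, 5), rnorm(5)), "zero variance")
  r <- dualRegression(c(-1, 0, 1), c(1, 0, 1))   # exactly zero covariance
  expect_true("zero-covariance" %in% r@flags)
  expect_true(is.na(r@slopeXYInv) && is.na(r@slopeMean))
})

test_that("group summaries: identical groups give unit ratios", {
  rec <- data.frame(donor_id = rep(sprintf("D%d", 1:6), 2),
                    method = rep(c("DC", "PA"), each = 6),
                    m = rep(c(1, 2, 3, 4, 5, 6), 2))
  s <- summarizeGroups(rec, "m", seed = 1, nBoot = 100)
  expect_equal(s$ratios$ratio, 1)
  expect_true(s$ratios$ci_lo <= 1 && s$ratios$ci_hi >= 1)
  # a method whose values are all missing is an empty group
  rec$m[rec$method == "PA"] <- NA_real_
  expect_error(summarizeGroups(rec, "m", seed = 1), "empty method group")
  expect_error(summarizeGroups(rec, "m", ref = "WA", seed = 1),
               "reference method absent|empty method group")
})

test_that("planted method multipliers are recovered exactly from ground truth", {
  tt <- cohortTruth(donorCV = 0, pathwayCV = 0)
  rec <- simulateCohort(nDonors = 29, truth = tt, seed = 2,
                        emitTraces = FALSE)$records
  for (pair in list(c("r_ce1P", 1.22), c("e_ce3U", 1.16),
                    c("s_1Dig", 0.57))) {
    s <- summarizeGroups(rec, pair[1], seed = 1, nBoot = 50)
    expect_equal(s$ratios$ratio[s$ratios$comparison == "PA/DC"],
                 as.numeric(pair[2]))
    expect_equal(s$ratios$ratio[s$ratios$comparison == "WA/DC"], 1)
  }
})

test_that("single-donor groups degenerate to value ratios with zero IQR", {
  rec <- data.frame(donor_id = "D1", method = c("DC", "PA"), m = c(2, 3))
  s <- summarizeGroups(rec, "m", seed = 1, nBoot = 50)
  expect_equal(s$ratios$ratio, 1.5)
  expect_equal(s$summary$q75 - s$summary$q25, c(0, 0))
})

test_that("paired tests delegate correctly and handle degenerate input", {
  rec <- data.frame(donor_id = rep(sprintf("D%d", 1:8), 2),
                    method = rep(c("DC", "PA"), each = 8),
                    m = c(1:8, 1:8))
  w <- pairedCompare(rec, "m", "wilcoxon")
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)
  expect_equal(w$n_pairs, 8)

  # planted large shift (3 IQRs) is detected
  set.seed(77)
  base <- rnorm(29)
  shift <- 3 * IQR(base)
  rec2 <- data.frame(donor_id = rep(sprintf("D%d", 1:29), 2),
                     method = rep(c("DC", "PA"), each = 29),
                     m = c(base, base + shift))
  w2 <- pairedCompare(rec2, "m", "wilcoxon")
  expect_lt(w2$p_value, 1e-4)
  a2 <- pairedCompare(rec2, "m", "anova")
  expect_lt(a2$p_value, 1e-4)

  # unpaired donors are dropped with a message
  rec3 <- rbind(rec2, data.frame(donor_id = "D99", method = "DC", m = 0))
  expect_message(pairedCompare(rec3, "m", "wilcoxon"), "unpaired")

  expect_error(pairedCompare(data.frame(donor_id = "D1", method = "DC",
                                        m = rep(1, 4)), "m", "anova"),
               "constant")
})

test_that("the pipeline runs a small simulated cohort reproducibly", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- list(seed = 9L,
              simulate = list(n_donors = 4, sigma_o2 = 0.1),
              output_dir = out1)
  res <- runPipeline(cfg)
  expect_equal(nrow(res$records), 12)   # 4 donors x 3 methods
  expect_true(all(file.exists(res$paths)))
  expect_true(length(res$summaries) > 0)
  expect_false(is.null(res$regression))

  cfg$output_dir <- out2
  runPipeline(cfg)
  for (f in c("metrics.csv", "report.json", "report.txt"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))

  empty <- withr::local_tempdir()
  expect_error(runPipeline(list(traces = empty)), "no trace CSV")
})

test_that("the pipeline analyzes traces read back from disk", {
  dir <- withr::local_tempdir()
  sim <- simulateCohort(nDonors = 2, sigmaO2 = 0, seed = 21,
                        methods = c("DC", "PA"))
  for (key in names(sim$runs))
    writeTrace(sim$runs[[key]]$trace,
               file.path(dir, paste0(key, ".csv")))
  out <- withr::local_tempdir()
  res <- runPipeline(list(traces = dir, output_dir = out, seed = 21L))
  expect_equal(nrow(res$records), 4)
  expect_equal(length(res$failures), 0)
  expect_true(all(res$records$vi_r > 0.7))
})
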