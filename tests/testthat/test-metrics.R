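test_that("viability index formula, bounds and failure modes", {
  expect_equal(as.numeric(viabilityIndex(2, 2, 22, 2)), 1)   # no succinate response
  expect_equal(as.numeric(viabilityIndex(22, 2, 22, 2)), 0)  # fully permeable
  vi <- viabilityIndex(5, 2, 22, 2)
  expect_equal(as.numeric(vi), 0.85)                          # 1 - 3/20
  expect_equal(attr(vi, "raw"), 0.85)
  # clipping keeps the report in [0, 1] but preserves the raw value
  vi2 <- viabilityIndex(1, 2, 22, 2)
  expect_equal(as.numeric(vi2), 1)
  expect_equal(attr(vi2, "raw"), 1.05)
  expect_error(viabilityIndex(5, 2, 2, 2), "non-positive denominator")
})

test_that("cytochrome-c control efficiency formula and failure modes", {
  expect_equal(cytcEfficiency(18, 18, 2), 0)
  expect_equal(cytcEfficiency(20, 18, 2), 2 / 18)
  expect_equal(cytcEfficiency(20, 2, 2), 1)
  expect_error(cytcEfficiency(2, 18, 2), "non-positive denominator")
})

test_that("flux control ratios cancel the normalization", {
  expect_equal(fluxControlRatio(0.26, 0.26), 1)
  expect_equal(fluxControlRatio(0, 0.26), 0)
  # per-cell and volume-specific inputs give the identical ratio
  conc <- 200
  expect_equal(fluxControlRatio(0.13, 0.26),
               fluxControlRatio(0.13 * conc, 0.26 * conc))
  expect_error(fluxControlRatio(1, 0), "> 0")
})

test_that("residual correction subtracts Rox and floors at zero", {
  flows <- c(ce1P = 0.13, ce3U = 0.26, ce4Rot = 0.005, "2Ama" = 0.008)
  rc <- roxCorrect(flows)
  expect_equal(rc$corrected[["ce1P"]], 0.122)
  expect_equal(rc$corrected[["ce4Rot"]], 0)       # floored
  expect_equal(rc$floored, "ce4Rot")
  zero <- roxCorrect(c(ce1P = 0.13, "2Ama" = 0))  # Rox = 0 is the identity
  expect_equal(zero$corrected[["ce1P"]], 0.13)
  expect_error(roxCorrect(c(ce1P = 0.13)), "2Ama")
})

test_that("oligomycin threshold: stabilization rule with strict boundary", {
  r <- findOligomycinThreshold(data.frame(conc = c(0, 5, 10),
                                          flow = c(100, 40, 38)))
  # |38-40|/40 = 5% is not strictly below tolerance, so the middle step
  # fails and the terminal step is taken
  expect_equal(r$omy_effective, 10)
  expect_equal(r$L, 38)
  expect_true(r$converged)
  # a genuinely stabilized series stops at the first stable step
  r2 <- findOligomycinThreshold(data.frame(conc = c(5, 10, 15),
                                           flow = c(70, 40, 40)))
  expect_equal(r2$omy_effective, 10)
  # single step: returned but unconverged
  r3 <- findOligomycinThreshold(data.frame(conc = 5, flow = 50))
  expect_false(r3$converged)
  # non-decreasing flows: inhibition failed
  r4 <- findOligomycinThreshold(data.frame(conc = c(5, 10, 15),
                                           flow = c(40, 40, 45)))
  expect_false(r4$converged)
  expect_error(findOligomycinThreshold(data.frame(conc = numeric(),
                                                  flow = numeric())),
               "empty")
})

test_that("uncoupler and digitonin optima: argmax at the lowest concentration", {
  tt <- data.frame(conc = c(0.1, 0.2, 0.3, 0.4), flow = c(40, 80, 95, 90))
  r <- findUncouplerOptimum(tt)
  expect_equal(r$E, 95); expect_equal(r$fccp_effective, 0.3)
  flat <- data.frame(conc = c(0.1, 0.2, 0.3), flow = c(50, 50, 50))
  expect_equal(findUncouplerOptimum(flat)$fccp_effective, 0.1)
  d <- findDigitoninOptimum(data.frame(conc = c(5, 10, 15),
                                       flow = c(20, 35, 35)))
  expect_equal(d$dig_effective, 10); expect_equal(d$S_E, 35)
  expect_error(findDigitoninOptimum(data.frame(conc = numeric(),
                                               flow = numeric())), "empty")
})

test_that("noiseless end-to-end runs recover planted optima exactly", {
  run <- dc_run()
  prof <- analyzeTrace(run$trace)
  m <- profileMetrics(prof)
  expect_equal(m@omyEffective, 10)
  expect_equal(m@fccpEffective, 1.0)
  expect_equal(m@digEffective, 5.0)
})

test_that("profile assembly populates all metrics and handles absences", {
  run <- dc_run()
  prof <- analyzeTrace(run$trace)
  m <- profileMetrics(prof)
  for (s in c("fcrR", "fcrL", "fcrS", "viR", "jc", "omyEffective",
              "fccpEffective", "digEffective"))
    expect_false(is.na(slot(m, s)))
  # planted flows recovered through the whole chain (incl. residual flow)
  expect_equal(stateFlows(prof)[["ce3U"]], 0.268, tolerance = 1e-3)
  expect_equal(stateFlows(prof)[["1Dig"]], 0.348, tolerance = 1e-3)

  fx <- correctBackground(computeFlux(run$trace), run$trace)
  steps <- extractStepFlux(fx, traceEvents(run$trace), 200)
  no1c <- buildProfile(steps[steps$state_label != "1c", ])
  expect_true(is.na(profileMetrics(no1c)@jc))
  expect_error(buildProfile(steps[steps$state_label != "2Ama", ]),
               "mandatory states missing: 2Ama")
})

test_that("noiseless viability recovery: vi_r = 1 - dead fraction within 0.02", {
  for (d in c(0, 0.1, 0.17, 0.5, 1)) {
    run <- dc_run(deadFraction = d)
    vi <- profileMetrics(analyzeTrace(run$trace))@viR
    expect_lt(abs(vi - (1 - d)), 0.02)
  }
})

test_that("cytochrome-c efficiency stays near zero without planted damage", {
  for (d in c(0, 0.13, 0.5)) {
    run <- dc_run(deadFraction = d)
    expect_lt(abs(profileMetrics(analyzeTrace(run$trace))@jc), 0.05)
  }
})

test_that("all derived ratios are invariant to a common flow rescaling", {
  run <- dc_run()
  fx <- correctBackground(computeFlux(run$trace), run$trace)
  steps <- extractStepFlux(fx, traceEvents(run$trace), 200)
  m1 <- profileMetrics(buildProfile(steps))
  alpha <- 3.7
  scaled <- steps
  scaled$i_o2 <- scaled$i_o2 * alpha
  scaled$j_v <- scaled$j_v * alpha
  m2 <- profileMetrics(buildProfile(scaled))
  for (s in c("fcrR", "fcrL", "fcrS", "viR", "jc"))
    expect_lt(abs(slot(m2, s) - slot(m1, s)), 1e-12)
  # and to the choice of normalization column
  m3 <- profileMetrics(buildProfile(steps, flow_col = "j_v"))
  for (s in c("fcrR", "fcrL", "fcrS", "viR", "jc"))
    expect_lt(abs(slot(m3, s) - slot(m1, s)), 1e-12)
})
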