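test_that("a single constant state integrates to the exact closed-form line", {
  # J = 20 pmol/s/mL at 200e6 cells/mL => per-cell flow 0.1 amol/s/x
  run <- simulateTrace(single_state_protocol(300), flat_sample(0.1),
                       clean_chamber(o2Init = 180), noiseParams(0))
  tr <- run$trace
  expect_equal(run$truth$j_cells, 20)
  expect_equal(o2Concentration(tr), 180 - 0.02 * traceTime(tr),
               tolerance = 1e-12)
})

test_that("with no consumers the trace stays at the initial concentration", {
  run <- simulateTrace(single_state_protocol(300), flat_sample(0),
                       clean_chamber(o2Init = 150), noiseParams(0))
  expect_true(all(o2Concentration(run$trace) == 150))
})

test_that("with every cell membrane-damaged, ce5S equals the 1Dig truth", {
  sp <- cellSampleParams(deadFraction = 1)
  run <- simulateTrace(ccvProtocol(sp), sp, clean_chamber(), noiseParams(0))
  tru <- run$truth
  j5 <- tru$j_cells[tru$state_label == "ce5S"]
  jd <- tru$j_cells[tru$state_label == "1Dig"]
  expect_equal(j5, max(jd))
})

test_that("oxygen bookkeeping: planted consumption equals the trace drop", {
  # independent analytic integral of the planted flux incl. ramps
  sp <- cellSampleParams()
  run <- simulateTrace(ccvProtocol(sp), sp, clean_chamber(),
                       noiseParams(0), rampDuration = 20)
  tr <- run$trace; tru <- run$truth
  tau <- attr(tru, "ramp_tau")
  jprev <- c(tru$j_cells[1], tru$j_cells[-nrow(tru)])
  dt <- tru$t_end - tru$t_start
  consumed <- sum(tru$j_cells * dt +
                  (jprev - tru$j_cells) * tau * (1 - exp(-dt / tau))) / 1000
  drop <- tr@metadata$o2_init - o2Concentration(tr)[length(tr@time)]
  expect_equal(consumed, drop, tolerance = 1e-9)
})

test_that("noiseless traces are non-increasing when background consumes", {
  sp <- cellSampleParams()
  ch <- chamberConfig(backgroundA = 0.5, backgroundB = 0.01)
  run <- simulateTrace(ccvProtocol(sp), sp, ch, noiseParams(0))
  expect_true(all(diff(o2Concentration(run$trace)) <= 0))
})

test_that("identical seeds reproduce identical traces, different seeds differ", {
  a <- dc_run(sigma = 0.2, seed = 11L)
  b <- dc_run(sigma = 0.2, seed = 11L)
  c <- dc_run(sigma = 0.2, seed = 12L)
  expect_identical(o2Concentration(a$trace), o2Concentration(b$trace))
  expect_false(identical(o2Concentration(a$trace), o2Concentration(c$trace)))
})

test_that("out-of-order protocols are rejected", {
  ev <- data.frame(time_s = c(0, 100), state_label = c("ce1P", "ce1"),
                   substance = c("pyruvate", "sample"),
                   cumulative_conc = c(10, NA), units = c("mmol/L", ""),
                   step_index = c(1L, 1L))
  expect_error(suitProtocol(ev), "protocol order")
  ev2 <- ev[2:1, ]   # labels fine, but times now decreasing
  expect_error(suitProtocol(ev2), "increasing")
})

test_that("an over-long run truncates at anoxia and is flagged", {
  expect_warning(
    run <- simulateTrace(single_state_protocol(20000), flat_sample(0.2),
                         clean_chamber(o2Init = 100), noiseParams(0)),
    "anoxic")
  expect_true(run$trace@truncated)
  expect_true(all(o2Concentration(run$trace) > 0))
  expect_lt(max(traceTime(run$trace)), 20000)
})

test_that("titration responses follow the planted dose-response shapes", {
  sp <- cellSampleParams()   # R=0.13, L=0.04, E=0.26, S=0.34
  # oligomycin saturates exactly at L from the threshold on
  expect_equal(simulateTitrationResponse("oligomycin", 10, sp), 0.04)
  expect_equal(simulateTitrationResponse("oligomycin", 40, sp), 0.04)
  expect_gt(simulateTitrationResponse("oligomycin", 5, sp), 0.04)
  # FCCP peaks exactly at E at the optimum
  expect_equal(simulateTitrationResponse("FCCP", 1.0, sp), 0.26)
  # two steps past the optimum with 5% decline per step: 0.90 E
  expect_equal(simulateTitrationResponse("FCCP", 1.0 + 2 * 0.5, sp),
               0.90 * 0.26)
  # digitonin reaches full S-linked capacity at its optimum
  expect_equal(simulateTitrationResponse("digitonin", 5, sp), 0.34)
  expect_equal(simulateTitrationResponse("digitonin", 5 + 2 * 2.5, sp),
               0.90 * 0.34)
  expect_error(simulateTitrationResponse("rotenone", 1, sp), "unknown")
})

test_that("planted cohort ground truth respects the coupling order E >= R >= L >= 0", {
  for (s in 1:5) {
    rec <- simulateCohort(nDonors = 8, seed = s, emitTraces = FALSE)$records
    expect_true(all(rec$e_ce3U >= rec$r_ce1P))
    expect_true(all(rec$r_ce1P >= rec$l_ce2Omy))
    expect_true(all(rec$l_ce2Omy >= 0))
  }
})

test_that("degenerate cohorts collapse to identical planted profiles", {
  tt <- cohortTruth(methodEffects = data.frame(
    method = c("DC", "PA", "WA"), rMult = 1, eMult = 1, sMult = 1,
    omyMult = 1, fccpMult = 1, digMult = 1, deadFraction = 0.13),
    donorCV = 0, pathwayCV = 0)
  rec <- simulateCohort(nDonors = 3, truth = tt, seed = 1,
                        emitTraces = FALSE)$records
  for (col in c("r_ce1P", "e_ce3U", "s_1Dig", "fcr_s_true"))
    expect_equal(length(unique(rec[[col]])), 1L)
  expect_error(simulateCohort(nDonors = 1), ">= 2")
})

test_that("planted method multipliers appear exactly in the ground truth", {
  tt <- cohortTruth(donorCV = 0, pathwayCV = 0)
  rec <- simulateCohort(nDonors = 29, truth = tt, seed = 5,
                        emitTraces = FALSE)$records
  wide <- split(rec, rec$donor_id)
  for (d in wide) {
    expect_equal(d$r_ce1P[d$method == "PA"] / d$r_ce1P[d$method == "DC"],
                 1.22)
    expect_equal(d$e_ce3U[d$method == "PA"] / d$e_ce3U[d$method == "DC"],
                 1.16)
    expect_equal(d$s_1Dig[d$method == "PA"] / d$s_1Dig[d$method == "DC"],
                 0.57)
  }
})

test_that("activation markers hit the target squared correlation", {
  r2s <- vapply(1:20, function(s) {
    rec <- simulateCohort(nDonors = 17, seed = s, emitTraces = FALSE)$records
    dualRegression(rec$fcr_s_true, rec$cd62p_pct)@r2
  }, numeric(1))
  expect_lt(abs(mean(r2s) - 0.27), 0.1)
})

test_that("optional dilution arithmetic scales O2 and cellular flux at injections", {
  ev <- data.frame(time_s = c(0, 100), state_label = c("ce1", "ce1P"),
                   substance = c("sample", "pyruvate"),
                   cumulative_conc = c(NA, 10), units = c("", "mmol/L"),
                   step_index = c(1L, 1L), injection_ul = c(0, 25))
  sp <- flat_sample(0.1)   # J = 20 pmol/s/mL before dilution
  ch <- clean_chamber(o2Init = 180)
  # off by default: the injection changes nothing
  plain <- simulateTrace(suitProtocol(ev, duration_s = 200), sp, ch,
                         noiseParams(0), rampDuration = 0)
  expect_equal(o2Concentration(plain$trace),
               180 - 0.02 * traceTime(plain$trace), tolerance = 1e-12)
  # on: a 25 uL injection into 0.5 mL dilutes O2 and cells by 5%
  run <- simulateTrace(suitProtocol(ev, duration_s = 200), sp, ch,
                       noiseParams(0), rampDuration = 0, dilution = TRUE)
  o2 <- o2Concentration(run$trace)
  t <- traceTime(run$trace)
  expect_equal(o2[t == 100], 178)   # sampled just before mixing
  expect_equal(o2[t == 102], 178 * 0.95 - 0.002 * 19, tolerance = 1e-9)
  expect_equal(run$truth$j_cells, c(20, 19))
})
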