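test_that("default spec carries the reference parameterization", {
  s <- default_spec()
  expect_equal(unlist(s$rates),
               c(kCAT = 0.034, kPRDX = 0.26, kTXN = 0.23, kTXNRD = 0.31,
                 kGSR = 0.08, kGPX = 67))
  expect_equal(unlist(s$pools),
               c(CAT = 0.001, GPX = 0.05, GSR = 0.05, TXNRD = 0.025,
                 PRDX_total = 0.15, TXN_total = 0.025, GSH_total = 3.0))
  expect_true(all(unlist(s$mask)))
  expect_equal(s$h2o2_influx, 1e-5)
})

test_that("constructors reject invalid parameters", {
  expect_error(rate_constants(kCAT = 0), "positive")
  expect_error(rate_constants(kGPX = -1), "positive")
  expect_error(enzyme_pools(CAT = -0.1), "non-negative")
  expect_error(pathway_mask(cat = NA), "TRUE or FALSE")
  expect_error(model_spec(h2o2_influx = -1e-6), "non-negative")
})

test_that("config round-trip honours table symbols and rejects unknowns", {
  expect_equal(spec_from_config(NULL), default_spec())
  s <- spec_from_config(list(kGPX = 10, GSH = 1.5, H2O2_IN = 2e-5))
  expect_equal(s$rates$kGPX, 10)
  expect_equal(s$pools$GSH_total, 1.5)
  expect_equal(s$h2o2_influx, 2e-5)
  expect_equal(s$rates$kCAT, 0.034) # omitted keys keep defaults
  expect_error(spec_from_config(list(kFOO = 1)), "kFOO")

  path <- tempfile(fileext = ".yaml")
  writeLines(c("kCAT: 0.05", "PRDX: 0.3"), path)
  s2 <- read_model_config(path)
  expect_equal(s2$rates$kCAT, 0.05)
  expect_equal(s2$pools$PRDX_total, 0.3)
})

test_that("derivatives match hand-computed mass-action values", {
  spec <- default_spec()
  # no peroxide, fully reduced: only the influx term survives
  d0 <- derivatives(initial_state(spec), spec)
  expect_equal(d0[["H2O2"]], 1e-5)
  expect_equal(unname(d0[names(d0) != "H2O2"]), rep(0, 6))

  # GSSG production at H2O2=0.1: kGPX*H*GSH*GPX = 67*0.1*3*0.05
  st <- redox_state(H2O2 = 0.1, GSH = 3, GSSG = 0, PRDX_red = 0.15,
                    PRDX_ox = 0, TXN_red = 0.025, TXN_ox = 0)
  expect_equal(derivatives(st, spec)[["GSSG"]], 1.005)

  # all pathways off: influx only, couples frozen
  off <- model_spec(mask = pathway_mask(FALSE, FALSE, FALSE))
  d <- derivatives(st, off)
  expect_identical(d[["H2O2"]], 1e-5)
  expect_equal(unname(d[names(d) != "H2O2"]), rep(0, 6))

  expect_error(derivatives(unclass(st) - 1, spec), "negative concentration")
})

test_that("derivatives agree with a literal equation transcription", {
  set.seed(42)
  for (i in 1:100) {
    spec <- random_spec()
    st <- random_state(spec)
    got <- derivatives(st, spec)
    want <- literal_rhs(st, redoxsim:::masked_rates(spec), spec$pools,
                        spec$h2o2_influx)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("couple derivative pairs sum to exactly zero", {
  set.seed(7)
  for (i in 1:25) {
    spec <- random_spec()
    d <- derivatives(random_state(spec), spec)
    expect_identical(d[["GSH"]] + d[["GSSG"]], 0)
    expect_identical(d[["PRDX_red"]] + d[["PRDX_ox"]], 0)
    expect_identical(d[["TXN_red"]] + d[["TXN_ox"]], 0)
  }
})

test_that("simulation conserves couples and stays non-negative", {
  set.seed(11)
  for (i in 1:10) {
    spec <- random_spec()
    traj <- simulate_redox(spec, t_end = 1e5, n_output = 51L)
    p <- spec$pools
    expect_lt(max(abs(traj$GSH + traj$GSSG - p$GSH_total)) /
                p$GSH_total, 1e-9)
    expect_lt(max(abs(traj$PRDX_red + traj$PRDX_ox - p$PRDX_total)) /
                p$PRDX_total, 1e-9)
    expect_lt(max(abs(traj$TXN_red + traj$TXN_ox - p$TXN_total)) /
                p$TXN_total, 1e-9)
    expect_true(all(as.matrix(traj[-1L]) >= 0))
  }
})

test_that("zero influx from the reduced state is a fixed point", {
  spec <- default_spec()
  spec$h2o2_influx <- 0
  traj <- simulate_redox(spec, t_end = 1e4, n_output = 21L)
  init <- initial_state(spec)
  for (nm in names(init))
    expect_equal(traj[[nm]], rep(init[[nm]], nrow(traj)))
})

test_that("inactive pathway leaves its couple exactly at init", {
  # catalase alone: both redox couples must never move
  spec <- model_spec(mask = pathway_mask(prdx_txn = FALSE, cat = TRUE,
                                         gpx_gsh = FALSE))
  traj <- simulate_redox(spec, t_end = 1e5, n_output = 31L)
  expect_true(all(traj$GSSG == 0) && all(traj$GSH == 3.0))
  expect_true(all(traj$PRDX_ox == 0) && all(traj$PRDX_red == 0.15))
  expect_true(all(traj$TXN_ox == 0) && all(traj$TXN_red == 0.025))
  expect_gt(traj$H2O2[nrow(traj)], 0)
})

test_that("large-glutathione limit matches the scalar linear ODE", {
  # influx raised so the peroxide level stays far above the integrator's
  # absolute tolerance; glutathione still depletes only negligibly
  spec <- model_spec(pools = enzyme_pools(GSH_total = 3000),
                     h2o2_influx = 1e-2)
  k <- spec$rates; p <- spec$pools
  slope <- k$kCAT * p$CAT + k$kGPX * p$GPX * p$GSH_total +
    k$kPRDX * p$PRDX_total
  t_end <- 12 / slope
  traj <- simulate_redox(spec, t_end = t_end, n_output = 41L)
  closed <- spec$h2o2_influx / slope * (1 - exp(-slope * traj$time_ms))
  idx <- traj$time_ms > 0
  expect_lt(max(abs(traj$H2O2[idx] - closed[idx]) / closed[idx]), 1e-4)
})

test_that("catalase-only steady level matches the closed form", {
  spec <- model_spec(mask = pathway_mask(FALSE, TRUE, FALSE))
  traj <- simulate_redox(spec, t_end = 1e6, n_output = 11L)
  expect_equal(traj$H2O2[nrow(traj)], 1e-5 / (0.034 * 0.001),
               tolerance = 1e-4)
})

test_that("simulate rejects inconsistent or negative initial states", {
  spec <- default_spec()
  bad <- redox_state(H2O2 = 0, GSH = 2.0, GSSG = 0, PRDX_red = 0.15,
                     PRDX_ox = 0, TXN_red = 0.025, TXN_ox = 0)
  expect_error(simulate_redox(spec, t_end = 10, init = bad),
               "conservation")
  expect_error(simulate_redox(spec, t_end = -5), "t_end")
  expect_error(redox_state(H2O2 = -1), "negative")
})

test_that("trajectory CSV export uses the documented schema", {
  spec <- default_spec()
  traj <- simulate_redox(spec, t_end = 100, n_output = 5L)
  path <- tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  got <- utils::read.csv(path)
  expect_identical(names(got),
                   c("time_ms", "H2O2", "GSH", "GSSG", "PRDX_red",
                     "PRDX_ox", "TXN_red", "TXN_ox"))
  expect_equal(got$GSH, traj$GSH)
})
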