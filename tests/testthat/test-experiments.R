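test_that("plasticity-curve classification follows the binning scheme", {
  scheme <- classification_scheme()
  mk <- function(r250, r50 = 0.9, r150 = 1.1) {
    structure(list(ca_amplitudes = c(0, 50, 150, 250),
                   responses = c(1, r50, r150, r250),
                   peak_free_ca = rep(100, 4), baseline_gsyn = 33),
              class = "plasticity_curve")
  }
  expect_equal(classify(mk(2.24), scheme), 6L)   # (2.24-0.16)/0.36 = 5.78
  expect_equal(classify(mk(0.16), scheme), 1L)
  expect_equal(classify(mk(0.01), scheme), 1L)   # clamped below
  expect_equal(classify(mk(99), scheme), 16L)    # clamped above
  expect_equal(classify(mk(1.96)), 6L)           # class-6 lower edge
  expect_equal(classify(mk(2.32)), 7L)
  alt <- classification_scheme(classify_on = 50)
  expect_equal(classify(mk(2.24, r50 = 0.5), alt), 1L)
})

test_that("subclass deviance and the BCM detector match hand arithmetic", {
  a <- c(`50` = 0.76, `150` = 0.96, `250` = 2.24)
  b <- c(`50` = 1.41, `150` = 1.83, `250` = 2.24)
  expect_equal(subclass_deviance(a, a), 0)
  expect_equal(subclass_deviance(a, b), abs(0.76 - 1.41) + abs(0.96 - 1.83))
  expect_error(subclass_deviance(a, b[1:2]), "match")
  mkc <- function(r) structure(list(ca_amplitudes = c(50, 150, 250),
                                    responses = r),
                               class = "plasticity_curve")
  expect_true(bcm_detector(mkc(c(0.76, 0.96, 2.24))))
  expect_true(bcm_detector(mkc(c(1.2, 0.9, 1.5))))
  expect_false(bcm_detector(mkc(c(1.41, 1.83, 2.24))))
  expect_false(bcm_detector(mkc(c(0.7, 0.8, 0.9))))
})

test_that("zero-amplitude experiments leave the conductance unchanged", {
  net <- builtin_net()
  out <- run_plasticity_experiment(net, NULL, measure_times_min = c(2, 5),
                                   eq_state = builtin_rest())
  expect_equal(unname(out$relative_conductance), c(1, 1), tolerance = 1e-2)
  expect_equal(unname(out$s880_fraction[1]), 0, tolerance = 1e-3)
})

test_that("saturation time is infinite without input", {
  net <- builtin_net()
  tr <- simulate(net, builtin_rest(), NULL, t_end = 310e3, out_dt = 5000)
  # at rest the pools sit at their steady level, so the 95% threshold is
  # already exceeded at t = 0 for a flat trajectory; a zero-amplitude
  # *increase* experiment is detected by comparing against an inflated
  # steady level instead
  expect_equal(ca_saturation_time(tr, net, "cam", threshold = 1.5), Inf)
})

test_that("parameter scans are reproducible from the seed and filter on Ca", {
  net <- builtin_net()
  # scaled-down curve settings keep this a machinery test, not a full experiment
  run <- function() parameter_scan(net, n_samples = 1, seed = 11,
                                   ca_amps = c(0, 250),
                                   duration_s = 20, measure_min = 1)
  a <- run(); b <- run()
  expect_identical(a, b)
  expect_true(all(c("glur1_ratio", "ncx_scale", "f_pka", "f_pkc",
                    "response_250", "class", "excluded") %in% names(a)))
  expect_true(all(a$class >= 1 & a$class <= 16))
  # the exclusion flag is a pure threshold on the recorded peak Ca
  expect_equal(a$excluded, a$peak_free_ca > 2000)
})

test_that("the robustness scan flags nothing under a zero perturbation", {
  net <- builtin_net()
  res <- robustness_scan(net, protocols = list(HFS = make_hfs()),
                         delta = 0, parameters = "init:PMCA",
                         measure_min = 2)
  expect_equal(nrow(res), 2L)   # 1 parameter x 2 (degenerate) directions
  expect_true(all(res$amplitude_change < 1e-9))
  expect_false(any(res$flagged))
  expect_equal(length(spinedyn:::enumerate_parameters(net)),
               47 + 140 + sum(net$grouped$kb > 0))
  expect_equal(sum(startsWith(spinedyn:::enumerate_parameters(net), "init:")),
               47)
})
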