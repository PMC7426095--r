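test_that("standard protocols have the documented pulse structure", {
  p4 <- make_4xhfs()
  ca <- p4$pulses[p4$pulses$channel == "Ca", ]
  expect_equal(nrow(ca), 400)
  expect_equal(max(ca$onset) - min(ca$onset), 12960)  # 3*(990+3000)+990
  expect_equal(program_span(p4), 12963)
  expect_true(all(ca$amplitude == 1900))
  expect_true(all(ca$duration == 3))

  lfs <- make_lfs()
  expect_equal(sum(lfs$pulses$channel == "Ca"), 900)
  expect_equal(program_span(lfs), 899 * 200 + 3)

  hfst <- make_6xhfst()
  expect_equal(sum(hfst$pulses$channel == "Ca"), 6 * 10 * 4)

  # channel suppression
  h <- make_hfs(ca = 0)
  expect_false("Ca" %in% h$pulses$channel)
  expect_equal(sum(h$pulses$channel == "L"), 100)
})

test_that("square pulses and bath applications build single pulses", {
  sq <- make_square_pulse(250, duration = 300)
  caq <- sq$pulses[sq$pulses$channel == "Ca", ]
  expect_equal(nrow(caq), 1)
  expect_equal(caq$duration, 3e5)
  expect_equal(nrow(make_square_pulse(0, 0, 0, 0)$pulses), 0)
  a <- make_square_pulse(150); b <- make_square_pulse(250)
  expect_equal(a$pulses[a$pulses$channel != "Ca", ],
               b$pulses[b$pulses$channel != "Ca", ])

  bath <- make_bath_application("L", 50, start = -480, duration = 600)
  expect_equal(bath$pulses$onset, -480e3)
  expect_equal(bath$pulses$amplitude, 0.05)      # 50/s = 0.05/ms
  expect_equal(nrow(make_bath_application("ACh", 0)$pulses), 0)
  expect_error(make_bath_application("Ca2"), "unknown")
})

test_that("program union merges channels and is order-independent", {
  a <- make_hfs(); b <- make_bath_application("L", 50)
  u1 <- program_union(a, b); u2 <- program_union(b, a)
  expect_equal(u1$pulses[order(u1$pulses$channel, u1$pulses$onset), ],
               u2$pulses[order(u2$pulses$channel, u2$pulses$onset), ],
               ignore_attr = TRUE)
  expect_equal(nrow(u1$pulses), nrow(a$pulses) + 1)
})

test_that("total injected particles equal amplitude x duration sums", {
  tot <- program_total_particles(make_lfs())
  expect_equal(unname(tot["Ca"]), 900 * 3 * 1900)
  expect_equal(unname(tot["L"]), 900 * 3 * 10)
})

test_that("injected Ca mass agrees with the trajectory source term", {
  net <- builtin_net()
  prog <- make_hfs(l = 0, glu = 0, ach = 0)
  tr <- simulate(net, builtin_rest(), prog, t_end = 2e3, out_dt = 100)
  # all Ca-containing pools: free + extruded + buffered (weights from the
  # saturation pools plus extracellular and CaM-bound calcium)
  w_cam <- spinedyn:::ca_pool_weights(net, "cam")
  w_bp <- spinedyn:::ca_pool_weights(net, "buffers_pumps")
  extra <- c(Ca = 1, CaOut = 1, CaOutLeak = 1, PKCCa = 1, PKCt = 1, PKCp = 1,
             CaDGL = 1, DAGCaDGL = 1, GluR2_memb_PKCt = 1, GluR2_memb_PKCp = 1,
             GluR1_memb_PKCt = 1, GluR1_memb_S845_PKCt = 1,
             GluR1_memb_PKCp = 1, GluR1_memb_S845_PKCp = 1)
  w <- c(w_cam, w_bp, extra)
  total_ca <- function(st) sum(st[names(w)] * w)
  injected_nM <- particles_to_concentration_rate(
    program_total_particles(prog)[["Ca"]], net$volume)
  gain <- total_ca(final_state(tr)) - total_ca(tr$concentrations[1, ])
  expect_equal(gain, injected_nM, tolerance = 1e-3)
})

test_that("Ca trace import validates the file format", {
  f <- tempfile()
  writeLines(c("time\tflux", "0\t0", "1\t5", "2\t3"), f)
  tr <- import_ca_trace(f)
  expect_s3_class(tr, "ca_flux_trace")
  expect_equal(tr$flux, c(0, 5, 3))
  expect_equal(tr$source_tag, "imported")
  writeLines(c("0\t0", "1\t5\t9"), f)
  expect_error(import_ca_trace(f), "line 2")
  expect_error(ca_flux_trace(c(0, 0), c(1, 1)), "strictly increasing")
  expect_error(ca_flux_trace(c(0, 1), c(1, -1)), "nonnegative")
})

test_that("pairing trains tile the per-pairing waveform without overlap", {
  tr <- ca_flux_trace(seq(0, 300, by = 2), rep(10, 151), "synthetic")
  prog <- make_stdp_train(tr, frequency = 1, duration = 120)
  f <- prog$fun_channels$Ca
  expect_equal(attr(f, "t_end"), 119e3 + 300)
  expect_equal(length(attr(f, "breaks")), 120)
  expect_equal(f(c(50, 1050, 119050)), rep(10, 3))
  expect_equal(f(c(-5, 500, 119500)), rep(0, 3))
  long <- ca_flux_trace(seq(0, 1200, by = 10), rep(1, 121), "synthetic")
  expect_error(make_stdp_train(long), "overlap")
})

test_that("the synthetic NMDAR trace peaks for pre-before-post pairings", {
  isis <- seq(-80, 200, by = 10)
  ints <- vapply(isis, function(i) trace_integral(synth_nmdar_trace(i)),
                 numeric(1))
  best <- isis[which.max(ints)]
  expect_true(best >= 10 && best <= 50)
  expect_gt(ints[isis == 0], ints[isis == 200])
  # unimodal: non-decreasing up to the peak (flat baseline for very
  # negative intervals, where the post window precedes the transient
  # entirely), strictly decreasing after
  k <- which.max(ints)
  tol <- 1e-6 * max(ints)
  expect_true(all(diff(ints[seq_len(k)]) >= -tol))
  expect_true(all(diff(ints[k:length(ints)]) < 0))
  # zero drive gives a zero trace
  z <- synth_nmdar_trace(20, peak = 0, bap_peak = 0)
  expect_true(all(z$flux == 0))
})
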