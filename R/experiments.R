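# End-to-end plasticity experiments: equilibrate, stimulate, measure the
# relative synaptic conductance, classify plasticity curves, scan
# parameters, and probe robustness.

.eq_cache <- new.env(parent = emptyenv())

#' Equilibrate with caching
#'
#' Same as \code{\link{equilibrate}} but memoised on the network fingerprint
#' and solver tolerances, so repeated experiments on the same network reuse
#' the resting state.
#' @inheritParams equilibrate
#' @export
equilibrate_cached <- function(network, config = solver_config(),
                               t_eq = 4040e3) {
  key <- paste(network_fingerprint(network), config$rel_tol, config$abs_tol,
               t_eq, sep = "|")
  if (!is.null(.eq_cache[[key]])) return(.eq_cache[[key]])
  st <- equilibrate(network, config, t_eq)
  .eq_cache[[key]] <- st
  st
}

state_at <- function(trajectory, t) {
  tt <- trajectory$times
  if (t <= tt[1]) return(trajectory$concentrations[1, ])
  if (t >= tt[length(tt)])
    return(trajectory$concentrations[length(tt), ])
  i <- findInterval(t, tt)
  w <- (t - tt[i]) / (tt[i + 1] - tt[i])
  (1 - w) * trajectory$concentrations[i, ] +
    w * trajectory$concentrations[i + 1, ]
}

shift_program <- function(program, dt) {
  if (is.null(program) || dt == 0) return(program)
  p <- program
  if (nrow(p$pulses)) p$pulses$onset <- p$pulses$onset + dt
  if (length(p$fun_channels)) {
    p$fun_channels <- lapply(p$fun_channels, function(f) {
      g <- local({ f <- f; dt <- dt; function(t) f(t - dt) })
      attr(g, "breaks") <- attr(f, "breaks") + dt
      attr(g, "t_end") <- attr(f, "t_end") + dt
      g
    })
  }
  p
}

#' Run a plasticity experiment
#'
#' Equilibrates the network (4040 s without inputs), applies the stimulus
#' program, and evaluates the relative synaptic conductance
#' gsyn(t)/gsyn(baseline) at the requested times after stimulation onset.
#' Programs with negative onsets (bath application beginning before the
#' protocol) are handled by simulating the pre-protocol phase first;
#' measurement times remain referenced to the protocol onset (t = 0).
#'
#' @param network a \code{reaction_network}.
#' @param program a \code{stimulus_program}.
#' @param measure_times_min measurement times in minutes after onset.
#' @param config a \code{solver_config}.
#' @param eq_state optional precomputed resting state.
#' @param rule tetramer rule for the conductance model.
#' @param out_dt trajectory output spacing, ms.
#' @return object of class \code{plasticity_outcome}: relative conductance
#'   per measurement time, baseline conductance (pS), auxiliary readouts
#'   (relative membrane GluR1/GluR2, S880-phosphorylated GluR2 fraction,
#'   peak free Ca in nM), and the trajectory.
#' @export
run_plasticity_experiment <- function(network, program, measure_times_min,
                                      config = solver_config(),
                                      eq_state = NULL, rule = "random",
                                      out_dt = 5000) {
  if (is.null(eq_state)) eq_state <- equilibrate_cached(network, config)
  onset_shift <- 0
  if (!is.null(program) && nrow(program$pulses) &&
      min(program$pulses$onset) < 0) {
    onset_shift <- -min(program$pulses$onset)
    program <- shift_program(program, onset_shift)
  }
  measure_ms <- onset_shift + measure_times_min * 60000
  t_end <- max(measure_ms, if (is.null(program)) 0 else program_span(program))
  traj <- simulate(network, eq_state, program, t_end = t_end,
                   config = config, out_dt = out_dt)
  pools <- glur_membrane_pools(network)
  base_g <- gsyn_from_state(eq_state, network, rule = rule)
  base_m1 <- sum(eq_state[pools$glur1])
  base_m2 <- sum(eq_state[pools$glur2])

  rel <- numeric(0); m1 <- numeric(0); m2 <- numeric(0); s880 <- numeric(0)
  for (i in seq_along(measure_ms)) {
    st <- state_at(traj, measure_ms[i])
    nm <- as.character(measure_times_min[i])
    rel[nm] <- gsyn_from_state(st, network, rule = rule) / base_g
    m1[nm] <- sum(st[pools$glur1]) / max(base_m1, 1e-12)
    m2[nm] <- sum(st[pools$glur2]) / max(base_m2, 1e-12)
    s880[nm] <- s880_fraction(st, network)
  }
  structure(list(
    relative_conductance = rel,
    baseline_gsyn = base_g,
    membrane_glur1_rel = m1,
    membrane_glur2_rel = m2,
    s880_fraction = s880,
    peak_free_ca = max(traj$concentrations[, "Ca"]),
    onset_shift_ms = onset_shift,
    trajectory = traj), class = "plasticity_outcome")
}

#' @export
print.plasticity_outcome <- function(x, ...) {
  cat("<plasticity_outcome> baseline", signif(x$baseline_gsyn, 4), "pS;",
      "relative conductance:",
      paste(sprintf("%s min: %.3f", names(x$relative_conductance),
                    x$relative_conductance), collapse = ", "), "\n")
  invisible(x)
}

# Ca-bound pool weights for the saturation-time analysis.
ca_pool_weights <- function(network, pool = c("buffers_pumps", "cam")) {
  pool <- match.arg(pool)
  if (pool == "buffers_pumps") {
    nms <- c("fixedbufferCa", "CalbinC", "PMCACa", "NCXCa",
             "PLCCa", "PLCCaGqaGTP", "PLCCaPip2", "PLCCaDAG",
             "PLCCaGqaGTPPip2", "PLCCaGqaGTPDAG", "CaPLA2", "CaPLA2Pip2")
    w <- stats::setNames(rep(1, length(nms)), nms)
  } else {
    w <- c(CaMCa2 = 2, CaMCa3 = 3, CaMCa4 = 4,
           PP2BCaMCa2 = 2, PP2BCaMCa3 = 3, PP2BCaMCa4 = 4,
           CKCaMCa4 = 4, CKpCaMCa4 = 4, CKpCaMCa4PP1 = 4,
           Complex = 8, pComplex = 8,
           AC1GsaGTPCaMCa4 = 4, AC1CaMCa4 = 4, AC1GiaGTPCaMCa4 = 4,
           AC1GsaGTPCaMCa4ATP = 4, AC1CaMCa4ATP = 4,
           AC1GiaGTPCaMCa4ATP = 4, AC8CaMCa4 = 4, AC8CaMCa4ATP = 4,
           PDE1CaMCa4 = 4, PDE1CaMCa4cAMP = 4,
           Ip35PP2BCaMCa4 = 4, Ip35PP1PP2BCaMCa4 = 4, PP1PP2BCaMCa4 = 4,
           GluR1_memb_CKCaMCa4 = 4, GluR1_memb_S845_CKCaMCa4 = 4,
           GluR1_memb_CKpCaMCa4 = 4, GluR1_memb_S845_CKpCaMCa4 = 4,
           GluR1_memb_S845_PP2B = 4, GluR1_memb_S845_S831_PP2B = 4,
           GluR1_S845_PP2B = 4, GluR1_S845_S831_PP2B = 4)
  }
  w[names(w) %in% network$species$name]
}

#' Time to 95% saturation of a Ca-binding pool
#'
#' For a square-pulse trajectory, finds the first time (after stimulation
#' onset) at which the summed Ca-bound amount of the pool exceeds
#' \code{threshold} times its steady level, the steady level being the value
#' at \code{steady_at_s} (5 min by default) after onset.
#'
#' @param trajectory a \code{trajectory_result} starting at the pulse onset.
#' @param network the network.
#' @param pool \code{"buffers_pumps"} (immobile buffer, calbindin, PMCA,
#'   NCX, PLC, PLA2) or \code{"cam"} (Ca bound to calmodulin in all forms).
#' @param threshold saturation threshold (default 0.95).
#' @param steady_at_s time defining the steady level, seconds after onset.
#' @return first-crossing time in seconds (\code{Inf} if never reached).
#' @export
ca_saturation_time <- function(trajectory, network, pool = "buffers_pumps",
                               threshold = 0.95, steady_at_s = 300) {
  w <- ca_pool_weights(network, pool)
  tot <- as.vector(trajectory$concentrations[, names(w), drop = FALSE] %*% w)
  tt <- trajectory$times
  steady <- stats::approx(tt, tot, xout = steady_at_s * 1000, rule = 2)$y
  target <- threshold * steady
  above <- which(tot >= target)
  if (!length(above)) return(Inf)
  i <- above[1]
  if (i == 1) return(tt[1] / 1000)
  # linear interpolation of the crossing
  t_cross <- tt[i - 1] + (target - tot[i - 1]) /
    (tot[i] - tot[i - 1]) * (tt[i] - tt[i - 1])
  t_cross / 1000
}

#' Classification scheme for plasticity curves
#'
#' Responses (relative conductance at the classifying Ca amplitude) are
#' binned into \code{n_classes} classes of width \code{bin_width} starting
#' at \code{range_min}: the observed response range 0.16..5.92 yields 16
#' classes of width 0.36.
#'
#' @param n_classes,bin_width,range_min binning parameters.
#' @param classify_on Ca amplitude (particles/ms) whose response drives the
#'   binning (250 by default; 50 for the alternative scheme).
#' @export
classification_scheme <- function(n_classes = 16, bin_width = 0.36,
                                  range_min = 0.16, classify_on = 250) {
  structure(list(n_classes = n_classes, bin_width = bin_width,
                 range_min = range_min, classify_on = classify_on),
            class = "classification_scheme")
}

#' Plasticity curve under square-pulse Ca inputs
#'
#' Applies 5-min square-pulse Ca inputs of each amplitude (with co-applied
#' square-pulse neuromodulators) to the scaled network and records the
#' relative synaptic conductance at \code{measure_min} after onset.
#'
#' @param network base \code{reaction_network}.
#' @param scalers a \code{concentration_scalers}.
#' @param ca_amps Ca flux amplitudes in particles/ms.
#' @param measure_min measurement time, minutes after onset.
#' @param duration_s square-pulse duration in seconds.
#' @param l_amp,glu_amp,ach_amp neuromodulator amplitudes, particles/ms.
#' @param config solver configuration.
#' @param rule tetramer rule.
#' @return object of class \code{plasticity_curve} with fields
#'   \code{ca_amplitudes}, \code{responses}, \code{peak_free_ca} (nM) and
#'   \code{baseline_gsyn}.
#' @export
plasticity_curve <- function(network, scalers = concentration_scalers(),
                             ca_amps = c(0, 50, 150, 250), measure_min = 15,
                             duration_s = 300, l_amp = 10, glu_amp = 20,
                             ach_amp = 20, config = solver_config(),
                             rule = "random") {
  net <- apply_scalers(network, scalers)
  eq <- equilibrate_cached(net, config)
  resp <- numeric(length(ca_amps)); pk <- numeric(length(ca_amps))
  base_g <- NA_real_
  for (i in seq_along(ca_amps)) {
    prog <- make_square_pulse(ca_amps[i], l_amp, glu_amp, ach_amp,
                              duration = duration_s, volume = net$volume)
    out <- run_plasticity_experiment(net, prog, measure_min, config,
                                     eq_state = eq, rule = rule)
    resp[i] <- out$relative_conductance[[1]]
    pk[i] <- out$peak_free_ca
    base_g <- out$baseline_gsyn
  }
  structure(list(ca_amplitudes = ca_amps, responses = resp,
                 peak_free_ca = pk, baseline_gsyn = base_g,
                 scalers = unclass(scalers)),
            class = "plasticity_curve")
}

#' Classify a plasticity curve
#'
#' Class index 1 + floor((response - range_min)/bin_width) at the scheme's
#' classifying amplitude, clamped to [1, n_classes].
#'
#' @param curve a \code{plasticity_curve} (or a named response vector with
#'   names equal to the Ca amplitudes).
#' @param scheme a \code{classification_scheme}.
#' @return integer class index.
#' @export
classify <- function(curve, scheme = classification_scheme()) {
  resp <- if (inherits(curve, "plasticity_curve")) {
    i <- match(scheme$classify_on, curve$ca_amplitudes)
    if (is.na(i)) stop("curve does not contain the classifying amplitude ",
                       scheme$classify_on)
    curve$responses[i]
  } else curve[[as.character(scheme$classify_on)]]
  # guard against float error at bin edges (e.g. (2.32-0.16)/0.36)
  cls <- 1 + floor((resp - scheme$range_min) / scheme$bin_width + 1e-9)
  as.integer(min(max(cls, 1), scheme$n_classes))
}

#' Summed absolute deviance between two plasticity curves
#'
#' @param curve_a,curve_b \code{plasticity_curve} objects (or response
#'   vectors) on matching nonzero-amplitude grids.
#' @return total deviance (sum of absolute response differences over the
#'   nonzero Ca amplitudes).
#' @export
subclass_deviance <- function(curve_a, curve_b) {
  get <- function(cv) {
    if (inherits(cv, "plasticity_curve")) {
      keep <- cv$ca_amplitudes > 0
      stats::setNames(cv$responses[keep], cv$ca_amplitudes[keep])
    } else cv
  }
  a <- get(curve_a); b <- get(curve_b)
  if (!identical(names(a), names(b)))
    stop("amplitude grids do not match")
  sum(abs(a - b))
}

#' Detect a BCM-shaped plasticity curve
#'
#' TRUE when a low or medium Ca amplitude (50 or 150 particles/ms) yields
#' depression while the high amplitude (250) yields potentiation.
#'
#' @param curve a \code{plasticity_curve}.
#' @return logical flag.
#' @export
bcm_detector <- function(curve) {
  r <- stats::setNames(curve$responses, curve$ca_amplitudes)
  need <- c("50", "150", "250")
  if (!all(need %in% names(r)))
    stop("curve must contain responses at 50, 150 and 250 particles/ms")
  (r[["50"]] < 1 || r[["150"]] < 1) && r[["250"]] > 1
}

#' Random scan of the concentration-parameter space
#'
#' Samples GluR1 ratio ~ U(0,1) and NCX / PKA-pathway / PKC-pathway factors
#' ~ U(0,2), computes the plasticity curve of every sample, classifies it,
#' and flags samples whose peak free Ca exceeds the physiological filter
#' (default 2 uM), which are excluded from classification summaries.
#'
#' @param network base network.
#' @param n_samples number of parameter sets.
#' @param seed RNG seed (required: scans are reproducible by construction).
#' @param ca_amps Ca amplitudes of the curve.
#' @param filter_ca_max free-Ca exclusion threshold in nM.
#' @param scheme classification scheme.
#' @param forced optional data.frame of parameter values to use instead of
#'   sampling (columns glur1_ratio, ncx_scale, f_pka, f_pkc).
#' @param ... passed to \code{\link{plasticity_curve}} (e.g. shorter
#'   \code{duration_s} and \code{measure_min} for scaled-down scans).
#' @return data.frame: one row per sample with the parameters, responses per
#'   amplitude, peak free Ca, class index and exclusion flag.
#' @export
parameter_scan <- function(network, n_samples = 2000, seed,
                           ca_amps = c(0, 50, 150, 250),
                           filter_ca_max = 2000,
                           scheme = classification_scheme(),
                           forced = NULL, ...) {
  if (missing(seed)) stop("a seed is required for a parameter scan")
  set.seed(seed)
  pars <- if (!is.null(forced)) forced else
    data.frame(glur1_ratio = stats::runif(n_samples, 0, 1),
               ncx_scale = stats::runif(n_samples, 0, 2),
               f_pka = stats::runif(n_samples, 0, 2),
               f_pkc = stats::runif(n_samples, 0, 2))
  rows <- lapply(seq_len(nrow(pars)), function(i) {
    sc <- concentration_scalers(glur1_ratio = pars$glur1_ratio[i],
                                ncx_scale = pars$ncx_scale[i],
                                f_pka = pars$f_pka[i],
                                f_pkc = pars$f_pkc[i])
    cv <- plasticity_curve(network, sc, ca_amps = ca_amps, ...)
    resp <- stats::setNames(as.list(cv$responses),
                            paste0("response_", cv$ca_amplitudes))
    peak <- max(cv$peak_free_ca)
    cbind(pars[i, , drop = FALSE],
          as.data.frame(resp),
          data.frame(peak_free_ca = peak,
                     class = classify(cv, scheme),
                     excluded = peak > filter_ca_max))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Enumerate the tunable parameters of the grouped table: nonzero initial
# concentrations and nonzero forward/backward rates (one parameter per
# grouped row; perturbing it moves all expanded members together).
enumerate_parameters <- function(network) {
  sp <- network$species
  g <- network$grouped
  c(paste0("init:", sp$name[sp$init > 0]),
    paste0("kf:", g$id[g$kf > 0]),
    paste0("kb:", g$id[g$kb > 0]))
}

perturb_parameter <- function(network, param, factor) {
  net <- network
  kind <- sub(":.*$", "", param)
  target <- sub("^[^:]*:", "", param)
  if (kind == "init") {
    i <- species_index(net, target)
    net$species$init[i] <- net$species$init[i] * factor
  } else {
    hit <- net$reactions$base_id == as.integer(target)
    if (!any(hit)) stop("unknown reaction id: ", target)
    if (kind == "kf") net$reactions$kf[hit] <- net$reactions$kf[hit] * factor
    else net$reactions$kb[hit] <- net$reactions$kb[hit] * factor
  }
  net$metadata$perturbation <- list(param = param, factor = factor)
  net
}

#' Single-parameter robustness scan
#'
#' Perturbs each parameter (initial concentration or grouped reaction rate)
#' one at a time by +/- \code{delta}, reruns the given protocols, and flags
#' parameters whose LTP/LTD amplitude (|relative conductance - 1|) changes
#' by more than \code{threshold} of the default amplitude.
#'
#' @param network base network.
#' @param protocols named list of \code{stimulus_program}s (default LFS and
#'   4xHFS).
#' @param delta relative perturbation (default 0.10).
#' @param threshold amplitude-change flag threshold (default 0.15).
#' @param parameters parameter ids (default: all enumerated parameters —
#'   a full scan is an overnight job; pass a subset for desk-scale runs).
#' @param measure_min measurement time, minutes after protocol onset.
#' @param config solver configuration.
#' @return data.frame: parameter, direction, protocol, relative conductance,
#'   amplitude change, flag.
#' @export
robustness_scan <- function(network,
                            protocols = list(LFS = make_lfs(),
                                             `4xHFS` = make_4xhfs()),
                            delta = 0.10, threshold = 0.15,
                            parameters = NULL, measure_min = 16,
                            config = solver_config()) {
  if (is.null(parameters)) parameters <- enumerate_parameters(network)
  base_rel <- vapply(protocols, function(p)
    run_plasticity_experiment(network, p, measure_min,
                              config)$relative_conductance[[1]],
    numeric(1))
  rows <- list()
  for (par in parameters) {
    for (dir in c(1 - delta, 1 + delta)) {
      net2 <- perturb_parameter(network, par, dir)
      for (pn in names(protocols)) {
        rel <- run_plasticity_experiment(net2, protocols[[pn]], measure_min,
                                         config)$relative_conductance[[1]]
        d_amp <- abs((rel - 1) - (base_rel[[pn]] - 1))
        rows[[length(rows) + 1]] <- data.frame(
          parameter = par, factor = dir, protocol = pn,
          relative_conductance = rel,
          amplitude_change = d_amp,
          flagged = d_amp > threshold * abs(base_rel[[pn]] - 1))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- base_rel
  out
}

#' Spike-timing-dependent plasticity curve
#'
#' For each inter-stimulus interval, builds the pairing protocol from the
#' supplied per-pairing Ca trace (1 Hz for 2 min by default), adds bath
#' neuromodulators per preset (beta-adrenergic ligand and/or ACh at 50
#' particles/s for 10 min starting 8 min before the protocol), blocks mGluR
#' activation throughout, and measures the outcome. Also reports the
#' correlation of the outcome with the peak and with the time-averaged Ca
#' input across the ISI sweep.
#'
#' @param network base network.
#' @param traces named list of \code{ca_flux_trace}s; names are ISIs in ms.
#' @param neuromod_preset one of "none", "beta", "ach", "beta+ach".
#' @param measure_min outcome time, minutes after protocol onset.
#' @param frequency pairing frequency, Hz.
#' @param duration_s pairing-train duration, seconds.
#' @param bath_rate,bath_start,bath_duration bath parameters (particles/s,
#'   s relative to onset, s).
#' @param config solver configuration.
#' @return object of class \code{stdp_curve}: per-ISI outcomes, input
#'   statistics, and the outcome/input correlations.
#' @export
stdp_curve <- function(network, traces,
                       neuromod_preset = c("beta+ach", "none", "beta", "ach"),
                       measure_min = 16, frequency = 1, duration_s = 120,
                       bath_rate = 50, bath_start = -480, bath_duration = 600,
                       config = solver_config()) {
  neuromod_preset <- match.arg(neuromod_preset)
  net <- apply_manipulation(network, "no_mglur")
  eq <- equilibrate_cached(net, config)
  isis <- as.numeric(names(traces))
  if (anyNA(isis)) stop("trace list must be named by ISI (ms)")
  outc <- numeric(length(isis))
  m1 <- numeric(length(isis)); m2 <- numeric(length(isis))
  pk <- numeric(length(isis)); mn <- numeric(length(isis))
  for (i in seq_along(isis)) {
    tr <- traces[[i]]
    prog <- make_stdp_train(tr, frequency = frequency,
                            duration = duration_s, volume = net$volume)
    if (neuromod_preset %in% c("beta", "beta+ach"))
      prog <- program_union(prog, make_bath_application(
        "L", bath_rate, bath_start, bath_duration, volume = net$volume))
    if (neuromod_preset %in% c("ach", "beta+ach"))
      prog <- program_union(prog, make_bath_application(
        "ACh", bath_rate, bath_start, bath_duration, volume = net$volume))
    out <- run_plasticity_experiment(net, prog, measure_min, config,
                                     eq_state = eq)
    outc[i] <- out$relative_conductance[[1]]
    m1[i] <- out$membrane_glur1_rel[[1]]
    m2[i] <- out$membrane_glur2_rel[[1]]
    pk[i] <- max(tr$flux)
    mn[i] <- trace_integral(tr) / (1000 / frequency)
  }
  structure(list(
    isi = isis, relative_conductance = outc,
    membrane_glur1_rel = m1, membrane_glur2_rel = m2,
    peak_ca_input = pk, mean_ca_input = mn,
    cor_peak = if (length(isis) > 2) stats::cor(outc, pk) else NA_real_,
    cor_mean = if (length(isis) > 2) stats::cor(outc, mn) else NA_real_,
    preset = neuromod_preset), class = "stdp_curve")
}
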