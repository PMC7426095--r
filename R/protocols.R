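# Stimulation programs: timed particle fluxes on the four input channels
# (Ca, L = beta-adrenergic ligand, Glu, ACh). Pulse onsets/durations are in
# ms and amplitudes in particles/ms; user-facing protocol constructors take
# durations in the units stated in their signatures.

#' Construct a stimulus program
#'
#' @param pulses data.frame with columns \code{channel} (one of Ca, L, Glu,
#'   ACh), \code{onset} (ms), \code{duration} (ms), \code{amplitude}
#'   (particles/ms).
#' @param label protocol name.
#' @param volume compartment volume (um^3) used for unit conversion.
#' @param fun_channels optional named list of functions \code{f(t_ms)}
#'   returning particles/ms for a channel with arbitrary waveform, each with
#'   attributes \code{breaks} (restart times, ms) and \code{t_end}.
#' @return object of class \code{stimulus_program}.
#' @export
stimulus_program <- function(pulses = NULL, label = "custom", volume = 0.5,
                             fun_channels = list()) {
  if (is.null(pulses))
    pulses <- data.frame(channel = character(), onset = numeric(),
                         duration = numeric(), amplitude = numeric())
  stopifnot(all(pulses$channel %in% INPUT_SPECIES))
  if (nrow(pulses)) {
    if (any(pulses$duration <= 0)) stop("pulse durations must be > 0")
    if (any(pulses$amplitude < 0)) stop("pulse amplitudes must be >= 0")
    pulses <- pulses[order(pulses$channel, pulses$onset), , drop = FALSE]
    rownames(pulses) <- NULL
  }
  structure(list(pulses = pulses, label = label, volume = volume,
                 fun_channels = fun_channels),
            class = "stimulus_program")
}

#' @export
print.stimulus_program <- function(x, ...) {
  cat("<stimulus_program>", x$label, "-", nrow(x$pulses), "pulses")
  if (length(x$fun_channels))
    cat(",", length(x$fun_channels), "waveform channel(s)")
  cat("; span", signif(program_span(x) / 1000, 4), "s\n")
  invisible(x)
}

#' Time span of a program in ms
#' @param program a \code{stimulus_program}.
#' @export
program_span <- function(program) {
  ends <- 0
  if (nrow(program$pulses))
    ends <- max(ends, program$pulses$onset + program$pulses$duration)
  for (f in program$fun_channels) ends <- max(ends, attr(f, "t_end"))
  ends
}

#' Union of two stimulus programs
#'
#' Channel lists are merged and re-sorted; union is associative and
#' order-independent.
#' @param a,b \code{stimulus_program} objects (same volume).
#' @export
program_union <- function(a, b) {
  stopifnot(a$volume == b$volume)
  if (length(intersect(names(a$fun_channels), names(b$fun_channels))))
    stop("cannot merge two waveform definitions of the same channel")
  stimulus_program(rbind(a$pulses, b$pulses),
                   label = paste(a$label, b$label, sep = "+"),
                   volume = a$volume,
                   fun_channels = c(a$fun_channels, b$fun_channels))
}

#' Total injected particles per channel
#' @param program a \code{stimulus_program}.
#' @return named vector, particles.
#' @export
program_total_particles <- function(program) {
  tot <- stats::setNames(numeric(length(INPUT_SPECIES)), INPUT_SPECIES)
  p <- program$pulses
  if (nrow(p))
    for (ch in unique(p$channel))
      tot[ch] <- sum(p$duration[p$channel == ch] * p$amplitude[p$channel == ch])
  for (ch in names(program$fun_channels)) {
    f <- program$fun_channels[[ch]]
    tt <- seq(0, attr(f, "t_end"), by = 1)
    tot[ch] <- tot[ch] + sum(f(tt)) * 1
  }
  tot
}

# Decompose a program into piecewise-constant integration segments.
# Returns list(table = data.frame(t0, t1), inputs = list of length-4
# nM/ms vectors or functions). Channels with waveform functions make the
# segment input a function of t.
program_segments <- function(program, t_end, volume, mask) {
  if (is.null(program))
    return(list(table = data.frame(t0 = 0, t1 = t_end),
                inputs = list(numeric(4))))
  p <- program$pulses
  edges <- c(0, t_end)
  if (nrow(p)) edges <- c(edges, p$onset, p$onset + p$duration)
  for (f in program$fun_channels) edges <- c(edges, attr(f, "breaks"))
  edges <- sort(unique(pmin(pmax(edges, 0), t_end)))
  t0 <- edges[-length(edges)]; t1 <- edges[-1]
  conv <- particles_to_concentration_rate(1, volume)
  maskv <- unname(mask[INPUT_SPECIES])

  base_inputs <- lapply(seq_along(t0), function(k) {
    mid <- (t0[k] + t1[k]) / 2
    v <- stats::setNames(numeric(4), INPUT_SPECIES)
    if (nrow(p)) {
      act <- p[p$onset <= mid & (p$onset + p$duration) > mid, , drop = FALSE]
      if (nrow(act))
        for (ch in unique(act$channel))
          v[ch] <- sum(act$amplitude[act$channel == ch])
    }
    unname(v) * conv * maskv
  })
  if (length(program$fun_channels)) {
    fidx <- match(names(program$fun_channels), INPUT_SPECIES)
    inputs <- lapply(seq_along(t0), function(k) {
      const <- base_inputs[[k]]
      fs <- program$fun_channels
      local({
        const <- const; fs <- fs; fidx <- fidx
        function(t) {
          v <- const
          for (j in seq_along(fs))
            v[fidx[j]] <- v[fidx[j]] + fs[[j]](t) * conv * maskv[fidx[j]]
          v
        }
      })
    })
  } else inputs <- base_inputs
  list(table = data.frame(t0 = t0, t1 = t1), inputs = inputs)
}

make_pulse_train <- function(label, train_onsets, pulses_per_train,
                             pulse_interval, width = 3,
                             ca = 1900, l = 10, glu = 20, ach = 20,
                             volume = 0.5) {
  onsets <- as.vector(outer(seq_len(pulses_per_train) - 1, train_onsets,
                            function(i, o) o + i * pulse_interval))
  amps <- c(Ca = ca, L = l, Glu = glu, ACh = ach)
  amps <- amps[amps > 0]
  if (!length(amps))
    return(stimulus_program(NULL, label = label, volume = volume))
  pulses <- do.call(rbind, lapply(names(amps), function(ch)
    data.frame(channel = ch, onset = onsets, duration = width,
               amplitude = amps[[ch]])))
  stimulus_program(pulses, label = label, volume = volume)
}

#' Standard induction protocols
#'
#' All protocols deliver 3 ms Ca pulses of 1900 particles/ms, each
#' accompanied by 3 ms pulses of beta-adrenergic ligand (10 particles/ms),
#' glutamate (20 particles/ms) and acetylcholine (20 particles/ms); set an
#' amplitude to 0 to suppress a channel.
#' \itemize{
#' \item \code{make_hfs}: 100 pulses at 100 Hz.
#' \item \code{make_4xhfs}: four HFS trains separated by 3 s of quiescence.
#' \item \code{make_lfs}: 900 pulses at 5 Hz (180 s).
#' \item \code{make_lfs_1hz}: 1800 pulses at 1 Hz.
#' \item \code{make_6xhfst}: 10 bursts of 4 pulses at 100 Hz repeated every
#'   100 ms, the whole train repeated 6 times every 10 s.
#' }
#' @param ca,l,glu,ach channel amplitudes in particles/ms.
#' @param width pulse width in ms.
#' @param volume compartment volume in um^3.
#' @return a \code{stimulus_program}.
#' @export
make_hfs <- function(ca = 1900, l = 10, glu = 20, ach = 20, width = 3,
                     volume = 0.5) {
  make_pulse_train("HFS", 0, 100, 10, width, ca, l, glu, ach, volume)
}

#' @rdname make_hfs
#' @export
make_4xhfs <- function(ca = 1900, l = 10, glu = 20, ach = 20, width = 3,
                       volume = 0.5) {
  make_pulse_train("4xHFS", (0:3) * 3990, 100, 10, width, ca, l, glu, ach,
                   volume)
}

#' @rdname make_hfs
#' @export
make_lfs <- function(ca = 1900, l = 10, glu = 20, ach = 20, width = 3,
                     volume = 0.5) {
  make_pulse_train("LFS", 0, 900, 200, width, ca, l, glu, ach, volume)
}

#' @rdname make_hfs
#' @export
make_lfs_1hz <- function(ca = 1900, l = 10, glu = 20, ach = 20, width = 3,
                         volume = 0.5) {
  make_pulse_train("LFS-1Hz", 0, 1800, 1000, width, ca, l, glu, ach, volume)
}

#' @rdname make_hfs
#' @export
make_6xhfst <- function(ca = 1900, l = 10, glu = 20, ach = 20, width = 3,
                        volume = 0.5) {
  bursts <- as.vector(outer((0:9) * 100, (0:5) * 10000, `+`))
  make_pulse_train("6xHFSt", bursts, 4, 10, width, ca, l, glu, ach, volume)
}

#' Generic pulse-train protocol
#'
#' Trains of \code{pulses_per_train} pulses at 100 Hz, train onsets at
#' \code{freq} Hz — the encoding of burst notations such as "10 x 4" (10
#' trains of 4 pulses with 10 ms interval).
#'
#' @param freq train (or pulse, when \code{pulses_per_train = 1}) frequency, Hz.
#' @param n_trains number of trains.
#' @param pulses_per_train pulses per train.
#' @param width pulse width in ms.
#' @param ca,l,glu,ach amplitudes in particles/ms.
#' @param volume compartment volume in um^3.
#' @export
make_train <- function(freq, n_trains, pulses_per_train = 1, width = 3,
                       ca = 1900, l = 10, glu = 20, ach = 20, volume = 0.5) {
  stopifnot(freq > 0, n_trains >= 1)
  make_pulse_train(sprintf("%gx%g@%gHz", n_trains, pulses_per_train, freq),
                   (seq_len(n_trains) - 1) * 1000 / freq,
                   pulses_per_train, 10, width, ca, l, glu, ach, volume)
}

#' Prolonged square-pulse stimulation
#'
#' One continuous pulse per nonzero channel with a common onset, the input
#' used for steady-state pathway-activation and plasticity-rule experiments.
#'
#' @param ca_amp,l_amp,glu_amp,ach_amp amplitudes in particles/ms.
#' @param duration pulse duration in seconds (default 5 min).
#' @param volume compartment volume in um^3.
#' @export
make_square_pulse <- function(ca_amp, l_amp = 10, glu_amp = 20, ach_amp = 20,
                              duration = 300, volume = 0.5) {
  stopifnot(duration > 0)
  amps <- c(Ca = ca_amp, L = l_amp, Glu = glu_amp, ACh = ach_amp)
  amps <- amps[amps > 0]
  pulses <- if (length(amps))
    data.frame(channel = names(amps), onset = 0, duration = duration * 1000,
               amplitude = unname(amps)) else NULL
  stimulus_program(pulses, label = sprintf("square(Ca=%g)", ca_amp),
                   volume = volume)
}

#' Bath application of a ligand
#'
#' A prolonged low-rate injection of one ligand channel, e.g. 50 particles/s
#' for 10 min starting 8 min before a pairing protocol. Negative start times
#' are supported by the experiment drivers (the pre-protocol portion is
#' simulated before the protocol onset).
#'
#' @param species one of "L", "Glu", "ACh".
#' @param rate particles per second.
#' @param start onset in seconds (may be negative = before protocol onset).
#' @param duration duration in seconds.
#' @param volume compartment volume in um^3.
#' @export
make_bath_application <- function(species, rate = 50, start = -480,
                                  duration = 600, volume = 0.5) {
  if (!species %in% c("L", "Glu", "ACh"))
    stop("unknown bath species: ", species)
  stopifnot(duration > 0, rate >= 0)
  pulses <- if (rate > 0)
    data.frame(channel = species, onset = start * 1000,
               duration = duration * 1000, amplitude = rate / 1000) else NULL
  stimulus_program(pulses, label = sprintf("bath(%s)", species),
                   volume = volume)
}

#' Import a calcium flux trace
#'
#' Reads a two-column delimited text file (time in ms, flux in
#' particles/ms; optional header) such as the per-pairing Ca waveforms
#' exported from a biophysical neuron simulation.
#'
#' @param path file path.
#' @return object of class \code{ca_flux_trace} (fields \code{times},
#'   \code{flux}, \code{source_tag}).
#' @export
import_ca_trace <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  first <- strsplit(trimws(lines[1]), "[,\t ]+")[[1]]
  skip <- if (suppressWarnings(anyNA(as.numeric(first)))) 1L else 0L
  for (i in seq((1 + skip), length(lines))) {
    nf <- length(strsplit(trimws(lines[i]), "[,\t ]+")[[1]])
    if (nf != 2)
      stop("malformed Ca trace at line ", i, ": expected 2 columns, got ", nf)
  }
  d <- utils::read.table(text = lines, skip = skip)
  tr <- ca_flux_trace(d[[1]], d[[2]], source_tag = "imported")
  tr
}

#' @rdname import_ca_trace
#' @param times ms, strictly increasing.
#' @param flux particles/ms, nonnegative.
#' @param source_tag "imported" or "synthetic".
#' @export
ca_flux_trace <- function(times, flux, source_tag = "imported") {
  if (any(diff(times) <= 0)) stop("trace times must be strictly increasing")
  if (any(flux < 0)) stop("trace flux must be nonnegative")
  structure(list(times = times, flux = flux, source_tag = source_tag),
            class = "ca_flux_trace")
}

#' Integral of a Ca trace (total particles)
#' @param trace a \code{ca_flux_trace}.
#' @export
trace_integral <- function(trace) {
  sum(diff(trace$times) * (utils::head(trace$flux, -1) +
                           utils::tail(trace$flux, -1)) / 2)
}

#' Spike-timing pairing train from a per-pairing Ca waveform
#'
#' Tiles the per-pairing Ca flux waveform (which already encodes the
#' pre/post inter-stimulus interval) at the pairing frequency for the given
#' duration; the tiled waveform is the complete Ca input of the protocol.
#'
#' @param trace a \code{ca_flux_trace} (per pairing).
#' @param frequency pairing frequency in Hz (default 1).
#' @param duration protocol duration in seconds (default 120 = 2 min).
#' @param volume compartment volume in um^3.
#' @return a \code{stimulus_program} with a waveform Ca channel.
#' @export
make_stdp_train <- function(trace, frequency = 1, duration = 120,
                            volume = 0.5) {
  period <- 1000 / frequency
  span <- max(trace$times)
  if (span > period)
    stop("trace spans ", span, " ms, longer than the pairing period (",
         period, " ms): tiled waveforms would overlap")
  n <- floor(duration * frequency)
  f_one <- stats::approxfun(trace$times, trace$flux, yleft = 0, yright = 0,
                            rule = 1)
  onsets <- (seq_len(n) - 1) * period
  fun <- function(t) {
    tm <- t - floor(t / period) * period
    val <- f_one(tm)
    val[t < 0 | t >= n * period] <- 0
    val
  }
  attr(fun, "breaks") <- onsets
  attr(fun, "t_end") <- (n - 1) * period + span
  stimulus_program(NULL, label = sprintf("STDP(%s, %g Hz)", trace$source_tag,
                                         frequency),
                   volume = volume, fun_channels = list(Ca = fun))
}

#' Synthetic NMDAR-like Ca flux trace for pre/post pairing
#'
#' A deterministic stand-in for Ca traces computed with a biophysically
#' detailed neuron model. The pre-synaptic glutamate transient opens an
#' NMDAR-like conductance (double-exponential, rise \code{tau_r}, decay
#' \code{tau_d}); its Mg-block gate sits at \code{gate_base} and is relieved
#' during the post-synaptic burst window \code{[isi, isi + post_window]}
#' (plus a small direct depolarisation-driven flux). The flux is capped at
#' \code{cap} (receptor saturation), so near-coincident pairings saturate in
#' peak while still differing in time-integral. The integral is maximal for
#' pre-before-post intervals of roughly +10..50 ms and decays toward the
#' unpaired baseline for large |isi|.
#'
#' @param isi inter-stimulus interval in ms (post onset minus pre onset;
#'   positive = pre before post).
#' @param peak peak NMDAR flux scale, particles/ms.
#' @param tau_r,tau_d rise/decay time constants, ms (the rise reflects
#'   glutamate binding and receptor-occupancy build-up, not channel gating
#'   alone).
#' @param gate_base Mg-gate openness without depolarisation, in (0, 1).
#' @param gate_boost additional openness during the post window.
#' @param post_window duration of post-burst depolarisation, ms.
#' @param bap_peak peak of the direct depolarisation-driven flux,
#'   particles/ms. The default peak scale corresponds to an NMDAR current
#'   of a few pA with a ~10 percent Ca fraction (thousands of ions/ms).
#' @param cap saturation cap, particles/ms.
#' @param dt sampling step, ms.
#' @return a \code{ca_flux_trace} with \code{source_tag = "synthetic"}.
#' @export
synth_nmdar_trace <- function(isi, peak = 3000, tau_r = 20, tau_d = 50,
                              gate_base = 0.12, gate_boost = 1,
                              post_window = 60, bap_peak = 150, cap = 2500,
                              dt = 2) {
  t0 <- min(0, isi)
  t_end <- max(5 * tau_d, isi + post_window + 100)
  tt <- seq(0, t_end - t0, by = dt)
  t_pre <- -t0          # pre onset within the trace
  t_post <- isi - t0    # post-burst onset within the trace
  g <- function(t, tr, td) ifelse(t > 0, exp(-t / td) - exp(-t / tr), 0)
  nmda <- peak * g(tt - t_pre, tau_r, tau_d) /
    max(g(seq(0, 5 * tau_d, by = 0.5), tau_r, tau_d))
  # depolarisation builds over the post-synaptic burst (4 spikes at 100 Hz
  # summate over ~30 ms), so the Mg-gate relief ramps up before holding
  in_win <- tt >= t_post & tt < t_post + post_window
  ramp <- pmin((tt - t_post) / 30, 1)
  gate <- gate_base + gate_boost * ifelse(in_win, ramp, 0)
  bap <- bap_peak * g(tt - t_post, 2, 20) /
    max(g(seq(0, 100, by = 0.5), 2, 20))
  flux <- pmin(nmda * gate, cap) + bap
  ca_flux_trace(tt, pmax(flux, 0), source_tag = "synthetic")
}
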