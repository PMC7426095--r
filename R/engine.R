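# Stiff ODE integration of the mass-action network. The right-hand side is
# evaluated from precomputed index matrices: each reaction stores up to five
# rate-law "slots" (species indices, repeated according to stoichiometry; a
# dummy index with unit concentration fills unused slots), so the forward
# flux of every reaction is kf * C[s1]*...*C[s5], fully vectorised across
# reactions. Reaction 93's backward flux is proportional to [PKAr]*[PKAc]
# rather than [PKAc]^2; its backward slots encode that law directly while
# the stoichiometry still returns two catalytic subunits per event.

INPUT_SPECIES <- c("Ca", "L", "Glu", "ACh")

compile_network <- function(network) {
  sp <- network$species$name
  ns <- length(sp)
  rx <- network$reactions
  nr <- nrow(rx)
  dummy <- ns + 1L

  slot_matrix <- function(sides, law = NULL) {
    M <- matrix(dummy, nr, 5L)
    for (i in seq_len(nr)) {
      v <- parse_side(sides[i])
      if (!is.null(law) && identical(rx$kb_law[i], "pkar_pkac")) {
        # footnote rate law: one factor of each product species
        idx <- match(names(v), sp)
      } else {
        idx <- rep(match(names(v), sp), times = v)
      }
      if (length(idx) > 5L) stop("reaction ", rx$id[i], " exceeds order 5")
      if (length(idx)) M[i, seq_along(idx)] <- idx
    }
    M
  }

  Fm <- slot_matrix(rx$reactants)
  Bm <- slot_matrix(rx$products, law = TRUE)

  S <- net_stoichiometry(network)         # ns x nr, dense
  ca_idx <- match(INPUT_SPECIES, sp)
  names(ca_idx) <- INPUT_SPECIES

  # Jacobian scaffolding: triplets (reaction, species) per slot, dummy rows
  # dropped; values are filled per call.
  jac_sets <- function(M) {
    keep <- which(M != dummy)
    list(keep = keep,
         row = ((keep - 1L) %% nr) + 1L,
         col = M[keep],
         slot = ((keep - 1L) %/% nr) + 1L)
  }
  list(ns = ns, nr = nr, dummy = dummy, species = sp,
       kf = rx$kf, kb = rx$kb, Fm = Fm, Bm = Bm, S = S,
       input_idx = ca_idx, jf = jac_sets(Fm), jb = jac_sets(Bm))
}

rhs_factory <- function(cmp) {
  Fm <- cmp$Fm; Bm <- cmp$Bm; S <- cmp$S
  kf <- cmp$kf; kb <- cmp$kb
  input_idx <- cmp$input_idx
  ns <- cmp$ns; nr <- cmp$nr

  flux <- function(C) {
    list(f = kf * C[Fm[, 1]] * C[Fm[, 2]] * C[Fm[, 3]] * C[Fm[, 4]] * C[Fm[, 5]],
         b = kb * C[Bm[, 1]] * C[Bm[, 2]] * C[Bm[, 3]] * C[Bm[, 4]] * C[Bm[, 5]])
  }

  func <- function(t, y, parms) {
    C <- c(pmax.int(y, 0), 1)
    fl <- flux(C)
    dy <- as.vector(S %*% (fl$f - fl$b))
    inp <- if (is.function(parms$input)) parms$input(t) else parms$input
    dy[input_idx] <- dy[input_idx] + inp
    list(dy)
  }

  slot_prod_excl <- function(C, M, k) {
    # product over all slots except each one in turn; 5 columns
    P <- cbind(C[M[, 2]] * C[M[, 3]] * C[M[, 4]] * C[M[, 5]],
               C[M[, 1]] * C[M[, 3]] * C[M[, 4]] * C[M[, 5]],
               C[M[, 1]] * C[M[, 2]] * C[M[, 4]] * C[M[, 5]],
               C[M[, 1]] * C[M[, 2]] * C[M[, 3]] * C[M[, 5]],
               C[M[, 1]] * C[M[, 2]] * C[M[, 3]] * C[M[, 4]])
    k * P
  }

  jacfunc <- function(t, y, parms) {
    C <- c(pmax.int(y, 0), 1)
    Pf <- slot_prod_excl(C, Fm, kf)
    Pb <- slot_prod_excl(C, Bm, kb)
    Df <- Matrix::sparseMatrix(i = cmp$jf$row, j = cmp$jf$col,
                               x = Pf[cmp$jf$keep], dims = c(nr, ns))
    Db <- Matrix::sparseMatrix(i = cmp$jb$row, j = cmp$jb$col,
                               x = Pb[cmp$jb$keep], dims = c(nr, ns))
    as.matrix(S %*% (Df - Db))
  }

  list(func = func, jacfunc = jacfunc, flux = flux)
}

#' Build the mass-action rate function of a network
#'
#' Returns the time-derivative function \code{d[state]/dt} implementing the
#' mass-action law for every expanded reaction (forward flux
#' \code{kf * prod [reactant]^stoich}, backward flux from the products, with
#' the documented special backward law of the PKA dissociation reaction),
#' plus external input fluxes added to the Ca/L/Glu/ACh pools.
#'
#' @param network a validated \code{reaction_network}.
#' @return a function \code{f(state, t = 0, inputs = c(Ca=0,L=0,Glu=0,ACh=0))}
#'   returning d(state)/dt in nM/ms; \code{inputs} are nM/ms source rates.
#' @export
build_rhs <- function(network) {
  cmp <- compile_network(network)
  r <- rhs_factory(cmp)
  function(state, t = 0, inputs = c(Ca = 0, L = 0, Glu = 0, ACh = 0)) {
    inp <- stats::setNames(numeric(4), INPUT_SPECIES)
    inp[names(inputs)] <- inputs
    stats::setNames(r$func(t, state, list(input = unname(inp)))[[1]],
                    cmp$species)
  }
}

#' Solver configuration
#'
#' @param rel_tol relative tolerance of the stiff integrator.
#' @param abs_tol absolute tolerance in nM.
#' @param max_step maximal internal step (ms).
#' @param method deSolve integrator tag (stiff-capable), or \code{"auto"}
#'   (default): the implicit BDF solver \code{"vode"} for short pulse
#'   segments, where its cheap restarts dominate, and \code{"lsoda"} for
#'   long smooth stretches (equilibration tails, bath phases), where its
#'   stiff/non-stiff switching is much faster.
#' @param event_alignment restart the integrator at every input
#'   discontinuity (pulse edge) instead of relying on step rejection.
#' @param maxsteps maximal internal steps per output interval.
#' @return object of class \code{solver_config}.
#' @export
solver_config <- function(rel_tol = 1e-6, abs_tol = 1e-6, max_step = Inf,
                          method = "auto", event_alignment = TRUE,
                          maxsteps = 500000) {
  stopifnot(rel_tol > 0, abs_tol > 0)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_step = max_step,
                 method = method, event_alignment = event_alignment,
                 maxsteps = maxsteps),
            class = "solver_config")
}

integrate_segment <- function(r, y0, times, input, config) {
  method <- config$method
  if (identical(method, "auto")) {
    # BDF (vode) restarts cheaply across dense pulse edges; lsoda's
    # stiff/non-stiff switching is far faster on long smooth stretches
    span <- times[length(times)] - times[1]
    method <- if (span <= 10e3) "vode" else "lsoda"
  }
  out <- deSolve::ode(
    y = y0, times = times, func = r$func, parms = list(input = input),
    jacfunc = r$jacfunc, jactype = "fullusr", method = method,
    rtol = config$rel_tol, atol = config$abs_tol,
    hmax = if (is.finite(config$max_step)) config$max_step else NULL,
    maxsteps = config$maxsteps)
  if (attr(out, "istate")[1] < 0)
    stop("integrator failure at t = ", utils::tail(out[, 1], 1), " ms")
  out
}

#' Simulate the network under a stimulus program
#'
#' Integrates the stiff mass-action system piecewise between input
#' discontinuities, restarting the solver at every pulse edge. Input pulse
#' amplitudes (particles/ms) are converted to concentration rates using the
#' network volume; blocked channels (see \code{\link{apply_manipulation}})
#' are silenced.
#'
#' @param network a \code{reaction_network}.
#' @param state initial state (named nM vector), e.g. from
#'   \code{\link{equilibrate}}.
#' @param program a \code{stimulus_program} (or \code{NULL} for no input).
#' @param t_end simulation horizon in ms (from program onset).
#' @param config a \code{solver_config}.
#' @param out_dt output grid spacing in ms (segment boundaries are always
#'   included).
#' @return object of class \code{trajectory_result} with fields
#'   \code{times} (ms), \code{concentrations} (time x species, nM),
#'   \code{program}, \code{network_fingerprint}.
#' @export
simulate <- function(network, state, program = NULL, t_end,
                     config = solver_config(), out_dt = 1000) {
  cmp <- compile_network(network)
  r <- rhs_factory(cmp)
  segs <- program_segments(program, t_end, network$volume,
                           network$channel_mask)
  sp <- cmp$species
  y <- unname(state[sp])
  if (anyNA(y)) stop("state vector is missing species")

  times_all <- list(); conc_all <- list()
  first <- TRUE
  for (k in seq_len(nrow(segs$table))) {
    t0 <- segs$table$t0[k]; t1 <- segs$table$t1[k]
    if (t1 <= t0) next
    from <- ceiling(t0 / out_dt) * out_dt
    mids <- if (from <= t1) seq(from, t1, by = out_dt) else numeric(0)
    grid <- unique(c(t0, mids, t1))
    grid <- grid[grid >= t0 & grid <= t1]
    if (length(grid) < 2) grid <- c(t0, t1)
    input <- segs$inputs[[k]]
    out <- integrate_segment(r, y, grid, input, config)
    y <- out[nrow(out), -1]
    neg <- min(y)
    if (neg < -1)
      stop("negative concentration excursion (", signif(neg, 3),
           " nM) at t = ", t1, " ms")
    if (neg < -max(0.1, config$abs_tol))
      warning("negative concentration excursion (", signif(neg, 3),
              " nM, clamped) at t = ", t1, " ms")
    y <- pmax(y, 0)
    keep <- if (first) seq_len(nrow(out)) else -1L
    times_all[[k]] <- out[keep, 1]
    conc_all[[k]] <- out[keep, -1, drop = FALSE]
    first <- FALSE
  }
  times <- do.call(c, times_all)
  conc <- do.call(rbind, conc_all)
  colnames(conc) <- sp
  structure(list(times = times, concentrations = conc,
                 program = program, config = config,
                 network_fingerprint = network_fingerprint(network)),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat("<trajectory_result>", length(x$times), "time points,",
      ncol(x$concentrations), "species, t in [",
      min(x$times), ",", max(x$times), "] ms\n")
  invisible(x)
}

#' Final state of a trajectory
#' @param trajectory a \code{trajectory_result}.
#' @return named nM vector.
#' @export
final_state <- function(trajectory) {
  n <- nrow(trajectory$concentrations)
  stats::setNames(trajectory$concentrations[n, ],
                  colnames(trajectory$concentrations))
}

#' Equilibrate the network
#'
#' Integrates the network without inputs (default 4040 s, sufficient for all
#' species to reach steady state) and returns the final state. The maximal
#' residual time-derivative is attached as attribute \code{"flatness"}
#' (nM/ms), a diagnostic of how flat the landing is.
#'
#' @param network a \code{reaction_network}.
#' @param config a \code{solver_config}.
#' @param t_eq equilibration time in ms.
#' @return named steady-state vector (nM).
#' @export
equilibrate <- function(network, config = solver_config(), t_eq = 4040e3) {
  cmp <- compile_network(network)
  r <- rhs_factory(cmp)
  grid <- c(0, 10^seq(1, log10(t_eq), length.out = 40))
  # the single multi-decade relaxation segment is lsoda territory (automatic
  # stiff/non-stiff switching); vode shines on event-dense pulse trains but
  # can stall here on strongly rescaled networks
  cfg <- config
  cfg$method <- "lsoda"
  out <- integrate_segment(r, unname(initial_state(network)), grid,
                           numeric(4), cfg)
  y <- stats::setNames(pmax(out[nrow(out), -1], 0), cmp$species)
  dy <- r$func(t_eq, y, list(input = numeric(4)))[[1]]
  attr(y, "flatness") <- max(abs(dy))
  y
}
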