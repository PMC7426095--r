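# Multi-objective fitting of input amplitudes and concentration scalers to
# cortical LTP/LTD measurements, using a self-contained NSGA-II
# implementation (fast non-dominated sorting, crowding distance, binary
# tournament, SBX crossover, polynomial mutation).

#' Load the packaged cortical LTP/LTD dataset
#'
#' Eleven experimental data sets (entorhinal, prefrontal, barrel, anterior
#' cingulate, visual and auditory cortex), each holding one or more
#' experiments (control plus pharmacological/genetic manipulations) with
#' relative synaptic-strength targets at 10/15/20 min after stimulation
#' onset and a pooled SD. Burst protocols are encoded as trains of
#' 100 Hz pulses repeated at the base frequency; the visual-cortex LFS rows
#' use the reduced 180 x 15 ms @ 1 Hz substitution.
#'
#' @param exclude_camkii_rows drop the rows marked excludable (the
#'   CaMKII-blocked visual-cortex experiments that could not be jointly
#'   fit).
#' @return data.frame of experiment records.
#' @export
load_table2_fixture <- function(exclude_camkii_rows = FALSE) {
  path <- system.file("extdata", "cortical_ltp_ltd.tsv", package = "spinedyn")
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$camkii_excludable <- as.logical(d$camkii_excludable)
  if (exclude_camkii_rows) d <- d[!d$camkii_excludable, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Fit parameter vector
#'
#' Box-constrained parameters of the fitting problem: per-pulse input
#' amplitudes (Ca, beta-adrenergic ligand, glutamate; ACh follows the
#' glutamate amplitude) and the concentration scalers.
#'
#' @param ca_amp,l_amp,glu_amp particles/ms.
#' @param glur1_ratio,f_pka,f_pkc,f_camkii,f_pp,f_pde,ncx_scale,pka_scale,pkc_scale
#'   see \code{\link{concentration_scalers}}.
#' @export
fit_parameter_vector <- function(ca_amp = 1900, l_amp = 10, glu_amp = 20,
                                 glur1_ratio = 0.5, f_pka = 1, f_pkc = 1,
                                 f_camkii = 1, f_pp = 1, f_pde = 1,
                                 ncx_scale = 1, pka_scale = 1,
                                 pkc_scale = 1) {
  v <- c(ca_amp = ca_amp, l_amp = l_amp, glu_amp = glu_amp,
         glur1_ratio = glur1_ratio, f_pka = f_pka, f_pkc = f_pkc,
         f_camkii = f_camkii, f_pp = f_pp, f_pde = f_pde,
         ncx_scale = ncx_scale, pka_scale = pka_scale,
         pkc_scale = pkc_scale)
  box <- fit_parameter_box()
  if (any(v < box$lower - 1e-12) || any(v > box$upper + 1e-12))
    stop("parameter outside its box: ",
         names(v)[which(v < box$lower | v > box$upper)][1])
  v
}

#' @rdname fit_parameter_vector
#' @export
fit_parameter_box <- function() {
  nm <- c("ca_amp", "l_amp", "glu_amp", "glur1_ratio", "f_pka", "f_pkc",
          "f_camkii", "f_pp", "f_pde", "ncx_scale", "pka_scale",
          "pkc_scale")
  list(lower = stats::setNames(rep(0, 12), nm),
       upper = stats::setNames(c(4000, 50, 100, 1, rep(2, 8)), nm))
}

record_program <- function(record, params) {
  make_train(freq = record$freq_hz, n_trains = record$n_trains,
             pulses_per_train = record$pulses_per_train,
             width = record$pulse_width_ms,
             ca = params[["ca_amp"]], l = params[["l_amp"]],
             glu = params[["glu_amp"]], ach = params[["glu_amp"]])
}

params_to_scalers <- function(params) {
  concentration_scalers(glur1_ratio = params[["glur1_ratio"]],
                        f_pka = params[["f_pka"]], f_pkc = params[["f_pkc"]],
                        f_camkii = params[["f_camkii"]],
                        f_pp = params[["f_pp"]], f_pde = params[["f_pde"]],
                        ncx_scale = params[["ncx_scale"]],
                        pka_scale = params[["pka_scale"]],
                        pkc_scale = params[["pkc_scale"]])
}

#' Predict one experiment of a dataset
#'
#' Applies the scalers and the row's manipulation preset, equilibrates, runs
#' the row's protocol and returns the relative conductance at 10/15/20 min
#' plus the peak free Ca.
#'
#' @param network base network.
#' @param params a fit parameter vector.
#' @param record one row of the dataset.
#' @param config solver configuration.
#' @param measure_min measurement times (min).
#' @export
predict_experiment <- function(network, params, record,
                               config = solver_config(),
                               measure_min = c(10, 15, 20)) {
  net <- apply_scalers(network, params_to_scalers(params))
  if (record$manipulation != "none")
    net <- apply_manipulation(net, record$manipulation)
  prog <- record_program(record, params)
  out <- run_plasticity_experiment(net, prog, measure_min, config)
  list(relative_conductance = out$relative_conductance,
       peak_free_ca = out$peak_free_ca)
}

#' Objective vector of a parameter set on a dataset
#'
#' One objective per experiment (mean absolute deviation of the predicted
#' relative conductance from the targets over the available time points)
#' plus one penalty objective for free-Ca transients exceeding the
#' physiological bound (max over experiments of max(0, peak Ca - 2 uM), in
#' uM).
#'
#' @param params fit parameter vector.
#' @param dataset data.frame of experiment records (one dataset).
#' @param network base network (ignored when \code{predictor} is supplied).
#' @param predictor optional function(params, record) returning a list like
#'   \code{\link{predict_experiment}} — used to substitute a cheap surrogate
#'   in optimiser tests.
#' @param config solver configuration.
#' @param ca_limit penalty threshold, nM.
#' @return numeric vector: one error per experiment, then \code{ca_penalty}.
#' @export
objective <- function(params, dataset, network = NULL, predictor = NULL,
                      config = solver_config(), ca_limit = 2000) {
  if (is.null(predictor))
    predictor <- function(p, rec)
      predict_experiment(network, p, rec, config)
  errs <- numeric(nrow(dataset))
  pen <- 0
  for (i in seq_len(nrow(dataset))) {
    rec <- dataset[i, ]
    targets <- c(`10` = rec$target_10, `15` = rec$target_15,
                 `20` = rec$target_20)
    ok <- !is.na(targets)
    pred <- tryCatch(predictor(params, rec), error = function(e) NULL)
    if (is.null(pred)) {
      errs[i] <- 1e6        # sentinel for failed simulations
      next
    }
    pr <- pred$relative_conductance[names(targets)[ok]]
    errs[i] <- mean(abs(pr - targets[ok]))
    pen <- max(pen, max(0, (pred$peak_free_ca - ca_limit) / 1000))
  }
  c(stats::setNames(errs, paste0("err_", seq_len(nrow(dataset)))),
    ca_penalty = pen)
}

# ---- NSGA-II ---------------------------------------------------------------

dominates <- function(a, b) all(a <= b) && any(a < b)

fast_nondominated_sort <- function(F) {
  n <- nrow(F)
  rank <- integer(n)
  dom_count <- integer(n)
  dominated <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(F[i, ], F[j, ]))
        dominated[[i]] <- c(dominated[[i]], j)
      else if (dominates(F[j, ], F[i, ]))
        dom_count[i] <- dom_count[i] + 1L
    }
  }
  front <- which(dom_count == 0L)
  r <- 1L
  while (length(front)) {
    rank[front] <- r
    nxt <- integer(0)
    for (i in front) {
      for (j in dominated[[i]]) {
        dom_count[j] <- dom_count[j] - 1L
        if (dom_count[j] == 0L) nxt <- c(nxt, j)
      }
    }
    front <- nxt
    r <- r + 1L
  }
  rank
}

crowding_distance <- function(F) {
  n <- nrow(F)
  d <- numeric(n)
  for (m in seq_len(ncol(F))) {
    o <- order(F[, m])
    rng <- F[o[n], m] - F[o[1], m]
    d[o[c(1, n)]] <- Inf
    if (n > 2 && rng > 0)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (F[o[3:n], m] - F[o[1:(n - 2)], m]) / rng
  }
  d
}

sbx_crossover <- function(p1, p2, lower, upper, eta = 15, pc = 0.9) {
  c1 <- p1; c2 <- p2
  if (stats::runif(1) < pc) {
    for (k in seq_along(p1)) {
      if (stats::runif(1) > 0.5 || abs(p1[k] - p2[k]) < 1e-14) next
      u <- stats::runif(1)
      beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1))
              else (1 / (2 * (1 - u)))^(1 / (eta + 1))
      c1[k] <- 0.5 * ((1 + beta) * p1[k] + (1 - beta) * p2[k])
      c2[k] <- 0.5 * ((1 - beta) * p1[k] + (1 + beta) * p2[k])
    }
  }
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

poly_mutation <- function(p, lower, upper, eta = 20, pm = NULL) {
  if (is.null(pm)) pm <- 1 / length(p)
  for (k in seq_along(p)) {
    if (stats::runif(1) > pm) next
    u <- stats::runif(1)
    delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1
             else 1 - (2 * (1 - u))^(1 / (eta + 1))
    p[k] <- p[k] + delta * (upper[k] - lower[k])
  }
  pmin(pmax(p, lower), upper)
}

#' NSGA-II multi-objective minimisation
#'
#' Standard generational NSGA-II over a box-constrained real parameter
#' space: fast non-dominated sorting, crowding-distance diversity, binary
#' tournament selection, simulated binary crossover and polynomial
#' mutation. Fully reproducible from the seed.
#'
#' @param fn vectorless objective function: \code{fn(x)} returns the
#'   objective vector (all minimised).
#' @param lower,upper named parameter bounds.
#' @param pop_size population size (even).
#' @param generations number of generations.
#' @param seed RNG seed (required).
#' @return list with \code{parameters} (matrix), \code{objectives}
#'   (matrix), \code{rank}, and \code{history} (per-generation populations).
#' @export
nsga2 <- function(fn, lower, upper, pop_size = 64, generations = 5, seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  if (pop_size %% 2 == 1) pop_size <- pop_size + 1
  npar <- length(lower)
  P <- matrix(stats::runif(pop_size * npar, rep(lower, each = pop_size),
                           rep(upper, each = pop_size)),
              pop_size, npar, dimnames = list(NULL, names(lower)))
  evals <- t(apply(P, 1, fn))
  history <- vector("list", generations)
  for (g in seq_len(generations)) {
    rank <- fast_nondominated_sort(evals)
    crowd <- numeric(pop_size)
    for (r in unique(rank)) {
      idx <- which(rank == r)
      crowd[idx] <- crowding_distance(evals[idx, , drop = FALSE])
    }
    tournament <- function() {
      ij <- sample.int(pop_size, 2)
      i <- ij[1]; j <- ij[2]
      if (rank[i] < rank[j] ||
          (rank[i] == rank[j] && crowd[i] > crowd[j])) i else j
    }
    Q <- matrix(0, pop_size, npar, dimnames = list(NULL, names(lower)))
    for (k in seq(1, pop_size, by = 2)) {
      ch <- sbx_crossover(P[tournament(), ], P[tournament(), ],
                          lower, upper)
      Q[k, ] <- poly_mutation(ch[[1]], lower, upper)
      Q[k + 1, ] <- poly_mutation(ch[[2]], lower, upper)
    }
    evals_q <- t(apply(Q, 1, fn))
    R <- rbind(P, Q)
    evals_r <- rbind(evals, evals_q)
    rank_r <- fast_nondominated_sort(evals_r)
    sel <- integer(0)
    for (r in sort(unique(rank_r))) {
      idx <- which(rank_r == r)
      if (length(sel) + length(idx) <= pop_size) {
        sel <- c(sel, idx)
      } else {
        cd <- crowding_distance(evals_r[idx, , drop = FALSE])
        sel <- c(sel, idx[order(cd, decreasing = TRUE)
                          [seq_len(pop_size - length(sel))]])
        break
      }
    }
    P <- R[sel, , drop = FALSE]
    evals <- evals_r[sel, , drop = FALSE]
    history[[g]] <- list(parameters = P, objectives = evals)
  }
  rank <- fast_nondominated_sort(evals)
  list(parameters = P, objectives = evals, rank = rank, history = history)
}

#' Fit the model to one cortical dataset by NSGA-II
#'
#' Minimises the per-experiment error objectives plus the free-Ca penalty.
#' A parameter set is "acceptable" when every experiment's mean error is at
#' most that experiment's SD; the acceptance fraction is tracked per
#' generation.
#'
#' @param dataset data.frame of records of one dataset.
#' @param network base network (ignored when \code{predictor} given).
#' @param population,generations NSGA-II budget (desk-scale defaults 64 x 5;
#'   the full-scale setting is 1000 x 20).
#' @param seed RNG seed (required).
#' @param predictor optional surrogate, see \code{\link{objective}}.
#' @param config solver configuration.
#' @return list: NSGA-II result plus \code{accepted} (logical per final
#'   individual), \code{acceptance_by_generation}, and the dataset.
#' @export
nsga2_fit <- function(dataset, network = NULL, population = 64,
                      generations = 5, seed, predictor = NULL,
                      config = solver_config()) {
  if (missing(seed)) stop("a seed is required")
  box <- fit_parameter_box()
  fn <- function(x) objective(stats::setNames(x, names(box$lower)),
                              dataset, network, predictor, config)
  res <- nsga2(fn, box$lower, box$upper, pop_size = population,
               generations = generations, seed = seed)
  nexp <- nrow(dataset)
  accept <- function(obj)
    apply(obj[, seq_len(nexp), drop = FALSE], 1,
          function(e) all(e <= dataset$sd))
  res$accepted <- accept(res$objectives)
  res$acceptance_by_generation <- vapply(
    res$history, function(h) mean(accept(h$objectives)), numeric(1))
  res$dataset <- dataset
  res
}

#' Counterfactual predictions for fitted parameter sets
#'
#' Re-simulates fitted parameter sets under modified conditions: the HFS
#' protocol and/or kinase blockades, as used to generate testable
#' predictions from data-fitted models.
#'
#' @param fitted_params matrix (rows = parameter sets, named columns).
#' @param dataset the dataset the parameters were fitted to (its control
#'   row defines the protocol).
#' @param network base network.
#' @param presets character vector drawn from "control", "HFS",
#'   "camkii_blocked", "pka_blocked", "pkc_blocked".
#' @param measure_min measurement times (min).
#' @param config solver configuration.
#' @return data.frame: parameter set x preset x time with the predicted
#'   relative conductance.
#' @export
predict_counterfactuals <- function(fitted_params, dataset, network,
                                    presets = c("control", "HFS",
                                                "camkii_blocked",
                                                "pka_blocked",
                                                "pkc_blocked"),
                                    measure_min = c(10, 15, 20),
                                    config = solver_config()) {
  ctrl <- dataset[dataset$manipulation == "none", ][1, ]
  rows <- list()
  for (k in seq_len(nrow(fitted_params))) {
    par <- fitted_params[k, ]
    for (pre in presets) {
      net <- apply_scalers(network, params_to_scalers(par))
      rec <- ctrl
      if (pre == "HFS") {
        rec$freq_hz <- 100; rec$n_trains <- 1
        rec$pulses_per_train <- 100; rec$pulse_width_ms <- 3
      } else if (pre != "control") {
        net <- apply_manipulation(net, pre)
      }
      out <- run_plasticity_experiment(net, record_program(rec, par),
                                       measure_min, config)
      rows[[length(rows) + 1]] <- data.frame(
        set = k, preset = pre, minutes = measure_min,
        relative_conductance = unname(out$relative_conductance))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
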