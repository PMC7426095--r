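# Surrogate predictors stand in for the ODE pipeline so the optimiser's
# behaviour (objective arithmetic, non-domination, seeding, recovery) can be
# tested at speed; the simulation-backed objective shares all code except
# the predictor.

surrogate <- function(effects) {
  function(params, record) {
    rel <- effects(params, record$manipulation)
    list(relative_conductance = c(`10` = rel, `15` = rel, `20` = rel),
         peak_free_ca = 500)
  }
}

synth_dataset <- function(targets, manipulations, sd = 0.05) {
  data.frame(dataset = "SYN", manipulation = manipulations,
             target_10 = targets, target_15 = targets, target_20 = targets,
             sd = sd, stringsAsFactors = FALSE)
}

test_that("the packaged cortical dataset has the documented structure", {
  d <- load_table2_fixture()
  expect_equal(length(unique(d$dataset)), 11)
  ec1 <- d[d$dataset == "EC-1" & d$manipulation == "none", ]
  expect_equal(c(ec1$target_10, ec1$target_15, ec1$target_20),
               c(1.3, 1.4, 1.3))
  expect_equal(ec1$sd, 0.1)
  auc2 <- d[d$dataset == "AuC-2", ]
  expect_equal(c(auc2$target_10, auc2$target_15, auc2$target_20),
               c(0.77, 0.68, 0.67))
  expect_equal(auc2$sd, 0.09)
  # visual-cortex CaMKII-blocked rows are flagged excludable
  excl <- d[d$camkii_excludable, ]
  expect_true(all(grepl("^VC", excl$dataset)))
  expect_equal(nrow(excl), 4)
  expect_false(any(load_table2_fixture(TRUE)$camkii_excludable))
  # missing 10-min targets only in the LFS substitution rows
  expect_true(all(is.na(d$target_10) == (d$pulses_per_train == 180)))
  expect_true(all(d$sd > 0))
})

test_that("objective errors average |prediction - target| over available times", {
  d <- load_table2_fixture()
  ec1 <- d[d$dataset == "EC-1", ]
  flat <- surrogate(function(p, m) 1.0)
  obj <- objective(fit_parameter_vector(), ec1, predictor = flat)
  expect_equal(unname(obj["err_1"]), mean(c(0.3, 0.4, 0.3)))
  expect_equal(unname(obj["ca_penalty"]), 0)   # 0.5 uM < 2 uM
  # exact predictions give zero error
  exact <- function(p, rec)
    list(relative_conductance = c(`10` = rec$target_10, `15` = rec$target_15,
                                  `20` = rec$target_20),
         peak_free_ca = 2500)
  obj2 <- objective(fit_parameter_vector(), ec1, predictor = exact)
  expect_equal(max(obj2[1:3]), 0)
  expect_equal(unname(obj2["ca_penalty"]), 0.5)  # (2.5 - 2) uM
  # NA targets are dropped from the average
  vc <- d[d$dataset == "VC-1" & d$pulses_per_train == 180, ][1, ]
  obj3 <- objective(fit_parameter_vector(), vc, predictor = flat)
  expect_equal(unname(obj3["err_1"]), mean(abs(1 - c(0.95, 0.95))))
})

test_that("NSGA-II produces a seeded, non-dominated archive", {
  fn <- function(x) c(f1 = (x[["a"]] - 1)^2 + x[["b"]]^2,
                      f2 = (x[["a"]] + 1)^2 + x[["b"]]^2)
  lower <- c(a = -4, b = -4); upper <- c(a = 4, b = 4)
  r1 <- nsga2(fn, lower, upper, pop_size = 24, generations = 12, seed = 7)
  r2 <- nsga2(fn, lower, upper, pop_size = 24, generations = 12, seed = 7)
  expect_identical(r1$parameters, r2$parameters)
  r3 <- nsga2(fn, lower, upper, pop_size = 24, generations = 12, seed = 8)
  expect_false(identical(r1$parameters, r3$parameters))
  # archive non-domination
  front <- r1$objectives[r1$rank == 1, , drop = FALSE]
  for (i in seq_len(nrow(front)))
    for (j in seq_len(nrow(front)))
      expect_false(spinedyn:::dominates(front[i, ], front[j, ]) &&
                     i != j)
  # the front approaches the known Pareto set b = 0, a in [-1, 1]
  expect_lt(stats::median(abs(front[, 2] - front[, 1]) /
                            (front[, 1] + front[, 2] + 1e-9)), 1)
  expect_lt(min(r1$objectives[, "f1"]), 0.3)
  expect_error(nsga2(fn, lower, upper, 8, 2), "seed")
})

test_that("parameters generating a synthetic dataset are recovered", {
  truth <- fit_parameter_vector(glur1_ratio = 0.7)
  eff <- function(p, m) 0.5 + p[["glur1_ratio"]]
  pred <- surrogate(eff)
  ds <- synth_dataset(eff(truth, "none"), "none", sd = 0.05)
  fit <- nsga2_fit(ds, population = 32, generations = 8, seed = 3,
                   predictor = pred)
  expect_true(any(fit$accepted))
  rec <- fit$parameters[fit$accepted, "glur1_ratio"]
  expect_lt(stats::median(abs(rec - 0.7)), 0.15)
  # acceptance fraction is tracked per generation and grows or holds
  expect_equal(length(fit$acceptance_by_generation), 8)
  expect_gte(utils::tail(fit$acceptance_by_generation, 1),
             fit$acceptance_by_generation[1])
})

test_that("a CaMKII-dependent condition shifts the recovered f_camkii up", {
  eff <- function(p, m) {
    base <- 1 + 0.2 * p[["f_pka"]]
    if (m == "camkii_blocked") base else base + 0.4 * p[["f_camkii"]]
  }
  pred <- surrogate(eff)
  # dataset A: blockade barely matters; dataset B: blockade removes the LTP
  dsA <- synth_dataset(c(1.5, 1.4), c("none", "camkii_blocked"), sd = 0.05)
  dsB <- synth_dataset(c(1.5, 1.0), c("none", "camkii_blocked"), sd = 0.05)
  fitA <- nsga2_fit(dsA, population = 40, generations = 10, seed = 5,
                    predictor = pred)
  fitB <- nsga2_fit(dsB, population = 40, generations = 10, seed = 5,
                    predictor = pred)
  expect_true(any(fitA$accepted) && any(fitB$accepted))
  expect_gt(stats::median(fitB$parameters[fitB$accepted, "f_camkii"]),
            stats::median(fitA$parameters[fitA$accepted, "f_camkii"]))
})

test_that("counterfactual presets reuse the control protocol", {
  d <- load_table2_fixture()
  ec1 <- d[d$dataset == "EC-1", ]
  ctrl <- ec1[ec1$manipulation == "none", ][1, ]
  prog <- spinedyn:::record_program(ctrl, fit_parameter_vector())
  expect_equal(sum(prog$pulses$channel == "Ca"), 100)
  # burst rows expand to trains of 100 Hz pulses
  bc <- d[d$dataset == "BC" & d$manipulation == "none", ]
  pb <- spinedyn:::record_program(bc, fit_parameter_vector())
  expect_equal(sum(pb$pulses$channel == "Ca"), 40)   # 10 trains x 4 pulses
})
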