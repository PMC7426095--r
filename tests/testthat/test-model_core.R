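test_that("builtin model loads, validates, and matches its manifest", {
  net <- builtin_net()
  expect_s3_class(net, "reaction_network")
  init <- initial_state(net)
  expect_equal(unname(init["PMCA"]), 22000)
  expect_equal(unname(init["CaM"]), 60000)
  expect_equal(sum(init[grep("^GluR", names(init))]), 540)
  r94 <- net$reactions[net$reactions$base_id == 94, ]
  expect_equal(r94$kf, 4e-4)
  expect_equal(r94$kb, 20)
  expect_equal(r94$reactants, "Ca + fixedbuffer")
  # the manifest freeze is enforced by load_model() itself
  man <- jsonlite::read_json(system.file("extdata", "manifest.json",
                                         package = "spinedyn"))
  expect_equal(nrow(net$species), man$n_species)
  expect_equal(nrow(net$reactions), man$n_reactions)
  expect_equal(network_fingerprint(net), man$fingerprint)
})

test_that("group expansion is reproducible, idempotent and validated", {
  net1 <- load_model()
  net2 <- load_model()
  expect_identical(net1$reactions, net2$reactions)
  # expanding an already explicit table is a pass-through
  explicit <- net1$reactions
  explicit$group <- ""
  re <- expand_reaction_groups(explicit, net1$groups)
  expect_equal(re$reactants, net1$reactions$reactants)
  expect_equal(re$products, net1$reactions$products)
  expect_equal(re$kf, net1$reactions$kf)
  # ungrouped rows yield exactly one reaction, grouped rows one per member
  g69 <- net1$reactions[net1$reactions$base_id == 69, ]
  expect_equal(nrow(g69), 2L)
  expect_true(all(g69$kf == g69$kf[1]))
  # a missing group definition is a hard error naming the symbol
  bad <- net1$grouped[1, ]
  bad$group <- "999"
  expect_error(expand_reaction_groups(bad, net1$groups), "999")
})

test_that("dangling species references are rejected with the culprit named", {
  expect_error(load_toy(bad_species = TRUE), "Foo")
})

test_that("every declared molecular family is closed under the stoichiometry", {
  net <- builtin_net()
  fams <- conserved_families(net)
  expect_gt(length(fams), 25)
  expect_silent(spinedyn:::check_conservation_symbolic(net, fams))
  # GluR subunit families cover all receptor states
  expect_equal(sum(grepl("^GluR1", net$species$name)),
               length(fams$glur1))
})

test_that("concentration scalers rescale their targets and round-trip", {
  net <- builtin_net()
  s1 <- concentration_scalers()
  expect_equal(apply_scalers(net, s1)$species$init, net$species$init)
  s2 <- concentration_scalers(f_pka = 2, ncx_scale = 0.5)
  net2 <- apply_scalers(net, s2)
  init2 <- initial_state(net2)
  expect_equal(unname(init2["AC1"]), 860)       # 2 x 430
  expect_equal(unname(init2["R"]), 3200)
  expect_equal(unname(init2["NCX"]), 270000)
  expect_equal(unname(init2["PKA"]), 6400)      # untouched
  # inverse factors restore the original initial concentrations
  s2inv <- concentration_scalers(f_pka = 0.5, ncx_scale = 2)
  net3 <- apply_scalers(net2, s2inv)
  expect_equal(net3$species$init, net$species$init, tolerance = 1e-12)
})

test_that("the GluR1 ratio redistributes a fixed 540 nM subunit total", {
  net <- builtin_net()
  for (r in c(0, 0.35, 0.5, 0.9)) {
    net2 <- apply_scalers(net, concentration_scalers(glur1_ratio = r))
    init <- initial_state(net2)
    tot1 <- sum(init[grep("^GluR1", names(init))])
    tot2 <- sum(init[grep("^GluR2", names(init))])
    expect_equal(tot1 + tot2, 540, tolerance = 1e-10)
    expect_equal(tot1, 540 * r, tolerance = 1e-10)
  }
  # the internal/membrane split within a family is preserved
  net2 <- apply_scalers(net, concentration_scalers(glur1_ratio = 0.25))
  init <- initial_state(net2)
  expect_equal(unname(init["GluR1"] / init["GluR1_memb"]), 2, tolerance = 1e-10)
  expect_error(concentration_scalers(glur1_ratio = 1.2), "glur1_ratio")
  expect_error(concentration_scalers(f_pp = 3), "f_pp")
})

test_that("manipulation presets modify the intended pieces and compose", {
  net <- builtin_net()
  pk <- apply_manipulation(net, "pka_blocked")
  expect_equal(initial_state(pk)[["PKA"]], 0)
  expect_equal(sum(pk$species$init != net$species$init), 1L)

  ca <- apply_manipulation(net, "no_ca")
  expect_equal(unname(ca$channel_mask["Ca"]), 0)
  expect_equal(unname(ca$channel_mask["Glu"]), 1)

  ck <- apply_manipulation(net, "camkii_blocked")
  hit <- ck$reactions$base_id %in% 51:55
  expect_true(all(ck$reactions$kf[hit] == 0))
  expect_true(all(ck$reactions$kf[!hit] == net$reactions$kf[!hit]))

  both <- apply_manipulation(apply_manipulation(net, "s845_deficient"),
                             "s831_deficient")
  hit2 <- both$reactions$base_id %in% c(67, 68, 73, 69:72)
  expect_true(all(both$reactions$kf[hit2] == 0))
  expect_true(all(both$reactions$kf[!hit2] == net$reactions$kf[!hit2]))

  expect_error(apply_manipulation(net, "no_such_preset"), "unknown")
  expect_error(manipulation("scale_rate", target = 1, value = -1),
               "nonnegative")
})
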