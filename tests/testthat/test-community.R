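test_that("build_community creates pool, transports and community exchanges", {
  pair <- make_crossfeeding_pair(toy_default)
  cm <- build_community(unname(pair))
  expect_s3_class(cm, "community_model")
  ## shared metabolites glc/leu/lys each get one pool exchange
  expect_setequal(cm$pool_mets, c("glc_pool", "leu_pool", "lys_pool"))
  expect_setequal(cm$exchange_ids, c("EX_glc_e", "EX_leu_e", "EX_lys_e"))
  ## two transports per shared metabolite: each member's former exchange
  for (base in c("glc", "leu", "lys")) {
    touching <- which(cm$S[paste0(base, "_pool"), ] != 0)
    owners <- cm$rxn_organism[colnames(cm$S)[touching]]
    expect_identical(sum(!is.na(owners)), 2L)
    expect_identical(sum(is.na(owners)), 1L)   # the community exchange
  }
  ## member reactions carry the organism prefix
  expect_true(all(startsWith(
    names(cm$rxn_organism)[!is.na(cm$rxn_organism)],
    paste0(cm$rxn_organism[!is.na(cm$rxn_organism)], "_"))))
  ## most permissive member bound becomes the default exchange bound
  expect_equal(unname(cm$lb["EX_glc_e"]), -10)
  ## most permissive ub across members: the producer's export cap
  expect_equal(unname(cm$ub["EX_leu_e"]), 0.2)
  expect_error(build_community(pair[1]), "two members")
  expect_error(build_community(list(pair$make, pair$make)), "distinct")
})

test_that("community merge is order-insensitive up to renaming", {
  pair <- make_crossfeeding_pair(toy_default)
  cm_ab <- build_community(list(pair$make, pair$partner))
  cm_ba <- build_community(list(pair$partner, pair$make))
  expect_identical(dim(cm_ab$S), dim(cm_ba$S))
  expect_setequal(colnames(cm_ab$S), colnames(cm_ba$S))
  expect_identical(cm_ab$S[rownames(cm_ba$S), colnames(cm_ba$S)], cm_ba$S)
  expect_identical(cm_ab$lb[colnames(cm_ba$S)], cm_ba$lb)
})

test_that("biomass recycling adds the printed pseudo-reaction pair", {
  cm0 <- make_chemolithotroph_community(toy_default)
  cm <- add_biomass_recycling(cm0, alpha = 0.2)
  expect_identical(ncol(cm$S), ncol(cm0$S) + 3L)
  expect_identical(nrow(cm$S), nrow(cm0$S) + 3L)
  ## Biomass_community -> alpha Biomass_degraded + (1 - alpha) Biomass_net
  expect_equal(unname(cm$S["Biomass_community", "BIOMASS_RECYCLING"]), -1)
  expect_equal(unname(cm$S["Biomass_degraded", "BIOMASS_RECYCLING"]), 0.2)
  expect_equal(unname(cm$S["Biomass_net", "BIOMASS_RECYCLING"]), 0.8)
  ## Biomass_degraded -> 6.169 glc_pool
  expect_equal(unname(cm$S["glc_pool", "BIOMASS_DEGRADATION"]), 6.169)
  ## each member biomass produces one unit of community biomass per gDW
  for (b in cm$biomass_ids)
    expect_equal(unname(cm$S["Biomass_community", b]), 1)
  expect_error(add_biomass_recycling(cm0, 1), "alpha")
  expect_error(add_biomass_recycling(cm0, -0.1), "alpha")
  ## sweep values all accepted
  for (a in c(0, 0.2, 0.4, 0.6, 0.8))
    expect_s3_class(add_biomass_recycling(cm0, a), "community_model")
})

test_that("apply_point scales member bounds and pins biomass", {
  cm <- crossfeed_community
  cmod <- apply_point(cm, c(0.5, 0.5), 0.1)
  ## member bound scaled by f_i: glucose uptake -10 -> -5
  expect_equal(unname(cmod$lb["eco_K_EX_glc_e"]), -5)
  ## pool exchange untouched
  expect_equal(unname(cmod$lb["EX_glc_e"]), unname(cm$lb["EX_glc_e"]))
  ## biomass pinned to f_i * mu
  expect_equal(unname(cmod$lb["eco_K_BIOMASS"]), 0.05)
  expect_equal(unname(cmod$ub["eco_K_BIOMASS"]), 0.05)
  cmod2 <- apply_point(cm, c(0.3, 0.7), 0.1)
  expect_equal(unname(cmod2$lb["eco_K_BIOMASS"]), 0.03)

  ## zero abundance shuts the member down completely
  cmod0 <- apply_point(cm, c(1, 0), 0)
  eco_L <- names(cm$rxn_organism)[cm$rxn_organism %in% "eco_L"]
  expect_true(all(cmod0$lb[eco_L] == 0 & cmod0$ub[eco_L] == 0))

  expect_error(apply_point(cm, c(0.6, 0.6), 0.1), "sum to 1")
  expect_error(apply_point(cm, c(0.5, 0.5), -1), "non-negative")
})

test_that("any feasible flux distribution obeys balanced growth and bounds", {
  cm <- crossfeed_community
  for (pt in list(c(0.5, 0.1), c(3 / 7, 0.08), c(0.8, 0.02))) {
    cmod <- apply_point(cm, c(pt[1], 1 - pt[1]), pt[2])
    v <- flux_sample(cmod)
    expect_lt(max(abs(cm$S %*% v)), 1e-6)              # steady state
    expect_true(all(v >= cmod$lb - 1e-6 & v <= cmod$ub + 1e-6))
    mu_sum <- sum(v[cm$biomass_ids])
    expect_equal(mu_sum, pt[2], tolerance = 1e-6)      # mu = sum biomass
  }
})
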