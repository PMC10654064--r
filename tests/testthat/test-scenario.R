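test_that("substrate split sets the reference uptake bounds", {
  cm <- make_chemolithotroph_community(toy_default)
  cm5 <- set_substrate_ratio(cm, scenario_config(lambda = 0.5))
  expect_equal(unname(cm5$lb["EX_fe2_e"]), -75)
  expect_equal(unname(cm5$lb["EX_tsul_e"]), -5)
  cm1 <- set_substrate_ratio(cm, scenario_config(lambda = 1))
  expect_equal(unname(cm1$lb["EX_tsul_e"]), 0)
  expect_equal(unname(cm1$lb["EX_fe2_e"]), -150)
  for (lam in c(0.25, 0.4, 0.5, 0.6, 0.75)) {
    cfg <- scenario_config(lambda = lam)
    cml <- set_substrate_ratio(cm, cfg)
    expect_equal(unname(cml$lb["EX_fe2_e"]), -lam * 150)
    expect_equal(unname(cml$lb["EX_tsul_e"]), -(1 - lam) * 10)
  }
  expect_error(set_substrate_ratio(crossfeed_community, scenario_config()),
               "not found")
})

test_that("lambda = 1 blocks the thiosulfate route everywhere", {
  cm <- chemo_reference(alpha = 0.2, lambda = 1)
  g <- build_grid(cm, 5)
  pm <- phenotype_matrix(cm, g, "EX_tsul_e")
  expect_true(all(pm$states == "0"))
})

test_that("efficiency constraint: S_min verified against the oracle, limits nest", {
  cm <- crossfeed_community
  cmod <- apply_point(cm, c(0.5, 0.5), 0.05)
  s_min <- agspace:::min_abs_flux_sum(cmod)
  ## closed-form oracle: at the parsimonious optimum every flux is forced
  ## (uptake mu of glucose per member, cross-feeding exactly meets needs),
  ## giving sum |v| = 12 mu regardless of composition
  expect_equal(s_min, 12 * 0.05, tolerance = 1e-8)
  v <- flux_sample(add_efficiency_constraint(cmod, 1))
  expect_equal(sum(abs(v)), s_min, tolerance = 1e-6)
  ## factor = 1 collapses ranges toward the parsimonious optimum set
  r1 <- flux_ranges(add_efficiency_constraint(cmod, 1))
  r0 <- flux_ranges(cmod)
  expect_lt(sum(r1$max - r1$min), sum(r0$max - r0$min))
  ## nested restriction across the analyzed factors
  r15 <- flux_ranges(add_efficiency_constraint(cmod, 1.5))
  r12 <- flux_ranges(add_efficiency_constraint(cmod, 1.2))
  r11 <- flux_ranges(add_efficiency_constraint(cmod, 1.1))
  expect_true(all(r12$min >= r15$min - 1e-6 & r12$max <= r15$max + 1e-6))
  expect_true(all(r11$min >= r12$min - 1e-6 & r11$max <= r12$max + 1e-6))
  expect_true(all(r15$min >= r0$min - 1e-6 & r15$max <= r0$max + 1e-6))
  expect_error(add_efficiency_constraint(cmod, 0.9), ">= 1")
})

test_that("cross-feeding case configuration follows the study constants", {
  cm <- make_crossfeeding_community(toy_default)
  cfg <- scenario_config()
  cm0 <- configure_ecoli_case(cm, cfg)
  expect_equal(unname(cm0$lb["eco_K_EX_glc_e"]), -10)
  expect_equal(unname(cm0$ub["eco_K_EX_leu_e"]), 0.2)  # producer cap
  expect_equal(unname(cm0$lb["EX_leu_e"]), 0)          # no supplementation
  cfg_s <- scenario_config(supplementation = c(leu = 0.01, lys = 0.01))
  cms <- configure_ecoli_case(cm, cfg_s)
  expect_equal(unname(cms$lb["EX_leu_e"]), -0.01)
  expect_equal(unname(cms$lb["EX_lys_e"]), -0.01)
})

test_that("amino-acid supplementation never shrinks the space or envelopes", {
  cm0 <- configure_ecoli_case(crossfeed_community, scenario_config())
  cms <- configure_ecoli_case(crossfeed_community,
                              scenario_config(supplementation =
                                                c(leu = 0.01, lys = 0.01)))
  g0 <- build_grid(cm0, 6)
  ## feasible set can only grow under supplementation
  for (i in which(g0$feasible))
    expect_true(is_feasible(cms, c(g0$f1[i], g0$f2[i]), g0$mu[i]))
  ## envelopes of the supplemented model contain the unsupplemented ones
  for (pt in list(c(0.5, 0.05), c(2 / 5, 0.08))) {
    e0 <- coupling_envelope(cm0, c(pt[1], 1 - pt[1]), pt[2],
                            "EX_glc_e", "eco_K_EX_leu_e", n = 9,
                            normalize = FALSE)
    es <- coupling_envelope(cms, c(pt[1], 1 - pt[1]), pt[2],
                            "EX_glc_e", "eco_K_EX_leu_e", n = 9,
                            normalize = FALSE)
    expect_lte(min(es$v1), min(e0$v1) + 1e-9)
    expect_gte(max(es$v1), max(e0$v1) - 1e-9)
    ## conditional ranges at shared v1 values can only widen
    for (i in seq_len(nrow(e0))) {
      j <- which.min(abs(es$v1 - e0$v1[i]))
      if (abs(es$v1[j] - e0$v1[i]) < 1e-9) {
        expect_lte(es$min2[j], e0$min2[i] + 1e-6)
        expect_gte(es$max2[j], e0$max2[i] - 1e-6)
      }
    }
  }
})

test_that("raising the recycling fraction enlarges the feasible space", {
  grids <- lapply(c(0, 0.4, 0.8), function(a)
    build_grid(chemo_reference(alpha = a), 5))
  ## compare feasibility of alpha = 0 grid points under larger alpha
  g0 <- grids[[1]]
  for (k in 2:3) {
    cmk <- chemo_reference(alpha = c(0, 0.4, 0.8)[k])
    for (i in which(g0$feasible))
      expect_true(is_feasible(cmk, c(g0$f1[i], g0$f2[i]), g0$mu[i]))
    expect_gte(attr(grids[[k]], "max_biomass"), attr(g0, "max_biomass") - 1e-9)
  }
  ## alpha = 0 is equivalent to no recycling block at all
  g_none <- build_grid(chemo_reference(alpha = NULL), 5)
  expect_identical(g0$feasible, g_none$feasible)
  expect_equal(attr(g0, "max_biomass"), attr(g_none, "max_biomass"))
})

test_that("run_sweep produces one result set per scenario and isolates errors", {
  mk <- function(cfg) {
    cm <- make_chemolithotroph_community(toy_default,
                                         alpha = if (cfg$alpha > 0) cfg$alpha
                                                 else NULL)
    set_substrate_ratio(cm, cfg)
  }
  alphas <- c(0, 0.2, 0.4, 0.6, 0.8)
  scen <- lapply(alphas, function(a) scenario_config(alpha = a))
  names(scen) <- paste0("alpha_", alphas)
  res <- run_sweep(mk, scen, l = 4)
  expect_length(res, 5)
  expect_true(all(vapply(res, function(x) is.null(x$error), logical(1))))
  expect_true(all(vapply(res, function(x)
    inherits(x$matrix, "phenotype_matrix"), logical(1))))
  ## empty scenario list -> empty output
  expect_length(run_sweep(mk, list(), l = 4), 0)
  ## one broken scenario does not abort the sweep
  scen_bad <- list(ok = scenario_config(alpha = 0.2),
                   bad = scenario_config(alpha = 0.2, lambda = 0))
  mk_bad <- function(cfg) {
    if (cfg$lambda == 0) stop("boom")
    mk(cfg)
  }
  res2 <- run_sweep(mk_bad, scen_bad, l = 4)
  expect_null(res2$ok$error)
  expect_identical(res2$bad$error, "boom")
})
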