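test_that("the eight qualitative states are total and mutually exclusive", {
  ## every named case from the classification table
  expect_identical(categorize(0, 0), "0")
  expect_identical(categorize(-2, -2), "-")
  expect_identical(categorize(3, 3), "+")
  expect_identical(categorize(-5, -1), "--")
  expect_identical(categorize(2, 5), "++")
  expect_identical(categorize(-0.3, 0), "-0")
  expect_identical(categorize(0, 0.7), "0+")
  expect_identical(categorize(-0.5, 0.5), "-+")
  ## tolerance snapping
  expect_identical(categorize(1e-12, 2e-12, eps = 1e-9), "0")
  expect_identical(categorize(-1e-10, 5, eps = 1e-9), "0+")
  expect_identical(categorize(-1e-10, 1e-10, eps = 1e-9), "0")
  ## randomized totality: exactly one category, consistent with predicates
  set.seed(7)
  lo <- round(runif(500, -3, 3), 3)
  hi <- lo + round(runif(500, 0, 3), 3)
  cats <- categorize(lo, hi)
  expect_true(all(cats %in% c("0", "-", "+", "--", "++", "-0", "0+", "-+")))
  expect_false(anyNA(cats))
  ## predicate cross-check with an independent straight-line classifier
  ref <- mapply(function(a, b) {
    if (a == b && a == 0) "0" else if (a == b && a < 0) "-"
    else if (a == b) "+" else if (b < 0) "--" else if (a > 0) "++"
    else if (b == 0) "-0" else if (a == 0) "0+" else "-+"
  }, lo, hi)
  expect_identical(cats, unname(ref))
  expect_error(categorize(1, 0), "min > max")
})

test_that("plasticity classes follow the state taxonomy", {
  expect_identical(plasticity_class(c("0", "-", "+")), rep("none", 3))
  expect_identical(plasticity_class(c("--", "++")), rep("flux", 2))
  expect_identical(plasticity_class(c("-0", "0+", "-+")),
                   rep("structural", 3))
})

test_that("FVA ranges and feasibility match the vertex-enumeration oracle", {
  ## main-path FVA vs brute force across grid points of both toys
  cmX <- crossfeed_community
  gX <- build_grid(cmX, 7)
  n_pts <- 0L
  for (i in seq_len(nrow(gX))) {
    F <- c(gX$f1[i], gX$f2[i]); mu <- gX$mu[i]
    expect_identical(brute_force_feasible(cmX, F, mu), gX$feasible[i])
    if (gX$feasible[i]) {
      cmod <- apply_point(cmX, F, mu)
      expect_ranges_equal(flux_ranges(cmod, cmX$exchange_ids),
                          brute_force_ranges(cmod, cmX$exchange_ids))
    }
    n_pts <- n_pts + 1L
  }
  cmC <- chemo_reference(alpha = 0.2)
  gC <- build_grid(cmC, 6)
  feas <- feasible_points(gC)
  take <- seq_len(min(nrow(feas), 100L - n_pts))
  for (i in take) {
    cmod <- apply_point(cmC, c(feas$f1[i], feas$f2[i]), feas$mu[i])
    expect_ranges_equal(flux_ranges(cmod, cmC$exchange_ids),
                        brute_force_ranges(cmod, cmC$exchange_ids))
    n_pts <- n_pts + 1L
  }
  expect_gte(n_pts, 75L)
})

test_that("pinned and blocked reactions classify as expected", {
  cm <- crossfeed_community
  cmod <- apply_point(cm, c(0.5, 0.5), 0.1)
  fr <- flux_ranges(cmod, c("eco_K_BIOMASS", "eco_L_BIOMASS",
                            "eco_L_EX_leu_e"))
  ## biomass fixed by the balanced-growth equality
  expect_equal(fr$min[1], 0.05, tolerance = 1e-9)
  expect_equal(fr$max[1], 0.05, tolerance = 1e-9)
  ## leucine consumption by the auxotroph is a fixed negative value
  expect_equal(fr$min[3], fr$max[3], tolerance = 1e-9)
  expect_lt(fr$max[3], 0)
  expect_identical(categorize(fr$min[3], fr$max[3]), "-")
  expect_error(flux_ranges(apply_point(cm, c(1, 0), 0.01)), "infeasible")
})

test_that("phenotype matrix has full shape and matches pointwise FVA", {
  cm <- crossfeed_community
  g <- build_grid(cm, 6)
  pm <- phenotype_matrix(cm, g)
  expect_identical(nrow(pm$states), sum(g$feasible))
  expect_identical(colnames(pm$states), cm$exchange_ids)
  expect_false(anyNA(pm$states))
  ## spot-check one row against a direct FVA call
  i <- which.max(pm$points$mu)
  cmod <- apply_point(cm, c(pm$points$f1[i], pm$points$f2[i]),
                      pm$points$mu[i])
  fr <- flux_ranges(cmod, cm$exchange_ids)
  expect_identical(unname(pm$states[i, ]), categorize(fr$min, fr$max))
})

test_that("tightening constraints never widens a flux range", {
  cm <- crossfeed_community
  cmod <- apply_point(cm, c(0.5, 0.5), 0.05)
  base <- flux_ranges(cmod)
  tight <- add_efficiency_constraint(cmod, 1.2)
  restr <- flux_ranges(tight)
  expect_true(all(restr$min >= base$min - 1e-6))
  expect_true(all(restr$max <= base$max + 1e-6))
})

test_that("plasticity summary labels blocked, fixed and variable reactions", {
  ## close the leucine pool exchange entirely: exchange of a metabolite
  ## absent from the environment is blocked everywhere
  pair <- make_crossfeeding_pair(toy_default)
  cm <- build_community(unname(pair),
                        exchange_bounds = list(EX_leu_e = c(0, 0),
                                               EX_lys_e = c(0, 1000)))
  g <- build_grid(cm, 6)
  rset <- c("eco_K_BIOMASS", "EX_leu_e", "EX_glc_e")
  pm <- phenotype_matrix(cm, g, rset)
  ps <- plasticity_summary(pm)
  expect_identical(ps$label[ps$rxn == "EX_leu_e"], "blocked")
  ## biomass flux is pinned at every point: fixed (nonzero somewhere)
  expect_identical(ps$label[ps$rxn == "eco_K_BIOMASS"], "fixed")
  expect_identical(ps$label[ps$rxn == "EX_glc_e"], "variable")
})
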