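## Shared fixtures: built once per test run, deterministic.

toy_default <- toy_spec()

crossfeed_community <- make_crossfeeding_community(toy_default)

chemo_reference <- function(alpha = 0.2, lambda = 0.5) {
  cm <- make_chemolithotroph_community(toy_default, alpha = alpha)
  set_substrate_ratio(cm, scenario_config(alpha = 0, lambda = lambda))
}

## contiguous-run check for logical vectors (convex sections)
is_contiguous_run <- function(x) {
  idx <- which(x)
  length(idx) == 0L || all(diff(idx) == 1L)
}

expect_ranges_equal <- function(a, b, tol = 1e-6) {
  expect_equal(a$rxn, b$rxn)
  expect_lt(max(abs(a$min - b$min)), tol)
  expect_lt(max(abs(a$max - b$max)), tol)
}
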