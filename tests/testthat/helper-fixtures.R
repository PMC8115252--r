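# Shared small fixtures, built once per test run.

tiny_geom <- function(shape = c(10, 10, 8)) phantom_geometry(shape)

# Cached phantom templates for tests that only need some smooth maps.
.fixture_env <- new.env(parent = emptyenv())
tiny_templates <- function() {
  if (is.null(.fixture_env$tpl)) {
    .fixture_env$tpl <- gen_templates(tiny_geom(), k_rsn = 3,
                                      adult_target_corrs = c(0.6, 0),
                                      seed = 42)
  }
  .fixture_env$tpl
}

# Independent OLS oracle: closed-form normal equations.
ols_oracle <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)

# Seeded evaluation that restores the global RNG state afterwards.
with_seed_local <- function(seed, code) neonox:::with_seed(seed, code)
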