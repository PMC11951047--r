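# Shared fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .cache)) assign(key, fn(), envir = .cache)
  get(key, envir = .cache)
}

restructured_fixture <- function(name, ordering = "chain") {
  cached(paste(name, ordering), function() {
    fx <- fixture_suite(name)
    restructure(fx$model, fx$enzymes, und = fx$underground,
                pool = fx$pool, ordering = ordering)
  })
}

random_fixture <- function(seed, n_underground = 1, ...) {
  cached(paste("rand", seed, n_underground, ...), function() {
    make_fixture(fixture_spec(n_steps = 5, profile = c(1, 2, 3),
                              n_underground = n_underground, seed = seed, ...))
  })
}

random_coral <- function(seed, ordering = "chain", ...) {
  cached(paste("randc", seed, ordering, ...), function() {
    fx <- random_fixture(seed, ...)
    restructure(fx$model, fx$enzymes, und = fx$underground, ordering = ordering)
  })
}

# minimal 3-reaction conventional model: uptake -> conversion -> biomass
chain_model <- function(uptake = 10) {
  stoich_model(
    metabolites = tibble::tibble(id = c("A", "B")),
    reactions = tibble::tibble(
      id = c("EX_A", "R1", "BIOMASS"),
      lb = 0, ub = c(uptake, 1000, 1000), gpr = c("", "g1", "")
    ),
    stoich = tibble::tibble(
      reaction = c("EX_A", "R1", "R1", "BIOMASS"),
      metabolite = c("A", "A", "B", "B"),
      coef = c(1, -1, 1, -1)
    ),
    objective = "BIOMASS"
  )
}

expect_close <- function(x, y, tol = 1e-6) {
  expect_true(abs(x - y) <= tol * max(1, abs(y)),
              label = sprintf("|%.10g - %.10g| <= %g (rel)", x, y, tol))
}
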