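## Shared fixtures and a small cache so expensive fits are computed once per
## test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

cached_density_fit <- function(variant) {
  cached(paste0("density_", variant),
         fit_density_model(variant, crizotinib_dataset()))
}

cached_eos_fit <- function(variant, n_starts = 6L, seed = 1L) {
  cached(paste0("eos_", variant),
         fit_interaction(variant, crizotinib_dataset(),
                         n_starts = n_starts, seed = seed,
                         reltol = 1e-8, maxit = 800))
}

pure_pair <- function(variant) {
  list(pure_constants(variant, co2_properties()),
       pure_constants(variant, crizotinib_properties()))
}

default_interaction <- function(variant) {
  switch(variant,
         RK = km_interaction("RK", 0.1, -0.1),
         PR = km_interaction("PR", 0.1, -0.1, 0.2),
         SRK3 = km_interaction("SRK3", 0.1, -0.1, 0.2),
         SRK4 = km_interaction("SRK4", 0.1, -0.1, 0.2, 0.1))
}

## interaction parameters published for the crizotinib system, used as
## optimizer starting points in descent tests
published_interaction_par <- function(variant) {
  switch(variant,
         RK = c(-0.137, -0.1476),
         PR = c(-0.775, -0.297, 1.810),
         SRK3 = c(0.367, -0.179, 0.899),
         SRK4 = c(0.256, -0.236, -0.293, 0.436))
}
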