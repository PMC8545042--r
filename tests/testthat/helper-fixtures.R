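# Shared fixtures.  The default paper-parameterised cohort is expensive
# (50 dynamic phantoms through the full pipeline), so one seeded run is
# cached for the whole test session.

.fixture_cache <- new.env(parent = emptyenv())

default_cohort_results <- function() {
  if (is.null(.fixture_cache$cohort)) {
    .fixture_cache$cohort <- run_cohort_pipeline(cohort_spec(), seed = 1)
  }
  .fixture_cache$cohort
}

small_cohort_spec <- function(n = c("HC" = 3, "3/4R" = 2, "4R" = 2)) {
  cohort_spec(n_per_group = n)
}

# a reference curve reused across kinetic tests
fixture_ref <- function(k2prime = 0.12) {
  if (is.null(.fixture_cache$ref) ||
      !isTRUE(all.equal(.fixture_cache$ref_k2p, k2prime))) {
    .fixture_cache$ref <- simulate_reference_tac(default_frame_schedule(),
                                                 k2prime = k2prime)
    .fixture_cache$ref_k2p <- k2prime
  }
  .fixture_cache$ref
}

strip_fine <- function(x) tac(x$schedule, x$values, x$label)
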