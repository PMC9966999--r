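# Shared fixtures, generated once per test run and memoized: the synthetic
# dataset is the ground-truth bench for every module.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

fixture_noisy <- function() memo("noisy", make_benchmark_fixture(seed = 42))

fixture_clean <- function() memo("clean",
                                 make_benchmark_fixture(seed = 42,
                                                           noise_sd = 0))

# Murcko scaffolds / cyclic skeletons of the clean fixture (same structures
# as the noisy one: the two share molecules, only pIC50 noise differs).
fixture_scaffolds <- function() memo("scaffolds",
  murcko_scaffold(fixture_clean()$records$smiles))

fixture_skeletons <- function() memo("skeletons",
  cyclic_skeleton(fixture_clean()$records$smiles))

fixture_ecfp4 <- function() memo("ecfp4", {
  r <- fixture_clean()$records
  fp <- compute_fingerprint(r$smiles, "ecfp4")
  rownames(fp) <- r$compound_id
  fp
})

# A small record table with arbitrary class counts; only the columns the
# balancing/splitting machinery needs.
dummy_records <- function(counts) {
  cls <- rep(names(counts), counts)
  data.frame(compound_id = sprintf("D%04d", seq_along(cls)),
             smiles = "c1ccccc1", pic50 = 7.5,
             activity_class = factor(cls, levels = names(counts)),
             stringsAsFactors = FALSE)
}

# Random confusion matrix with k classes.
random_cm <- function(k, max_count = 20) {
  matrix(sample.int(max_count + 1L, k * k, replace = TRUE) - 1L, k, k)
}
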