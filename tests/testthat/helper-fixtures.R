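# Shared fixture builders. Everything is generated in code; sizes are kept
# small so individual test files stay fast.

# A compact generator spec for pipeline tests (the full-size default spec is
# exercised by the parameter-recovery acceptance tests only).
tiny_spec <- function(...) {
  generator_spec(
    n_pfams = 80,
    n_photosynthesis = 10,
    n_motility = 8,
    n_phagocytosis = 8,
    n_housekeeping = 24,
    class_counts = c(phototrophy = 24, mixotrophy = 14, heterotrophy = 12),
    ...
  )
}

# A small scaled labeled_profiles set for classifier-level tests.
tiny_training <- function(seed = 421) {
  tr <- generate_training(tiny_spec(), seed = seed)
  sc <- fit_scaler(tr$profiles$x)
  list(
    raw = tr$profiles,
    scaled = labeled_profiles(apply_scaler(tr$profiles$x, sc),
                              as.character(tr$profiles$label),
                              tr$profiles$id),
    signal = tr$signal_pfams,
    ctg = tr$ctg_pfams,
    spec = tiny_spec()
  )
}

# A trained bundle over the tiny spec, cached per test run.
tiny_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- generate_training(tiny_spec(), seed = 77)
      cache <<- train_trophic_model(tr$profiles, colnames(tr$profiles$x))
    }
    cache
  }
})

# Hand-built three-contig abundance table used by the TPM oracle tests.
three_contig_table <- function() {
  tibble::tibble(
    contig_id = c("c1", "c2", "c3"),
    length_nt = c(500, 1000, 2000),
    est_count = c(10, 20, 30),
    species_bin = "binA",
    sample_id = "s1"
  )
}

# Minimal prediction tibble for exclusion/agreement/capability tests.
prediction_rows <- function(species_bin, grouping_unit, mode,
                            replicate = "rep1", size_fraction = "all",
                            excluded = FALSE) {
  tibble::tibble(
    species_bin = species_bin,
    sample_id = paste0(grouping_unit, "_", seq_along(mode)),
    grouping_unit = grouping_unit,
    replicate = replicate,
    size_fraction = size_fraction,
    mode = mode,
    excluded = excluded,
    reason = NA_character_
  )
}

mode_counts <- function(p = 0, m = 0, h = 0) {
  c(phototrophy = p, mixotrophy = m, heterotrophy = h)
}
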