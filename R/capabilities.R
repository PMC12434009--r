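#' Dominant trophic mode of a species bin
#'
#' The mode with the most predictions. Exact ties are broken by the fixed
#' precedence heterotrophy > mixotrophy > phototrophy (so a bin is never
#' called a phototrophic specialist on a tie).
#'
#' @param counts Named numeric vector of prediction counts; names from
#'   [TROPHIC_MODES] (missing modes count 0).
#' @return One of [TROPHIC_MODES].
#' @export
dominant_mode <- function(counts) {
  counts <- complete_counts(counts)
  if (sum(counts) == 0) stop("no predictions: dominant mode undefined")
  precedence <- c("heterotrophy", "mixotrophy", "phototrophy")
  counts <- counts[precedence]
  precedence[which.max(counts)]
}

complete_counts <- function(counts) {
  if (is.null(names(counts))) stop("counts must be named by trophic mode")
  unknown <- setdiff(names(counts), TROPHIC_MODES)
  if (length(unknown) > 0) stop("unknown mode(s): ", paste(unknown, collapse = ", "))
  out <- setNames(numeric(3), TROPHIC_MODES)
  out[names(counts)] <- counts
  out
}

#' Classify the trophic capability of a species bin
#'
#' A bin has mixotrophic capabilities if at least `divergence_threshold`
#' (default 23%, the model's estimated error rate) of its predictions differ
#' from its dominant mode and that divergence is not attributable solely to
#' replicates or size fractions, or if strictly more than `mixo_threshold`
#' (default 77%) of its predictions are mixotrophy. Otherwise the bin is a
#' phototrophic or heterotrophic specialist named by its dominant mode (a bin
#' whose dominant mode is mixotrophy but that clears neither rule is also
#' reported as mixotrophic-capable, the only capability consistent with
#' dominant mixotrophy).
#'
#' @param counts Named prediction counts per mode.
#' @param replicate_split_only Logical from [detect_replicate_split()].
#' @param divergence_threshold Inclusive threshold on the divergence fraction.
#' @param mixo_threshold Strict threshold on the mixotrophy fraction.
#' @return One of `"mixotrophic_capable"`, `"phototrophic_specialist"`,
#'   `"heterotrophic_specialist"`.
#' @export
classify_capability <- function(counts, replicate_split_only = FALSE,
                                divergence_threshold = 0.23,
                                mixo_threshold = 0.77) {
  counts <- complete_counts(counts)
  total <- sum(counts)
  if (total == 0) stop("no predictions: capability undefined")
  dom <- dominant_mode(counts)
  divergence <- 1 - counts[[dom]] / total
  mixo_frac <- counts[["mixotrophy"]] / total
  if ((divergence >= divergence_threshold && !replicate_split_only) ||
      mixo_frac > mixo_threshold) {
    return("mixotrophic_capable")
  }
  switch(dom,
    phototrophy = "phototrophic_specialist",
    heterotrophy = "heterotrophic_specialist",
    mixotrophy = "mixotrophic_capable"
  )
}

#' Is a bin's trophic divergence only a replicate/size-fraction split?
#'
#' Divergent predictions count toward mixotrophic capability only when they
#' are reproducible rather than a disagreement between replicates or size
#' fractions of the same sample. Operationalized as: the divergence is
#' "split-only" (returns `TRUE`) iff no grouping unit exists in which all of
#' the unit's predictions are a single non-dominant mode - i.e. every
#' non-dominant prediction co-occurs in its unit with predictions of the
#' dominant mode from other replicates or size fractions.
#'
#' @param predictions Tibble of non-excluded predictions for one species bin
#'   with columns `mode` and `grouping_unit`.
#' @param dominant Dominant mode; computed from `predictions` when omitted.
#' @return Logical.
#' @export
detect_replicate_split <- function(predictions, dominant = NULL) {
  predictions <- as_tibble(predictions)
  modes <- predictions$mode
  if (is.null(dominant)) {
    dominant <- dominant_mode(table_to_counts(modes))
  }
  units <- split(modes, predictions$grouping_unit)
  unanimous_nondominant <- vapply(units, function(m) {
    length(unique(m)) == 1 && m[1] != dominant
  }, logical(1))
  !any(unanimous_nondominant)
}

table_to_counts <- function(modes) {
  tab <- table(factor(modes, levels = TROPHIC_MODES))
  setNames(as.numeric(tab), names(tab))
}

#' Capability calls for all species bins
#'
#' Aggregates non-excluded trophic predictions per species bin across every
#' dataset supplied (aggregation is a plain sum of counts, so merging
#' datasets before or after makes no difference) and applies
#' [classify_capability()] with the replicate-split caveat.
#'
#' @param predictions Prediction tibble(s) from [apply_exclusion()]; rows
#'   with `excluded = TRUE` or no mode are ignored.
#' @param divergence_threshold,mixo_threshold Passed through.
#' @return Tibble with one row per species bin: per-mode counts, `dominant`,
#'   `divergence_fraction`, `replicate_split_only`, `capability`.
#' @export
call_capabilities <- function(predictions, divergence_threshold = 0.23,
                              mixo_threshold = 0.77) {
  predictions <- as_tibble(predictions) %>%
    filter(!.data$excluded, !is.na(.data$mode))
  if (nrow(predictions) == 0) {
    stop("no usable (non-excluded) predictions to classify")
  }
  bind_rows(lapply(split(predictions, predictions$species_bin), function(df) {
    counts <- table_to_counts(df$mode)
    dom <- dominant_mode(counts)
    split_only <- detect_replicate_split(df, dominant = dom)
    tibble(
      species_bin = df$species_bin[1],
      n_phototrophy = counts[["phototrophy"]],
      n_mixotrophy = counts[["mixotrophy"]],
      n_heterotrophy = counts[["heterotrophy"]],
      dominant = dom,
      divergence_fraction = 1 - counts[[dom]] / sum(counts),
      replicate_split_only = split_only,
      capability = classify_capability(
        counts, split_only,
        divergence_threshold = divergence_threshold,
        mixo_threshold = mixo_threshold
      )
    )
  })) %>%
    arrange(.data$species_bin)
}
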