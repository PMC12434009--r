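#' Core Transcribed Gene coverage of species-bin profiles
#'
#' The fraction of the CTG reference Pfams (605 in the reference list) with at
#' least one mapped read (TPM > 0) in a given species bin and sample. A
#' trophic prediction is attempted only when coverage is at least the
#' eligibility threshold (0.70 by default; 424/605 passes, 423/605 does not).
#'
#' @param profiles Long profile tibble `(species_bin, sample_id, pfam_acc,
#'   tpm)`.
#' @param ctg_list Character vector of CTG Pfam accessions.
#' @param threshold Eligibility threshold on the coverage fraction.
#' @return Tibble `(species_bin, sample_id, ctg_coverage, eligible)`.
#' @export
ctg_coverage <- function(profiles, ctg_list, threshold = 0.70) {
  ctg_list <- unique(ctg_list)
  if (length(ctg_list) == 0) stop("CTG list is empty")
  as_tibble(profiles) %>%
    group_by(.data$species_bin, .data$sample_id) %>%
    summarise(
      ctg_coverage = sum(unique(.data$pfam_acc[.data$tpm > 0]) %in% ctg_list) /
        length(ctg_list),
      .groups = "drop"
    ) %>%
    mutate(eligible = .data$ctg_coverage >= threshold)
}

#' Predict trophic modes for environmental species-bin profiles
#'
#' Each (species bin, sample) profile is zero-filled to the model bundle's
#' feature list, scaled with the bundle's training scaler (values outside the
#' fitted range are clipped; set `scaler_mode = "refit"` to re-fit min-max
#' scaling on the environmental profiles instead) and scored by the
#' classifier. Pairs below the CTG coverage threshold are emitted with
#' `excluded = TRUE` and `reason = "low_coverage"` rather than dropped.
#'
#' @param profiles Long profile tibble with raw TPM values.
#' @param bundle A `trophic_model_bundle`.
#' @param ctg_list CTG Pfam accessions for the completeness gate.
#' @param metadata Optional tibble keyed by `sample_id` carrying `replicate`,
#'   `size_fraction`, `grouping_unit`, joined onto the output.
#' @param ctg_threshold Coverage eligibility threshold (default 0.70).
#' @param scaler_mode `"bundle"` (default; training min/max, clipped) or
#'   `"refit"` (min/max re-fitted on the environmental profiles).
#' @return Tibble with one row per (species bin, sample): `mode`, one
#'   probability column per trophic mode, `ctg_coverage`, `excluded`,
#'   `reason`, plus metadata columns when supplied.
#' @export
predict_modes <- function(profiles, bundle, ctg_list, metadata = NULL,
                          ctg_threshold = 0.70,
                          scaler_mode = c("bundle", "refit")) {
  if (!inherits(bundle, "trophic_model_bundle")) {
    stop("corrupt or missing model bundle")
  }
  scaler_mode <- match.arg(scaler_mode)
  profiles <- as_tibble(profiles)
  cov <- ctg_coverage(profiles, ctg_list, threshold = ctg_threshold)
  x <- profile_matrix(profiles, features = bundle$features)
  meta <- attr(x, "meta")
  x_in <- if (bundle$binarize_input) {
    binarize(x)
  } else if (scaler_mode == "bundle") {
    apply_scaler(x, bundle$scaler)
  } else {
    if (nrow(x) < 2) stop("scaler_mode = 'refit' needs at least 2 profiles")
    apply_scaler(x, fit_scaler(x))
  }
  probs <- predict_proba(bundle$classifier, x_in)
  out <- meta %>%
    mutate(
      mode = TROPHIC_MODES[max.col(probs, ties.method = "first")],
      p_phototrophy = probs[, "phototrophy"],
      p_mixotrophy = probs[, "mixotrophy"],
      p_heterotrophy = probs[, "heterotrophy"]
    ) %>%
    left_join(cov, by = c("species_bin", "sample_id")) %>%
    mutate(
      excluded = !.data$eligible,
      reason = ifelse(.data$eligible, NA_character_, "low_coverage"),
      mode = ifelse(.data$eligible, .data$mode, NA_character_)
    ) %>%
    select(-"eligible")
  if (!is.null(metadata)) {
    out <- left_join(out, as_tibble(metadata), by = "sample_id")
  }
  out
}

#' Flag groups with predictions split between phototrophy and heterotrophy
#'
#' Phototrophy and heterotrophy are not expected for the same species bin
#' under the same conditions, so a split between them signals model failure.
#' Within each (species bin, grouping unit) group, if phototrophy and
#' heterotrophy each account for strictly more than `threshold` (default 25%)
#' of the non-excluded predictions across replicates and size fractions, all
#' predictions in the group are flagged `excluded` with reason `"split_P_H"`.
#' Flags are added, never removed; already-excluded rows keep their reason.
#'
#' @param predictions Output of [predict_modes()] carrying a `grouping_unit`
#'   column.
#' @param group_cols Columns defining a group (default species bin within
#'   grouping unit).
#' @param threshold Fraction above which each of P and H must fall (strict
#'   inequality).
#' @return `predictions` with updated `excluded`/`reason`.
#' @export
apply_exclusion <- function(predictions,
                            group_cols = c("species_bin", "grouping_unit"),
                            threshold = 0.25) {
  predictions <- as_tibble(predictions)
  predictions %>%
    group_by(dplyr::across(dplyr::all_of(group_cols))) %>%
    mutate(
      .split = {
        modes <- .data$mode[!.data$excluded & !is.na(.data$mode)]
        n_grp <- length(modes)
        n_grp > 0 &&
          sum(modes == "phototrophy") / n_grp > threshold &&
          sum(modes == "heterotrophy") / n_grp > threshold
      }
    ) %>%
    ungroup() %>%
    mutate(
      reason = ifelse(.data$.split & !.data$excluded, "split_P_H", .data$reason),
      excluded = .data$excluded | .data$.split
    ) %>%
    select(-".split")
}

#' Agreement of trophic predictions across replicates and size fractions
#'
#' The proportion of non-excluded predictions in each (species bin, grouping
#' unit) group that share the group's most frequent mode. A unanimous group
#' scores 1; a 50/50 two-mode group scores 0.5.
#'
#' @param predictions Output of [predict_modes()] / [apply_exclusion()].
#' @param group_cols Columns defining a group.
#' @return Tibble of the grouping columns plus `n_predictions` and
#'   `agreement`; groups with no usable predictions are omitted.
#' @export
agreement <- function(predictions,
                      group_cols = c("species_bin", "grouping_unit")) {
  as_tibble(predictions) %>%
    filter(!.data$excluded, !is.na(.data$mode)) %>%
    group_by(dplyr::across(dplyr::all_of(group_cols))) %>%
    summarise(
      n_predictions = dplyr::n(),
      agreement = max(table(.data$mode)) / dplyr::n(),
      .groups = "drop"
    )
}
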