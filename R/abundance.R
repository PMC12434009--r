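#' Transcripts per liter from internal spike-in standards
#'
#' Standard internal-standard estimator: with `standard_copies_added` synthetic
#' RNA copies added before sequencing and `reads_mapped_to_standards` reads
#' recovered from them, each read represents
#' `standard_copies_added / reads_mapped_to_standards` transcripts, so
#' `T/L = bin_reads / reads_mapped_to_standards * standard_copies_added /
#' volume_filtered_l`. Linear in `bin_reads`.
#'
#' @param bin_reads Reads mapped to the species bin (vectorized).
#' @param standard_copies_added Spike-in copies added to the sample.
#' @param reads_mapped_to_standards Reads mapped to the spike-in standards;
#'   must be positive (a sample with none is unquantifiable).
#' @param volume_filtered_l Volume filtered, liters.
#' @return Transcripts per liter (numeric).
#' @export
transcripts_per_liter <- function(bin_reads, standard_copies_added,
                                  reads_mapped_to_standards,
                                  volume_filtered_l) {
  if (any(reads_mapped_to_standards <= 0)) {
    stop("sample(s) with no reads mapped to spike-in standards are unquantifiable")
  }
  if (any(standard_copies_added <= 0) || any(volume_filtered_l <= 0)) {
    stop("standard copies added and volume filtered must be positive")
  }
  if (any(bin_reads < 0)) stop("negative bin read counts")
  bin_reads / reads_mapped_to_standards * standard_copies_added /
    volume_filtered_l
}

#' Sum transcript abundance across size fractions
#'
#' When a sample was filtered into several size fractions (e.g. either side
#' of a 3 um filter), per-bin transcript concentrations are summed across
#' fractions; replicate structure is preserved.
#'
#' @param records Tibble with a `transcripts_per_l` column plus grouping
#'   columns.
#' @param group_cols Columns identifying one summed record (default species
#'   bin x station x replicate).
#' @return Tibble of `group_cols` plus summed `transcripts_per_l`.
#' @export
sum_size_fractions <- function(records,
                               group_cols = c("species_bin", "station",
                                              "replicate")) {
  as_tibble(records) %>%
    group_by(dplyr::across(dplyr::all_of(group_cols))) %>%
    summarise(transcripts_per_l = sum(.data$transcripts_per_l),
              .groups = "drop")
}

#' Taxon-specific transcript-to-biomass correction
#'
#' Dinoflagellates carry about 6.4 times more transcripts per unit carbon
#' biomass than other plankton, so their transcript concentrations are scaled
#' down by that factor before cross-taxon comparison. The correction table is
#' configurable per broad lineage.
#'
#' @param records Tibble with `transcripts_per_l` and a logical
#'   `is_dinoflagellate` column (or a `lineage` column naming entries of
#'   `corrections`).
#' @param corrections Named divisors per lineage (default
#'   `c(dinoflagellate = 6.4)`).
#' @return `records` with a `corrected_transcripts_per_l` column.
#' @export
dino_correction <- function(records, corrections = c(dinoflagellate = 6.4)) {
  records <- as_tibble(records)
  if ("is_dinoflagellate" %in% names(records)) {
    divisor <- ifelse(records$is_dinoflagellate,
                      corrections[["dinoflagellate"]], 1)
  } else if ("lineage" %in% names(records)) {
    divisor <- ifelse(records$lineage %in% names(corrections),
                      unname(corrections[records$lineage]), 1)
    divisor[is.na(divisor)] <- 1
  } else {
    stop("records need an is_dinoflagellate or lineage column")
  }
  mutate(records, corrected_transcripts_per_l = .data$transcripts_per_l / divisor)
}

#' Transcript abundance totals by trophic group
#'
#' Joins capability calls onto abundance records, sums corrected transcript
#' concentrations within each replicate across the species bins of each
#' trophic group, then averages across replicates per location, and reports
#' each group's proportion of the summed location total. Locations with zero
#' total abundance get `NA` proportions.
#'
#' @param records Abundance tibble with `species_bin`,
#'   `corrected_transcripts_per_l`, a location column, and a replicate
#'   column.
#' @param capability_calls Output of [call_capabilities()] (`species_bin`,
#'   `capability`); every bin in `records` must be present.
#' @param location_col,replicate_col Column names (defaults `"station"`,
#'   `"replicate"`).
#' @return Tibble per (location, capability): `mean_transcripts_per_l`,
#'   `se_transcripts_per_l`, `n_replicates`, `proportion`.
#' @export
group_totals <- function(records, capability_calls,
                         location_col = "station",
                         replicate_col = "replicate") {
  records <- as_tibble(records)
  calls <- select(as_tibble(capability_calls), "species_bin", "capability")
  missing <- setdiff(unique(records$species_bin), calls$species_bin)
  if (length(missing) > 0) {
    stop("species bin(s) without a capability call: ",
         paste(missing, collapse = ", "))
  }
  per_replicate <- records %>%
    left_join(calls, by = "species_bin") %>%
    group_by(dplyr::across(dplyr::all_of(c(location_col, replicate_col, "capability")))) %>%
    summarise(total = sum(.data$corrected_transcripts_per_l), .groups = "drop")
  out <- per_replicate %>%
    group_by(dplyr::across(dplyr::all_of(c(location_col, "capability")))) %>%
    summarise(
      mean_transcripts_per_l = mean(.data$total),
      se_transcripts_per_l = if (dplyr::n() > 1) {
        stats::sd(.data$total) / sqrt(dplyr::n())
      } else {
        NA_real_
      },
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) %>%
    group_by(dplyr::across(dplyr::all_of(location_col))) %>%
    mutate(
      proportion = if (sum(.data$mean_transcripts_per_l) > 0) {
        .data$mean_transcripts_per_l / sum(.data$mean_transcripts_per_l)
      } else {
        NA_real_
      }
    ) %>%
    ungroup()
  out
}
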