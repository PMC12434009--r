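#' Select the best-scoring Pfam annotation per contig
#'
#' Applies the two-stage rule used to assign a single protein-family domain to
#' each contig: hits with an e-value at or above `e_value_max` are discarded,
#' and among the survivors the hit with the highest bitscore is kept. Bitscore
#' ties are broken deterministically by the lexicographically smallest Pfam
#' accession.
#'
#' @param hits Data frame with columns `contig_id`, `pfam_acc`, `e_value`,
#'   `bitscore` (one row per domain hit).
#' @param e_value_max Strict upper bound on the e-value (default `1e-5`).
#' @return A tibble with columns `contig_id`, `pfam_acc`, one row per contig
#'   that retains at least one hit. Contigs whose hits are all filtered out are
#'   absent (unannotated).
#' @export
select_best_pfam <- function(hits, e_value_max = 1e-5) {
  hits <- as_tibble(hits)
  required <- c("contig_id", "pfam_acc", "e_value", "bitscore")
  missing <- setdiff(required, names(hits))
  if (length(missing) > 0) {
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(is.na(hits$e_value) | hits$e_value < 0)
  if (length(bad) > 0) {
    stop(
      "malformed annotation rows (negative or missing e-value): ",
      paste(head(bad, 10), collapse = ", ")
    )
  }
  hits %>%
    filter(.data$e_value < e_value_max) %>%
    arrange(.data$contig_id, dplyr::desc(.data$bitscore), .data$pfam_acc) %>%
    group_by(.data$contig_id) %>%
    slice(1L) %>%
    ungroup() %>%
    select("contig_id", "pfam_acc")
}

#' Compute per-contig TPM within each species bin and sample
#'
#' Transcripts per million are computed per (species bin, sample) group:
#' reads-per-kilobase `RPK = est_count / (length_nt / 1000)`, a conversion
#' factor `sum(RPK) / 1e6` within the group, and `TPM = RPK / factor`. TPM
#' therefore sums to one million within every group that has any mapped reads;
#' a group with all-zero counts yields all-zero TPM (bins legitimately absent
#' from a sample are not an error).
#'
#' @param contigs Data frame with columns `contig_id`, `length_nt`,
#'   `est_count`, `species_bin`, `sample_id`.
#' @return The input as a tibble with columns `rpk` and `tpm` added.
#' @export
compute_tpm <- function(contigs) {
  contigs <- as_tibble(contigs)
  required <- c("contig_id", "length_nt", "est_count", "species_bin", "sample_id")
  missing <- setdiff(required, names(contigs))
  if (length(missing) > 0) {
    stop("abundance table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(is.na(contigs$length_nt) | contigs$length_nt < 1)
  if (length(bad) > 0) {
    stop(
      "contig(s) with length < 1 nt: ",
      paste(head(contigs$contig_id[bad], 10), collapse = ", ")
    )
  }
  if (any(contigs$est_count < 0)) {
    stop("negative estimated counts are not allowed")
  }
  contigs %>%
    mutate(rpk = .data$est_count / (.data$length_nt / 1000)) %>%
    group_by(.data$species_bin, .data$sample_id) %>%
    mutate(
      tpm = {
        factor <- sum(.data$rpk) / 1e6
        if (factor == 0) rep(0, length(.data$rpk)) else .data$rpk / factor
      }
    ) %>%
    ungroup()
}

#' Aggregate per-contig TPM into species-bin Pfam profiles
#'
#' Sums contig TPM by assigned Pfam within each (species bin, sample).
#' Contigs without a Pfam assignment are dropped. When `feature_list` is
#' supplied, every listed Pfam is present in every profile, zero-filled where
#' it has no mapped transcripts.
#'
#' @param contig_tpm Output of [compute_tpm()] (needs `contig_id`,
#'   `species_bin`, `sample_id`, `tpm`).
#' @param pfam_map Output of [select_best_pfam()] (`contig_id`, `pfam_acc`).
#' @param feature_list Optional character vector of Pfam accessions to
#'   zero-fill.
#' @return Long tibble `(species_bin, sample_id, pfam_acc, tpm)`.
#' @export
aggregate_by_pfam <- function(contig_tpm, pfam_map, feature_list = NULL) {
  contig_tpm <- as_tibble(contig_tpm)
  pfam_map <- as_tibble(pfam_map)
  prof <- contig_tpm %>%
    dplyr::inner_join(pfam_map, by = "contig_id") %>%
    group_by(.data$species_bin, .data$sample_id, .data$pfam_acc) %>%
    summarise(tpm = sum(.data$tpm), .groups = "drop")
  if (!is.null(feature_list)) {
    pairs <- distinct(contig_tpm, .data$species_bin, .data$sample_id)
    if (nrow(pairs) == 0 && nrow(prof) == 0) {
      # no contigs at all: emit nothing unless a caller supplied explicit pairs
      pairs <- tibble(species_bin = character(), sample_id = character())
    }
    filled <- tidyr::crossing(pairs, pfam_acc = feature_list)
    prof <- filled %>%
      left_join(prof, by = c("species_bin", "sample_id", "pfam_acc")) %>%
      mutate(tpm = tidyr::replace_na(.data$tpm, 0)) %>%
      bind_rows(prof %>%
        dplyr::anti_join(filled, by = c("species_bin", "sample_id", "pfam_acc")))
  }
  arrange(prof, .data$species_bin, .data$sample_id, .data$pfam_acc)
}

#' Training-transcriptome quality control
#'
#' A culture transcriptome enters the training set only if it has at least
#' 1,200 total sequences, at least 500 assigned Pfam domains, and less than
#' 50% contamination (percent of ribosomal-protein sequences with a taxonomic
#' identity other than the recorded one, supplied as precomputed metadata).
#'
#' @param qc Data frame with columns `total_sequences`, `total_pfam_domains`,
#'   `contamination_pct` (plus any id columns, carried through).
#' @param min_sequences,min_pfam_domains,max_contamination_pct Thresholds;
#'   contamination is compared strictly (`< 50` passes, `50` fails).
#' @return The input tibble with logical `pass` and character `reasons`
#'   (comma-separated failure reasons, `NA` when passing) columns appended.
#' @export
qc_training_transcriptome <- function(qc,
                                      min_sequences = 1200,
                                      min_pfam_domains = 500,
                                      max_contamination_pct = 50) {
  qc <- as_tibble(qc)
  required <- c("total_sequences", "total_pfam_domains", "contamination_pct")
  missing <- setdiff(required, names(qc))
  if (length(missing) > 0) {
    stop("QC table lacks column(s): ", paste(missing, collapse = ", "))
  }
  reasons <- mapply(function(s, p, c) {
    r <- c(
      if (s < min_sequences) "sequences" else NULL,
      if (p < min_pfam_domains) "pfam_domains" else NULL,
      if (c >= max_contamination_pct) "contamination" else NULL
    )
    if (length(r) == 0) NA_character_ else paste(r, collapse = ",")
  }, qc$total_sequences, qc$total_pfam_domains, qc$contamination_pct)
  mutate(qc, pass = is.na(reasons), reasons = unname(reasons))
}

#' Min-max scaling of Pfam expression
#'
#' `fit_scaler()` learns per-feature minima and maxima on a training matrix;
#' `apply_scaler()` maps values to `(x - min) / (max - min)`. Constant
#' features (min equal to max) map to 0, and values outside the fitted range
#' are clipped to \[0, 1\] so that environmental profiles more extreme than
#' anything seen in training stay inside the domain the classifier was fitted
#' on.
#'
#' @param x Numeric matrix, samples in rows, Pfam features in columns (column
#'   names required).
#' @return `fit_scaler()` returns an object of class `trophic_scaler`;
#'   `apply_scaler()` returns the scaled matrix.
#' @export
fit_scaler <- function(x) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  if (nrow(x) < 2) stop("fitting a scaler requires at least 2 profiles")
  params <- tibble(
    pfam_acc = colnames(x),
    min = apply(x, 2, min),
    max = apply(x, 2, max)
  )
  structure(list(params = params), class = "trophic_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `trophic_scaler`.
#' @export
apply_scaler <- function(x, scaler) {
  if (!inherits(scaler, "trophic_scaler")) {
    stop("scaler has not been fitted (expected a 'trophic_scaler' object)")
  }
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  p <- scaler$params
  missing <- setdiff(colnames(x), p$pfam_acc)
  if (length(missing) > 0) {
    stop("scaler was not fitted for feature(s): ", paste(head(missing, 5), collapse = ", "))
  }
  idx <- match(colnames(x), p$pfam_acc)
  mins <- p$min[idx]
  ranges <- p$max[idx] - mins
  out <- sweep(x, 2, mins, "-")
  out <- sweep(out, 2, ifelse(ranges == 0, 1, ranges), "/")
  out[, ranges == 0] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Binarize expression values
#'
#' Converts TPM to presence/absence: 1 where expression is strictly positive,
#' 0 otherwise. Idempotent.
#'
#' @param x Numeric matrix or vector of non-negative expression values.
#' @return Object of the same shape with values in \{0, 1\}.
#' @export
binarize <- function(x) {
  (x > 0) * 1
}

#' Build a samples-by-Pfam matrix from a long profile table
#'
#' @param profiles Long tibble `(species_bin, sample_id, pfam_acc, tpm)`.
#' @param features Optional character vector fixing the column set and order;
#'   Pfams absent from the table are zero-filled, Pfams absent from `features`
#'   are dropped.
#' @return Numeric matrix with one row per (species bin, sample) pair, Pfams
#'   in columns, and a `meta` attribute holding the row-aligned tibble of
#'   `species_bin` and `sample_id`.
#' @export
profile_matrix <- function(profiles, features = NULL) {
  profiles <- as_tibble(profiles)
  if (!is.null(features)) {
    profiles <- filter(profiles, .data$pfam_acc %in% features)
  }
  meta <- profiles %>%
    distinct(.data$species_bin, .data$sample_id) %>%
    arrange(.data$species_bin, .data$sample_id)
  cols <- features %||% sort(unique(profiles$pfam_acc))
  x <- matrix(0, nrow = nrow(meta), ncol = length(cols),
              dimnames = list(NULL, cols))
  i <- match(
    paste(profiles$species_bin, profiles$sample_id, sep = "\r"),
    paste(meta$species_bin, meta$sample_id, sep = "\r")
  )
  j <- match(profiles$pfam_acc, cols)
  keep <- !is.na(j)
  x[cbind(i[keep], j[keep])] <- profiles$tpm[keep]
  attr(x, "meta") <- meta
  x
}

#' Build species-bin Pfam profiles from contig-level tables
#'
#' Convenience pipeline: best-bitscore Pfam selection, per-contig TPM, and
#' aggregation to (species bin, sample, Pfam) in one call.
#'
#' @param abundance Data frame `(contig_id, length_nt, est_count, sample_id)`
#'   or with `species_bin` already joined.
#' @param annotation Data frame of Pfam hits for [select_best_pfam()].
#' @param taxonomy Optional data frame `(contig_id, species_bin)`; required
#'   when `abundance` lacks a `species_bin` column.
#' @param e_value_max Passed to [select_best_pfam()].
#' @param feature_list Passed to [aggregate_by_pfam()].
#' @return Long profile tibble `(species_bin, sample_id, pfam_acc, tpm)`.
#' @export
build_profiles <- function(abundance, annotation, taxonomy = NULL,
                           e_value_max = 1e-5, feature_list = NULL) {
  abundance <- as_tibble(abundance)
  if (!"species_bin" %in% names(abundance)) {
    if (is.null(taxonomy)) {
      stop("abundance table has no species_bin column and no taxonomy table was given")
    }
    abundance <- dplyr::inner_join(
      abundance, select(as_tibble(taxonomy), "contig_id", "species_bin"),
      by = "contig_id"
    )
  }
  pfam_map <- select_best_pfam(annotation, e_value_max = e_value_max)
  contig_tpm <- compute_tpm(abundance)
  aggregate_by_pfam(contig_tpm, pfam_map, feature_list = feature_list)
}
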