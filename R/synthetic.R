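#' Specification for the synthetic expression generator
#'
#' Defines the statistical structure of simulated species profiles: Pfams are
#' grouped into archetypes - photosynthesis-like (high in phototrophs and
#' mixotrophs, largely silent in heterotrophs), motility-like and
#' phagocytosis-like (high in mixotrophs and heterotrophs), housekeeping/
#' CTG-like (expressed by everything; these accessions double as the
#' synthetic Core Transcribed Gene list), and mode-independent noise.
#' Expression is zero-inflated log-normal with archetype-by-mode mean TPM and
#' dropout probabilities, a shared log-scale standard deviation, and a
#' per-Pfam baseline offset (so Pfams within an archetype are correlated but
#' not interchangeable). Profiles are renormalized to sum to one million.
#'
#' @param n_pfams Total number of Pfams (default 2000).
#' @param n_photosynthesis,n_motility,n_phagocytosis,n_housekeeping Archetype
#'   sizes (defaults 40/30/30/605; the remainder is noise).
#' @param class_counts Named training-set composition (default 258
#'   phototrophic, 85 mixotrophic, 44 heterotrophic).
#' @param mean_tpm 5 x 3 matrix of mean TPM for an expressed Pfam, rows =
#'   archetypes, columns = [TROPHIC_MODES].
#' @param zero_inflation 5 x 3 matrix of dropout probabilities.
#' @param log_sd Log-scale within-Pfam standard deviation (default 1.0).
#' @param pfam_sd Log-scale per-Pfam baseline spread (default 0.4).
#' @return An object of class `trophic_generator_spec`.
#' @export
generator_spec <- function(n_pfams = 2000,
                           n_photosynthesis = 40,
                           n_motility = 30,
                           n_phagocytosis = 30,
                           n_housekeeping = 605,
                           class_counts = c(phototrophy = 258,
                                            mixotrophy = 85,
                                            heterotrophy = 44),
                           mean_tpm = NULL,
                           zero_inflation = NULL,
                           log_sd = 1.0,
                           pfam_sd = 0.4) {
  archetypes <- c("photosynthesis", "motility", "phagocytosis",
                  "housekeeping", "noise")
  n_noise <- n_pfams - n_photosynthesis - n_motility - n_phagocytosis -
    n_housekeeping
  if (n_noise < 0) stop("archetype sizes exceed n_pfams")
  if (any(class_counts <= 0)) stop("class counts must be positive")
  if (!all(names(class_counts) %in% TROPHIC_MODES)) {
    stop("class_counts must be named by trophic mode")
  }
  # Individual Pfams are deliberately weak, noisy markers - modest on/off
  # contrast and wide log-normal spread - so class separation is only
  # reliable in aggregate, as in real transcriptomes where no single domain
  # family separates trophic modes across all species.
  default_mean <- matrix(
    c(600, 500,  60,   # photosynthesis: elevated in P and M, low in H
       60, 500, 600,   # motility: elevated in M and H
       50, 400, 600,   # phagocytosis: elevated in M and H
      600, 600, 600,   # housekeeping: uniform everywhere
      300, 300, 300),  # noise: mode-independent
    nrow = 5, byrow = TRUE, dimnames = list(archetypes, TROPHIC_MODES)
  )
  # Dropout in the "on" modes reflects that species deploy overlapping but
  # different subsets of a pathway's Pfams: each profile expresses roughly
  # two-thirds of its mode-informative Pfams (medians stay non-zero), so no
  # single Pfam separates the classes for every species.
  default_zi <- matrix(
    c(0.35, 0.40, 0.80,
      0.75, 0.35, 0.30,
      0.80, 0.40, 0.30,
      0.02, 0.02, 0.02,
      0.50, 0.50, 0.50),
    nrow = 5, byrow = TRUE, dimnames = list(archetypes, TROPHIC_MODES)
  )
  mean_tpm <- mean_tpm %||% default_mean
  zero_inflation <- zero_inflation %||% default_zi
  if (any(zero_inflation < 0 | zero_inflation > 1)) {
    stop("zero-inflation probabilities must lie in [0, 1]")
  }
  sizes <- c(photosynthesis = n_photosynthesis, motility = n_motility,
             phagocytosis = n_phagocytosis, housekeeping = n_housekeeping,
             noise = n_noise)
  pfam_map <- tibble(
    pfam_acc = sprintf("PF%05d", seq_len(n_pfams)),
    archetype = rep(archetypes, times = sizes)
  )
  structure(
    list(
      n_pfams = n_pfams,
      sizes = sizes,
      class_counts = class_counts[TROPHIC_MODES],
      mean_tpm = mean_tpm,
      zero_inflation = zero_inflation,
      log_sd = log_sd,
      pfam_sd = pfam_sd,
      pfam_map = pfam_map
    ),
    class = "trophic_generator_spec"
  )
}

#' Signal and CTG Pfam accessions of a generator spec
#'
#' Signal Pfams are the mode-informative archetypes (photosynthesis,
#' motility, phagocytosis); the housekeeping block doubles as the synthetic
#' CTG reference list.
#'
#' @param spec A `trophic_generator_spec`.
#' @return Character vector of accessions.
#' @export
signal_pfams <- function(spec) {
  spec$pfam_map$pfam_acc[spec$pfam_map$archetype %in%
                           c("photosynthesis", "motility", "phagocytosis")]
}

#' @rdname signal_pfams
#' @export
ctg_pfams <- function(spec) {
  spec$pfam_map$pfam_acc[spec$pfam_map$archetype == "housekeeping"]
}

# Draw one block of profiles for a single trophic mode.
# offsets: per-Pfam log-scale baseline. Returns k x n_pfams TPM matrix.
draw_mode_block <- function(spec, mode, k, offsets, extra_dropout = NULL) {
  n <- spec$n_pfams
  arch <- spec$pfam_map$archetype
  mu <- log(spec$mean_tpm[arch, mode]) + offsets
  zi <- spec$zero_inflation[arch, mode]
  x <- exp(matrix(mu, k, n, byrow = TRUE) +
             matrix(rnorm(k * n, 0, spec$log_sd), k, n))
  expressed <- matrix(runif(k * n), k, n) >= matrix(zi, k, n, byrow = TRUE)
  if (!is.null(extra_dropout) && extra_dropout > 0) {
    is_ctg <- arch == "housekeeping"
    drop <- matrix(runif(k * n), k, n) < extra_dropout
    expressed[, is_ctg] <- expressed[, is_ctg] & !drop[, is_ctg]
  }
  x <- x * expressed
  sums <- rowSums(x)
  x[sums > 0, ] <- x[sums > 0, , drop = FALSE] * (1e6 / sums[sums > 0])
  colnames(x) <- spec$pfam_map$pfam_acc
  x
}

#' Generate a synthetic labeled training set
#'
#' Draws `sum(class_counts)` transcriptome profiles (default 258 phototrophic,
#' 85 mixotrophic, 44 heterotrophic) from the zero-inflated log-normal model
#' defined by `spec`, renormalized to one million TPM each. Deterministic for
#' a given seed.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed.
#' @return List with `profiles` (a [labeled_profiles()] object of raw TPM),
#'   `signal_pfams`, `ctg_pfams`, and `pfam_map`.
#' @export
generate_training <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "trophic_generator_spec"))
  offsets <- withr::with_seed(
    substream_seed(seed, "pfam-offsets"),
    rnorm(spec$n_pfams, 0, spec$pfam_sd)
  )
  blocks <- withr::with_seed(substream_seed(seed, "training-draws"), {
    lapply(TROPHIC_MODES, function(mode) {
      draw_mode_block(spec, mode, spec$class_counts[[mode]], offsets)
    })
  })
  x <- do.call(rbind, blocks)
  label <- rep(TROPHIC_MODES, times = spec$class_counts)
  rownames(x) <- sprintf("%s_%03d", substr(label, 1, 5),
                         unlist(lapply(spec$class_counts, seq_len)))
  list(
    profiles = labeled_profiles(x, label),
    signal_pfams = signal_pfams(spec),
    ctg_pfams = ctg_pfams(spec),
    pfam_map = spec$pfam_map
  )
}

#' Default mock environmental scenario: a latitudinal gradient
#'
#' Six stations along a latitude transect, two replicates and two size
#' fractions per station, and five species bins: two phototrophic
#' specialists, a heterotrophic specialist, and two bins (one of them a
#' dinoflagellate) that shift trophic mode between the southern and northern
#' stations - the pattern a capability classifier should flag as mixotrophic
#' capability.
#'
#' @param n_stations Number of stations (default 6).
#' @param ctg_dropout Extra dropout probability applied to CTG Pfams, to
#'   exercise the completeness gate (default 0).
#' @return Scenario list consumed by [generate_environment()].
#' @export
gradient_scenario <- function(n_stations = 6, ctg_dropout = 0) {
  stations <- sprintf("lat%02d", round(seq(25, 42, length.out = n_stations)))
  south <- stations[seq_len(ceiling(n_stations / 2))]
  bins <- tibble(
    species_bin = c("pelagophyte_A", "chlorophyte_B", "bolidophyte_C",
                    "dinoflagellate_D", "ciliate_E"),
    is_dinoflagellate = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  mode_of <- function(bin, station) {
    switch(bin,
      pelagophyte_A = "phototrophy",
      chlorophyte_B = "phototrophy",
      bolidophyte_C = if (station %in% south) "phototrophy" else "mixotrophy",
      dinoflagellate_D = if (station %in% south) "heterotrophy" else "mixotrophy",
      ciliate_E = "heterotrophy"
    )
  }
  modes <- tidyr::crossing(species_bin = bins$species_bin, station = stations) %>%
    mutate(mode = mapply(mode_of, .data$species_bin, .data$station))
  list(
    name = "gradient-shift",
    stations = stations,
    replicates = 2,
    size_fractions = c("0.2-3um", ">3um"),
    bins = bins,
    modes = modes,
    ctg_dropout = ctg_dropout,
    volume_filtered_l = 2,
    standard_copies_added = 1e9,
    standard_reads_mean = 1e5,
    concentration_mean = 1e8
  )
}

#' Generate a mock environmental metatranscriptome dataset
#'
#' Every (station, replicate, size fraction) combination becomes one sample.
#' Each species bin emits a profile drawn from its scenario-assigned trophic
#' mode, with optional extra dropout on CTG Pfams to test the completeness
#' gate. Spike-in records and per-bin read counts are generated consistently
#' with a drawn true transcript concentration, so the internal-standard
#' estimator recovers the generated concentrations exactly.
#'
#' @param spec A [generator_spec()].
#' @param scenario Scenario list (default [gradient_scenario()]).
#' @param seed Integer seed.
#' @return List: `profiles` (long TPM tibble), `metadata` (per-sample
#'   replicate/size fraction/grouping unit and spike-in fields), `bin_reads`
#'   (reads per species bin and sample), `truth` (modes per bin and station,
#'   true concentrations per bin and sample), `taxonomy` (bin lineage
#'   flags), `ctg_pfams`.
#' @export
generate_environment <- function(spec, scenario = gradient_scenario(),
                                 seed = 1) {
  stopifnot(inherits(spec, "trophic_generator_spec"))
  offsets <- withr::with_seed(
    substream_seed(seed, "pfam-offsets"),
    rnorm(spec$n_pfams, 0, spec$pfam_sd)
  )
  metadata <- tidyr::crossing(
    station = scenario$stations,
    replicate = sprintf("rep%d", seq_len(scenario$replicates)),
    size_fraction = scenario$size_fractions
  ) %>%
    mutate(
      sample_id = paste(.data$station, .data$replicate, .data$size_fraction,
                        sep = "."),
      grouping_unit = .data$station,
      volume_filtered_l = scenario$volume_filtered_l,
      standard_copies_added = scenario$standard_copies_added
    )
  metadata$reads_mapped_to_standards <- withr::with_seed(
    substream_seed(seed, "spike-reads"),
    pmax(1, round(stats::rlnorm(nrow(metadata),
                                log(scenario$standard_reads_mean), 0.2)))
  )
  pairs <- tidyr::crossing(species_bin = scenario$bins$species_bin,
                           sample_id = metadata$sample_id) %>%
    left_join(select(metadata, "sample_id", "station", "volume_filtered_l",
                     "standard_copies_added", "reads_mapped_to_standards"),
              by = "sample_id") %>%
    left_join(scenario$modes, by = c("species_bin", "station"))
  pairs$true_transcripts_per_l <- withr::with_seed(
    substream_seed(seed, "concentrations"),
    stats::rlnorm(nrow(pairs), log(scenario$concentration_mean), 0.5)
  )
  # reads implied by the concentration under the internal-standard estimator;
  # kept real-valued so the estimator inverts the generator exactly
  pairs$bin_reads <- pairs$true_transcripts_per_l * pairs$volume_filtered_l /
    pairs$standard_copies_added * pairs$reads_mapped_to_standards
  profile_rows <- withr::with_seed(substream_seed(seed, "env-draws"), {
    lapply(seq_len(nrow(pairs)), function(i) {
      x <- draw_mode_block(spec, pairs$mode[i], 1, offsets,
                           extra_dropout = scenario$ctg_dropout)
      nz <- which(x[1, ] > 0)
      tibble(
        species_bin = pairs$species_bin[i],
        sample_id = pairs$sample_id[i],
        pfam_acc = colnames(x)[nz],
        tpm = x[1, nz]
      )
    })
  })
  list(
    profiles = bind_rows(profile_rows),
    metadata = metadata,
    bin_reads = select(pairs, "species_bin", "sample_id", "bin_reads"),
    truth = list(
      modes = scenario$modes,
      concentrations = select(pairs, "species_bin", "sample_id",
                              "true_transcripts_per_l")
    ),
    taxonomy = scenario$bins,
    ctg_pfams = ctg_pfams(spec)
  )
}

#' Median expression by archetype and trophic mode
#'
#' Validates the generator's structure: the median TPM over all (profile,
#' Pfam) values within each archetype-by-mode cell. Photosynthesis-like
#' Pfams should have near-zero medians in heterotrophic profiles,
#' housekeeping Pfams positive medians everywhere.
#'
#' @param training Output of [generate_training()].
#' @return Tibble `(archetype, mode, median_tpm)`.
#' @export
summarize_archetypes <- function(training) {
  lp <- training$profiles
  arch <- training$pfam_map$archetype[match(colnames(lp$x),
                                            training$pfam_map$pfam_acc)]
  bind_rows(lapply(unique(arch), function(a) {
    cols <- which(arch == a)
    bind_rows(lapply(TROPHIC_MODES, function(m) {
      rows <- which(lp$label == m)
      tibble(archetype = a, mode = m,
             median_tpm = median(lp$x[rows, cols]))
    }))
  }))
}
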