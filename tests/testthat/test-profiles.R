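test_that("best-bitscore Pfam selection filters, ranks, and breaks ties", {
  hits <- tibble::tribble(
    ~contig_id, ~pfam_acc, ~e_value, ~bitscore,
    "c1", "PF00001", 1e-10, 50,
    "c1", "PF00002", 1e-08, 60, # higher bitscore wins despite worse e-value
    "c2", "PF00001", 1e-04, 99, # at/above the 1e-05 cutoff: dropped
    "c3", "PF00001", 1e-10, 50,
    "c3", "PF00002", 1e-10, 50  # bitscore tie: smallest accession wins
  )
  sel <- select_best_pfam(hits)
  expect_equal(sel$pfam_acc[sel$contig_id == "c1"], "PF00002")
  expect_false("c2" %in% sel$contig_id)
  expect_equal(sel$pfam_acc[sel$contig_id == "c3"], "PF00001")

  # exactly at the threshold is excluded ("less than")
  at_cutoff <- tibble::tibble(contig_id = "c9", pfam_acc = "PF1",
                              e_value = 1e-05, bitscore = 10)
  expect_equal(nrow(select_best_pfam(at_cutoff)), 0)

  bad <- tibble::tibble(contig_id = "c1", pfam_acc = "PF1",
                        e_value = -1, bitscore = 10)
  expect_error(select_best_pfam(bad), "malformed")
})

test_that("TPM matches the hand-computed three-contig oracle", {
  # RPK = {10/0.5, 20/1, 30/2} = {20, 20, 15}; factor = 55/1e6
  out <- compute_tpm(three_contig_table())
  expect_equal(out$tpm, c(20, 20, 15) / (55 / 1e6), tolerance = 1e-12)
  expect_equal(sum(out$tpm), 1e6, tolerance = 1e-6)
})

test_that("TPM normalization invariants hold on random contig tables", {
  set.seed(1203)
  contigs <- tibble::tibble(
    contig_id = sprintf("c%03d", 1:120),
    length_nt = sample(200:5000, 120, replace = TRUE),
    est_count = round(stats::rexp(120, 1 / 50), 2),
    species_bin = sample(c("binA", "binB", "binC"), 120, replace = TRUE),
    sample_id = sample(c("s1", "s2"), 120, replace = TRUE)
  )
  out <- compute_tpm(contigs)
  sums <- tapply(out$tpm, paste(out$species_bin, out$sample_id),
                 sum)
  expect_true(all(abs(sums - 1e6) / 1e6 < 1e-6 | sums == 0))

  # invariant under count rescaling within a group
  scaled <- compute_tpm(dplyr::mutate(contigs, est_count = est_count * 7.3))
  expect_equal(out$tpm, scaled$tpm, tolerance = 1e-12)

  # the nt-vs-kb length convention cancels in TPM
  kb <- dplyr::mutate(contigs, rpk_kb = est_count / (length_nt / 1000))
  manual <- kb |>
    dplyr::group_by(species_bin, sample_id) |>
    dplyr::mutate(tpm_kb = rpk_kb / (sum(rpk_kb) / 1e6)) |>
    dplyr::ungroup()
  nt <- dplyr::mutate(contigs, rpk_nt = est_count / length_nt)
  manual_nt <- nt |>
    dplyr::group_by(species_bin, sample_id) |>
    dplyr::mutate(tpm_nt = rpk_nt / (sum(rpk_nt) / 1e6)) |>
    dplyr::ungroup()
  expect_equal(manual$tpm_kb, manual_nt$tpm_nt, tolerance = 1e-9)
  expect_equal(out$tpm, manual$tpm_kb, tolerance = 1e-9)
})

test_that("TPM degenerate and error cases behave as specified", {
  single <- tibble::tibble(contig_id = "c1", length_nt = 800, est_count = 3,
                           species_bin = "b", sample_id = "s")
  expect_equal(compute_tpm(single)$tpm, 1e6)

  zeros <- tibble::tibble(contig_id = c("c1", "c2"), length_nt = c(500, 900),
                          est_count = 0, species_bin = "b", sample_id = "s")
  expect_equal(compute_tpm(zeros)$tpm, c(0, 0))

  bad <- tibble::tibble(contig_id = "cX", length_nt = 0, est_count = 1,
                        species_bin = "b", sample_id = "s")
  expect_error(compute_tpm(bad), "cX")
})

test_that("Pfam aggregation sums, zero-fills, and conserves total TPM", {
  contig_tpm <- tibble::tibble(
    contig_id = c("c1", "c2", "c3", "c4"),
    species_bin = "b", sample_id = "s",
    tpm = c(100, 50, 25, 10)
  )
  pfam_map <- tibble::tibble(contig_id = c("c1", "c2", "c3"),
                             pfam_acc = c("PFA", "PFA", "PFB"))
  prof <- aggregate_by_pfam(contig_tpm, pfam_map)
  expect_equal(prof$tpm[prof$pfam_acc == "PFA"], 150)
  expect_equal(prof$tpm[prof$pfam_acc == "PFB"], 25)
  # c4 is unannotated and dropped; annotated total conserved
  expect_equal(sum(prof$tpm), 175)

  filled <- aggregate_by_pfam(contig_tpm, pfam_map,
                              feature_list = c("PFA", "PFC"))
  expect_equal(filled$tpm[filled$pfam_acc == "PFC"], 0)
  expect_equal(filled$tpm[filled$pfam_acc == "PFA"], 150)
  expect_true("PFB" %in% filled$pfam_acc)
})

test_that("training-transcriptome QC applies the 1200/500/<50 thresholds", {
  qc <- tibble::tibble(
    total_sequences = c(1200, 1199, 5000, 2000),
    total_pfam_domains = c(500, 500, 600, 499),
    contamination_pct = c(49.9, 0, 50.0, 10)
  )
  res <- qc_training_transcriptome(qc)
  expect_equal(res$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(res$reasons[2], "sequences")
  expect_match(res$reasons[3], "contamination") # 50.0 fails the strict < 50
  expect_match(res$reasons[4], "pfam_domains")
})

test_that("min-max scaler maps to [0,1], zeroes constants, and clips", {
  x <- cbind(a = c(0, 5, 10), b = c(7, 7, 7))
  sc <- fit_scaler(x)
  scaled <- apply_scaler(x, sc)
  expect_equal(scaled[, "a"], c(0, 0.5, 1))
  expect_equal(scaled[, "b"], c(0, 0, 0))

  new <- cbind(a = c(-3, 20), b = c(7, 9))
  clipped <- apply_scaler(new, sc)
  expect_equal(clipped[, "a"], c(0, 1))
  expect_true(all(clipped >= 0 & clipped <= 1))

  # monotone per feature
  grid <- cbind(a = sort(runif(20, -5, 25)), b = rep(7, 20))
  expect_true(!is.unsorted(apply_scaler(grid, sc)[, "a"]))

  expect_error(apply_scaler(x, list()), "not been fitted")
  expect_error(fit_scaler(x[1, , drop = FALSE]), "at least 2")
})

test_that("binarization is a 0/1 indicator and idempotent", {
  x <- cbind(a = c(12.3, 0), b = c(0, 0))
  b <- binarize(x)
  expect_equal(b, cbind(a = c(1, 0), b = c(0, 0)))
  expect_equal(binarize(b), b)
})

test_that("build_profiles wires annotation, abundance and taxonomy together", {
  abundance <- tibble::tibble(
    contig_id = c("c1", "c2", "c3"),
    length_nt = c(500, 1000, 2000),
    est_count = c(10, 20, 30),
    sample_id = "s1"
  )
  annotation <- tibble::tibble(
    contig_id = c("c1", "c2", "c3", "c3"),
    pfam_acc = c("PFA", "PFA", "PFB", "PFC"),
    e_value = c(1e-10, 1e-12, 1e-9, 1e-3),
    bitscore = c(50, 60, 40, 90)
  )
  taxonomy <- tibble::tibble(contig_id = c("c1", "c2", "c3"),
                             species_bin = "binA")
  prof <- build_profiles(abundance, annotation, taxonomy)
  expect_equal(sort(prof$pfam_acc), c("PFA", "PFB"))
  expect_equal(sum(prof$tpm), 1e6, tolerance = 1e-6)
  expect_error(build_profiles(abundance, annotation), "taxonomy")
})
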