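# Sample/transcript gates, spliced frequency, PSR and the public /
# cancer-specific neojunction calls.

test_that("purity gate is inclusive at the boundary and keeps all normals", {
  samples <- data.frame(
    sample_id = c("T1", "T2", "T3", "N1"),
    cohort = c("tumour", "tumour", "tumour", "normal"),
    purity = c(0.59, 0.60, 0.90, NA)
  )
  kept <- gate_samples(samples)
  expect_setequal(kept$sample_id, c("T2", "T3", "N1"))
  # tumour sample without purity is dropped with a warning
  samples2 <- rbind(samples,
                    data.frame(sample_id = "T4", cohort = "tumour", purity = NA))
  expect_warning(kept2 <- gate_samples(samples2), "purity unavailable")
  expect_false("T4" %in% kept2$sample_id)
  # all tumours failing is a pipeline error
  low <- data.frame(sample_id = c("T1", "N1"), cohort = c("tumour", "normal"),
                    purity = c(0.3, NA))
  expect_error(gate_samples(low), "purity gate")
})

test_that("transcript gate requires coding, non-mitochondrial, median TPM >= 10 in one subtype", {
  txs <- list(
    transcript_model("tx_ok", "g1", "chr1", "+",
                     data.frame(start = c(1, 101), end = c(50, 200)),
                     cds_span = c(10, 150)),
    transcript_model("tx_low", "g2", "chr1", "+",
                     data.frame(start = c(301, 401), end = c(350, 500)),
                     cds_span = c(310, 450)),
    transcript_model("tx_nc", "g3", "chr1", "+",
                     data.frame(start = c(601, 701), end = c(650, 800))),
    transcript_model("tx_mt", "g4", "chrM", "+",
                     data.frame(start = c(1, 101), end = c(50, 200)),
                     cds_span = c(10, 150))
  )
  expr <- rbind(
    tx_ok = c(12, 12, 3, 3), tx_low = c(9.9, 9.9, 9.9, 9.9),
    tx_nc = c(100, 100, 100, 100), tx_mt = c(100, 100, 100, 100)
  )
  colnames(expr) <- c("s1", "s2", "s3", "s4")
  subtypes <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  kept <- gate_transcripts(txs, expr, subtypes)
  expect_equal(names(kept), "tx_ok")
  expect_equal(unname(kept$tx_ok$median_tpm["A"]), 12)
  # transcript absent from the matrix is excluded with a warning
  txs5 <- c(txs, list(transcript_model("tx_missing", "g5", "chr1", "+",
                                       data.frame(start = c(901, 1001),
                                                  end = c(950, 1100)),
                                       cds_span = c(910, 1050))))
  expect_warning(kept5 <- gate_transcripts(txs5, expr, subtypes),
                 "absent from expression")
  expect_false("tx_missing" %in% names(kept5))
})

test_that("spliced frequency follows target/(target+canonical) with 0/0 = 0", {
  expect_equal(compute_frequency(10, 990), 0.01)
  expect_equal(compute_frequency(50, 0), 1.0)
  expect_equal(compute_frequency(0, 0), 0.0)
  expect_error(compute_frequency(-1, 5), "non-negative")
})

test_that("per-sample expression requires count, depth and frequency gates", {
  expect_true(sample_expresses(10, 10))          # boundary on all three
  expect_false(sample_expresses(9, 1000))        # count gate
  expect_false(sample_expresses(10, 5))          # depth 15 < 20
  expect_false(sample_expresses(10, 1990))       # freq 0.005 < 0.01
  expect_true(sample_expresses(10, 990))         # freq exactly 0.01 (inclusive)
  strict <- threshold_config(freq_inclusive = FALSE)
  expect_false(sample_expresses(10, 990, strict))
})

test_that("PSR is the fraction of expressing gated samples", {
  expect_equal(compute_psr(c(rep(TRUE, 3), rep(FALSE, 17))), 0.15)
  expect_equal(compute_psr(rep(FALSE, 10)), 0)
  expect_equal(compute_psr(rep(TRUE, 4)), 1)
  expect_error(compute_psr(logical(0)), "empty cohort")
})

test_that("PSR never decreases when a sample's target reads rise", {
  cfg <- threshold_config()
  for (reads in list(c(5, 12, 40), c(0, 10, 25))) {
    ex1 <- sample_expresses(reads, rep(100, 3), cfg)
    ex2 <- sample_expresses(reads + 10, rep(100, 3), cfg)
    expect_true(all(ex2 >= ex1))
    expect_gte(compute_psr(ex2), compute_psr(ex1))
  }
})

make_mini_cohort <- function(n_tumour, n_normal, expr_tumour, expr_normal) {
  # one gene with one annotated intron and one A3-loss neojunction;
  # expressing samples get 30 target reads against 100 canonical reads
  tx <- toy_tx("+")
  ids <- c(sprintf("T%02d", seq_len(n_tumour)), sprintf("N%02d", seq_len(n_normal)))
  cohorts <- rep(c("tumour", "normal"), c(n_tumour, n_normal))
  expressing <- c(sprintf("T%02d", expr_tumour), sprintf("N%02d", expr_normal))
  rows <- lapply(seq_along(ids), function(i) {
    base <- data.frame(chrom = "chrT", intron_start = c(201L, 401L),
                       intron_end = c(300L, 500L), strand = "+", motif = 1L,
                       annotated = 1L, unique_reads = 100L, multi_reads = 0L,
                       max_overhang = 50L, sample_id = ids[i])
    if (ids[i] %in% expressing) {
      base <- rbind(base, data.frame(chrom = "chrT", intron_start = 201L,
                                     intron_end = 320L, strand = "+", motif = 1L,
                                     annotated = 0L, unique_reads = 30L,
                                     multi_reads = 0L, max_overhang = 50L,
                                     sample_id = ids[i]))
    }
    base
  })
  junctions <- do.call(rbind, rows)
  junctions$key <- jx_key(junctions$chrom, junctions$intron_start,
                          junctions$intron_end, junctions$strand)
  samples <- data.frame(sample_id = ids, cohort = cohorts,
                        purity = ifelse(cohorts == "tumour", 0.9, NA),
                        subtype = "A", stringsAsFactors = FALSE)
  list(junctions = junctions, samples = samples,
       index = build_annotation_index(list(tx)))
}

test_that("public and cancer-specific boundaries behave as documented", {
  # tumour PSR exactly 0.10 (inclusive), normal PSR 0 -> public and specific
  mc <- make_mini_cohort(20, 100, expr_tumour = 1:2, expr_normal = integer(0))
  res <- discover_neojunctions(mc$junctions, mc$index, mc$samples)
  expect_equal(nrow(res$calls), 1L)
  expect_equal(res$calls$psr_tumour, 0.10)
  expect_true(res$calls$public)
  expect_true(res$calls$cancer_specific)
  # normal PSR exactly 0.01 (exclusive) -> public but not cancer-specific
  mc2 <- make_mini_cohort(20, 100, expr_tumour = 1:10, expr_normal = 1)
  res2 <- discover_neojunctions(mc2$junctions, mc2$index, mc2$samples)
  expect_equal(res2$calls$psr_tumour, 0.5)
  expect_equal(res2$calls$psr_normal, 0.01)
  expect_true(res2$calls$public)
  expect_false(res2$calls$cancer_specific)
})

test_that("cohort-sum pre-filter removes junctions too weak across the tumour cohort", {
  mc <- make_mini_cohort(20, 10, expr_tumour = 1, expr_normal = integer(0))
  # shrink the single expressing sample's target reads below the cohort sum gate
  sel <- mc$junctions$annotated == 0
  mc$junctions$unique_reads[sel] <- 9L
  res <- call_neojunctions(
    build_junction_catalogue(mc$junctions, mc$index,
                             gate_samples(mc$samples)),
    mc$junctions, gate_samples(mc$samples)
  )
  expect_equal(nrow(res$calls), 0L)
})

test_that("calls are sorted by decreasing tumour PSR and annotated junctions are never called", {
  cfg <- sim_config(seed = 12, n_genes = 6, n_tumour_samples = 10,
                    n_normal_samples = 10, n_cases = 1, regions_per_case = 2)
  ref <- generate_reference(cfg)
  coh <- plant_and_emit_cohort(cfg, ref)
  res <- discover_neojunctions(coh$junctions, build_annotation_index(ref$transcripts),
                               coh$samples, coh$expression)
  expect_true(all(diff(res$calls$psr_tumour) <= 0))
  idx <- build_annotation_index(ref$transcripts)
  expect_false(any(res$calls$key %in% idx$intron_keys))
})
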