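# Mutant transcript construction, translation, peptide tiling,
# proteome filtering, two-scorer selection and MS matching.

test_that("an in-frame 6-nt acceptor-side loss deletes exactly two amino acids", {
  ref <- small_reference(seed = 11, n_genes = 2)
  for (tx in ref$transcripts) {
    pc <- plant_junction_coords(tx, "A3_loss", -6)
    m <- build_mutant_transcript(
      tx, list(chrom = tx$chrom, intron_start = pc$intron_start,
               intron_end = pc$intron_end), ref$genome)
    rp <- m$reference_protein; mp <- m$mutant_protein
    expect_false(m$frameshift)
    expect_false(m$premature_stop)
    expect_equal(nchar(mp), nchar(rp) - 2L)
    # the mutant is the reference minus two consecutive residues
    hit <- FALSE
    for (i in seq_len(nchar(rp) - 2L)) {
      if (paste0(substr(rp, 1, i - 1), substr(rp, i + 2, nchar(rp))) == mp) {
        hit <- TRUE
        # the junction residue span brackets the fusion point
        expect_lte(abs(m$junction_residue_span[1] - (i - 1)), 1)
        break
      }
    }
    expect_true(hit, info = tx$transcript_id)
  }
})

test_that("a 2-nt acceptor-side loss frameshifts with a novel tail and premature stop", {
  ref <- small_reference(seed = 12, n_genes = 3)
  any_stop <- FALSE
  for (tx in ref$transcripts) {
    pc <- plant_junction_coords(tx, "A3_loss", -2)
    m <- build_mutant_transcript(
      tx, list(chrom = tx$chrom, intron_start = pc$intron_start,
               intron_end = pc$intron_end), ref$genome)
    expect_true(m$frameshift)
    expect_equal(m$junction_residue_span[2], nchar(m$mutant_protein))
    # prefix up to the junction matches the reference
    pre <- m$junction_residue_span[1] - 1L
    expect_equal(substr(m$mutant_protein, 1, pre),
                 substr(m$reference_protein, 1, pre))
    if (m$found_stop) {
      expect_true(m$premature_stop)
      any_stop <- TRUE
    }
  }
  expect_true(any_stop)
})

test_that("translation truncates at the first stop codon", {
  tr <- njatlas:::translate_to_stop("ATGGCCTAAGGGTTT")
  expect_equal(tr$protein, "MA")
  expect_true(tr$found_stop)
  tr2 <- njatlas:::translate_to_stop("ATGGCCGGG")
  expect_equal(tr2$protein, "MAG")
  expect_false(tr2$found_stop)
})

test_that("mutant proteins equal codon-by-codon translation of the mutant CDS", {
  ref <- small_reference(seed = 13, n_genes = 8)
  set.seed(77)
  n_checked <- 0
  for (rep in 1:5) {
    for (tx in ref$transcripts) {
      pj <- random_planted_junction(tx)
      m <- build_mutant_transcript(
        tx, list(chrom = tx$chrom, intron_start = pj$intron_start,
                 intron_end = pj$intron_end), ref$genome)
      if (nchar(m$mutant_cds) == 0) next
      expect_equal(m$mutant_protein, oracle_translate(m$mutant_cds),
                   info = sprintf("%s %s", tx$transcript_id, pj$type))
      # frameshift flag consistent with the classified nt_delta
      expect_equal(m$frameshift, abs(m$nt_delta) %% 3L != 0L)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 30)
})

test_that("tiling enumerates every junction-overlapping window of each length", {
  set.seed(3)
  prot <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                         "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                       30, replace = TRUE), collapse = "")
  mut <- structure(list(mutant_protein = prot, junction_residue_span = c(15L, 15L),
                        junction_key = "jx"), class = "mutant_transcript")
  tiles <- tile_peptides(mut)
  expect_equal(nrow(tiles), 8 + 9 + 10 + 11)   # 38 windows around residue 15
  expect_true(all(tiles$position <= 15 & tiles$position + tiles$length - 1 >= 15))
  # affected residue at position 1: one window per k
  mut$junction_residue_span <- c(1L, 1L)
  expect_equal(nrow(tile_peptides(mut)), 4L)
  # duplicated sequences collapse to the first occurrence
  mut$mutant_protein <- strrep("ACDEFGHIKLMN", 3)
  mut$junction_residue_span <- c(13L, 24L)
  tiles3 <- tile_peptides(mut)
  expect_false(any(duplicated(tiles3$sequence)))
  # flanks are bounded by 30 residues
  expect_true(all(nchar(tiles$flank_n) <= 30 & nchar(tiles$flank_c) <= 30))
})

test_that("proteome filtering flags exactly the planted decoy tile", {
  set.seed(4)
  prot <- paste(sample(c("A", "D", "E", "G", "K", "L", "R", "S"), 40, TRUE),
                collapse = "")
  mut <- structure(list(mutant_protein = prot, junction_residue_span = c(20L, 20L),
                        junction_key = "jx"), class = "mutant_transcript")
  tiles <- tile_peptides(mut)
  decoy <- tiles$sequence[5]
  proteome <- c(paste0("MMMM", decoy, "WWWW"), "MCCCCCCCCCC")
  out <- filter_tumour_specific(tiles, proteome)
  # the decoy (and any tile nested inside it) is non-specific
  expect_false(out$tumour_specific[5])
  nested <- vapply(out$sequence, function(s) grepl(s, proteome[1], fixed = TRUE),
                   logical(1))
  expect_equal(out$tumour_specific, unname(!nested))
})

test_that("selection requires top-percentile rank in both scorers for one allele", {
  peptides <- sprintf("PEPTIDE%03d", 1:100)
  df <- data.frame(sequence = peptides, junction_key = "j1",
                   tumour_specific = TRUE, stringsAsFactors = FALSE)
  al <- "HLA-A*02:01"
  # scorer A ranks pep 1 best; scorer B ranks it worst
  ta <- data.frame(peptide = peptides, allele = al, score = 100:1)
  tb <- data.frame(peptide = peptides, allele = al, score = 1:100)
  sel <- select_presented(df, ta, tb, alleles = al, q = 0.05)
  expect_equal(sum(sel$selected), 0L)
  # both scorers agree on the top candidate
  tb2 <- data.frame(peptide = peptides, allele = al, score = c(200, 2:100))
  sel2 <- select_presented(df, ta, tb2, alleles = al, q = 0.01)
  expect_equal(sel2$sequence[sel2$selected], peptides[1])
  # q = 1 selects every tumour-specific candidate
  sel3 <- select_presented(df, ta, tb, alleles = al, q = 1)
  expect_true(all(sel3$selected))
  # enlarging q never removes a selected candidate
  sel05 <- select_presented(df, ta, tb2, alleles = al, q = 0.05)
  expect_true(all(sel2$selected <= sel05$selected))
  # non-specific candidates can never be selected
  df2 <- df; df2$tumour_specific[1] <- FALSE
  sel4 <- select_presented(df2, ta, tb2, alleles = al, q = 1)
  expect_false(sel4$selected[1])
  # missing table entries are an error naming the peptides
  expect_error(select_presented(df, ta[-1, ], tb, alleles = al), "missing")
})

test_that("NEJ mapping counts distinct parent junctions of selected candidates", {
  cand <- data.frame(sequence = sprintf("P%02d", 1:10),
                     junction_key = rep(c("j1", "j2"), c(7, 3)),
                     selected = c(rep(TRUE, 5), rep(FALSE, 2), rep(TRUE, 3)))
  nej <- map_to_nej(cand)
  expect_setequal(nej$junction_key, c("j1", "j2"))
  expect_equal(nej$n_selected[nej$junction_key == "j1"], 5L)
  expect_equal(nej$n_selected[nej$junction_key == "j2"], 3L)
  cand$selected <- FALSE
  expect_equal(nrow(map_to_nej(cand)), 0L)
})

test_that("MS confirmation requires junction overlap and proteome absence", {
  mut <- structure(list(mutant_protein = "MAAAACDEFGHIKLMNPQRST",
                        junction_residue_span = c(10L, 11L),
                        junction_key = "j1"), class = "mutant_transcript")
  proteome <- "MWWWWCCCCWWWW"
  # spans residues 8..15: overlaps the junction span
  expect_true(match_ms_peptides("EFGHIKLM", list(mut), proteome)$ms_confirmed)
  # matches only upstream of the junction span (residues 2..7)
  expect_false(match_ms_peptides("AAAACD", list(mut), proteome)$ms_confirmed)
  # also present in the proteome: not confirmed
  proteome2 <- c(proteome, "XXEFGHIKLMXX")
  expect_false(match_ms_peptides("EFGHIKLM", list(mut), proteome2)$ms_confirmed)
})

test_that("the full neoantigen stage recovers planted binders end to end", {
  cfg <- sim_config(seed = 22, n_genes = 8, n_tumour_samples = 10,
                    n_normal_samples = 10, n_cases = 1, regions_per_case = 2)
  ref <- generate_reference(cfg)
  coh <- plant_and_emit_cohort(cfg, ref)
  idx <- build_annotation_index(ref$transcripts)
  res <- discover_neojunctions(coh$junctions, idx, coh$samples, coh$expression)
  pre <- nj_neoantigens(res$calls, res$index, ref$genome, ref$proteome)
  expect_gt(nrow(pre$candidates), 50)
  ts <- pre$candidates$sequence[pre$candidates$tumour_specific]
  planted <- ts[seq_len(min(3, floor(length(ts) * 0.05)))]
  tabs <- generate_score_tables(ts, planted, seed = 5, q = 0.05)
  out <- nj_neoantigens(res$calls, res$index, ref$genome, ref$proteome,
                        tables = tabs, q = 0.05)
  expect_setequal(out$candidates$sequence[out$candidates$selected], planted)
  expect_setequal(out$nejs$junction_key,
                  unique(out$candidates$junction_key[out$candidates$selected]))
})
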