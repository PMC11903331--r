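# Junction table parsing, annotation indexing, splice-type
# classification and canonical-partner assignment.

test_that("SJ.out.tab parsing maps fields and strand codes, retains zero-read rows", {
  path <- withr::local_tempfile(fileext = ".tab")
  writeLines(c("chr1\t201\t300\t1\t1\t1\t42\t0\t50",
               "chr1\t401\t500\t0\t0\t0\t0\t3\t21",
               "chr2\t10\t90\t2\t2\t1\t7\t0\t33"), path)
  jx <- parse_junction_table(path, "S1")
  expect_equal(nrow(jx), 3L)
  expect_equal(jx$chrom[1], "chr1")
  expect_equal(jx$intron_start[1], 201L)
  expect_equal(jx$intron_end[1], 300L)
  expect_equal(jx$strand, c("+", "*", "-"))
  expect_equal(jx$unique_reads, c(42L, 0L, 7L))
  expect_equal(jx$sample_id, rep("S1", 3))
})

test_that("malformed junction rows raise errors naming the line", {
  path <- withr::local_tempfile(fileext = ".tab")
  writeLines(c("chr1\t201\t300\t1\t1\t1\t42\t0\t50",
               "chr1\t401\t500\t1\t1\t1\t9\t0"), path)
  expect_error(parse_junction_table(path, "S1"), "line 2")
  path2 <- withr::local_tempfile(fileext = ".tab")
  writeLines("chr1\t201\t300\t7\t1\t1\t42\t0\t50", path2)
  expect_error(parse_junction_table(path2, "S1"), "strand code")
  path3 <- withr::local_tempfile(fileext = ".tab")
  file.create(path3)
  expect_equal(nrow(parse_junction_table(path3, "S1")), 0L)
})

test_that("junction tables round-trip through the writer", {
  path <- withr::local_tempfile(fileext = ".tab")
  jx <- data.frame(chrom = "chr1", intron_start = 201L, intron_end = 300L,
                   strand = "+", motif = 1L, annotated = 1L,
                   unique_reads = 12L, multi_reads = 0L, max_overhang = 50L)
  write_junction_table(jx, path)
  back <- parse_junction_table(path, "S1")
  expect_equal(back$intron_start, 201L)
  expect_equal(back$strand, "+")
  expect_equal(back$unique_reads, 12L)
})

test_that("annotation index answers intron and gene-overlap queries", {
  idx <- toy_index("+")
  expect_true(is_annotated_junction(idx, "chrT", 201, 300, "+"))
  expect_true(is_annotated_junction(idx, "chrT", 401, 500, "+"))
  expect_false(is_annotated_junction(idx, "chrT", 201, 320, "+"))
  expect_equal(genes_overlapping(idx, "chrT", 250, 260), "toyG+")
  expect_equal(length(genes_overlapping(idx, "chrT", 5000, 5100)), 0L)
})

test_that("splice types are classified per the documented precedence", {
  idx <- toy_index("+")
  cases <- list(
    list(a = 201, b = 320, type = "A3_loss", delta = -20L),
    list(a = 201, b = 280, type = "A3_gain", delta = 20L),
    list(a = 201, b = 500, type = "exon_skip", delta = -100L),
    list(a = 150, b = 180, type = "in_exon", delta = -31L),
    list(a = 230, b = 270, type = "in_intron", delta = 59L),
    list(a = 381, b = 500, type = "A5_loss", delta = -20L),
    list(a = 421, b = 500, type = "A5_gain", delta = 20L)
  )
  for (cs in cases) {
    call <- classify_splice_type(mk_jx(cs$a, cs$b), idx)
    expect_equal(call$splice_type, cs$type,
                 info = sprintf("junction (%d,%d)", cs$a, cs$b))
    expect_equal(call$nt_delta, cs$delta,
                 info = sprintf("junction (%d,%d)", cs$a, cs$b))
  }
  # outside any gene
  expect_equal(classify_splice_type(mk_jx(5000, 5100), idx)$splice_type, "other")
  # fully annotated junction is never promoted
  expect_equal(classify_splice_type(mk_jx(201, 300), idx)$splice_type, "other")
})

test_that("frame status follows nt_delta mod 3 within the CDS", {
  idx <- toy_index("+")
  expect_equal(classify_splice_type(mk_jx(201, 320), idx)$frame_status,
               "frameshift")  # -20
  expect_equal(classify_splice_type(mk_jx(201, 321), idx)$frame_status,
               "in_frame")    # -21
  # junction upstream of the CDS (5' UTR region of exon 1)
  utr <- classify_splice_type(mk_jx(110, 120), idx)
  expect_equal(utr$splice_type, "in_exon")
  expect_equal(utr$frame_status, "noncoding")
})

test_that("mirroring the gene to the minus strand swaps A3 and A5 and keeps nt_delta", {
  plus <- toy_index("+"); minus <- toy_index("-")
  pairs <- list(c(201, 320), c(201, 280), c(381, 500), c(421, 500))
  for (p in pairs) {
    cp <- classify_splice_type(mk_jx(p[1], p[2], "+"), plus)
    cm <- classify_splice_type(mk_jx(p[1], p[2], "-"), minus)
    swap <- c(A3_loss = "A5_loss", A5_loss = "A3_loss",
              A3_gain = "A5_gain", A5_gain = "A3_gain")
    expect_equal(cm$splice_type, unname(swap[cp$splice_type]))
    expect_equal(cm$nt_delta, cp$nt_delta)
  }
})

test_that("strand-unknown junctions inherit the unique overlapping gene's strand", {
  idx <- toy_index("-")
  call <- classify_splice_type(mk_jx(201, 320, "*"), idx)
  expect_equal(call$strand, "-")
  expect_equal(call$splice_type, "A5_loss")
})

test_that("canonical assignment prefers shared donor, then acceptor, then containment", {
  idx <- toy_index("+")
  # A3 loss shares the donor of intron (201,300)
  can <- assign_canonical(mk_jx(201, 320), "toyG+", idx)
  expect_equal(can$canonical_key, "chrT:201:300:+")
  expect_equal(can$shared_site, "donor")
  # A5 loss shares the acceptor only
  can2 <- assign_canonical(mk_jx(381, 500), "toyG+", idx)
  expect_equal(can2$canonical_key, "chrT:401:500:+")
  expect_equal(can2$shared_site, "acceptor")
  # in-intron junction: containing intron
  can3 <- assign_canonical(mk_jx(230, 270), "toyG+", idx)
  expect_equal(can3$canonical_key, "chrT:201:300:+")
  expect_equal(can3$shared_site, "none")
  # in-exon junction: no overlap, canonical absent
  can4 <- assign_canonical(mk_jx(150, 180), "toyG+", idx)
  expect_true(is.na(can4$canonical_key))
})

test_that("canonical ties resolve by highest tumour-cohort read count", {
  # second transcript creates two introns sharing the exon-skip donor
  tx1 <- toy_tx("+")
  tx2 <- transcript_model("toyT2", "toyG+", "chrT", "+",
                          exons = data.frame(start = c(101, 501), end = c(200, 600)),
                          cds_span = c(131, 570))
  idx <- build_annotation_index(list(tx1, tx2))
  counts <- c("chrT:201:300:+" = 900, "chrT:201:500:+" = 100)
  can <- assign_canonical(mk_jx(201, 480), "toyG+", idx, counts)
  expect_equal(can$canonical_key, "chrT:201:300:+")
  counts2 <- c("chrT:201:300:+" = 10, "chrT:201:500:+" = 500)
  can2 <- assign_canonical(mk_jx(201, 480), "toyG+", idx, counts2)
  expect_equal(can2$canonical_key, "chrT:201:500:+")
})

test_that("classification agrees with the per-base oracle on random junctions (both strands)", {
  ref <- small_reference(seed = 303, n_genes = 10)
  idx <- build_annotation_index(ref$transcripts)
  set.seed(17)
  n_checked <- 0
  for (rep in 1:10) {
    for (tx in ref$transcripts) {
      pj <- random_planted_junction(tx)
      call <- classify_splice_type(
        mk_jx(pj$intron_start, pj$intron_end, tx$strand, tx$chrom), idx)
      orc <- oracle_classify(tx, pj$intron_start, pj$intron_end)
      expect_equal(call$splice_type, orc$splice_type,
                   info = sprintf("%s %d-%d", tx$transcript_id,
                                  pj$intron_start, pj$intron_end))
      expect_equal(call$splice_type, pj$type)
      expect_equal(call$nt_delta, orc$nt_delta)
      expect_equal(call$frame_status, orc$frame_status)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 100)
})
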