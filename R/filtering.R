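# Cohort gates and neojunction calling.
#
# A junction is "expressed" in a sample when it clears three per-sample
# gates: at least `count_min` target spliced reads, at least `depth_min`
# total (target + canonical) spliced reads, and a spliced frequency
# target/(target+canonical) of at least `freq_min`. A junction's
# positive sample rate (PSR) is the fraction of gated cohort samples
# expressing it; public neojunctions have tumour PSR >= `psr_public_min`
# and cancer-specific ones have normal PSR < `psr_normal_max`.

#' Threshold configuration for neojunction calling
#'
#' Defaults: `count_min = 10` target reads, `depth_min = 20` total
#' reads, `freq_min = 0.01` spliced frequency (inclusive boundary by
#' default; set `freq_inclusive = FALSE` for a strict `>` comparison),
#' `psr_public_min = 0.10` (inclusive), `psr_normal_max = 0.01`
#' (exclusive), `purity_min = 0.60` (inclusive), `tpm_min = 10`.
#' A cohort-sum pre-filter (summed target reads >= `count_min` and
#' summed depth >= `depth_min` across the tumour cohort) is applied
#' before per-sample evaluation.
#'
#' @param count_min,depth_min,freq_min,psr_public_min,psr_normal_max,purity_min,tpm_min
#'   Numeric thresholds (see above).
#' @param freq_inclusive Logical; if `TRUE` (default) the frequency gate
#'   is `>= freq_min`, otherwise `> freq_min`.
#' @return List of class `threshold_config`.
#' @export
threshold_config <- function(count_min = 10, depth_min = 20, freq_min = 0.01,
                             psr_public_min = 0.10, psr_normal_max = 0.01,
                             purity_min = 0.60, tpm_min = 10,
                             freq_inclusive = TRUE) {
  stopifnot(count_min >= 0, depth_min >= 0,
            freq_min >= 0, freq_min <= 1,
            psr_public_min >= 0, psr_public_min <= 1,
            psr_normal_max >= 0, psr_normal_max <= 1,
            purity_min >= 0, purity_min <= 1, tpm_min >= 0)
  structure(as.list(environment()), class = "threshold_config")
}

#' Apply the sample purity gate
#'
#' Tumour samples with purity >= `purity_min` are retained; tumour
#' samples lacking a purity estimate are dropped with a warning; normal
#' samples are always retained.
#'
#' @param samples data.frame with `sample_id`, `cohort` (`"tumour"` /
#'   `"normal"`) and `purity` (fraction, `NA` allowed).
#' @param config A [threshold_config()].
#' @return The retained subset of `samples`.
#' @export
gate_samples <- function(samples, config = threshold_config()) {
  stopifnot(all(c("sample_id", "cohort", "purity") %in% names(samples)),
            all(samples$cohort %in% c("tumour", "normal")))
  tum <- samples$cohort == "tumour"
  no_purity <- tum & is.na(samples$purity)
  if (any(no_purity)) {
    warning(sum(no_purity), " tumour sample(s) dropped: purity unavailable")
  }
  keep <- !tum | (!is.na(samples$purity) & samples$purity >= config$purity_min)
  out <- samples[keep, , drop = FALSE]
  if (!any(out$cohort == "tumour")) {
    stop("no tumour samples pass the purity gate (purity_min = ",
         config$purity_min, ")")
  }
  rownames(out) <- NULL
  out
}

#' Apply the transcript expression gate
#'
#' Retains coding, non-mitochondrial transcripts whose median TPM is at
#' least `tpm_min` in at least one subtype. Median TPM per subtype is
#' computed from the expression matrix and attached to the returned
#' models (`median_tpm`).
#'
#' @param transcripts List of `transcript_model`s.
#' @param expression Numeric matrix, transcripts x samples (TPM),
#'   rownames = transcript ids.
#' @param subtypes Named character: subtype per sample id (matrix
#'   columns).
#' @param config A [threshold_config()].
#' @return Named list of retained `transcript_model`s with `median_tpm`
#'   filled in.
#' @export
gate_transcripts <- function(transcripts, expression, subtypes,
                             config = threshold_config()) {
  mito <- c("chrM", "MT", "M")
  subtypes <- subtypes[colnames(expression)]
  groups <- split(colnames(expression), subtypes)
  out <- list()
  for (tx in transcripts) {
    if (is.null(tx$cds_span) || tx$chrom %in% mito) next
    if (!tx$transcript_id %in% rownames(expression)) {
      warning("transcript absent from expression matrix, excluded: ",
              tx$transcript_id)
      next
    }
    med <- vapply(groups, function(cols) {
      median(expression[tx$transcript_id, cols])
    }, numeric(1))
    if (any(med >= config$tpm_min)) {
      tx$median_tpm <- med
      out[[tx$transcript_id]] <- tx
    }
  }
  out
}

#' Spliced frequency of a target junction
#'
#' target / (target + canonical), defined as 0 when both counts are 0.
#'
#' @param target_reads,canonical_reads Non-negative counts (vectorized).
#' @return Fraction in \[0, 1\].
#' @export
compute_frequency <- function(target_reads, canonical_reads) {
  if (any(target_reads < 0) || any(canonical_reads < 0)) {
    stop("read counts must be non-negative")
  }
  tot <- target_reads + canonical_reads
  ifelse(tot > 0, target_reads / tot, 0)
}

#' Per-sample expression decision for a junction
#'
#' @param target_reads,canonical_reads Counts for one junction in one
#'   sample (vectorized over samples).
#' @param config A [threshold_config()].
#' @return Logical: all of count, depth and frequency gates met.
#' @export
sample_expresses <- function(target_reads, canonical_reads,
                             config = threshold_config()) {
  freq <- compute_frequency(target_reads, canonical_reads)
  freq_ok <- if (config$freq_inclusive) freq >= config$freq_min
             else freq > config$freq_min
  target_reads >= config$count_min &
    (target_reads + canonical_reads) >= config$depth_min &
    freq_ok
}

#' Positive sample rate
#'
#' @param expressed Logical vector: one entry per gated cohort sample.
#' @return Fraction of samples expressing the junction.
#' @export
compute_psr <- function(expressed) {
  if (length(expressed) == 0) stop("empty cohort: PSR undefined")
  mean(expressed)
}

# coordinate-only key used to look up read counts (strand-unknown
# records must still match their stranded catalogue entry)
coord_key <- function(chrom, start, end) paste(chrom, start, end, sep = ":")

#' Build the candidate neojunction catalogue
#'
#' Collects junctions observed (unique reads > 0) in tumour samples that
#' are not annotated introns, assigns each its unique overlapping gene,
#' classifies splice type / frame status and assigns the canonical
#' partner. Junctions outside genes, in several genes, or in genes
#' without a gated coding transcript are excluded.
#'
#' @param junctions Long junction record data.frame (see
#'   [parse_junction_table()]) covering the tumour cohort at least.
#' @param index `annotation_index` over the full annotation.
#' @param samples Gated sample metadata ([gate_samples()] output).
#' @param gated_tx Optional character vector of transcript ids that
#'   passed [gate_transcripts()]; if given, junctions whose affected
#'   transcript is not in the set are dropped.
#' @return data.frame catalogue: key, chrom, intron_start, intron_end,
#'   strand, gene_id, transcript_id, splice_type, nt_delta,
#'   frame_status, canonical_key, shared_site.
#' @export
build_junction_catalogue <- function(junctions, index, samples,
                                     gated_tx = NULL) {
  tumour_ids <- samples$sample_id[samples$cohort == "tumour"]
  jt <- junctions[junctions$sample_id %in% tumour_ids &
                    junctions$unique_reads > 0, , drop = FALSE]
  jt <- jt[!duplicated(coord_key(jt$chrom, jt$intron_start, jt$intron_end)), ,
           drop = FALSE]
  # summed tumour-cohort reads per annotated junction (canonical tie-break)
  ann <- junctions[junctions$sample_id %in% tumour_ids, , drop = FALSE]
  cohort_counts <- tapply(ann$unique_reads,
                          jx_key(ann$chrom, ann$intron_start, ann$intron_end,
                                 ann$strand),
                          sum)

  rows <- vector("list", nrow(jt))
  for (i in seq_len(nrow(jt))) {
    j <- jt[i, ]
    if (is_annotated_junction(index, j$chrom, j$intron_start, j$intron_end,
                              j$strand)) next
    call <- classify_splice_type(j, index)
    if (is.na(call$gene_id)) next
    if (!is.null(gated_tx) &&
        (is.na(call$transcript_id) || !call$transcript_id %in% gated_tx)) next
    j$strand <- call$strand
    can <- assign_canonical(j, call$gene_id, index, cohort_counts)
    rows[[i]] <- data.frame(
      key = jx_key(j$chrom, j$intron_start, j$intron_end, call$strand),
      chrom = j$chrom, intron_start = j$intron_start,
      intron_end = j$intron_end, strand = call$strand,
      gene_id = call$gene_id, transcript_id = call$transcript_id,
      splice_type = call$splice_type, nt_delta = call$nt_delta,
      frame_status = call$frame_status,
      canonical_key = can$canonical_key, shared_site = can$shared_site,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(key = character(0), chrom = character(0),
                      intron_start = integer(0), intron_end = integer(0),
                      strand = character(0), gene_id = character(0),
                      transcript_id = character(0), splice_type = character(0),
                      nt_delta = integer(0), frame_status = character(0),
                      canonical_key = character(0), shared_site = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Call public and cancer-specific neojunctions
#'
#' For every catalogue junction, computes per-sample target/canonical
#' reads, spliced frequency and the expressed flag over the gated
#' tumour and normal cohorts, applies the cohort-sum pre-filter, and
#' derives tumour/normal PSRs and the public / cancer-specific flags.
#'
#' @param catalogue [build_junction_catalogue()] output.
#' @param junctions Long junction record data.frame covering all gated
#'   samples (tumour and normal).
#' @param samples Gated sample metadata; `cohort` selects the PSR
#'   denominators.
#' @param config A [threshold_config()].
#' @return List with `calls` (one row per retained junction: key, gene,
#'   splice type, frame status, canonical key, psr_tumour, psr_normal,
#'   public, cancer_specific; sorted by decreasing tumour PSR then key)
#'   and `observations` (long per-junction x per-sample table with
#'   target/canonical reads, frequency, expressed flag, cohort).
#' @export
call_neojunctions <- function(catalogue, junctions, samples,
                              config = threshold_config()) {
  tumour_ids <- samples$sample_id[samples$cohort == "tumour"]
  normal_ids <- samples$sample_id[samples$cohort == "normal"]
  if (length(tumour_ids) == 0) stop("empty tumour cohort")
  all_ids <- c(tumour_ids, normal_ids)
  jx <- junctions[junctions$sample_id %in% all_ids, , drop = FALSE]
  jx$ckey <- coord_key(jx$chrom, jx$intron_start, jx$intron_end)

  # reads[junction coord-key, sample]
  lookup <- new.env(parent = emptyenv())
  assign_reads <- function(ck, sid, reads) {
    k <- paste(ck, sid, sep = "\r")
    assign(k, reads, envir = lookup)
  }
  for (i in seq_len(nrow(jx))) {
    assign_reads(jx$ckey[i], jx$sample_id[i], jx$unique_reads[i])
  }
  get_reads <- function(ck, ids) {
    vapply(ids, function(sid) {
      k <- paste(ck, sid, sep = "\r")
      if (exists(k, envir = lookup, inherits = FALSE)) {
        get(k, envir = lookup)
      } else 0
    }, numeric(1))
  }

  obs_list <- list()
  call_rows <- list()
  for (i in seq_len(nrow(catalogue))) {
    cat_row <- catalogue[i, ]
    tgt_ck <- coord_key(cat_row$chrom, cat_row$intron_start, cat_row$intron_end)
    target <- get_reads(tgt_ck, all_ids)
    if (!is.na(cat_row$canonical_key)) {
      ck <- jx_unkey(cat_row$canonical_key)
      canonical <- get_reads(coord_key(ck$chrom, ck$start, ck$end), all_ids)
    } else {
      canonical <- rep(0, length(all_ids))
    }
    is_tum <- all_ids %in% tumour_ids
    # cohort-sum pre-filter over the tumour cohort
    if (sum(target[is_tum]) < config$count_min ||
        sum(target[is_tum] + canonical[is_tum]) < config$depth_min) next

    freq <- compute_frequency(target, canonical)
    expressed <- sample_expresses(target, canonical, config)
    psr_t <- compute_psr(expressed[is_tum])
    psr_n <- if (any(!is_tum)) compute_psr(expressed[!is_tum]) else 0

    obs_list[[cat_row$key]] <- data.frame(
      key = cat_row$key, sample_id = all_ids,
      cohort = ifelse(is_tum, "tumour", "normal"),
      target_reads = target, canonical_reads = canonical,
      frequency = freq, expressed = expressed,
      stringsAsFactors = FALSE, row.names = NULL
    )
    call_rows[[cat_row$key]] <- data.frame(
      cat_row[, c("key", "gene_id", "transcript_id", "splice_type",
                  "nt_delta", "frame_status", "canonical_key", "shared_site")],
      psr_tumour = psr_t, psr_normal = psr_n,
      public = psr_t >= config$psr_public_min,
      cancer_specific = psr_n < config$psr_normal_max,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  calls <- do.call(rbind, call_rows)
  if (is.null(calls)) {
    calls <- data.frame(key = character(0), gene_id = character(0),
                        transcript_id = character(0), splice_type = character(0),
                        nt_delta = integer(0), frame_status = character(0),
                        canonical_key = character(0), shared_site = character(0),
                        psr_tumour = numeric(0), psr_normal = numeric(0),
                        public = logical(0), cancer_specific = logical(0))
  }
  calls <- calls[order(-calls$psr_tumour, calls$key), , drop = FALSE]
  rownames(calls) <- NULL
  obs <- do.call(rbind, obs_list)
  rownames(obs) <- NULL
  list(calls = calls, observations = obs)
}

#' End-to-end neojunction discovery
#'
#' Runs the full discovery pipeline: sample purity gating, transcript
#' expression gating, catalogue construction and neojunction calling.
#'
#' @param junctions Long junction record data.frame (all samples) or a
#'   directory of `SJ.out.tab` tables.
#' @param annotation `annotation_index`, list of `transcript_model`s, or
#'   a GTF path.
#' @param samples Sample metadata data.frame (`sample_id`, `cohort`,
#'   `purity`, `subtype`, optional `case_id`/`region_id`). Multi-region
#'   samples (non-empty `region_id`) are excluded from the PSR cohorts.
#' @param expression Optional TPM matrix for transcript gating (skipped
#'   with all coding transcripts retained if `NULL`).
#' @param config A [threshold_config()].
#' @return List: `calls`, `observations`, `catalogue`, `samples`
#'   (gated), `index`.
#' @export
discover_neojunctions <- function(junctions, annotation, samples,
                                  expression = NULL,
                                  config = threshold_config()) {
  if (is.character(junctions)) junctions <- read_junction_dir(junctions)
  index <- if (inherits(annotation, "annotation_index")) annotation
    else if (is.character(annotation)) build_annotation_index(read_annotation_gtf(annotation))
    else build_annotation_index(annotation)
  if (!is.null(samples$region_id)) {
    bulk <- is.na(samples$region_id) | samples$region_id == ""
    samples <- samples[bulk, , drop = FALSE]
  }
  gated <- gate_samples(samples, config)
  gated_tx <- NULL
  if (!is.null(expression)) {
    subtypes <- setNames(gated$subtype, gated$sample_id)
    expr <- expression[, colnames(expression) %in% gated$sample_id, drop = FALSE]
    kept <- gate_transcripts(index$transcripts, expr, subtypes, config)
    gated_tx <- names(kept)
    for (id in gated_tx) index$transcripts[[id]]$median_tpm <- kept[[id]]$median_tpm
  }
  catalogue <- build_junction_catalogue(junctions, index, gated, gated_tx)
  res <- call_neojunctions(catalogue, junctions, gated, config)
  c(res, list(catalogue = catalogue, samples = gated, index = index))
}

#' Write neojunction calls and the per-sample frequency matrix
#'
#' @param result [call_neojunctions()] / [discover_neojunctions()] output.
#' @param dir Output directory (created if needed).
#' @return Paths of the written TSVs, invisibly.
#' @export
write_neojunction_calls <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  calls_path <- file.path(dir, "neojunction_calls.tsv")
  write.table(result$calls, calls_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  freq_path <- file.path(dir, "frequency_matrix.tsv")
  obs <- result$observations
  if (!is.null(obs) && nrow(obs) > 0) {
    m <- tapply(obs$frequency, list(obs$key, obs$sample_id), `[`, 1L)
    write.table(data.frame(key = rownames(m), m, check.names = FALSE),
                freq_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(calls_path, freq_path))
}
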