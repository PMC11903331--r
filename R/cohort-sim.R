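# Planting neojunctions into synthetic cohorts with machine-readable
# ground truth.
#
# Read model: every annotated intron receives Poisson(read_depth_scale)
# unique reads per sample. A planted junction's reads in a designated
# expressing sample are chosen to hit the target spliced frequency in
# expectation given that sample's canonical reads, then clamped so the
# per-sample count (>= 10), depth (>= 20) and frequency gates are met
# unambiguously; non-designated samples carry no planted reads. This
# separates threshold logic from sampling noise: the emitted truth table
# is exact, not approximate. Expressing tumour samples are a seeded
# shuffled prefix of the purity-gated tumour cohort of size
# ceiling(PSR x n_gated), so target PSRs are hit exactly.

#' Genomic coordinates for a planted neojunction
#'
#' Maps a splice-type / nt_delta specification onto the gene's middle
#' intron (or a middle exon) with strand-aware donor/acceptor
#' orientation. Returns 1-based inclusive intron coordinates of the
#' novel junction plus the realized signed nucleotide change.
#'
#' @param tx `transcript_model` of the target gene (4 exons assumed for
#'   exon skips; at least 2 otherwise).
#' @param splice_type,nt_delta See [plant_spec()].
#' @return List: `intron_start`, `intron_end`, `nt_delta`.
#' @export
plant_junction_coords <- function(tx, splice_type, nt_delta = NULL) {
  ir <- transcript_introns(tx)
  if (nrow(ir) < 2) stop("gene must have at least 2 introns for planting")
  k <- 2L
  s <- ir$start[k]; e <- ir$end[k]
  strand <- tx$strand
  d <- if (!is.null(nt_delta)) abs(nt_delta) else NA_integer_
  coords <- switch(splice_type,
    A3_loss = if (strand == "+") c(s, e + d) else c(s - d, e),
    A3_gain = if (strand == "+") c(s, e - d) else c(s + d, e),
    A5_loss = if (strand == "+") c(s - d, e) else c(s, e + d),
    A5_gain = if (strand == "+") c(s + d, e) else c(s, e - d),
    exon_skip = {
      ex <- tx$exons
      d <- ex$end[2] - ex$start[2] + 1L
      c(ir$start[1], ir$end[2])
    },
    in_exon = {
      ex <- tx$exons
      a <- ex$start[3] + 8L
      c(a, a + d - 1L)
    },
    in_intron = {
      left <- max(1L, d %/% 2L)
      right <- d - left
      if (right < 1L) { left <- d - 1L; right <- 1L }
      c(s + left, e - right)
    },
    stop("unknown splice type: ", splice_type)
  )
  signed <- switch(splice_type,
    A3_loss = , A5_loss = , exon_skip = , in_exon = -d,
    A3_gain = , A5_gain = , in_intron = d
  )
  list(intron_start = as.integer(coords[1]), intron_end = as.integer(coords[2]),
       nt_delta = as.integer(signed))
}

expected_tier <- function(n_expressing, n_regions) {
  f <- n_expressing / n_regions
  if (n_expressing == 0) "absent"
  else if (f == 1) "tumour_wide"
  else if (f > 0.7) "highly"
  else if (f > 0.3) "moderately"
  else "weakly"
}

#' Plant neojunctions and emit a full synthetic cohort
#'
#' Generates per-sample junction tables (STAR `SJ.out.tab` dialect) for
#' the bulk tumour cohort, the normal cohort and the multi-region
#' cases, together with sample metadata, a transcript TPM matrix and a
#' truth table describing every planted junction (splice type, frame
#' status, expressing samples/regions, expected public /
#' cancer-specific flags and conservation tiers).
#'
#' @param config A [sim_config()].
#' @param reference A [generate_reference()] output for the same config.
#' @param outdir Optional directory; when given, junction tables
#'   (`junctions/<sample>.SJ.out.tab`), `metadata.tsv`,
#'   `expression.tsv` and `truth.json` are written there.
#' @param thresholds [threshold_config()] used for the purity gate and
#'   the read clamps (defaults match the pipeline defaults).
#' @return List of class `nj_cohort`: `junctions` (long record
#'   data.frame), `samples` (metadata), `expression` (TPM matrix),
#'   `truth` (list per planted junction), `paths` (if written).
#' @export
plant_and_emit_cohort <- function(config, reference, outdir = NULL,
                                  thresholds = threshold_config()) {
  stopifnot(inherits(config, "sim_config"), inherits(reference, "nj_reference"))
  specs <- config$planted_junctions %||% default_plant_specs(config)
  index <- build_annotation_index(reference$transcripts)
  gene_ids <- vapply(specs, `[[`, "", "gene_id")
  missing <- setdiff(gene_ids, index$genes$gene_id)
  if (length(missing)) stop("plant spec references unknown gene(s): ",
                            paste(missing, collapse = ", "))

  with_seed(child_seed(config$seed, 2L), {
    tumour_ids <- sprintf("T%02d", seq_len(config$n_tumour_samples))
    normal_ids <- sprintf("N%02d", seq_len(config$n_normal_samples))
    case_ids <- sprintf("C%02d", seq_len(config$n_cases))
    region_tab <- expand.grid(region = seq_len(config$regions_per_case),
                              case = case_ids, stringsAsFactors = FALSE)
    region_ids <- sprintf("%s_R%02d", region_tab$case, region_tab$region)

    purity <- function(n) pmin(1, pmax(0, rnorm(n, config$purity_mean,
                                                config$purity_sd)))
    samples <- rbind(
      data.frame(sample_id = tumour_ids, cohort = "tumour",
                 purity = purity(length(tumour_ids)),
                 subtype = rep_len(c("A", "B"), length(tumour_ids)),
                 case_id = "", region_id = "", stringsAsFactors = FALSE),
      data.frame(sample_id = normal_ids, cohort = "normal", purity = NA_real_,
                 subtype = "normal", case_id = "", region_id = "",
                 stringsAsFactors = FALSE),
      data.frame(sample_id = region_ids, cohort = "tumour",
                 purity = purity(length(region_ids)),
                 subtype = rep(rep_len(c("A", "B"), config$n_cases),
                               each = config$regions_per_case),
                 case_id = region_tab$case,
                 region_id = sprintf("R%02d", region_tab$region),
                 stringsAsFactors = FALSE)
    )
    gated_tumour <- tumour_ids[samples$purity[match(tumour_ids, samples$sample_id)] >=
                                 thresholds$purity_min]
    if (length(gated_tumour) == 0) stop("no tumour sample passes the purity gate; ",
                                        "raise purity_mean")

    all_ids <- samples$sample_id
    introns <- index$introns[!duplicated(index$introns$key), , drop = FALSE]
    introns <- introns[order(introns$key), , drop = FALSE]
    n_intron <- nrow(introns)
    # canonical reads: intron x sample Poisson draws
    reads <- matrix(rpois(n_intron * length(all_ids), config$read_depth_scale),
                    nrow = n_intron,
                    dimnames = list(introns$key, all_ids))

    # resolve planted coordinates and canonical partners
    planted <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      tx <- representative_transcript(index, sp$gene_id)
      pc <- plant_junction_coords(tx, sp$splice_type, sp$nt_delta)
      key <- jx_key(tx$chrom, pc$intron_start, pc$intron_end, tx$strand)
      if (key %in% index$intron_keys) {
        stop("planted junction coincides with an annotated intron: ", key)
      }
      can <- assign_canonical(
        list(chrom = tx$chrom, intron_start = pc$intron_start,
             intron_end = pc$intron_end, strand = tx$strand),
        sp$gene_id, index
      )
      in_cds <- pc$intron_end >= tx$cds_span[1] && pc$intron_start <= tx$cds_span[2]
      frame <- if (!in_cds) "noncoding"
        else if (abs(pc$nt_delta) %% 3L == 0L) "in_frame" else "frameshift"

      n_expr <- ceiling(sp$target_tumour_psr * length(gated_tumour))
      expr_tumour <- if (n_expr > 0) sort(sample(gated_tumour)[seq_len(n_expr)])
                     else character(0)
      leak <- rbinom(length(normal_ids), 1L, config$normal_leak_rate) == 1L
      expr_normal <- normal_ids[leak]
      regions_by_case <- lapply(setNames(case_ids, case_ids), function(cid) {
        r_ids <- region_ids[region_tab$case == cid]
        m <- ceiling(sp$clonality * length(r_ids))
        sort(sample(r_ids)[seq_len(m)])
      })
      planted[[i]] <- list(
        key = key, gene_id = sp$gene_id, transcript_id = tx$transcript_id,
        chrom = tx$chrom, intron_start = pc$intron_start,
        intron_end = pc$intron_end, strand = tx$strand,
        splice_type = sp$splice_type, nt_delta = pc$nt_delta,
        frame_status = frame, canonical_key = can$canonical_key,
        target_frequency = sp$target_frequency,
        expressing_tumour_samples = expr_tumour,
        expressing_normal_samples = expr_normal,
        regions_by_case = regions_by_case,
        psr_tumour = n_expr / length(gated_tumour),
        psr_normal = length(expr_normal) / length(normal_ids),
        public = n_expr / length(gated_tumour) >= thresholds$psr_public_min,
        cancer_specific = length(expr_normal) / length(normal_ids) <
          thresholds$psr_normal_max,
        tier_by_case = lapply(regions_by_case, function(r) {
          expected_tier(length(r), config$regions_per_case)
        })
      )
    }
    if (anyDuplicated(vapply(planted, `[[`, "", "key"))) {
      stop("planted junctions collide; use distinct genes per spec")
    }

    planted_reads <- function(f, canonical) {
      t <- round(f * canonical / (1 - f))
      t <- max(t, thresholds$count_min)
      if (t + canonical < thresholds$depth_min) t <- thresholds$depth_min - canonical
      as.integer(max(t, thresholds$count_min))
    }

    jx_rows <- list()
    for (sid in all_ids) {
      ann <- data.frame(
        chrom = introns$chrom, intron_start = introns$start,
        intron_end = introns$end, strand = introns$strand,
        motif = ifelse(introns$strand == "+", 1L, 2L), annotated = 1L,
        unique_reads = reads[, sid], multi_reads = 0L, max_overhang = 50L,
        sample_id = sid, stringsAsFactors = FALSE
      )
      extra <- list()
      for (p in planted) {
        expressing <- sid %in% p$expressing_tumour_samples ||
          sid %in% p$expressing_normal_samples ||
          sid %in% unlist(p$regions_by_case, use.names = FALSE)
        if (!expressing) next
        canon <- if (!is.na(p$canonical_key)) reads[p$canonical_key, sid] else 0L
        extra[[p$key]] <- data.frame(
          chrom = p$chrom, intron_start = p$intron_start,
          intron_end = p$intron_end, strand = p$strand,
          motif = ifelse(p$strand == "+", 1L, 2L), annotated = 0L,
          unique_reads = planted_reads(p$target_frequency, canon),
          multi_reads = 0L, max_overhang = 50L, sample_id = sid,
          stringsAsFactors = FALSE
        )
      }
      tab <- rbind(ann, do.call(rbind, extra))
      tab <- tab[order(tab$chrom, tab$intron_start, tab$intron_end), , drop = FALSE]
      rownames(tab) <- NULL
      jx_rows[[sid]] <- tab
    }
    junctions <- do.call(rbind, jx_rows)
    junctions$key <- jx_key(junctions$chrom, junctions$intron_start,
                            junctions$intron_end, junctions$strand)
    rownames(junctions) <- NULL

    tx_ids <- names(reference$transcripts)
    expression <- matrix(20 + stats::rgamma(length(tx_ids) * length(all_ids),
                                            shape = 2, scale = 15),
                         nrow = length(tx_ids),
                         dimnames = list(tx_ids, all_ids))

    names(planted) <- vapply(planted, `[[`, "", "key")
    out <- structure(list(junctions = junctions, samples = samples,
                          expression = expression, truth = planted,
                          paths = NULL),
                     class = "nj_cohort")
    if (!is.null(outdir)) out$paths <- write_cohort(out, outdir)
    out
  })
}

#' Write a synthetic cohort to disk
#'
#' @param cohort [plant_and_emit_cohort()] output.
#' @param outdir Output directory.
#' @return Named list of paths, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  jdir <- file.path(outdir, "junctions")
  dir.create(jdir, showWarnings = FALSE, recursive = TRUE)
  for (sid in unique(cohort$junctions$sample_id)) {
    write_junction_table(
      cohort$junctions[cohort$junctions$sample_id == sid, , drop = FALSE],
      file.path(jdir, paste0(sid, ".SJ.out.tab"))
    )
  }
  meta_path <- file.path(outdir, "metadata.tsv")
  write.table(cohort$samples, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expr_path <- file.path(outdir, "expression.tsv")
  write.table(data.frame(transcript_id = rownames(cohort$expression),
                         cohort$expression, check.names = FALSE),
              expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(cohort$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(junctions = jdir, metadata = meta_path,
                 expression = expr_path, truth = truth_path))
}
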