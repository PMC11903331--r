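# Seeded synthetic reference: multi-exon protein-coding genes on a
# random genome, with matching annotation and proteome. Exon boundaries
# are placed at codon boundaries of the CDS (a deliberate
# simplification: it makes in-frame splice losses remove whole codons,
# so worked examples are directly interpretable). GT..AG motifs are
# written at intron boundaries for realism but are not validated
# downstream.

#' Simulation configuration
#'
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @param n_genes Number of protein-coding genes to generate.
#' @param n_tumour_samples,n_normal_samples Bulk cohort sizes.
#' @param n_cases Number of multi-region tumour cases.
#' @param regions_per_case Intratumoural regions sampled per case.
#' @param planted_junctions List of [plant_spec()]s; `NULL` uses
#'   [default_plant_specs()] (one planted neojunction per gene, cycling
#'   splice types, PSRs and clonality).
#' @param purity_mean,purity_sd Tumour purity distribution (fractions).
#' @param normal_leak_rate Probability that a normal sample expresses a
#'   planted neojunction.
#' @param read_depth_scale Mean unique reads per annotated junction per
#'   sample (Poisson).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 30L, n_tumour_samples = 20L,
                       n_normal_samples = 50L, n_cases = 6L,
                       regions_per_case = 10L, planted_junctions = NULL,
                       purity_mean = 0.75, purity_sd = 0.08,
                       normal_leak_rate = 0.04, read_depth_scale = 100) {
  stopifnot(n_genes >= 1, n_tumour_samples >= 1, n_normal_samples >= 1,
            n_cases >= 1, regions_per_case >= 1,
            purity_mean >= 0, purity_mean <= 1, purity_sd >= 0,
            normal_leak_rate >= 0, normal_leak_rate <= 1,
            read_depth_scale > 0)
  if (n_genes == 0) stop("n_genes must be at least 1")
  structure(as.list(environment()), class = "sim_config")
}

#' Specification of one planted neojunction
#'
#' @param gene_id Gene to plant into.
#' @param splice_type One of `A3_loss`, `A3_gain`, `A5_loss`, `A5_gain`,
#'   `exon_skip`, `in_exon`, `in_intron`.
#' @param nt_delta Signed nucleotide change (losses negative, gains
#'   positive). For `exon_skip` the value is derived from the skipped
#'   exon length at planting time and may be `NULL` here.
#' @param target_tumour_psr Fraction of gated tumour samples that will
#'   express the junction.
#' @param target_frequency Spliced frequency aimed for in each
#'   expressing sample.
#' @param clonality 1 for tumour-wide; a fraction in (0, 1) for a
#'   subclonal event expressed in that fraction of each case's regions.
#' @return List of class `plant_spec`.
#' @export
plant_spec <- function(gene_id, splice_type, nt_delta = NULL,
                       target_tumour_psr = 0.5, target_frequency = 0.1,
                       clonality = 1) {
  types <- c("A3_loss", "A3_gain", "A5_loss", "A5_gain",
             "exon_skip", "in_exon", "in_intron")
  splice_type <- match.arg(splice_type, types)
  stopifnot(target_tumour_psr >= 0, target_tumour_psr <= 1,
            target_frequency > 0, target_frequency < 1,
            clonality > 0, clonality <= 1)
  if (!is.null(nt_delta)) {
    neg <- c("A3_loss", "A5_loss", "exon_skip", "in_exon")
    pos <- c("A3_gain", "A5_gain", "in_intron")
    if (splice_type %in% neg && nt_delta >= 0) {
      stop("nt_delta must be negative for ", splice_type)
    }
    if (splice_type %in% pos && nt_delta <= 0) {
      stop("nt_delta must be positive for ", splice_type)
    }
    if (splice_type == "in_intron" && nt_delta < 2) {
      stop("in_intron requires nt_delta >= 2 (retained bases on both sides)")
    }
  } else if (splice_type != "exon_skip") {
    stop("nt_delta is required except for exon_skip")
  }
  structure(list(gene_id = gene_id, splice_type = splice_type,
                 nt_delta = nt_delta, target_tumour_psr = target_tumour_psr,
                 target_frequency = target_frequency, clonality = clonality),
            class = "plant_spec")
}

#' Default planted neojunctions: one per gene
#'
#' Cycles the seven splice types, in-frame and frameshift nucleotide
#' deltas, tumour PSRs well away from the 10% public threshold (0.05 or
#' 0.2-0.9), per-sample frequencies of 0.05-0.3, and tumour-wide vs
#' subclonal clonality.
#'
#' @param config A [sim_config()].
#' @return List of [plant_spec()]s.
#' @export
default_plant_specs <- function(config) {
  types <- c("A3_loss", "A3_gain", "A5_loss", "A5_gain",
             "exon_skip", "in_exon", "in_intron")
  deltas <- list(A3_loss = c(-6L, -5L), A3_gain = c(9L, 7L),
                 A5_loss = c(-9L, -4L), A5_gain = c(6L, 8L),
                 exon_skip = list(NULL, NULL), in_exon = c(-12L, -7L),
                 in_intron = c(6L, 11L))
  psrs <- c(0.05, 0.2, 0.3, 0.5, 0.75, 0.9)
  freqs <- c(0.05, 0.1, 0.2, 0.3)
  clon <- c(1, 1, 0.5, 0.3, 1, 0.6)
  lapply(seq_len(config$n_genes), function(i) {
    ty <- types[(i - 1L) %% length(types) + 1L]
    dd <- deltas[[ty]][[(i - 1L) %/% length(types) %% 2 + 1L]]
    plant_spec(
      gene_id = sprintf("G%03d", i), splice_type = ty,
      nt_delta = if (is.null(dd) || ty == "exon_skip") NULL else dd,
      target_tumour_psr = psrs[(i - 1L) %% length(psrs) + 1L],
      target_frequency = freqs[(i - 1L) %% length(freqs) + 1L],
      clonality = clon[(i - 1L) %% length(clon) + 1L]
    )
  })
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

reverse_translate <- function(protein) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(x) {
    opts <- by_aa[[x]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

#' Generate a synthetic reference (annotation, genome, proteome)
#'
#' Each gene has 4 exons / 3 introns, a CDS beginning with ATG and
#' ending at a stop codon, 5'/3' UTRs, and a strand drawn at random.
#' The proteome contains the translation of every CDS. All coordinates
#' are 1-based inclusive on a single synthetic chromosome.
#'
#' @param config A [sim_config()].
#' @return List of class `nj_reference`: `transcripts` (list of
#'   [transcript_model()]s), `genome` (`DNAStringSet`), `proteome`
#'   (`AAStringSet`), `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 1L), {
    segs <- character(0)
    cursor <- 1L
    transcripts <- list()
    proteins <- character(0)
    for (i in seq_len(config$n_genes)) {
      gene_id <- sprintf("G%03d", i)
      tx_id <- sprintf("T%03d", i)
      strand <- sample(c("+", "-"), 1L)
      prot_len <- sample(90:150, 1L)
      protein <- paste0("M", paste(sample(AA20, prot_len - 1L, replace = TRUE),
                                   collapse = ""))
      cds <- paste0(reverse_translate(protein),
                    sample(c("TAA", "TAG", "TGA"), 1L))
      cds_len <- nchar(cds)
      u5 <- random_dna(sample(30:60, 1L))
      u3 <- random_dna(sample(30:60, 1L))
      mrna <- paste0(u5, cds, u3)
      n5 <- nchar(u5)
      # exon cut points, snapped to codon boundaries of the CDS
      hi <- (cds_len - 39L) %/% 3L * 3L
      raw <- 39L + round((1:3) * (cds_len - 80) / 4) + sample(-9:9, 3L)
      cuts <- sort(pmin(hi, pmax(39L, round(raw / 3) * 3L)))
      if (any(diff(cuts) < 40L)) {
        cuts <- round((1:3) * (cds_len - 80) / 4 / 3) * 3L
      }
      cuts <- n5 + cuts
      tx_bounds <- c(0L, cuts, nchar(mrna))
      intron_len <- sample(150:400, 3L)
      introns_seq <- vapply(intron_len, function(L) {
        paste0("GT", random_dna(L - 4L), "AG")
      }, character(1))
      pre <- paste0(
        substr(mrna, tx_bounds[1] + 1L, tx_bounds[2]), introns_seq[1],
        substr(mrna, tx_bounds[2] + 1L, tx_bounds[3]), introns_seq[2],
        substr(mrna, tx_bounds[3] + 1L, tx_bounds[4]), introns_seq[3],
        substr(mrna, tx_bounds[4] + 1L, tx_bounds[5])
      )
      pre_len <- nchar(pre)
      # pre-mRNA coordinates of exons
      ex_tx <- data.frame(tx_start = tx_bounds[1:4] + 1L, tx_end = tx_bounds[2:5])
      offs <- c(0L, cumsum(intron_len))
      ex_pre <- data.frame(start = ex_tx$tx_start + offs,
                           end = ex_tx$tx_end + offs)
      map_pre <- function(txpos) {
        k <- findInterval(txpos, ex_tx$tx_start)
        txpos + offs[k]
      }
      cds_pre <- map_pre(c(n5 + 1L, n5 + cds_len))
      if (strand == "+") {
        g_ex <- data.frame(start = cursor + ex_pre$start - 1L,
                           end = cursor + ex_pre$end - 1L)
        g_cds <- cursor + cds_pre - 1L
        segs <- c(segs, pre)
      } else {
        g_ex <- data.frame(start = cursor + pre_len - ex_pre$end,
                           end = cursor + pre_len - ex_pre$start)
        g_ex <- g_ex[order(g_ex$start), ]
        g_cds <- sort(cursor + pre_len - cds_pre)
        segs <- c(segs, as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(pre))))
      }
      transcripts[[tx_id]] <- transcript_model(
        transcript_id = tx_id, gene_id = gene_id, chrom = "chr1",
        strand = strand, exons = g_ex, cds_span = g_cds
      )
      proteins[tx_id] <- protein
      gap <- sample(400:600, 1L)
      segs <- c(segs, random_dna(gap))
      cursor <- cursor + pre_len + gap
    }
    genome <- Biostrings::DNAStringSet(setNames(paste(segs, collapse = ""), "chr1"))
    proteome <- Biostrings::AAStringSet(proteins)
    structure(list(transcripts = transcripts, genome = genome,
                   proteome = proteome, config = config),
              class = "nj_reference")
  })
}

#' Write a synthetic reference to disk
#'
#' Emits `annotation.gtf`, `genome.fa` and `proteome.fa`.
#'
#' @param reference [generate_reference()] output.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gtf <- file.path(dir, "annotation.gtf")
  genome <- file.path(dir, "genome.fa")
  proteome <- file.path(dir, "proteome.fa")
  write_annotation_gtf(reference$transcripts, gtf)
  Biostrings::writeXStringSet(reference$genome, genome)
  Biostrings::writeXStringSet(reference$proteome, proteome)
  invisible(c(gtf = gtf, genome = genome, proteome = proteome))
}
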