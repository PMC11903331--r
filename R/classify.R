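# Splice-type classification of non-annotated junctions and canonical
# partner assignment.
#
# Categories follow the usual alternative-splicing taxonomy: A3/A5 loss
# (exonic loss at the 3' acceptor / 5' donor splice site, nt_delta < 0),
# A3/A5 gain (intronic gain at the acceptor/donor, nt_delta > 0), exon
# skip, junction-in-exon, junction-in-intron, and `other`. 5'/3' are
# oriented by transcription strand: the donor (5') end of an intron is
# its genomic-left end on "+" and genomic-right end on "-".

#' Classify a non-annotated splice junction
#'
#' Classification precedence: (1) both splice sites annotated and at
#' least one full exon strictly inside the junction: exon skip; (2)
#' exactly one site annotated: A3/A5 gain or loss according to which
#' side deviates from the matched annotated intron and whether the
#' deviant end lies in an exon (loss) or inside the intron (gain); (3)
#' both ends inside one exon: in-exon; (4) both ends strictly inside one
#' intron: in-intron; (5) anything else (including junctions outside
#' all genes, overlapping several genes, or fully annotated): `other`.
#'
#' `nt_delta` is the signed nucleotide change in the mature transcript:
#' exonic nucleotides removed are negative, intronic nucleotides gained
#' positive, exon skips the negative sum of skipped exon lengths.
#'
#' `frame_status` is `in_frame` iff `|nt_delta|` is a multiple of 3 and
#' the junction overlaps the CDS; `frameshift` iff not a multiple of 3
#' and within the CDS; `noncoding` otherwise.
#'
#' @param junction List or one-row data.frame with `chrom`,
#'   `intron_start`, `intron_end`, `strand` (`"*"` allowed: the strand
#'   of the unique overlapping gene is inherited).
#' @param index An [build_annotation_index()] result.
#' @return List of class `splice_type_call`: `splice_type`, `nt_delta`,
#'   `frame_status`, `gene_id`, `transcript_id`, `strand`.
#' @export
classify_splice_type <- function(junction, index) {
  a <- as.integer(junction$intron_start)
  b <- as.integer(junction$intron_end)
  chrom <- junction$chrom
  strand <- junction$strand %||% "*"

  other <- function(gene = NA_character_) {
    structure(list(splice_type = "other", nt_delta = NA_integer_,
                   frame_status = "noncoding", gene_id = gene,
                   transcript_id = NA_character_, strand = strand),
              class = "splice_type_call")
  }

  cand <- genes_overlapping(index, chrom, a, b, strand = "*")
  if (strand %in% c("+", "-")) {
    gs <- index$genes
    cand <- cand[gs$strand[match(cand, gs$gene_id)] == strand]
  }
  if (length(cand) != 1L) return(other())
  gene_id <- cand
  gstrand <- index$genes$strand[match(gene_id, index$genes$gene_id)]
  if (strand == "*") strand <- gstrand

  tx <- representative_transcript(index, gene_id)
  if (is.null(tx)) {
    txs <- Filter(function(t) t$gene_id == gene_id, index$transcripts)
    tx <- txs[[1]]
  }
  ex <- tx$exons
  ir <- transcript_introns(tx)
  if (nrow(ir) > 0 && any(ir$start == a & ir$end == b)) return(other(gene_id))

  exonic_overlap <- function(lo, hi) {
    if (hi < lo) return(0L)
    sum(pmax(0L, pmin(ex$end, hi) - pmax(ex$start, lo) + 1L))
  }
  in_exon_at <- function(p) any(ex$start <= p & ex$end >= p)

  left_annot <- nrow(ir) > 0 && a %in% ir$start
  right_annot <- nrow(ir) > 0 && b %in% ir$end
  # which transcript end each genomic side corresponds to
  left_label <- if (strand == "+") "A5" else "A3"
  right_label <- if (strand == "+") "A3" else "A5"

  splice_type <- NULL
  nt_delta <- NA_integer_

  if (left_annot && right_annot) {
    skipped <- ex$start > a & ex$end < b
    if (any(skipped)) {
      splice_type <- "exon_skip"
      nt_delta <- -sum(ex$end[skipped] - ex$start[skipped] + 1L)
    } else {
      return(other(gene_id))
    }
  } else if (xor(left_annot, right_annot)) {
    if (left_annot) {
      k <- which(ir$start == a)[1]
      e_k <- ir$end[k]
      if (b > e_k) {
        if (!in_exon_at(b)) return(other(gene_id))
        splice_type <- paste0(right_label, "_loss")
        nt_delta <- -exonic_overlap(e_k + 1L, b)
      } else {
        splice_type <- paste0(right_label, "_gain")
        nt_delta <- e_k - b
      }
    } else {
      k <- which(ir$end == b)[1]
      s_k <- ir$start[k]
      if (a < s_k) {
        if (!in_exon_at(a)) return(other(gene_id))
        splice_type <- paste0(left_label, "_loss")
        nt_delta <- -exonic_overlap(a, s_k - 1L)
      } else {
        splice_type <- paste0(left_label, "_gain")
        nt_delta <- a - s_k
      }
    }
  } else {
    same_exon <- any(ex$start <= a & ex$end >= b)
    same_intron <- nrow(ir) > 0 && any(ir$start <= a & ir$end >= b)
    if (same_exon) {
      splice_type <- "in_exon"
      nt_delta <- -(b - a + 1L)
    } else if (same_intron) {
      k <- which(ir$start <= a & ir$end >= b)[1]
      splice_type <- "in_intron"
      nt_delta <- (a - ir$start[k]) + (ir$end[k] - b)
    } else {
      return(other(gene_id))
    }
  }

  coding <- !is.null(tx$cds_span)
  in_cds <- coding && b >= tx$cds_span[1] && a <= tx$cds_span[2]
  frame_status <- if (!in_cds) "noncoding"
    else if (abs(nt_delta) %% 3L == 0L) "in_frame" else "frameshift"

  structure(list(splice_type = splice_type, nt_delta = as.integer(nt_delta),
                 frame_status = frame_status, gene_id = gene_id,
                 transcript_id = tx$transcript_id, strand = strand),
            class = "splice_type_call")
}

#' Assign the canonical (annotated) partner junction
#'
#' The canonical junction is the annotated intron of the same gene that
#' shares the neojunction's donor splice site; failing that, its
#' acceptor site; if several share a site, the one with the highest
#' summed read count across the tumour cohort (ties broken by shortest
#' intron, then key order). When neither site is shared (in-exon /
#' in-intron junctions) the annotated intron fully containing the
#' junction is used, else the one with the largest overlap, else the
#' canonical partner is absent.
#'
#' @param junction List with `chrom`, `intron_start`, `intron_end`,
#'   `strand` (must be `"+"` or `"-"`).
#' @param gene_id Gene the junction was assigned to.
#' @param index An `annotation_index`.
#' @param cohort_counts Optional named numeric: summed tumour-cohort
#'   unique reads per annotated junction key.
#' @return List of class `canonical_assignment`: `canonical_key`
#'   (or `NA`), `shared_site` (`"donor"`, `"acceptor"`, `"none"`).
#' @export
assign_canonical <- function(junction, gene_id, index, cohort_counts = NULL) {
  a <- as.integer(junction$intron_start)
  b <- as.integer(junction$intron_end)
  strand <- junction$strand
  stopifnot(strand %in% c("+", "-"))
  gi <- gene_introns(index, gene_id)
  gi <- gi[gi$strand == strand & gi$chrom == junction$chrom, , drop = FALSE]
  gi <- gi[!duplicated(gi$key), , drop = FALSE]
  res <- function(key, site) {
    structure(list(canonical_key = key, shared_site = site),
              class = "canonical_assignment")
  }
  if (nrow(gi) == 0) return(res(NA_character_, "none"))

  pick <- function(rows) {
    if (nrow(rows) == 1L) return(rows$key)
    counts <- if (is.null(cohort_counts)) rep(0, nrow(rows))
      else as.numeric(cohort_counts[rows$key])
    counts[is.na(counts)] <- 0
    rows <- rows[order(-counts, rows$end - rows$start, rows$key), , drop = FALSE]
    rows$key[1]
  }

  jx_donor <- if (strand == "+") a else b
  jx_acceptor <- if (strand == "+") b else a
  gi$donor <- if (strand == "+") gi$start else gi$end
  gi$acceptor <- if (strand == "+") gi$end else gi$start

  same_donor <- gi[gi$donor == jx_donor, , drop = FALSE]
  if (nrow(same_donor) > 0) return(res(pick(same_donor), "donor"))
  same_acceptor <- gi[gi$acceptor == jx_acceptor, , drop = FALSE]
  if (nrow(same_acceptor) > 0) return(res(pick(same_acceptor), "acceptor"))

  containing <- gi[gi$start <= a & gi$end >= b, , drop = FALSE]
  if (nrow(containing) > 0) return(res(pick(containing), "none"))
  ov <- pmax(0L, pmin(gi$end, b) - pmax(gi$start, a) + 1L)
  if (any(ov > 0)) {
    overl <- gi[ov == max(ov), , drop = FALSE]
    return(res(pick(overl), "none"))
  }
  res(NA_character_, "none")
}
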