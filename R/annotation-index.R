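# Transcript models and the annotation index used to decide annotated vs
# non-annotated junction status and to resolve gene context.

#' Construct a transcript model
#'
#' Coordinates are 1-based inclusive genomic positions. Exons must be
#' non-overlapping; they are stored sorted by coordinate. A transcript is
#' coding iff `cds_span` is given; `cds_span` must lie within the exon
#' union.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of (start, end).
#' @param cds_span Optional length-2 numeric `(start, end)` of the coding
#'   region (genomic span from start codon to stop codon inclusive).
#' @param median_tpm Optional named numeric: median TPM per subtype.
#' @return Object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_span = NULL, median_tpm = NULL) {
  exons <- as.data.frame(exons)
  names(exons)[1:2] <- c("start", "end")
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start > exons$end)) stop("exon start exceeds end")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("exons overlap or touch")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (!is.null(cds_span)) {
    cds_span <- as.numeric(cds_span)
    if (cds_span[1] > cds_span[2]) stop("cds_span start exceeds end")
    if (cds_span[1] < min(exons$start) || cds_span[2] > max(exons$end)) {
      stop("cds_span outside exon span")
    }
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons, cds_span = cds_span,
         median_tpm = median_tpm),
    class = "transcript_model"
  )
}

#' Annotated introns of a transcript
#' @param tx A `transcript_model`.
#' @return data.frame of (start, end) intron coordinates (1-based
#'   inclusive intronic bases), empty for single-exon transcripts.
#' @export
transcript_introns <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 2) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
}

#' Build an annotation index
#'
#' Indexes annotated introns, gene extents and per-gene splice sites so
#' that junction annotation status, gene overlap and canonical-partner
#' lookups are O(1)/interval queries.
#'
#' @param transcripts List of `transcript_model` objects.
#' @return Object of class `annotation_index`.
#' @export
build_annotation_index <- function(transcripts) {
  stopifnot(length(transcripts) > 0)
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  intron_rows <- lapply(transcripts, function(tx) {
    ir <- transcript_introns(tx)
    if (nrow(ir) == 0) return(NULL)
    data.frame(chrom = tx$chrom, start = ir$start, end = ir$end,
               strand = tx$strand, gene_id = tx$gene_id,
               transcript_id = tx$transcript_id, stringsAsFactors = FALSE)
  })
  introns <- do.call(rbind, intron_rows)
  if (is.null(introns)) {
    introns <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          gene_id = character(0), transcript_id = character(0))
  }
  rownames(introns) <- NULL
  introns$key <- jx_key(introns$chrom, introns$start, introns$end, introns$strand)

  gene_tab <- do.call(rbind, lapply(transcripts, function(tx) {
    data.frame(gene_id = tx$gene_id, chrom = tx$chrom, strand = tx$strand,
               start = min(tx$exons$start), end = max(tx$exons$end),
               stringsAsFactors = FALSE)
  }))
  genes <- do.call(rbind, lapply(split(gene_tab, gene_tab$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1], strand = g$strand[1],
               start = min(g$start), end = max(g$end), stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand
  )
  mcols(gene_gr)$gene_id <- genes$gene_id

  structure(
    list(transcripts = transcripts, introns = introns, genes = genes,
         gene_gr = gene_gr, intron_keys = unique(introns$key)),
    class = "annotation_index"
  )
}

#' Is a junction an annotated intron?
#' @param index An `annotation_index`.
#' @param chrom,start,end Junction intron coordinates.
#' @param strand Junction strand; `"*"` matches either strand.
#' @return Logical.
#' @export
is_annotated_junction <- function(index, chrom, start, end, strand = "*") {
  if (strand == "*") {
    any(jx_key(chrom, start, end, c("+", "-")) %in% index$intron_keys)
  } else {
    jx_key(chrom, start, end, strand) %in% index$intron_keys
  }
}

#' Genes overlapping an interval
#' @param index An `annotation_index`.
#' @param chrom,start,end Interval (1-based inclusive).
#' @param strand Optional strand filter (`"*"` = both).
#' @return Character vector of gene ids.
#' @export
genes_overlapping <- function(index, chrom, start, end, strand = "*") {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
  hits <- GenomicRanges::findOverlaps(q, index$gene_gr,
                                      ignore.strand = identical(strand, "*"))
  unique(mcols(index$gene_gr)$gene_id[S4Vectors::subjectHits(hits)])
}

gene_introns <- function(index, gene_id) {
  index$introns[index$introns$gene_id == gene_id, , drop = FALSE]
}

# The transcript used for splice-type calls and translation when a gene
# has several: the coding transcript with the highest median TPM (any
# subtype); first coding transcript if expression is unknown.
representative_transcript <- function(index, gene_id) {
  txs <- Filter(function(tx) tx$gene_id == gene_id && !is.null(tx$cds_span),
                index$transcripts)
  if (length(txs) == 0) return(NULL)
  scores <- vapply(txs, function(tx) {
    if (is.null(tx$median_tpm) || length(tx$median_tpm) == 0) -Inf
    else max(tx$median_tpm)
  }, numeric(1))
  if (all(!is.finite(scores))) txs[[1]] else txs[[which.max(scores)]]
}

# ---- GTF I/O (Ensembl-style, 1-based inclusive) -------------------------

#' Write transcript models to a GTF file
#'
#' Emits gene, transcript, exon and CDS features with `gene_id` /
#' `transcript_id` attributes. CDS features are the per-exon pieces of
#' `cds_span`.
#'
#' @param transcripts List of `transcript_model`s.
#' @param path Output `.gtf` path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(transcripts, path) {
  rows <- lapply(transcripts, function(tx) {
    ex <- tx$exons
    feat <- data.frame(start = ex$start, end = ex$end, type = "exon",
                       phase = NA_integer_)
    if (!is.null(tx$cds_span)) {
      keep <- ex$end >= tx$cds_span[1] & ex$start <= tx$cds_span[2]
      cds <- ex[keep, , drop = FALSE]
      cds$start <- pmax(cds$start, tx$cds_span[1])
      cds$end <- pmin(cds$end, tx$cds_span[2])
      w <- cds$end - cds$start + 1L
      cum <- if (tx$strand == "+") cumsum(c(0L, w[-length(w)]))
        else rev(cumsum(c(0L, rev(w)[-length(w)])))
      feat <- rbind(feat, data.frame(start = cds$start, end = cds$end,
                                     type = "CDS",
                                     phase = (3L - cum %% 3L) %% 3L))
    }
    feat <- rbind(
      data.frame(start = min(ex$start), end = max(ex$end),
                 type = c("gene", "transcript"), phase = NA_integer_),
      feat
    )
    data.frame(chrom = tx$chrom, start = feat$start, end = feat$end,
               type = feat$type, phase = feat$phase, strand = tx$strand,
               gene_id = tx$gene_id, transcript_id = tx$transcript_id,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$start, tab$end),
                               strand = tab$strand)
  mcols(gr)$type <- tab$type
  mcols(gr)$source <- "njatlas"
  mcols(gr)$phase <- tab$phase
  mcols(gr)$gene_id <- tab$gene_id
  mcols(gr)$transcript_id <- tab$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Reconstructs `transcript_model`s from exon and CDS features; the CDS
#' span is the range of a transcript's CDS pieces.
#'
#' @param path `.gtf` path.
#' @return List of `transcript_model`s (named by transcript id).
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  out <- lapply(split(df, df$transcript_id), function(d) {
    ex <- d[d$type == "exon", , drop = FALSE]
    cds <- d[d$type == "CDS", , drop = FALSE]
    transcript_model(
      transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
      chrom = as.character(d$seqnames[1]), strand = as.character(d$strand[1]),
      exons = ex[, c("start", "end")],
      cds_span = if (nrow(cds)) c(min(cds$start), max(cds$end)) else NULL
    )
  })
  out[order(names(out))]
}
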