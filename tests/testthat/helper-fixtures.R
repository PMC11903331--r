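# Shared fixtures: a toy three-exon gene model on each strand, and
# independent brute-force oracles (per-base interval arithmetic for
# splice classification, codon-by-codon translation) used to check the
# package implementations.

toy_tx <- function(strand = "+", chrom = "chrT") {
  transcript_model(
    transcript_id = paste0("toyT", strand), gene_id = paste0("toyG", strand),
    chrom = chrom, strand = strand,
    exons = data.frame(start = c(101, 301, 501), end = c(200, 400, 600)),
    cds_span = c(131, 570)
  )
}

toy_index <- function(strand = "+") build_annotation_index(list(toy_tx(strand)))

mk_jx <- function(a, b, strand = "+", chrom = "chrT") {
  list(chrom = chrom, intron_start = a, intron_end = b, strand = strand)
}

# Brute-force splice classification: per-base exonic membership instead
# of interval arithmetic. Returns list(splice_type, nt_delta, frame_status).
oracle_classify <- function(tx, a, b) {
  ex <- tx$exons
  ir <- transcript_introns(tx)
  lo <- min(ex$start); hi <- max(ex$end)
  exonic <- rep(FALSE, hi - lo + 1L)
  for (i in seq_len(nrow(ex))) exonic[(ex$start[i]:ex$end[i]) - lo + 1L] <- TRUE
  is_ex <- function(p) p >= lo && p <= hi && exonic[p - lo + 1L]
  n_exonic <- function(p1, p2) {
    if (p2 < p1) return(0L)
    sum(exonic[pmax(p1, lo):pmin(p2, hi) - lo + 1L])
  }
  left_ann <- a %in% ir$start
  right_ann <- b %in% ir$end
  exon_inside <- any(ex$start > a & ex$end < b)
  side_right <- if (tx$strand == "+") "A3" else "A5"
  side_left <- if (tx$strand == "+") "A5" else "A3"
  type <- "other"; delta <- NA_integer_
  if (left_ann && right_ann && exon_inside) {
    type <- "exon_skip"; delta <- -n_exonic(a, b)
  } else if (left_ann && !right_ann) {
    ce <- ir$end[which(ir$start == a)[1]]
    if (b > ce) {
      if (is_ex(b)) { type <- paste0(side_right, "_loss"); delta <- -n_exonic(ce + 1L, b) }
    } else {
      type <- paste0(side_right, "_gain"); delta <- ce - b
    }
  } else if (right_ann && !left_ann) {
    cs <- ir$start[which(ir$end == b)[1]]
    if (a < cs) {
      if (is_ex(a)) { type <- paste0(side_left, "_loss"); delta <- -n_exonic(a, cs - 1L) }
    } else {
      type <- paste0(side_left, "_gain"); delta <- a - cs
    }
  } else if (!left_ann && !right_ann) {
    if (any(ex$start <= a & ex$end >= b)) {
      type <- "in_exon"; delta <- -(b - a + 1L)
    } else if (nrow(ir) > 0 && any(ir$start <= a & ir$end >= b)) {
      k <- which(ir$start <= a & ir$end >= b)[1]
      type <- "in_intron"; delta <- (a - ir$start[k]) + (ir$end[k] - b)
    }
  }
  frame <- if (type == "other" || is.null(tx$cds_span) ||
               b < tx$cds_span[1] || a > tx$cds_span[2]) "noncoding"
    else if (abs(delta) %% 3L == 0L) "in_frame" else "frameshift"
  list(splice_type = type, nt_delta = as.integer(delta), frame_status = frame)
}

# Codon-by-codon translation oracle (stops excluded from the product).
oracle_translate <- function(cds) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(cds) %/% 3L
  out <- character(0)
  for (i in seq_len(n)) {
    codon <- substr(cds, 3L * i - 2L, 3L * i)
    aa <- code[codon]
    if (is.na(aa)) aa <- "X"
    if (aa == "*") break
    out <- c(out, aa)
  }
  paste(out, collapse = "")
}

# Random single-junction proposals of every splice type on a transcript
# (used for property suites; coordinates built independently of
# plant_junction_coords so planted intent, oracle and implementation
# are three separate routes).
random_planted_junction <- function(tx) {
  ir <- transcript_introns(tx)
  ex <- tx$exons
  types <- c("A3_loss", "A3_gain", "A5_loss", "A5_gain",
             "exon_skip", "in_exon", "in_intron")
  ty <- sample(types, 1)
  k <- sample(nrow(ir), 1)
  s <- ir$start[k]; e <- ir$end[k]
  d <- sample(2:12, 1)
  plus <- tx$strand == "+"
  coords <- switch(ty,
    A3_loss = if (plus) c(s, e + d) else c(s - d, e),
    A3_gain = if (plus) c(s, e - d) else c(s + d, e),
    A5_loss = if (plus) c(s - d, e) else c(s, e + d),
    A5_gain = if (plus) c(s + d, e) else c(s, e - d),
    exon_skip = {
      kk <- sample(2:(nrow(ex) - 1L), 1)
      c(ex$end[kk - 1L] + 1L, ex$start[kk + 1L] - 1L)
    },
    in_exon = {
      kk <- sample(2:(nrow(ex) - 1L), 1)
      a0 <- ex$start[kk] + sample(5:12, 1)
      c(a0, a0 + d - 1L)
    },
    in_intron = {
      left <- max(1L, d %/% 2L)
      c(s + left, e - (d - left))
    }
  )
  list(type = ty, intron_start = coords[1], intron_end = coords[2])
}

small_reference <- function(seed = 101, n_genes = 6) {
  cfg <- sim_config(seed = seed, n_genes = n_genes, n_tumour_samples = 8,
                    n_normal_samples = 8, n_cases = 2, regions_per_case = 4)
  generate_reference(cfg)
}
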