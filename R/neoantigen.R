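# From neojunctions to neoantigen candidates.
#
# A neojunction (a, b) is treated as the intron used *instead of* the
# annotated splicing in the region it spans: the mutant transcript's
# intron set is the annotated introns that do not overlap [a, b], plus
# (a, b) itself. This single rule realizes every splice type: A3/A5
# losses trim exonic sequence, gains retain intronic sequence, exon
# skips drop the spanned exon(s), in-exon junctions delete an internal
# exonic interval and in-intron junctions turn the flanking intronic
# sequence into exonic sequence. The CDS is re-read from the annotated
# start codon and translated to the first stop codon; frameshifted
# tails are translated in the new frame.

trim_to_codons <- function(seq) substr(seq, 1L, nchar(seq) %/% 3L * 3L)

translate_to_stop <- function(cds) {
  cds <- trim_to_codons(cds)
  if (nchar(cds) < 3L) return(list(protein = "", found_stop = FALSE, n_nt = 0L))
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(cds), if.fuzzy.codon = "X")))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) {
    list(protein = substr(aa, 1L, stop_at - 1L), found_stop = TRUE,
         n_nt = (stop_at - 1L) * 3L)
  } else {
    list(protein = aa, found_stop = FALSE, n_nt = nchar(aa) * 3L)
  }
}

# intervals as data.frames (start, end); complement of sorted disjoint
# intervals within [lo, hi]
interval_complement <- function(iv, lo, hi) {
  iv <- iv[order(iv$start), , drop = FALSE]
  starts <- pmax(lo, c(lo, iv$end + 1L))
  ends <- pmin(hi, c(iv$start - 1L, hi))
  keep <- starts <= ends
  data.frame(start = starts[keep], end = ends[keep])
}

#' Build the mutant transcript implied by a neojunction
#'
#' @param tx Coding `transcript_model` affected by the junction.
#' @param junction List with `chrom`, `intron_start`, `intron_end` (the
#'   neojunction's intron coordinates, 1-based inclusive).
#' @param genome `DNAStringSet` containing the transcript's chromosome.
#' @return List of class `mutant_transcript`: `transcript_id`,
#'   `junction_key`, `mutant_cds`, `reference_protein`,
#'   `mutant_protein`, `junction_residue_span` (first/last affected
#'   residue, or `integer(0)` when the protein is unaffected),
#'   `frameshift`, `premature_stop`, `found_stop`, `nt_delta`,
#'   `coding_effect`.
#' @export
build_mutant_transcript <- function(tx, junction, genome) {
  if (is.null(tx$cds_span)) stop("transcript is non-coding")
  a <- as.integer(junction$intron_start)
  b <- as.integer(junction$intron_end)
  key <- jx_key(tx$chrom, a, b, tx$strand)
  chrom_seq <- genome[[tx$chrom]]
  ex <- tx$exons
  span <- c(min(ex$start), max(ex$end))
  ir <- transcript_introns(tx)

  mut_introns <- ir[!(ir$start <= b & ir$end >= a), , drop = FALSE]
  mut_introns <- rbind(mut_introns, data.frame(start = a, end = b))
  mut_ex <- interval_complement(mut_introns, span[1], span[2])

  extract <- function(exons) {
    pieces <- lapply(seq_len(nrow(exons)), function(i) {
      as.character(Biostrings::subseq(chrom_seq, exons$start[i], exons$end[i]))
    })
    s <- paste(unlist(pieces), collapse = "")
    if (tx$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }
  # transcript-orientation position of a genomic base within an exon set
  tx_pos <- function(exons, gpos) {
    hit <- which(exons$start <= gpos & exons$end >= gpos)
    if (length(hit) == 0) return(NA_integer_)
    if (tx$strand == "+") {
      sum((pmin(exons$end, gpos) - exons$start + 1L)[seq_len(hit)])
    } else {
      n <- nrow(exons)
      before <- if (hit < n) sum(exons$end[(hit + 1):n] - exons$start[(hit + 1):n] + 1L) else 0L
      before + (exons$end[hit] - gpos) + 1L
    }
  }

  ref_cds_len <- sum(pmax(0L, pmin(ex$end, tx$cds_span[2]) -
                            pmax(ex$start, tx$cds_span[1]) + 1L))
  ref_start_g <- if (tx$strand == "+") tx$cds_span[1] else tx$cds_span[2]
  ref_mrna <- extract(ex)
  ref_cds <- substr(ref_mrna, tx_pos(ex, ref_start_g),
                    tx_pos(ex, ref_start_g) + ref_cds_len - 1L)
  ref_tr <- translate_to_stop(ref_cds)

  nt_delta <- as.integer(sum(mut_ex$end - mut_ex$start + 1L) -
                           sum(ex$end - ex$start + 1L))

  out <- list(transcript_id = tx$transcript_id, junction_key = key,
              mutant_cds = "", reference_protein = ref_tr$protein,
              mutant_protein = "", junction_residue_span = integer(0),
              frameshift = FALSE, premature_stop = FALSE, found_stop = FALSE,
              nt_delta = nt_delta, coding_effect = FALSE)
  class(out) <- "mutant_transcript"

  mut_start_pos <- tx_pos(mut_ex, ref_start_g)
  if (is.na(mut_start_pos)) return(out)  # start codon removed: noncoding product

  in_cds <- b >= tx$cds_span[1] && a <= tx$cds_span[2]
  mut_mrna <- extract(mut_ex)
  mut_cds_full <- substr(mut_mrna, mut_start_pos, nchar(mut_mrna))
  if (substr(mut_cds_full, 1L, 3L) != "ATG") return(out)
  tr <- translate_to_stop(mut_cds_full)
  out$mutant_protein <- tr$protein
  out$found_stop <- tr$found_stop
  out$mutant_cds <- substr(mut_cds_full, 1L,
                           if (tr$found_stop) tr$n_nt + 3L else tr$n_nt)
  if (!in_cds || nchar(out$mutant_protein) == 0) return(out)

  out$coding_effect <- TRUE
  out$frameshift <- abs(nt_delta) %% 3L != 0L
  if (tr$found_stop) {
    # the reference stop is reached iff the translated CDS has the
    # in-frame expected length; anything else is a premature stop
    expected <- ref_cds_len + nt_delta - 3L  # translated nt, minus stop
    out$premature_stop <- !(!out$frameshift && tr$n_nt == expected)
  }

  # novel exonic bases (gains) determine the edited CDS interval;
  # pure deletions use the fusion point
  novel <- mut_ex
  for (i in seq_len(nrow(ex))) {
    novel_new <- list()
    for (j in seq_len(nrow(novel))) {
      s <- novel$start[j]; e <- novel$end[j]
      os <- max(s, ex$start[i]); oe <- min(e, ex$end[i])
      if (os > oe) { novel_new[[length(novel_new) + 1L]] <- c(s, e); next }
      if (s < os) novel_new[[length(novel_new) + 1L]] <- c(s, os - 1L)
      if (e > oe) novel_new[[length(novel_new) + 1L]] <- c(oe + 1L, e)
    }
    novel <- if (length(novel_new)) {
      m <- do.call(rbind, novel_new)
      data.frame(start = m[, 1], end = m[, 2])
    } else data.frame(start = integer(0), end = integer(0))
  }
  prot_len <- nchar(out$mutant_protein)
  cds_pos_of <- function(gpos) tx_pos(mut_ex, gpos) - mut_start_pos + 1L
  novel_cds <- integer(0)
  if (nrow(novel) > 0) {
    for (j in seq_len(nrow(novel))) {
      novel_cds <- c(novel_cds, cds_pos_of(novel$start[j]), cds_pos_of(novel$end[j]))
    }
    novel_cds <- novel_cds[!is.na(novel_cds) & novel_cds >= 1L]
  }
  if (length(novel_cds) > 0) {
    q1 <- min(novel_cds); q2 <- max(novel_cds)
  } else {
    # fusion point: last transcript base before the junction
    anchor_g <- if (tx$strand == "+") a - 1L else b + 1L
    p <- cds_pos_of(anchor_g)
    if (is.na(p) || p < 1L) p <- 1L
    q1 <- if (out$frameshift) p + 1L else max(1L, p)
    q2 <- min(p + 1L, nchar(out$mutant_cds))
  }
  first <- min(ceiling(q1 / 3), prot_len)
  last <- if (out$frameshift) prot_len else min(ceiling(q2 / 3), prot_len)
  if (first >= 1L && last >= first) {
    out$junction_residue_span <- c(as.integer(first), as.integer(last))
  }
  out
}

#' Tile junction-spanning 8-11-mer peptide candidates
#'
#' Enumerates every k-mer (k in `k_range`) of the mutant protein that
#' contains at least one residue of the junction residue span,
#' deduplicates by sequence (first occurrence kept), and records up to
#' `flank_max` residues of mutant-protein context on each side. Tiles
#' containing an ambiguous residue (`X`) are discarded.
#'
#' @param mutant A [build_mutant_transcript()] result.
#' @param k_range Peptide lengths (default 8:11).
#' @param flank_max Maximum flank length (default 30 residues).
#' @return data.frame of peptide candidates: sequence, junction_key,
#'   position, length, flank_n, flank_c.
#' @export
tile_peptides <- function(mutant, k_range = 8:11, flank_max = 30) {
  empty <- data.frame(sequence = character(0), junction_key = character(0),
                      position = integer(0), length = integer(0),
                      flank_n = character(0), flank_c = character(0),
                      stringsAsFactors = FALSE)
  span <- mutant$junction_residue_span
  if (length(span) == 0) {
    warning("junction has no affected residues; no peptides emitted: ",
            mutant$junction_key)
    return(empty)
  }
  prot <- mutant$mutant_protein
  L <- nchar(prot)
  rows <- list()
  for (k in sort(k_range)) {
    if (L < k) next
    lo <- max(1L, span[1] - k + 1L)
    hi <- min(span[2], L - k + 1L)
    if (lo > hi) next
    for (s in lo:hi) {
      seq <- substr(prot, s, s + k - 1L)
      if (grepl("X", seq, fixed = TRUE)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = seq, junction_key = mutant$junction_key,
        position = s, length = k,
        flank_n = substr(prot, max(1L, s - flank_max), s - 1L),
        flank_c = substr(prot, s + k, min(L, s + k - 1L + flank_max)),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag candidates absent from the reference proteome
#'
#' A candidate is tumour-specific iff its sequence is not an exact
#' substring of any reference proteome entry (case-normalized).
#' Non-specific candidates are retained but can never be selected.
#'
#' @param candidates [tile_peptides()] output (rows from one or more
#'   junctions).
#' @param proteome `AAStringSet` or character vector of reference
#'   proteins.
#' @return `candidates` with a logical `tumour_specific` column.
#' @export
filter_tumour_specific <- function(candidates, proteome) {
  prot <- toupper(as.character(proteome))
  if (length(prot) == 0) stop("proteome must be non-empty")
  candidates$tumour_specific <- vapply(toupper(candidates$sequence), function(s) {
    !any(grepl(s, prot, fixed = TRUE))
  }, logical(1), USE.NAMES = FALSE)
  candidates
}

rank_percentiles <- function(table, peptides, allele, higher_is_better = TRUE) {
  sub <- table[table$allele == allele & table$peptide %in% peptides, , drop = FALSE]
  missing <- setdiff(peptides, sub$peptide)
  if (length(missing) > 0) {
    stop("score table is missing ", length(missing), " candidate(s) for ",
         allele, ": ", paste(head(missing, 5), collapse = ", "))
  }
  sub <- sub[match(peptides, sub$peptide), ]
  s <- if (higher_is_better) -sub$score else sub$score
  rank(s, ties.method = "min") / length(peptides)
}

#' Select HLA-presented candidates by two-scorer top-percentile intersection
#'
#' Percentile ranks are computed per allele within the tumour-specific
#' candidate set for each scorer (ties share the better rank). A
#' candidate is selected iff it is tumour-specific and, for at least
#' one allele, ranks in the top `q` of BOTH scorers.
#'
#' @param candidates [filter_tumour_specific()] output.
#' @param table_a,table_b Score data.frames (peptide, allele, score) or
#'   a [generate_score_tables()] `score_tables` list in `table_a`.
#' @param alleles Alleles to evaluate (default [default_alleles()]).
#' @param q Top percentile threshold; 0.01 by default, 0.10 is the
#'   documented alternative.
#' @param higher_is_better Score orientation (default `TRUE`).
#' @return `candidates` with a logical `selected` column and a
#'   `"ranks"` attribute (long data.frame: peptide, allele, rank_a,
#'   rank_b).
#' @export
select_presented <- function(candidates, table_a, table_b = NULL,
                             alleles = default_alleles(), q = 0.01,
                             higher_is_better = TRUE) {
  if (inherits(table_a, "score_tables")) {
    table_b <- table_a$table_b
    table_a <- table_a$table_a
  }
  stopifnot(q > 0, q <= 1)
  ts <- candidates$tumour_specific
  peptides <- candidates$sequence[ts]
  candidates$selected <- FALSE
  if (length(peptides) == 0) {
    attr(candidates, "ranks") <- NULL
    return(candidates)
  }
  hit <- rep(FALSE, length(peptides))
  ranks <- list()
  for (al in alleles) {
    ra <- rank_percentiles(table_a, peptides, al, higher_is_better)
    rb <- rank_percentiles(table_b, peptides, al, higher_is_better)
    hit <- hit | (ra <= q & rb <= q)
    ranks[[al]] <- data.frame(peptide = peptides, allele = al,
                              rank_a = ra, rank_b = rb,
                              stringsAsFactors = FALSE)
  }
  candidates$selected[ts] <- hit
  attr(candidates, "ranks") <- do.call(rbind, c(ranks, make.row.names = FALSE))
  candidates
}

#' Collapse selected candidates to neopeptide-encoding junctions (NEJs)
#'
#' @param candidates [select_presented()] output.
#' @return data.frame: junction_key, n_selected (selected candidates
#'   per junction); empty when nothing is selected.
#' @export
map_to_nej <- function(candidates) {
  sel <- candidates[candidates$selected, , drop = FALSE]
  if (nrow(sel) == 0) {
    return(data.frame(junction_key = character(0), n_selected = integer(0)))
  }
  counts <- table(sel$junction_key)
  data.frame(junction_key = names(counts), n_selected = as.integer(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Match mass-spectrometry-detected peptides to neojunction products
#'
#' A junction is MS-confirmed iff some detected peptide matches its
#' mutant protein at a position overlapping the junction residue span
#' and is not a substring of the reference proteome.
#'
#' @param detected_peptides Character vector of detected peptide
#'   sequences.
#' @param mutants List of [build_mutant_transcript()] results.
#' @param proteome Reference proteome (`AAStringSet` or character).
#' @return data.frame: junction_key, ms_confirmed, peptides
#'   (semicolon-joined confirming peptides).
#' @export
match_ms_peptides <- function(detected_peptides, mutants, proteome) {
  prot <- toupper(as.character(proteome))
  detected_peptides <- toupper(unique(detected_peptides))
  in_proteome <- vapply(detected_peptides, function(p) {
    any(grepl(p, prot, fixed = TRUE))
  }, logical(1))
  rows <- lapply(mutants, function(m) {
    span <- m$junction_residue_span
    hits <- character(0)
    if (length(span) == 2 && nchar(m$mutant_protein) > 0) {
      for (p in detected_peptides[!in_proteome]) {
        starts <- gregexpr(p, m$mutant_protein, fixed = TRUE)[[1]]
        if (starts[1] == -1) next
        ends <- starts + nchar(p) - 1L
        if (any(starts <= span[2] & ends >= span[1])) hits <- c(hits, p)
      }
    }
    data.frame(junction_key = m$junction_key, ms_confirmed = length(hits) > 0,
               peptides = paste(hits, collapse = ";"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Neoantigen candidates for a set of neojunction calls
#'
#' Builds the mutant transcript for every CDS-affecting call, tiles
#' junction-spanning peptides, removes proteome matches and applies
#' two-scorer selection.
#'
#' @param calls Neojunction call data.frame ([call_neojunctions()]
#'   `calls`), requiring `key`, `transcript_id`, `frame_status`.
#' @param index `annotation_index` carrying the transcript models.
#' @param genome Genome `DNAStringSet`.
#' @param proteome Reference proteome.
#' @param tables Optional `score_tables` (or `NULL` to skip selection).
#' @param alleles,q Passed to [select_presented()].
#' @return List: `mutants`, `candidates`, `nejs`.
#' @export
nj_neoantigens <- function(calls, index, genome, proteome, tables = NULL,
                           alleles = default_alleles(), q = 0.01) {
  coding <- calls[calls$frame_status %in% c("in_frame", "frameshift"), ,
                  drop = FALSE]
  mutants <- list()
  cand_rows <- list()
  for (i in seq_len(nrow(coding))) {
    row <- coding[i, ]
    tx <- index$transcripts[[row$transcript_id]]
    if (is.null(tx) || is.null(tx$cds_span)) next
    jk <- jx_unkey(row$key)
    m <- build_mutant_transcript(
      tx, list(chrom = jk$chrom, intron_start = jk$start, intron_end = jk$end),
      genome
    )
    mutants[[row$key]] <- m
    if (m$coding_effect) {
      tiles <- suppressWarnings(tile_peptides(m))
      if (nrow(tiles) > 0) cand_rows[[row$key]] <- tiles
    }
  }
  candidates <- do.call(rbind, c(cand_rows, make.row.names = FALSE))
  if (is.null(candidates) || nrow(candidates) == 0) {
    return(list(mutants = mutants,
                candidates = data.frame(), nejs = map_to_nej(
                  data.frame(junction_key = character(0), selected = logical(0)))))
  }
  candidates <- candidates[!duplicated(candidates$sequence), , drop = FALSE]
  candidates <- filter_tumour_specific(candidates, proteome)
  if (!is.null(tables)) {
    candidates <- select_presented(candidates, tables, alleles = alleles, q = q)
  } else {
    candidates$selected <- FALSE
  }
  list(mutants = mutants, candidates = candidates, nejs = map_to_nej(candidates))
}
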