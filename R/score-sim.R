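# Deterministic surrogate presentation-score tables.
#
# Real HLA presentation scorers are consumed by the pipeline as
# pluggable score tables (peptide, allele, score). This surrogate
# constructs two such tables in which exactly a designated set of
# "planted binders" lands in the top q percentile of BOTH scorers for
# every allele, while every other candidate falls below the top q
# percentile of at least one scorer (the second scorer reverses the
# first scorer's ordering of non-planted candidates, which guarantees
# the property for any q < 0.5).

#' Generate two surrogate presentation score tables
#'
#' @param candidates Character vector of candidate peptide sequences
#'   (or a data.frame with a `sequence` column).
#' @param planted_binders Character vector of peptides to plant as
#'   double-top-percentile binders; must be a subset of `candidates`.
#' @param alleles HLA class I allele names; defaults to
#'   [default_alleles()].
#' @param seed Integer seed (tables are byte-deterministic).
#' @param q Top-percentile used to verify the construction (planted
#'   fraction must not exceed `q`).
#' @return List of class `score_tables`: `table_a`, `table_b`
#'   (data.frames peptide, allele, score; higher scores are better).
#' @export
generate_score_tables <- function(candidates, planted_binders = character(0),
                                  alleles = default_alleles(), seed = 1L,
                                  q = 0.01) {
  if (is.data.frame(candidates)) candidates <- candidates$sequence
  candidates <- unique(as.character(candidates))
  if (length(candidates) == 0) stop("candidates must be non-empty")
  planted_binders <- unique(as.character(planted_binders))
  if (!all(planted_binders %in% candidates)) {
    stop("planted_binders must be a subset of candidates")
  }
  n <- length(candidates)
  p <- length(planted_binders)
  if (p > 0 && p / n > q) {
    stop(sprintf("cannot plant %d binders in the top %.3f percentile of %d candidates",
                 p, q, n))
  }
  if (q >= 0.5) stop("construction requires q < 0.5")
  others <- setdiff(candidates, planted_binders)
  with_seed(seed, {
    rows_a <- list(); rows_b <- list()
    for (al in alleles) {
      shuffled <- sample(others)
      ord_a <- c(planted_binders, shuffled)
      ord_b <- c(planted_binders, rev(shuffled))
      score <- (n - seq_len(n) + 1) / n
      rows_a[[al]] <- data.frame(peptide = ord_a, allele = al, score = score,
                                 stringsAsFactors = FALSE)
      rows_b[[al]] <- data.frame(peptide = ord_b, allele = al, score = score,
                                 stringsAsFactors = FALSE)
    }
    structure(list(table_a = do.call(rbind, c(rows_a, make.row.names = FALSE)),
                   table_b = do.call(rbind, c(rows_b, make.row.names = FALSE))),
              class = "score_tables")
  })
}

#' The five prevalent HLA-A alleles used by default
#' @return Character vector of allele names.
#' @export
default_alleles <- function() {
  c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01", "HLA-A*11:01", "HLA-A*24:02")
}

#' Write surrogate score tables to disk
#' @param tables [generate_score_tables()] output.
#' @param dir Output directory.
#' @return Paths, invisibly.
#' @export
write_score_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pa <- file.path(dir, "scores_a.tsv")
  pb <- file.path(dir, "scores_b.tsv")
  write.table(tables$table_a, pa, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tables$table_b, pb, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(table_a = pa, table_b = pb))
}
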