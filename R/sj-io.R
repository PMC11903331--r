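# I/O for the STAR SJ.out.tab 9-column splice-junction dialect.
#
# Columns: chrom, first intronic base, last intronic base, strand code
# (0 unknown / 1 "+" / 2 "-"), intron motif code, annotated flag,
# unique-mapping reads, multi-mapping reads, maximum spliced overhang.
# Coordinates are 1-based inclusive.

#' Parse a splice-junction table (STAR `SJ.out.tab` dialect)
#'
#' Rows with zero unique reads are retained; downstream filters decide
#' what counts as expressed. Strand codes are mapped 0 to `"*"`
#' (unknown), 1 to `"+"`, 2 to `"-"`.
#'
#' @param path Path to a 9-column tab-separated junction table.
#' @param sample_id Sample identifier attached to every record.
#' @return data.frame of junction records: chrom, intron_start,
#'   intron_end, strand, motif, annotated, unique_reads, multi_reads,
#'   max_overhang, sample_id, key.
#' @export
parse_junction_table <- function(path, sample_id) {
  if (!file.exists(path)) stop("junction table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_junction_df(sample_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1]
    stop(sprintf("malformed junction row at line %d of %s: expected 9 tab-separated columns, found %d",
                 bad, path, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 2:9, drop = FALSE], 2L, as.integer))
  num <- matrix(num, ncol = 8L)
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    stop(sprintf("malformed junction row at line %d of %s: non-integer field", bad, path))
  }
  strand <- c("*", "+", "-")[num[, 3L] + 1L]
  if (anyNA(strand)) {
    bad <- which(is.na(strand))[1]
    stop(sprintf("malformed junction row at line %d of %s: strand code must be 0, 1 or 2", bad, path))
  }
  out <- data.frame(
    chrom = m[, 1L],
    intron_start = num[, 1L],
    intron_end = num[, 2L],
    strand = strand,
    motif = num[, 4L],
    annotated = num[, 5L],
    unique_reads = num[, 6L],
    multi_reads = num[, 7L],
    max_overhang = num[, 8L],
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
  if (any(out$intron_start > out$intron_end)) {
    bad <- which(out$intron_start > out$intron_end)[1]
    stop(sprintf("malformed junction row at line %d of %s: intron start exceeds end", bad, path))
  }
  if (any(out$unique_reads < 0)) {
    bad <- which(out$unique_reads < 0)[1]
    stop(sprintf("malformed junction row at line %d of %s: negative read count", bad, path))
  }
  out$key <- jx_key(out$chrom, out$intron_start, out$intron_end, out$strand)
  out
}

empty_junction_df <- function(sample_id = character(0)) {
  data.frame(
    chrom = character(0), intron_start = integer(0), intron_end = integer(0),
    strand = character(0), motif = integer(0), annotated = integer(0),
    unique_reads = integer(0), multi_reads = integer(0),
    max_overhang = integer(0), sample_id = character(0), key = character(0),
    stringsAsFactors = FALSE
  )
}

#' Write a junction table in the `SJ.out.tab` dialect
#'
#' @param jx data.frame with at least chrom, intron_start, intron_end,
#'   strand, motif, annotated, unique_reads, multi_reads, max_overhang.
#' @param path Output path (tab-separated, no header).
#' @return `path`, invisibly.
#' @export
write_junction_table <- function(jx, path) {
  code <- match(jx$strand, c("*", "+", "-")) - 1L
  out <- data.frame(jx$chrom, jx$intron_start, jx$intron_end, code,
                    jx$motif, jx$annotated, jx$unique_reads,
                    jx$multi_reads, jx$max_overhang)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a directory of junction tables
#'
#' File names (minus the `.SJ.out.tab` / `.tab` / `.tsv` suffix) become
#' sample identifiers.
#'
#' @param dir Directory of junction tables.
#' @return Long data.frame of records across samples.
#' @export
read_junction_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(tab|tsv)$", full.names = TRUE)
  if (length(files) == 0L) stop("no junction tables found in ", dir)
  ids <- sub("\\.SJ\\.out\\.tab$|\\.tab$|\\.tsv$", "", basename(files))
  do.call(rbind, Map(parse_junction_table, files, ids))
}
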