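#' @keywords internal
"_PACKAGE"

#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom stats rpois rnorm rbinom runif median cor wilcox.test p.adjust
#' @importFrom utils write.table read.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical string key for a splice junction
#'
#' Junction coordinates are 1-based inclusive *intron* coordinates
#' (first and last intronic base), the convention used by STAR's
#' `SJ.out.tab`.
#'
#' @param chrom Chromosome name.
#' @param start First intronic base (1-based).
#' @param end Last intronic base (1-based, `>= start`).
#' @param strand One of `"+"`, `"-"`, `"*"` (unknown).
#' @return Character key `"chrom:start:end:strand"`.
#' @export
jx_key <- function(chrom, start, end, strand) {
  paste(chrom, start, end, strand, sep = ":")
}

#' Split a junction key back into its fields
#' @param key Character vector of keys as produced by [jx_key()].
#' @return data.frame with columns chrom, start, end, strand.
#' @export
jx_unkey <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) stop("malformed junction key: ", key[bad][1])
  data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)),
    end = as.integer(vapply(parts, `[`, "", 3L)),
    strand = vapply(parts, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.  All stochastic generator functions route their
# randomness through this so a fixed seed gives byte-identical output.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed, kept within 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}
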