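# Intratumoural (multi-region) and temporal conservation of
# neojunctions.
#
# Detection in a region uses two rules: "detectable" (junction CPM > 0,
# CPM computed over the region's total unique junction reads) and
# "putative" (>= 10 spliced reads). Conservation tiers are driven by
# the putative rule: tumour-wide (expressed in 100% of regions), highly
# (> 70%), moderately (> 30% to <= 70%) and weakly (>= 1 region but
# <= 30%) conserved.

#' Per-region detection calls for a set of junctions
#'
#' @param reads Numeric matrix: junctions x regions, unique reads.
#' @param total_reads Optional named numeric of total unique junction
#'   reads per region (CPM denominator); defaults to column sums of the
#'   full junction table the matrix came from, here `colSums(reads)`.
#' @param putative_min Putative-expression read threshold (default 10).
#' @return data.frame: key, region_id, reads, cpm, detectable, putative.
#' @export
region_detection <- function(reads, total_reads = NULL, putative_min = 10) {
  if (is.null(total_reads)) total_reads <- colSums(reads)
  total_reads <- total_reads[colnames(reads)]
  cpm <- sweep(reads, 2L, pmax(total_reads, 1), "/") * 1e6
  out <- data.frame(
    key = rep(rownames(reads), times = ncol(reads)),
    region_id = rep(colnames(reads), each = nrow(reads)),
    reads = as.vector(reads), cpm = as.vector(cpm),
    stringsAsFactors = FALSE
  )
  out$detectable <- out$cpm > 0
  out$putative <- out$reads >= putative_min
  out
}

#' Conservation tier of a junction within one case
#'
#' @param n_expressing Number of regions with putative expression.
#' @param n_regions Total sampled regions in the case (>= 1).
#' @return List of class `conservation_call`: `n_regions`,
#'   `n_expressing`, `fraction`, `tier` (one of `tumour_wide`,
#'   `highly`, `moderately`, `weakly`, `absent`).
#' @export
classify_conservation <- function(n_expressing, n_regions) {
  if (n_regions < 1) stop("n_regions must be at least 1")
  if (n_expressing < 0 || n_expressing > n_regions) {
    stop("n_expressing must lie in [0, n_regions]")
  }
  f <- n_expressing / n_regions
  tier <- if (n_expressing == 0) "absent"
    else if (f == 1) "tumour_wide"
    else if (f > 0.7) "highly"
    else if (f > 0.3) "moderately"
    else "weakly"
  structure(list(n_regions = as.integer(n_regions),
                 n_expressing = as.integer(n_expressing),
                 fraction = f, tier = tier),
            class = "conservation_call")
}

#' Is a junction spatially conserved within a case?
#'
#' Putative expression (>= `putative_min` reads) in two or more regions
#' of the same case. Cases with a single region are undefined and
#' rejected.
#'
#' @param region_reads Numeric vector: the junction's reads per region.
#' @param putative_min Putative threshold (default 10).
#' @return Logical.
#' @export
spatially_conserved <- function(region_reads, putative_min = 10) {
  if (length(region_reads) < 2) {
    stop("spatial conservation is undefined for single-region cases")
  }
  sum(region_reads >= putative_min) >= 2
}

#' Per-case conservation table
#'
#' @param reads Numeric matrix: junctions x regions of one case.
#' @param case_id Case identifier attached to the output.
#' @param putative_min Putative threshold (default 10).
#' @return data.frame: case_id, key, n_regions, n_expressing, fraction,
#'   tier, spatially_conserved, detectable_regions.
#' @export
case_conservation <- function(reads, case_id = "case", putative_min = 10) {
  det <- region_detection(reads, putative_min = putative_min)
  per <- split(det, det$key)
  rows <- lapply(per, function(d) {
    cc <- classify_conservation(sum(d$putative), nrow(d))
    data.frame(case_id = case_id, key = d$key[1], n_regions = cc$n_regions,
               n_expressing = cc$n_expressing, fraction = cc$fraction,
               tier = cc$tier,
               spatially_conserved = if (nrow(d) >= 2) sum(d$putative) >= 2 else NA,
               detectable_regions = sum(d$detectable),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$key), , drop = FALSE]
}

#' Region-downsampling curve of ubiquitously expressed junctions
#'
#' For k = 1..k_max, draws `n_draws` seeded region subsets of size k
#' and counts the junctions putatively expressed in all k regions.
#' Subsets are nested within a draw (size-k subset is a prefix of the
#' size-(k+1) subset), so each draw's curve is exactly non-increasing
#' in k; the returned curve is the mean over draws.
#'
#' @param reads Numeric matrix: junctions x regions of one case.
#' @param k_max Largest subset size (<= number of regions).
#' @param n_draws Number of seeded draws (default 20).
#' @param seed Integer seed.
#' @param putative_min Putative threshold (default 10).
#' @return data.frame: k, mean_ubiquitous.
#' @export
downsample_curve <- function(reads, k_max, n_draws = 20, seed = 1L,
                             putative_min = 10) {
  n_regions <- ncol(reads)
  if (k_max > n_regions) stop("k_max exceeds the number of regions")
  putative <- reads >= putative_min
  with_seed(seed, {
    counts <- matrix(0, nrow = n_draws, ncol = k_max)
    for (d in seq_len(n_draws)) {
      perm <- sample.int(n_regions)
      for (k in seq_len(k_max)) {
        sub <- putative[, perm[seq_len(k)], drop = FALSE]
        counts[d, k] <- sum(rowSums(sub) == k)
      }
    }
    data.frame(k = seq_len(k_max), mean_ubiquitous = colMeans(counts))
  })
}

#' Paired (primary vs secondary) conservation fraction
#'
#' Fraction of the junctions identified in a primary tumour that
#' persist in a paired secondary sample (metastasis or recurrence).
#'
#' @param set_primary,set_secondary Character vectors of junction keys.
#' @return |primary intersect secondary| / |primary|.
#' @export
paired_conservation <- function(set_primary, set_secondary) {
  set_primary <- unique(set_primary)
  if (length(set_primary) == 0) stop("primary junction set is empty")
  length(intersect(set_primary, unique(set_secondary))) / length(set_primary)
}
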