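# Cancer-specific intron retention.
#
# The intron retention (IR) ratio at an intron is
# intronic_reads / (intronic_reads + spliced_reads). Events are tested
# tumour vs normal with a two-sided Wilcoxon rank-sum test and
# Benjamini-Hochberg adjustment across introns (a declared stand-in for
# GLM-based differential IR tools; the decision criteria are the ones
# that matter: |delta IR| >= 0.10 and adjusted P < 0.05). Per-sample
# retention flags (|sample ratio - normal mean| >= 0.10) yield
# tumour/normal PSRs; cancer-specific events have tumour PSR >= 0.10
# and normal PSR < 0.01.

#' Intron retention ratio
#'
#' intronic / (intronic + spliced), 0 when both are 0.
#'
#' @param intronic_reads,spliced_reads Non-negative counts (vectorized).
#' @return Fraction in \[0, 1\].
#' @export
compute_ir_ratio <- function(intronic_reads, spliced_reads) {
  if (any(intronic_reads < 0) || any(spliced_reads < 0)) {
    stop("read counts must be non-negative")
  }
  tot <- intronic_reads + spliced_reads
  ifelse(tot > 0, intronic_reads / tot, 0)
}

#' Call cancer-specific intron retention events
#'
#' @param tumour_ir,normal_ir Numeric matrices of IR ratios (introns x
#'   samples) sharing row names (intron keys).
#' @param delta_min Minimum absolute tumour-normal mean IR difference
#'   (default 0.10).
#' @param p_max Adjusted-P significance cutoff (default 0.05).
#' @param psr_tumour_min,psr_normal_max PSR thresholds for the
#'   cancer-specific call (defaults 0.10 inclusive / 0.01 exclusive).
#' @return data.frame per intron: delta_ir, p_value, p_adjusted,
#'   significant, psr_tumour, psr_normal, cancer_specific. Introns with
#'   fewer than 2 samples in either group are skipped with a warning.
#' @export
call_ir_events <- function(tumour_ir, normal_ir, delta_min = 0.10,
                           p_max = 0.05, psr_tumour_min = 0.10,
                           psr_normal_max = 0.01) {
  keys <- intersect(rownames(tumour_ir), rownames(normal_ir))
  if (length(keys) == 0) stop("matrices share no intron keys")
  if (any(tumour_ir < 0 | tumour_ir > 1, na.rm = TRUE) ||
      any(normal_ir < 0 | normal_ir > 1, na.rm = TRUE)) {
    stop("IR ratios must lie in [0, 1]")
  }
  rows <- list()
  for (k in keys) {
    tum <- tumour_ir[k, ]; tum <- tum[!is.na(tum)]
    nor <- normal_ir[k, ]; nor <- nor[!is.na(nor)]
    if (length(tum) < 2 || length(nor) < 2) {
      warning("intron skipped (fewer than 2 samples in a group): ", k)
      next
    }
    p <- suppressWarnings(wilcox.test(tum, nor, exact = NULL)$p.value)
    nmean <- mean(nor)
    rows[[k]] <- data.frame(
      key = k, delta_ir = mean(tum) - nmean, p_value = p,
      psr_tumour = mean(abs(tum - nmean) >= delta_min),
      psr_normal = mean(abs(nor - nmean) >= delta_min),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(key = character(0), delta_ir = numeric(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0), psr_tumour = numeric(0),
                      psr_normal = numeric(0), cancer_specific = logical(0)))
  }
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out$significant <- abs(out$delta_ir) >= delta_min & out$p_adjusted < p_max
  out$cancer_specific <- out$psr_tumour >= psr_tumour_min &
    out$psr_normal < psr_normal_max
  rownames(out) <- NULL
  out[, c("key", "delta_ir", "p_value", "p_adjusted", "significant",
          "psr_tumour", "psr_normal", "cancer_specific")]
}

#' Read a per-intron read-count table and compute IR ratios
#'
#' Expects a TSV with columns `key`, `sample_id`, `intronic_reads`,
#' `spliced_reads` (long form).
#'
#' @param path TSV path.
#' @return Matrix of IR ratios, introns x samples.
#' @export
read_ir_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  req <- c("key", "sample_id", "intronic_reads", "spliced_reads")
  if (!all(req %in% names(tab))) {
    stop("IR table must have columns: ", paste(req, collapse = ", "))
  }
  ratio <- compute_ir_ratio(tab$intronic_reads, tab$spliced_reads)
  out <- tapply(ratio, list(tab$key, tab$sample_id), `[`, 1L)
  out
}
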