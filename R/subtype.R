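# Subtype-level neojunction statistics: per-sample burden, pairwise
# burden comparison (Wilcoxon rank-sum, BH across pairs), neojunction /
# splicing-gene Pearson correlations with a +-0.10 classification, and
# differential neojunction expression between subtypes.

#' Per-sample public neojunction burden
#'
#' @param observations Long per-junction x per-sample table
#'   ([call_neojunctions()] `observations`) restricted or joined to
#'   public junctions by the caller via `public_keys`.
#' @param public_keys Character vector of public junction keys.
#' @param samples Sample metadata (sample_id, subtype).
#' @return data.frame: sample_id, subtype, nj_count.
#' @export
compute_burden <- function(observations, public_keys, samples) {
  obs <- observations[observations$key %in% public_keys &
                        observations$expressed, , drop = FALSE]
  counts <- table(factor(obs$sample_id, levels = samples$sample_id))
  data.frame(sample_id = samples$sample_id,
             subtype = samples$subtype,
             nj_count = as.integer(counts[samples$sample_id]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Two-sided rank-sum p-value: exact for <= 8 per group (no ties
# permitting), normal approximation with continuity correction
# otherwise.
ranksum_p <- function(x, y) {
  exact <- length(x) <= 8 && length(y) <= 8
  suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Pairwise between-subtype burden comparison
#'
#' @param groups Named list: subtype -> numeric burden vector.
#' @return data.frame: group_a, group_b, p_value, p_adjusted (BH across
#'   pairs). Pairs with fewer than 2 samples in a group are skipped
#'   with a warning.
#' @export
compare_burden <- function(groups) {
  nm <- names(groups)
  if (length(nm) < 2) stop("at least two groups required")
  rows <- list()
  for (i in seq_len(length(nm) - 1L)) {
    for (j in (i + 1L):length(nm)) {
      if (length(groups[[i]]) < 2 || length(groups[[j]]) < 2) {
        warning("pair skipped (group with < 2 samples): ", nm[i], " vs ", nm[j])
        next
      }
      rows[[paste(nm[i], nm[j])]] <- data.frame(
        group_a = nm[i], group_b = nm[j],
        p_value = ranksum_p(groups[[i]], groups[[j]]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(group_a = character(0), group_b = character(0),
                      p_value = numeric(0), p_adjusted = numeric(0)))
  }
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Pearson correlation between a neojunction and a gene
#'
#' Expression is expected on a log scale (the pipeline uses
#' log2(CPM + 1) for junctions and log2(TPM + 1) for genes). Constant
#' vectors have no defined correlation: `NA` is returned.
#'
#' @param nj_expr,gene_expr Numeric vectors of equal length >= 3.
#' @return Pearson r, or `NA` for degenerate input.
#' @export
correlate_nj_gene <- function(nj_expr, gene_expr) {
  if (length(nj_expr) != length(gene_expr)) stop("vectors differ in length")
  if (length(nj_expr) < 3) stop("at least 3 paired samples required")
  if (stats::sd(nj_expr) == 0 || stats::sd(gene_expr) == 0) return(NA_real_)
  cor(nj_expr, gene_expr, method = "pearson")
}

#' Classify neojunction-gene correlations averaged over subtypes
#'
#' The per-subtype coefficients are averaged (unweighted); junctions
#' with mean r >= `threshold` are `positive`, <= -`threshold`
#' `negative`, otherwise `none`.
#'
#' @param records data.frame with columns `junction_key`, `gene` and
#'   one numeric column per subtype (or a `r` column plus `subtype`,
#'   long form).
#' @param threshold Classification boundary (default 0.10).
#' @return data.frame: junction_key, gene, subtype_mean_r, class.
#' @export
classify_correlations <- function(records, threshold = 0.10) {
  if (all(c("subtype", "r") %in% names(records))) {
    agg <- stats::aggregate(r ~ junction_key + gene, data = records,
                            FUN = mean, na.action = stats::na.omit)
    names(agg)[names(agg) == "r"] <- "subtype_mean_r"
  } else {
    num <- vapply(records, is.numeric, logical(1))
    agg <- records[, c("junction_key", "gene"), drop = FALSE]
    agg$subtype_mean_r <- rowMeans(records[, num, drop = FALSE], na.rm = TRUE)
  }
  agg$class <- ifelse(agg$subtype_mean_r >= threshold, "positive",
                      ifelse(agg$subtype_mean_r <= -threshold, "negative",
                             "none"))
  agg
}

#' Differential neojunction expression between two groups
#'
#' Per junction: log2 fold change of group means (pseudocount 1),
#' rank-sum p-value, BH adjustment across junctions. A junction is
#' differential iff |log2 FC| > `fc_min` and adjusted P < `p_max`
#' (both strict on the fold-change side).
#'
#' @param expr Numeric matrix: junctions x samples (e.g. junction CPM).
#' @param group_a,group_b Character vectors of column names.
#' @param fc_min log2 fold-change threshold (default 1.5, strict `>`).
#' @param p_max Adjusted-P threshold (default 0.05).
#' @return data.frame: key, log2_fc, p_value, p_adjusted, differential.
#' @export
differential_nj <- function(expr, group_a, group_b, fc_min = 1.5,
                            p_max = 0.05) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    warning("degenerate groups (< 2 samples): no differential set")
    return(data.frame(key = character(0), log2_fc = numeric(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      differential = logical(0)))
  }
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  log2_fc <- log2((rowMeans(a) + 1) / (rowMeans(b) + 1))
  p <- vapply(seq_len(nrow(expr)), function(i) ranksum_p(a[i, ], b[i, ]),
              numeric(1))
  p_adj <- p.adjust(p, method = "BH")
  data.frame(key = rownames(expr), log2_fc = log2_fc, p_value = p,
             p_adjusted = p_adj,
             differential = abs(log2_fc) > fc_min & p_adj < p_max,
             stringsAsFactors = FALSE, row.names = NULL)
}
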