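#' Differential expression between two sample groups (Welch-t stand-in)
#'
#' A deliberately simple differential-expression stage: per gene, the log2
#' fold change is the difference of group means on the log2 scale, the
#' p-value comes from a Welch two-sample t-test, and q-values from
#' Benjamini-Hochberg. A gene passes if `|log2FC| > lfc_threshold` (default
#' 1, i.e. fold change > 2 or < 0.5) and `q < fdr_threshold` (default
#' 0.05). Externally produced DEG tables (e.g. from a negative-binomial
#' GLM tool) can be dropped in via [read_deg_table()].
#'
#' Genes with zero variance in both groups get `p = 1` when the means agree
#' and `p = .Machine$double.xmin` otherwise.
#'
#' @param dataset an [expression_dataset()] (counts are log2-converted).
#' @param sheet a [sample_sheet()].
#' @param group_a,group_b character vectors of sample ids (each >= 2).
#' @param lfc_threshold absolute log2-fold-change threshold.
#' @param fdr_threshold BH-adjusted q-value threshold.
#' @return data.frame of class `deg_table` with columns `gene_id`,
#'   `log2fc` (A minus B), `p`, `q`, `pass`.
#' @export
differential <- function(dataset, sheet, group_a, group_b,
                         lfc_threshold = 1, fdr_threshold = 0.05) {
  dataset <- as_log2(dataset)
  X <- dataset$values
  if (!all(c(group_a, group_b) %in% colnames(X)))
    stop("group sample(s) absent from matrix")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs >= 2 samples")
  A <- X[, group_a, drop = FALSE]; B <- X[, group_b, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  lfc <- ma - mb
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  if (any(degenerate))
    p[degenerate] <- ifelse(lfc[degenerate] == 0, 1, .Machine$double.xmin)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene_id = rownames(X), log2fc = lfc, p = p, q = q,
                    pass = abs(lfc) > lfc_threshold & q < fdr_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Split samples before and after a tipping point
#'
#' Treated samples at times strictly before and strictly after `t_star`;
#' the tipping timepoint itself is excluded so neither side is contaminated
#' by the unstable state.
#'
#' @param sheet a [sample_sheet()].
#' @param t_star tipping timepoint.
#' @return list with character vectors `before` and `after`.
#' @export
samples_before_after <- function(sheet, t_star) {
  tr <- sheet[sheet$group == "treated", ]
  list(before = tr$sample_id[tr$time < t_star],
       after = tr$sample_id[tr$time > t_star])
}

#' Read an externally produced DEG table
#'
#' TSV with columns `gene_id`, `log2fc`, `p`, `q` (a `pass` column is
#' recomputed from the thresholds if absent).
#'
#' @param path TSV file.
#' @param lfc_threshold,fdr_threshold thresholds used when recomputing
#'   `pass`.
#' @return a `deg_table`.
#' @export
read_deg_table <- function(path, lfc_threshold = 1, fdr_threshold = 0.05) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "p", "q")
  if (!all(need %in% names(df)))
    stop("DEG table must have columns: ", paste(need, collapse = ", "))
  if (!"pass" %in% names(df))
    df$pass <- abs(df$log2fc) > lfc_threshold & df$q < fdr_threshold
  class(df) <- c("deg_table", "data.frame")
  df
}

#' Intersect passing DEGs with DNB members
#'
#' @param deg_table a `deg_table` (from [differential()] or
#'   [read_deg_table()]).
#' @param dnb_genes character vector of DNB gene ids.
#' @return list with `genes` (sorted intersection), `n_deg`, `n_dnb`,
#'   `n_intersection`.
#' @export
intersect_dnb_deg <- function(deg_table, dnb_genes) {
  degs <- deg_table$gene_id[deg_table$pass]
  inter <- sort(intersect(degs, dnb_genes))
  list(genes = inter, n_deg = length(degs), n_dnb = length(unique(dnb_genes)),
       n_intersection = length(inter))
}
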