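#' Centre treated samples on the pooled control mean
#'
#' Subtracts, gene-wise, the mean over all control samples (pooled across
#' control timepoints) from every treated sample, so per-timepoint statistics
#' measure deviation from the normal baseline rather than developmental
#' drift. A time-matched mode subtracts the control mean of the nearest
#' control timepoint instead.
#'
#' @param dataset an [expression_dataset()] on the log2 scale (counts are
#'   converted first).
#' @param sheet a [sample_sheet()].
#' @param mode `"pooled"` (default), `"time_matched"`, or `"none"` (no
#'   centring; must be requested explicitly when there are no controls).
#' @return object of class `adjusted_matrix`: list with `values` (genes x
#'   treated samples), `control_means` (per gene; 0 in `"none"` mode),
#'   `sheet` (treated rows only) and `mode`.
#' @export
adjust_to_control <- function(dataset, sheet, mode = c("pooled", "time_matched", "none")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "expression_dataset"))
  dataset <- as_log2(dataset)
  X <- dataset$values
  treated <- sheet$sample_id[sheet$group == "treated"]
  controls <- sheet$sample_id[sheet$group == "control"]
  if (mode != "none" && length(controls) == 0L)
    stop("no control samples; request mode = \"none\" explicitly to skip adjustment")
  Xt <- X[, treated, drop = FALSE]
  if (mode == "pooled") {
    cm <- rowMeans(X[, controls, drop = FALSE])
    V <- Xt - cm
  } else if (mode == "time_matched") {
    ctimes <- sort(unique(sheet$time[sheet$group == "control"]))
    cm_by_t <- vapply(ctimes, function(ct)
      rowMeans(X[, samples_at(sheet, ct, "control"), drop = FALSE]),
      numeric(nrow(X)))
    tt <- sheet$time[match(treated, sheet$sample_id)]
    nearest <- vapply(tt, function(t) which.min(abs(ctimes - t)), integer(1))
    V <- Xt - cm_by_t[, nearest, drop = FALSE]
    cm <- cm_by_t
  } else {
    cm <- rep(0, nrow(X))
    V <- Xt
  }
  structure(
    list(values = V, control_means = cm,
         sheet = sheet[sheet$group == "treated", , drop = FALSE], mode = mode),
    class = "adjusted_matrix")
}

row_sds <- function(X) {
  n <- ncol(X)
  sqrt(pmax(rowSums((X - rowMeans(X))^2), 0) / (n - 1))
}

# Absolute Pearson correlation across replicates; rows with zero variance
# yield undefined correlations, mapped to 0 (count returned as an attribute).
abs_cor <- function(X) {
  X0 <- X - rowMeans(X)
  ss <- sqrt(rowSums(X0^2))
  C <- abs(tcrossprod(X0 / ss))
  bad <- !is.finite(C)
  n_undef <- (sum(bad) - sum(!is.finite(diag(C)))) / 2
  if (any(bad)) C[bad] <- 0
  diag(C) <- 1
  C[C > 1] <- 1
  attr(C, "n_undefined") <- n_undef
  C
}

#' Per-timepoint dispersion and correlation statistics
#'
#' At one treated timepoint, computes each gene's sample standard deviation
#' (denominator n-1) across replicates and the absolute Pearson correlation
#' matrix of gene pairs across replicates. Constant genes get sd 0; their
#' undefined correlations are mapped to 0 and counted in
#' `attr(pcc, "n_undefined")`.
#'
#' @param adj an [adjust_to_control()] result.
#' @param t a treated timepoint present in the design.
#' @return list with `sd` (named vector) and `pcc` (genes x genes absolute
#'   correlation matrix).
#' @export
per_time_stats <- function(adj, t) {
  stopifnot(inherits(adj, "adjusted_matrix"))
  cols <- adj$sheet$sample_id[adj$sheet$time == t]
  if (length(cols) < 3L)
    stop("need >= 3 treated replicates at time ", t, ", got ", length(cols))
  X <- adj$values[, cols, drop = FALSE]
  list(sd = row_sds(X), pcc = abs_cor(X))
}

#' Candidate co-expression modules at one timepoint
#'
#' Genes are clustered by average-linkage hierarchical clustering on the
#' distance `1 - |PCC|` at the given timepoint; the tree is cut at a fixed
#' height and every cluster of at least `min_size` genes is returned as a
#' candidate dominant group. Deterministic given the input; members are
#' sorted lexicographically and candidates ordered by their first member.
#'
#' @param adj an [adjust_to_control()] result.
#' @param t treated timepoint.
#' @param min_size minimum cluster size (default 5).
#' @param cut_height tree-cut height on the `1 - |PCC|` scale (default 0.3,
#'   i.e. mean within-cluster `|PCC|` of roughly 0.7; with few replicates
#'   the null `|PCC|` is large, so the cut must sit well below the null
#'   distance mass).
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return list of character vectors (module gene ids); empty if no cluster
#'   reaches `min_size`.
#' @export
candidate_modules <- function(adj, t, min_size = 5, cut_height = 0.3,
                              linkage = "average") {
  st <- per_time_stats(adj, t)
  ct <- cut_clusters(st$pcc, cut_height, linkage)
  sizes <- tabulate(ct)
  keep <- which(sizes >= min_size)
  mods <- lapply(keep, function(k) sort(names(ct)[ct == k]))
  mods[order(vapply(mods, `[[`, character(1), 1L))]
}

cut_clusters <- function(C, cut_height, linkage) {
  n <- nrow(C)
  d <- 1 - C
  dv <- d[lower.tri(d)]
  attributes(dv) <- list(Size = n, Labels = rownames(C), Diag = FALSE,
                         Upper = FALSE, method = "user", class = "dist")
  stats::cutree(stats::hclust(dv, method = linkage), h = cut_height)
}

#' Composite index of a candidate module at one timepoint
#'
#' The early-warning statistic `CI = PCC_in * SD_in / max(PCC_out, eps)`:
#' `PCC_in` is the mean absolute Pearson correlation over unordered
#' within-module gene pairs, `PCC_out` the mean absolute correlation over
#' all module x outside pairs, and `SD_in` the mean replicate standard
#' deviation of the module genes, all at timepoint `t`.
#'
#' @param adj an [adjust_to_control()] result.
#' @param module character vector of module gene ids (length >= 2, not all
#'   genes).
#' @param t treated timepoint.
#' @param eps guard for a vanishing `PCC_out` (default 1e-6).
#' @return list of class `dnb_score`: `pcc_in`, `pcc_out`, `sd_in`, `ci`.
#' @export
composite_index <- function(adj, module, t, eps = 1e-6) {
  st <- per_time_stats(adj, t)
  score_module(st$pcc, st$sd, module, eps)
}

score_module <- function(C, sds, module, eps) {
  genes <- rownames(C)
  if (length(module) < 2L) stop("module must have >= 2 genes")
  if (!all(module %in% genes))
    stop("module gene(s) absent from matrix: ",
         paste(setdiff(module, genes), collapse = ", "))
  outside <- setdiff(genes, module)
  if (length(outside) == 0L)
    stop("module spans all genes; PCC_out undefined")
  Cm <- C[module, module, drop = FALSE]
  m <- length(module)
  pcc_in <- (sum(Cm) - m) / (m * (m - 1))
  pcc_out <- mean(C[module, outside, drop = FALSE])
  sd_in <- mean(sds[module])
  structure(list(pcc_in = pcc_in, pcc_out = pcc_out, sd_in = sd_in,
                 ci = pcc_in * sd_in / max(pcc_out, eps)),
            class = "dnb_score")
}

#' @export
print.dnb_score <- function(x, ...) {
  cat(sprintf("dnb_score: PCC_in=%.4f PCC_out=%.4f SD_in=%.4f CI=%.4f\n",
              x$pcc_in, x$pcc_out, x$sd_in, x$ci))
  invisible(x)
}

#' Refine a module by factor-aligned dispersion
#'
#' Estimates the module's collective-fluctuation direction as the leading
#' right singular vector of the row-centred member submatrix at timepoint
#' `t`, scores every gene by its dispersion along that direction
#' (`|x_centred . f| / sqrt(r - 1)`), and returns the genes whose aligned
#' dispersion exceeds `tau` times the median replicate SD of all genes at
#' `t`. This implements, at membership level, the requirement that module
#' members both co-fluctuate and carry inflated variance: a gene merely
#' correlated with the module by chance, but with baseline variance, falls
#' below the threshold.
#'
#' @param adj an [adjust_to_control()] result.
#' @param module seed module (>= 2 genes), e.g. a cluster from
#'   [candidate_modules()].
#' @param t treated timepoint.
#' @param tau aligned-dispersion threshold in units of the background
#'   (median) replicate SD; default 1.4.
#' @return character vector of refined member gene ids (possibly empty).
#' @export
refine_module <- function(adj, module, t, tau = 1.4) {
  stopifnot(inherits(adj, "adjusted_matrix"))
  cols <- adj$sheet$sample_id[adj$sheet$time == t]
  X <- adj$values[, cols, drop = FALSE]
  refine_members(X, module, tau)
}

refine_members <- function(X, module, tau) {
  r <- ncol(X)
  X0 <- X - rowMeans(X)
  f <- svd(X0[module, , drop = FALSE], nu = 0, nv = 1)$v[, 1]
  aligned <- abs(X0 %*% f)[, 1] / sqrt(r - 1)
  bg <- stats::median(sqrt(rowSums(X0^2) / (r - 1)))
  rownames(X)[aligned >= tau * bg]
}

# Evaluate one timepoint: cluster, then score every cluster >= min_size in
# one pass with grouped sums (identical, to rounding, to score_module run
# per cluster; asserted by tests). With refine = TRUE the best cluster is
# refined by factor-aligned dispersion and the refined set kept when it
# improves the CI.
eval_time <- function(X, min_size, cut_height, linkage, eps,
                      refine = FALSE, refine_tau = 1.4) {
  n <- nrow(X)
  sds <- row_sds(X)
  C <- abs_cor(X)
  ct <- cut_clusters(C, cut_height, linkage)
  sizes <- tabulate(ct)
  keep <- which(sizes >= min_size)
  if (!length(keep))
    return(list(ci = 0, module = character(), score = NULL,
                clusters = ct, C = C, sd = sds))
  S1 <- rowsum(C, ct, reorder = TRUE)              # cluster x gene sums
  block <- rowsum(t(S1), ct, reorder = TRUE)       # cluster x cluster sums
  labs <- as.integer(rownames(block))
  m <- sizes[labs]
  within <- diag(block) - m                        # remove self-correlations
  pcc_in <- within / (m * (m - 1))
  cross <- rowSums(block) - diag(block)
  pcc_out <- cross / (m * (n - m))
  sd_in <- as.vector(rowsum(sds, ct, reorder = TRUE)) / m
  ci <- pcc_in * sd_in / pmax(pcc_out, eps)
  ci[m < min_size | m == n] <- -Inf
  if (!any(is.finite(ci)))
    return(list(ci = 0, module = character(), score = NULL,
                clusters = ct, C = C, sd = sds))
  best <- which.max(ci)
  module <- sort(names(ct)[ct == labs[best]])
  score <- structure(list(pcc_in = pcc_in[best], pcc_out = pcc_out[best],
                          sd_in = sd_in[best], ci = ci[best]),
                     class = "dnb_score")
  if (refine) {
    ref <- refine_members(X, module, refine_tau)
    if (length(ref) >= min_size && length(ref) < n) {
      ref_score <- score_module(C, sds, sort(ref), eps)
      if (ref_score$ci > score$ci) {
        module <- sort(ref)
        score <- ref_score
      }
    }
  }
  list(ci = score$ci, module = module, score = score,
       clusters = ct, C = C, sd = sds)
}

permute_rows <- function(X) {
  s <- ncol(X)
  for (g in seq_len(nrow(X))) X[g, ] <- X[g, sample.int(s)]
  X
}

# Reorder each gene's replicates independently within every timepoint
# block: destroys gene-gene co-fluctuation while preserving per-gene,
# per-timepoint marginals (and hence every SD) exactly.
permute_within_times <- function(X, cols) {
  for (cc in cols) {
    Xb <- X[, cc, drop = FALSE]
    X[, cc] <- matrix(Xb[order(row(Xb) + stats::runif(length(Xb)))],
                      nrow(Xb), ncol(Xb), byrow = TRUE)
  }
  X
}

#' Select the dominant DNB module and call the tipping point
#'
#' The full estimator. Per treated timepoint it discovers candidate modules
#' ([candidate_modules()]), scores each with the composite index and keeps
#' the highest-scoring ("dominant") one. The tipping point is the timepoint
#' whose dominant CI is maximal (earliest timepoint on ties), reported only
#' if a permutation test rejects at `alpha`. Each null replicate destroys
#' gene-gene co-fluctuation and recomputes the max-over-timepoints dominant
#' CI; with the default `"within_time"` scheme every gene's replicates are
#' reordered independently within each timepoint, which preserves each
#' gene's per-timepoint marginal distribution (and so every SD) exactly
#' while removing all cross-gene correlation. The alternative
#' `"across_time"` scheme permutes each gene's values across all treated
#' samples; it preserves only the pooled marginal and therefore also
#' redistributes variance structure across timepoints;
#' `p = (1 + #\{null max-CI >= observed max-CI\}) / (N + 1)`. With
#' `early_stop = TRUE` (default) permutation sampling stops as soon as the
#' exceedance count already rules out a call at `alpha` (the sequential
#' Monte-Carlo rule); the call decision is identical to running all `N`
#' permutations.
#'
#' For each timepoint's dominant module the three DNB criteria are evaluated
#' against the mean of the other timepoints: within-module correlation
#' higher, member standard deviation higher, module-outside correlation
#' lower.
#'
#' @param dataset an [expression_dataset()] (counts are log2-converted).
#' @param sheet a [sample_sheet()].
#' @param min_size,cut_height,linkage module discovery tunables; see
#'   [candidate_modules()].
#' @param eps `PCC_out` guard; see [composite_index()].
#' @param n_perm number of permutations (default 200; must be >= 1).
#' @param alpha significance level of the tipping call (default 0.05).
#' @param adjust control-adjustment mode; see [adjust_to_control()].
#' @param universe optional character vector restricting the gene universe
#'   (e.g. to a DEG list).
#' @param seed optional integer seed for the permutation RNG.
#' @param early_stop stop permuting once a call is impossible (default
#'   `TRUE`).
#' @param refine refine each timepoint's best cluster by factor-aligned
#'   dispersion ([refine_module()]), keeping the refined set when it
#'   improves the CI (default `TRUE`).
#' @param refine_tau refinement threshold; see [refine_module()].
#' @param perm_scheme permutation null: `"within_time"` (default) or
#'   `"across_time"`; see Details.
#' @return object of class `dnb_result`; see Details. Key fields:
#'   `table` (per-timepoint statistics and criteria flags), `modules`
#'   (dominant module per timepoint), `tipping_time` (`NA` if not called),
#'   `dnb_genes` (dominant module at the called tipping point),
#'   `p_value`, `n_perm_used`, `config`.
#' @examples
#' sim <- simulate_expression(simulation_design(n_genes = 60, module_size = 8,
#'                                              seed = 7))
#' fit <- select_dnb(sim$dataset, sim$sheet, n_perm = 50, seed = 1)
#' print(fit)
#' @export
select_dnb <- function(dataset, sheet, min_size = 5, cut_height = 0.3,
                       linkage = "average", eps = 1e-6, n_perm = 200,
                       alpha = 0.05, adjust = c("pooled", "time_matched", "none"),
                       universe = NULL, seed = NULL, early_stop = TRUE,
                       refine = TRUE, refine_tau = 1.4,
                       perm_scheme = c("within_time", "across_time")) {
  adjust <- match.arg(adjust)
  perm_scheme <- match.arg(perm_scheme)
  if (n_perm < 1) stop("permutations must be >= 1")
  validate_design(sheet, dataset)
  adj <- adjust_to_control(dataset, sheet, mode = adjust)
  X <- adj$values
  if (!is.null(universe)) {
    universe <- intersect(rownames(X), universe)
    if (length(universe) < 2 * min_size)
      stop("universe too small after intersecting with dataset genes")
    X <- X[universe, , drop = FALSE]
  }
  times <- sort(unique(adj$sheet$time))
  cols <- lapply(times, function(t) which(adj$sheet$time == t))

  obs <- lapply(seq_along(times), function(i)
    eval_time(X[, cols[[i]], drop = FALSE], min_size, cut_height, linkage,
              eps, refine, refine_tau))
  obs_ci <- vapply(obs, `[[`, numeric(1), "ci")
  tip_idx <- which.max(obs_ci)            # first max = earliest tie-break
  obs_max <- obs_ci[tip_idx]

  # permutation null for the max-CI statistic
  if (!is.null(seed)) set.seed(seed)
  k_stop <- if (early_stop) ceiling(alpha * (n_perm + 1)) else Inf
  k <- 0L; b <- 0L
  while (b < n_perm && k < k_stop) {
    b <- b + 1L
    Xp <- if (perm_scheme == "within_time") permute_within_times(X, cols)
          else permute_rows(X)
    null_max <- max(vapply(seq_along(times), function(i)
      eval_time(Xp[, cols[[i]], drop = FALSE], min_size, cut_height,
                linkage, eps, refine, refine_tau)$ci, numeric(1)))
    if (null_max >= obs_max) k <- k + 1L
  }
  p_value <- (1 + k) / (1 + b)
  called <- p_value < alpha && is.finite(obs_max) && obs_max > 0

  # criteria flags: each timepoint's dominant module tracked across times
  flag <- function(i) {
    mod <- obs[[i]]$module
    if (length(mod) < 2) return(c(NA, NA, NA))
    sc <- t(vapply(seq_along(times), function(j) {
      s <- score_module(obs[[j]]$C, obs[[j]]$sd, mod, eps)
      c(s$pcc_in, s$sd_in, s$pcc_out)
    }, numeric(3)))
    other <- colMeans(sc[-i, , drop = FALSE])
    c(sc[i, 1] > other[1], sc[i, 2] > other[2], sc[i, 3] < other[3])
  }
  flags <- t(vapply(seq_along(times), flag, logical(3)))
  colnames(flags) <- c("pcc_in_up", "sd_in_up", "pcc_out_down")

  tab <- data.frame(
    time = times,
    module_size = vapply(obs, function(o) length(o$module), integer(1)),
    pcc_in = vapply(obs, function(o) if (is.null(o$score)) NA_real_ else o$score$pcc_in, numeric(1)),
    pcc_out = vapply(obs, function(o) if (is.null(o$score)) NA_real_ else o$score$pcc_out, numeric(1)),
    sd_in = vapply(obs, function(o) if (is.null(o$score)) NA_real_ else o$score$sd_in, numeric(1)),
    ci = obs_ci)
  tab <- cbind(tab, flags)

  structure(
    list(table = tab,
         modules = stats::setNames(lapply(obs, `[[`, "module"),
                                   paste0("t", times)),
         tipping_time = if (called) times[tip_idx] else NA_integer_,
         tipping_candidate = times[tip_idx],
         dnb_genes = if (called) obs[[tip_idx]]$module else character(),
         p_value = p_value, n_perm = n_perm, n_perm_used = b,
         config = list(min_size = min_size, cut_height = cut_height,
                       linkage = linkage, eps = eps, n_perm = n_perm,
                       alpha = alpha, adjust = adjust, seed = seed,
                       early_stop = early_stop, refine = refine,
                       refine_tau = refine_tau, perm_scheme = perm_scheme)),
    class = "dnb_result")
}

#' @export
print.dnb_result <- function(x, ...) {
  cat("Dynamic network biomarker analysis\n")
  cat(sprintf("  %d treated timepoints; dominant-module CI per timepoint:\n",
              nrow(x$table)))
  print(format(x$table[, c("time", "module_size", "pcc_in", "pcc_out",
                           "sd_in", "ci")], digits = 4), row.names = FALSE)
  if (is.na(x$tipping_time)) {
    cat(sprintf("  no tipping point called (max CI at t=%d, permutation p=%.4g >= alpha)\n",
                x$tipping_candidate, x$p_value))
  } else {
    cat(sprintf("  tipping point: t=%d (permutation p=%.4g, %d permutations), %d DNB genes\n",
                x$tipping_time, x$p_value, x$n_perm_used,
                length(x$dnb_genes)))
  }
  invisible(x)
}

#' @export
summary.dnb_result <- function(object, ...) {
  out <- list(table = object$table, tipping_time = object$tipping_time,
              p_value = object$p_value, n_dnb = length(object$dnb_genes),
              config = object$config)
  class(out) <- "summary.dnb_result"
  out
}

#' @export
print.summary.dnb_result <- function(x, ...) {
  cat("DNB analysis summary\n")
  print(format(x$table, digits = 4), row.names = FALSE)
  cat(sprintf("  tipping: %s  p = %.4g  DNB genes: %d\n",
              ifelse(is.na(x$tipping_time), "not called", x$tipping_time),
              x$p_value, x$n_dnb))
  invisible(x)
}

#' Plot the composite-index profile of a DNB fit
#'
#' CI of the dominant module against time, with the called tipping point
#' highlighted.
#'
#' @param x a `dnb_result`.
#' @param ... passed to [plot()].
#' @export
plot.dnb_result <- function(x, ...) {
  plot(x$table$time, x$table$ci, type = "b", pch = 19,
       xlab = "time", ylab = "composite index (CI)", ...)
  if (!is.na(x$tipping_time)) {
    i <- match(x$tipping_time, x$table$time)
    graphics::points(x$table$time[i], x$table$ci[i], col = 2, cex = 2, lwd = 2)
    graphics::abline(v = x$tipping_time, lty = 2, col = 2)
  }
  invisible(x)
}

#' Per-timepoint replicate dispersion (QC)
#'
#' Mean pairwise Euclidean distance between replicate expression profiles at
#' each treated timepoint. Samples at a low-resilience (pre-transition)
#' state disperse instead of clustering, so a dispersion peak corroborates a
#' tipping call.
#'
#' @param adj an [adjust_to_control()] result.
#' @return data.frame with columns `time`, `n_reps`, `dispersion`.
#' @export
sample_dispersion <- function(adj) {
  stopifnot(inherits(adj, "adjusted_matrix"))
  times <- sort(unique(adj$sheet$time))
  rows <- lapply(times, function(t) {
    cols <- adj$sheet$sample_id[adj$sheet$time == t]
    if (length(cols) < 2L)
      stop("need >= 2 replicates at time ", t)
    D <- stats::dist(t(adj$values[, cols, drop = FALSE]))
    data.frame(time = t, n_reps = length(cols), dispersion = mean(D))
  })
  do.call(rbind, rows)
}
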