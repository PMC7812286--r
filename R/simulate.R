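#' Describe a synthetic time-course design
#'
#' Encodes the study layout the generator emulates: treated animals sampled
#' at five timepoints with five replicates each, controls at three of those
#' timepoints with three replicates, and a planted dynamic-network-biomarker
#' (DNB) module whose within-module correlation and variance rise at exactly
#' one tipping timepoint. Defaults are the package's reference conditions.
#'
#' @param n_genes number of genes.
#' @param module_size size of the planted DNB module.
#' @param treated_times ordered integer treated timepoints (weeks).
#' @param reps_treated treated replicates per timepoint.
#' @param control_times ordered integer control timepoints.
#' @param reps_control control replicates per timepoint.
#' @param tipping_time the planted tipping timepoint; must be one of
#'   `treated_times`.
#' @param rho_in target pairwise correlation of module genes at the tipping
#'   time, in `[0, 1)`.
#' @param var_fold variance inflation (>= 1) of module genes at the tipping
#'   time, relative to the baseline replicate variance.
#' @param rho_bg background correlation shared by non-module cells (default
#'   0; implemented as a weak global factor).
#' @param de_fraction fraction of genes given a post-tipping expression
#'   shift.
#' @param de_log2fc size of that shift in log2 units.
#' @param noise_sd baseline replicate standard deviation, log2 units.
#' @param count_mode if `TRUE`, log2 means are pushed through `2^x` into
#'   negative-binomial sampling.
#' @param dispersion NB dispersion `phi` (variance `mu + phi*mu^2`) used in
#'   count mode.
#' @param module_in_de if `TRUE` the planted DE set starts with the module
#'   genes (module becomes a subset of the DE genes when
#'   `de_fraction * n_genes >= module_size`).
#' @param seed integer RNG seed.
#' @return a list of class `simulation_design`.
#' @export
simulation_design <- function(n_genes = 500, module_size = 20,
                              treated_times = c(3L, 5L, 9L, 14L, 17L),
                              reps_treated = 5, control_times = c(3L, 9L, 17L),
                              reps_control = 3, tipping_time = 9L,
                              rho_in = 0.9, var_fold = 3, rho_bg = 0,
                              de_fraction = 0.1, de_log2fc = 2,
                              noise_sd = 0.5, count_mode = FALSE,
                              dispersion = 0.05, module_in_de = FALSE,
                              seed = 1L) {
  design <- list(n_genes = as.integer(n_genes),
                 module_size = as.integer(module_size),
                 treated_times = as.integer(treated_times),
                 reps_treated = as.integer(reps_treated),
                 control_times = as.integer(control_times),
                 reps_control = as.integer(reps_control),
                 tipping_time = as.integer(tipping_time),
                 rho_in = rho_in, var_fold = var_fold, rho_bg = rho_bg,
                 de_fraction = de_fraction, de_log2fc = de_log2fc,
                 noise_sd = noise_sd, count_mode = isTRUE(count_mode),
                 dispersion = dispersion,
                 module_in_de = isTRUE(module_in_de),
                 seed = as.integer(seed))
  class(design) <- "simulation_design"
  validate_simulation_design(design)
  design
}

validate_simulation_design <- function(d) {
  if (d$module_size >= d$n_genes) stop("module_size must be < n_genes")
  if (!(d$tipping_time %in% d$treated_times))
    stop("tipping_time must be one of treated_times")
  if (is.unsorted(d$treated_times, strictly = TRUE))
    stop("treated_times must be strictly increasing")
  if (d$rho_in < 0 || d$rho_in >= 1)
    stop("infeasible module correlation: need 0 <= rho_in < 1 so the ",
         "single-factor residual variance (1 - rho_in) * var_fold * sigma^2 ",
         "stays positive (loading^2 = rho_in * var_fold * sigma^2)")
  if (d$var_fold < 1) stop("var_fold must be >= 1")
  if (d$rho_bg < 0 || d$rho_bg >= 1) stop("rho_bg must be in [0, 1)")
  if (d$noise_sd <= 0) stop("noise_sd must be > 0")
  if (d$reps_treated < 3) stop("reps_treated must be >= 3")
  invisible(d)
}

#' Simulate a time-course expression experiment with a planted DNB module
#'
#' Per gene g and sample s the log2 value is `mu_g + effect + eps`. Module
#' genes at the tipping time share one latent factor `z ~ N(0,1)` per
#' replicate: `value = mu_g + lambda * z + eps`, with
#' `lambda^2 = rho_in * var_fold * sigma^2` and residual variance
#' `(1 - rho_in) * var_fold * sigma^2`, so the pairwise correlation is
#' `rho_in` and the variance `var_fold * sigma^2` in expectation. All other
#' gene/sample cells are independent `N(mu_g, sigma^2)` apart from an
#' optional weak global factor carrying `rho_bg` (never applied to module
#' genes at the tipping time, so module-outside correlation drops there).
#' Planted DE genes gain `de_log2fc` at treated times after the tipping
#' time; controls always sit at baseline. In count mode the log2 means are
#' mapped through `2^x` into negative-binomial sampling.
#'
#' @param design a [simulation_design()].
#' @return list with `dataset` (an [expression_dataset()]; counts scale in
#'   count mode, log2 otherwise), `sheet` (a [sample_sheet()]) and `truth`
#'   (class `synthetic_truth`: module gene ids, tipping time, DE gene ids,
#'   the design, the seed).
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  validate_simulation_design(design)
  d <- design
  set.seed(d$seed)

  gene_ids <- sprintf("g%0*d", nchar(d$n_genes), seq_len(d$n_genes))
  module <- gene_ids[seq_len(d$module_size)]
  n_de <- round(d$de_fraction * d$n_genes)
  de_idx <- if (d$module_in_de) seq_len(n_de)
            else if (n_de > 0) d$module_size + seq_len(min(n_de, d$n_genes - d$module_size))
            else integer()
  de_genes <- gene_ids[de_idx]

  t_sid <- unlist(lapply(d$treated_times, function(t)
    sprintf("T%02dw_r%d", t, seq_len(d$reps_treated))))
  c_sid <- unlist(lapply(d$control_times, function(t)
    sprintf("C%02dw_r%d", t, seq_len(d$reps_control))))
  sheet <- sample_sheet(
    c(t_sid, c_sid),
    c(rep("treated", length(t_sid)), rep("control", length(c_sid))),
    c(rep(d$treated_times, each = d$reps_treated),
      rep(d$control_times, each = d$reps_control)))
  n_s <- nrow(sheet)

  sigma <- d$noise_sd
  lambda <- sqrt(d$rho_in * d$var_fold) * sigma
  resid_sd_mod <- sqrt((1 - d$rho_in) * d$var_fold) * sigma

  # fixed draw order: baselines, shared factors, then the residual matrix
  mu <- stats::rnorm(d$n_genes, mean = 6, sd = 2)
  z <- stats::rnorm(d$reps_treated)          # module factor at t*
  w <- stats::rnorm(n_s)                     # weak global background factor
  E <- matrix(stats::rnorm(d$n_genes * n_s), d$n_genes, n_s)

  is_tip <- sheet$group == "treated" & sheet$time == d$tipping_time
  mod_rows <- seq_len(d$module_size)

  sd_mat <- matrix(sigma, d$n_genes, n_s)
  X <- mu + 0 * E
  if (d$rho_bg > 0) {
    bg_load <- sqrt(d$rho_bg) * sigma
    X <- X + matrix(w, d$n_genes, n_s, byrow = TRUE) * bg_load
    sd_mat[] <- sqrt(1 - d$rho_bg) * sigma
  }
  # module cells at the tipping time override the background structure
  if (any(is_tip)) {
    X[mod_rows, is_tip] <- mu[mod_rows] +
      matrix(z[seq_len(sum(is_tip))], d$module_size, sum(is_tip),
             byrow = TRUE) * lambda
    sd_mat[mod_rows, is_tip] <- resid_sd_mod
  }
  if (length(de_idx)) {
    late <- sheet$group == "treated" & sheet$time > d$tipping_time
    X[de_idx, late] <- X[de_idx, late] + d$de_log2fc
  }
  X <- X + E * sd_mat
  dimnames(X) <- list(gene_ids, sheet$sample_id)

  if (d$count_mode) {
    mu_count <- 2^X
    counts <- matrix(stats::rnbinom(length(X), mu = mu_count,
                                    size = 1 / d$dispersion),
                     d$n_genes, n_s, dimnames = dimnames(X))
    dataset <- expression_dataset(counts + 0, scale = "counts")
  } else {
    dataset <- expression_dataset(X, scale = "log2")
  }

  truth <- structure(
    list(module = module, tipping_time = d$tipping_time, de_genes = de_genes,
         design = d, seed = d$seed),
    class = "synthetic_truth")
  list(dataset = dataset, sheet = sheet, truth = truth)
}

#' Simulate an interaction network around a planted truth
#'
#' Builds a simple undirected network whose structure is known by
#' construction: each named module gene is linked to a requested number of
#' planted DE genes, plus optional random noise edges.
#'
#' @param truth a `synthetic_truth` from [simulate_expression()].
#' @param n_extra_edges random extra edges among all genes.
#' @param deg_links named integer vector: for each name (a module gene),
#'   how many DE genes to link it to (links are taken in DE-gene order, the
#'   gene itself excluded).
#' @param seed RNG seed for the noise edges.
#' @return an [interaction_network()].
#' @export
simulate_network <- function(truth, n_extra_edges = 0, deg_links = NULL,
                             seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  from <- character(); to <- character()
  if (!is.null(deg_links)) {
    if (is.null(names(deg_links))) stop("deg_links must be named")
    for (g in names(deg_links)) {
      partners <- setdiff(truth$de_genes, g)
      k <- deg_links[[g]]
      if (k > length(partners))
        stop("requested ", k, " DEG links for ", g, " but only ",
             length(partners), " DE genes available")
      from <- c(from, rep(g, k)); to <- c(to, partners[seq_len(k)])
    }
  }
  if (n_extra_edges > 0) {
    genes <- truth$design; all_genes <- sprintf("g%0*d", nchar(genes$n_genes),
                                                seq_len(genes$n_genes))
    n <- length(all_genes)
    capacity <- n * (n - 1) / 2
    existing <- length(from)
    if (n_extra_edges + existing > capacity)
      stop("requested edges exceed simple-graph capacity (", capacity, ")")
    set.seed(seed)
    have <- paste(pmin(from, to), pmax(from, to))
    while (n_extra_edges > 0) {
      a <- all_genes[sample.int(n, n_extra_edges, replace = TRUE)]
      b <- all_genes[sample.int(n, n_extra_edges, replace = TRUE)]
      ok <- a != b
      key <- paste(pmin(a, b), pmax(a, b))
      ok <- ok & !duplicated(key) & !(key %in% have)
      from <- c(from, a[ok]); to <- c(to, b[ok])
      have <- c(have, key[ok])
      n_extra_edges <- n_extra_edges - sum(ok)
    }
  }
  interaction_network(from, to)
}

#' Simulate gene-set collections with known membership multiplicities
#'
#' Builds `n_sets` gene sets in which each named gene appears in exactly the
#' requested number of sets (its first `k` sets in order), so expected
#' pathway-count rankings are computable by construction. Each set is padded
#' with unique filler gene ids to `set_size`.
#'
#' @param truth a `synthetic_truth` (used only for context; fillers avoid
#'   its gene ids).
#' @param n_sets number of sets.
#' @param memberships named integer vector: gene id -> number of sets that
#'   must contain it (each value <= `n_sets`).
#' @param set_size minimum set size after padding.
#' @param prefix id prefix for the generated sets.
#' @return a [gene_set_collection()].
#' @export
simulate_genesets <- function(truth, n_sets, memberships = NULL,
                              set_size = 5, prefix = "set") {
  if (n_sets < 1) stop("n_sets must be >= 1")
  sets <- lapply(seq_len(n_sets), function(i) character())
  if (!is.null(memberships)) {
    if (is.null(names(memberships))) stop("memberships must be named")
    if (any(memberships > n_sets))
      stop("membership multiplicity exceeds n_sets")
    for (g in names(memberships)) {
      k <- memberships[[g]]
      if (k > 0) for (i in seq_len(k)) sets[[i]] <- c(sets[[i]], g)
    }
  }
  sets <- lapply(seq_len(n_sets), function(i) {
    s <- sets[[i]]
    pad <- set_size - length(s)
    if (pad > 0) s <- c(s, sprintf("%s%02d_filler%d", prefix, i, seq_len(pad)))
    s
  })
  names(sets) <- sprintf("%s%02d", prefix, seq_len(n_sets))
  gene_set_collection(sets)
}
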