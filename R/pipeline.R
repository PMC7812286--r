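#' Declarative configuration for a full pipeline run
#'
#' Collects every tunable of every stage with its default. Unknown keys are
#' errors, not warnings, so typos cannot silently fall back to defaults.
#' The single `seed` is expanded deterministically into per-stage seeds.
#'
#' @param ... named overrides of the defaults listed below.
#' @return list of class `pipeline_config`.
#' @section Defaults:
#' Simulation: the reference design of [simulation_design()].
#' DNB: `min_size = 5`, `cut_height = 0.3`, `linkage = "average"`,
#' `eps = 1e-6`, `n_perm = 200`, `alpha = 0.05`, `adjust = "pooled"`,
#' `early_stop = TRUE`, `refine = TRUE`, `refine_tau = 1.4`.
#' DEG: `lfc_threshold = 1`, `fdr_threshold = 0.05`.
#' Ranking fixtures: `n_sets = 6`, `n_extra_edges = 50`.
#' Toggle: `alpha1 = alpha2 = 3`, `beta1 = beta2 = 2`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    # simulation
    n_genes = 500L, module_size = 20L,
    treated_times = c(3L, 5L, 9L, 14L, 17L), reps_treated = 5L,
    control_times = c(3L, 9L, 17L), reps_control = 3L,
    tipping_time = 9L, rho_in = 0.9, var_fold = 3, rho_bg = 0,
    de_fraction = 0.1, de_log2fc = 2, noise_sd = 0.5,
    count_mode = FALSE, dispersion = 0.05, module_in_de = FALSE,
    # dnb
    min_size = 5L, cut_height = 0.3, linkage = "average", eps = 1e-6,
    n_perm = 200L, alpha = 0.05, adjust = "pooled", early_stop = TRUE,
    refine = TRUE, refine_tau = 1.4, perm_scheme = "within_time",
    # deg
    lfc_threshold = 1, fdr_threshold = 0.05,
    # ranking fixtures
    n_sets = 6L, n_extra_edges = 50L,
    # toggle
    alpha1 = 3, alpha2 = 3, beta1 = 2, beta2 = 2)
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("all config overrides must be named")
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    defaults[names(over)] <- over
  }
  cfg <- defaults
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_perm < 1) stop("permutations must be >= 1")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (cfg$min_size < 2) stop("min_size must be >= 2")
  if (cfg$lfc_threshold < 0) stop("lfc_threshold must be >= 0")
  invisible(cfg)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

stage_seed <- function(cfg, offset) (cfg$seed + offset) %% .Machine$integer.max

#' Run the full pipeline: simulate, DNB, DEG, rank, toggle
#'
#' Executes the stages in dependency order on a synthetic dataset drawn
#' from the config's design, aborting with the failing stage named if any
#' stage errors. Returns (and optionally writes) a consolidated report plus
#' a run manifest (config hash, per-stage seeds and wall times, output
#' paths), so a run is reproducible from its manifest alone.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the expression matrix,
#'   sample sheet, CI table, DEG table, ranking and JSON report are written
#'   there.
#' @return list of class `pipeline_run` with elements `manifest` and
#'   `report` (plus the fitted objects in `fits`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(force(expr),
                    error = function(e) stop("pipeline stage '", name,
                                             "' failed: ", conditionMessage(e),
                                             call. = FALSE))
    list(value = val, wall = proc.time()[["elapsed"]] - t0)
  }
  walls <- list()

  s1 <- stage("simulate", {
    design <- simulation_design(
      n_genes = config$n_genes, module_size = config$module_size,
      treated_times = config$treated_times, reps_treated = config$reps_treated,
      control_times = config$control_times, reps_control = config$reps_control,
      tipping_time = config$tipping_time, rho_in = config$rho_in,
      var_fold = config$var_fold, rho_bg = config$rho_bg,
      de_fraction = config$de_fraction, de_log2fc = config$de_log2fc,
      noise_sd = config$noise_sd, count_mode = config$count_mode,
      dispersion = config$dispersion, module_in_de = config$module_in_de,
      seed = stage_seed(config, 0))
    simulate_expression(design)
  })
  sim <- s1$value; walls$simulate <- s1$wall

  s2 <- stage("dnb", select_dnb(
    sim$dataset, sim$sheet, min_size = config$min_size,
    cut_height = config$cut_height, linkage = config$linkage,
    eps = config$eps, n_perm = config$n_perm, alpha = config$alpha,
    adjust = config$adjust, seed = stage_seed(config, 1),
    early_stop = config$early_stop, refine = config$refine,
    refine_tau = config$refine_tau, perm_scheme = config$perm_scheme))
  dnb <- s2$value; walls$dnb <- s2$wall
  t_star <- if (!is.na(dnb$tipping_time)) dnb$tipping_time else
    dnb$tipping_candidate

  s3 <- stage("deg", {
    grp <- samples_before_after(sim$sheet, t_star)
    # if the tipping candidate sits at an extreme timepoint, widen the
    # degenerate side to include the candidate's own samples
    tr <- sim$sheet[sim$sheet$group == "treated", ]
    if (length(grp$after) < 2) grp$after <- tr$sample_id[tr$time >= t_star]
    if (length(grp$before) < 2) grp$before <- tr$sample_id[tr$time <= t_star]
    differential(sim$dataset, sim$sheet, grp$after, grp$before,
                 lfc_threshold = config$lfc_threshold,
                 fdr_threshold = config$fdr_threshold)
  })
  deg <- s3$value; walls$deg <- s3$wall
  inter <- intersect_dnb_deg(deg, dnb$dnb_genes)

  s4 <- stage("rank", {
    rank_genes <- if (length(inter$genes) >= 2) inter$genes else
      if (length(dnb$dnb_genes)) dnb$dnb_genes else sim$truth$module
    n_rank <- length(rank_genes)
    memberships <- stats::setNames(
      ((seq_len(n_rank) - 1L) %% config$n_sets) + 1L, rank_genes)
    sets <- simulate_genesets(sim$truth, n_sets = config$n_sets,
                              memberships = memberships)
    links <- stats::setNames(
      pmin(3L, max(0L, length(sim$truth$de_genes) - 1L)) +
        integer(n_rank), rank_genes)
    network <- simulate_network(sim$truth,
                                n_extra_edges = config$n_extra_edges,
                                deg_links = links,
                                seed = stage_seed(config, 2))
    adj <- adjust_to_control(sim$dataset, sim$sheet, mode = config$adjust)
    ranking <- rank_dnbs(rank_genes, sets, network = network,
                         deg_genes = deg$gene_id[deg$pass],
                         adj = adj, t_star = t_star)
    list(ranking = ranking, network = network, sets = sets)
  })
  ranked <- s4$value; walls$rank <- s4$wall

  s5 <- stage("toggle", {
    model <- toggle_model(config$alpha1, config$alpha2,
                          config$beta1, config$beta2)
    list(fixed_points = fixed_points(model), bistable = is_bistable(model))
  })
  tg <- s5$value; walls$toggle <- s5$wall

  report <- list(
    schema_version = "1.0",
    config = unclass(config),
    truth = list(module = sim$truth$module,
                 tipping_time = sim$truth$tipping_time,
                 n_de = length(sim$truth$de_genes)),
    dnb = list(table = dnb$table, tipping_time = dnb$tipping_time,
               p_value = dnb$p_value, n_perm_used = dnb$n_perm_used,
               dnb_genes = dnb$dnb_genes),
    deg = list(n_tested = nrow(deg), n_pass = sum(deg$pass),
               intersection = inter),
    ranking = ranked$ranking,
    toggle = tg,
    seeds = list(simulate = stage_seed(config, 0), dnb = stage_seed(config, 1),
                 rank = stage_seed(config, 2)))

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths$expression <- file.path(out_dir, "expression.tsv")
    paths$sheet <- file.path(out_dir, "sample_sheet.tsv")
    write_expression(sim$dataset, paths$expression, sim$sheet, paths$sheet)
    paths$ci_table <- file.path(out_dir, "ci_table.tsv")
    utils::write.table(dnb$table, paths$ci_table, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$deg_table <- file.path(out_dir, "deg_table.tsv")
    utils::write.table(deg, paths$deg_table, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$ranking <- file.path(out_dir, "ranking.tsv")
    utils::write.table(ranked$ranking, paths$ranking, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$report <- file.path(out_dir, "report.json")
    write_report(report, paths$report)
  }

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stage_seeds = report$seeds, wall_times = walls,
                   paths = paths, timestamp = format(Sys.time(), tz = "UTC"))
  structure(list(manifest = manifest, report = report,
                 fits = list(dnb = dnb, deg = deg, ranking = ranked$ranking,
                             truth = sim$truth)),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run (config", x$manifest$config_hash, ")\n")
  cat(sprintf("  tipping: %s (p=%.4g), DNB genes: %d, DEGs: %d, intersection: %d\n",
              ifelse(is.na(x$report$dnb$tipping_time), "not called",
                     x$report$dnb$tipping_time),
              x$report$dnb$p_value, length(x$report$dnb$dnb_genes),
              x$report$deg$n_pass, x$report$deg$intersection$n_intersection))
  invisible(x)
}
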