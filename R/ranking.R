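#' Induced subnetwork on a gene set
#'
#' Edges of the network whose two endpoints both belong to `genes`.
#'
#' @param network an [interaction_network()].
#' @param genes character vector of gene ids.
#' @return an [interaction_network()].
#' @export
subnetwork <- function(network, genes) {
  stopifnot(inherits(network, "interaction_network"))
  if (nrow(network) == 0L) return(network)
  g <- as_igraph(network)
  keep <- intersect(igraph::V(g)$name, genes)
  sub <- igraph::induced_subgraph(g, keep)
  el <- igraph::as_edgelist(sub)
  interaction_network(el[, 1], el[, 2])
}

#' Count DEG neighbours of a gene in a network
#'
#' Number of distinct DEG genes directly linked to `gene` (the gene itself
#' excluded). A gene absent from the network has 0 neighbours; a warning is
#' emitted.
#'
#' @param network an [interaction_network()].
#' @param gene one gene id.
#' @param deg_genes character vector of DEG gene ids.
#' @return integer count.
#' @export
linked_deg_count <- function(network, gene, deg_genes) {
  stopifnot(length(gene) == 1L)
  if (nrow(network) == 0L) return(0L)
  g <- as_igraph(network)
  if (!gene %in% igraph::V(g)$name) {
    warning("gene ", gene, " absent from network")
    return(0L)
  }
  nb <- igraph::neighbors(g, gene)$name
  length(intersect(setdiff(unique(nb), gene), deg_genes))
}

#' Hypergeometric over-representation p-value
#'
#' One-sided upper-tail probability of observing at least the query's
#' overlap with a gene set, drawing `|query|` genes without replacement
#' from the universe (Fisher's exact test, one-sided).
#'
#' @param query_genes character vector (must be a subset of `universe`).
#' @param gene_set character vector of set members (clipped to the
#'   universe).
#' @param universe character vector, the gene universe.
#' @return p-value in (0, 1].
#' @export
enrich <- function(query_genes, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query_genes <- unique(query_genes)
  if (!all(query_genes %in% universe))
    stop("query gene(s) outside universe: ",
         paste(setdiff(query_genes, universe), collapse = ", "))
  set_in <- intersect(unique(gene_set), universe)
  k <- length(intersect(query_genes, set_in))
  stats::phyper(k - 1, length(set_in), length(universe) - length(set_in),
                length(query_genes), lower.tail = FALSE)
}

#' Over-representation across a collection, with BH correction
#'
#' @param query_genes character vector of query gene ids.
#' @param collection a [gene_set_collection()].
#' @param universe gene universe.
#' @param p_threshold significance threshold on the raw p (default 0.05).
#' @return data.frame with `set_id`, `overlap`, `set_size`, `p`, `q`,
#'   `significant` (raw `p < p_threshold`).
#' @export
enrich_collection <- function(query_genes, collection, universe,
                              p_threshold = 0.05) {
  ps <- vapply(collection, function(s) enrich(query_genes, s, universe),
               numeric(1))
  overlap <- vapply(collection, function(s)
    length(intersect(unique(query_genes), intersect(s, universe))), integer(1))
  data.frame(set_id = names(collection), overlap = overlap,
             set_size = lengths(collection), p = ps,
             q = stats::p.adjust(ps, "BH"),
             significant = ps < p_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank DNB genes by pathway involvement and DEG connectivity
#'
#' Candidate driver genes are ranked by the total number of supplied
#' (fibrosis-associated) gene sets containing them — counted per set across
#' all collections, so a gene in four sets of one collection and five of
#' another scores nine. Ties are broken by the number of DEGs directly
#' linked in the interaction network (descending), then by gene id. The
#' post-tipping direction of each gene (up/down) is taken from the sign of
#' its mean adjusted expression after minus before the tipping point when
#' an adjusted matrix is supplied.
#'
#' An optional alias map (named character vector, `alias -> canonical`)
#' lets externally annotated paralog conversions be applied to set members
#' before counting.
#'
#' @param dnb_genes character vector of genes to rank.
#' @param collections a [gene_set_collection()] or list of them.
#' @param network optional [interaction_network()].
#' @param deg_genes optional character vector of passing DEG ids.
#' @param adj optional [adjust_to_control()] result for directions.
#' @param t_star optional tipping timepoint (required with `adj`).
#' @param aliases optional named character vector mapping set-member
#'   aliases to canonical gene ids.
#' @param count_mode `"sum"` (default; per-set membership summed across
#'   collections) or `"unique"` (count over the union of distinct set ids).
#' @return data.frame of class `dnb_ranking` with `gene_id`,
#'   `pathway_count`, `linked_deg_count`, `direction`, `rank`, sorted by
#'   rank.
#' @export
rank_dnbs <- function(dnb_genes, collections, network = NULL,
                      deg_genes = character(), adj = NULL, t_star = NULL,
                      aliases = NULL, count_mode = c("sum", "unique")) {
  count_mode <- match.arg(count_mode)
  dnb_genes <- unique(dnb_genes)
  if (inherits(collections, "gene_set_collection"))
    collections <- list(collections)
  apply_alias <- function(members) {
    if (is.null(aliases)) return(members)
    hit <- members %in% names(aliases)
    members[hit] <- aliases[members[hit]]
    members
  }
  count_in <- function(gene) {
    per_col <- vapply(collections, function(col)
      sum(vapply(col, function(s) gene %in% apply_alias(s), logical(1))),
      numeric(1))
    if (count_mode == "sum") sum(per_col)
    else {
      ids <- unlist(lapply(seq_along(collections), function(i)
        paste0(i, ":", names(collections[[i]])[vapply(collections[[i]],
          function(s) gene %in% apply_alias(s), logical(1))])))
      length(unique(ids))
    }
  }
  pathway_count <- vapply(dnb_genes, count_in, numeric(1))
  linked <- if (is.null(network)) rep(0L, length(dnb_genes)) else
    vapply(dnb_genes, function(g)
      suppressWarnings(linked_deg_count(network, g, deg_genes)), integer(1))
  direction <- rep(NA_character_, length(dnb_genes))
  if (!is.null(adj)) {
    if (is.null(t_star)) stop("t_star required to compute directions")
    before <- adj$sheet$sample_id[adj$sheet$time < t_star]
    after <- adj$sheet$sample_id[adj$sheet$time > t_star]
    present <- dnb_genes %in% rownames(adj$values)
    delta <- rowMeans(adj$values[dnb_genes[present], after, drop = FALSE]) -
      rowMeans(adj$values[dnb_genes[present], before, drop = FALSE])
    direction[present] <- ifelse(delta >= 0, "up", "down")
  }
  ord <- order(-pathway_count, -linked, dnb_genes)
  out <- data.frame(gene_id = dnb_genes[ord],
                    pathway_count = pathway_count[ord],
                    linked_deg_count = linked[ord],
                    direction = direction[ord],
                    rank = seq_along(dnb_genes),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("dnb_ranking", "data.frame")
  out
}
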