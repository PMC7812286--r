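#' Read an expression matrix and sample sheet
#'
#' The expression file is TSV/CSV with a header row of sample ids and gene
#' ids in the first column (genes in rows, the dominant transcriptome-matrix
#' layout; use `transpose = TRUE` for samples-in-rows files). The sample
#' sheet is a TSV with columns `sample_id`, `group`, `time`. Counts-scale
#' input is converted to `log2(count + 1)` on ingest so that all downstream
#' statistics operate on a variance-stabilised scale.
#'
#' @param path expression matrix file (TSV or CSV; decided by extension,
#'   `.csv` means comma).
#' @param sample_sheet_path sample sheet TSV.
#' @param scale `"log2"` or `"counts"` — how the file's values are encoded.
#' @param transpose if `TRUE` the file has samples in rows.
#' @param log2_transform convert counts to log2(count+1) (default `TRUE`;
#'   ignored for log2-scale input).
#' @return list with elements `dataset` (an [expression_dataset()], log2
#'   scale unless `log2_transform = FALSE`) and `sheet` (a [sample_sheet()]).
#' @export
read_expression <- function(path, sample_sheet_path, scale = c("log2", "counts"),
                            transpose = FALSE, log2_transform = TRUE) {
  scale <- match.arg(scale)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) == 0L) stop("empty expression matrix: ", path)
  if (!all(vapply(raw, is.numeric, logical(1)))) {
    bad <- names(raw)[!vapply(raw, is.numeric, logical(1))]
    stop("non-numeric expression column(s): ", paste(bad, collapse = ", "))
  }
  m <- as.matrix(raw)
  if (transpose) m <- t(m)
  dataset <- expression_dataset(m, scale = scale)
  if (scale == "counts" && log2_transform) dataset <- as_log2(dataset)
  sheet <- read_sample_sheet(sample_sheet_path)
  missing <- setdiff(dataset$sample_ids, sheet$sample_id)
  if (length(missing))
    stop("unannotated sample(s) in matrix: ", paste(missing, collapse = ", "))
  list(dataset = dataset, sheet = sheet)
}

#' Read a sample sheet TSV
#' @param path TSV with columns `sample_id`, `group`, `time`.
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "time")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  sample_sheet(df$sample_id, df$group, df$time)
}

#' Write an expression dataset (and optionally its sample sheet) to TSV
#' @param dataset an [expression_dataset()].
#' @param path output TSV path (genes in rows).
#' @param sheet optional [sample_sheet()]; written next to `path` when
#'   `sheet_path` given.
#' @param sheet_path optional sample sheet output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(dataset, path, sheet = NULL, sheet_path = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(gene_id = dataset$gene_ids, dataset$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sheet) && !is.null(sheet_path))
    utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `set_id TAB description TAB member...`.
#'
#' @param path GMT file.
#' @return object of class `gene_set_collection`: named list of character
#'   vectors (members), with per-set descriptions in
#'   `attr(, "descriptions")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line(s) (need id, description, >=1 member): line ",
         paste(bad, collapse = ", "))
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate set ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  gene_set_collection(sets, vapply(parts, `[[`, character(1), 2L))
}

#' Construct a gene-set collection
#' @param sets named list of character vectors of member gene ids.
#' @param descriptions optional character vector, one per set.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be uniquely named")
  if (any(lengths(sets) == 0L)) stop("empty gene set(s)")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, median size %d\n",
              length(x), as.integer(stats::median(lengths(x)))))
  invisible(x)
}

#' Write a gene-set collection as GMT
#' @param collection a [gene_set_collection()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(id) {
    paste(c(id, if (nzchar(desc[[id]])) desc[[id]] else "na",
            collection[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-gene interaction network from an edge list
#'
#' Two whitespace/tab-separated gene-id columns, optional third source
#' column. Self-loops are dropped with a warning; duplicate (unordered)
#' edges are collapsed.
#'
#' @param path edge-list file.
#' @param header does the file have a header row?
#' @return an [interaction_network()].
#' @export
read_edgelist <- function(path, header = FALSE) {
  df <- utils::read.table(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("edge list needs at least two columns: ", path)
  interaction_network(df[[1]], df[[2]],
                      source = if (ncol(df) >= 3L) df[[3]] else NULL)
}

#' Construct an interaction network
#'
#' Undirected simple graph over gene ids. Self-loops are removed with a
#' warning; duplicate unordered edges are collapsed (first source tag wins).
#'
#' @param from,to character vectors of gene ids.
#' @param source optional per-edge provenance tag.
#' @return data.frame of class `interaction_network` with columns `from`,
#'   `to` (and `source` if given), `from < to` lexicographically.
#' @export
interaction_network <- function(from = character(), to = character(),
                                source = NULL) {
  from <- as.character(from); to <- as.character(to)
  stopifnot(length(from) == length(to))
  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    from <- from[!loops]; to <- to[!loops]
    if (!is.null(source)) source <- source[!loops]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  out <- data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE)
  if (!is.null(source)) out$source <- as.character(source)[keep]
  class(out) <- c("interaction_network", "data.frame")
  out
}

#' Number of edges in an interaction network
#' @param network an [interaction_network()].
#' @return integer edge count.
#' @export
n_edges <- function(network) nrow(network)

network_genes <- function(network) unique(c(network$from, network$to))

as_igraph <- function(network) {
  igraph::graph_from_data_frame(network[, c("from", "to")], directed = FALSE)
}

#' Write an analysis report as JSON
#'
#' Serialises any result list (CI tables, module members, tipping call,
#' rankings, seeds, config) to pretty-printed JSON at full double precision
#' so that a write/read round trip is lossless.
#'
#' @param result a list (or classed result object coercible to one).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null",
                       force = TRUE)
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#' @param path JSON file.
#' @return a list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
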