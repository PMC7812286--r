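#' Construct an expression dataset
#'
#' Bundles a genes x samples expression matrix with its measurement scale.
#' Matrices on the `"counts"` scale hold non-negative raw counts; matrices on
#' the `"log2"` scale hold log2 expression values. All downstream statistics
#' in this package operate on the log2 scale; see [as_log2()].
#'
#' @param values numeric matrix, genes in rows. Row names are gene ids and
#'   column names are sample ids; both must be present and unique. No missing
#'   values are allowed.
#' @param scale `"log2"` or `"counts"`.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `scale`.
#' @examples
#' m <- matrix(rnorm(12, 6), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' expression_dataset(m)
#' @export
expression_dataset <- function(values, scale = c("log2", "counts")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (length(values) == 0L)
    stop("empty expression matrix")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression matrix contains missing or non-finite values")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("expression matrix must have row names (genes) and column names (samples)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (scale == "counts" && any(values < 0))
    stop("counts-scale matrix contains negative values")
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         scale = scale),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Convert a counts-scale dataset to log2 scale
#'
#' Applies `log2(count + 1)`. Datasets already on the log2 scale are returned
#' unchanged.
#'
#' @param dataset an [expression_dataset()].
#' @return an `expression_dataset` on the `"log2"` scale.
#' @export
as_log2 <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$scale == "log2") return(dataset)
  expression_dataset(log2(dataset$values + 1), scale = "log2")
}

#' Construct and validate a sample sheet
#'
#' The sample sheet annotates every sample with a group (`treated` or
#' `control`) and an integer time label (e.g. weeks on treatment).
#'
#' @param sample_id character vector of unique sample ids.
#' @param group character/factor, `"treated"` or `"control"` per sample.
#' @param time integer time label per sample.
#' @return A `data.frame` of class `sample_sheet` with columns `sample_id`,
#'   `group`, `time`.
#' @export
sample_sheet <- function(sample_id, group, time) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  time <- as.integer(time)
  if (length(sample_id) == 0L) stop("empty sample sheet")
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in sample sheet")
  if (!all(group %in% c("treated", "control")))
    stop("group must be 'treated' or 'control'")
  if (anyNA(time)) stop("non-integer time labels in sample sheet")
  out <- data.frame(sample_id = sample_id, group = group, time = time,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_sheet", "data.frame")
  out
}

#' Validate a sample sheet against a dataset
#'
#' Checks that every matrix sample is annotated exactly once, that treated
#' timepoints form a strictly increasing sequence of length at least 3, and
#' that every treated timepoint has at least 3 replicates (standard
#' deviations and correlations over replicates need >= 3 observations).
#'
#' @param sheet a [sample_sheet()].
#' @param dataset an [expression_dataset()].
#' @return `sheet`, invisibly, if valid; otherwise an error.
#' @export
validate_design <- function(sheet, dataset) {
  stopifnot(inherits(sheet, "data.frame"), inherits(dataset, "expression_dataset"))
  missing <- setdiff(dataset$sample_ids, sheet$sample_id)
  if (length(missing))
    stop("unannotated sample(s) in matrix: ", paste(missing, collapse = ", "))
  tt <- treated_times(sheet)
  if (length(tt) < 3L)
    stop("need >= 3 treated timepoints, got ", length(tt))
  reps <- table(sheet$time[sheet$group == "treated"])
  if (any(reps < 3L))
    stop("every treated timepoint needs >= 3 replicates; offending time(s): ",
         paste(names(reps)[reps < 3L], collapse = ", "))
  invisible(sheet)
}

#' Ordered treated timepoints of a design
#' @param sheet a [sample_sheet()].
#' @return sorted integer vector of unique treated time labels.
#' @export
treated_times <- function(sheet) {
  sort(unique(sheet$time[sheet$group == "treated"]))
}

samples_at <- function(sheet, time, group = "treated") {
  sheet$sample_id[sheet$group == group & sheet$time == time]
}
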