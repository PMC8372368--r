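#' Expression matrix container
#'
#' An expression matrix is a plain numeric matrix with genes in rows and
#' samples in columns, carrying a `scale` attribute that records whether the
#' values are raw counts, median-of-ratios normalized counts, or
#' log2-transformed values. Row and column names are the gene and sample
#' identifiers and must be unique.
#'
#' @param values numeric matrix, genes x samples, with rownames and colnames.
#' @param scale one of `"raw_counts"`, `"normalized_counts"`, `"log2"`.
#' @return the validated matrix with a `scale` attribute.
#' @export
expression_matrix <- function(values,
                              scale = c("raw_counts", "normalized_counts", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  check_unique_ids(rownames(values), "gene")
  check_unique_ids(colnames(values), "sample")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression matrix contains non-finite values")
  if (scale == "raw_counts" && any(values < 0))
    stop("raw counts must be non-negative")
  attr(values, "scale") <- scale
  values
}

#' @rdname expression_matrix
#' @param x an expression matrix.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) stop("matrix has no `scale` attribute; build it with expression_matrix()")
  s
}

check_unique_ids <- function(ids, what) {
  d <- unique(ids[duplicated(ids)])
  if (length(d))
    stop(sprintf("duplicate %s ids: %s", what, paste(d, collapse = ", ")))
  invisible(ids)
}

require_scale <- function(x, scale) {
  if (!identical(expr_scale(x), scale))
    stop(sprintf("expected a %s matrix, got %s", scale, expr_scale(x)))
  invisible(x)
}

#' Clinical table constructor
#'
#' Validates a per-sample clinical data frame. Columns: `sample_id`, `fab`
#' (M1/M2/M4/M5), `eln` (favorable/intermediate/unfavorable), `age` (years),
#' `sex` (female/male), `ahd` (logical), `treatment`, `blast_pct`, and the
#' survival endpoints `os_time`/`os_event`, `efs_time`/`efs_event`,
#' `remdur_time`/`remdur_event` (times in weeks, events 0/1). Missing values
#' are allowed everywhere except `sample_id` and are excluded listwise per
#' analysis, never imputed.
#'
#' @param df data frame with the columns above (extra columns are kept).
#' @return the validated data frame, classed `clinical_table`.
#' @export
clinical_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"sample_id" %in% names(df)) stop("clinical table needs a sample_id column")
  check_unique_ids(df$sample_id, "sample")
  if ("fab" %in% names(df)) {
    bad <- setdiff(stats::na.omit(unique(df$fab)), c("M1", "M2", "M4", "M5"))
    if (length(bad))
      stop("unknown FAB level(s): ", paste(bad, collapse = ", "),
           " (cohort restricted to M1/M2/M4/M5)")
  }
  if ("eln" %in% names(df)) {
    bad <- setdiff(stats::na.omit(unique(df$eln)),
                   c("favorable", "intermediate", "unfavorable"))
    if (length(bad)) stop("unknown ELN level(s): ", paste(bad, collapse = ", "))
  }
  for (ep in c("os", "efs", "remdur")) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    if (tcol %in% names(df)) {
      tt <- df[[tcol]]
      if (any(tt < 0, na.rm = TRUE)) stop("negative ", tcol)
    }
    if (ecol %in% names(df)) {
      ee <- df[[ecol]]
      if (!all(ee %in% c(0, 1, NA))) stop(ecol, " must be 0/1")
    }
  }
  class(df) <- c("clinical_table", class(df))
  df
}

#' Lineage binning of FAB labels
#'
#' Collapses the four FAB levels to the two morphologic lineages used
#' throughout: M1/M2 versus M4/M5.
#'
#' @param fab character vector of FAB labels.
#' @return factor with levels `"M1/M2"`, `"M4/M5"`.
#' @export
fab_lineage <- function(fab) {
  out <- ifelse(fab %in% c("M1", "M2"), "M1/M2",
                ifelse(fab %in% c("M4", "M5"), "M4/M5", NA))
  factor(out, levels = c("M1/M2", "M4/M5"))
}

#' Gene set collection constructor
#'
#' @param sets named list of character vectors of gene ids.
#' @param descriptions optional named character vector of set descriptions.
#' @return named list classed `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets))
  if (length(sets)) {
    if (is.null(names(sets)) || any(names(sets) == ""))
      stop("all gene sets must be named")
    check_unique_ids(names(sets), "gene set")
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  attr(sets, "descriptions") <- descriptions
  class(sets) <- "gene_set_collection"
  sets
}

#' Restrict a gene set collection to a gene universe
#'
#' Intersects each set with `universe`; sets that become empty are dropped
#' with a warning naming them.
#'
#' @param collection a `gene_set_collection`.
#' @param universe character vector of available gene ids.
#' @export
restrict_gene_sets <- function(collection, universe) {
  out <- lapply(unclass(collection), intersect, y = universe)
  empty <- names(out)[lengths(out) == 0]
  if (length(empty))
    warning("gene set(s) empty after restriction: ", paste(empty, collapse = ", "))
  gene_set_collection(out[lengths(out) > 0])
}

#' Mutation matrix constructor (genes x samples, entries 0/1)
#' @param calls numeric/logical matrix coercible to 0/1, with dimnames.
#' @return integer matrix of 0/1.
#' @export
mutation_matrix <- function(calls) {
  if (is.logical(calls)) calls[] <- as.integer(calls)
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("mutation matrix needs gene rownames and sample colnames")
  check_unique_ids(rownames(calls), "gene")
  check_unique_ids(colnames(calls), "sample")
  if (anyNA(calls) || !all(calls %in% c(0, 1)))
    stop("mutation calls must be binary 0/1")
  storage.mode(calls) <- "integer"
  calls
}

#' Protein (RPPA) matrix constructor (proteins x samples)
#' @param values numeric matrix with dimnames; all entries finite.
#' @export
protein_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) stop("`values` must be numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("protein matrix needs protein rownames and sample colnames")
  check_unique_ids(rownames(values), "protein")
  check_unique_ids(colnames(values), "sample")
  if (anyNA(values) || any(!is.finite(values)))
    stop("protein matrix contains non-finite values")
  values
}
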