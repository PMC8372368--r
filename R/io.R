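#' Read an expression matrix
#'
#' Supports dense TSV/CSV (gene ids in the first column, sample ids in the
#' header) and MatrixMarket-style sparse triplets. For `mtx_triplet`, the
#' matrix file is accompanied by `<path>.genes` and `<path>.samples` index
#' files with one id per line; entries absent from the triplet are zero.
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"csv"`, `"mtx_triplet"`.
#' @param scale declared scale of the values (default raw counts).
#' @param transpose set TRUE when the file has samples in rows.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, format = c("tsv", "csv", "mtx_triplet"),
                                   scale = "raw_counts", transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "mtx_triplet") {
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(paste0(path, ".genes"))
    samples <- readLines(paste0(path, ".samples"))
    if (nrow(m) != length(genes) || ncol(m) != length(samples))
      stop("index files do not match matrix dimensions")
    dimnames(m) <- list(genes, samples)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                            colClasses = "character", quote = "")
    ids <- df[[1]]
    check_unique_ids(ids, "gene")
    m <- as.matrix(df[-1])
    suppressWarnings(storage.mode(m) <- "double")
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                   ids[bad[1]], colnames(m)[bad[2]]))
    }
    rownames(m) <- ids
  }
  if (transpose) m <- t(m)
  expression_matrix(m, scale = scale)
}

#' Write an expression matrix as TSV (genes in rows)
#' @param x expression matrix.
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are deduplicated with a warning; duplicate set names
#' and lines with fewer than three fields are errors.
#'
#' @param path GMT file path.
#' @return a [gene_set_collection()].
#' @export
read_gene_sets_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line(s) with fewer than 3 fields: line ", paste(short, collapse = ", "))
  nm <- vapply(fields, `[[`, "", 1)
  check_unique_ids(nm, "gene set")
  desc <- vapply(fields, `[[`, "", 2)
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- vapply(sets, function(g) length(g) - length(unique(g)), 0L)
  if (any(ndup > 0))
    warning("deduplicated genes within set(s): ",
            paste(nm[ndup > 0], collapse = ", "))
  names(sets) <- nm
  names(desc) <- nm
  gene_set_collection(sets, descriptions = desc)
}

#' Write a gene set collection as GMT
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @export
write_gene_sets_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read the clinical table (CSV)
#'
#' Empty cells are read as missing and preserved (per-analysis listwise
#' exclusion downstream, no imputation). Survival times are in weeks.
#'
#' @param path CSV path.
#' @return a [clinical_table()].
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if ("ahd" %in% names(df) && !is.logical(df$ahd))
    df$ahd <- as.logical(df$ahd)
  clinical_table(df)
}

#' Write a clinical table as CSV
#' @param df clinical table.
#' @param path output path.
#' @export
write_clinical_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Per-variable missingness report
#' @param df clinical table.
#' @return data.frame with columns variable, n_missing.
#' @export
missingness_report <- function(df) {
  data.frame(variable = names(df),
             n_missing = vapply(df, function(x) sum(is.na(x)), 0L),
             row.names = NULL)
}

#' Read mutation, protein and (optional) drug-response tables
#'
#' The mutation TSV holds genes x samples entries coercible to 0/1
#' (0/1, TRUE/FALSE); the protein TSV holds finite continuous values;
#' the drug CSV needs columns `cell_line`, `drug`, `auc`. Intersection sizes
#' of the sample universes are reported via message().
#'
#' @param mutation_path,protein_path TSV paths (genes/proteins in rows).
#' @param drug_path optional CSV path.
#' @return list with elements `mutations`, `proteins`, `drug` (NULL if absent).
#' @export
read_omics_tables <- function(mutation_path, protein_path, drug_path = NULL) {
  mraw <- utils::read.table(mutation_path, header = TRUE, sep = "\t",
                            check.names = FALSE, row.names = 1)
  m <- as.matrix(mraw)
  if (is.character(m)) {
    up <- toupper(m)
    m2 <- ifelse(up %in% c("TRUE", "1"), 1L, ifelse(up %in% c("FALSE", "0"), 0L, NA))
    dim(m2) <- dim(m); dimnames(m2) <- dimnames(m); m <- m2
  }
  if (anyNA(m) || !all(m %in% c(0, 1)))
    stop("mutation entries must be coercible to 0/1")
  muts <- mutation_matrix(m)
  praw <- utils::read.table(protein_path, header = TRUE, sep = "\t",
                            check.names = FALSE, row.names = 1)
  prot <- protein_matrix(as.matrix(praw))
  drug <- NULL
  if (!is.null(drug_path)) {
    drug <- utils::read.csv(drug_path, check.names = FALSE)
    need <- c("cell_line", "drug", "auc")
    miss <- setdiff(need, names(drug))
    if (length(miss))
      stop("drug table missing required column(s): ", paste(miss, collapse = ", "),
           " (required: ", paste(need, collapse = ", "), ")")
  }
  message(sprintf("mutation/protein shared samples: %d",
                  length(intersect(colnames(muts), colnames(prot)))))
  list(mutations = muts, proteins = prot, drug = drug)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths derive from the merge heights of the hclust tree.
#'
#' @param hc an `hclust` object.
#' @param path optional path; if given the tree is written there.
#' @return the Newick string, invisibly when writing to file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
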