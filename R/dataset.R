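#' Expression dataset container
#'
#' Bundles a genes x samples matrix of log2 expression values with a
#' sample-to-condition annotation and a designated reference ("normal")
#' condition. All downstream stages consume this container.
#'
#' @param matrix numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). No missing values.
#' @param condition_of named character vector mapping every sample id to a
#'   condition label.
#' @param normal_label condition label treated as the reference.
#' @return An object of class `expression_dataset` with elements `matrix`,
#'   `condition_of`, `normal_label`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ann <- setNames(c("normal", "normal", "dz", "dz"), colnames(m))
#' ds <- expression_dataset(m, ann, "normal")
#' conditions(ds)
#' @export
expression_dataset <- function(matrix, condition_of, normal_label) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix")
  gid <- rownames(matrix); sid <- colnames(matrix)
  if (is.null(gid) || is.null(sid))
    stop("matrix must have gene rownames and sample colnames")
  if (anyDuplicated(gid))
    stop("duplicate gene id: ", gid[duplicated(gid)][1L])
  if (anyDuplicated(sid))
    stop("duplicate sample id: ", sid[duplicated(sid)][1L])
  bad <- which(!is.finite(matrix), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite expression value for gene '%s' in sample '%s'",
                 gid[bad[1, 1]], sid[bad[1, 2]]))
  extra <- setdiff(names(condition_of), sid)
  if (length(extra) > 0)
    stop("annotation sample(s) not in matrix: ",
         paste(extra, collapse = ", "))
  missing_ann <- setdiff(sid, names(condition_of))
  if (length(missing_ann) > 0)
    stop("sample(s) without condition annotation: ",
         paste(missing_ann, collapse = ", "))
  condition_of <- condition_of[sid]
  if (!normal_label %in% condition_of)
    stop("normal_label '", normal_label, "' absent from conditions")
  tab <- table(condition_of)
  if (any(tab < 2))
    stop("condition(s) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  structure(list(matrix = matrix,
                 condition_of = condition_of,
                 normal_label = normal_label),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$condition_of)
  cat(sprintf("expression_dataset: %d genes x %d samples\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("conditions (normal = '%s'):\n", x$normal_label))
  for (cn in names(tab)) cat(sprintf("  %s: %d samples\n", cn, tab[[cn]]))
  invisible(x)
}

#' Condition labels of a dataset
#' @param dataset an `expression_dataset`.
#' @return character vector of distinct condition labels, normal first.
#' @export
conditions <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  lv <- unique(dataset$condition_of)
  c(dataset$normal_label, setdiff(lv, dataset$normal_label))
}

#' Sample ids belonging to given conditions
#' @param dataset an `expression_dataset`.
#' @param labels condition labels to keep.
#' @return character vector of sample ids.
#' @export
samples_of <- function(dataset, labels) {
  names(dataset$condition_of)[dataset$condition_of %in% labels]
}

#' Restrict a dataset to the normal condition plus one disease condition
#' @param dataset an `expression_dataset`.
#' @param condition a non-normal condition label present in the dataset.
#' @return an `expression_dataset` over the subset of samples.
#' @export
subset_condition_pair <- function(dataset, condition) {
  if (identical(condition, dataset$normal_label))
    stop("condition must differ from the normal label")
  if (!condition %in% dataset$condition_of)
    stop("condition '", condition, "' not present in dataset")
  keep <- samples_of(dataset, c(dataset$normal_label, condition))
  expression_dataset(dataset$matrix[, keep, drop = FALSE],
                     dataset$condition_of[keep],
                     dataset$normal_label)
}

#' Read an expression dataset from TSV files
#'
#' The matrix file is tab-separated with a header row of sample ids and gene
#' ids in the first column; the annotation file has columns `sample_id` and
#' `condition`. Samples present in the matrix but absent from the annotation
#' (or vice versa) are an error, never silently dropped.
#'
#' @param matrix_path path to the expression TSV.
#' @param annotation_path path to the sample annotation TSV.
#' @param normal_label condition treated as the reference.
#' @return an `expression_dataset`.
#' @export
read_expression_dataset <- function(matrix_path, annotation_path, normal_label) {
  df <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  gid <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(m), nrow(m)))) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric cell for gene '%s' in sample '%s'",
                   gid[bad[1, 1]], colnames(m)[bad[1, 2]]))
    storage.mode(m) <- "double"
  }
  rownames(m) <- gid
  ann <- utils::read.delim(annotation_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns sample_id and condition")
  condition_of <- stats::setNames(as.character(ann$condition),
                                  as.character(ann$sample_id))
  expression_dataset(m, condition_of, normal_label)
}

#' Write an expression dataset to TSV files
#'
#' Values are written with 17 significant digits so a read/write round trip
#' reproduces the matrix to full double precision.
#'
#' @param dataset an `expression_dataset`.
#' @param matrix_path,annotation_path output paths.
#' @return invisibly, the two paths.
#' @export
write_expression_dataset <- function(dataset, matrix_path, annotation_path) {
  m <- dataset$matrix
  txt <- apply(m, 2L, function(col) sprintf("%.17g", col))
  out <- cbind(gene_id = rownames(m), txt)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  ann <- data.frame(sample_id = names(dataset$condition_of),
                    condition = unname(dataset$condition_of))
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(c(matrix_path, annotation_path))
}

#' Read a candidate-regulator (TF) list
#'
#' One gene id per line; `#` starts a comment. Returns the ids measured in
#' the dataset; unmeasured ids are reported via a message, not an error —
#' merged TF lists routinely contain genes absent from any one platform.
#'
#' @param path path to the TF list file.
#' @param dataset an `expression_dataset` supplying the measured gene universe.
#' @return character vector of TF ids present in the dataset.
#' @export
read_tf_list <- function(path, dataset) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  ids <- unique(trimws(lines))
  ids <- ids[nzchar(ids)]
  found <- intersect(ids, rownames(dataset$matrix))
  n_missing <- length(ids) - length(found)
  if (n_missing > 0)
    message(n_missing, " TF id(s) not measured in the dataset; dropped")
  if (length(found) == 0)
    stop("no TF in the list is measured in the dataset")
  found
}
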