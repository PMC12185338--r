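## Readers and writers for the plain-text interchange formats.
##
## On disk, object and dimension indices are 0-based (the convention shared
## with the wider ecosystem of triplet-behaviour tooling); inside R everything
## is 1-based. The converters below are the only place the offset is applied.

#' Read / write a feature matrix
#'
#' Features are stored as headerless tab-separated numeric text, one object
#' per row, with an optional companion file of object identifiers (one per
#' line) at `<path>.ids`.
#'
#' @param path File path.
#' @return `read_features()`: a numeric matrix with object ids as row names
#'   when the companion file exists.
#' @export
read_features <- function(path) {
  x <- as.matrix(read.delim(path, header = FALSE))
  dimnames(x) <- NULL
  ids_path <- paste0(path, ".ids")
  if (file.exists(ids_path)) {
    ids <- readLines(ids_path)
    if (length(ids) != nrow(x)) stop("object id file does not match feature rows")
    rownames(x) <- ids
  }
  x
}

#' @rdname read_features
#' @param x Numeric matrix (objects in rows).
#' @export
write_features <- function(x, path) {
  write.table(x, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  if (!is.null(rownames(x))) writeLines(rownames(x), paste0(path, ".ids"))
  invisible(path)
}

#' Read / write triplet files
#'
#' Triplet choice files are tab-separated with header `i j k odd`, 0-based
#' indices, one trial per line, triplets in canonical sorted order. A bare
#' triplet file (no choices) has columns `i j k` only.
#'
#' @param path File path.
#' @return `read_triplets()`: a `data.frame` with 1-based columns `i`, `j`,
#'   `k` and, when present in the file, `odd`.
#' @export
read_triplets <- function(path) {
  x <- read.delim(path, header = TRUE)
  keep <- intersect(c("i", "j", "k", "odd"), names(x))
  if (!all(c("i", "j", "k") %in% keep)) stop("triplet file must have columns i, j, k")
  x <- x[, keep, drop = FALSE]
  x[] <- lapply(x, function(v) as.integer(v) + 1L)
  if ("odd" %in% names(x)) validate_triplet_dataset(x)
  x
}

#' @rdname read_triplets
#' @param data Triplet `data.frame` (1-based), with or without an `odd` column.
#' @export
write_triplets <- function(data, path) {
  out <- data[, intersect(c("i", "j", "k", "odd"), names(data)), drop = FALSE]
  out[] <- lapply(out, function(v) as.integer(v) - 1L)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a point embedding
#'
#' Embeddings are tab-separated with a header row of dimension ids, one object
#' per row, preceded by an `object_id` column.
#'
#' @param path File path.
#' @return `read_embedding()`: a non-negative numeric matrix with object ids
#'   as row names and dimension ids as column names.
#' @export
read_embedding <- function(path) {
  x <- read.delim(path, header = TRUE, check.names = FALSE)
  ids <- x[[1]]
  x <- as.matrix(x[, -1, drop = FALSE])
  rownames(x) <- as.character(ids)
  x
}

#' @rdname read_embedding
#' @param emb Numeric matrix, objects in rows.
#' @export
write_embedding <- function(emb, path) {
  if (is.null(rownames(emb))) rownames(emb) <- default_object_ids(nrow(emb))
  if (is.null(colnames(emb))) colnames(emb) <- default_dim_ids(ncol(emb))
  out <- data.frame(object_id = rownames(emb), emb, check.names = FALSE)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a representational similarity matrix
#'
#' Square tab-separated matrix with object ids as header.
#' @param path File path.
#' @export
read_rsm <- function(path) {
  x <- read.delim(path, header = TRUE, check.names = FALSE)
  x <- as.matrix(x)
  rownames(x) <- colnames(x)
  x
}

#' @rdname read_rsm
#' @param rsm Symmetric numeric matrix.
#' @export
write_rsm <- function(rsm, path) {
  if (is.null(colnames(rsm))) colnames(rsm) <- default_object_ids(ncol(rsm))
  write.table(rsm, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_object_ids <- function(m) sprintf("obj_%04d", seq_len(m))
default_dim_ids <- function(k) sprintf("dim_%03d", seq_len(k))
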