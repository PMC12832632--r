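# Plain-text on-disk exchange formats: MTX expression matrices with TSV
# sidecars for genes and cell annotations.

#' Write an expression section as MTX + TSV
#'
#' Emits `matrix.mtx` (cell x gene sparse MatrixMarket), `genes.tsv`
#' (gene_id, raw_name), and `cells.tsv` (cell_id, celltype, x, y,
#' condition).
#'
#' @param section an [new_expression_section()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_section <- function(section, dir) {
  stopifnot(inherits(section, "expression_section"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(section$expr, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  write_tsv_file(section$genes, file.path(dir, "genes.tsv"))
  cells <- section$cells
  cells$condition <- section$condition
  write_tsv_file(cells[, c("cell_id", "celltype", "x", "y", "condition")],
                 file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read an expression section written by [write_section()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return An [new_expression_section()].
#' @export
read_section <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  cells <- read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  dimnames(m) <- list(cells$cell_id, genes$gene_id)
  new_expression_section(m, cells, unique(cells$condition)[1], genes)
}

#' Write a metacell matrix as MTX + TSV
#'
#' Members are serialized as comma-joined cell ids.
#'
#' @param m a [new_metacell_matrix()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_metacells <- function(m, dir) {
  stopifnot(inherits(m, "metacell_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE),
                  file.path(dir, "metacells.mtx"))
  write_tsv_file(data.frame(gene_id = colnames(m$values)),
                 file.path(dir, "genes.tsv"))
  write_tsv_file(data.frame(
    metacell_id = rownames(m$values) %||% sprintf("mc%03d", seq_len(nrow(m$values))),
    group = m$group,
    source_section = m$source_section,
    members = vapply(m$members, paste, character(1), collapse = ",")),
    file.path(dir, "metacell_info.tsv"))
  invisible(dir)
}

#' Read a metacell matrix written by [write_metacells()]
#'
#' @param dir directory containing `metacells.mtx`, `genes.tsv`,
#'   `metacell_info.tsv`.
#' @return A [new_metacell_matrix()].
#' @export
read_metacells <- function(dir) {
  v <- as.matrix(Matrix::readMM(file.path(dir, "metacells.mtx")))
  genes <- read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  info <- read.delim(file.path(dir, "metacell_info.tsv"),
                     stringsAsFactors = FALSE)
  dimnames(v) <- list(info$metacell_id, genes$gene_id)
  new_metacell_matrix(v, strsplit(info$members, ",", fixed = TRUE),
                      info$group, unique(info$source_section)[1])
}
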