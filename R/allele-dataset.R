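#' Allele-resolved single-nucleus count dataset
#'
#' An `allele_dataset` bundles two parallel cells-by-genes sparse count
#' matrices — reads assigned to the active-X (reference, *M. musculus*) strain
#' genome and reads assigned to the inactive-X (alternate, *M. castaneus*)
#' strain genome — together with cell metadata and gene annotation. It is the
#' sole input of the escape-calling and differential-expression pipeline.
#'
#' @param counts_xa cells-by-genes matrix of reads assigned to the active-X
#'   strain genome (coercible to a sparse `dgCMatrix`); entries are
#'   non-negative integers.
#' @param counts_xi cells-by-genes matrix of reads assigned to the inactive-X
#'   strain genome; same dimensions and ordering as `counts_xa`.
#' @param cells data.frame with columns `barcode`, `cell_type`, `sample_id`,
#'   `age_group` (values `"young"`/`"old"`); one row per matrix row.
#' @param genes data.frame with columns `gene_id`, `chromosome` (autosome
#'   name or `"X"`); one row per matrix column.
#' @return An object of class `allele_dataset`.
#' @seealso [read_allele_dataset()], [write_allele_dataset()],
#'   [validate_allele_dataset()]
#' @export
allele_dataset <- function(counts_xa, counts_xi, cells, genes) {
  counts_xa <- methods::as(methods::as(counts_xa, "CsparseMatrix"), "generalMatrix")
  counts_xi <- methods::as(methods::as(counts_xi, "CsparseMatrix"), "generalMatrix")
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need_c <- c("barcode", "cell_type", "sample_id", "age_group")
  if (!all(need_c %in% names(cells)))
    stop("cells metadata must have columns: ", paste(need_c, collapse = ", "))
  need_g <- c("gene_id", "chromosome")
  if (!all(need_g %in% names(genes)))
    stop("gene annotation must have columns: ", paste(need_g, collapse = ", "))
  if (!all(dim(counts_xa) == dim(counts_xi)))
    stop("inconsistent bundle: allele matrices have different dimensions (",
         paste(dim(counts_xa), collapse = "x"), " vs ",
         paste(dim(counts_xi), collapse = "x"), ")")
  if (nrow(counts_xa) != nrow(cells))
    stop("inconsistent bundle: ", nrow(counts_xa), " matrix rows but ",
         nrow(cells), " cell metadata rows")
  if (ncol(counts_xa) != nrow(genes))
    stop("inconsistent bundle: ", ncol(counts_xa), " matrix columns but ",
         nrow(genes), " gene annotation rows")
  dimnames(counts_xa) <- list(cells$barcode, genes$gene_id)
  dimnames(counts_xi) <- list(cells$barcode, genes$gene_id)
  structure(
    list(xa = counts_xa, xi = counts_xi,
         cells = cells[need_c], genes = genes[need_g]),
    class = "allele_dataset"
  )
}

#' @export
dim.allele_dataset <- function(x) dim(x$xa)

#' @export
print.allele_dataset <- function(x, ...) {
  cat("allele_dataset:", nrow(x$cells), "cells x", nrow(x$genes), "genes\n")
  cat("  X-linked genes:", sum(x$genes$chromosome == "X"),
      "| autosomal genes:", sum(x$genes$chromosome != "X"), "\n")
  cat("  assigned reads: xa-strain", sum(x$xa), "| xi-strain", sum(x$xi), "\n")
  cat("  cell types:", paste(sort(unique(x$cells$cell_type)), collapse = ", "), "\n")
  tab <- table(x$cells$age_group)
  cat("  age groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Validate an allele dataset against its structural invariants
#'
#' Checks non-negativity of both count matrices, uniqueness of barcodes and
#' gene ids, completeness of metadata labels, membership of `age_group` in
#' `{young, old}`, and that each `sample_id` maps to exactly one age group.
#'
#' @param ds an [allele_dataset()].
#' @return A data.frame report with columns `invariant`, `index`, `message`;
#'   zero rows when all invariants hold.
#' @export
validate_allele_dataset <- function(ds) {
  bad <- list()
  add <- function(invariant, index, message)
    bad[[length(bad) + 1L]] <<- data.frame(
      invariant = invariant, index = as.character(index),
      message = message, stringsAsFactors = FALSE)

  for (al in c("xa", "xi")) {
    m <- ds[[al]]
    neg <- which(m@x < 0)
    if (length(neg))
      add("negative count", paste0(al, ":", neg[1L]),
          paste0("matrix '", al, "' contains ", length(neg), " negative entries"))
  }
  dup <- duplicated(ds$cells$barcode)
  if (any(dup)) add("duplicate barcode", which(dup)[1L], "cell barcodes must be unique")
  dup <- duplicated(ds$genes$gene_id)
  if (any(dup)) add("duplicate gene_id", which(dup)[1L], "gene ids must be unique")
  emp <- which(is.na(ds$genes$chromosome) | ds$genes$chromosome == "")
  if (length(emp)) add("empty chromosome", emp[1L], "chromosome labels must be nonempty")
  for (col in c("cell_type", "sample_id", "age_group")) {
    miss <- which(is.na(ds$cells[[col]]) | ds$cells[[col]] == "")
    if (length(miss))
      add("missing cell label", miss[1L], paste0("cells lack a '", col, "' label"))
  }
  badage <- which(!ds$cells$age_group %in% c("young", "old"))
  if (length(badage))
    add("invalid age_group", badage[1L], "age_group must be 'young' or 'old'")
  map <- unique(ds$cells[c("sample_id", "age_group")])
  dup <- duplicated(map$sample_id)
  if (any(dup))
    add("sample/age inconsistency", map$sample_id[dup][1L],
        "a sample_id maps to more than one age group")
  if (nrow(ds$genes) > 0 && !any(ds$genes$chromosome == "X"))
    add("no X genes", NA, "at least one X-linked gene is required for escape analysis")
  if (nrow(ds$genes) > 0 && !any(ds$genes$chromosome != "X"))
    add("no autosomal genes", NA, "at least one autosomal gene is required for bias correction")

  if (length(bad)) do.call(rbind, bad)
  else data.frame(invariant = character(), index = character(),
                  message = character(), stringsAsFactors = FALSE)
}

# Minimal Matrix Market writer: coordinate integer field plus an orientation
# comment, neither of which Matrix::writeMM emits. Entries are written in
# column-major order so output is deterministic.
write_mm_integer <- function(m, path, orientation = "genes x cells") {
  tm <- methods::as(m, "TsparseMatrix")
  ord <- order(tm@j, tm@i)
  lines <- c(
    "%%MatrixMarket matrix coordinate integer general",
    paste0("% orientation: ", orientation),
    paste(nrow(m), ncol(m), length(tm@x)),
    if (length(tm@x)) sprintf("%d %d %d", tm@i[ord] + 1L, tm@j[ord] + 1L,
                              as.integer(round(tm@x[ord])))
  )
  writeLines(lines, path)
}

read_mm_oriented <- function(path) {
  m <- methods::as(methods::as(Matrix::readMM(path), "CsparseMatrix"),
                   "generalMatrix")
  hdr <- readLines(path, n = 5L)
  cells_first <- any(grepl("orientation:\\s*cells\\s*x\\s*genes", hdr))
  if (cells_first) m else Matrix::t(m)
}

bundle_files <- c(xa = "xa_strain.mtx", xi = "xi_strain.mtx",
                  cells = "cells.tsv", genes = "genes.tsv")

#' Write an allele dataset to a plain-text bundle directory
#'
#' The bundle holds `xa_strain.mtx` and `xi_strain.mtx` (Matrix Market
#' coordinate integer format, stored genes-by-cells with the orientation
#' recorded in a header comment), `cells.tsv` and `genes.tsv`. Writing is
#' deterministic: the same dataset always produces byte-identical files.
#'
#' @param ds an [allele_dataset()].
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_allele_dataset <- function(ds, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create bundle directory: ", path)
  write_mm_integer(Matrix::t(ds$xa), file.path(path, bundle_files["xa"]))
  write_mm_integer(Matrix::t(ds$xi), file.path(path, bundle_files["xi"]))
  utils::write.table(ds$cells, file.path(path, bundle_files["cells"]),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$genes, file.path(path, bundle_files["genes"]),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele dataset bundle
#'
#' Inverse of [write_allele_dataset()]. Matrices are re-oriented to
#' cells-by-genes regardless of stored orientation (taken from the `%
#' orientation:` header comment; genes-by-cells is assumed when absent).
#'
#' @param path bundle directory produced by [write_allele_dataset()].
#' @return An [allele_dataset()].
#' @export
read_allele_dataset <- function(path) {
  for (f in bundle_files) {
    if (!file.exists(file.path(path, f)))
      stop("missing component: ", f, " not found in bundle ", path)
  }
  xa <- read_mm_oriented(file.path(path, bundle_files["xa"]))
  xi <- read_mm_oriented(file.path(path, bundle_files["xi"]))
  cells <- utils::read.delim(file.path(path, bundle_files["cells"]),
                             colClasses = "character")
  genes <- utils::read.delim(file.path(path, bundle_files["genes"]),
                             colClasses = "character")
  if (!all(dim(xa) == dim(xi)))
    stop("inconsistent bundle: allele matrices have different dimensions (",
         paste(dim(xa), collapse = "x"), " vs ", paste(dim(xi), collapse = "x"), ")")
  allele_dataset(xa, xi, cells, genes)
}
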