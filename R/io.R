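#' Read a cell-by-feature count matrix
#'
#' Reads raw UMI or antibody-derived tag (ADT) counts from either a 10x-style
#' MatrixMarket directory or a dense delimited file. The returned matrix is
#' always oriented cells-by-features: 10x MTX triplets are stored
#' features-by-cells on disk and are transposed on load.
#'
#' @param path For `format = "mtx_dir"` a directory containing `matrix.mtx`,
#'   `features.tsv` and `barcodes.tsv`; otherwise a delimited file whose header
#'   row holds feature ids and whose first column holds cell ids.
#' @param format One of `"mtx_dir"`, `"csv"`, `"tsv"`; `"auto"` (default)
#'   infers from the path (directory or file extension).
#' @param modality `"rna"` or `"adt"`; stored as an attribute, used only for
#'   bookkeeping.
#' @return A numeric cells-by-features matrix with unique dimnames and
#'   attribute `modality`.
#' @examples
#' d <- file.path(tempdir(), "counts.csv")
#' write_matrix(matrix(0:3, 2, 2, dimnames = list(c("c1", "c2"),
#'                                                c("g1", "g2"))), d)
#' read_counts(d, modality = "rna")
#' @export
read_counts <- function(path, format = c("auto", "mtx_dir", "csv", "tsv"),
                        modality = c("rna", "adt")) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  if (format == "auto") format <- infer_format(path)
  if (format == "mtx_dir") {
    m <- read_mtx_dir(path)
  } else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    sep <- if (format == "csv") "," else "\t"
    hdr <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]][-1]
    if (anyDuplicated(hdr)) {
      stop("counts (", path, "): duplicate feature ids: ",
           paste(unique(hdr[duplicated(hdr)]), collapse = ", "),
           call. = FALSE)
    }
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            data.table = FALSE)
    if (ncol(dt) < 1) stop("empty table: ", path, call. = FALSE)
    cells <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- cells
  }
  m <- validate_counts(m, paste0("counts (", path, ")"))
  attr(m, "modality") <- modality
  m
}

infer_format <- function(path) {
  if (dir.exists(path)) return("mtx_dir")
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx_dir",
         stop("cannot infer format from path: ", path, call. = FALSE))
}

read_mtx_dir <- function(path) {
  if (!dir.exists(path)) stop("directory not found: ", path, call. = FALSE)
  files <- c(matrix = "matrix.mtx", features = "features.tsv",
             barcodes = "barcodes.tsv")
  full <- file.path(path, files)
  names(full) <- names(files)
  missing <- full[!file.exists(full)]
  if (length(missing)) {
    stop("missing file(s) in MTX directory: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mm <- Matrix::readMM(full[["matrix"]])
  feats <- data.table::fread(full[["features"]], header = FALSE,
                             sep = "\t", data.table = FALSE)
  bars <- data.table::fread(full[["barcodes"]], header = FALSE,
                            sep = "\t", data.table = FALSE)
  if (nrow(feats) != nrow(mm) || nrow(bars) != ncol(mm)) {
    stop("MTX dimensions disagree with features/barcodes files",
         call. = FALSE)
  }
  m <- t(as.matrix(mm))                   # disk is features x cells
  dimnames(m) <- list(as.character(bars[[1]]), as.character(feats[[1]]))
  storage.mode(m) <- "double"
  m
}

#' Write a named numeric matrix
#'
#' Text round-trips reproduce values to at least 1e-12; MTX of integer counts
#' round-trips exactly. The MTX directory follows the 10x convention
#' (features-by-cells triplet plus `features.tsv`/`barcodes.tsv`).
#'
#' @param matrix Numeric matrix with row and column names.
#' @param path Output file (csv/tsv) or directory (mtx_dir).
#' @param format `"auto"` (from extension; a directory path means mtx_dir),
#'   `"csv"`, `"tsv"` or `"mtx_dir"`.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(matrix, path,
                         format = c("auto", "csv", "tsv", "mtx_dir")) {
  format <- match.arg(format)
  m <- validate_matrix(matrix, "matrix to write")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "csv") "csv" else if (ext %in% c("tsv", "txt"))
      "tsv" else "mtx_dir"
  }
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(t(m), sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(colnames(m), file.path(path, "features.tsv"))
    writeLines(rownames(m), file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    ids <- if (is.null(rownames(m))) character(nrow(m)) else rownames(m)
    dt <- data.table::data.table(cell_id = ids)
    for (j in colnames(m)) data.table::set(dt, j = j, value = m[, j])
    ok <- tryCatch({
      data.table::fwrite(dt, path, sep = sep)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write ", path, ": ",
                          conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Read or write weighted receptor gene sets
#'
#' A gene set file stores, per receptor, the ordered genes and their positive
#' weights (rank 1 = most correlated). Two formats are supported: a TSV with
#' columns `receptor_id`, `gene_id`, `weight`, `rank`, and a JSON object
#' mapping each receptor to an ordered array of `[gene, weight]` pairs.
#' Weights must be strictly positive; genes must be unique within a receptor.
#'
#' @param path File ending in `.tsv` or `.json`.
#' @return A `receptor_gene_sets` object: a named list of data frames with
#'   columns `gene` and `weight`, ordered by decreasing weight.
#' @seealso [build_gene_sets()]
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    raw <- jsonlite::read_json(path)
    sets <- lapply(raw, function(entries) {
      data.frame(
        gene = vapply(entries, function(p) as.character(p[[1]]), ""),
        weight = vapply(entries, function(p) as.numeric(p[[2]]), 0),
        stringsAsFactors = FALSE
      )
    })
    names(sets) <- names(raw)
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    need <- c("receptor_id", "gene_id", "weight", "rank")
    if (!all(need %in% names(dt))) {
      stop("gene set TSV must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    dt <- dt[order(match(dt$receptor_id, unique(dt$receptor_id)), dt$rank), ]
    sets <- lapply(split(dt, factor(dt$receptor_id,
                                    levels = unique(dt$receptor_id))),
                   function(d) data.frame(gene = as.character(d$gene_id),
                                          weight = as.numeric(d$weight),
                                          stringsAsFactors = FALSE))
  }
  new_gene_sets(sets)
}

#' @rdname read_gene_sets
#' @param sets A `receptor_gene_sets` object (or compatible named list).
#' @export
write_gene_sets <- function(sets, path) {
  sets <- new_gene_sets(sets)
  keep <- vapply(sets, nrow, 0L) > 0L
  sets <- sets[keep]
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    out <- lapply(sets, function(d) {
      lapply(seq_len(nrow(d)), function(i) list(d$gene[i], d$weight[i]))
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    rows <- lapply(names(sets), function(r) {
      d <- sets[[r]]
      data.frame(receptor_id = r, gene_id = d$gene, weight = d$weight,
                 rank = seq_len(nrow(d)), stringsAsFactors = FALSE)
    })
    data.table::fwrite(do.call(rbind, rows), path, sep = "\t")
  }
  invisible(path)
}

# Constructor/validator for the gene set container.
new_gene_sets <- function(sets, set_size = NA_integer_) {
  if (!is.list(sets) || is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene sets must be a named list with unique receptor ids",
         call. = FALSE)
  }
  for (r in names(sets)) {
    d <- sets[[r]]
    if (!all(c("gene", "weight") %in% names(d))) {
      stop("gene set for ", r, " lacks gene/weight columns", call. = FALSE)
    }
    if (anyDuplicated(d$gene)) {
      stop("duplicate genes in set for receptor ", r, call. = FALSE)
    }
    if (nrow(d) && any(!is.finite(d$weight) | d$weight <= 0)) {
      stop("non-positive weight in set for receptor ", r,
           " (weights are positive rank correlations)", call. = FALSE)
    }
  }
  structure(sets, class = "receptor_gene_sets", set_size = set_size)
}

#' @exportS3Method base::print
print.receptor_gene_sets <- function(x, ...) {
  sizes <- vapply(x, nrow, 0L)
  cat("receptor_gene_sets:", length(x), "receptors;",
      "set sizes", paste(range(sizes), collapse = "-"), "\n")
  invisible(x)
}

#' Read a receptor-to-gene rename map
#'
#' Two-column TSV (no header required: `receptor_id`, `gene_id`) used to match
#' antibody names to gene symbols when they differ. Matching elsewhere in the
#' package is exact and case-sensitive.
#'
#' @param path TSV path.
#' @return Named character vector: names are receptor ids, values gene ids.
#' @export
read_rename_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          data.table = FALSE)
  if (ncol(dt) < 2) stop("rename map needs two columns", call. = FALSE)
  stats::setNames(as.character(dt[[2]]), as.character(dt[[1]]))
}
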