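#' Spearman rank correlation
#'
#' Pearson correlation of the two rank vectors, with average ranks for ties.
#' Returns `NaN` if either vector is constant. Computed explicitly from the
#' centered rank cross-products so stored gene set weights can be reproduced
#' call-for-call.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A value in `[-1, 1]`, or `NaN` where undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  den <- sqrt(sum(cx^2)) * sqrt(sum(cy^2))
  if (den == 0) return(NaN)
  sum(cx * cy) / den
}

#' Full gene-by-receptor Spearman correlation table
#'
#' Correlates every gene column of the reconstructed training RNA matrix with
#' every receptor column of the CLR-normalized ADT matrix. Entries are `NaN`
#' where either column is constant. [build_gene_sets()] is the top-k positive
#' truncation of this table.
#'
#' @param recon_train Cells-by-genes reconstructed training matrix.
#' @param adt_train Cells-by-receptors CLR-normalized ADT matrix with the
#'   same cells in the same order.
#' @return Genes-by-receptors matrix of Spearman correlations.
#' @export
correlation_table <- function(recon_train, adt_train) {
  recon_train <- validate_matrix(recon_train, "reconstructed RNA")
  adt_train <- validate_matrix(adt_train, "normalized ADT")
  if (!identical(rownames(recon_train), rownames(adt_train))) {
    stop("RNA and ADT matrices must share identical cell ids in identical ",
         "order", call. = FALSE)
  }
  m <- nrow(recon_train)
  rg <- apply(recon_train, 2, rank)
  ra <- apply(adt_train, 2, rank)
  cg <- sweep(rg, 2, colMeans(rg))
  ca <- sweep(ra, 2, colMeans(ra))
  sg <- sqrt(colSums(cg^2))
  sa <- sqrt(colSums(ca^2))
  num <- crossprod(cg, ca)
  den <- outer(sg, sa)
  out <- num / den                       # 0/0 -> NaN for constant columns
  dimnames(out) <- list(colnames(recon_train), colnames(adt_train))
  out
}

#' Build weighted receptor gene sets from paired training data
#'
#' For each receptor (ADT column), ranks all genes by the Spearman
#' correlation between their reconstructed RNA expression and the receptor's
#' CLR-normalized ADT level, and keeps the top `set_size` genes among those
#' with strictly positive correlation (fewer if fewer are positive). The
#' correlations themselves become the gene weights. Constant gene columns are
#' excluded; a receptor with no positively correlated gene yields an empty
#' set with a warning and is skipped by downstream scoring.
#'
#' Ties at the cutoff correlation are broken lexicographically on gene id so
#' the result is reproducible.
#'
#' @inheritParams correlation_table
#' @param set_size Genes per receptor (default 10).
#' @return A `receptor_gene_sets` object (see [read_gene_sets()]).
#' @export
build_gene_sets <- function(recon_train, adt_train, set_size = 10L) {
  stopifnot(set_size >= 1)
  tab <- correlation_table(recon_train, adt_train)
  sets <- lapply(colnames(tab), function(r) {
    rho <- tab[, r]
    keep <- is.finite(rho) & rho > 0
    genes <- rownames(tab)[keep]
    w <- rho[keep]
    ord <- order(-w, genes)
    take <- head(ord, set_size)
    data.frame(gene = genes[take], weight = unname(w[take]),
               stringsAsFactors = FALSE)
  })
  names(sets) <- colnames(tab)
  empty <- names(sets)[vapply(sets, nrow, 0L) == 0L]
  if (length(empty)) {
    warning("receptor(s) with no positively correlated gene: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  new_gene_sets(sets, set_size = as.integer(set_size))
}
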