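#' Run configuration for training and estimation
#'
#' Bundles and validates the tunable parameters of the pipeline. All
#' randomness (randomized SVD, permutation nulls, benchmark splits) is
#' derived from the single root `seed` via a fixed per-stage rule
#' (`seed * 131 + stage offset, mod 2^31 - 1`), so a run is fully
#' reproducible from the configuration alone.
#'
#' @param set_size Genes per receptor set (default 10).
#' @param rank `"auto"` (elbow selection on the singular-value spectrum) or
#'   a fixed positive integer.
#' @param seed Root integer seed.
#' @param scale_factor Library-size scale for log-normalization.
#' @param clr_margin CLR margin for ADT normalization (`"per_cell"` or
#'   `"per_feature"`).
#' @param k_max Upper bound on the number of distance clusters (default 4).
#' @param null_mode Gamma-calibration null: `"permutation"` or `"direct"`.
#' @param max_rank Largest rank considered by automatic selection.
#' @param rank_threshold,rank_smooth Elbow rule parameters (see
#'   [select_rank()]).
#' @return A validated list of class `abundance_config`.
#' @export
abundance_config <- function(set_size = 10L, rank = "auto", seed = 1L,
                             scale_factor = 1e4,
                             clr_margin = c("per_cell", "per_feature"),
                             k_max = 4L,
                             null_mode = c("permutation", "direct"),
                             max_rank = 100L, rank_threshold = 0.01,
                             rank_smooth = 3L) {
  clr_margin <- match.arg(clr_margin)
  null_mode <- match.arg(null_mode)
  stopifnot(set_size >= 1, scale_factor > 0, k_max >= 1, max_rank >= 1,
            rank_threshold > 0, rank_smooth >= 1,
            is.numeric(seed), length(seed) == 1)
  if (!(identical(rank, "auto") || (is.numeric(rank) && rank >= 1))) {
    stop("rank must be \"auto\" or a positive integer", call. = FALSE)
  }
  structure(list(set_size = as.integer(set_size), rank = rank,
                 seed = as.integer(seed), scale_factor = scale_factor,
                 clr_margin = clr_margin, k_max = as.integer(k_max),
                 null_mode = null_mode, max_rank = as.integer(max_rank),
                 rank_threshold = rank_threshold,
                 rank_smooth = as.integer(rank_smooth)),
            class = "abundance_config")
}

# Normalize + pick rank + reconstruct; shared by training and estimation.
# seed_offset separates the SVD streams of the two stages.
normalize_and_reconstruct <- function(counts, config, seed_offset) {
  ln <- log_normalize(counts, config$scale_factor)
  k <- if (identical(config$rank, "auto")) {
    mr <- min(config$max_rank, nrow(ln) - 1L, ncol(ln))
    select_rank(ln, max_rank = mr,
                seed = stage_seed(config$seed, seed_offset),
                threshold = config$rank_threshold,
                smooth = config$rank_smooth)$selected_rank
  } else as.integer(config$rank)
  rrr_reconstruct(ln, k, seed = stage_seed(config$seed, seed_offset + 1L))
}

#' Learn weighted receptor gene sets from paired training data
#'
#' End-to-end training: log-normalize and reduced-rank reconstruct the RNA
#' counts, CLR-normalize the ADT counts, then build the weighted gene sets
#' by Spearman co-expression (see [build_gene_sets()]). The ADT matrix must
#' cover the same cells as the RNA matrix; rows are reordered to the RNA
#' cell order if needed.
#'
#' @param rna_train Cells-by-genes RNA count matrix.
#' @param adt_train Cells-by-antibodies ADT count matrix over the same
#'   cells.
#' @param config An [abundance_config()].
#' @return A `receptor_gene_sets` object with attributes `rank_used` and
#'   `config`.
#' @export
train_receptor_sets <- function(rna_train, adt_train,
                                config = abundance_config()) {
  rna_train <- validate_counts(rna_train, "RNA training counts")
  adt_train <- validate_counts(adt_train, "ADT training counts")
  if (!setequal(rownames(rna_train), rownames(adt_train))) {
    stop("RNA and ADT training matrices must cover the same cells",
         call. = FALSE)
  }
  adt_train <- adt_train[rownames(rna_train), , drop = FALSE]
  # an antibody with constant raw counts carries no signal; flag it before
  # CLR (per-cell centering would lend it spurious variation)
  const <- apply(adt_train, 2, function(x) min(x) == max(x))
  if (any(const)) {
    warning("constant antibody column(s) dropped: ",
            paste(colnames(adt_train)[const], collapse = ", "),
            call. = FALSE)
  }
  recon <- normalize_and_reconstruct(rna_train, config, seed_offset = 11L)
  clr <- clr_normalize(adt_train[, !const, drop = FALSE],
                       config$clr_margin)
  sets <- build_gene_sets(recon, clr, config$set_size)
  if (any(const)) {
    for (r in colnames(adt_train)[const]) {
      sets[[r]] <- data.frame(gene = character(0), weight = numeric(0),
                              stringsAsFactors = FALSE)
    }
    sets <- new_gene_sets(sets[colnames(adt_train)],
                          set_size = as.integer(config$set_size))
  }
  attr(sets, "rank_used") <- attr(recon, "rank_used")
  attr(sets, "config") <- config
  sets
}

# Score every scoreable receptor on an already-reconstructed target matrix
# and threshold the scores. Exposed so sweeps can reuse one reconstruction
# across gene set sizes.
#' Score and threshold gene sets on a reconstructed matrix
#'
#' Lower-level entry point of [estimate_abundance()]: takes an existing
#' reconstructed target matrix, scores each receptor's weighted set
#' ([score_receptor()]), clusters the squared distances ([ckmeans_1d()]),
#' and zeroes the lowest cluster's scores ([threshold_scores()]). Receptors
#' with empty sets or with genes absent from the target are skipped with a
#' warning.
#'
#' @param recon_target Cells-by-genes reconstructed target matrix.
#' @param gene_sets A `receptor_gene_sets` object.
#' @param config An [abundance_config()].
#' @return Cells-by-receptors matrix of thresholded scores in `[0, 1]`.
#' @export
score_and_threshold <- function(recon_target, gene_sets,
                                config = abundance_config()) {
  gene_sets <- new_gene_sets(gene_sets)
  scoreable <- character(0)
  skipped <- character(0)
  for (r in names(gene_sets)) {
    d <- gene_sets[[r]]
    if (nrow(d) == 0L || !all(d$gene %in% colnames(recon_target))) {
      skipped <- c(skipped, r)
    } else {
      scoreable <- c(scoreable, r)
    }
  }
  if (length(skipped)) {
    warning("skipping receptor(s) with empty sets or genes absent from ",
            "target: ", paste(skipped, collapse = ", "), call. = FALSE)
  }
  if (!length(scoreable)) {
    stop("no scoreable receptor: every set is empty or has genes missing ",
         "from the target", call. = FALSE)
  }
  out <- matrix(0, nrow(recon_target), length(scoreable),
                dimnames = list(rownames(recon_target), scoreable))
  for (i in seq_along(scoreable)) {
    r <- scoreable[i]
    # seed indexed by position in the full set list so skipped receptors
    # never shift the permutation stream of the others
    ri <- match(r, names(gene_sets))
    sc <- score_receptor(recon_target, gene_sets[[r]],
                         null_mode = config$null_mode,
                         seed = stage_seed(config$seed, 100L + ri))
    cl <- ckmeans_1d(sc$distances, 1L, config$k_max)
    out[, i] <- threshold_scores(sc$scores, sc$distances, cl)
  }
  out
}

#' Estimate receptor abundance for target scRNA-seq data
#'
#' End-to-end estimation: log-normalize and reduced-rank reconstruct the
#' target counts, then score and threshold every scoreable receptor's
#' weighted gene set. The reconstruction rank is selected on the target data
#' itself (independently of training) unless `config$rank` fixes it.
#'
#' @param rna_target Cells-by-genes RNA count matrix.
#' @param gene_sets A `receptor_gene_sets` object (from
#'   [train_receptor_sets()] or [read_gene_sets()]).
#' @param config An [abundance_config()].
#' @return Cells-by-receptors matrix of abundance estimates in `[0, 1]`,
#'   with a `provenance` attribute recording the rank used, the seed, the
#'   parameter block and a hash of the gene sets.
#' @export
estimate_abundance <- function(rna_target, gene_sets,
                               config = abundance_config()) {
  rna_target <- validate_counts(rna_target, "RNA target counts")
  gene_sets <- new_gene_sets(gene_sets)
  recon <- normalize_and_reconstruct(rna_target, config, seed_offset = 21L)
  out <- score_and_threshold(recon, gene_sets, config)
  attr(out, "provenance") <- list(
    rank_used = attr(recon, "rank_used"),
    seed = config$seed,
    gene_sets_hash = rlang::hash(lapply(unclass(gene_sets), identity)),
    config = unclass(config)
  )
  out
}

#' Normalized-transcript baseline
#'
#' The naive unsupervised estimator: each receptor's abundance is its
#' cognate transcript's log-normalized expression (values >= 0, not bounded
#' by 1). Receptors whose mapped gene is absent are skipped with a warning.
#'
#' @param rna_target Cells-by-genes RNA count matrix.
#' @param receptor_to_gene Named character vector mapping receptor ids to
#'   gene ids.
#' @param scale_factor Library-size scale for log-normalization.
#' @return Cells-by-receptors matrix.
#' @export
rna_baseline <- function(rna_target, receptor_to_gene,
                         scale_factor = 1e4) {
  rna_target <- validate_counts(rna_target, "RNA target counts")
  ln <- log_normalize(rna_target, scale_factor)
  present <- receptor_to_gene %in% colnames(ln)
  if (any(!present)) {
    warning("unmapped receptor(s) skipped: ",
            paste(names(receptor_to_gene)[!present], collapse = ", "),
            call. = FALSE)
  }
  keep <- receptor_to_gene[present]
  out <- ln[, keep, drop = FALSE]
  colnames(out) <- names(keep)
  out
}

#' Reconstruction-and-threshold baseline
#'
#' Unsupervised per-gene estimator: log-normalize, reduced-rank
#' reconstruct, then cluster each reconstructed gene column with
#' [ckmeans_1d()] and zero the lowest cluster's values — thresholding the
#' expression values themselves rather than gene set scores.
#'
#' @param rna_target Cells-by-genes RNA count matrix.
#' @param config An [abundance_config()].
#' @param genes Optional character vector restricting the output columns
#'   (default: all genes).
#' @return Cells-by-genes matrix of thresholded reconstructed expression.
#' @export
reconstruction_baseline <- function(rna_target,
                                    config = abundance_config(),
                                    genes = NULL) {
  rna_target <- validate_counts(rna_target, "RNA target counts")
  recon <- normalize_and_reconstruct(rna_target, config, seed_offset = 31L)
  if (is.null(genes)) genes <- colnames(recon)
  missing <- setdiff(genes, colnames(recon))
  if (length(missing)) {
    stop("unknown gene id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- recon[, genes, drop = FALSE]
  for (j in seq_along(genes)) {
    col <- out[, j]
    cl <- ckmeans_1d(col, 1L, config$k_max)
    out[, j] <- threshold_scores(col, col, cl)
  }
  out
}
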