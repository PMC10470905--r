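#' Draw repeated train/target splits
#'
#' Draws `n_repeats` independent seeded splits of the cell ids, each with
#' `round(train_frac * N)` training cells and the remaining cells as target
#' — five independent draws at a 20/80 split rather than a disjoint
#' partition, since 20% folds cannot tile the data.
#'
#' @param cell_ids Character vector of unique cell ids.
#' @param n_repeats Number of independent splits (default 5).
#' @param train_frac Training fraction in (0, 1) (default 0.2).
#' @param seed Integer root seed.
#' @return List of split plans: `repeat_index`, `train`, `target`,
#'   `train_frac`.
#' @export
make_splits <- function(cell_ids, n_repeats = 5L, train_frac = 0.2,
                        seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must lie in (0, 1)", call. = FALSE)
  }
  n <- length(cell_ids)
  n_train <- round(train_frac * n)
  if (n_train < 1 || n_train >= n) {
    stop("too few cells for a non-empty train and target part",
         call. = FALSE)
  }
  lapply(seq_len(n_repeats), function(r) {
    train <- withr::with_seed(stage_seed(seed, 1000L + r),
                              sample(cell_ids, n_train))
    list(repeat_index = r, train = train,
         target = setdiff(cell_ids, train), train_frac = train_frac)
  })
}

#' Per-receptor concordance with CITE-seq ADT data
#'
#' Spearman rank correlation between each estimated abundance column and the
#' matched (by id, or via `rename_map`) CLR-normalized ADT column over the
#' shared cells. `NaN` marks receptors where either column is constant.
#'
#' @param estimates Cells-by-receptors estimate matrix.
#' @param adt_target Cells-by-antibodies ADT count matrix over the same
#'   cells.
#' @param rename_map Optional named character vector translating estimate
#'   column ids to ADT feature ids.
#' @param adt_raw Compare against raw ADT counts instead of CLR-normalized
#'   values (default `FALSE`).
#' @param clr_margin CLR margin used when normalizing the ADT side.
#' @return Named numeric vector of correlations, one per matched receptor.
#' @export
concordance <- function(estimates, adt_target, rename_map = NULL,
                        adt_raw = FALSE,
                        clr_margin = c("per_cell", "per_feature")) {
  clr_margin <- match.arg(clr_margin)
  estimates <- validate_matrix(estimates, "estimates")
  adt_target <- validate_counts(adt_target, "ADT target counts")
  if (!setequal(rownames(estimates), rownames(adt_target))) {
    stop("estimates and ADT matrix must cover the same cells",
         call. = FALSE)
  }
  adt_target <- adt_target[rownames(estimates), , drop = FALSE]
  adt_side <- if (adt_raw) adt_target else
    clr_normalize(adt_target, clr_margin)
  ids <- colnames(estimates)
  mapped <- if (is.null(rename_map)) ids else {
    ifelse(ids %in% names(rename_map), rename_map[ids], ids)
  }
  keep <- mapped %in% colnames(adt_side)
  if (!any(keep)) stop("no receptor matched to an ADT feature",
                       call. = FALSE)
  rho <- vapply(which(keep), function(i) {
    spearman_rho(estimates[, i], adt_side[, mapped[i]])
  }, 0)
  stats::setNames(rho, ids[keep])
}

#' Share of receptors each method estimates best
#'
#' From a long-format concordance table (one row per method, receptor and
#' repeat), averages the correlations over repeats within each receptor and
#' method, finds the best method per receptor, and reports each method's
#' share of wins as a percentage. Exact ties split the win equally among the
#' tied methods, so the shares always sum to 100.
#'
#' @param table Data frame with columns `method`, `receptor`, `rho` and
#'   optionally `repeat_index`.
#' @return Named numeric vector of percentages (one per method).
#' @export
best_method_proportions <- function(table) {
  stopifnot(all(c("method", "receptor", "rho") %in% names(table)))
  methods <- unique(table$method)
  avg <- stats::aggregate(rho ~ receptor + method, data = table,
                          FUN = function(v) mean(v, na.rm = TRUE),
                          na.action = stats::na.pass)
  wins <- stats::setNames(numeric(length(methods)), methods)
  n_scored <- 0L
  for (r in unique(avg$receptor)) {
    sub <- avg[avg$receptor == r, ]
    vals <- stats::setNames(sub$rho, sub$method)
    vals <- vals[is.finite(vals)]
    if (!length(vals)) {
      warning("receptor with no defined correlation excluded: ", r,
              call. = FALSE)
      next
    }
    n_scored <- n_scored + 1L
    best <- names(vals)[vals == max(vals)]
    wins[best] <- wins[best] + 1 / length(best)
  }
  if (n_scored == 0L) stop("no receptor with a defined correlation",
                           call. = FALSE)
  100 * wins / n_scored
}

#' Sensitivity sweep over gene set size and training size
#'
#' Runs train + estimate + concordance for every combination of `set_sizes`
#' and `train_sizes` over `n_repeats` seeded splits, comparing the gene-set
#' estimator against the normalized-transcript baseline. The target
#' reconstruction and the full correlation table are computed once per
#' split and reused across set sizes (smaller sets are prefixes of larger
#' ones), which keeps the sweep affordable. Per-point failures are recorded
#' and the sweep continues.
#'
#' @param rna,adt Paired cells-by-features count matrices.
#' @param receptor_to_gene Named map used by the transcript baseline.
#' @param set_sizes Integer vector of gene set sizes.
#' @param train_sizes Integer vector of training cell counts.
#' @param n_repeats Splits per grid point.
#' @param config Base [abundance_config()]; its `set_size` is overridden by
#'   the grid.
#' @return Long-format data frame: `set_size`, `n_train`, `repeat_index`,
#'   `method`, `receptor`, `rho` (NA rows mark failed grid points).
#' @export
sensitivity_sweep <- function(rna, adt, receptor_to_gene = NULL,
                              set_sizes = c(5L, 10L, 20L, 30L),
                              train_sizes = NULL, n_repeats = 1L,
                              config = abundance_config()) {
  rna <- validate_counts(rna, "RNA counts")
  adt <- validate_counts(adt, "ADT counts")
  if (is.null(train_sizes)) train_sizes <- round(0.2 * nrow(rna))
  rows <- list()
  for (n_train in train_sizes) {
    frac <- n_train / nrow(rna)
    splits <- make_splits(rownames(rna), n_repeats, frac, config$seed)
    for (sp in splits) {
      res <- tryCatch(
        sweep_one_split(rna, adt, sp, set_sizes, receptor_to_gene, config),
        error = function(e) {
          data.frame(set_size = NA_integer_, method = "error",
                     receptor = conditionMessage(e), rho = NA_real_,
                     stringsAsFactors = FALSE)
        })
      res$n_train <- n_train
      res$repeat_index <- sp$repeat_index
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("set_size", "n_train", "repeat_index", "method", "receptor",
          "rho")]
}

# One split of the sweep: train once at max(set_sizes), reuse the target
# reconstruction across set sizes, and score the baseline once.
sweep_one_split <- function(rna, adt, sp, set_sizes, receptor_to_gene,
                            config) {
  cfg_max <- config
  cfg_max$set_size <- max(set_sizes)
  sets_max <- train_receptor_sets(rna[sp$train, , drop = FALSE],
                                  adt[sp$train, , drop = FALSE], cfg_max)
  target_rna <- rna[sp$target, , drop = FALSE]
  target_adt <- adt[sp$target, , drop = FALSE]
  recon <- normalize_and_reconstruct(target_rna, config, seed_offset = 21L)
  rows <- list()
  for (ss in set_sizes) {
    sets <- new_gene_sets(lapply(unclass(sets_max), head, ss))
    est <- score_and_threshold(recon, sets, config)
    rho <- concordance(est, target_adt, clr_margin = config$clr_margin)
    rows[[length(rows) + 1L]] <- data.frame(
      set_size = ss, method = "gene_set", receptor = names(rho),
      rho = unname(rho), stringsAsFactors = FALSE)
  }
  if (!is.null(receptor_to_gene)) {
    base <- rna_baseline(target_rna, receptor_to_gene,
                         config$scale_factor)
    rho <- concordance(base, target_adt, clr_margin = config$clr_margin)
    for (ss in set_sizes) {
      rows[[length(rows) + 1L]] <- data.frame(
        set_size = ss, method = "rna", receptor = names(rho),
        rho = unname(rho), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
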