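# Internal validators shared across modules. All take a cells-by-features
# numeric matrix with unique dimnames; counts additionally must be >= 0.

as_dense <- function(x) {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a numeric matrix (cells in rows, features in columns)",
         call. = FALSE)
  }
  x
}

validate_matrix <- function(x, what = "matrix") {
  x <- as_dense(x)
  if ((nrow(x) > 0 && is.null(rownames(x))) ||
      (ncol(x) > 0 && is.null(colnames(x)))) {
    stop(what, " must have cell row names and feature column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop(what, ": duplicate cell ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop(what, ": duplicate feature ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(what, " contains missing or non-finite values", call. = FALSE)
  }
  x
}

validate_counts <- function(x, what = "count matrix") {
  x <- validate_matrix(x, what)
  if (any(x < 0)) stop(what, " contains negative entries", call. = FALSE)
  x
}

# Derive a stage-specific 32-bit seed from the run's root seed. Documented
# rule: seed * 131 + stage offset, reduced mod 2^31 - 1.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131 + offset) %% 2147483647)
}
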