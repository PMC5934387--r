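# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.check_expr <- function(x, min_samples = 1L) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression input must be a numeric matrix (features x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have feature and sample names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate feature IDs: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (!all(is.finite(x)))
    stop("expression matrix contains non-finite values")
  if (ncol(x) < min_samples)
    stop("at least ", min_samples, " samples required")
  invisible(x)
}

#' @noRd
.check_labels <- function(labels, sample_ids = NULL) {
  if (is.null(labels)) stop("labels required")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (!is.null(sample_ids) && length(labels) != length(sample_ids))
    stop("labels length must equal the number of samples")
  if (length(unique(labels)) < 2L) stop("labels required: both classes must be present")
  labels
}

# Deterministic order: numeric key first, character tie-break in C locale.
#' @noRd
.order_by <- function(key, tie) order(key, tie, method = "radix")
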