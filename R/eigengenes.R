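#' Expand samples so both classes are equally represented
#'
#' Oversampling for eigengene estimation: each sample of class c is repeated
#' `factors[c]` times. When `factors` is omitted, the larger class gets a
#' reference factor of `f_ref` (default 9) and the other class gets
#' `round(f_ref * n_ref / n_c)`; for class sizes 202/164 this yields the
#' factors (9, 11) and 1,818/1,804 expanded rows. Expansion is deterministic:
#' samples keep their input order and repeats are contiguous.
#'
#' @param sample_ids character vector of sample IDs.
#' @param labels 0/1 class labels, one per sample.
#' @param factors optional per-class integer repeat counts, named `"0"`/`"1"`
#'   (or an unnamed length-2 vector in that order).
#' @param f_ref reference factor for the largest class when `factors` is
#'   omitted.
#' @return integer vector of expanded sample indices (into `sample_ids`),
#'   with attribute `factors`.
#' @export
balance_classes <- function(sample_ids, labels, factors = NULL, f_ref = 9L) {
  labels <- .check_labels(labels, sample_ids)
  n <- c(`0` = sum(labels == 0L), `1` = sum(labels == 1L))
  if (is.null(factors)) {
    ref <- names(n)[which.max(n)]
    other <- setdiff(names(n), ref)
    factors <- stats::setNames(c(f_ref, round(f_ref * n[[ref]] / n[[other]])),
                               c(ref, other))
    factors <- factors[c("0", "1")]
  } else {
    if (is.null(names(factors))) names(factors) <- c("0", "1")
    factors <- factors[c("0", "1")]
  }
  factors <- stats::setNames(as.integer(factors), names(factors))
  if (any(factors < 1L)) stop("oversampling factors must be >= 1")
  idx <- rep(seq_along(labels), times = factors[as.character(labels)])
  attr(idx, "factors") <- factors
  idx
}

#' Compute module eigengenes on class-balanced data
#'
#' Each module is summarized by its eigengene: the first principal component
#' of the module's per-gene standardized expression. The principal-component
#' weights are estimated on the class-balanced (oversampled) submatrix, so
#' that both classes contribute comparably; eigengene values are then
#' computed for the original (non-expanded) samples, so that downstream model
#' fitting sees the true sample size. The weight vector has unit norm and its
#' sign is chosen so the eigengene correlates positively with the module's
#' mean standardized expression.
#'
#' @param x gene x sample matrix.
#' @param modules a `module_assignment` (named integer vector; 0 = skip).
#' @param labels optional 0/1 labels; when present the weight estimation uses
#'   [balance_classes()] oversampling.
#' @param factors optional per-class oversampling factors (see
#'   [balance_classes()]).
#' @return list with `model` (an `eigengene_model`: per-module genes and
#'   weights, per-gene training center/scale, oversampling factors) and
#'   `eigengenes` (samples x modules matrix, columns `M1`, `M2`, ...).
#' @export
compute_eigengenes <- function(x, modules, labels = NULL, factors = NULL) {
  .check_expr(x)
  modules <- stats::setNames(as.integer(modules), names(modules))
  if (!all(names(modules) %in% rownames(x)))
    stop("every module gene must be present in the expression matrix")
  ids <- sort(unique(modules[modules > 0]))
  if (length(ids) == 0) stop("no non-grey module to summarize")

  if (!is.null(labels)) {
    idx <- balance_classes(colnames(x), labels, factors = factors)
    fac <- attr(idx, "factors")
  } else {
    idx <- seq_len(ncol(x))
    fac <- stats::setNames(c(1L, 1L), c("0", "1"))
  }

  mod_list <- list()
  E <- matrix(NA_real_, nrow = ncol(x), ncol = length(ids),
              dimnames = list(colnames(x), paste0("M", ids)))
  center <- numeric(0)
  scale_ <- numeric(0)

  for (j in seq_along(ids)) {
    genes <- names(modules)[modules == ids[j]]
    xe <- x[genes, idx, drop = FALSE]
    sds_exp <- apply(xe, 1, stats::sd)
    if (any(sds_exp == 0)) {
      warning("module ", ids[j], ": dropping ", sum(sds_exp == 0),
              " zero-variance gene(s)")
      genes <- genes[sds_exp > 0]
      if (length(genes) == 0)
        stop("module ", ids[j], " has no gene with positive variance")
      xe <- x[genes, idx, drop = FALSE]
    }
    Z <- scale(t(xe))  # expanded samples x genes
    if (length(genes) == 1L) {
      w <- 1
    } else {
      w <- svd(Z, nu = 0, nv = 1)$v[, 1]
      score <- Z %*% w
      if (stats::sd(score) > 0 &&
          stats::cor(score, rowMeans(Z)) < 0) w <- -w
    }
    w <- stats::setNames(as.numeric(w), genes)

    # training-sample standardization used for the reported eigengene values
    mu <- rowMeans(x[genes, , drop = FALSE])
    sdv <- apply(x[genes, , drop = FALSE], 1, stats::sd)
    Zo <- (t(x[genes, , drop = FALSE]) - rep(mu, each = ncol(x))) /
      rep(sdv, each = ncol(x))
    E[, j] <- Zo %*% w
    mod_list[[paste0("M", ids[j])]] <- list(genes = genes, weights = w)
    center[genes] <- mu
    scale_[genes] <- sdv
  }

  model <- structure(list(modules = mod_list, center = center,
                          scale = scale_, factors = fac),
                     class = "eigengene_model")
  list(model = model, eigengenes = E)
}

#' Project trained eigengenes onto a new dataset
#'
#' For each module, the trained gene weights are restricted to the genes
#' present in the new dataset and renormalized to unit norm; the shared genes
#' are z-scored *within the new dataset* and the eigengene is their weighted
#' sum. Because the new data are standardized internally, the projection is
#' invariant to any per-gene affine transform of the new dataset -- the
#' mechanism that makes eigengenes robust across profiling platforms (e.g.
#' microarray-trained models applied to log10 RPKM RNA-seq values).
#'
#' @param model an `eigengene_model`.
#' @param y gene x sample matrix on the new platform.
#' @return samples x modules eigengene matrix.
#' @export
project_eigengenes <- function(model, y) {
  .check_expr(y)
  mods <- model$modules
  shared_any <- vapply(mods, function(m) any(m$genes %in% rownames(y)),
                       logical(1))
  if (!any(shared_any)) stop("no shared genes between the model and the new dataset")
  E <- matrix(0, nrow = ncol(y), ncol = length(mods),
              dimnames = list(colnames(y), names(mods)))
  for (j in seq_along(mods)) {
    shared <- intersect(mods[[j]]$genes, rownames(y))
    if (length(shared) == 0) {
      warning("module ", names(mods)[j],
              " shares no genes with the new dataset; eigengene set to 0")
      next
    }
    ys <- y[shared, , drop = FALSE]
    sds <- apply(ys, 1, stats::sd)
    if (any(sds == 0)) {
      warning("module ", names(mods)[j], ": ", sum(sds == 0),
              " zero-variance gene(s) in the new dataset dropped")
      shared <- shared[sds > 0]
      if (length(shared) == 0) next
      ys <- y[shared, , drop = FALSE]
      sds <- sds[sds > 0]
    }
    w <- mods[[j]]$weights[shared]
    w <- w / sqrt(sum(w^2))
    Z <- (t(ys) - rep(rowMeans(ys), each = ncol(y))) / rep(sds, each = ncol(y))
    E[, j] <- Z %*% w
  }
  E
}

#' Welch t-tests on eigengenes between classes
#'
#' Per-eigengene two-sample Welch t-test with BH-adjusted p-values; the
#' standard check that the module summaries discriminate the two classes.
#'
#' @param e samples x modules eigengene matrix.
#' @param labels 0/1 labels, one per sample (row).
#' @return data.frame with `module`, `t_statistic`, `p_value`,
#'   `adjusted_p_value`.
#' @export
eigengene_differential_test <- function(e, labels) {
  labels <- .check_labels(labels, rownames(e))
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L)
    stop("both classes need at least 2 samples")
  res <- moderated_t_test(t(e), labels, method = "welch")
  data.frame(module = res$feature_id,
             t_statistic = res$t_statistic,
             p_value = res$p_value,
             adjusted_p_value = res$adjusted_p_value,
             stringsAsFactors = FALSE)
}
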