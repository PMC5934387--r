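#' Moderated or Welch two-sample t-test per feature
#'
#' Ranks features (probes or genes) by differential expression between the two
#' classes. The default test is an empirical-Bayes moderated t: the per-feature
#' pooled variance \eqn{s^2} is shrunk towards a common prior variance
#' \eqn{s_0^2} with prior degrees of freedom \eqn{d_0},
#' \deqn{\tilde{s}^2 = \frac{d_0 s_0^2 + d s^2}{d_0 + d},}
#' where \eqn{d = n_1 + n_2 - 2} is the residual degrees of freedom. The
#' hyperparameters \eqn{(d_0, s_0^2)} are estimated by the trigamma-matching
#' method of moments on the log sample variances (via
#' [limma::squeezeVar()]), and p-values use a t distribution on
#' \eqn{d + d_0} degrees of freedom. A plain Welch t-test is available with
#' `method = "welch"`.
#'
#' @param x numeric matrix, features x samples, log-scale expression.
#' @param labels integer 0/1 vector, one per sample (1 = positive class).
#' @param method `"moderated"` (default) or `"welch"`.
#' @param d0,s0sq optional fixed shrinkage hyperparameters; when supplied they
#'   override the empirical-Bayes estimates. `d0 = 0` recovers the ordinary
#'   pooled-variance t; `d0 = Inf` gives a z-statistic with variance `s0sq`.
#' @param adjust p-value adjustment method passed to [adjust_pvalues()].
#'
#' @return A data.frame with columns `feature_id`, `t_statistic`, `p_value`,
#'   `adjusted_p_value`, plus attributes `d0`, `s0sq` and `df_total` for the
#'   moderated test.
#' @export
moderated_t_test <- function(x, labels, method = c("moderated", "welch"),
                             d0 = NULL, s0sq = NULL, adjust = "BH") {
  method <- match.arg(method)
  .check_expr(x)
  labels <- .check_labels(labels, colnames(x))
  i1 <- labels == 1L
  i0 <- labels == 0L
  n1 <- sum(i1); n0 <- sum(i0)
  if (n1 < 2L || n0 < 2L) stop("both classes need at least 2 samples")

  m1 <- rowMeans(x[, i1, drop = FALSE])
  m0 <- rowMeans(x[, i0, drop = FALSE])
  v1 <- apply(x[, i1, drop = FALSE], 1, stats::var)
  v0 <- apply(x[, i0, drop = FALSE], 1, stats::var)

  if (method == "welch") {
    se2 <- v1 / n1 + v0 / n0
    tt <- ifelse(se2 > 0, (m1 - m0) / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1)),
                 1)
    pp <- ifelse(se2 > 0, 2 * stats::pt(-abs(tt), df), 1)
    d0 <- NA_real_; s0sq <- NA_real_; df_total <- df
  } else {
    d <- n1 + n0 - 2L
    s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / d
    if (is.null(d0)) {
      sv <- limma::squeezeVar(s2, df = d)
      d0 <- sv$df.prior
      s0sq <- sv$var.prior
      stilde <- sv$var.post
    } else {
      if (is.null(s0sq) && d0 > 0) stop("s0sq must be given alongside d0")
      stilde <- if (is.infinite(d0)) rep(s0sq, length(s2))
                else if (d0 == 0) s2
                else (d0 * s0sq + d * s2) / (d0 + d)
    }
    se2 <- stilde * (1 / n1 + 1 / n0)
    tt <- ifelse(se2 > 0, (m1 - m0) / sqrt(se2), 0)
    df_total <- d + d0
    pp <- ifelse(se2 > 0,
                 if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tt))
                 else 2 * stats::pt(-abs(tt), df_total),
                 1)
  }

  res <- data.frame(feature_id = rownames(x),
                    t_statistic = unname(tt),
                    p_value = unname(pp),
                    adjusted_p_value = adjust_pvalues(unname(pp), adjust),
                    stringsAsFactors = FALSE)
  attr(res, "d0") <- d0
  attr(res, "s0sq") <- s0sq
  attr(res, "df_total") <- unname(df_total)
  res
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up adjustment by default; `"bonferroni"` and
#' `"none"` are also accepted.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method adjustment method.
#' @return adjusted p-values, monotone and capped at 1.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  if (any(is.na(p))) stop("p-values must not contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Keep the top fraction of features by p-value
#'
#' Retains the `ceiling(fraction * P)` features with the smallest p-values
#' (the most variably expressed features across classes). Ties at the cutoff
#' are broken by feature ID in lexicographic (C locale) order so the result is
#' deterministic. The row order of the survivors is preserved.
#'
#' @param x feature x sample matrix.
#' @param stats result of [moderated_t_test()] (or any data.frame with
#'   `feature_id` and `p_value` covering the rows of `x`).
#' @param fraction fraction of features to keep, in `(0, 1]`.
#' @return the filtered matrix.
#' @export
filter_top_fraction <- function(x, stats, fraction = 1 / 3) {
  .check_expr(x)
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  idx <- match(rownames(x), stats$feature_id)
  if (any(is.na(idx))) stop("stats do not cover all features of the matrix")
  p <- stats$p_value[idx]
  m <- ceiling(fraction * nrow(x))
  keep_ids <- rownames(x)[.order_by(p, rownames(x))][seq_len(m)]
  x[rownames(x) %in% keep_ids, , drop = FALSE]
}

#' Collapse probes to one representative per gene
#'
#' Probes mapped to multiple genes are excluded first; unmapped probes are
#' dropped (with a message). Among the surviving probes of each gene, the one
#' with the smallest p-value is taken as the gene's representative, and the
#' output rows are keyed by gene ID. Ties are broken by probe ID.
#'
#' @param x probe x sample matrix.
#' @param map data.frame with columns `probe_id`, `gene_id`; a probe may map
#'   to several genes (it is then discarded as multi-mapped).
#' @param stats per-probe test results as from [moderated_t_test()].
#' @return gene x sample matrix with attribute `representative_probe`.
#' @export
select_gene_representatives <- function(x, map, stats) {
  .check_expr(x)
  map <- unique(data.frame(probe_id = as.character(map[[1]]),
                           gene_id = as.character(map[[2]]),
                           stringsAsFactors = FALSE))
  multi <- unique(map$probe_id[duplicated(map$probe_id)])
  probes <- rownames(x)
  unmapped <- setdiff(probes, map$probe_id)
  if (length(unmapped) > 0)
    message(length(unmapped), " unmapped probe(s) dropped")
  keep <- setdiff(intersect(probes, map$probe_id), multi)
  if (length(keep) == 0) stop("no mappable probes")
  map <- map[map$probe_id %in% keep, , drop = FALSE]

  p <- stats$p_value[match(map$probe_id, stats$feature_id)]
  if (any(is.na(p))) stop("stats do not cover all mapped probes")
  ord <- .order_by(p, map$probe_id)
  map <- map[ord, , drop = FALSE]
  rep_map <- map[!duplicated(map$gene_id), , drop = FALSE]

  # output rows follow the original row order of the representative probes
  rows <- match(rep_map$probe_id, probes)
  o <- order(rows)
  out <- x[rows[o], , drop = FALSE]
  rownames(out) <- rep_map$gene_id[o]
  attr(out, "representative_probe") <- stats::setNames(rep_map$probe_id[o],
                                                       rep_map$gene_id[o])
  out
}
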