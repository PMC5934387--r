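# Synthetic data with the statistical structure the method assumes: a
# Gaussian latent factor per module, class-dependent shifts of some factors,
# pure-noise genes, probe-level multi-mapping, and a monotone cross-platform
# transform. The defaults are the desk-scale study conditions used by the
# package's validation suite: 10 modules of 30 genes, two of which carry a
# class effect of d = 2, 150 + 150 samples, within-module gene-factor
# correlation 0.85, and 100 noise genes.

#' Generate a modular expression matrix with class-linked modules
#'
#' Per module m, a latent factor \eqn{f_m \sim N(y \cdot d_m, 1)} is drawn
#' for each sample with class label y; each gene of the module is
#' \eqn{\rho f_m + \sqrt{1-\rho^2}\,\varepsilon} with
#' \eqn{\varepsilon \sim N(0,1)}, so the within-class gene-factor
#' correlation is \eqn{\rho} (`within_cor`). Noise genes are i.i.d. N(0, 1).
#'
#' @param n_pos,n_neg samples per class (class 1 first, then class 0).
#' @param module_sizes integer vector of genes per module.
#' @param n_noise_genes unassigned pure-noise genes.
#' @param within_cor within-class gene-factor correlation, in (0, 1).
#' @param effect_sizes per-module class shift d_m of the latent factor (same
#'   length as `module_sizes`).
#' @param seed RNG seed; output is byte-identical given the seed.
#' @return list with `expression` (genes x samples), `labels` (named 0/1),
#'   and `truth` (a `synthetic_truth`: module membership, factors,
#'   parameters).
#' @export
generate_expression <- function(n_pos = 150, n_neg = 150,
                                module_sizes = rep(30, 10),
                                n_noise_genes = 100, within_cor = 0.85,
                                effect_sizes = c(2, 2, rep(0, 8)),
                                seed = NULL) {
  stopifnot(within_cor > 0, within_cor < 1, all(module_sizes >= 2),
            length(effect_sizes) == length(module_sizes))
  if (!is.null(seed)) set.seed(seed)
  n <- n_pos + n_neg
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  sample_ids <- sprintf("S%03d", seq_len(n))
  names(labels) <- sample_ids

  M <- length(module_sizes)
  n_genes <- sum(module_sizes) + n_noise_genes
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  modules <- stats::setNames(
    c(rep(seq_len(M), times = module_sizes), rep(0L, n_noise_genes)),
    gene_ids)

  factors <- matrix(stats::rnorm(n * M), n, M,
                    dimnames = list(sample_ids, paste0("M", seq_len(M))))
  factors <- factors + outer(as.numeric(labels), effect_sizes)

  x <- matrix(NA_real_, n_genes, n, dimnames = list(gene_ids, sample_ids))
  lam <- within_cor
  sde <- sqrt(1 - within_cor^2)
  g <- 0L
  for (m in seq_len(M)) {
    for (i in seq_len(module_sizes[m])) {
      g <- g + 1L
      x[g, ] <- lam * factors[, m] + sde * stats::rnorm(n)
    }
  }
  if (n_noise_genes > 0)
    x[(g + 1L):n_genes, ] <- stats::rnorm(n_noise_genes * n)

  truth <- structure(list(modules = modules, module_sizes = module_sizes,
                          effect_sizes = effect_sizes,
                          within_cor = within_cor, n_pos = n_pos,
                          n_neg = n_neg, factors = factors, seed = seed),
                     class = "synthetic_truth")
  list(expression = x, labels = labels, truth = truth)
}

#' Bayes-optimal accuracy of the generative model on latent factors
#'
#' The optimal classifier under the generator is linear in the latent
#' factors: \eqn{\sum_m d_m (f_m - d_m/2) > 0} predicts class 1. Applying
#' it to the generated factors gives the ceiling any classifier trained on
#' the observed genes can approach.
#'
#' @param truth a `synthetic_truth`.
#' @param labels the matching 0/1 labels.
#' @return the empirical Bayes-rule accuracy on the generated samples.
#' @export
generative_bayes_accuracy <- function(truth, labels) {
  d <- truth$effect_sizes
  score <- truth$factors %*% d - sum(d^2) / 2
  mean(as.integer(score > 0) == as.integer(labels))
}

#' Expand a gene-level matrix to noisy probes with a probe-gene map
#'
#' Each gene is replicated into 1-3 probes with independent Gaussian noise;
#' a fraction of probes is additionally mapped to a second random gene
#' (multi-mapped probes, which the preprocessing stage must exclude).
#'
#' @param x gene x sample matrix.
#' @param probes_per_gene integer range (min, max) of probes per gene.
#' @param multimap_fraction probability that a probe also maps to a second
#'   gene.
#' @param probe_noise_sd sd of the probe-level measurement noise.
#' @param seed RNG seed.
#' @return list with `probes` (probe x sample matrix) and `map`
#'   (data.frame `probe_id`, `gene_id`).
#' @export
generate_probe_level <- function(x, probes_per_gene = c(1, 3),
                                 multimap_fraction = 0.05,
                                 probe_noise_sd = 0.2, seed = NULL) {
  stopifnot(multimap_fraction >= 0, multimap_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  genes <- rownames(x)
  np <- sample(seq(probes_per_gene[1], probes_per_gene[2]),
               length(genes), replace = TRUE)
  total <- sum(np)
  probe_ids <- sprintf("P%05d", seq_len(total))
  probes <- matrix(NA_real_, total, ncol(x),
                   dimnames = list(probe_ids, colnames(x)))
  map <- data.frame(probe_id = probe_ids,
                    gene_id = rep(genes, times = np),
                    stringsAsFactors = FALSE)
  probes[] <- x[map$gene_id, ] +
    stats::rnorm(total * ncol(x), sd = probe_noise_sd)
  mm <- stats::runif(total) < multimap_fraction
  if (any(mm) && length(genes) > 1) {
    second <- vapply(map$gene_id[mm], function(gn)
      sample(setdiff(genes, gn), 1), character(1))
    map <- rbind(map, data.frame(probe_id = probe_ids[mm], gene_id = second,
                                 stringsAsFactors = FALSE))
  }
  list(probes = probes, map = map)
}

#' Monotone per-gene platform transform
#'
#' Emulates profiling the same samples on a different expression platform
#' (e.g. microarray-trained, RNA-seq-tested): each gene is transformed by an
#' independent affine map \eqn{y = a_g x + b_g + \varepsilon} with
#' \eqn{a_g \sim U(0.5, 2)}, \eqn{b_g \sim U(-2, 2)} and fresh Gaussian
#' noise, and a fraction of genes can be dropped entirely (not measured on
#' the new platform).
#'
#' @param x gene x sample matrix.
#' @param slope_range,intercept_range ranges of the per-gene affine map.
#' @param noise_sd sd of the added measurement noise.
#' @param dropout fraction of genes removed.
#' @param seed RNG seed.
#' @return the transformed matrix (possibly with fewer genes).
#' @export
platform_transform <- function(x, slope_range = c(0.5, 2),
                               intercept_range = c(-2, 2), noise_sd = 0,
                               dropout = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- stats::runif(nrow(x), slope_range[1], slope_range[2])
  b <- stats::runif(nrow(x), intercept_range[1], intercept_range[2])
  y <- x * a + b
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), sd = noise_sd)
  if (dropout > 0) {
    keep <- sort(sample.int(nrow(x), round((1 - dropout) * nrow(x))))
    y <- y[keep, , drop = FALSE]
  }
  y
}
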