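#' Absolute Pearson correlation similarity
#'
#' The unsigned coexpression similarity \eqn{s_{ij} = |cor(x_i, x_j)|} across
#' samples. Genes with zero variance get similarity 0 to every other gene
#' (reported with a message); the diagonal is 1.
#'
#' @param x gene x sample matrix with at least 3 samples.
#' @return symmetric similarity matrix with entries in `[0, 1]`.
#' @export
similarity <- function(x) {
  .check_expr(x)
  if (ncol(x) < 3) stop("at least 3 samples are required for correlations")
  sds <- apply(x, 1, stats::sd)
  s <- abs(suppressWarnings(stats::cor(t(x))))
  if (any(sds == 0)) {
    message(sum(sds == 0), " zero-variance gene(s); similarity set to 0")
    s[sds == 0, ] <- 0
    s[, sds == 0] <- 0
  }
  diag(s) <- 1
  s
}

# Scale-free topology fit index of a connectivity vector: bin k into n_bins
# equal-width bins, regress log10(frequency) on log10(mean k) over non-empty
# bins, and return -sign(slope) * R^2 (so a decreasing power law scores +R^2).
#' @noRd
.scale_free_fit <- function(k, n_bins = 10) {
  if (length(unique(k)) < 2) return(0)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE, labels = FALSE)
  freq <- tabulate(bin, nbins = n_bins)
  km <- vapply(seq_len(n_bins),
               function(b) if (freq[b] > 0) mean(k[bin == b]) else NA_real_,
               numeric(1))
  ok <- freq > 0 & !is.na(km) & km > 0
  if (sum(ok) < 2) return(0)
  lx <- log10(km[ok])
  ly <- log10(freq[ok] / sum(freq))
  if (length(unique(lx)) < 2) return(0)
  fit <- stats::lm(ly ~ lx)
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[[2]]) * r2
}

#' Choose the soft-thresholding power
#'
#' For each candidate power the similarity matrix is raised elementwise to
#' that power (adjacency, zero diagonal) and the scale-free topology fit index
#' of the connectivity distribution is computed. The chosen power is the
#' smallest candidate whose fit reaches `rsq_cut`; if none qualifies, the
#' power with the best fit is returned and `reached_cut` is `FALSE` (with a
#' warning).
#'
#' @param x gene x sample matrix; ignored when `sim` is supplied.
#' @param powers candidate integer powers.
#' @param rsq_cut required scale-free fit index (default 0.85).
#' @param n_bins number of equal-width connectivity bins for the fit.
#' @param sim optional precomputed similarity matrix.
#' @return an object of class `soft_threshold_scan`: a list with `table`
#'   (power, fit, mean_k), `chosen_beta`, and `reached_cut`.
#' @export
pick_soft_threshold <- function(x = NULL, powers = 1:20, rsq_cut = 0.85,
                                n_bins = 10, sim = NULL) {
  if (is.null(sim)) sim <- similarity(x)
  if (nrow(sim) < n_bins) stop("need at least n_bins genes")
  fits <- numeric(length(powers))
  mean_k <- numeric(length(powers))
  for (i in seq_along(powers)) {
    a <- sim^powers[i]
    diag(a) <- 0
    k <- rowSums(a)
    fits[i] <- .scale_free_fit(k, n_bins)
    mean_k[i] <- mean(k)
  }
  qualifying <- which(fits >= rsq_cut)
  if (length(qualifying) > 0) {
    chosen <- powers[qualifying[1]]
    reached <- TRUE
  } else {
    chosen <- powers[which.max(fits)]
    reached <- FALSE
    warning("no power reached the scale-free fit cut ", rsq_cut,
            "; using the best fit (beta = ", chosen, ")")
  }
  structure(list(table = data.frame(power = powers, fit = fits,
                                    mean_k = mean_k),
                 chosen_beta = chosen, reached_cut = reached),
            class = "soft_threshold_scan")
}

#' Choose a usable soft-thresholding power from a scan
#'
#' The plain scale-free criterion (smallest power whose fit reaches the cut)
#' can be satisfied spuriously on hub-free, block-modular data at powers so
#' high that the network disintegrates. This helper restricts the choice to
#' powers whose mean connectivity stays at or above `min_mean_k`; among
#' those it takes the smallest power reaching the cut, else the best fit,
#' and falls back to the conventional unsigned-network default of 6 when no
#' power retains usable connectivity.
#'
#' @param scan a `soft_threshold_scan` from [pick_soft_threshold()].
#' @param rsq_cut required scale-free fit.
#' @param min_mean_k minimum acceptable mean connectivity.
#' @param fallback power used when no candidate keeps `min_mean_k`.
#' @return a single power.
#' @export
choose_power <- function(scan, rsq_cut = 0.85, min_mean_k = 1,
                         fallback = 6) {
  tab <- scan$table
  usable <- tab$mean_k >= min_mean_k
  qualifying <- which(usable & tab$fit >= rsq_cut)
  beta <- if (length(qualifying) > 0) {
    tab$power[qualifying[1]]
  } else if (any(usable)) {
    tab$power[which(usable)[which.max(tab$fit[usable])]]
  } else fallback
  if (beta != scan$chosen_beta)
    message("soft-threshold scan suggested beta = ", scan$chosen_beta,
            " with mean connectivity below ", min_mean_k,
            "; using beta = ", beta)
  beta
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat("Soft-threshold scan: chosen beta =", x$chosen_beta,
      if (x$reached_cut) "(fit cut reached)\n" else "(best fit, cut not reached)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Soft-thresholded adjacency
#'
#' @param sim similarity matrix.
#' @param beta soft-thresholding power.
#' @return adjacency `sim^beta` with zero diagonal.
#' @export
adjacency <- function(sim, beta) {
  a <- sim^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix (unsigned)
#'
#' \deqn{TOM_{ij} = \frac{L_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
#'   \quad L_{ij} = \sum_u a_{iu} a_{uj},}
#' with \eqn{TOM_{ii} = 1}. The TOM augments pairwise adjacency with
#' shared-neighbour structure; `1 - TOM` is the clustering dissimilarity.
#'
#' @param a symmetric adjacency matrix, zero diagonal, entries in `[0, 1]`.
#' @return the TOM matrix.
#' @export
topological_overlap <- function(a) {
  if (!isSymmetric(unname(a))) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency must have zero diagonal")
  if (any(a < 0 | a > 1)) stop("adjacency entries must be in [0, 1]")
  L <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  stopifnot(all(denom > 0))
  tom <- (L + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect coexpression modules by average-linkage clustering of 1 - TOM
#'
#' Genes are clustered with average-linkage hierarchical clustering on the
#' dissimilarity `1 - TOM`; the tree is cut at `cut_height` times the maximum
#' merge height. Clusters smaller than `min_module_size` are assigned module 0
#' (unassigned, "grey"); surviving clusters are renumbered 1..M by decreasing
#' size.
#'
#' @param tom topological overlap matrix.
#' @param min_module_size minimum genes per module (default 20).
#' @param cut_height static cut as a fraction of the maximum merge height.
#' @return named integer vector of module indices (0 = unassigned), with
#'   attribute `sizes` (module inventory); class `module_assignment`.
#' @export
detect_modules <- function(tom, min_module_size = 20, cut_height = 0.99) {
  diss <- 1 - tom
  tree <- stats::hclust(stats::as.dist(diss), method = "average")
  # ties can leave the merge heights non-monotone by ~1e-16; repair before cutree
  if (is.unsorted(tree$height)) tree$height <- cummax(tree$height)
  h <- cut_height * max(tree$height)
  cl <- stats::cutree(tree, h = h)
  names(cl) <- rownames(tom)
  sizes <- table(cl)
  surviving <- names(sizes)[sizes >= min_module_size]
  if (length(surviving) == 0) {
    warning("no cluster reached min_module_size; all genes assigned module 0")
    modules <- stats::setNames(integer(length(cl)), names(cl))
    return(.as_module_assignment(modules))
  }
  # renumber surviving clusters by decreasing size (stable on ties)
  surv_sizes <- sizes[surviving]
  ord <- surviving[order(-as.integer(surv_sizes), seq_along(surviving))]
  modules <- stats::setNames(integer(length(cl)), names(cl))
  for (i in seq_along(ord)) modules[cl == as.integer(ord[i])] <- i
  .as_module_assignment(modules)
}

#' @noRd
.as_module_assignment <- function(modules) {
  sizes <- table(factor(modules, levels = sort(unique(modules))))
  structure(modules, sizes = sizes, class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  s <- attr(x, "sizes")
  cat(length(x), "genes in", sum(names(s) != "0"), "modules",
      "(", sum(x == 0), "unassigned )\n")
  print(s)
  invisible(x)
}

#' Merge modules with highly correlated eigengenes
#'
#' Computes provisional eigengenes and repeatedly merges the closest pair of
#' modules whose eigengene dissimilarity `1 - cor` is below `merge_cut`,
#' recomputing eigengenes after each merge, until stable. Modules are then
#' renumbered by decreasing size.
#'
#' @param x gene x sample matrix.
#' @param modules a `module_assignment`.
#' @param merge_cut eigengene dissimilarity below which modules merge.
#' @param labels optional 0/1 labels used for class balancing of the
#'   provisional eigengenes.
#' @return updated `module_assignment`.
#' @export
merge_close_modules <- function(x, modules, merge_cut = 0.15, labels = NULL) {
  modules <- stats::setNames(as.integer(modules), names(modules))
  repeat {
    ids <- sort(unique(modules[modules > 0]))
    if (length(ids) < 2 || merge_cut <= 0) break
    eg <- compute_eigengenes(x, modules, labels = labels)$eigengenes
    d <- 1 - stats::cor(eg)
    diag(d) <- Inf
    if (min(d) >= merge_cut) break
    pair <- which(d == min(d), arr.ind = TRUE)[1, ]
    m_from <- ids[max(pair)]
    m_to <- ids[min(pair)]
    modules[modules == m_from] <- m_to
  }
  # renumber by decreasing size
  ids <- sort(unique(modules[modules > 0]))
  sizes <- vapply(ids, function(m) sum(modules == m), integer(1))
  ord <- ids[order(-sizes, seq_along(ids))]
  out <- stats::setNames(integer(length(modules)), names(modules))
  for (i in seq_along(ord)) out[modules == ord[i]] <- i
  .as_module_assignment(out)
}
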