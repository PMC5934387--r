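#' Configuration for Bayesian-network learning
#'
#' Collects the tunables of the structure-learning stage with the package
#' defaults: `R = 500` bootstrap networks, the top third averaged, a 0.5 arc
#' strength threshold, imaginary sample size 1, 3 discretization levels from
#' 20 initial quantile bins, no random restarts, and 500 particles for
#' likelihood-weighting inference.
#'
#' @param R number of bootstrap networks per model.
#' @param top_fraction fraction of highest-scoring networks averaged.
#' @param strength_threshold minimum consensus arc strength.
#' @param iss imaginary sample size of the BDe prior.
#' @param levels discretization levels per eigengene.
#' @param ibreaks initial quantile bins for Hartemink discretization.
#' @param restarts random restarts in hill climbing.
#' @param tol minimum score improvement for a hill-climbing move.
#' @param n_particles particles for likelihood weighting.
#' @return a named list of class `bn_config`.
#' @export
bn_config <- function(R = 500, top_fraction = 1 / 3, strength_threshold = 0.5,
                      iss = 1, levels = 3, ibreaks = 20, restarts = 0,
                      tol = 1e-8, n_particles = 500) {
  stopifnot(R >= 1, top_fraction > 0, top_fraction <= 1,
            strength_threshold >= 0, strength_threshold <= 1,
            iss > 0, levels >= 2, ibreaks >= levels, restarts >= 0,
            n_particles >= 1)
  structure(list(R = R, top_fraction = top_fraction,
                 strength_threshold = strength_threshold, iss = iss,
                 levels = as.integer(levels), ibreaks = as.integer(ibreaks),
                 restarts = restarts, tol = tol,
                 n_particles = as.integer(n_particles)),
            class = "bn_config")
}

# stratified k-fold assignment; keeps per-class and overall fold sizes
# within one of each other. Uses the current RNG state.
#' @noRd
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  loads <- stats::setNames(integer(k), seq_len(k))
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    target <- rep_len(order(loads, sample.int(k)), length(idx))
    fold[idx] <- target
    loads <- loads + tabulate(target, nbins = k)
  }
  fold
}

#' Train the subsampled ensemble of consensus Bayesian networks
#'
#' Partitions the samples into `k` stratified folds and trains one consensus
#' network per fold on the other `k - 1` folds (subsampling without
#' replacement, distinct from bagging), so the ensemble consists of `k`
#' models each trained on a 4/5 subsample when `k = 5`. All models share one
#' Hartemink discretization of the eigengenes; the binary `Effect` node is
#' appended to the discrete data and all of its outgoing arcs are
#' blacklisted.
#'
#' @param e samples x modules eigengene matrix.
#' @param labels 0/1 class labels per sample (1 = positive).
#' @param k number of models; must be odd (so the majority vote cannot tie)
#'   or 1.
#' @param seed RNG seed; the run is fully reproducible given the seed.
#' @param config a [bn_config()].
#' @param eigen_model optional `eigengene_model` to embed, making the
#'   ensemble deployable on new expression matrices.
#' @return an object of class `ensemble_model`.
#' @export
train_ensemble <- function(e, labels, k = 5, seed = NULL,
                           config = bn_config(), eigen_model = NULL) {
  labels <- .check_labels(labels, rownames(e))
  if (k != 1 && k %% 2 == 0) stop("k must be odd")
  if (!is.null(seed)) set.seed(seed)

  disc <- hartemink_discretize(e, levels = config$levels,
                               ibreaks = config$ibreaks)
  nodes <- colnames(e)
  d <- cbind(disc$discrete, Effect = labels + 1L)
  levels <- stats::setNames(c(rep(config$levels, length(nodes)), 2L),
                            c(nodes, "Effect"))
  level_labels <- c(lapply(stats::setNames(nodes, nodes),
                           function(v) as.character(seq_len(config$levels))),
                    list(Effect = c("0", "1")))
  blacklist <- cbind(from = rep("Effect", length(nodes)), to = nodes)

  folds <- .stratified_folds(labels, k)
  model_seeds <- sample.int(.Machine$integer.max, k)

  models <- vector("list", k)
  strengths <- vector("list", k)
  for (i in seq_len(k)) {
    rows <- if (k == 1) rep(TRUE, nrow(d)) else folds != i
    di <- d[rows, , drop = FALSE]
    boot <- bootstrap_structures(di, levels = levels, R = config$R,
                                 blacklist = blacklist, iss = config$iss,
                                 seed = model_seeds[i], tol = config$tol,
                                 restarts = config$restarts)
    cons <- consensus_network(boot, top_fraction = config$top_fraction,
                              strength_threshold = config$strength_threshold,
                              blacklist = blacklist)
    models[[i]] <- fit_parameters(cons$dag, di, levels = levels,
                                  iss = config$iss,
                                  level_labels = level_labels)
    strengths[[i]] <- cons$strength
  }

  structure(list(eigen_model = eigen_model, discretization = disc$model,
                 discrete = d, models = models, strengths = strengths,
                 folds = folds, labels = labels, k = k, seed = seed,
                 config = config, nodes = nodes),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("Ensemble of", x$k, "consensus Bayesian network(s) over",
      length(x$nodes), "eigengene(s) + Effect\n")
  for (i in seq_len(x$k)) {
    pa <- sort(names(which(x$models[[i]]$dag[, "Effect"])))
    cat("  model", i, "- Effect parents:",
        if (length(pa)) paste(pa, collapse = ", ") else "(none)", "\n")
  }
  invisible(x)
}

#' Parents of the Effect node across the ensemble
#'
#' By the Markov property, the parents of the childless `Effect` node form
#' its Markov blanket: the modules most predictive of the disease class.
#'
#' @param ensemble an `ensemble_model`.
#' @return named integer vector: for each module that is an Effect parent in
#'   at least one model, the number of models in which it is a parent.
#' @export
effect_parents <- function(ensemble) {
  tab <- table(unlist(lapply(ensemble$models, function(m)
    names(which(m$dag[, "Effect"])))))
  sort(stats::setNames(as.integer(tab), names(tab)), decreasing = TRUE)
}

#' Predict disease class by ensemble majority vote
#'
#' New samples are mapped to eigengenes (by [project_eigengenes()] when an
#' expression matrix is given and the ensemble embeds an eigengene model),
#' the trained discretization is replayed, each model predicts `Effect` by
#' exact CPT lookup, and the majority vote of the `k` models is the final
#' class. The mean posterior probability of class 1 across models is
#' reported as the ROC score. A per-model posterior tie is counted as a
#' vote for class 0.
#'
#' @param object an `ensemble_model`.
#' @param newdata either a genes x samples expression matrix (projected via
#'   the embedded eigengene model) or a samples x modules eigengene matrix
#'   whose columns match the ensemble's nodes.
#' @param ... unused.
#' @return data.frame with `sample_id`, per-model votes `vote_1..vote_k`,
#'   `majority`, and `posterior` (mean P(Effect = 1)).
#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  if (is.matrix(newdata) && all(object$nodes %in% colnames(newdata))) {
    e <- newdata[, object$nodes, drop = FALSE]
  } else {
    if (is.null(object$eigen_model))
      stop("ensemble has no embedded eigengene model; supply an eigengene matrix")
    e <- project_eigengenes(object$eigen_model, newdata)
  }
  dnew <- apply_discretization(object$discretization, e)
  .predict_discrete(object, dnew)
}

#' @noRd
.predict_discrete <- function(object, dnew) {
  n <- nrow(dnew)
  k <- object$k
  votes <- matrix(NA_integer_, n, k)
  post <- matrix(NA_real_, n, k)
  for (i in seq_len(k)) {
    m <- object$models[[i]]
    for (s in seq_len(n)) {
      pr <- suppressWarnings(
        predict_effect_exact(m, dnew[s, ]))
      votes[s, i] <- as.integer(pr$class)
      post[s, i] <- pr$posterior[["1"]]
    }
  }
  majority <- as.integer(rowSums(votes) * 2 > k)
  out <- data.frame(sample_id = rownames(dnew) %||% seq_len(n),
                    votes, majority = majority,
                    posterior = rowMeans(post),
                    stringsAsFactors = FALSE)
  names(out)[1 + seq_len(k)] <- paste0("vote_", seq_len(k))
  out
}

#' Cross-validated performance of the ensemble
#'
#' Uses the same stratified partition as [train_ensemble()] (the `k` trained
#' models are exactly the ensemble's models): model `i`, trained without
#' fold `i`, predicts the held-out fold `i`, and per-fold performance is
#' reported.
#'
#' @param e samples x modules eigengene matrix.
#' @param labels 0/1 class labels.
#' @param k folds / models.
#' @param seed RNG seed.
#' @param config a [bn_config()].
#' @return list of class `cv_result` with the `ensemble`, per-fold
#'   `reports`, and `mean_accuracy`.
#' @export
cross_validate <- function(e, labels, k = 5, seed = NULL,
                           config = bn_config()) {
  ens <- train_ensemble(e, labels, k = k, seed = seed, config = config)
  reports <- vector("list", k)
  for (i in seq_len(k)) {
    hold <- if (k == 1) rep(TRUE, length(labels)) else ens$folds == i
    dnew <- ens$discrete[hold, ens$nodes, drop = FALSE]
    truth <- ens$labels[hold]
    m <- ens$models[[i]]
    pred <- integer(sum(hold))
    score <- numeric(sum(hold))
    for (s in seq_len(nrow(dnew))) {
      pr <- suppressWarnings(predict_effect_exact(m, dnew[s, ]))
      pred[s] <- as.integer(pr$class)
      score[s] <- pr$posterior[["1"]]
    }
    reports[[i]] <- performance(pred, truth, scores = score)
  }
  structure(list(ensemble = ens, reports = reports,
                 mean_accuracy = mean(vapply(reports, `[[`, numeric(1),
                                             "accuracy"))),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  acc <- vapply(x$reports, `[[`, numeric(1), "accuracy")
  cat(length(x$reports), "-fold cross-validation: mean accuracy ",
      round(100 * x$mean_accuracy, 1), "% (folds: ",
      paste(round(100 * acc, 1), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Classification performance report
#'
#' Confusion counts and the standard metrics, with AML-style conventions:
#' class 1 ("positive") drives precision and recall. When `scores` are
#' given, the ROC curve is computed by sweeping a threshold over the scores
#' and the AUC by the trapezoid rule (equal to the Mann-Whitney U statistic
#' divided by \eqn{n_+ n_-}).
#'
#' @param predicted 0/1 predicted classes.
#' @param truth 0/1 true classes.
#' @param scores optional numeric scores (larger = more positive) for the
#'   ROC/AUC.
#' @param positive_class the label treated as positive (default 1).
#' @return an object of class `performance_report`: confusion counts (TP,
#'   FP, FN, TN), `accuracy`, `precision`, `recall`, and (with scores)
#'   `auc` and the `roc` points.
#' @export
performance <- function(predicted, truth, scores = NULL, positive_class = 1) {
  stopifnot(length(predicted) == length(truth))
  pos <- truth == positive_class
  ppos <- predicted == positive_class
  TP <- sum(ppos & pos); FP <- sum(ppos & !pos)
  FN <- sum(!ppos & pos); TN <- sum(!ppos & !pos)
  accuracy <- (TP + TN) / length(truth)
  if (TP + FN == 0) {
    warning("no positive samples in truth; recall undefined")
    recall <- NaN
  } else recall <- TP / (TP + FN)
  precision <- if (TP + FP == 0) NaN else TP / (TP + FP)

  auc <- NA_real_
  roc <- NULL
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(truth))
    np <- sum(pos); nn <- sum(!pos)
    if (np > 0 && nn > 0) {
      thr <- sort(unique(scores), decreasing = TRUE)
      tpr <- vapply(thr, function(t) sum(scores >= t & pos) / np, numeric(1))
      fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / nn, numeric(1))
      fpr <- c(0, fpr); tpr <- c(0, tpr)
      if (fpr[length(fpr)] < 1 || tpr[length(tpr)] < 1) {
        fpr <- c(fpr, 1); tpr <- c(tpr, 1)
      }
      auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
      roc <- data.frame(fpr = fpr, tpr = tpr)
    }
  }
  structure(list(confusion = c(TP = TP, FP = FP, FN = FN, TN = TN),
                 accuracy = accuracy, precision = precision, recall = recall,
                 auc = auc, roc = roc),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cf <- x$confusion
  cat("Confusion: TP =", cf["TP"], "FP =", cf["FP"],
      "FN =", cf["FN"], "TN =", cf["TN"], "\n")
  cat(sprintf("Accuracy %.1f%%  Precision %.1f%%  Recall %.1f%%",
              100 * x$accuracy, 100 * x$precision, 100 * x$recall))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.3f", x$auc))
  cat("\n")
  invisible(x)
}

#' End-to-end training from a gene-level expression matrix
#'
#' Runs the full pipeline on a filtered gene-level matrix: coexpression
#' network on the positive-class training samples (soft threshold chosen by
#' scale-free fit), TOM, module detection, eigengene computation with class
#' balancing, and ensemble training. Returns a deployable classifier.
#'
#' @param x gene x sample matrix (log-scale expression).
#' @param labels 0/1 labels per sample.
#' @param k ensemble size.
#' @param seed RNG seed.
#' @param config a [bn_config()].
#' @param network_class class whose samples build the coexpression network
#'   (default 1, the positive class); `NULL` uses all samples.
#' @param min_module_size,cut_height,merge_cut module detection parameters,
#'   see [detect_modules()] and [merge_close_modules()].
#' @param rsq_cut scale-free fit cut for [pick_soft_threshold()].
#' @param beta optional fixed soft-thresholding power; when `NULL` (default)
#'   the power is chosen by [pick_soft_threshold()], restricted to powers at
#'   which the mean connectivity stays at or above `min_mean_k` -- the
#'   scale-free fit index can be satisfied spuriously at powers so high that
#'   the network disintegrates, in which case the classifier falls back to
#'   the conventional unsigned-network default of 6.
#' @param min_mean_k minimum acceptable mean connectivity for an
#'   automatically chosen power.
#' @param factors optional per-class oversampling factors.
#' @return list of class `modulebayes_classifier` with `ensemble`,
#'   `modules`, `soft_threshold`, and `eigengenes` (training values).
#' @export
train_classifier <- function(x, labels, k = 5, seed = NULL,
                             config = bn_config(), network_class = 1,
                             min_module_size = 20, cut_height = 0.99,
                             merge_cut = 0.15, rsq_cut = 0.85, beta = NULL,
                             min_mean_k = 1, factors = NULL) {
  .check_expr(x)
  labels <- .check_labels(labels, colnames(x))
  xn <- if (is.null(network_class)) x
        else x[, labels == network_class, drop = FALSE]
  sim <- similarity(xn)
  sft <- pick_soft_threshold(sim = sim, rsq_cut = rsq_cut)
  if (is.null(beta))
    beta <- choose_power(sft, rsq_cut = rsq_cut, min_mean_k = min_mean_k)
  sft$chosen_beta <- beta
  tom <- topological_overlap(adjacency(sim, sft$chosen_beta))
  modules <- detect_modules(tom, min_module_size = min_module_size,
                            cut_height = cut_height)
  if (all(modules == 0)) stop("no module detected")
  modules <- merge_close_modules(x, modules, merge_cut = merge_cut,
                                 labels = labels)
  eig <- compute_eigengenes(x, modules, labels = labels, factors = factors)
  ensemble <- train_ensemble(eig$eigengenes, labels, k = k, seed = seed,
                             config = config, eigen_model = eig$model)
  structure(list(ensemble = ensemble, modules = modules,
                 soft_threshold = sft, eigengenes = eig$eigengenes),
            class = "modulebayes_classifier")
}

#' @export
predict.modulebayes_classifier <- function(object, newdata, ...) {
  predict(object$ensemble, newdata, ...)
}

#' @export
print.modulebayes_classifier <- function(x, ...) {
  s <- attr(x$modules, "sizes")
  cat("modulebayes classifier: beta =", x$soft_threshold$chosen_beta, "|",
      sum(names(s) != "0"), "modules |", x$ensemble$k, "BN models\n")
  print(x$ensemble)
  invisible(x)
}
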