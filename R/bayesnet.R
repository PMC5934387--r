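# Discrete Bayesian networks over eigengenes plus a binary Effect node.
#
# A DAG is a logical adjacency matrix (rows = from, columns = to) with node
# names as dimnames. Discrete data are integer matrices with codes 1..r per
# column; `levels` is a named vector of level counts (declared, not inferred,
# so bootstrap replicates that miss a level still score correctly).

#' Create an empty DAG over a node set
#' @param nodes character vector of node names.
#' @return logical adjacency matrix with all arcs absent.
#' @export
empty_dag <- function(nodes) {
  matrix(FALSE, length(nodes), length(nodes),
         dimnames = list(nodes, nodes))
}

#' Arcs of a DAG as a two-column matrix
#' @param dag logical adjacency matrix.
#' @return character matrix with columns `from`, `to`.
#' @export
dag_arcs <- function(dag) {
  idx <- which(dag, arr.ind = TRUE)
  cbind(from = rownames(dag)[idx[, 1]], to = colnames(dag)[idx[, 2]])
}

#' Test a directed graph for acyclicity
#' @param dag logical adjacency matrix.
#' @return `TRUE` if the graph has no directed cycle.
#' @export
is_acyclic <- function(dag) {
  indeg <- colSums(dag)
  remaining <- rep(TRUE, ncol(dag))
  repeat {
    src <- which(remaining & indeg == 0)
    if (length(src) == 0) break
    for (s in src) {
      remaining[s] <- FALSE
      indeg <- indeg - dag[s, ]
    }
  }
  !any(remaining)
}

# reach[i, j] = TRUE iff a directed path i -> ... -> j exists
#' @noRd
.transitive_closure <- function(dag) {
  reach <- dag
  repeat {
    nxt <- reach | ((reach %*% dag) > 0)
    if (identical(nxt, reach)) return(reach)
    reach <- nxt
  }
}

#' @noRd
.topological_order <- function(dag) {
  n <- ncol(dag)
  indeg <- colSums(dag)
  remaining <- rep(TRUE, n)
  out <- integer(0)
  while (length(out) < n) {
    src <- which(remaining & indeg == 0)
    if (length(src) == 0) stop("graph is cyclic")
    s <- src[1]
    out <- c(out, s)
    remaining[s] <- FALSE
    indeg <- indeg - dag[s, ]
    indeg[!remaining] <- 1L  # keep processed nodes out of src
  }
  colnames(dag)[out]
}

# BDeu family score: node with a given parent set.
# alpha_ijk = iss / (r q), alpha_ij = iss / q.
#' @noRd
.bde_family <- function(d, levels, node, parents, iss) {
  r <- levels[[node]]
  n <- nrow(d)
  idx <- d[, node]
  mult <- r
  q <- 1L
  for (p in parents) {
    idx <- idx + (d[, p] - 1L) * mult
    mult <- mult * levels[[p]]
    q <- q * levels[[p]]
  }
  N <- tabulate(idx, nbins = r * q)
  a_ijk <- iss / (r * q)
  a_ij <- iss / q
  Nij <- colSums(matrix(N, nrow = r))
  q * lgamma(a_ij) - sum(lgamma(a_ij + Nij)) +
    sum(lgamma(a_ijk + N)) - r * q * lgamma(a_ijk)
}

#' BDe (BDeu) log score of a DAG
#'
#' The Bayesian Dirichlet equivalent (uniform) log marginal likelihood of a
#' discrete network structure,
#' \deqn{\sum_i \sum_{j=1}^{q_i} \Big[\ln\Gamma(\alpha_{ij}) -
#'   \ln\Gamma(\alpha_{ij}+N_{ij}) + \sum_{k=1}^{r_i}
#'   \big(\ln\Gamma(\alpha_{ijk}+N_{ijk}) - \ln\Gamma(\alpha_{ijk})\big)\Big]}
#' with \eqn{\alpha_{ijk} = iss/(r_i q_i)} and \eqn{\alpha_{ij} = iss/q_i}.
#' The score decomposes over node families and is identical for
#' Markov-equivalent DAGs.
#'
#' @param dag logical adjacency matrix (acyclic).
#' @param d integer data matrix (codes 1..r per column).
#' @param levels named vector of level counts per node; inferred from the
#'   data maxima when omitted.
#' @param iss imaginary sample size of the Dirichlet prior (default 1).
#' @return the log score (a single number).
#' @export
bde_score <- function(dag, d, levels = NULL, iss = 1) {
  if (!is_acyclic(dag)) stop("graph must be acyclic")
  if (is.null(levels)) levels <- apply(d, 2, max)
  nodes <- colnames(dag)
  sum(vapply(nodes, function(v) {
    .bde_family(d, levels, v, nodes[dag[, v]], iss)
  }, numeric(1)))
}

#' @noRd
.make_blacklist_matrix <- function(blacklist, nodes) {
  bl <- matrix(FALSE, length(nodes), length(nodes),
               dimnames = list(nodes, nodes))
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    for (i in seq_len(nrow(blacklist)))
      bl[blacklist[i, 1], blacklist[i, 2]] <- TRUE
  }
  bl
}

#' Greedy hill climbing on the BDe score
#'
#' Starts from the empty DAG and repeatedly applies the best strictly
#' improving single-arc addition, deletion or reversal that keeps the graph
#' acyclic and respects the blacklist, until no move improves the score by
#' more than `tol`. Ties between equally scoring moves are broken
#' lexicographically by (operation, from-node, to-node), so the search is
#' deterministic. With `restarts > 0` the local optimum is perturbed by
#' `perturb` random valid arc changes and re-climbed, keeping the best
#' result (uses the current RNG state).
#'
#' @param d integer data matrix.
#' @param levels named vector of level counts.
#' @param blacklist optional 2-column character matrix of forbidden arcs
#'   (from, to).
#' @param iss imaginary sample size.
#' @param tol minimum score improvement for a move.
#' @param restarts number of random restarts (default 0).
#' @param perturb number of random arc changes per restart.
#' @return list with `dag` (logical adjacency) and `score`.
#' @export
hill_climb <- function(d, levels = NULL, blacklist = NULL, iss = 1,
                       tol = 1e-8, restarts = 0, perturb = 2) {
  if (is.null(levels)) levels <- apply(d, 2, max)
  nodes <- sort(colnames(d))
  d <- d[, nodes, drop = FALSE]
  levels <- levels[nodes]
  p <- length(nodes)
  bl <- .make_blacklist_matrix(blacklist, nodes)
  cache <- new.env(parent = emptyenv(), hash = TRUE)

  fam_score <- function(v, parents) {
    key <- paste0(v, "|", paste(sort(parents), collapse = ","))
    val <- cache[[key]]
    if (is.null(val)) {
      val <- .bde_family(d, levels, v, parents, iss)
      cache[[key]] <- val
    }
    val
  }

  climb <- function(dag) {
    fam <- vapply(nodes, function(v) fam_score(v, nodes[dag[, v]]),
                  numeric(1))
    repeat {
      reach <- .transitive_closure(dag)
      best_delta <- tol
      best <- NULL
      # additions, then deletions, then reversals; nodes in sorted order
      for (x in nodes) for (y in nodes) {
        if (x == y) next
        if (!dag[x, y] && !dag[y, x] && !bl[x, y] && !reach[y, x]) {
          delta <- fam_score(y, c(nodes[dag[, y]], x)) - fam[y]
          if (delta > best_delta) {
            best_delta <- delta
            best <- list(op = "add", x = x, y = y)
          }
        }
      }
      for (x in nodes) for (y in nodes) {
        if (dag[x, y]) {
          delta <- fam_score(y, setdiff(nodes[dag[, y]], x)) - fam[y]
          if (delta > best_delta) {
            best_delta <- delta
            best <- list(op = "delete", x = x, y = y)
          }
        }
      }
      for (x in nodes) for (y in nodes) {
        if (dag[x, y] && !bl[y, x]) {
          tmp <- dag
          tmp[x, y] <- FALSE
          if (.transitive_closure(tmp)[x, y]) next  # x ~> y would close a cycle
          # delta for removing x from pa(y) and adding y to pa(x)
          delta <- (fam_score(y, setdiff(nodes[dag[, y]], x)) - fam[y]) +
            (fam_score(x, c(nodes[dag[, x]], y)) - fam[x])
          if (delta > best_delta) {
            best_delta <- delta
            best <- list(op = "reverse", x = x, y = y)
          }
        }
      }
      if (is.null(best)) break
      if (best$op == "add") {
        dag[best$x, best$y] <- TRUE
        fam[best$y] <- fam_score(best$y, nodes[dag[, best$y]])
      } else if (best$op == "delete") {
        dag[best$x, best$y] <- FALSE
        fam[best$y] <- fam_score(best$y, nodes[dag[, best$y]])
      } else {
        dag[best$x, best$y] <- FALSE
        dag[best$y, best$x] <- TRUE
        fam[best$y] <- fam_score(best$y, nodes[dag[, best$y]])
        fam[best$x] <- fam_score(best$x, nodes[dag[, best$x]])
      }
    }
    list(dag = dag, score = sum(fam))
  }

  best <- climb(empty_dag(nodes))
  if (restarts > 0) {
    for (r in seq_len(restarts)) {
      dag <- best$dag
      for (m in seq_len(perturb)) {
        arcs <- dag_arcs(dag)
        candidates <- list()
        reach <- .transitive_closure(dag)
        for (x in nodes) for (y in nodes) {
          if (x != y && !dag[x, y] && !dag[y, x] && !bl[x, y] &&
              !reach[y, x])
            candidates[[length(candidates) + 1]] <- c("add", x, y)
        }
        if (nrow(arcs) > 0) {
          for (i in seq_len(nrow(arcs)))
            candidates[[length(candidates) + 1]] <- c("delete", arcs[i, 1],
                                                      arcs[i, 2])
        }
        if (length(candidates) == 0) break
        mv <- candidates[[sample.int(length(candidates), 1)]]
        dag[mv[2], mv[3]] <- (mv[1] == "add")
      }
      res <- climb(dag)
      if (res$score > best$score) best <- res
    }
  }
  best
}

#' Learn bootstrap replicates of the network structure
#'
#' Draws `R` bootstrap replicates of the rows (sampling with replacement),
#' runs [hill_climb()] on each, and scores each learned DAG on the *full*
#' dataset so the replicate structures are ranked on a common footing.
#' Reproducible given `seed`.
#'
#' @param d integer data matrix.
#' @param levels named vector of level counts.
#' @param R number of bootstrap networks (default 500).
#' @param blacklist optional forbidden-arc matrix.
#' @param iss imaginary sample size.
#' @param seed optional RNG seed.
#' @param ... further arguments passed to [hill_climb()].
#' @return list of `R` elements, each a list with `dag` and `score` (the
#'   BDe score on the full data).
#' @export
bootstrap_structures <- function(d, levels = NULL, R = 500, blacklist = NULL,
                                 iss = 1, seed = NULL, ...) {
  stopifnot(R >= 1)
  if (is.null(levels)) levels <- apply(d, 2, max)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(d)
  lapply(seq_len(R), function(r) {
    idx <- sample.int(n, n, replace = TRUE)
    hc <- hill_climb(d[idx, , drop = FALSE], levels = levels,
                     blacklist = blacklist, iss = iss, ...)
    list(dag = hc$dag, score = bde_score(hc$dag, d, levels, iss))
  })
}

#' Consensus network from bootstrap structures
#'
#' Retains the top `ceiling(R * top_fraction)` highest-scoring bootstrap
#' DAGs (ties broken by earlier replicate index), computes the strength of
#' every directed arc as the fraction of retained DAGs containing it, and
#' builds the consensus DAG from the arcs with strength at or above
#' `strength_threshold`, inserted in decreasing strength order; an insertion
#' that would create a cycle or violate the blacklist is skipped (with a
#' message).
#'
#' @param boot result of [bootstrap_structures()] (at least 3 networks).
#' @param top_fraction fraction of highest-scoring networks to average.
#' @param strength_threshold minimum arc strength for the consensus.
#' @param blacklist optional forbidden-arc matrix.
#' @return list with `dag`, `strength` (data.frame of arcs with positive
#'   strength), `retained` (number of averaged networks), `scores`.
#' @export
consensus_network <- function(boot, top_fraction = 1 / 3,
                              strength_threshold = 0.5, blacklist = NULL) {
  R <- length(boot)
  if (R < 3) stop("need at least 3 bootstrap networks")
  scores <- vapply(boot, `[[`, numeric(1), "score")
  m <- ceiling(R * top_fraction)
  retained <- order(-scores, seq_len(R))[seq_len(m)]
  nodes <- colnames(boot[[1]]$dag)
  bl <- .make_blacklist_matrix(blacklist, nodes)

  strength <- Reduce(`+`, lapply(boot[retained], function(b) b$dag + 0)) / m
  idx <- which(strength > 0, arr.ind = TRUE)
  tab <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                    strength = strength[idx], stringsAsFactors = FALSE)
  tab <- tab[order(-tab$strength, tab$from, tab$to, method = "radix"), ,
             drop = FALSE]
  rownames(tab) <- NULL

  dag <- empty_dag(nodes)
  for (i in seq_len(nrow(tab))) {
    if (tab$strength[i] < strength_threshold) break
    from <- tab$from[i]; to <- tab$to[i]
    if (bl[from, to]) {
      message("consensus: skipping blacklisted arc ", from, " -> ", to)
      next
    }
    dag[from, to] <- TRUE
    if (!is_acyclic(dag)) {
      dag[from, to] <- FALSE
      message("consensus: skipping cycle-inducing arc ", from, " -> ", to)
    }
  }
  list(dag = dag, strength = tab, retained = m, scores = scores)
}

#' Fit conditional probability tables on a DAG
#'
#' Posterior-mean (Dirichlet-smoothed) CPT entries,
#' \eqn{(N_{ijk} + \alpha_{ijk}) / (N_{ij} + \alpha_{ij})}, so every
#' probability is strictly positive and an unseen parent configuration
#' yields a uniform distribution. CPT array dimensions are (node, parents in
#' lexicographic order).
#'
#' @param dag logical adjacency matrix (acyclic).
#' @param d integer data matrix.
#' @param levels named vector of level counts.
#' @param iss imaginary sample size.
#' @param level_labels optional named list of level labels per node.
#' @return an object of class `bn_model`: list with `dag`, `cpts`,
#'   `levels`, `level_labels`, `iss`.
#' @export
fit_parameters <- function(dag, d, levels = NULL, iss = 1,
                           level_labels = NULL) {
  if (!is_acyclic(dag)) stop("graph must be acyclic")
  if (is.null(levels)) levels <- apply(d, 2, max)
  nodes <- colnames(dag)
  if (is.null(level_labels))
    level_labels <- lapply(stats::setNames(nodes, nodes),
                           function(v) as.character(seq_len(levels[[v]])))
  cpts <- list()
  for (v in nodes) {
    parents <- sort(nodes[dag[, v]])
    r <- levels[[v]]
    q <- if (length(parents)) prod(levels[parents]) else 1L
    idx <- d[, v]
    mult <- r
    for (pa in parents) {
      idx <- idx + (d[, pa] - 1L) * mult
      mult <- mult * levels[[pa]]
    }
    N <- matrix(tabulate(idx, nbins = r * q), nrow = r)
    a_ijk <- iss / (r * q)
    a_ij <- iss / q
    theta <- (N + a_ijk) / rep(colSums(N) + a_ij, each = r)
    cpt <- array(theta, dim = c(r, if (length(parents)) levels[parents]),
                 dimnames = c(list(level_labels[[v]]),
                              level_labels[parents]))
    names(dimnames(cpt)) <- c(v, parents)
    cpts[[v]] <- cpt
  }
  structure(list(dag = dag, cpts = cpts, levels = levels,
                 level_labels = level_labels, iss = iss),
            class = "bn_model")
}

#' @export
print.bn_model <- function(x, ...) {
  arcs <- dag_arcs(x$dag)
  cat("Discrete Bayesian network:", ncol(x$dag), "nodes,",
      nrow(arcs), "arcs\n")
  if (nrow(arcs) > 0)
    cat(paste0("  ", arcs[, 1], " -> ", arcs[, 2], collapse = "\n"), "\n")
  invisible(x)
}

#' @noRd
.effect_posterior <- function(m, evidence, effect = "Effect") {
  cpt <- m$cpts[[effect]]
  parents <- names(dimnames(cpt))[-1]
  if (length(parents) > 0) {
    miss <- setdiff(parents, names(evidence))
    if (length(miss) > 0)
      stop("evidence missing for parent(s): ", paste(miss, collapse = ", "))
    post <- do.call(`[`, c(list(cpt), list(TRUE),
                           as.list(as.integer(evidence[parents]))))
  } else post <- as.vector(cpt)
  stats::setNames(as.numeric(post), m$level_labels[[effect]])
}

#' Exact Effect prediction by CPT lookup
#'
#' Because the Effect node has no children (all of its outgoing arcs are
#' blacklisted), its Markov blanket is its parent set, and the posterior
#' given fully observed parents is simply the matching row of its CPT.
#'
#' @param m a `bn_model` containing an `Effect` node.
#' @param evidence named integer vector of discrete codes (1..r) covering at
#'   least the parents of Effect.
#' @param effect name of the class node.
#' @return list with `class` (the predicted level label; ties go to the
#'   first level, with a warning) and `posterior`.
#' @export
predict_effect_exact <- function(m, evidence, effect = "Effect") {
  post <- .effect_posterior(m, evidence, effect)
  if (length(unique(post)) == 1L)
    warning("posterior tie; predicting the first level")
  cls <- names(post)[which.max(post)]
  list(class = cls, posterior = post)
}

#' Effect prediction by likelihood weighting
#'
#' Importance-sampling inference: each particle samples the unobserved nodes
#' from their CPTs in topological order and is weighted by the likelihood of
#' the evidence nodes given their sampled/observed parents. With the Effect
#' node as the only unobserved node this is a Monte-Carlo estimate of the
#' CPT-lookup posterior of [predict_effect_exact()], and the two agree in
#' the limit of many particles.
#'
#' @param m a `bn_model`.
#' @param evidence named integer vector of discrete codes for the observed
#'   nodes (all non-Effect nodes in the intended use).
#' @param n_particles number of particles (default 500).
#' @param seed optional RNG seed.
#' @param effect name of the class node.
#' @return list with `class`, `posterior`, and `n_effective` (effective
#'   sample size of the importance weights).
#' @export
predict_effect_lw <- function(m, evidence, n_particles = 500, seed = NULL,
                              effect = "Effect") {
  if (!is.null(seed)) set.seed(seed)
  nodes <- .topological_order(m$dag)
  np <- as.integer(n_particles)
  particles <- matrix(NA_integer_, np, length(nodes),
                      dimnames = list(NULL, nodes))
  w <- rep(1, np)
  for (v in nodes) {
    cpt <- m$cpts[[v]]
    parents <- names(dimnames(cpt))[-1]
    r <- m$levels[[v]]
    flat <- as.vector(cpt)
    if (length(parents) > 0) {
      cfg <- rep(1L, np)
      mult <- 1L
      for (pa in parents) {
        cfg <- cfg + (particles[, pa] - 1L) * mult
        mult <- mult * m$levels[[pa]]
      }
    } else cfg <- rep(1L, np)
    if (v %in% names(evidence)) {
      val <- as.integer(evidence[[v]])
      particles[, v] <- val
      w <- w * flat[val + r * (cfg - 1L)]
    } else {
      vals <- integer(np)
      for (u in unique(cfg)) {
        sel <- which(cfg == u)
        pr <- flat[seq_len(r) + r * (u - 1L)]
        vals[sel] <- sample.int(r, length(sel), replace = TRUE, prob = pr)
      }
      particles[, v] <- vals
    }
  }
  wsum <- sum(w)
  stopifnot(wsum > 0)
  post <- vapply(seq_len(m$levels[[effect]]), function(k)
    sum(w[particles[, effect] == k]) / wsum, numeric(1))
  names(post) <- m$level_labels[[effect]]
  cls <- names(post)[which.max(post)]
  list(class = cls, posterior = post,
       n_effective = wsum^2 / sum(w^2))
}
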