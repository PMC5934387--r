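# Independent oracle implementations used to cross-check the package.
# These deliberately use naive algorithms (triple loops, exhaustive
# enumeration, direct formula transcription) and share no code with R/.

# --- moderated t: direct transcription -----------------------------------

# Newton iteration for the inverse of the trigamma function
oracle_trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-12) break
  }
  y
}

# method-of-moments fit of the scaled inverse chi-square prior on variances
oracle_fit_prior <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * oracle_trigamma_inverse(evar)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(emean)
  }
  list(d0 = d0, s0sq = s0)
}

# moderated t with given hyperparameters, feature by feature
oracle_moderated_t <- function(x, labels, d0, s0sq) {
  t_out <- p_out <- numeric(nrow(x))
  for (g in seq_len(nrow(x))) {
    a <- x[g, labels == 1]
    b <- x[g, labels == 0]
    d <- length(a) + length(b) - 2
    s2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / d
    stilde <- if (is.infinite(d0)) s0sq else (d0 * s0sq + d * s2) / (d0 + d)
    se <- sqrt(stilde * (1 / length(a) + 1 / length(b)))
    if (se == 0) {
      t_out[g] <- 0; p_out[g] <- 1
    } else {
      t_out[g] <- (mean(a) - mean(b)) / se
      df_tot <- d + d0
      p_out[g] <- if (is.infinite(df_tot)) 2 * pnorm(-abs(t_out[g]))
                  else 2 * pt(-abs(t_out[g]), df_tot)
    }
  }
  list(t = t_out, p = p_out)
}

# --- TOM: naive O(n^3) loop ----------------------------------------------

oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    L <- 0
    for (u in seq_len(n)) L <- L + a[i, u] * a[u, j]
    tom[i, j] <- (L + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# --- BDe score: separate transcription of the closed form ----------------

oracle_bde <- function(dag, d, levels, iss = 1) {
  nodes <- colnames(dag)
  total <- 0
  for (v in nodes) {
    parents <- nodes[dag[, v]]
    r <- levels[[v]]
    q <- if (length(parents)) prod(levels[parents]) else 1
    # enumerate parent configurations explicitly
    cfgs <- if (length(parents)) {
      do.call(expand.grid, lapply(parents, function(p) seq_len(levels[[p]])))
    } else data.frame(row.names = 1)
    a_ijk <- iss / (r * q)
    a_ij <- iss / q
    for (j in seq_len(q)) {
      sel <- rep(TRUE, nrow(d))
      if (length(parents))
        for (pi in seq_along(parents))
          sel <- sel & d[, parents[pi]] == cfgs[j, pi]
      Nij <- sum(sel)
      total <- total + lgamma(a_ij) - lgamma(a_ij + Nij)
      for (k in seq_len(r)) {
        Nijk <- sum(sel & d[, v] == k)
        total <- total + lgamma(a_ijk + Nijk) - lgamma(a_ijk)
      }
    }
  }
  total
}

# --- DAG enumeration and Markov equivalence ------------------------------

# all DAGs over the given nodes (feasible up to 4 nodes: 543 DAGs)
oracle_all_dags <- function(nodes) {
  p <- length(nodes)
  pairs <- which(diag(p) == 0, arr.ind = TRUE)  # ordered pairs
  n_arcs <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^n_arcs - 1)) {
    dag <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
    bits <- bitwAnd(bitwShiftR(mask, seq_len(n_arcs) - 1L), 1L) == 1L
    dag[pairs[bits, , drop = FALSE]] <- TRUE
    if (is_acyclic(dag)) out[[length(out) + 1]] <- dag
  }
  out
}

# equivalence-class signature: skeleton + unshielded colliders
oracle_cpdag_signature <- function(dag) {
  nodes <- colnames(dag)
  und <- dag | t(dag)
  skel <- apply(which(und & upper.tri(und), arr.ind = TRUE), 1,
                function(ij) paste(nodes[ij[1]], nodes[ij[2]], sep = "-"))
  vstr <- character(0)
  for (y in seq_along(nodes)) {
    pa <- which(dag[, y])
    if (length(pa) >= 2) {
      cmb <- combn(pa, 2)
      for (c_ in seq_len(ncol(cmb))) {
        a <- cmb[1, c_]; b <- cmb[2, c_]
        if (!und[a, b])
          vstr <- c(vstr, paste(sort(nodes[c(a, b)])[1], nodes[y],
                                sort(nodes[c(a, b)])[2], sep = ">"))
      }
    }
  }
  paste(paste(sort(skel), collapse = ";"), "|",
        paste(sort(vstr), collapse = ";"))
}

# --- AUC: Mann-Whitney oracle --------------------------------------------

oracle_mw_auc <- function(scores, truth) {
  sp <- scores[truth == 1]
  sn <- scores[truth == 0]
  u <- 0
  for (a in sp) for (b in sn) u <- u + (a > b) + 0.5 * (a == b)
  u / (length(sp) * length(sn))
}

# --- random discrete BN models and samplers ------------------------------

# random bn_model over `p` 3-level nodes plus a binary Effect with random
# parents; CPT columns drawn from a flat Dirichlet
random_effect_bn <- function(p = 3, max_parents = 2) {
  nodes <- c(paste0("M", seq_len(p)), "Effect")
  levels <- stats::setNames(c(rep(3L, p), 2L), nodes)
  dag <- empty_dag(nodes)
  # random DAG among the M nodes (upper-triangular order keeps it acyclic)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i < j && runif(1) < 0.4) dag[nodes[i], nodes[j]] <- TRUE
  }
  n_pa <- sample.int(min(max_parents, p), 1)
  pa <- sample(nodes[seq_len(p)], n_pa)
  dag[pa, "Effect"] <- TRUE
  level_labels <- c(lapply(stats::setNames(nodes[seq_len(p)],
                                           nodes[seq_len(p)]),
                           function(v) c("1", "2", "3")),
                    list(Effect = c("0", "1")))
  cpts <- list()
  for (v in nodes) {
    parents <- sort(nodes[dag[, v]])
    r <- levels[[v]]
    q <- if (length(parents)) prod(levels[parents]) else 1L
    theta <- vapply(seq_len(q), function(j) {
      g <- rgamma(r, 1)
      g / sum(g)
    }, numeric(r))
    cpt <- array(theta, dim = c(r, if (length(parents)) levels[parents]),
                 dimnames = c(list(level_labels[[v]]), level_labels[parents]))
    names(dimnames(cpt)) <- c(v, parents)
    cpts[[v]] <- cpt
  }
  structure(list(dag = dag, cpts = cpts, levels = levels,
                 level_labels = level_labels, iss = 1),
            class = "bn_model")
}

# forward-sample n rows from a bn_model (integer codes)
sample_bn <- function(m, n) {
  nodes <- colnames(m$dag)
  # simple topological order by repeatedly taking parentless nodes
  dag <- m$dag
  ord <- character(0)
  left <- nodes
  while (length(left)) {
    src <- left[colSums(dag[, left, drop = FALSE]) == 0]
    ord <- c(ord, src[1])
    dag[src[1], ] <- FALSE
    left <- setdiff(left, src[1])
  }
  d <- matrix(NA_integer_, n, length(nodes), dimnames = list(NULL, nodes))
  for (v in ord) {
    cpt <- m$cpts[[v]]
    parents <- names(dimnames(cpt))[-1]
    r <- m$levels[[v]]
    flat <- as.vector(cpt)
    if (length(parents) == 0) {
      d[, v] <- sample.int(r, n, replace = TRUE, prob = flat)
    } else {
      cfg <- rep(1L, n)
      mult <- 1L
      for (pa in parents) {
        cfg <- cfg + (d[, pa] - 1L) * mult
        mult <- mult * m$levels[[pa]]
      }
      for (u in unique(cfg)) {
        sel <- which(cfg == u)
        pr <- flat[seq_len(r) + r * (u - 1L)]
        d[sel, v] <- sample.int(r, length(sel), replace = TRUE, prob = pr)
      }
    }
  }
  d
}

# adjusted Rand index between two labelings (independent check via mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
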