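# BDe scoring, hill climbing, bootstrap consensus, CPTs, inference.

rand_discrete <- function(n, levels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- vapply(levels, function(r) sample.int(r, n, replace = TRUE),
              integer(n))
  colnames(d) <- names(levels)
  d
}

test_that("BDe score matches an independent transcription of the formula", {
  levels <- c(X = 2L, Y = 2L, Z = 2L)
  d <- rand_discrete(8, levels, seed = 1)
  dag <- empty_dag(names(levels))
  dag["X", "Y"] <- TRUE
  dag["Y", "Z"] <- TRUE
  expect_lt(abs(bde_score(dag, d, levels) - oracle_bde(dag, d, levels)),
            1e-10)
  # also on a 3-level, larger instance with a collider
  levels2 <- c(A = 3L, B = 3L, C = 3L)
  d2 <- rand_discrete(60, levels2, seed = 2)
  dag2 <- empty_dag(names(levels2))
  dag2["A", "C"] <- TRUE
  dag2["B", "C"] <- TRUE
  expect_lt(abs(bde_score(dag2, d2, levels2, iss = 2) -
                  oracle_bde(dag2, d2, levels2, iss = 2)), 1e-10)
  expect_error(bde_score({
    g <- empty_dag(c("A", "B")); g["A", "B"] <- g["B", "A"] <- TRUE; g
  }, d2[, 1:2], levels2[1:2]), "acyclic")
})

test_that("Markov-equivalent structures score equally, others decompose", {
  levels <- c(X = 2L, Y = 2L)
  d <- rand_discrete(40, levels, seed = 3)
  g1 <- empty_dag(names(levels)); g1["X", "Y"] <- TRUE
  g2 <- empty_dag(names(levels)); g2["Y", "X"] <- TRUE
  expect_equal(bde_score(g1, d, levels), bde_score(g2, d, levels),
               tolerance = 1e-12)
  # empty graph = sum of single-variable family scores
  g0 <- empty_dag(names(levels))
  s_marginal <- sum(vapply(names(levels), function(v)
    oracle_bde(empty_dag(v), d[, v, drop = FALSE],
               levels[v]), numeric(1)))
  expect_equal(bde_score(g0, d, levels), s_marginal, tolerance = 1e-10)
})

test_that("hill climbing finds the exhaustive optimum on 4-node data", {
  # data from a known chain X1 -> X2 -> X3 -> X4
  set.seed(4)
  n <- 200
  flip <- function(parent, p_copy = 0.85)
    ifelse(runif(n) < p_copy, parent, sample.int(2, n, replace = TRUE))
  X1 <- sample.int(2, n, replace = TRUE)
  X2 <- flip(X1); X3 <- flip(X2); X4 <- flip(X3)
  d <- cbind(X1 = X1, X2 = X2, X3 = X3, X4 = X4)
  levels <- setNames(rep(2L, 4), colnames(d))
  hc <- hill_climb(d, levels)
  dags <- oracle_all_dags(colnames(d))
  expect_equal(length(dags), 543)
  best_oracle <- max(vapply(dags, oracle_bde, numeric(1), d = d,
                            levels = levels))
  expect_equal(hc$score, best_oracle, tolerance = 1e-8)
})

test_that("hill climbing respects blacklists and independence", {
  levels <- c(A = 2L, B = 2L, C = 2L)
  d <- rand_discrete(500, levels, seed = 5)  # mutually independent
  hc <- hill_climb(d, levels)
  expect_equal(sum(hc$dag), 0)  # empty DAG: no improving move
  # blacklist of all arcs forces the empty DAG even with dependence
  d2 <- d; d2[, "B"] <- d2[, "A"]
  nodes <- names(levels)
  bl <- as.matrix(expand.grid(from = nodes, to = nodes,
                              stringsAsFactors = FALSE))
  bl <- bl[bl[, 1] != bl[, 2], ]
  hc2 <- hill_climb(d2, levels, blacklist = bl)
  expect_equal(sum(hc2$dag), 0)
})

test_that("bootstrap structures are reproducible and recover planted arcs", {
  set.seed(6)
  n <- 500
  noisy <- function(parent, r = 3, p_copy = 0.8)
    ifelse(runif(n) < p_copy, parent, sample.int(r, n, replace = TRUE))
  A <- sample.int(3, n, replace = TRUE)
  B <- noisy(A); C <- noisy(B); D <- noisy(B); E <- sample.int(3, n, TRUE)
  d <- cbind(A = A, B = B, C = C, D = D, E = E)
  levels <- setNames(rep(3L, 5), colnames(d))
  b1 <- bootstrap_structures(d, levels, R = 50, seed = 42)
  b2 <- bootstrap_structures(d, levels, R = 50, seed = 42)
  expect_identical(lapply(b1, `[[`, "dag"), lapply(b2, `[[`, "dag"))
  # every true arc present (in some orientation) in >= 80% of replicates
  for (arc in list(c("A", "B"), c("B", "C"), c("B", "D"))) {
    frac <- mean(vapply(b1, function(r)
      r$dag[arc[1], arc[2]] || r$dag[arc[2], arc[1]], logical(1)))
    expect_gte(frac, 0.8)
  }
  # R = 1 with a replicate forced to the full data reduces to hill_climb
  d_tiny <- d[1:5, ]
  set.seed(1); idx <- sample.int(5, 5, replace = TRUE)
  hc_ref <- hill_climb(d_tiny[idx, ], levels)
  b3 <- bootstrap_structures(d_tiny, levels, R = 1, seed = 1)
  expect_identical(b3[[1]]$dag, hc_ref$dag)
})

test_that("consensus follows retention, threshold and acyclicity rules", {
  nodes <- c("A", "B", "C")
  mk <- function(arcs) {
    g <- empty_dag(nodes)
    for (a in arcs) g[a[1], a[2]] <- TRUE
    g
  }
  # 6 hand-written DAGs with hand-assigned scores; top third = 2 retained
  boot <- list(
    list(dag = mk(list(c("A", "B"), c("B", "C"))), score = -10),  # retained
    list(dag = mk(list(c("A", "B"), c("C", "B"))), score = -11),  # retained
    list(dag = mk(list(c("B", "A"))), score = -50),
    list(dag = mk(list(c("C", "A"))), score = -60),
    list(dag = mk(list()), score = -70),
    list(dag = mk(list(c("A", "C"))), score = -80))
  cons <- consensus_network(boot, top_fraction = 1 / 3,
                            strength_threshold = 0.5)
  expect_equal(cons$retained, 2)
  # A->B in 2/2 retained (strength 1); B->C and C->B in 1/2 each (0.5);
  # B->C inserted first (ties broken lexicographically by from, to),
  # C->B then skipped as cycle-inducing
  expect_true(cons$dag["A", "B"])
  expect_true(cons$dag["B", "C"])
  expect_false(cons$dag["C", "B"])
  expect_equal(sum(cons$dag), 2)
  st <- cons$strength
  expect_equal(st$strength[st$from == "A" & st$to == "B"], 1)
  # all identical bootstrap DAGs: consensus is that DAG, strengths 1
  same <- replicate(6, list(dag = mk(list(c("A", "B"))), score = -1),
                    simplify = FALSE)
  cons2 <- consensus_network(same)
  expect_identical(cons2$dag, mk(list(c("A", "B"))))
  expect_true(all(cons2$strength$strength == 1))
  # 40% arc with threshold 0.5 is excluded
  boot3 <- c(replicate(2, list(dag = mk(list(c("A", "B"))), score = -1),
                       simplify = FALSE),
             replicate(3, list(dag = mk(list()), score = -2),
                       simplify = FALSE))
  cons3 <- consensus_network(boot3, top_fraction = 1)
  expect_equal(sum(cons3$dag), 0)
  expect_error(consensus_network(boot[1:2]), "at least 3")
})

test_that("fitted CPTs are smoothed posterior means", {
  # binary node, no parents, counts (3, 1), iss = 1 -> (0.7, 0.3)
  d <- cbind(X = c(1L, 1L, 1L, 2L))
  m <- fit_parameters(empty_dag("X"), d, c(X = 2L), iss = 1)
  expect_equal(as.vector(m$cpts$X), c(0.7, 0.3))
  # iss -> 0 approaches maximum likelihood
  m0 <- fit_parameters(empty_dag("X"), d, c(X = 2L), iss = 1e-9)
  expect_equal(as.vector(m0$cpts$X), c(0.75, 0.25), tolerance = 1e-8)
  # CPT columns sum to 1 and stay positive on random instances
  levels <- c(A = 3L, B = 2L, C = 3L)
  dr <- rand_discrete(30, levels, seed = 7)
  dag <- empty_dag(names(levels))
  dag["A", "B"] <- dag["C", "B"] <- TRUE
  mr <- fit_parameters(dag, dr, levels)
  cpt <- mr$cpts$B
  expect_lt(max(abs(apply(cpt, c(2, 3), sum) - 1)), 1e-12)
  expect_true(all(cpt > 0))
  # unseen parent configuration is uniform (pure prior)
  dag1 <- empty_dag(c("A", "B"))
  dag1["A", "B"] <- TRUE
  d1 <- cbind(A = rep(1L, 10), B = sample.int(2, 10, replace = TRUE))
  m1 <- fit_parameters(dag1, d1, c(A = 3L, B = 2L))
  expect_equal(unname(m1$cpts$B[, 2]), c(0.5, 0.5))
  expect_equal(unname(m1$cpts$B[, 3]), c(0.5, 0.5))
})

test_that("exact Effect prediction reads the CPT row", {
  set.seed(8)
  m <- random_effect_bn(p = 2)
  ev <- c(M1 = 2L, M2 = 3L)
  pr <- predict_effect_exact(m, ev)
  pa <- sort(names(which(m$dag[, "Effect"])))
  cpt <- m$cpts$Effect
  row <- do.call(`[`, c(list(cpt), list(TRUE), as.list(ev[pa])))
  expect_equal(unname(pr$posterior), as.numeric(row))
  expect_equal(sum(pr$posterior), 1, tolerance = 1e-12)
  expect_equal(pr$class, c("0", "1")[which.max(row)])
  # no parents: posterior is the marginal CPT
  m2 <- random_effect_bn(p = 2)
  m2$dag[, "Effect"] <- FALSE
  m2$cpts$Effect <- array(c(0.7, 0.3), dim = 2,
                          dimnames = stats::setNames(list(c("0", "1")),
                                                     "Effect"))
  pr2 <- predict_effect_exact(m2, ev)
  expect_equal(unname(pr2$posterior), c(0.7, 0.3))
  expect_equal(pr2$class, "0")
  # tie -> class 0 with a warning
  m2$cpts$Effect[] <- c(0.5, 0.5)
  expect_warning(pr3 <- predict_effect_exact(m2, ev), "tie")
  expect_equal(pr3$class, "0")
  # missing parent errors
  m3 <- random_effect_bn(p = 3)
  m3$dag[, "Effect"] <- FALSE
  m3$dag["M1", "Effect"] <- TRUE
  m3$cpts$Effect <- array(rep(0.5, 6), dim = c(2, 3),
                          dimnames = list(Effect = c("0", "1"),
                                          M1 = c("1", "2", "3")))
  expect_error(predict_effect_exact(m3, c(M2 = 1L)), "missing")
})

test_that("likelihood weighting agrees with the exact CPT lookup", {
  set.seed(9)
  n_draws <- 60
  for (i in seq_len(n_draws)) {
    m <- random_effect_bn(p = 3)
    ev <- setNames(sample.int(3, 3, replace = TRUE), paste0("M", 1:3))
    exact <- suppressWarnings(predict_effect_exact(m, ev))
    lw <- predict_effect_lw(m, ev, n_particles = 50000)
    se <- sqrt(exact$posterior[["1"]] * (1 - exact$posterior[["1"]]) /
                 lw$n_effective)
    expect_lt(abs(lw$posterior[["1"]] - exact$posterior[["1"]]),
              max(5 * se, 1e-3))
  }
  # fixed seed is reproducible, even with a single particle
  m <- random_effect_bn(p = 2)
  ev <- c(M1 = 1L, M2 = 2L)
  r1 <- predict_effect_lw(m, ev, n_particles = 1, seed = 99)
  r2 <- predict_effect_lw(m, ev, n_particles = 1, seed = 99)
  expect_identical(r1, r2)
  # deterministic CPT: posterior exactly (1, 0)
  m$dag[, "Effect"] <- FALSE
  m$dag["M1", "Effect"] <- TRUE
  m$cpts$Effect <- array(rep(c(1, 0), 3), dim = c(2, 3),
                         dimnames = list(Effect = c("0", "1"),
                                         M1 = c("1", "2", "3")))
  r3 <- predict_effect_lw(m, ev, n_particles = 100, seed = 1)
  expect_equal(unname(r3$posterior), c(1, 0))
})

test_that("consensus structure recovery on a known 10-node network", {
  set.seed(10)
  truth <- random_effect_bn(p = 9)   # 9 three-level nodes + binary Effect
  # strengthen the dependencies: deterministic-ish CPT columns
  for (v in colnames(truth$dag)) {
    cpt <- truth$cpts[[v]]
    flat <- matrix(as.vector(cpt), nrow = dim(cpt)[1])
    for (j in seq_len(ncol(flat))) {
      peak <- which.max(flat[, j])
      flat[, j] <- 0.1 / (nrow(flat) - 1)
      flat[peak, j] <- 0.9
    }
    truth$cpts[[v]][] <- flat
  }
  d <- sample_bn(truth, 1000)
  boot <- bootstrap_structures(d, truth$levels, R = 30, seed = 11)
  cons <- consensus_network(boot)
  skel <- function(g) {
    und <- g | t(g)
    apply(which(und & upper.tri(und), arr.ind = TRUE), 1, function(ij)
      paste(sort(c(colnames(g)[ij[1]], colnames(g)[ij[2]])), collapse = "~"))
  }
  s_true <- skel(truth$dag)
  s_est <- skel(cons$dag)
  tp <- length(intersect(s_true, s_est))
  f1 <- 2 * tp / (length(s_true) + length(s_est))
  expect_gte(f1, 0.8)
})

test_that("hill-climb output is always acyclic and blacklist-compliant", {
  set.seed(12)
  for (i in 1:5) {
    levels <- setNames(rep(2L, 5), paste0("N", 1:5))
    d <- rand_discrete(100, levels)
    d[, 2] <- ifelse(runif(100) < 0.7, d[, 1], d[, 2])
    d[, 4] <- ifelse(runif(100) < 0.7, d[, 3], d[, 4])
    bl <- cbind(from = "N5", to = paste0("N", 1:4))
    hc <- hill_climb(d, levels, blacklist = bl, restarts = 1)
    expect_true(is_acyclic(hc$dag))
    expect_true(all(!hc$dag["N5", paste0("N", 1:4)]))
  }
})
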