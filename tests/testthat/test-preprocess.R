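# Probe-level preprocessing: moderated/Welch tests, BH adjustment,
# top-fraction filtering, probe-to-gene collapsing.

toy_expr <- function(nf = 4, ns = 6, seed = 42) {
  set.seed(seed)
  matrix(rnorm(nf * ns), nf, ns,
         dimnames = list(sprintf("f%02d", seq_len(nf)),
                         sprintf("s%02d", seq_len(ns))))
}

test_that("moderated t with fixed hyperparameters matches the direct formula", {
  x <- toy_expr(4, 6)
  y <- c(1, 1, 1, 0, 0, 0)
  for (hp in list(c(2, 0.5), c(0.7, 1.3))) {
    res <- moderated_t_test(x, y, d0 = hp[1], s0sq = hp[2])
    orac <- oracle_moderated_t(x, y, d0 = hp[1], s0sq = hp[2])
    expect_equal(res$t_statistic, orac$t, tolerance = 1e-12)
    expect_equal(res$p_value, orac$p, tolerance = 1e-12)
  }
})

test_that("d0 = 0 reproduces the ordinary pooled-variance t exactly", {
  x <- toy_expr(12, 10, seed = 7)
  y <- rep(c(1, 0), each = 5)
  res <- moderated_t_test(x, y, d0 = 0)
  for (g in seq_len(nrow(x))) {
    tt <- t.test(x[g, y == 1], x[g, y == 0], var.equal = TRUE)
    expect_equal(res$t_statistic[g], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p_value[g], tt$p.value, tolerance = 1e-12)
  }
})

test_that("d0 = Inf gives a z-statistic with the prior variance", {
  x <- toy_expr(5, 8, seed = 3)
  y <- rep(c(1, 0), each = 4)
  res <- moderated_t_test(x, y, d0 = Inf, s0sq = 2)
  m1 <- rowMeans(x[, y == 1]); m0 <- rowMeans(x[, y == 0])
  z <- (m1 - m0) / sqrt(2 * (1 / 4 + 1 / 4))
  expect_equal(res$t_statistic, unname(z), tolerance = 1e-12)
  expect_equal(res$p_value, unname(2 * pnorm(-abs(z))), tolerance = 1e-12)
})

test_that("estimated shrinkage agrees with the independent prior fit and limma", {
  x <- toy_expr(80, 12, seed = 11)
  y <- rep(c(1, 0), each = 6)
  res <- moderated_t_test(x, y)
  d <- ncol(x) - 2
  s2 <- apply(x, 1, function(v)
    ((5) * var(v[y == 1]) + (5) * var(v[y == 0])) / d)
  prior <- oracle_fit_prior(s2, d)
  expect_equal(attr(res, "d0"), prior$d0, tolerance = 1e-6)
  expect_equal(attr(res, "s0sq"), prior$s0sq, tolerance = 1e-6)
  orac <- oracle_moderated_t(x, y, prior$d0, prior$s0sq)
  expect_equal(res$t_statistic, orac$t, tolerance = 1e-8)
  # independent route: limma's lmFit + eBayes moderated t
  fit <- limma::eBayes(limma::lmFit(x, cbind(1, y)))
  expect_equal(res$t_statistic, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(order(res$p_value), order(fit$p.value[, 2]))
})

test_that("identical groups give t = 0 and p = 1", {
  x <- matrix(rep(c(1, 2, 3), each = 6), 3, 6, byrow = TRUE,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:6)))
  y <- rep(c(1, 0), 3)
  res <- moderated_t_test(x, y, d0 = 0)
  expect_equal(res$t_statistic, rep(0, 3))
  expect_equal(res$p_value, rep(1, 3))
  resw <- moderated_t_test(x, y, method = "welch")
  expect_equal(resw$t_statistic, rep(0, 3))
  expect_equal(resw$p_value, rep(1, 3))
})

test_that("welch mode matches t.test and single-class input errors", {
  x <- toy_expr(6, 9, seed = 5)
  y <- c(rep(1, 4), rep(0, 5))
  res <- moderated_t_test(x, y, method = "welch")
  for (g in seq_len(nrow(x))) {
    tt <- t.test(x[g, y == 1], x[g, y == 0])
    expect_equal(res$t_statistic[g], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p_value[g], tt$p.value, tolerance = 1e-12)
  }
  expect_error(moderated_t_test(x, rep(1, 9)), "labels")
})

test_that("BH adjustment matches the hand computation and rejects NaN", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_error(adjust_pvalues(c(0.1, NaN)), "NA")
  expect_equal(adjust_pvalues(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  # monotone and >= raw
  set.seed(1)
  p <- runif(50)
  a <- adjust_pvalues(p)
  expect_true(all(a >= p))
  expect_true(all(a <= 1))
})

test_that("top-fraction filter keeps smallest p-values, ties by probe ID", {
  x <- toy_expr(9, 6, seed = 2)
  y <- rep(c(1, 0), each = 3)
  stats <- moderated_t_test(x, y)
  kept <- filter_top_fraction(x, stats, 1 / 3)
  expect_equal(nrow(kept), 3)
  expect_setequal(rownames(kept),
                  stats$feature_id[order(stats$p_value)][1:3])
  # survivors keep their original row order
  expect_equal(rownames(kept),
               rownames(x)[rownames(x) %in% rownames(kept)])
  # fraction 1 is the identity
  expect_identical(filter_top_fraction(x, stats, 1), x)
  # ties at the cutoff: deterministic lexicographic tie-break, exact count
  x10 <- toy_expr(10, 6, seed = 8)
  st <- data.frame(feature_id = rownames(x10),
                   p_value = c(0.001, rep(0.5, 8), 0.002))
  kept10 <- filter_top_fraction(x10, st, 0.4)   # ceiling(4) kept
  expect_equal(nrow(kept10), 4)
  expect_setequal(rownames(kept10), c("f01", "f10", "f02", "f03"))
  expect_error(filter_top_fraction(x, stats[1:3, ], 0.5), "cover")
})

test_that("gene representatives follow the multi-map/lowest-p rules", {
  x <- toy_expr(3, 6, seed = 4)
  rownames(x) <- c("p1", "p2", "p3")
  map <- data.frame(probe_id = c("p1", "p2", "p3", "p3"),
                    gene_id = c("gA", "gA", "gA", "gB"))
  stats <- data.frame(feature_id = c("p1", "p2", "p3"),
                      p_value = c(0.01, 0.001, 1e-9))
  out <- select_gene_representatives(x, map, stats)
  # p3 excluded (multi-mapped); gA represented by p2 (lowest p among p1, p2)
  expect_equal(rownames(out), "gA")
  expect_equal(unname(attr(out, "representative_probe")["gA"]), "p2")
  expect_equal(unname(out["gA", ]), unname(x["p2", ]))
})

test_that("representative selection is idempotent and handles edge cases", {
  x <- toy_expr(6, 5, seed = 9)
  map <- data.frame(probe_id = rownames(x),
                    gene_id = paste0("g", c(1, 1, 2, 2, 3, 3)))
  stats <- data.frame(feature_id = rownames(x),
                      p_value = c(0.5, 0.1, 0.3, 0.2, 0.9, 0.8))
  out <- select_gene_representatives(x, map, stats)
  expect_equal(nrow(out), 3)
  expect_false(anyDuplicated(rownames(out)) > 0)
  # idempotent: re-apply with an identity map and matching stats
  map2 <- data.frame(probe_id = rownames(out), gene_id = rownames(out))
  stats2 <- data.frame(feature_id = rownames(out),
                       p_value = stats$p_value[match(
                         attr(out, "representative_probe"),
                         stats$feature_id)])
  out2 <- select_gene_representatives(out, map2, stats2)
  expect_equal(out2[seq_len(nrow(out2)), ], out[seq_len(nrow(out)), ])
  # single probe, single gene: passthrough with renamed row
  single <- select_gene_representatives(
    x[1, , drop = FALSE],
    data.frame(probe_id = rownames(x)[1], gene_id = "gX"),
    stats[1, ])
  expect_equal(rownames(single), "gX")
  expect_equal(unname(single[1, ]), unname(x[1, ]))
  # unmapped probes are dropped with a message
  expect_message(
    select_gene_representatives(x, map[-1, , drop = FALSE], stats),
    "unmapped")
  # nothing mappable
  expect_error(
    select_gene_representatives(x, map[0, , drop = FALSE], stats),
    "no mappable probes")
})
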