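test_that("delta-Ct method reproduces hand-checked pairwise SDs and scores", {
  m <- toy_matrix_abc()
  res <- delta_ct_method(m)
  # values frozen from the brute-force oracle
  expect_equal(unname(res$pairwise_sd["A", "B"]), 1.0, tolerance = 1e-10)
  expect_equal(unname(res$pairwise_sd["A", "C"]), 0.5773503, tolerance = 1e-6)
  expect_equal(unname(res$pairwise_sd["B", "C"]), 0.5773503, tolerance = 1e-6)
  expect_equal(unname(res$score), c(0.7886751, 0.7886751, 0.5773503),
               tolerance = 1e-6)
  expect_equal(unname(res$rank["C"]), 1)
  expect_equal(res$score, oracle_delta_ct_scores(m), tolerance = 1e-12)
  expect_equal(diag(res$pairwise_sd), c(A = 0, B = 0, C = 0))

  # parallel profiles have pairwise SD zero
  m2 <- ct_matrix(matrix(c(20, 21, 22, 23, 24, 25, 19, 25, 20), 3,
                         byrow = TRUE,
                         dimnames = list(c("A", "B", "C"), paste0("s", 1:3))))
  expect_equal(unname(delta_ct_method(m2)$pairwise_sd["A", "B"]), 0)
  expect_error(delta_ct_method(ct_matrix(unclass(m)[1:2, ])), "3 genes")
})

test_that("geNorm M equals the delta-Ct score at E = 2 and degenerates correctly", {
  m <- toy_matrix_abc()
  g <- genorm(m)
  expect_equal(unname(g$full_set_M), c(0.7886751, 0.7886751, 0.5773503),
               tolerance = 1e-6)
  expect_equal(g$full_set_M, oracle_genorm_M(m), tolerance = 1e-12)
  # k = 3 genes: exactly one V entry, n = 2
  expect_equal(g$v_series$n, 2L)

  # proportional quantities: all M and V are zero
  base <- c(s1 = 20, s2 = 21.5, s3 = 23, s4 = 19)
  mp <- ct_matrix(rbind(A = base, B = base + 2, C = base + 5))
  gp <- genorm(mp)
  expect_equal(unname(gp$full_set_M), rep(0, 3))
  expect_equal(gp$v_series$V, 0)
  expect_error(genorm(structure(list(q = matrix(c(-1, 1, 1, 1, 1, 1, 1, 1, 1),
                                                3, 3, dimnames = list(letters[1:3], letters[4:6])),
                                     efficiency = NULL),
                                class = "rel_quantities")),
               "positive")
})

test_that("geNorm full-set M and delta-Ct scores coincide on random matrices", {
  set.seed(101)
  for (i in 1:25) {
    m <- ct_matrix(matrix(runif(5 * 6, 15, 32), 5, 6,
                          dimnames = list(paste0("g", 1:5), paste0("s", 1:6))))
    expect_equal(genorm(m)$full_set_M, delta_ct_method(m)$score,
                 tolerance = 1e-12)
  }
})

test_that("per-sample shifts leave ratio methods invariant but move BestKeeper", {
  set.seed(11)
  m <- random_grid_matrix(4, 6)
  # shifts large against the grid spread, so per-gene dispersion must grow
  shift <- c(6, -6, 7, -7, 8, -8)
  m_shift <- ct_matrix(sweep(unclass(m), 2, -shift))
  expect_equal(delta_ct_method(m_shift)$score, delta_ct_method(m)$score,
               tolerance = 1e-12)
  expect_equal(delta_ct_method(m_shift)$pairwise_sd,
               delta_ct_method(m)$pairwise_sd, tolerance = 1e-12)
  expect_equal(genorm(m_shift)$full_set_M, genorm(m)$full_set_M,
               tolerance = 1e-12)
  expect_equal(genorm(m_shift)$v_series$V, genorm(m)$v_series$V,
               tolerance = 1e-12)
  # BestKeeper dispersion strictly increases under this non-uniform pattern
  bk0 <- bestkeeper(m)$stats$sd_mad
  bk1 <- bestkeeper(m_shift)$stats$sd_mad
  expect_true(all(bk1 > bk0))
})

test_that("per-gene shifts cancel everywhere except BestKeeper's CV", {
  set.seed(12)
  m <- random_grid_matrix(4, 6)
  m_shift <- unclass(m); m_shift["g2", ] <- m_shift["g2", ] + 4
  m_shift <- ct_matrix(m_shift)
  expect_equal(delta_ct_method(m_shift)$score, delta_ct_method(m)$score,
               tolerance = 1e-12)
  expect_equal(genorm(m_shift)$full_set_M, genorm(m)$full_set_M,
               tolerance = 1e-12)
  expect_equal(normfinder(m_shift)$score, normfinder(m)$score,
               tolerance = 1e-10)
  expect_equal(bestkeeper(m_shift)$stats$sd_mad, bestkeeper(m)$stats$sd_mad,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(bestkeeper(m_shift)$stats$cv_percent[2],
                                bestkeeper(m)$stats$cv_percent[2])))
})

test_that("geNorm stepwise exclusion removes the least stable gene first", {
  # one gene wildly unstable: it must be excluded at step 1 and ranked last
  set.seed(4)
  base <- stats::setNames(runif(6, 19, 21), paste0("s", 1:6))
  m <- ct_matrix(rbind(stableA = base + rnorm(6, 0, 0.05),
                       stableB = base + rnorm(6, 0, 0.05),
                       mid = base + rnorm(6, 0, 0.4),
                       wild = base + rnorm(6, 0, 3)))
  g <- genorm(m)
  expect_equal(g$removal_order[1], "wild")
  expect_equal(unname(g$rank["wild"]), 4)
  expect_setequal(names(sort(g$rank))[1:2], c("stableA", "stableB"))
  # v_series entries: k - 2
  expect_equal(nrow(g$v_series), 2L)
  # full_set mode ranks by full-set M without removal
  gf <- genorm(m, mode = "full_set")
  expect_equal(gf$rank, rank(gf$full_set_M, ties.method = "average")[names(gf$rank)],
               ignore_attr = FALSE)
})

test_that("NormFinder: model-perfect data scores zero; planted order recovered", {
  alpha <- c(g1 = -20, g2 = -22, g3 = -25, g4 = -18)
  beta <- c(s1 = 0.5, s2 = -0.3, s3 = 0.1, s4 = 0, s5 = -0.8)
  y <- outer(alpha, beta, `+`)
  nf0 <- normfinder(ct_matrix(-y), mode = "ungrouped")
  expect_equal(unname(nf0$score), rep(0, 4))

  sig <- c(0.05, 0.05, 0.5, 1.0)
  genes <- data.frame(gene = paste0("g", 1:4), mu = c(20, 22, 25, 18),
                      sigma_bio = sig)
  cfg <- sim_config(genes, data.frame(sample = paste0("s", 1:60)),
                    sigma_load = 0.2, sigma_tech = 0, n_tech_reps = 1)
  ok <- 0
  for (seed in 1:10) {
    sim <- simulate_ct_table(cfg, seed = seed)
    nf <- normfinder(aggregate_replicates(sim$table), mode = "ungrouped")
    ok <- ok + (all(names(sort(nf$rank))[3:4] == c("g3", "g4")) &&
                  all(names(sort(nf$rank))[1:2] %in% c("g1", "g2")))
  }
  expect_gte(ok, 9)
})

test_that("NormFinder matches the moment-system oracle and REML is sane", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_grid_matrix(4, 6)
    expect_equal(normfinder(m, mode = "ungrouped")$score,
                 oracle_normfinder_sigma(unclass(m)), tolerance = 1e-10)
  }
})

test_that("grouped NormFinder follows the centering algebra on a planted shift", {
  k <- 4
  m <- matrix(20, k, 4, dimnames = list(paste0("g", 1:k), paste0("s", 1:4)))
  m["g1", c("s3", "s4")] <- 19  # +1 log2 expression in group B, zero noise
  ss <- sample_set("two", paste0("s", 1:4),
                   c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
  nf <- normfinder(ct_matrix(m), ss)
  expect_equal(nf$mode, "grouped")
  # after per-sample centering: d = +/- (1 - 1/k)/2 for the shifted gene,
  # -/+ 1/(2k) for the others; within-group variances are exactly zero
  expect_equal(unname(nf$score["g1"]), (1 - 1 / k) / 2, tolerance = 1e-12)
  expect_equal(unname(nf$score[c("g2", "g3", "g4")]), rep(1 / (2 * k), 3),
               tolerance = 1e-12)
  expect_equal(unname(colSums(nf$inter_group_deviation)), c(0, 0),
               tolerance = 1e-9)
  expect_equal(unname(nf$intra_group_variance), matrix(0, k, 2),
               tolerance = 1e-12)

  ss_bad <- sample_set("bad", paste0("s", 1:3),
                       c(s1 = "A", s2 = "A", s3 = "B"))
  expect_error(normfinder(ct_matrix(m[, 1:3]), ss_bad), ">= 2 samples")
})

test_that("BestKeeper statistics match hand arithmetic and tie correctly", {
  m <- ct_matrix(matrix(c(20, 20, 20, 20, 19, 21, 20, 20), 2, byrow = TRUE,
                        dimnames = list(c("flat", "vary"), paste0("s", 1:4))))
  bk <- bestkeeper(m)
  st <- bk$stats
  expect_equal(st$sd_mad, c(0, 0.5))
  expect_equal(st$cv_percent, c(0, 2.5))
  expect_equal(st$arithmetic_mean_ct, c(20, 20))
  tol <- 1e-9
  expect_true(all(st$min_ct <= st$geometric_mean_ct + tol &
                    st$geometric_mean_ct <= st$arithmetic_mean_ct + tol &
                    st$arithmetic_mean_ct <= st$max_ct + tol))
  # duplicated gene profiles tie with average ranks (a, b beat c: mad 0.5 < 0.75)
  m2 <- ct_matrix(matrix(c(19, 21, 20, 20, 19, 21, 20, 20, 25, 25, 25, 27),
                         3, byrow = TRUE,
                         dimnames = list(c("a", "b", "c"), paste0("s", 1:4))))
  bk2 <- bestkeeper(m2)
  expect_equal(unname(bk2$rank[c("a", "b", "c")]), c(1.5, 1.5, 3))
  expect_equal(bk2$stats$sd_mad[1], bk2$stats$sd_mad[2])
  expect_error(bestkeeper(ct_matrix(matrix(c(-1, 2, 2, 2), 2,
                                           dimnames = list(c("x", "y"), c("s1", "s2"))))),
               "non-positive")
  # BestKeeper index correlation is 1 for a gene proportional to the index
  prof <- c(s1 = 20, s2 = 21, s3 = 22, s4 = 23)
  mi <- ct_matrix(rbind(g1 = prof, g2 = prof, g3 = prof))
  expect_equal(unname(bestkeeper(mi)$index_correlation), rep(1, 3))
})

test_that("all four algorithms agree with brute-force oracles on integer grids", {
  set.seed(2025)
  for (i in 1:60) {
    m <- random_grid_matrix(3, 3)
    expect_equal(delta_ct_method(m)$score, oracle_delta_ct_scores(m),
                 tolerance = 1e-12)
    g <- genorm(m)
    expect_equal(g$full_set_M, oracle_genorm_M(m), tolerance = 1e-12)
    top <- names(sort(g$rank))
    expect_equal(g$v_series$V, oracle_v_series(unclass(m), top),
                 tolerance = 1e-12)
    bk <- bestkeeper(m)$stats
    ob <- oracle_bestkeeper(unclass(m))
    expect_equal(bk$sd_mad, unname(ob[, "mad"]), tolerance = 1e-12)
    expect_equal(bk$cv_percent, unname(ob[, "cv"]), tolerance = 1e-12)
    expect_equal(bk$geometric_mean_ct, unname(ob[, "gm"]), tolerance = 1e-12)
    mn <- random_grid_matrix(3, 4)
    expect_lt(max(abs(normfinder(mn, mode = "ungrouped")$score -
                        oracle_normfinder_sigma(unclass(mn)))), 1e-8)
  }
})

test_that("stability recovery: planted stable genes reach the top of all methods", {
  genes <- data.frame(gene = sprintf("g%d", 1:8), mu = 20 + 1:8,
                      sigma_bio = c(0.05, 0.05, rep(0.8, 6)))
  cfg <- sim_config(genes, data.frame(sample = sprintf("s%03d", 1:100)),
                    sigma_load = 0.15, sigma_tech = 0, n_tech_reps = 1)
  hits <- c(delta_ct = 0, genorm = 0, normfinder = 0, bestkeeper = 0)
  for (seed in 1:20) {
    sim <- simulate_ct_table(cfg, seed = seed)
    ev <- evaluate_stability(aggregate_replicates(sim$table))
    top2 <- vapply(ev$ranks, function(r)
      all(names(sort(r))[1:2] %in% c("g1", "g2")), logical(1))
    hits <- hits + top2
  }
  expect_true(all(hits >= 19))
})
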