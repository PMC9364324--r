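test_that("min-shift removes the global minimum and is idempotent", {
  m <- matrix(c(-1, 2, 0.5, 3), 2, 2)
  shifted <- min_shift(m)
  expect_equal(min(shifted), 0)
  expect_equal(shifted, m + 1)
  expect_equal(min_shift(shifted), shifted)

  df <- tibble::tibble(enm_id = c("a", "b"), x = c(-1, 2), y = c(0.5, 3))
  sdf <- min_shift(df)
  expect_equal(sdf$x, c(0, 3))
  expect_equal(sdf$enm_id, df$enm_id)

  pos <- matrix(c(0, 1, 2, 3), 2, 2)
  expect_equal(min_shift(pos), pos)
})

test_that("Bray-Curtis follows its definition and permutation invariance", {
  m <- rbind(u = c(2, 1), v = c(1, 1), w = c(2, 1))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["u", "v"], oracle_bray(c(2, 1), c(1, 1)))  # 0.2
  expect_equal(d["u", "v"], 0.2)
  expect_equal(d["u", "w"], 0)

  disjoint <- rbind(c(1, 0), c(0, 1))
  expect_equal(as.vector(bray_curtis(disjoint)), 1)

  withr::with_seed(17, {
    x <- matrix(stats::runif(40), 8, 5)
    rownames(x) <- paste0("r", 1:8)
    d1 <- as.matrix(bray_curtis(x))
    perm <- sample(8)
    d2 <- as.matrix(bray_curtis(x[perm, ]))
    expect_equal(d2[rownames(d1), colnames(d1)], d1)
    # pairwise against the oracle
    for (i in 1:7) for (j in (i + 1):8) {
      expect_equal(d1[i, j], oracle_bray(x[i, ], x[j, ]))
    }
  })

  expect_error(bray_curtis(rbind(c(0, 0), c(0, 0))), "zero",
               class = "nanosorb_validation_error")
  expect_error(bray_curtis(rbind(c(-1, 1), c(1, 1))),
               class = "nanosorb_validation_error")
})

test_that("marginal dbRDA reproduces vegan's pseudo-F and the df convention", {
  withr::with_seed(42, {
    n <- 19
    pred <- as.data.frame(matrix(stats::rnorm(n * 5), n, 5,
                                 dimnames = list(NULL, c("r_e", "p_s", "a", "b", "v"))))
    y <- matrix(stats::runif(n * 30, 1, 10), n, 30)
    y[, 1] <- y[, 1] + 3 * pred$a
    d <- bray_curtis(min_shift(y))
    res <- dbrda_marginal(d, pred, n_perm = 199, seed = 7)
    expect_equal(res$df_resid, rep(13, 5))  # n - p - 1 = 19 - 5 - 1
    expect_equal(res$df, rep(1L, 5))
    expect_true(all(res$statistic >= 0))
    expect_true(all(res$p_value >= 1 / 200))

    # independent route: vegan's constrained-ordination marginal tests
    ref <- stats::anova(vegan::dbrda(d ~ r_e + p_s + a + b + v, data = pred),
                        by = "margin", permutations = 29)
    expect_equal(res$statistic, ref$F[1:5], tolerance = 1e-8)
  })
})

test_that("dbRDA p-values hit the permutation floor and flag collinearity", {
  withr::with_seed(4, {
    n <- 15
    pred <- data.frame(a = stats::rnorm(n))
    y <- matrix(stats::runif(n * 10, 1, 2), n, 10)
    y[, 1:5] <- y[, 1:5] + 5 * pmax(pred$a, 0)  # strong signal
    res <- dbrda_marginal(bray_curtis(y), pred, n_perm = 999, seed = 3)
    expect_equal(res$p_value, 0.001)  # 1 / (999 + 1)

    pred2 <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n))
    pred2$b <- 2 * pred2$a
    expect_error(dbrda_marginal(bray_curtis(y), pred2, n_perm = 9),
                 "collinear", class = "nanosorb_validation_error")
  })
})

test_that("null dbRDA p-values are uniform under exchangeability", {
  # calibration: noise predictor, Euclidean-embedded exchangeable items
  withr::with_seed(2024, {
    pvals <- replicate(200, {
      n <- 12
      y <- matrix(stats::runif(n * 4, 1, 5), n, 4)
      pred <- data.frame(noise = stats::rnorm(n))
      d <- stats::dist(y)
      dbrda_marginal(d, pred, n_perm = 199,
                     seed = sample.int(1e6, 1))$p_value
    })
    ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
    expect_gt(ks$p.value, 0.01)
    # super-uniformity: the empirical CDF never markedly exceeds the diagonal
    grid <- seq(0.05, 1, by = 0.05)
    ecdf_vals <- vapply(grid, function(q) mean(pvals <= q), 1.0)
    expect_true(all(ecdf_vals <= grid + 0.1))
  })
})

test_that("Dunn z statistics match the rank-sum oracle with Holm monotonicity", {
  two_same <- data.frame(g = rep(c("a", "b"), each = 4), y = rep(1:4, 2))
  res_same <- kruskal_dunn(two_same, y, g)
  expect_equal(res_same$p_adj, 1)

  sep <- data.frame(g = rep(c("a", "b", "c"), each = 3),
                    y = c(1, 2, 3, 101, 102, 103, 201, 202, 203))
  res_sep <- kruskal_dunn(sep, y, g)
  expect_true(all(res_sep$z < 0))  # ranks increase a -> b -> c
  expect_lt(res_sep$z[res_sep$group1 == "a" & res_sep$group2 == "c"],
            res_sep$z[res_sep$group1 == "a" & res_sep$group2 == "b"])

  withr::with_seed(77, {
    df <- data.frame(g = sample(rep(c("a", "b", "c"), times = c(6, 8, 7))),
                     y = round(stats::rnorm(21, 5), 1))  # rounding forces ties
    res <- kruskal_dunn(df, y, g)
    expect_equal(res$z, unname(oracle_dunn(df$y, df$g)), tolerance = 1e-12)
    expect_true(all(res$p_adj >= res$p_raw))
    expect_equal(res$p_adj,
                 stats::p.adjust(res$p_raw, method = "holm"))
    expect_true(is.numeric(attr(res, "kw_p")))
  })

  expect_error(kruskal_dunn(data.frame(g = "a", y = 1), y, g),
               class = "nanosorb_validation_error")
})

test_that("Spearman correlation handles monotone and tied data", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)

  withr::with_seed(5, {
    a <- sample(rep(1:4, times = c(2, 3, 1, 2)))
    b <- stats::rnorm(8)
    expect_equal(spearman_cor(a, b)$rho,
                 oracle_pearson(rank(a), rank(b)), tolerance = 1e-12)
  })
  expect_error(spearman_cor(rep(1, 5), 1:5), class = "nanosorb_validation_error")
})
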