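test_that("leverages equal the explicit projection diagonal and sum to p", {
  withr::with_seed(13, {
    x <- matrix(stats::rnorm(80), 20, 4)
    h <- leverages(x)
    expect_equal(h, unname(oracle_hat(cbind(1, x))), tolerance = 1e-10)
    expect_equal(sum(h), 5)  # intercept + 4 columns
    expect_true(all(h >= 0 & h <= 1))
  })

  # square invertible design: projection is the identity
  sq <- matrix(c(1, 2, 3, 5, 4, 9, 2, 7, 1), 3, 3)
  expect_equal(leverages(sq, add_intercept = FALSE), rep(1, 3))

  # symmetric +/-1 single predictor: equal leverages
  expect_equal(leverages(data.frame(x = c(-1, 1, -1, 1))), rep(0.5, 4))

  expect_error(leverages(data.frame(a = 1:5, b = 1:5)), "rank",
               class = "nanosorb_validation_error")
})

test_that("the critical hat follows 3(N+1)/n", {
  expect_equal(round(critical_hat(5, 23), 2), 0.78)
  expect_equal(critical_hat(0, 3), 1)
  expect_equal(critical_hat(5, 18), 1)
})

test_that("Insubria filtering honours its mode and boundary conventions", {
  probes <- c(1, 2, 3)  # mean 2, sd 1 -> band (-1, 5)
  rep_both <- insubria_filter(predictions = c(2, 6, -2, 2),
                              hats = c(0.01, 0.01, 0.01, 0.9),
                              h_star = 0.78, probe_predictions = probes,
                              mode = "both_thresholds")
  expect_equal(rep_both$in_domain, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(attr(rep_both, "thresholds")), c(-1, 5))

  rep_hat <- insubria_filter(c(2, 6, -2, 2), c(0.01, 0.01, 0.01, 0.9),
                             h_star = 0.78, mode = "hat_only")
  expect_equal(rep_hat$in_domain, c(TRUE, TRUE, TRUE, FALSE))

  rep_none <- insubria_filter(c(2, 6, -2, 2), c(0.01, 0.01, 0.01, 0.9),
                              h_star = 0.78, mode = "none")
  expect_true(all(rep_none$in_domain))

  # a compound exactly at h* is out (strict inequality)
  at_boundary <- insubria_filter(2, 0.78, h_star = 0.78, mode = "hat_only")
  expect_false(at_boundary$in_domain)

  expect_error(insubria_filter(1, 0.1, 0.78, probe_predictions = NULL,
                               mode = "both_thresholds"),
               class = "nanosorb_validation_error")
})

test_that("hat-only domains contain the double-threshold domains", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n <- 40
      preds <- stats::rnorm(n, 2, 3)
      hats <- stats::runif(n, 0, 1)
      probes <- stats::rnorm(10, 2, 0.5)
      both <- insubria_filter(preds, hats, 0.5, probes, "both_thresholds")
      hat <- insubria_filter(preds, hats, 0.5, mode = "hat_only")
      none <- insubria_filter(preds, hats, 0.5, mode = "none")
      expect_true(all(hat$in_domain[both$in_domain]))
      expect_true(all(none$in_domain[hat$in_domain]))
      expect_true(sum(both$in_domain) <= sum(hat$in_domain),
                  sum(hat$in_domain) <= sum(none$in_domain))
    }
  })
})

test_that("Williams flags use |residual| <= 3 and h <= h* (boundary in)", {
  fl <- williams_flags(std_residuals = c(0, 3.1, -3.1, 3, 0),
                       hats = c(0, 0.1, 0.1, 0.1, 0.78),
                       h_star = 0.78)
  expect_equal(fl$in_domain, c(TRUE, FALSE, FALSE, TRUE, TRUE))
})

test_that("Williams coverage on well-specified data matches its nominal level", {
  # |t residual| <= 3 keeps ~99.7% of gaussian data; leverage cut removes few
  withr::with_seed(99, {
    frac <- replicate(20, {
      n <- 100
      x <- data.frame(x1 = stats::rnorm(n), x2 = stats::rnorm(n))
      y <- 1 + x$x1 - 0.5 * x$x2 + stats::rnorm(n)
      res <- loo_residuals(x, y)
      h <- leverages(x)
      mean(williams_flags(res, h, critical_hat(2, n))$in_domain)
    })
    expect_gt(mean(frac), 0.93)
    expect_lte(mean(frac), 1)
  })
})

test_that("the ordination-centroid domain accepts central and rejects remote points", {
  withr::with_seed(41, {
    probes <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
    cloud <- probes[rep(1:4, 3), ] + matrix(stats::rnorm(24, sd = 0.15), 12, 2)
    center <- c(0.5, 0.5)
    far <- c(10, 10)
    x <- rbind(probes, cloud, center, far)
    df <- tibble::tibble(compound_id = sprintf("p%02d", seq_len(nrow(x))),
                         d1 = x[, 1], d2 = x[, 2])
    # low-stress warning from the NMDS backend is expected on clean 2-D data
    res <- suppressWarnings(
      ordination_centroid_ad(df, probe_ids = sprintf("p%02d", 1:4)))
    expect_true(res$in_domain[res$compound_id == "p17"])   # the centre point
    expect_false(res$in_domain[res$compound_id == "p18"])  # 10x the spread away
    expect_true(all(res$in_domain[1:4]))                   # probes inside own domain
  })

  # degenerate all-identical cloud: no embedding needed, everything inside
  same <- tibble::tibble(compound_id = paste0("c", 1:6), d1 = 1, d2 = 2)
  res0 <- ordination_centroid_ad(same, probe_ids = c("c1", "c2", "c3"))
  expect_true(all(res0$in_domain))
  expect_equal(attr(res0, "radius"), 0)

  expect_error(ordination_centroid_ad(same, probe_ids = c("c1", "c2")),
               class = "nanosorb_validation_error")
})

test_that("larger training pools produce non-decreasing in-domain counts across modes", {
  # the three threshold modes are nested, so the count of metabolites usable
  # for model building can only grow when thresholds are dropped
  withr::with_seed(53, {
    compounds <- gen_abraham_compounds(150, seed = 8)
    probes <- gen_abraham_compounds(23, seed = 9)
    design <- rbind(as.matrix(probes[c("E", "S", "A", "B", "V")]),
                    as.matrix(compounds[c("E", "S", "A", "B", "V")]))
    h_all <- leverages(design)
    h <- utils::tail(h_all, 150)
    nano <- list(c = -0.4, r_e = 0.3, p_s = 0.6, a = -1.1, b = -2.8, v = 3.0)
    preds <- predict_bsai(compounds, nano)
    probe_preds <- predict_bsai(probes, nano)
    h_star <- critical_hat(5, 23)
    n_both <- sum(insubria_filter(preds, h, h_star, probe_preds, "both_thresholds")$in_domain)
    n_hat <- sum(insubria_filter(preds, h, h_star, mode = "hat_only")$in_domain)
    n_none <- sum(insubria_filter(preds, h, h_star, mode = "none")$in_domain)
    expect_true(n_both <= n_hat && n_hat <= n_none)
    expect_equal(n_none, 150)
  })
})
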