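test_that("a flat profile integrates to its length", {
  flat <- gen_pmf("flat", n = 100, z_max = 2)
  res <- logk_from_pmf(flat, cutoff = 2)
  expect_equal(res$k_calc, 2, tolerance = 1e-12)
  expect_equal(res$log10_k, log10(2), tolerance = 1e-12)
})

test_that("trapezoid integration matches the square-well closed form", {
  temperature <- 310
  beta <- 1 / (8.3144621e-3 * temperature)
  # beta * depth = ln 2 -> k = 1 * 2 + (2 - 1) = 3
  depth <- log(2) / beta
  sw <- gen_pmf("square_well", n = 1e4 + 1, z_max = 2, depth = depth,
                width = 1, temperature = temperature)
  res <- logk_from_pmf(sw, cutoff = 2)
  expect_equal(res$k_calc, 3, tolerance = 1e-3)
  expect_equal(res$k_calc, attr(sw, "truth")$k_true, tolerance = 1e-3)

  # and against a dense-quadrature oracle for a deeper well
  depth2 <- 8
  sw2 <- gen_pmf("square_well", n = 1e4 + 1, z_max = 2, depth = depth2,
                 width = 0.5, temperature = temperature)
  k_oracle <- oracle_boltzmann_integral(
    function(z) ifelse(z <= 0.5, -depth2, 0), 0, 2, temperature)
  expect_equal(logk_from_pmf(sw2, cutoff = 2)$k_calc, k_oracle, tolerance = 1e-3)
})

test_that("integration converges under grid refinement on smooth profiles", {
  k_at <- function(n) {
    prof <- gen_pmf("smooth_well", n = n, z_max = 2, depth = 6,
                    center = 0.6, halfwidth = 0.4)
    logk_from_pmf(prof, cutoff = 2)$k_calc
  }
  expect_equal(k_at(2001), k_at(4001), tolerance = 1e-3)
  expect_lt(abs(k_at(4001) / k_at(8001) - 1), 1e-4)
})

test_that("affinity of an attractive well decreases monotonically with temperature", {
  temps <- c(280, 310, 340, 370)
  ks <- vapply(temps, function(tt) {
    prof <- gen_pmf("square_well", n = 2001, z_max = 2, depth = 10,
                    width = 0.5, temperature = tt)
    logk_from_pmf(prof, cutoff = 2)$k_calc
  }, 1.0)
  expect_true(all(diff(ks) < 0))
})

test_that("the log-sum-exp path agrees with naive integration where both work", {
  prof <- gen_pmf("square_well", n = 501, z_max = 2, depth = 20, width = 0.5)
  res <- logk_from_pmf(prof, cutoff = 2)
  beta <- 1 / (8.3144621e-3 * 310)
  f <- exp(-beta * prof$w)
  naive <- sum(diff(prof$z) * (f[-length(f)] + f[-1]) / 2)
  expect_equal(res$k_calc, naive, tolerance = 1e-12)

  # a well deep enough to overflow exp() still yields finite log10 k
  deep <- pmf_profile(seq(0, 2, length.out = 500),
                      c(rep(-6000, 100), rep(0, 400)))
  res_deep <- logk_from_pmf(deep, cutoff = 2)
  expect_true(is.finite(res_deep$log10_k))
  expect_gt(res_deep$log10_k, 100)
})

test_that("plateau detection finds constructed onsets and fails on ramps", {
  z <- seq(0, 3, length.out = 301)
  w <- ifelse(z < 1.5, -8 * (1.5 - z), 0)  # flat exactly from z = 1.5
  prof <- pmf_profile(z, w)
  c_hat <- detect_plateau(prof)
  expect_lt(abs(c_hat - 1.5), diff(z)[1] + 1e-9)

  ramp <- pmf_profile(z, 5 * z)
  expect_error(detect_plateau(ramp), "plateau")

  # noisy smooth well: recovered within two grid steps of the construction
  prof2 <- gen_pmf("smooth_well", n = 301, z_max = 3, depth = 12,
                   center = 0.8, halfwidth = 0.5, noise_sd = 0.1, seed = 6)
  truth <- attr(prof2, "truth")$c_plateau
  expect_lt(abs(detect_plateau(prof2) - truth), 2 * (3 / 300) + 1e-9)

  # noise-free: within two grid steps of the constructed onset (the slope
  # window necessarily fires slightly before the exact C1 edge)
  prof3 <- gen_pmf("smooth_well", n = 301, z_max = 3, depth = 12,
                   center = 0.8, halfwidth = 0.5)
  expect_lt(abs(detect_plateau(prof3) - attr(prof3, "truth")$c_plateau),
            2 * (3 / 300) + 1e-9)
})

test_that("PMF files round-trip through the two-column text reader", {
  prof <- gen_pmf("smooth_well", n = 50, z_max = 2, depth = 4,
                  center = 0.5, halfwidth = 0.3)
  f <- withr::local_tempfile(fileext = ".dat")
  utils::write.table(data.frame(z = prof$z, w = prof$w), f,
                     row.names = FALSE, col.names = TRUE)
  back <- read_pmf(f, temperature = 310)
  expect_equal(back$z, prof$z, tolerance = 1e-10)
  expect_equal(back$w, prof$w, tolerance = 1e-10)

  # headerless, comma-separated variant
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(data.frame(prof$z, prof$w), f2, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  back2 <- read_pmf(f2)
  expect_equal(back2$w, prof$w, tolerance = 1e-10)
})

test_that("MD vs QSAR comparison applies exclusions and matches the Pearson oracle", {
  same <- tibble::tibble(compound_id = letters[1:4],
                         log_k_md = c(1, 2, 3, 4), log_k_qsar = c(1, 2, 3, 4))
  expect_equal(compare_md_qsar(same)$r, 1)

  # one high-leverage outlier: exclusion improves the correlation
  out <- tibble::tibble(compound_id = letters[1:5],
                        log_k_md = c(1, 2, 3, 4, 10),
                        log_k_qsar = c(1.1, 1.9, 3.2, 3.8, -5))
  r_all <- compare_md_qsar(out)$r
  r_excl <- compare_md_qsar(out, exclude = "e")$r
  expect_gt(r_excl, r_all)
  expect_equal(compare_md_qsar(out, exclude = "e")$n_excluded, 1)

  withr::with_seed(23, {
    df <- tibble::tibble(compound_id = as.character(1:10),
                         log_k_md = stats::rnorm(10), log_k_qsar = stats::rnorm(10))
    expect_equal(compare_md_qsar(df)$r,
                 oracle_pearson(df$log_k_md, df$log_k_qsar), tolerance = 1e-12)
  })

  expect_error(compare_md_qsar(same, exclude = c("a", "b")),
               class = "nanosorb_validation_error")
})
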