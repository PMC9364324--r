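#' Shift a log k table to non-negative values
#'
#' Abundance-style dissimilarities (Bray-Curtis) require non-negative input,
#' so predicted log k values are shifted by subtracting the global minimum
#' from every cell. Applying the shift twice changes nothing after the first
#' pass.
#'
#' @param x A numeric matrix, or a data frame whose numeric columns hold the
#'   log k values (id columns are left alone).
#' @return Object of the same shape with global minimum 0.
#' @export
min_shift <- function(x) {
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, TRUE)
    if (!any(num)) abort_validation("no numeric columns to shift.")
    vals <- unlist(x[num], use.names = FALSE)
    check_finite(vals, "log k values")
    x[num] <- lapply(x[num], function(col) col - min(vals))
    return(tibble::as_tibble(x))
  }
  check_finite(as.vector(x), "log k values")
  x - min(x)
}

#' Bray-Curtis dissimilarity between rows
#'
#' `d(u, v) = sum(|u - v|) / sum(u + v)` for non-negative rows; values lie in
#' \[0, 1\], 0 for identical rows, 1 for rows with disjoint support.
#'
#' @param x Non-negative numeric matrix or data frame (items in rows; an id
#'   column named `compound_id` or `enm_id`, or rownames, become labels).
#' @return A `dist` object over the rows.
#' @export
bray_curtis <- function(x) {
  labels <- NULL
  if (is.data.frame(x)) {
    for (idcol in c("enm_id", "compound_id")) {
      if (idcol %in% names(x)) {
        labels <- as.character(x[[idcol]])
        x[[idcol]] <- NULL
        break
      }
    }
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  check_finite(as.vector(x), "matrix")
  if (any(x < 0)) abort_validation("Bray-Curtis needs non-negative input; call min_shift() first.")
  zero_rows <- which(rowSums(x) == 0)
  if (length(zero_rows) >= 2) {
    abort_validation("rows %s are all zero; their Bray-Curtis dissimilarity is undefined.",
                     paste(zero_rows, collapse = ", "))
  }
  if (!is.null(labels)) rownames(x) <- labels
  vegan::vegdist(x, method = "bray")
}

#' Marginal permutation tests in distance-based redundancy analysis
#'
#' Tests the marginal (type-III-like) contribution of each predictor to the
#' structure of a dissimilarity matrix, following the McArdle-Anderson
#' formulation: the squared dissimilarities are Gower-centred into an inner
#' product matrix `G`; for each predictor the explained sum of squares is the
#' drop in `tr(H G)` when that predictor is removed from the full hat matrix
#' `H`, and `F = SS_marginal / (SS_residual / (n - p - 1))`. Negative
#' eigenvalues of `G` are retained in the totals. Significance is assessed by
#' freely permuting the rows (items) of the dissimilarity matrix `n_perm`
#' times and counting permuted statistics at least as large as the observed
#' one, so the smallest attainable p-value is `1 / (n_perm + 1)`.
#'
#' @param dissim A `dist` object or symmetric dissimilarity matrix over n
#'   items.
#' @param predictors Data frame of n rows of numeric predictors (e.g. the
#'   five nanodescriptors).
#' @param n_perm Number of permutations (default 999, so the p-value floor is
#'   0.001).
#' @param seed Integer seed for the permutations.
#' @return A tibble with one row per predictor: `term`, `df` (1), `df_resid`
#'   (n - p - 1), `statistic` (the pseudo-F), `p_value` and `n_perm`.
#' @export
dbrda_marginal <- function(dissim, predictors, n_perm = 999, seed = 1L) {
  d <- as.matrix(dissim)
  n <- nrow(d)
  predictors <- as.data.frame(predictors)
  num <- vapply(predictors, is.numeric, TRUE)
  predictors <- predictors[num]
  p <- ncol(predictors)
  if (nrow(predictors) != n) abort_validation("predictor rows must match dissimilarity items.")
  if (n <= p + 1) abort_validation("need more items (%d) than predictors + 1 (%d).", n, p + 1)
  x <- as.matrix(predictors)
  check_finite(as.vector(x), "predictors")

  # collinearity guard, naming an offending pair where one exists
  if (qr(cbind(1, scale(x, scale = FALSE)))$rank < p + 1) {
    cors <- stats::cor(x)
    diag(cors) <- 0
    hit <- which(abs(cors) > 1 - 1e-10, arr.ind = TRUE)
    pair <- if (nrow(hit) > 0) {
      sprintf(" ('%s' and '%s')", colnames(x)[hit[1, 1]], colnames(x)[hit[1, 2]])
    } else ""
    abort_validation("predictors are collinear%s.", pair)
  }

  # Gower-centred inner product matrix of the squared dissimilarities
  a <- -0.5 * d^2
  cmat <- diag(n) - matrix(1 / n, n, n)
  g <- cmat %*% a %*% cmat

  hat_of <- function(cols) {
    xc <- scale(x[, cols, drop = FALSE], scale = FALSE)
    q <- qr.Q(qr(xc))
    tcrossprod(q)
  }
  h_full <- hat_of(seq_len(p))
  h_minus <- lapply(seq_len(p), function(j) {
    if (p == 1) matrix(0, n, n) else hat_of(setdiff(seq_len(p), j))
  })

  df_resid <- n - p - 1
  stat_for <- function(gm) {
    tr_full <- sum(h_full * gm)
    ss_res <- sum(diag(gm)) - tr_full
    vapply(seq_len(p), function(j) {
      ss_j <- tr_full - sum(h_minus[[j]] * gm)
      ss_j / (ss_res / df_resid)
    }, 1.0)
  }
  f_obs <- stat_for(g)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  exceed <- rep(0L, p)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    exceed <- exceed + (stat_for(g[idx, idx]) >= f_obs)
  }

  tibble::tibble(term = colnames(x),
                 df = 1L, df_resid = df_resid,
                 statistic = f_obs,
                 p_value = (exceed + 1) / (n_perm + 1),
                 n_perm = n_perm)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Non-parametric comparison of log k values across nanomaterial groups: a
#' Kruskal-Wallis rank-sum test over all groups, followed by Dunn's pairwise
#' z tests on the mean ranks (with the usual tie correction) and Holm
#' step-down adjustment of the pairwise p-values.
#'
#' @param data Data frame holding the observations.
#' @param value Column of values (bare name).
#' @param group Column of group labels (bare name).
#' @return A tibble of pairwise results -- `group1`, `group2`, `z`, `p_raw`,
#'   `p_adj` -- with the Kruskal-Wallis statistic, df and p-value as
#'   attributes `kw_statistic`, `kw_df`, `kw_p`.
#' @export
#' @examples
#' df <- data.frame(g = rep(c("a", "b", "c"), each = 4), y = c(1:4, 3:6, 10:13))
#' kruskal_dunn(df, y, g)
kruskal_dunn <- function(data, value, group) {
  y <- dplyr::pull(data, {{ value }})
  grp <- factor(dplyr::pull(data, {{ group }}))
  if (nlevels(grp) < 2) abort_validation("need at least two groups.")
  check_finite(y, "values")

  kw <- stats::kruskal.test(y, grp)

  n <- length(y)
  r <- rank(y)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, grp, mean)
  sizes <- table(grp)
  levs <- levels(grp)
  pairs <- utils::combn(levs, 2)
  z <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / sizes[[i]] + 1 / sizes[[j]]))
    (mean_rank[[i]] - mean_rank[[j]]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  out <- tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                        z = z, p_raw = p_raw,
                        p_adj = stats::p.adjust(p_raw, method = "holm"))
  attr(out, "kw_statistic") <- unname(kw$statistic)
  attr(out, "kw_df") <- unname(kw$parameter)
  attr(out, "kw_p") <- kw$p.value
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of the (average-tie) ranks, with the p-value from the
#' standard large-sample approximation.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A tibble with `rho`, `p_value` and `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort_validation("need two equal-length vectors with at least 3 values.")
  }
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    abort_validation("ranks have zero variance; correlation undefined.")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
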