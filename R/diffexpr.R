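#' Per-feature linear models with a two-group contrast
#'
#' Fits ordinary least squares per feature on a shared design: an intercept,
#' a group indicator (1 for the first cluster, 0 for the second, so the
#' contrast coefficient is cluster1 - cluster2), and any covariates. Data are
#' assumed already on the log2 scale, so the contrast coefficient is the
#' logFC directly.
#'
#' @param m numeric matrix, samples x features.
#' @param group factor or vector with exactly two levels, one per sample;
#'   the first level plays the role of cluster 1.
#' @param covariates optional data.frame of numeric/binary covariates
#'   (samples in the same order as `m` rows).
#' @return list with `coef` (contrast coefficient per feature),
#'   `stdev_unscaled` (SE of the contrast per unit residual SD), `s2`
#'   (residual variances), `df` (residual degrees of freedom),
#'   `feature_ids`.
#' @export
fit_linear_models <- function(m, group, covariates = NULL) {
  stopifnot(is.matrix(m), nrow(m) == length(group))
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("group must have exactly two levels, got ",
         nlevels(droplevels(group)))
  g <- as.integer(group == levels(group)[1L])  # 1 = cluster1
  X <- cbind(`(Intercept)` = 1, group = g)
  if (!is.null(covariates)) {
    cv <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1L,
                                                                     drop = FALSE]
    X <- cbind(X, cv)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  df <- nrow(X) - ncol(X)
  if (df < 1L) stop("no residual degrees of freedom")
  fit <- stats::lm.fit(X, m)
  coefs <- fit$coefficients["group", ]
  res <- m - X %*% fit$coefficients
  s2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  su <- sqrt(xtx_inv[2L, 2L])
  list(coef = coefs, stdev_unscaled = su, s2 = s2, df = df,
       feature_ids = colnames(m))
}

# Newton inversion of the trigamma function (for prior df estimation)
trigamma_inverse <- function(x) {
  stopifnot(x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-feature residual variances towards a common prior by fitting
#' a scaled-F model to the observed variances: the log variances' mean and
#' spread are matched to the digamma/trigamma moments implied by
#' \eqn{s_g^2 \sim s_0^2 F(df, d_0)}, giving prior df `d0` and prior
#' variance `s0^2`. Posterior variances are the weighted combination
#' \deqn{\tilde s_g^2 = (d_0 s_0^2 + df\, s_g^2) / (d_0 + df).}
#' When the observed spread of log variances is no larger than expected under
#' a common variance, `d0` is infinite and every posterior variance equals
#' `s0^2`.
#'
#' @param s2 per-feature residual variances (length >= 10).
#' @param df residual degrees of freedom (scalar, shared design).
#' @return list with `s2_post`, `d0`, `s0_2`.
#' @export
moderate_variances <- function(s2, df) {
  if (length(s2) < 10L) stop("need at least 10 features to estimate the prior")
  if (any(s2 < 0)) stop("negative residual variance")
  stopifnot(df >= 1L)
  # guard exact zeros before taking logs
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread beyond chi-square sampling noise: a common variance
    d0 <- Inf
    s0_2 <- mean(s2)
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2))
             else (d0 * s0_2 + df * s2) / (d0 + df)
  list(s2_post = stats::setNames(s2_post, names(s2)), d0 = d0, s0_2 = s0_2)
}

#' Moderated t-statistics and p-values
#'
#' t = coefficient / (unscaled SE x posterior SD), referred to a t
#' distribution with `d0 + df` degrees of freedom (the prior df earned by
#' borrowing variance information across features). With `d0 = 0` this is
#' exactly the classical per-feature t-test. Features with zero coefficient
#' and zero posterior variance get t = 0, p = 1.
#'
#' @param coef per-feature contrast coefficients.
#' @param stdev_unscaled unscaled SE of the contrast (scalar or per feature).
#' @param s2_post posterior (moderated) variances.
#' @param d0 prior degrees of freedom (0 = no moderation, Inf = full pooling).
#' @param df residual degrees of freedom.
#' @return list with `t` and `p` (two-sided).
#' @export
moderated_t_test <- function(coef, stdev_unscaled, s2_post, d0, df) {
  se <- stdev_unscaled * sqrt(s2_post)
  t <- ifelse(se == 0, ifelse(coef == 0, 0, sign(coef) * Inf), coef / se)
  df_total <- d0 + df
  p <- 2 * stats::pt(-abs(t), df = df_total)
  p[se == 0 & coef == 0] <- 1
  list(t = t, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: sorted ascending,
#' `p_adj(i) = min_{j >= i} min(1, p(j) * m / j)`, mapped back to input
#' order. Input must lie in \[0, 1\].
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  stats::p.adjust(p, method = "BH")
}

#' Apply the significance calling rule
#'
#' A feature is called significant when its BH-adjusted p-value is below
#' `fdr` AND its |logFC| is at least `lfc` (default 0.05 and 0.7). Direction
#' is the sign of logFC: up means higher in cluster 1. `use_raw_p` switches
#' the first condition to the raw p-value, the relaxed rule used for
#' low-signal tissues such as blood.
#'
#' @param tab data.frame with columns `logFC`, `p`, `p_adj`.
#' @param fdr adjusted-p threshold; default 0.05.
#' @param lfc absolute logFC threshold; default 0.7.
#' @param use_raw_p use raw p instead of adjusted; default FALSE.
#' @return `tab` with `significant` and `direction` columns set.
#' @export
call_degs <- function(tab, fdr = 0.05, lfc = 0.7, use_raw_p = FALSE) {
  stopifnot(all(c("logFC", "p", "p_adj") %in% names(tab)))
  pcol <- if (use_raw_p) tab$p else tab$p_adj
  tab$significant <- pcol < fdr & abs(tab$logFC) >= lfc
  tab$direction <- ifelse(tab$logFC > 0, "up",
                          ifelse(tab$logFC < 0, "down", "none"))
  tab
}

#' Two-group moderated differential expression
#'
#' The full DE stage: per-feature OLS with covariate adjustment,
#' empirical-Bayes variance moderation, moderated t-tests, BH adjustment,
#' and the conjunctive significance rule.
#'
#' @inheritParams fit_linear_models
#' @inheritParams call_degs
#' @return a DE table: data.frame with feature_id, logFC, t, p, p_adj,
#'   significant, direction; rows in input feature order.
#' @export
run_diffexpr <- function(m, group, covariates = NULL, fdr = 0.05, lfc = 0.7,
                         use_raw_p = FALSE) {
  fit <- fit_linear_models(m, group, covariates)
  mod <- moderate_variances(fit$s2, fit$df)
  tt <- moderated_t_test(fit$coef, fit$stdev_unscaled, mod$s2_post,
                         mod$d0, fit$df)
  tab <- data.frame(feature_id = fit$feature_ids,
                    logFC = unname(fit$coef),
                    t = unname(tt$t),
                    p = unname(tt$p),
                    p_adj = unname(bh_adjust(tt$p)),
                    row.names = NULL)
  call_degs(tab, fdr = fdr, lfc = lfc, use_raw_p = use_raw_p)
}
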