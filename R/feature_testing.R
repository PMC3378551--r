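#' Two-group linear model fit, feature by feature
#'
#' For each feature computes the group-mean difference (group 2 minus
#' group 1, log2 units, so positive = up-regulated in group 2) and the pooled
#' within-group variance on d = n1 + n2 - 2 degrees of freedom.
#'
#' @param x log-expression matrix (features x samples).
#' @param design a [group_design()] covering all columns of `x`.
#' @return list of class `"two_group_fit"` with `diff`, `s_sq` (named numeric
#'   vectors), `d` (residual df), `n1`, `n2`.
#' @export
fit_two_group_model <- function(x, design) {
  grp <- match_design(x, design)
  i1 <- which(grp == 1L); i2 <- which(grp == 2L)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 samples for variance estimation")
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  ss1 <- rowSums((x[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, i2, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2L
  structure(list(diff = m2 - m1, s_sq = (ss1 + ss2) / d,
                 d = d, n1 = n1, n2 = n2),
            class = "two_group_fit")
}

#' Invert the trigamma function
#'
#' Solves trigamma(y) = x for y > 0 by Newton iteration on the reciprocal
#' scale, initialized from the large-argument expansion
#' trigamma(y) ~ 1/y + 1/(2 y^2).
#'
#' @param x positive target value(s).
#' @param tol convergence tolerance on the step (default 1e-8).
#' @return y with trigamma(y) = x.
#' @export
trigamma_inverse <- function(x, tol = 1e-8) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(if (xi <= 0) Inf else NaN)
    if (xi > 1e7) return(1 / sqrt(xi))  # trigamma(y) ~ 1/y^2 for tiny y
    if (xi < 1e-6) return(1 / xi)       # trigamma(y) ~ 1/y for large y
    y <- 0.5 + 1 / xi
    for (iter in 1:60) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2)
      y <- y + dif
      if (abs(dif / y) < tol) break
    }
    y
  }, numeric(1))
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment matching on e_g = log s_g^2 under the scaled-F sampling model for
#' gene-wise variances: the excess of var(e) over trigamma(d/2) identifies the
#' prior degrees of freedom d0 through trigamma(d0/2), and the mean of e then
#' identifies the prior variance s0^2. If the observed spread does not exceed
#' the sampling component, d0 = +Inf (full shrinkage to a common variance).
#'
#' @param s_sq vector of pooled feature variances.
#' @param d residual degrees of freedom of each s_sq.
#' @return list of class `"eb_hyper"`: `d0` (possibly `Inf`), `s0_sq`.
#' @export
estimate_prior <- function(s_sq, d) {
  pos <- s_sq > 0
  if (sum(pos) < 2) stop("degenerate variances: need >= 2 features with s_sq > 0")
  if (any(!pos))
    warning(sum(!pos), " feature(s) with zero variance excluded from the ",
            "prior moment equations")
  e <- log(s_sq[pos])
  excess <- stats::var(e) - trigamma(d / 2)
  if (is.na(excess) || excess <= 0) {
    d0 <- Inf
    log_s0 <- mean(e) - digamma(d / 2) + log(d / 2)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    log_s0 <- mean(e) - digamma(d / 2) + log(d / 2) +
      digamma(d0 / 2) - log(d0 / 2)
  }
  structure(list(d0 = d0, s0_sq = exp(log_s0)), class = "eb_hyper")
}

#' Moderated t statistics and one-sided p-values
#'
#' Shrinks each pooled variance toward the prior,
#' s~^2 = (d0 s0^2 + d s^2) / (d0 + d), and refers
#' t = diff / sqrt(s~^2 (1/n1 + 1/n2)) to a Student t distribution on
#' d0 + d degrees of freedom. With d0 = 0 this is the ordinary pooled
#' two-sample t test; with d0 = Inf all features share s0^2.
#' `p_up` is the upper-tail probability (evidence for up-regulation in
#' group 2); `p_down = 1 - p_up`; `p_two = 2 min(p_up, p_down)`.
#'
#' @param fit a [fit_two_group_model()] result.
#' @param hyper an [estimate_prior()] result (or `list(d0=, s0_sq=)`).
#' @return data.frame of class `"feature_stats"` with columns `feature`,
#'   `diff`, `s_sq`, `s_tilde_sq`, `t_mod`, `df_total`, `p_up`, `p_down`,
#'   `p_two`.
#' @export
moderated_stats <- function(fit, hyper) {
  d0 <- hyper$d0; s0 <- hyper$s0_sq; d <- fit$d
  if (is.infinite(d0)) {
    s_tilde <- rep(s0, length(fit$s_sq))
    df_total <- Inf
  } else {
    s_tilde <- (d0 * s0 + d * fit$s_sq) / (d0 + d)
    df_total <- d0 + d
  }
  se <- sqrt(s_tilde * (1 / fit$n1 + 1 / fit$n2))
  t_mod <- fit$diff / se
  degen <- se == 0
  if (any(degen)) {
    warning(sum(degen), " feature(s) with zero posterior variance; ",
            "statistic set to signed infinity")
    t_mod[degen] <- sign(fit$diff[degen]) * Inf
    t_mod[degen & fit$diff == 0] <- 0
  }
  p_up <- stats::pt(t_mod, df = df_total, lower.tail = FALSE)
  p_down <- 1 - p_up
  out <- data.frame(feature = names(fit$diff), diff = unname(fit$diff),
                    s_sq = unname(fit$s_sq), s_tilde_sq = unname(s_tilde),
                    t_mod = unname(t_mod), df_total = df_total,
                    p_up = unname(p_up), p_down = unname(p_down),
                    p_two = unname(2 * pmin(p_up, p_down)),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("feature_stats", class(out))
  out
}

#' Feature-wise moderated testing in one call
#'
#' Convenience wrapper: pooled fit, prior estimation, moderated statistics.
#'
#' @inheritParams fit_two_group_model
#' @return a `"feature_stats"` data.frame; the fitted prior is attached as
#'   attribute `"hyper"`, the fit as `"fit"`.
#' @export
feature_test <- function(x, design) {
  fit <- fit_two_group_model(x, design)
  hyper <- estimate_prior(fit$s_sq, fit$d)
  out <- moderated_stats(fit, hyper)
  attr(out, "hyper") <- hyper
  attr(out, "fit") <- fit
  out
}
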