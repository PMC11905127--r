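#' Per-gene negative-binomial dispersion with empirical-Bayes shrinkage
#'
#' Counts are scaled to a common effective library size, a method-of-moments
#' dispersion is computed per gene from within-group residual variance under
#' the variance model var = mu + phi * mu^2, a mean-dispersion trend is fit
#' by lowess on average log expression, and per-gene estimates are shrunk
#' toward the trend with weight prior_df / (prior_df + residual_df).
#' Estimates are floored at `floor`.
#'
#' @param x A CountMatrix.
#' @param groups Factor/character of condition labels, one per sample. By
#'   default the (stage, fraction) interaction from the design.
#' @param prior_df Prior degrees of freedom for shrinkage (default 10).
#' @param floor Lower bound for the returned dispersion (default 1e-4).
#' @param norm Optional normalization factors (computed if NULL).
#' @return Named numeric vector of per-gene dispersions, with the fitted
#'   trend in attribute "trend".
#' @export
estimate_dispersion <- function(x, groups = NULL, prior_df = 10, floor = 1e-4,
                                norm = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  if (is.null(groups)) {
    groups <- interaction(x$design$stage, x$design$fraction, drop = TRUE)
  }
  groups <- droplevels(as.factor(groups))
  n_rep <- table(groups)
  if (all(n_rep < 2)) stop("no replication in any group", call. = FALSE)
  if (is.null(norm)) norm <- normalization_factors(x)
  eff <- effective_lib_sizes(norm)
  scale_to <- exp(mean(log(eff)))
  z <- sweep(x$counts, 2, scale_to / eff, "*")  # counts at a common library size

  resid_df <- sum(pmax(n_rep - 1, 0))
  phi_raw <- numeric(nrow(z))
  mu_bar <- numeric(nrow(z))
  use <- names(n_rep)[n_rep >= 2]
  for (g in seq_len(nrow(z))) {
    num <- 0; den <- 0; mu_sum <- 0; mu_n <- 0
    for (lv in use) {
      zi <- z[g, groups == lv]
      m <- mean(zi)
      v <- stats::var(zi)
      df <- length(zi) - 1
      if (m > 0) {
        # method of moments, v = m + phi m^2, with the small-sample
        # correction m^2 -> m^2 - v/n (the plug-in group mean is noisy:
        # E[m^2] = mu^2 + var/n)
        d2 <- m^2 - v / length(zi)
        if (d2 > 0) {
          num <- num + df * (v - m) / d2
          den <- den + df
        }
      }
      mu_sum <- mu_sum + m * length(zi)
      mu_n <- mu_n + length(zi)
    }
    phi_raw[g] <- if (den > 0) max(num / den, 0) else NA_real_
    mu_bar[g] <- mu_sum / max(mu_n, 1)
  }
  ok <- !is.na(phi_raw) & mu_bar > 0
  trend <- rep(stats::median(phi_raw[ok]), nrow(z))
  if (sum(ok) >= 50) {
    fit <- stats::lowess(log(mu_bar[ok]), phi_raw[ok], f = 0.5)
    trend[ok] <- stats::approx(fit$x, fit$y, xout = log(mu_bar[ok]),
                               rule = 2, ties = mean)$y
  }
  trend <- pmax(trend, floor)
  w <- prior_df / (prior_df + resid_df)
  phi <- w * trend + (1 - w) * ifelse(is.na(phi_raw), trend, phi_raw)
  phi <- pmax(phi, floor)
  names(phi) <- rownames(z)
  attr(phi, "trend") <- trend
  phi
}
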