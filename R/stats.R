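# Group-level inference: paired t with Cohen's d, JZS (Cauchy-prior) Bayes
# factors with prior sensitivity, cluster-based sign-flip permutation tests
# on time courses, and the noncentral-t power-sensitivity solver.

#' Paired-samples t-test with effect size and CI
#'
#' Classical two-sided paired t-test on the within-participant differences,
#' reported with Cohen's d for paired designs (`|t| / sqrt(n)`) and the
#' 95% confidence interval on the mean difference.
#'
#' @param x,y Equal-length paired samples (n >= 2).
#' @return Object of class `stat_result`: `t`, `df`, `p`, `d`,
#'   `mean_diff`, `ci_low`, `ci_high`, `n`.
#' @export
paired_stats <- function(x, y) {
  abort_if(length(x) != length(y), "x and y must be paired (equal length)")
  n <- length(x)
  abort_if(n < 2, "need at least 2 pairs")
  d <- x - y
  abort_if(stats::sd(d) == 0, "zero variance of paired differences")
  tt <- stats::t.test(x, y, paired = TRUE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, d = cohen_d_from_t(unname(tt$statistic), n),
                 mean_diff = unname(tt$estimate),
                 ci_low = tt$conf.int[1], ci_high = tt$conf.int[2], n = n),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g, d = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$df, x$t, x$p, x$d, x$ci_low, x$ci_high))
  invisible(x)
}

#' Cohen's d from a paired/one-sample t statistic
#'
#' `d = |t| / sqrt(n)` for a within-subject design with `n` pairs.
#'
#' @param t t statistic.
#' @param n Number of pairs (>= 2).
#' @return Cohen's d.
#' @export
cohen_d_from_t <- function(t, n) {
  abort_if(n < 2, "n must be >= 2")
  abs(t) / sqrt(n)
}

# log marginal likelihood ratio integrand for the JZS Bayes factor, on the
# log-substituted prior variable u = log(g). The Cauchy(0, r) prior on the
# standardized effect is the scale mixture delta | g ~ N(0, g) with
# g ~ InvGamma(1/2, r^2/2).
jzs_log_integrand <- function(u, t, n, r, nu) {
  g <- exp(u)
  ng1 <- 1 + n * g
  -0.5 * log(ng1) - (nu + 1) / 2 * log1p(t^2 / (ng1 * nu)) +
    log(r) - 0.5 * log(2 * pi) - 1.5 * u - r^2 / (2 * g) + u
}

#' JZS Bayes factor for a one-sample t-test (evidence for the null)
#'
#' Default-prior Bayes factor with a Cauchy(0, `r`) prior on the
#' standardized effect size, computed by adaptive quadrature over the
#' log-substituted prior mixing variable (relative tolerance 1e-8, so
#' 2-decimal reporting is stable). `bf01` quantifies the evidence for the
#' null (mu = 0) over the alternative; `bf10 = 1/bf01`.
#'
#' @param t Observed t statistic.
#' @param n Sample size (pairs), >= 2.
#' @param r Cauchy prior scale (default 0.707, i.e. sqrt(2)/2).
#' @return Object of class `bf_result`: `t`, `n`, `df`, `r`, `bf01`,
#'   `bf10`.
#' @export
jzs_bf01 <- function(t, n, r = 0.707) {
  abort_if(n < 2, "n must be >= 2")
  abort_if(r <= 0, "prior scale r must be positive")
  nu <- n - 1
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  # scale the integrand by the null likelihood for numerical headroom
  f <- function(u) exp(jzs_log_integrand(u, t, n, r, nu) - log_null)
  q <- stats::integrate(f, lower = -Inf, upper = Inf, rel.tol = 1e-8,
                        abs.tol = 0, subdivisions = 400L)
  abort_if(q$message != "OK",
           "JZS integration did not converge: %s", q$message)
  bf10 <- q$value
  structure(list(t = t, n = n, df = nu, r = r, bf01 = 1 / bf10,
                 bf10 = bf10), class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("JZS BF01 = %.3f (BF10 = %.3f) for t = %.3f, n = %d, r = %g\n",
              x$bf01, x$bf10, x$t, x$n, x$r))
  invisible(x)
}

#' Prior-scale sensitivity analysis for the JZS Bayes factor
#'
#' Recomputes the Bayes factor across a set of Cauchy prior scales
#' (default 0.5, 0.707, 1, 2).
#'
#' @inheritParams jzs_bf01
#' @param scales Vector of prior scales.
#' @return Data frame: `r`, `t`, `n`, `bf01`, `bf10`, one row per scale.
#' @export
bf_sensitivity <- function(t, n, scales = c(0.5, 0.707, 1, 2)) {
  res <- lapply(scales, function(r) jzs_bf01(t, n, r))
  data.frame(r = scales, t = t, n = n,
             bf01 = vapply(res, `[[`, numeric(1), "bf01"),
             bf10 = vapply(res, `[[`, numeric(1), "bf10"))
}

# Per-column paired/one-sample t statistics of a difference matrix
# (participants x time).
col_tstats <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  v[v < .Machine$double.eps] <- .Machine$double.eps
  m / sqrt(v / n)
}

# Maximal contiguous supra-threshold clusters of a t curve; returns a data
# frame (start, end, sign, mass) where start/end are column indices.
find_clusters <- function(tv, thr) {
  out <- NULL
  for (sgn in c(1, -1)) {
    supra <- if (sgn > 0) tv > thr else tv < -thr
    if (!any(supra)) next
    r <- rle(supra)
    e_i <- cumsum(r$lengths)
    s_i <- e_i - r$lengths + 1L
    ss <- s_i[r$values]; ee <- e_i[r$values]
    mass <- vapply(seq_along(ss),
                   function(k) sum(tv[ss[k]:ee[k]]), numeric(1))
    out <- rbind(out, data.frame(start = ss, end = ee, sign = sgn,
                                 mass = mass))
  }
  if (is.null(out)) data.frame(start = integer(0), end = integer(0),
                               sign = numeric(0), mass = numeric(0))
  else out
}

# Extreme cluster mass of each sign for one t curve.
max_cluster_masses <- function(tv, thr) {
  cl <- find_clusters(tv, thr)
  c(pos = if (any(cl$sign > 0)) max(cl$mass[cl$sign > 0]) else 0,
    neg = if (any(cl$sign < 0)) min(cl$mass[cl$sign < 0]) else 0)
}

#' Cluster-based sign-flip permutation test on paired time courses
#'
#' Per-sample paired t statistics are thresholded two-sidedly at the
#' cluster-forming alpha (default 0.05, i.e. `|t| > t_{0.975, n-1}`);
#' contiguous supra-threshold samples form clusters whose summed t is the
#' cluster mass. The null distribution is built by randomly sign-flipping
#' the participant difference curves and recording the maximal cluster
#' mass of each sign per permutation; positive and negative clusters are
#' each evaluated at `side_alpha` (default 0.025 per side). Monte-Carlo p
#' values use the `(b + 1) / (m + 1)` convention; with
#' `exhaustive = TRUE` all `2^n` sign patterns are enumerated and p is the
#' exact proportion.
#'
#' @param x Participants x time matrix for the first condition, or a
#'   difference matrix if `y` is `NULL`.
#' @param y Optional matching matrix for the second condition.
#' @param n_permutations Number of random sign flips (default 10000).
#' @param cluster_alpha Two-sided sample-level cluster-forming alpha.
#' @param side_alpha Significance level per sign (default 0.025).
#' @param time Optional time axis labelling the columns.
#' @param seed Optional seed making the permutation draw reproducible.
#' @param exhaustive Enumerate all sign patterns instead of sampling.
#' @return Object of class `cluster_test`: `clusters` data frame
#'   (`start_ms`, `end_ms`, `sign`, `mass`, `p`, `significant`), the
#'   observed t curve, threshold, and null-distribution summaries.
#' @export
cluster_permutation_test <- function(x, y = NULL, n_permutations = 10000,
                                     cluster_alpha = 0.05,
                                     side_alpha = 0.025, time = NULL,
                                     seed = NULL, exhaustive = FALSE) {
  d <- if (is.null(y)) as.matrix(x) else {
    abort_if(!all(dim(x) == dim(y)),
             "condition matrices must share dimensions (equal time axes)")
    as.matrix(x) - as.matrix(y)
  }
  n <- nrow(d)
  nt <- ncol(d)
  abort_if(n < 2, "need at least 2 participants")
  if (is.null(time)) time <- seq_len(nt) - 1L
  abort_if(length(time) != nt, "time axis does not match the matrices")
  thr <- stats::qt(1 - cluster_alpha / 2, df = n - 1)

  t_obs <- col_tstats(d)
  clusters <- find_clusters(t_obs, thr)

  if (exhaustive) {
    m <- 2^n
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    m <- n_permutations
    signs <- with_seed(seed,
                       matrix(sample(c(-1, 1), n * m, replace = TRUE), m, n))
  }
  ss <- colSums(d^2)
  null_pos <- numeric(m)
  null_neg <- numeric(m)
  chunk <- 500L
  for (a in seq(1, m, by = chunk)) {
    b <- min(a + chunk - 1L, m)
    S <- signs[a:b, , drop = FALSE]
    M <- (S %*% d) / n
    V <- sweep(-n * M^2, 2, ss, `+`) / (n - 1)
    V[V < .Machine$double.eps] <- .Machine$double.eps
    Tm <- M / sqrt(V / n)
    for (k in seq_len(nrow(Tm))) {
      mm <- max_cluster_masses(Tm[k, ], thr)
      null_pos[a + k - 1L] <- mm["pos"]
      null_neg[a + k - 1L] <- mm["neg"]
    }
  }

  if (nrow(clusters)) {
    clusters$p <- NA_real_
    for (k in seq_len(nrow(clusters))) {
      if (clusters$sign[k] > 0) {
        b <- sum(null_pos >= clusters$mass[k])
      } else {
        b <- sum(null_neg <= clusters$mass[k])
      }
      clusters$p[k] <- if (exhaustive) b / m else (b + 1) / (m + 1)
    }
    clusters$significant <- clusters$p <= side_alpha
    clusters$start_ms <- time[clusters$start]
    clusters$end_ms <- time[clusters$end]
    clusters <- clusters[order(clusters$start),
                         c("start_ms", "end_ms", "sign", "mass", "p",
                           "significant")]
  } else {
    clusters <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                           sign = numeric(0), mass = numeric(0),
                           p = numeric(0), significant = logical(0))
  }
  structure(list(clusters = clusters, t = t_obs, time = time,
                 threshold = thr, n = n, n_permutations = m,
                 side_alpha = side_alpha, exhaustive = exhaustive,
                 null_pos = stats::quantile(null_pos, c(0.5, 0.95, 0.975)),
                 null_neg = stats::quantile(null_neg, c(0.5, 0.05, 0.025))),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> n = %d, %s permutations, |t| threshold %.3f\n",
              x$n, if (x$exhaustive) "exhaustive" else x$n_permutations,
              x$threshold))
  if (nrow(x$clusters)) print(x$clusters) else cat("  no clusters\n")
  invisible(x)
}

#' Power of a two-sided paired/one-sample t-test
#'
#' Computed from the noncentral t distribution with noncentrality
#' `d * sqrt(n)`.
#'
#' @param d Cohen's d.
#' @param n Number of pairs.
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @export
power_paired_t <- function(d, n, alpha = 0.05) {
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  1 - stats::pt(tc, df, ncp = ncp) + stats::pt(-tc, df, ncp = ncp)
}

#' Minimal detectable effect size at a target power
#'
#' Solves for the smallest Cohen's d whose two-sided paired/one-sample
#' t-test power at sample size `n` reaches `power`, by monotone
#' root-finding on the noncentral-t power function.
#'
#' @param n Number of pairs.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @return Cohen's d.
#' @export
sensitivity_power_d <- function(n, alpha = 0.05, power = 0.80) {
  abort_if(alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1,
           "alpha and power must lie in (0, 1)")
  abort_if(n < 2, "n must be >= 2")
  f <- function(d) power_paired_t(d, n, alpha) - power
  upper <- 10
  abort_if(f(upper) < 0, "target power unreachable at n = %d", n)
  stats::uniroot(f, c(1e-8, upper), tol = 1e-10)$root
}
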