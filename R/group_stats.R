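# Group comparisons and regression: Welch's t, Cohen's d, Dunnett
# many-to-one and Steel-Dwass all-pairs multiple comparisons, OLS with
# pointwise confidence bands, and Monte-Carlo calibration utilities.

#' Welch's unequal-variance t-test
#'
#' @param x,y numeric samples (each n >= 2, finite variance).
#' @return list with `statistic`, `df` (Welch-Satterthwaite), `p`
#'   (two-sided).
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs n >= 2")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Cohen's d effect size (pooled SD, df-weighted)
#'
#' @param x,y numeric samples (each n >= 2).
#' @return (mean(x) - mean(y)) / pooled SD.
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs n >= 2")
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled SD: effect size undefined")
  (mean(x) - mean(y)) / sp
}

#' Dunnett many-to-one comparisons against a control
#'
#' Single-step multiplicity adjustment under the multivariate-t
#' distribution (via multcomp::glht on a one-way fit). The adjustment's
#' quasi-random integration is seeded locally for reproducibility.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length as `values`.
#' @param control_label label of the control group.
#' @param alpha significance level recorded in the output.
#' @param seed seed for the multivariate-t integration.
#' @return data.frame with comparison, estimate, statistic, p_adjusted,
#'   significant; `method` attribute records the adjustment.
#' @export
dunnett <- function(values, groups, control_label, alpha = 0.05, seed = 1L) {
  groups <- as.character(groups)
  if (!control_label %in% groups)
    stop(sprintf("control label '%s' absent", control_label))
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with n >= 2 each")
  g <- stats::relevel(factor(groups), ref = control_label)
  d <- data.frame(y = values, g = g)
  fit <- stats::aov(y ~ g, data = d)
  s <- with_seed(seed, summary(multcomp::glht(
    fit, linfct = multcomp::mcp(g = "Dunnett"))))
  out <- data.frame(
    comparison = names(s$test$coefficients),
    estimate = as.numeric(s$test$coefficients),
    statistic = as.numeric(s$test$tstat),
    p_adjusted = as.numeric(s$test$pvalues)
  )
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  attr(out, "method") <-
    "Dunnett single-step, multivariate-t adjustment (multcomp::glht)"
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  out
}

#' Steel-Dwass all-pairs nonparametric multiple comparisons
#'
#' For each pair of groups, the Wilcoxon rank-sum statistic is computed on
#' the two groups' data with midranks for ties (a warning is issued when
#' ties are present), standardized with the tie-corrected variance, and
#' referred to the studentized-range distribution with k groups and
#' infinite df (p = P(q >= sqrt(2) |z|)).
#'
#' @param values numeric response vector.
#' @param groups group labels, same length as `values`.
#' @param alpha significance level recorded in the output.
#' @return data.frame with group1, group2, statistic (standardized z),
#'   p_adjusted, significant.
#' @export
steel_dwass <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  labs <- sort(unique(groups))
  k <- length(labs)
  tab <- table(groups)
  if (k < 2 || any(tab < 2)) stop("need >= 2 groups with n >= 2 each")
  pairs <- utils::combn(labs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- values[groups == pairs[1, j]]
    b <- values[groups == pairs[2, j]]
    ni <- length(a); nj <- length(b); N <- ni + nj
    r <- rank(c(a, b))            # midranks
    if (anyDuplicated(c(a, b)) > 0)
      warning("ties present: using midranks")
    W <- sum(r[seq_len(ni)])
    E <- ni * (N + 1) / 2
    V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
    z <- if (V > 0) (W - E) / sqrt(V) else 0
    p <- 1 - stats::ptukey(sqrt(2) * abs(z), nmeans = k, df = Inf)
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               statistic = z, p_adjusted = p)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  attr(out, "method") <-
    "Steel-Dwass: pairwise rank sums, studentized-range adjustment"
  out
}

#' OLS regression with a pointwise confidence band for the mean response
#'
#' @param x,y numeric vectors (>= 3 points, non-constant x).
#' @param level confidence level (default 0.95).
#' @param at x values at which to evaluate the band (defaults to `x`).
#' @return list with `slope`, `intercept`, and `band` (data.frame: x, fit,
#'   lower, upper).
#' @export
linear_fit_ci <- function(x, y, level = 0.95, at = NULL) {
  if (length(x) < 3 || length(x) != length(y))
    stop("need >= 3 (x, y) points")
  if (stats::var(x) == 0) stop("constant x: regression undefined")
  d <- data.frame(x = x, y = y)
  fit <- stats::lm(y ~ x, data = d)
  if (is.null(at)) at <- sort(unique(x))
  pr <- stats::predict(fit, newdata = data.frame(x = at),
                       interval = "confidence", level = level)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       band = data.frame(x = at, fit = pr[, "fit"],
                         lower = pr[, "lwr"], upper = pr[, "upr"]))
}

#' Familywise type-I error of a multiple-comparison procedure under the null
#'
#' Draws all groups from N(0, 1) and records how often the procedure
#' rejects at least one comparison at `alpha`.
#'
#' @param test "dunnett" or "steel_dwass".
#' @param n_groups number of groups (the first is the Dunnett control).
#' @param n_per_group sample size per group.
#' @param n_sims Monte-Carlo replicates.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return empirical familywise rejection rate.
#' @export
simulate_null_fwer <- function(test = c("dunnett", "steel_dwass"),
                               n_groups = 3, n_per_group = 10,
                               n_sims = 1000, alpha = 0.05, seed = 1L) {
  test <- match.arg(test)
  labs <- paste0("g", seq_len(n_groups))
  groups <- rep(labs, each = n_per_group)
  rej <- with_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      y <- rnorm(n_groups * n_per_group)
      res <- if (test == "dunnett")
        dunnett(y, groups, control_label = "g1", alpha = alpha,
                seed = mix_seed(seed, 11L, i))
      else steel_dwass(y, groups, alpha = alpha)
      any(res$p_adjusted < alpha)
    }, logical(1))
  })
  mean(rej)
}

#' Coverage of the regression confidence band at the mean of x
#'
#' Simulates y = intercept + slope x + N(0, sigma), fits the band, and
#' records how often the band at x-bar covers the true mean response.
#'
#' @param n points per replicate.
#' @param slope,intercept,sigma true model parameters.
#' @param level band confidence level.
#' @param n_sims Monte-Carlo replicates.
#' @param seed integer seed.
#' @return empirical coverage at x-bar.
#' @export
ci_coverage_sim <- function(n = 20, slope = 3, intercept = 1, sigma = 1,
                            level = 0.95, n_sims = 1000, seed = 1L) {
  x <- seq(0, 1, length.out = n)
  xbar <- mean(x)
  truth <- intercept + slope * xbar
  cov <- with_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      y <- intercept + slope * x + rnorm(n, 0, sigma)
      b <- linear_fit_ci(x, y, level = level, at = xbar)$band
      b$lower[1] <= truth && truth <= b$upper[1]
    }, logical(1))
  })
  mean(cov)
}
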