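#' Tukey-Kramer all-pairs comparison with unequal group sizes
#'
#' All pairwise mean differences between processing groups with p-values and
#' simultaneous 95% confidence intervals from the studentized range
#' distribution, using the pooled within-group mean square. With unequal
#' sample sizes, the Kramer modification applies
#' \eqn{q = |\bar y_i - \bar y_j| / \sqrt{MSE/2\,(1/n_i + 1/n_j)}}.
#' The reported standard error column follows the conventional ANOVA
#' post-hoc layout, \eqn{SE = \sqrt{MSE\,(1/n_i + 1/n_j)}}.
#'
#' @param values numeric vector of measurements.
#' @param group factor/character of group labels (>= 2 groups, each n >= 2).
#' @param conf_level simultaneous confidence level.
#' @param mirror return both orderings of every pair (the published table
#'   layout) instead of each unordered pair once.
#' @return data frame with columns `group1`, `group2`, `difference`, `se`,
#'   `p`, `ci_low`, `ci_high`.
#' @export
tukey_kramer <- function(values, group, conf_level = 0.95, mirror = FALSE) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  ns <- tapply(values, group, length)
  if (nlevels(group) < 2) stop("need at least two groups")
  if (any(ns < 2)) stop("every group needs n >= 2")
  means <- tapply(values, group, mean)
  k <- nlevels(group)
  N <- length(values)
  df <- N - k
  mse_w <- sum(tapply(values, group, function(v) sum((v - mean(v))^2))) / df
  combs <- utils::combn(levels(group), 2)
  rows <- lapply(seq_len(ncol(combs)), function(i) {
    g1 <- combs[1, i]; g2 <- combs[2, i]
    diff <- means[[g1]] - means[[g2]]
    se_q <- sqrt(mse_w / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    q <- abs(diff) / se_q
    p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    qc <- stats::qtukey(conf_level, nmeans = k, df = df)
    data.frame(group1 = g1, group2 = g2, difference = unname(diff),
               se = sqrt(2) * se_q, p = p,
               ci_low = unname(diff) - qc * se_q,
               ci_high = unname(diff) + qc * se_q,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (mirror) {
    rev_ <- out
    rev_$group1 <- out$group2
    rev_$group2 <- out$group1
    rev_$difference <- -out$difference
    rev_$ci_low <- -out$ci_high
    rev_$ci_high <- -out$ci_low
    out <- rbind(out, rev_)
    out <- out[order(out$group1, out$group2), ]
    rownames(out) <- NULL
  }
  out
}

#' Two-way ANOVA of processing arm by dose level
#'
#' Factorial analysis of the FWHM (or other) measurements with processing
#' arm and dose level as crossed factors, Type II sums of squares for
#' unbalanced cells. The reference arm carries no dose factor and is
#' excluded from the factorial block by the caller. With three processing
#' arms and two dose levels the degrees of freedom are 2, 1 and 2 for the
#' main effects and interaction.
#'
#' @param values numeric vector of measurements.
#' @param processing factor of processing arms.
#' @param dose factor of dose levels.
#' @return data frame with columns `source`, `df`, `ss`, `ms`, `F`, `p`
#'   (rows: Processing, Dose, Processing x Dose, Error).
#' @export
two_way_anova <- function(values, processing, dose) {
  processing <- factor(processing)
  dose <- factor(dose)
  stopifnot(length(values) == length(processing),
            length(values) == length(dose))
  tab <- table(processing, dose)
  if (any(tab == 0)) stop("empty cell in the processing x dose design")
  d <- data.frame(y = values, p = processing, dd = dose)
  fit <- stats::lm(y ~ p * dd, data = d)
  a2 <- car::Anova(fit, type = 2)
  idx <- c("p", "dd", "p:dd", "Residuals")
  ss <- a2[idx, "Sum Sq"]
  dfs <- a2[idx, "Df"]
  ms <- ss / dfs
  Fv <- c(ms[1:3] / ms[4], NA)
  pv <- c(stats::pf(Fv[1:3], dfs[1:3], dfs[4], lower.tail = FALSE), NA)
  data.frame(source = c("Processing", "Dose", "Processing x Dose", "Error"),
             df = dfs, ss = ss, ms = ms, F = Fv, p = pv,
             stringsAsFactors = FALSE, row.names = NULL)
}
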