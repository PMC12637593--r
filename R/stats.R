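#' One-way analysis of variance
#'
#' Classical fixed-effects F test on between/within group mean squares
#' (fitted via `stats::lm`/`anova`); unequal group sizes are supported.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor, >= 2 levels with
#'   n >= 2 each).
#' @return A list of class `"fs_stat"`: `test`, `statistic` (F), `df`
#'   (numerator, denominator), `p_value`, plus `ms_error` and group
#'   sizes used by [tukey_kramer()].
#' @examples
#' one_way_anova(c(1, 2, 3, 4, 6, 8), rep(c("a", "b"), each = 3))
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  check_groups(values, groups, min_groups = 2)
  if (all(tapply(values, groups, sd) == 0) &&
      length(unique(tapply(values, groups, mean))) == 1L)
    stop("F undefined: zero within-group variance and equal means")
  fit <- lm(values ~ groups)
  a <- anova(fit)
  structure(list(test = "one-way ANOVA", statistic = a$`F value`[1],
                 df = c(a$Df[1], a$Df[2]), p_value = a$`Pr(>F)`[1],
                 ms_error = a$`Mean Sq`[2],
                 group_means = tapply(values, groups, mean),
                 group_n = as.integer(table(groups))),
            class = "fs_stat")
}

check_groups <- function(values, groups, min_groups) {
  stopifnot(length(values) == length(groups), all(is.finite(values)))
  n <- table(groups)
  if (length(n) < min_groups)
    stop("need at least ", min_groups, " groups")
  if (any(n < 2)) stop("every group needs n >= 2")
  invisible(NULL)
}

#' Tukey-Kramer pairwise comparisons
#'
#' Studentized-range post hoc comparisons after a one-way ANOVA, with
#' the Kramer standard error `sqrt(MSE/2 * (1/n_i + 1/n_j))` for unequal
#' group sizes (reducing to classical Tukey HSD when sizes are equal).
#' P values come from `stats::ptukey`.
#'
#' @inheritParams one_way_anova
#' @return Data.frame with one row per pair: `group1`, `group2`, `diff`,
#'   `q` (studentized-range statistic), `p_adj`.
#' @export
tukey_kramer <- function(values, groups) {
  groups <- factor(groups)
  aov1 <- one_way_anova(values, groups)
  k <- nlevels(groups)
  df_err <- aov1$df[2]
  mse <- aov1$ms_error
  means <- aov1$group_means
  ns <- aov1$group_n
  pairs <- utils::combn(levels(groups), 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- match(pr[1], levels(groups)); j <- match(pr[2], levels(groups))
    d <- means[[i]] - means[[j]]
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(d) / se
    data.frame(group1 = pr[1], group2 = pr[2], diff = d, q = q,
               p_adj = ptukey(q, nmeans = k, df = df_err,
                              lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Unpaired two-tailed t test
#'
#' Pooled-variance (classical Student) by default; Welch's unequal-
#' variance form behind `var_equal = FALSE`.
#'
#' @param x,y Numeric samples (n >= 2 each).
#' @param var_equal Pool variances (default `TRUE`).
#' @return A list of class `"fs_stat"` with `statistic` (t), `df`,
#'   `p_value`.
#' @export
unpaired_t <- function(x, y, var_equal = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y))
    stop("t undefined: zero variance in both groups with equal means")
  tt <- stats::t.test(x, y, var.equal = var_equal)
  structure(list(test = if (var_equal) "pooled t" else "Welch t",
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value),
            class = "fs_stat")
}

#' Mixed (split-plot) repeated-measures ANOVA with Greenhouse-Geisser
#' correction
#'
#' Two-way mixed design: one between-subject factor (e.g. genotype) and
#' one within-subject factor (e.g. interstimulus interval), each subject
#' measured at every within level (subjects with incomplete profiles are
#' dropped listwise). Sums of squares come from `stats::aov` with an
#' `Error(subject)` stratum; the within-subject effects' degrees of
#' freedom are multiplied by the Greenhouse-Geisser epsilon
#' \deqn{\epsilon = (\sum \lambda_i)^2 / ((k-1) \sum \lambda_i^2)}
#' where \eqn{\lambda_i} are the eigenvalues of the double-centred,
#' group-pooled covariance matrix of the k within levels. With k = 2
#' levels epsilon is exactly 1.
#'
#' @param data Data.frame containing the columns named below.
#' @param value,subject,within,between Column names (strings).
#' @return A list of class `"fs_rm_anova"`: `epsilon`, `n_dropped`, and
#'   `effects`, a data.frame with one row per effect (`between`,
#'   `within`, `interaction`) holding `F`, uncorrected `df1`/`df2`,
#'   GG-corrected `df1_gg`/`df2_gg` and `p_gg` (between-subject rows are
#'   uncorrected: `p_gg` equals the classical p).
#' @export
mixed_rm_anova <- function(data, value = "value", subject = "subject",
                           within = "within", between = "between") {
  d <- data.frame(y = data[[value]], id = factor(data[[subject]]),
                  w = factor(data[[within]]), g = factor(data[[between]]))
  if (nlevels(d$w) < 2)
    stop("within factor needs at least 2 levels")
  # listwise completeness
  k <- nlevels(d$w)
  cnt <- table(d$id)
  keep <- names(cnt)[cnt == k]
  complete <- d$id %in% keep &
    !is.na(d$y)
  n_dropped <- nlevels(d$id) - length(keep)
  d <- droplevels(d[d$id %in% keep, ])
  if (any(table(d$id) != k))
    stop("subjects must be measured exactly once at every within level")
  if (nlevels(d$g) < 2) stop("between factor needs at least 2 levels")

  fit <- aov(y ~ g * w + Error(id), data = d)
  s <- summary(fit)
  btab <- s[["Error: id"]][[1]]
  wtab <- s[["Error: Within"]][[1]]
  rn_b <- trimws(rownames(btab))
  rn_w <- trimws(rownames(wtab))

  eps <- gg_epsilon(d)

  get <- function(tab, rn, term) {
    i <- match(term, rn)
    c(df = tab$Df[i], ss = tab$`Sum Sq`[i], ms = tab$`Mean Sq`[i],
      f = tab$`F value`[i])
  }
  b_g <- get(btab, rn_b, "g"); b_res <- get(btab, rn_b, "Residuals")
  w_w <- get(wtab, rn_w, "w"); w_gw <- get(wtab, rn_w, "g:w")
  w_res <- get(wtab, rn_w, "Residuals")

  eff <- rbind(
    data.frame(effect = "between", F = b_g[["f"]], df1 = b_g[["df"]],
               df2 = b_res[["df"]], df1_gg = b_g[["df"]],
               df2_gg = b_res[["df"]],
               p_gg = pf(b_g[["f"]], b_g[["df"]], b_res[["df"]],
                         lower.tail = FALSE)),
    data.frame(effect = "within", F = w_w[["f"]], df1 = w_w[["df"]],
               df2 = w_res[["df"]], df1_gg = w_w[["df"]] * eps,
               df2_gg = w_res[["df"]] * eps,
               p_gg = pf(w_w[["f"]], w_w[["df"]] * eps,
                         w_res[["df"]] * eps, lower.tail = FALSE)),
    data.frame(effect = "interaction", F = w_gw[["f"]], df1 = w_gw[["df"]],
               df2 = w_res[["df"]], df1_gg = w_gw[["df"]] * eps,
               df2_gg = w_res[["df"]] * eps,
               p_gg = pf(w_gw[["f"]], w_gw[["df"]] * eps,
                         w_res[["df"]] * eps, lower.tail = FALSE)))
  structure(list(epsilon = eps, n_dropped = n_dropped, effects = eff,
                 n_subjects = nlevels(d$id), k_within = k),
            class = "fs_rm_anova")
}

# Greenhouse-Geisser epsilon from the group-pooled within-subject
# covariance matrix (wide layout), via the double-centred eigenvalues.
gg_epsilon <- function(d) {
  k <- nlevels(d$w)
  if (k == 2) return(1)
  pool <- matrix(0, k, k)
  wsum <- 0
  for (g in levels(d$g)) {
    dg <- d[d$g == g, ]
    wide <- tapply(dg$y, list(dg$id, dg$w), mean)
    wide <- wide[rowSums(is.na(wide)) == 0, , drop = FALSE]
    ng <- nrow(wide)
    if (ng >= 2) {
      pool <- pool + (ng - 1) * stats::cov(wide)
      wsum <- wsum + (ng - 1)
    }
  }
  if (wsum == 0) return(1)
  S <- pool / wsum
  P <- diag(k) - matrix(1 / k, k, k)
  M <- P %*% S %*% P
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  min(1, max(eps, 1 / (k - 1)))
}

#' Bootstrap distribution of the sample mean
#'
#' `n_iter` resamples with replacement of the full sample, returning the
#' resampled means (used to visualise the sampling distribution of group
#' means). Deterministic given `seed`.
#'
#' @param values Numeric sample (n >= 1).
#' @param n_iter Number of iterations (default 1000).
#' @param seed Optional RNG seed.
#' @return Numeric vector of `n_iter` bootstrap means.
#' @export
bootstrap_means <- function(values, n_iter = 1000, seed = NULL) {
  stopifnot(length(values) >= 1, n_iter >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  vapply(seq_len(n_iter),
         function(i) mean(values[sample.int(n, n, replace = TRUE)]),
         numeric(1))
}

#' Per-group mean and standard error
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @return Data.frame with `group`, `n`, `mean`, `sem` (`sem` is `NA`
#'   for singleton groups, flagged in `note`).
#' @export
summarize_groups <- function(values, groups) {
  groups <- factor(groups)
  rows <- lapply(levels(groups), function(g) {
    x <- values[groups == g]
    data.frame(group = g, n = length(x), mean = mean(x),
               sem = if (length(x) > 1) sd(x) / sqrt(length(x))
                     else NA_real_,
               note = if (length(x) > 1) "" else "single observation",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.fs_stat <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$test,
              x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' @export
print.fs_rm_anova <- function(x, ...) {
  cat(sprintf(
    "mixed RM-ANOVA (%d subjects, %d within levels), GG epsilon = %.3f\n",
    x$n_subjects, x$k_within, x$epsilon))
  print(x$effects, row.names = FALSE)
  invisible(x)
}
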