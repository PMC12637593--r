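test_that("two-group ANOVA equals the squared pooled t", {
  set.seed(1)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  av <- one_way_anova(c(x, y), rep(c("a", "b"), c(12, 15)))
  tt <- unpaired_t(x, y)
  expect_equal(av$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(av$p_value, tt$p_value, tolerance = 1e-10)
})

test_that("ANOVA F matches an independent sum-of-squares computation", {
  set.seed(2)
  vals <- rnorm(54, rep(c(0, 0.3, 0.6), c(18, 16, 20)))
  grp <- rep(c("g1", "g2", "g3"), c(18, 16, 20))
  av <- one_way_anova(vals, grp)
  # brute force: explicit between/within sums of squares
  gm <- mean(vals)
  ss_b <- sum(tapply(vals, grp, function(v) length(v) * (mean(v) - gm)^2))
  ss_w <- sum(unlist(tapply(vals, grp, function(v) (v - mean(v))^2)))
  f_oracle <- (ss_b / 2) / (ss_w / (54 - 3))
  expect_equal(av$statistic, f_oracle, tolerance = 1e-10)
  expect_error(one_way_anova(rep(1, 6), rep(c("a", "b"), 3)),
               "undefined")
})

test_that("Tukey-Kramer matches TukeyHSD and is conservative", {
  set.seed(3)
  # equal n: reduces to classical Tukey HSD (cross-check vs stats::TukeyHSD)
  vals <- rnorm(30, rep(c(0, 0.5, 1), each = 10))
  grp <- factor(rep(c("a", "b", "c"), each = 10))
  tk <- tukey_kramer(vals, grp)
  hsd <- TukeyHSD(aov(vals ~ grp))$grp
  for (r in seq_len(nrow(tk))) {
    key <- paste0(tk$group2[r], "-", tk$group1[r])
    expect_equal(tk$p_adj[r], hsd[key, "p adj"], tolerance = 1e-4)
  }
  # unequal n cross-check (TukeyHSD implements the Kramer form too)
  vals2 <- rnorm(54, rep(c(0, 0.4, 0.8), c(18, 16, 20)))
  grp2 <- factor(rep(c("a", "b", "c"), c(18, 16, 20)))
  tk2 <- tukey_kramer(vals2, grp2)
  hsd2 <- TukeyHSD(aov(vals2 ~ grp2))$grp2
  for (r in seq_len(nrow(tk2))) {
    key <- paste0(tk2$group2[r], "-", tk2$group1[r])
    expect_equal(tk2$p_adj[r], hsd2[key, "p adj"], tolerance = 1e-4)
  }
  # adjusted p never below the unadjusted pairwise t p
  for (r in seq_len(nrow(tk2))) {
    x <- vals2[grp2 == tk2$group1[r]]
    y <- vals2[grp2 == tk2$group2[r]]
    expect_gte(tk2$p_adj[r] + 1e-12, unpaired_t(x, y)$p_value)
  }
})

test_that("pooled t matches the closed form", {
  set.seed(4)
  x <- rnorm(10); y <- rnorm(12, 1)
  tt <- unpaired_t(x, y)
  sp2 <- ((9 * var(x) + 11 * var(y)) / 20)
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 10 + 1 / 12))
  p_oracle <- 2 * pt(abs(t_oracle), 20, lower.tail = FALSE)
  expect_equal(tt$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(tt$p_value, p_oracle, tolerance = 1e-10)
  expect_error(unpaired_t(rep(1, 3), rep(1, 3)), "undefined")
})

test_that("GG epsilon: k = 2 exact unity, compound symmetry -> 1", {
  mk <- function(n_per_g, k, rho = 0, ar1 = FALSE) {
    rows <- list()
    for (g in 1:2) for (i in 1:n_per_g) {
      if (ar1) {
        e <- as.numeric(arima.sim(list(ar = rho), k))
      } else {
        shared <- rnorm(1, 0, sqrt(rho / max(1e-9, 1 - rho)))
        e <- shared + rnorm(k)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        value = e, subject = sprintf("g%d_s%d", g, i),
        within = seq_len(k), between = paste0("g", g))
    }
    do.call(rbind, rows)
  }
  set.seed(5)
  d2 <- mk(8, 2)
  expect_identical(mixed_rm_anova(d2)$epsilon, 1)
  # compound-symmetric covariance: epsilon approaches 1 for large n
  d_cs <- mk(100, 5, rho = 0.5)
  expect_gt(mixed_rm_anova(d_cs)$epsilon, 0.95)
})

test_that("mixed RM-ANOVA agrees with the multivariate-model route", {
  skip_if_not_installed("car")
  set.seed(6)
  k <- 5; n1 <- 11; n2 <- 10
  mk_subj <- function() as.numeric(arima.sim(list(ar = 0.6), k))
  wide <- t(replicate(n1 + n2, mk_subj()))
  wide[seq_len(n1), 2] <- wide[seq_len(n1), 2] + 1
  g <- factor(rep(c("wt", "ko"), c(n1, n2)))
  long <- data.frame(value = as.vector(t(wide)),
                     subject = rep(sprintf("s%02d", 1:(n1 + n2)), each = k),
                     within = rep(1:k, n1 + n2),
                     between = rep(g, each = k))
  mine <- mixed_rm_anova(long)
  mlm <- lm(wide ~ g)
  idata <- data.frame(within = factor(1:k))
  ca <- car::Anova(mlm, idata = idata, idesign = ~within, type = 3)
  s <- summary(ca, multivariate = FALSE)
  adj <- s$pval.adjustments
  expect_equal(mine$epsilon, unname(adj["within", "GG eps"]),
               tolerance = 1e-6)
  # the interaction (the effect of interest: does the within-profile
  # differ between groups?) and the between effect agree exactly; the
  # within main effect can differ under unequal n because the
  # multivariate route uses type-III sums of squares
  expect_equal(mine$effects$p_gg[mine$effects$effect == "interaction"],
               unname(adj["g:within", "Pr(>F[GG])"]), tolerance = 1e-6)
  ut <- s$univariate.tests
  expect_equal(mine$effects$F[mine$effects$effect == "between"],
               unname(ut["g", "F value"]), tolerance = 1e-8)
  expect_equal(mine$effects$F[mine$effects$effect == "interaction"],
               unname(ut["g:within", "F value"]), tolerance = 1e-8)
})

test_that("bootstrap: degeneracy, consistency, determinism", {
  expect_true(all(bootstrap_means(5, 1000, seed = 1) == 5))
  set.seed(7)
  x <- rnorm(18, 10, 2)
  b <- bootstrap_means(x, 1000, seed = 2)
  sem <- sd(x) / sqrt(18)
  expect_lt(abs(mean(b) - mean(x)), 2 * sem)
  expect_identical(bootstrap_means(x, 50, seed = 9),
                   bootstrap_means(x, 50, seed = 9))
})

test_that("group summaries: arithmetic and singleton flagging", {
  s <- summarize_groups(c(1, 2, 3), rep("a", 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3))
  s2 <- summarize_groups(c(1, 2, 3, 9), c("a", "a", "a", "b"))
  expect_true(is.na(s2$sem[s2$group == "b"]))
  expect_match(s2$note[s2$group == "b"], "single")
  # two-pass variance oracle
  x <- rnorm(25)
  s3 <- summarize_groups(x, rep("g", 25))
  m <- sum(x) / 25
  v <- sum((x - m)^2) / 24
  expect_equal(s3$sem, sqrt(v / 25), tolerance = 1e-12)
})
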