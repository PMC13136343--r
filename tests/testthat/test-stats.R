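test_that("normality gate routes distributions to the right test family", {
  set.seed(71)
  heavy <- mean(vapply(1:40, function(i)
    normality_gate(rt(200, df = 2)) == "nonparametric", logical(1)))
  expect_gte(heavy, 0.95)
  normal <- mean(vapply(1:40, function(i)
    normality_gate(rnorm(200)) == "parametric", logical(1)))
  expect_gt(normal, 0.85)
  expect_lte(normal, 1)
  g <- normality_gate(rep(1, 10))
  expect_equal(as.character(g), "nonparametric")
  expect_true(attr(g, "degenerate"))
  expect_true(attr(normality_gate(c(1, 2)), "degenerate"))
})

test_that("BH mask equals the literal step-up definition", {
  expect_equal(fdr_bh(c(0.01, 0.04, 0.03, 0.005), q = 0.05),
               rep(TRUE, 4))
  expect_equal(fdr_bh(rep(0.9, 6)), rep(FALSE, 6))
  set.seed(73)
  for (i in 1:200) {
    m <- sample(1:60, 1)
    p <- runif(m)^sample(c(1, 2, 0.5), 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(fdr_bh(p, q), bf_bh_mask(p, q))
  }
  # order invariance
  p <- runif(30)
  o <- sample(30)
  expect_identical(fdr_bh(p)[o], fdr_bh(p[o]))
  expect_identical(fdr_bh(numeric(0)), logical(0))
  expect_error(fdr_bh(c(0.5, 1.2)))
})

test_that("closed-form balanced LMM equals the lme4 route, on and off boundary", {
  set.seed(79)
  design <- expand.grid(subject = sprintf("s%02d", 1:10),
                        condition = LETTERS[1:3])
  mk <- function(subj_sd) {
    dplyr::bind_rows(lapply(1:6, function(b) {
      se <- rnorm(10, 0, subj_sd)
      tibble::tibble(subject = design$subject, condition = design$condition,
                     bin = b,
                     value = se[as.integer(factor(design$subject))] +
                       rnorm(nrow(design)))
    }))
  }
  for (ssd in c(1, 0)) {
    d <- mk(ssd)
    a <- per_bin_lmm(d, pairwise = TRUE, method = "auto")
    b <- suppressMessages(per_bin_lmm(d, pairwise = TRUE, method = "lme4"))
    expect_equal(a$statistic, b$statistic, tolerance = 1e-6)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-6)
    expect_equal(a$df2, b$df2)
  }
})

test_that("per-bin LMM finds planted condition effects and flags fallback designs", {
  set.seed(83)
  design <- expand.grid(subject = sprintf("s%02d", 1:12),
                        condition = LETTERS[1:4])
  d <- dplyr::bind_rows(lapply(1:30, function(b) {
    se <- rnorm(12)
    v <- se[as.integer(factor(design$subject))] + rnorm(nrow(design))
    if (b >= 10 & b <= 15) v <- v + 3 * (design$condition == "D")
    tibble::tibble(subject = design$subject, condition = design$condition,
                   bin = b, value = v)
  }))
  res <- add_fdr(per_bin_lmm(d))
  hit <- res$bin[res$q_significant]
  expect_true(all(10:15 %in% hit))
  expect_lt(length(setdiff(hit, 10:15)), 5)
  # single subject falls back to fixed effects, flagged
  d1 <- dplyr::filter(d, subject == "s01")
  # 4 observations per bin saturate the fixed-effects fallback; base R warns
  r1 <- suppressWarnings(per_bin_lmm(d1))
  expect_true(all(r1$fallback))
  # pairwise contrasts isolate the planted condition
  pw <- per_bin_lmm(dplyr::filter(d, bin == 12), pairwise = TRUE)
  sig <- pw$contrast[pw$contrast != "omnibus" & pw$p_value < 0.01]
  expect_true(all(grepl("D", sig)))
})

test_that("omnibus and post-hoc tests behave across designs", {
  set.seed(89)
  # three identical groups: no effect
  d0 <- tibble::tibble(value = rep(rnorm(40), 3),
                       group = rep(c("a", "b", "c"), each = 40))
  expect_gt(omnibus_and_posthoc(d0)$omnibus$p_value, 0.99)
  # planted shift flagged only against the shifted group
  d1 <- tibble::tibble(value = c(rnorm(50), rnorm(50), rnorm(50) + 2),
                       group = rep(c("a", "b", "c"), each = 50))
  r1 <- omnibus_and_posthoc(d1)
  expect_lt(r1$omnibus$p_value, 1e-6)
  sig <- r1$posthoc$contrast[r1$posthoc$p_adj < 0.01]
  expect_setequal(sig, c("c-a", "c-b"))
  # two groups reduce to the two-sample test
  d2 <- tibble::tibble(value = c(rnorm(30), rnorm(30) + 1),
                       group = rep(c("a", "b"), each = 30))
  r2 <- omnibus_and_posthoc(d2, family = "parametric")
  tt <- t.test(value ~ group, data = d2, var.equal = TRUE)
  expect_equal(r2$omnibus$p_value, tt$p.value, tolerance = 1e-10)
  # tiny group excluded with a warning
  d3 <- dplyr::bind_rows(d1, tibble::tibble(value = 1, group = "tiny"))
  expect_warning(r3 <- omnibus_and_posthoc(d3), "n < 2")
  expect_equal(r3$excluded_groups, "tiny")
})

test_that("Cohen's d has the right value, sign convention and CI behavior", {
  expect_equal(cohen_d(rnorm(20), rnorm(20))$d * 0, 0)
  a <- c(0, 0, 0, 0) + rnorm(4, sd = 1e-6)
  b <- c(1, 1, 1, 1) + rnorm(4, sd = 1e-6)
  expect_lt(cohen_d(a, b)$d, -100)
  set.seed(97)
  big <- cohen_d(rnorm(10000, 0.5), rnorm(10000, 0))
  expect_lt(abs(big$d - 0.5), 0.05)
  expect_true(big$ci_low <= big$d && big$d <= big$ci_high)
  z <- cohen_d(rep(1, 5), rep(1, 5))
  expect_true(is.na(z$d))
  expect_error(cohen_d(1, 1:5))
})

test_that("identical samples give Cohen's d of exactly zero", {
  x <- rnorm(25)
  expect_equal(cohen_d(x, x)$d, 0)
})

test_that("max-statistic permutation controls FWER and detects planted cells", {
  set.seed(101)
  x <- matrix(rnorm(40 * 20), 40, 20)
  labels <- rep(c("a", "b"), each = 20)
  null_res <- permutation_fwer(x, labels, n_perm = 500, seed = 1)
  expect_gte(min(null_res$p_corrected), 0.05)
  x2 <- x
  x2[labels == "b", 7] <- x2[labels == "b", 7] + 5
  res <- permutation_fwer(x2, labels, n_perm = 500, seed = 1)
  expect_lte(res$p_corrected[7], 0.005)
  expect_gt(min(res$p_corrected[-7]), 0.05)
  # one-cell map reduces to a plain permutation test
  one <- permutation_fwer(x2[, 7, drop = FALSE], labels, n_perm = 500, seed = 2)
  expect_lte(one$p_corrected, 0.005)
  expect_warning(permutation_fwer(x, labels, n_perm = 50, seed = 1))
})

test_that("chi-squared wrapper reports the standard test", {
  tab <- matrix(c(20, 30, 25, 25), 2, 2)
  r <- chisq_table(tab)
  expect_equal(r$p_value, suppressWarnings(chisq.test(tab))$p.value)
})
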