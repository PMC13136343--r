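#' Normality gate for test-family selection
#'
#' Shapiro-Wilk test at `alpha`; a rejection routes downstream analyses to
#' the nonparametric family (Kruskal-Wallis / Wilcoxon), otherwise the
#' parametric family (ANOVA / t-tests). Samples with n < 3 or zero variance
#' go nonparametric with a degenerate-data flag.
#'
#' @param x Numeric sample.
#' @param alpha Gate level (default 0.05).
#'
#' @return `"parametric"` or `"nonparametric"`, with attributes `p_value`
#'   and `degenerate`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || stats::var(x) == 0) {
    out <- "nonparametric"
    attr(out, "p_value") <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  xs <- if (length(x) > 5000) x[round(seq(1, length(x), length.out = 5000))] else x
  p <- shapiro.test(xs)$p.value
  out <- if (p < alpha) "nonparametric" else "parametric"
  attr(out, "p_value") <- p
  attr(out, "degenerate") <- FALSE
  out
}

#' Benjamini-Hochberg significance mask
#'
#' Step-up false-discovery-rate control at level `q` (delegated to
#' [stats::p.adjust()]; rank-based, hence invariant to input order).
#'
#' @param p_values Numeric p-values in [0, 1].
#' @param q FDR level (default 0.05).
#'
#' @return Logical rejection mask, same length as the input.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH") <= q
}

#' Per-bin linear mixed-effects tests
#'
#' Fits `value ~ condition + (1 | subject)` independently at every time bin
#' (REML via lme4; the model for one bin is fitted once and re-used as a
#' template with [lme4::refit()] when the design rows are identical across
#' bins). The omnibus condition test is a Wald F; for the balanced
#' one-observation-per-cell design its Satterthwaite denominator df equals
#' `(n_subjects - 1) * (n_conditions - 1)` exactly, which is used in closed
#' form; unbalanced designs fall back to [lmerTest] Satterthwaite ANOVA.
#' Pairwise contrasts (equivalent to rotating the condition reference
#' level) are two-sided Wald t-tests on condition-level differences.
#' Designs that cannot support a random intercept (a single subject, or a
#' failed fit) fall back to a fixed-effects-only fit, flagged in the
#' output.
#'
#' @param data Long tibble with columns `value`, `condition`, `subject`,
#'   `bin`.
#' @param pairwise Also emit all pairwise condition contrasts per bin.
#' @param method `"auto"` (default) uses the exact closed form of the REML
#'   fit for the balanced one-observation-per-cell design (identical to the
#'   lme4 result, including zero-variance boundary fits; equality is
#'   asserted in the test suite) and lme4 otherwise; `"lme4"` forces the
#'   numerical route for every design.
#'
#' @return A tibble with `bin`, `contrast` (`"omnibus"` or `"A-B"`),
#'   `statistic`, `df1`, `df2`, `p_value`, `fallback`.
#' @export
per_bin_lmm <- function(data, pairwise = FALSE, method = c("auto", "lme4")) {
  method <- match.arg(method)
  stopifnot(all(c("value", "condition", "subject", "bin") %in% names(data)))
  data <- mutate(data, condition = factor(.data$condition),
                 subject = factor(.data$subject))
  bins <- sort(unique(data$bin))
  n_cond <- nlevels(data$condition)
  if (n_cond < 2) abort("Need >= 2 conditions.")
  fallback <- nlevels(data$subject) < 2

  split_bins <- split(data, data$bin)
  # template reuse requires identical (subject, condition) rows per bin
  key <- function(d) paste(d$subject, d$condition, collapse = ";")
  keys <- vapply(split_bins, key, character(1))
  templated <- !fallback && length(unique(keys)) == 1L

  d1 <- split_bins[[1]]
  balanced <- templated &&
    all(table(d1$subject, d1$condition) == 1L)
  df2_closed <- (nlevels(data$subject) - 1) * (n_cond - 1)

  if (balanced && method == "auto") {
    return(balanced_lmm_closed_form(split_bins, bins, pairwise))
  }

  template <- NULL
  if (!fallback) {
    template <- tryCatch(
      lme4::lmer(value ~ condition + (1 | subject), data = d1,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
      error = function(e) NULL)
    if (is.null(template)) fallback <- TRUE
  }

  rows <- vector("list", length(bins))
  for (i in seq_along(bins)) {
    d <- split_bins[[i]]
    if (fallback) {
      fit <- stats::lm(value ~ condition, data = d)
      an <- stats::anova(fit)
      rows[[i]] <- tibble(bin = bins[i], contrast = "omnibus",
                          statistic = an$`F value`[1], df1 = an$Df[1],
                          df2 = an$Df[2], p_value = an$`Pr(>F)`[1],
                          fallback = TRUE)
      next
    }
    m <- if (templated && i > 1) lme4::refit(template, d$value) else {
      if (templated) template else
        lme4::lmer(value ~ condition + (1 | subject), data = d,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = "ignore"))
    }
    b <- lme4::fixef(m)
    V <- as.matrix(stats::vcov(m))
    ci <- seq_len(n_cond - 1) + 1L
    bb <- b[ci]
    Vi <- V[ci, ci, drop = FALSE]
    Fstat <- drop(t(bb) %*% solve(Vi, bb)) / (n_cond - 1)
    df2 <- if (balanced) {
      # boundary fits (zero subject variance) collapse to OLS residual df
      if (lme4::getME(m, "theta") <= 1e-8) nrow(d) - n_cond else df2_closed
    } else {
      satterthwaite_df2(m, d)
    }
    p <- pf(Fstat, n_cond - 1, df2, lower.tail = FALSE)
    out_i <- tibble(bin = bins[i], contrast = "omnibus", statistic = Fstat,
                    df1 = n_cond - 1, df2 = df2, p_value = p,
                    fallback = FALSE)
    if (pairwise) {
      lev <- levels(data$condition)
      # condition-level means in coefficient space: level 1 is the
      # reference; rotating the reference is equivalent to testing the
      # difference of level effects
      eff <- c(0, b[ci])
      prs <- utils::combn(seq_len(n_cond), 2)
      pw <- lapply(seq_len(ncol(prs)), function(j) {
        a <- prs[1, j]; bidx <- prs[2, j]
        L <- numeric(n_cond - 1)
        if (a > 1) L[a - 1] <- 1
        if (bidx > 1) L[bidx - 1] <- L[bidx - 1] - 1
        est <- unname(eff[a] - eff[bidx])
        se <- sqrt(drop(t(L) %*% Vi %*% L))
        tval <- est / se
        dfp <- df2
        tibble(bin = bins[i],
               contrast = paste(lev[a], lev[bidx], sep = "-"),
               statistic = tval, df1 = 1, df2 = dfp,
               p_value = 2 * pt(abs(tval), dfp, lower.tail = FALSE),
               fallback = FALSE)
      })
      out_i <- bind_rows(out_i, bind_rows(pw))
    }
    rows[[i]] <- out_i
  }
  bind_rows(rows)
}

# Exact REML solution of value ~ condition + (1 | subject) for the balanced
# one-observation-per-cell design. With the between-subject mean square
# MS_S and interaction mean square MSE, REML gives tau^2 =
# max(0, (MS_S - MSE)/c). Off the boundary the Wald F for condition equals
# MS_C/MSE with Satterthwaite denominator df (s-1)(c-1); on the boundary the
# model collapses to OLS on condition with sigma^2 = RSS/(n - c) and
# denominator df n - c. Matches the lme4 route to numerical precision.
balanced_lmm_closed_form <- function(split_bins, bins, pairwise) {
  d1 <- split_bins[[1]]
  s <- nlevels(droplevels(d1$subject))
  cc <- nlevels(d1$condition)
  lev <- levels(d1$condition)
  rows <- vector("list", length(bins))
  for (i in seq_along(bins)) {
    d <- split_bins[[i]]
    y <- matrix(NA_real_, s, cc)
    y[cbind(as.integer(droplevels(d$subject)), as.integer(d$condition))] <-
      d$value
    mS <- rowMeans(y); mC <- colMeans(y); mG <- mean(y)
    ssS <- cc * sum((mS - mG)^2)
    ssC <- s * sum((mC - mG)^2)
    sse <- sum((y - outer(mS, rep(1, cc)) -
                  outer(rep(1, s), mC) + mG)^2)
    msS <- ssS / (s - 1)
    msC <- ssC / (cc - 1)
    mse <- sse / ((s - 1) * (cc - 1))
    boundary <- msS < mse
    if (!boundary) {
      sig2 <- mse
      df2 <- (s - 1) * (cc - 1)
    } else {
      sig2 <- (ssS + sse) / (s * cc - cc)
      df2 <- s * cc - cc
    }
    Fstat <- msC / sig2
    out_i <- tibble(bin = bins[i], contrast = "omnibus", statistic = Fstat,
                    df1 = cc - 1, df2 = df2,
                    p_value = pf(Fstat, cc - 1, df2, lower.tail = FALSE),
                    fallback = FALSE)
    if (pairwise) {
      prs <- utils::combn(seq_len(cc), 2)
      se <- sqrt(2 * sig2 / s)
      pw <- lapply(seq_len(ncol(prs)), function(j) {
        a <- prs[1, j]; b <- prs[2, j]
        tval <- (mC[a] - mC[b]) / se
        tibble(bin = bins[i], contrast = paste(lev[a], lev[b], sep = "-"),
               statistic = tval, df1 = 1, df2 = df2,
               p_value = 2 * pt(abs(tval), df2, lower.tail = FALSE),
               fallback = FALSE)
      })
      out_i <- bind_rows(out_i, bind_rows(pw))
    }
    rows[[i]] <- out_i
  }
  bind_rows(rows)
}

satterthwaite_df2 <- function(m, d) {
  mt <- tryCatch(lmerTest::as_lmerModLmerTest(
    lme4::lmer(value ~ condition + (1 | subject), data = d)),
    error = function(e) NULL)
  if (is.null(mt)) return(nrow(d) - nlevels(d$condition))
  an <- tryCatch(stats::anova(mt, ddf = "Satterthwaite"),
                 error = function(e) NULL)
  if (is.null(an)) return(nrow(d) - nlevels(d$condition))
  an$DenDF[1]
}

#' Add an FDR significance flag to bin-wise test results
#'
#' Applies [fdr_bh()] across bins separately within each contrast (the FDR
#' family is the bins of one comparison).
#'
#' @param results Output of [per_bin_lmm()].
#' @param q FDR level (default 0.05).
#'
#' @return `results` with a logical `q_significant` column.
#' @export
add_fdr <- function(results, q = 0.05) {
  bind_rows(lapply(split(results, results$contrast), function(d) {
    mutate(d, q_significant = fdr_bh(.data$p_value, q = q))
  }))
}

#' Omnibus group comparison with post-hoc follow-ups
#'
#' Selects the test family by the normality gate (all groups pass
#' Shapiro-Wilk -> parametric): one-way ANOVA with Tukey HSD follow-ups, or
#' Kruskal-Wallis. Two groups reduce to the corresponding two-sample test
#' (paired or independent). Groups with n < 2 are excluded with a flag.
#'
#' @param data Long tibble with columns `value` and `group`.
#' @param paired Use a paired design (two groups only; rows matched by
#'   position within group).
#' @param alpha Normality-gate level.
#' @param family Force `"parametric"` or `"nonparametric"` instead of
#'   gating.
#'
#' @return A list with `omnibus` (tibble: method, statistic, df, p_value,
#'   family), `posthoc` (Tukey HSD tibble or `NULL`), `excluded_groups`.
#' @export
omnibus_and_posthoc <- function(data, paired = FALSE, alpha = 0.05,
                                family = NULL) {
  stopifnot(all(c("value", "group") %in% names(data)))
  data <- mutate(data, group = factor(.data$group))
  sizes <- table(data$group)
  excluded <- names(sizes)[sizes < 2]
  if (length(excluded)) {
    warn(sprintf("Excluding groups with n < 2: %s",
                 paste(excluded, collapse = ", ")))
    data <- filter(data, !(.data$group %in% excluded))
    data$group <- droplevels(data$group)
  }
  if (nlevels(data$group) < 2) abort("Need >= 2 groups with n >= 2.")
  if (is.null(family)) {
    gates <- vapply(split(data$value, data$group),
                    function(x) normality_gate(x, alpha), character(1))
    family <- if (all(gates == "parametric")) "parametric" else "nonparametric"
  }
  k <- nlevels(data$group)
  posthoc <- NULL
  if (k == 2) {
    g <- split(data$value, data$group)
    ht <- if (family == "parametric") {
      t.test(g[[1]], g[[2]], paired = paired, var.equal = !paired)
    } else if (paired) {
      wilcox.test(g[[1]], g[[2]], paired = TRUE, exact = FALSE)
    } else {
      wilcox.test(g[[1]], g[[2]], exact = FALSE)
    }
    omnibus <- tibble(method = ht$method, statistic = unname(ht$statistic),
                      df = unname(ht$parameter %||% NA_real_),
                      p_value = ht$p.value, family = family)
  } else if (family == "parametric") {
    fit <- aov(value ~ group, data = data)
    an <- summary(fit)[[1]]
    omnibus <- tibble(method = "One-way ANOVA",
                      statistic = an$`F value`[1],
                      df = an$Df[1], p_value = an$`Pr(>F)`[1],
                      family = family)
    tk <- TukeyHSD(fit, conf.level = 0.95)$group
    posthoc <- tibble(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"])
  } else {
    ht <- kruskal.test(value ~ group, data = data)
    omnibus <- tibble(method = "Kruskal-Wallis", statistic = unname(ht$statistic),
                      df = unname(ht$parameter), p_value = ht$p.value,
                      family = family)
    fit <- aov(value ~ group, data = data)
    tk <- TukeyHSD(fit, conf.level = 0.95)$group
    posthoc <- tibble(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"])
  }
  list(omnibus = omnibus, posthoc = posthoc, excluded_groups = excluded)
}

#' Categorical distribution test
#'
#' Pearson chi-squared test on a contingency table (wrapper kept so every
#' significance call in pipeline outputs traces to a named procedure).
#'
#' @param tab A table or matrix of counts.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
chisq_table <- function(tab) {
  ht <- suppressWarnings(chisq.test(tab))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Cohen's d with a normal-approximation confidence interval
#'
#' `d = (mean(a) - mean(b)) / pooled SD`; the 95% CI uses the usual
#' large-sample variance `(na + nb)/(na nb) + d^2 / (2 (na + nb))`.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param conf_level Confidence level (default 0.95).
#'
#' @return Tibble with `d`, `ci_low`, `ci_high`; `d` is `NA` (flagged) when
#'   the pooled SD is zero.
#' @export
cohen_d <- function(a, b, conf_level = 0.95) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) abort("Need n >= 2 in both samples.")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    out <- tibble(d = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    attr(out, "zero_pooled_sd") <- TRUE
    return(out)
  }
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  se <- sqrt((na + nb) / (na * nb) + d^2 / (2 * (na + nb)))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tibble(d = d, ci_low = d - zq * se, ci_high = d + zq * se)
}

#' Max-statistic permutation test with FWER control
#'
#' Permutes group labels, recomputes the per-cell statistic map each time,
#' and compares every observed cell statistic against the permutation null
#' of the map-wise maximum: `p_corr = (1 + #{max_null >= observed}) /
#' (n_perm + 1)`. Controls the family-wise error rate across the map.
#'
#' @param x Observations x cells numeric matrix (one row per observation).
#' @param labels Two-level grouping vector (length `nrow(x)`), exchangeable
#'   under the null.
#' @param n_perm Number of permutations (default 10000; < 100 warns).
#' @param seed RNG seed.
#' @param statistic Function `(x, labels) -> per-cell statistic vector`;
#'   default is the absolute two-sample t statistic per cell.
#'
#' @return Tibble with `cell`, `statistic`, `p_corrected`.
#' @export
permutation_fwer <- function(x, labels, n_perm = 10000, seed = 1,
                             statistic = NULL) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) abort("`labels` must have exactly two levels.")
  if (n_perm < 100) warn("Fewer than 100 permutations: p-values are coarse.")
  if (is.null(statistic)) statistic <- abs_t_map
  set.seed(seed)
  obs <- statistic(x, labels)
  null_max <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    null_max[i] <- max(statistic(x, sample(labels)))
  }
  p <- vapply(obs, function(s) (1 + sum(null_max >= s)) / (n_perm + 1),
              numeric(1))
  tibble(cell = seq_along(obs), statistic = obs, p_corrected = p)
}

abs_t_map <- function(x, labels) {
  g <- levels(labels)
  a <- x[labels == g[1], , drop = FALSE]
  b <- x[labels == g[2], , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  se[se == 0] <- Inf
  abs(colMeans(a) - colMeans(b)) / se
}
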