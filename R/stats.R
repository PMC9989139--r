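#' Paired t-test with degenerate-case handling
#'
#' Two-sided paired t-test. If the paired differences have zero variance the
#' result is flagged degenerate (t undefined) instead of raising or faking
#' significance — except for the exactly-equal case, which returns t = 0,
#' p = 1.
#'
#' @param a,b Numeric vectors paired by subject (equal length >= 3).
#' @param alpha Significance level (default 0.01, the behavioural threshold).
#' @return List `t`, `df`, `p`, `significant`, `degenerate`, `mean_diff`.
#' @export
paired_ttest <- function(a, b, alpha = 0.01) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = length(d) - 1, p = 1, significant = FALSE,
                  degenerate = FALSE, mean_diff = 0))
    return(list(t = NA_real_, df = length(d) - 1, p = NA_real_,
                significant = NA, degenerate = TRUE, mean_diff = mean(d)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, significant = tt$p.value < alpha,
       degenerate = FALSE, mean_diff = mean(d))
}

#' Two-way repeated-measures ANOVA (condition x time)
#'
#' Within-subject factorial ANOVA on a complete balanced long table. Effects
#' involving more than one degree of freedom are accompanied by Mauchly's
#' sphericity test; when sphericity is rejected (p < 0.05) the
#' Greenhouse-Geisser corrected p-value should be consulted (`p_gg`).
#' Implemented through the multivariate linear model route of `car::Anova`.
#'
#' @param tab Long data frame with columns `subject`, `condition`, `time`,
#'   `value`; every subject must have exactly one value per condition x time
#'   cell.
#' @return An `anova_result`: data frame `effect`, `F`, `df_num`, `df_den`,
#'   `p`, `sphericity_p`, `gg_eps`, `p_gg`.
#' @export
rm_anova_2way <- function(tab) {
  need <- c("subject", "condition", "time", "value")
  if (!all(need %in% names(tab)))
    stop("table must have columns ", paste(need, collapse = ", "))
  tab$subject <- factor(tab$subject)
  tab$condition <- factor(tab$condition)
  tab$time <- factor(tab$time, levels = unique(tab$time))
  counts <- table(tab$subject, tab$condition, tab$time)
  if (any(counts != 1)) {
    miss <- which(counts == 0, arr.ind = TRUE)
    lab <- apply(utils::head(miss, 5), 1, function(r)
      paste(dimnames(counts)[[1]][r[1]], dimnames(counts)[[2]][r[2]],
            dimnames(counts)[[3]][r[3]], sep = ":"))
    stop("unbalanced design; missing/duplicated cells e.g. [",
         paste(lab, collapse = "; "), "]")
  }
  # wide subject x cell matrix, time varying fastest within condition
  conds <- levels(tab$condition); times <- levels(tab$time)
  subjects <- levels(tab$subject)
  Y <- matrix(0, length(subjects), length(conds) * length(times))
  cellnames <- character(ncol(Y))
  k <- 0
  for (cn in conds) for (tm in times) {
    k <- k + 1
    sel <- tab$condition == cn & tab$time == tm
    Y[, k] <- tab$value[sel][match(subjects, tab$subject[sel])]
    cellnames[k] <- paste(cn, tm, sep = ".")
  }
  colnames(Y) <- cellnames
  idata <- data.frame(condition = factor(rep(conds, each = length(times)),
                                         levels = conds),
                      time = factor(rep(times, times = length(conds)),
                                    levels = times))
  fit <- stats::lm(Y ~ 1)
  av <- car::Anova(fit, idata = idata, idesign = ~ condition * time,
                   type = "III")
  # car warns when error df are too small for sphericity corrections or when
  # the HF epsilon exceeds 1; both are expected on small designs
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  effects <- c("condition", "time", "condition:time")
  res <- data.frame(effect = effects, F = NA_real_, df_num = NA_real_,
                    df_den = NA_real_, p = NA_real_,
                    sphericity_p = NA_real_, gg_eps = NA_real_,
                    p_gg = NA_real_, stringsAsFactors = FALSE)
  for (e in effects) {
    if (!e %in% rownames(ut)) next
    i <- match(e, effects)
    res$F[i] <- ut[e, "F value"]
    res$df_num[i] <- ut[e, "num Df"]
    res$df_den[i] <- ut[e, "den Df"]
    res$p[i] <- ut[e, "Pr(>F)"]
  }
  sph <- s$sphericity.tests
  if (!is.null(sph) && nrow(sph) > 0) {
    for (e in rownames(sph)) {
      i <- match(e, effects)
      if (!is.na(i)) res$sphericity_p[i] <- sph[e, "p-value"]
    }
  }
  pv <- s$pval.adjustments
  if (!is.null(pv) && nrow(pv) > 0) {
    for (e in rownames(pv)) {
      i <- match(e, effects)
      eps <- pv[e, "GG eps"]
      if (!is.na(i) && is.finite(eps) && eps > 0) {
        res$gg_eps[i] <- eps
        res$p_gg[i] <- pv[e, "Pr(>F[GG])"]
      }
    }
  }
  structure(list(table = res, wide = Y), class = "anova_result")
}

#' Post hoc paired contrasts between time windows
#'
#' Paired t-tests per contrast with Bonferroni correction across the family.
#' Schemes: `"consecutive"` tests each consecutive window pair (baseline vs
#' T1, T1 vs T2, ..., T5 vs T6); `"vs_baseline"` tests each post-stimulus
#' window against baseline.
#'
#' @param tab Long data frame `subject`, `time`, `value` (one value per
#'   subject x window; average over other factors first).
#' @param scheme `"consecutive"` or `"vs_baseline"`.
#' @param baseline Name of the baseline window (default `"baseline"`).
#' @param alpha Family-wise significance level after Bonferroni correction.
#' @return Data frame `contrast`, `t`, `p`, `p_bonf`, `significant`.
#' @export
posthoc_contrasts <- function(tab, scheme = c("consecutive", "vs_baseline"),
                              baseline = "baseline", alpha = 0.05) {
  scheme <- match.arg(scheme)
  wins <- unique(as.character(tab$time))
  pairs <- switch(scheme,
    consecutive = Map(c, wins[-length(wins)], wins[-1]),
    vs_baseline = Map(c, rep(baseline, length(wins) - 1), setdiff(wins, baseline))
  )
  rows <- lapply(pairs, function(pr) {
    xa <- tab$value[tab$time == pr[2]][order(tab$subject[tab$time == pr[2]])]
    xb <- tab$value[tab$time == pr[1]][order(tab$subject[tab$time == pr[1]])]
    tt <- paired_ttest(xa, xb, alpha = alpha)
    data.frame(contrast = paste(pr[2], "vs", pr[1]), t = tt$t, p = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(1, out$p * nrow(out))
  out$significant <- !is.na(out$p_bonf) & out$p_bonf < alpha
  rownames(out) <- NULL
  out
}

#' Pearson correlation with Bonferroni correction
#'
#' @param x,y Paired numeric vectors (length >= 4).
#' @param family Number of tests in the correction family (default 1).
#' @param alpha Significance level applied to the adjusted p.
#' @return List `r`, `p_raw`, `p_adj`, `significant`, `degenerate`.
#' @export
correlate_bonferroni <- function(x, y, family = 1, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                significant = NA, degenerate = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  p_adj <- min(1, ct$p.value * family)
  list(r = unname(ct$estimate), p_raw = ct$p.value, p_adj = p_adj,
       significant = p_adj < alpha, degenerate = FALSE)
}

#' Shapiro-Wilk normality check (reported, non-gating)
#' @param x Numeric vector.
#' @return List `W`, `p`.
#' @export
normality_check <- function(x) {
  s <- stats::shapiro.test(x)
  list(W = unname(s$statistic), p = s$p.value)
}
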