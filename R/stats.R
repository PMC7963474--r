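#' Assumption-gated two-sample comparison
#'
#' Runs Shapiro-Wilk on each sample and Levene's test (group means as
#' centers) across the two; if every gating p-value exceeds `alpha`, the
#' comparison is an unpaired two-sided Student t-test, otherwise a
#' two-sided Mann-Whitney U (Wilcoxon rank-sum) test. A zero-variance
#' sample leaves Shapiro undefined; the comparison then falls back to
#' Mann-Whitney with a warning.
#'
#' @param x,y numeric samples, each n >= 3.
#' @param alpha gating level, default 0.05.
#' @return an object of class `two_sample_result`: `test_used`
#'   (`"t_test"` or `"mann_whitney"`), `statistic`, `p_value`, `n1`, `n2`,
#'   `shapiro_p` (length 2), `levene_p`, `alpha`, `stars`.
#' @export
choose_and_run_test <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3)
    stop("each sample needs n >= 3")
  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  shapiro_p <- c(NA_real_, NA_real_)
  levene_p <- NA_real_
  if (degenerate) {
    warning("zero-variance sample: Shapiro undefined, using Mann-Whitney")
    gate_ok <- FALSE
  } else {
    shapiro_p <- c(stats::shapiro.test(x)$p.value,
                   stats::shapiro.test(y)$p.value)
    lev <- car::leveneTest(c(x, y),
                           factor(rep(c("a", "b"), c(length(x), length(y)))),
                           center = mean)
    levene_p <- lev[["Pr(>F)"]][1]
    gate_ok <- all(c(shapiro_p, levene_p) > alpha)
  }
  if (gate_ok) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    res <- list(test_used = "t_test", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    res <- list(test_used = "mann_whitney",
                statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  structure(
    c(res, list(n1 = length(x), n2 = length(y), shapiro_p = shapiro_p,
                levene_p = levene_p, alpha = alpha,
                stars = signif_stars(res$p_value))),
    class = "two_sample_result")
}

#' @export
print.two_sample_result <- function(x, ...) {
  cat(sprintf(
    "%s: statistic = %.4g, p = %.4g %s (n1 = %d, n2 = %d)\n",
    x$test_used, x$statistic, x$p_value, x$stars, x$n1, x$n2))
  cat(sprintf("  gating: Shapiro p = %.3g / %.3g, Levene p = %.3g (alpha = %g)\n",
              x$shapiro_p[1], x$shapiro_p[2], x$levene_p, x$alpha))
  invisible(x)
}

#' Two-way ANOVA on a window of aligned profiles
#'
#' Restricts each per-synapse aligned profile to positions within
#' `window_nm / 2` of the scaffold peak (position 0) and fits a two-way
#' ANOVA of intensity on genotype and position (both categorical),
#' including their interaction. The genotype main effect is the headline
#' value. Degenerate inputs (zero residual variance) are reported as
#' F = 0, p = 1 when the effect sum of squares is also zero, and as an
#' infinite F with p = 0 plus a warning otherwise.
#'
#' @param data data frame with columns `synapse`, `genotype`,
#'   `position_nm`, `intensity`: one aligned intensity per synapse and
#'   position.
#' @param window_nm full window width centered on position 0, default
#'   200 nm.
#' @return an object of class `profile_anova_result`: `table` (term, df,
#'   sumsq, meansq, F, p, stars), `window_nm`, `genotype_p`,
#'   `n_positions`, `n_synapses`.
#' @export
profile_anova <- function(data, window_nm = 200) {
  stopifnot(all(c("synapse", "genotype", "position_nm", "intensity") %in%
                  names(data)), window_nm > 0)
  d <- data[abs(data$position_nm) <= window_nm / 2 + 1e-9, ]
  if (nrow(d) == 0) stop("no positions inside the window")
  d$genotype <- factor(d$genotype)
  d$position <- factor(d$position_nm)
  if (nlevels(d$genotype) < 2) stop("need >= 2 genotypes")
  if (min(table(d$genotype)) / nlevels(d$position) < 2)
    stop("need >= 2 synapses per genotype")
  fit <- stats::aov(intensity ~ genotype * position, data = d)
  a <- summary(fit)[[1]]
  terms <- trimws(rownames(a))
  tab <- data.frame(term = terms, df = a$Df, sumsq = a$`Sum Sq`,
                    meansq = a$`Mean Sq`, F = a$`F value`, p = a$`Pr(>F)`)
  resid_ms <- tab$meansq[tab$term == "Residuals"]
  total_ms <- sum(tab$sumsq) / sum(tab$df)
  if (is.finite(resid_ms) && total_ms > 0 && resid_ms < 1e-12 * total_ms) {
    eff <- tab$term != "Residuals"
    zero_eff <- eff & tab$sumsq < 1e-12 * sum(tab$sumsq)
    tab$F[zero_eff] <- 0; tab$p[zero_eff] <- 1
    inf_eff <- eff & !zero_eff
    if (any(inf_eff)) {
      warning("degenerate data: zero residual variance with non-zero effect")
      tab$F[inf_eff] <- Inf; tab$p[inf_eff] <- 0
    }
  } else if (total_ms == 0) {
    ## identical intensities everywhere: no variance at all
    eff <- tab$term != "Residuals"
    tab$F[eff] <- 0; tab$p[eff] <- 1
  }
  tab$stars <- ifelse(tab$term == "Residuals", "",
                      signif_stars(tab$p))
  structure(
    list(table = tab, window_nm = window_nm,
         genotype_p = tab$p[tab$term == "genotype"],
         n_positions = nlevels(d$position),
         n_synapses = length(unique(paste(d$genotype, d$synapse)))),
    class = "profile_anova_result")
}

#' @export
print.profile_anova_result <- function(x, ...) {
  cat(sprintf(
    "profile_anova_result (window %g nm, %d positions, %d synapses)\n",
    x$window_nm, x$n_positions, x$n_synapses))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("headline genotype effect: p = %.4g %s\n", x$genotype_p,
              signif_stars(x$genotype_p)))
  invisible(x)
}

#' Mean, SEM and n summary
#'
#' @param x numeric vector (NAs dropped).
#' @return data frame with `mean`, `sem` (sample SD / sqrt(n); `NA` for
#'   n < 2), `sd`, `n`.
#' @export
summarize_mean_sem <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  data.frame(mean = if (n > 0) mean(x) else NA_real_,
             sem = sem(x),
             sd = if (n >= 2) stats::sd(x) else NA_real_,
             n = n)
}
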