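#' Repeated-measures ANOVA with a between-unit factor
#'
#' Classical split-plot decomposition: one within-unit factor measured
#' repeatedly on each experimental unit and one optional between-unit factor.
#' Units with missing cells are dropped listwise (the count is reported).
#' Sphericity is assessed with Mauchly's test and the Greenhouse-Geisser
#' corrected p-value is reported alongside the uncorrected one; `p` in the
#' result uses the GG correction whenever Mauchly's test rejects at 0.05.
#'
#' Computation is delegated to a multivariate linear model with
#' [car::Anova()] (type III); the repeated-measures sums of squares it
#' produces agree with the hand decomposition (checked in the test suite).
#'
#' @param data data.frame in long format.
#' @param dv name of the response column.
#' @param within name of the repeated (within-unit) factor column.
#' @param between name of the between-unit factor column, or `NULL` for a
#'   one-way repeated-measures design.
#' @param unit name of the experimental-unit (subject) column.
#'
#' @return an `anova_result`: data.frame with one row per effect (between,
#'   within, interaction): `F`, `df1`, `df2`, `p_uncorrected`, `gg_eps`,
#'   `p_gg`, `mauchly_p`, `p`; attribute `n_units_dropped`.
#' @export
rm_anova <- function(data, dv = "value", within = "session", between = NULL,
                     unit = "subject") {
  stopifnot(all(c(dv, within, unit, between) %in% names(data)))
  data[[within]] <- factor(data[[within]])
  data[[unit]] <- factor(data[[unit]])
  lv <- levels(data[[within]])
  wide <- stats::reshape(
    data[, c(unit, within, between, dv)],
    idvar = c(unit, between), timevar = within, direction = "wide")
  resp_cols <- paste(dv, lv, sep = ".")
  complete <- stats::complete.cases(wide[, resp_cols])
  n_dropped <- sum(!complete)
  if (n_dropped > 0L)
    message(sprintf("rm_anova(): dropped %d unit(s) with missing cells", n_dropped))
  wide <- wide[complete, ]
  if (!is.null(between)) {
    wide[[between]] <- factor(wide[[between]])
    counts <- table(wide[[between]])
    if (any(counts < 2L))
      stop("fewer than 2 units in between-group(s): ",
           paste(names(counts)[counts < 2L], collapse = ", "))
  }
  Y <- as.matrix(wide[, resp_cols])
  rhs <- if (is.null(between)) "1" else between
  old_contr <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old_contr), add = TRUE)
  mod <- stats::lm(stats::as.formula(paste("Y ~", rhs)), data = wide)
  idata <- data.frame(W = factor(lv, levels = lv))
  names(idata) <- within
  aov_res <- car::Anova(mod, idata = idata,
                        idesign = stats::as.formula(paste("~", within)),
                        type = 3)
  s <- suppressWarnings(summary(aov_res, multivariate = FALSE))
  ut <- s$univariate.tests
  effects <- setdiff(rownames(ut), "(Intercept)")
  res <- data.frame(effect = effects,
                    F = ut[effects, "F value"],
                    df1 = ut[effects, "num Df"],
                    df2 = ut[effects, "den Df"],
                    p_uncorrected = ut[effects, "Pr(>F)"],
                    gg_eps = NA_real_, p_gg = NA_real_, mauchly_p = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  pa <- s$pval.adjustments
  sp <- s$sphericity.tests
  if (!is.null(pa) && nrow(pa) > 0) {
    for (e in rownames(pa)) {
      i <- match(e, res$effect)
      res$gg_eps[i] <- pa[e, "GG eps"]
      res$p_gg[i] <- pa[e, "Pr(>F[GG])"]
    }
  }
  if (!is.null(sp) && nrow(sp) > 0) {
    for (e in rownames(sp)) {
      i <- match(e, res$effect)
      res$mauchly_p[i] <- sp[e, "p-value"]
    }
  }
  res$p <- ifelse(!is.na(res$mauchly_p) & res$mauchly_p < 0.05 & !is.na(res$p_gg),
                  res$p_gg, res$p_uncorrected)
  attr(res, "n_units_dropped") <- n_dropped
  class(res) <- c("anova_result", "data.frame")
  res
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Repeated-measures ANOVA\n")
  df <- as.data.frame(x)
  df$F <- signif(df$F, 4); df$p <- signif(df$p, 3)
  df$p_uncorrected <- signif(df$p_uncorrected, 3)
  print(df[, c("effect", "F", "df1", "df2", "p_uncorrected", "p")],
        row.names = FALSE)
  if (any(!is.na(x$mauchly_p) & x$mauchly_p < 0.05))
    cat("(Greenhouse-Geisser correction applied where Mauchly's test rejected)\n")
  invisible(x)
}

#' Holm-corrected paired post-hoc comparisons
#'
#' Pairwise comparisons between levels of a repeated factor: a paired t-test
#' per pair, replaced by the Wilcoxon signed-rank test when a Shapiro-Wilk
#' check on the paired differences rejects normality at `normality_alpha`.
#' p-values are Holm-Bonferroni adjusted across the comparison family.
#'
#' @param data long data.frame with one observation per unit and level.
#' @param dv,within,unit column names as in [rm_anova()].
#' @param comparisons list of length-2 level vectors; default all level pairs.
#' @param normality_alpha Shapiro-Wilk gate (default 0.05).
#'
#' @return a data.frame: level_a, level_b, n, mean_diff (a - b), test,
#'   statistic, p_raw, p_holm.
#' @export
posthoc <- function(data, dv = "value", within = "session", unit = "subject",
                    comparisons = NULL, normality_alpha = 0.05) {
  data[[within]] <- as.character(data[[within]])
  lv <- unique(data[[within]])
  if (is.null(comparisons)) {
    cb <- utils::combn(lv, 2L)
    comparisons <- lapply(seq_len(ncol(cb)), function(i) cb[, i])
  }
  rows <- lapply(comparisons, function(cmp) {
    a <- data[data[[within]] == cmp[1L], c(unit, dv)]
    b <- data[data[[within]] == cmp[2L], c(unit, dv)]
    m <- merge(a, b, by = unit, suffixes = c("_a", "_b"))
    m <- m[stats::complete.cases(m), ]
    if (nrow(m) < 3L)
      stop("fewer than 3 paired observations for ", cmp[1L], " vs ", cmp[2L])
    d <- m[[paste0(dv, "_a")]] - m[[paste0(dv, "_b")]]
    if (stats::sd(d) == 0) {
      # degenerate: all paired differences equal; no evidence either way
      return(data.frame(level_a = cmp[1L], level_b = cmp[2L], n = length(d),
                        mean_diff = mean(d), test = "paired t",
                        statistic = if (mean(d) == 0) 0 else Inf,
                        p_raw = if (mean(d) == 0) 1 else 0,
                        stringsAsFactors = FALSE))
    }
    normal <- stats::shapiro.test(d)$p.value >= normality_alpha
    if (normal) {
      tt <- stats::t.test(d)
      data.frame(level_a = cmp[1L], level_b = cmp[2L], n = length(d),
                 mean_diff = mean(d), test = "paired t",
                 statistic = unname(tt$statistic), p_raw = tt$p.value,
                 stringsAsFactors = FALSE)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(d))
      data.frame(level_a = cmp[1L], level_b = cmp[2L], n = length(d),
                 mean_diff = mean(d), test = "wilcoxon",
                 statistic = unname(wt$statistic), p_raw = wt$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_raw, method = "holm")
  out
}

#' Bootstrap-corrected rank correlation
#'
#' Spearman correlation between a per-subject connectivity measure and a
#' per-subject skill metric, with a percentile bootstrap confidence interval
#' over paired resamples (default n = 50,000) and a permutation p-value from
#' the same number of label permutations. Pearson is available via `method`.
#'
#' @param x,y paired numeric vectors (>= 5 pairs, neither constant).
#' @param n_boot number of bootstrap resamples and permutations.
#' @param conf confidence level of the percentile interval.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param seed RNG seed (recorded in the result).
#'
#' @return a `correlation_result`: list with `rho`, `p` (two-sided
#'   permutation), `ci` (percentile bounds), `conf`, `n`, `n_boot`,
#'   `method`, `seed`.
#' @export
bootstrap_correlation <- function(x, y, n_boot = 50000, conf = 0.95,
                                  method = c("spearman", "pearson"), seed = 1) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5L) stop("need at least 5 paired subjects")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rho <- stats::cor(x, y, method = method)
  d <- cbind(x, y)
  bt <- boot::boot(d, function(dd, i) {
    xi <- dd[i, 1L]; yi <- dd[i, 2L]
    if (stats::sd(xi) == 0 || stats::sd(yi) == 0) return(NA_real_)
    stats::cor(xi, yi, method = method)
  }, R = n_boot)
  tvals <- bt$t[is.finite(bt$t)]
  ci <- if (length(tvals) == 0L || diff(range(tvals)) < 1e-12) {
    c(rho, rho)
  } else {
    bc <- boot::boot.ci(bt, conf = conf, type = "perc")
    bc$percent[1L, 4:5]
  }
  # permutation null for the p-value
  n <- length(x)
  sx <- if (method == "spearman") as.numeric(scale(rank(x))) else as.numeric(scale(x))
  sy <- if (method == "spearman") as.numeric(scale(rank(y))) else as.numeric(scale(y))
  perm <- vapply(seq_len(n_boot),
                 function(i) sum(sx * sy[sample.int(n)]) / (n - 1), 0)
  rho_c <- sum(sx * sy) / (n - 1)
  p <- (1 + sum(abs(perm) >= abs(rho_c) - 1e-12)) / (n_boot + 1)
  structure(list(rho = rho, p = p, ci = unname(ci), conf = conf, n = n,
                 n_boot = n_boot, method = method, seed = seed),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s rho = %.3f (n = %d), permutation p = %.4g\n",
              x$method, x$rho, x$n, x$p))
  cat(sprintf("%.0f%% percentile bootstrap CI [%.3f, %.3f] (%d resamples, seed %d)\n",
              100 * x$conf, x$ci[1L], x$ci[2L], x$n_boot, x$seed))
  invisible(x)
}
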