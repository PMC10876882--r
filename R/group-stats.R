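#' Mixed-model ANOVA on fractional power change
#'
#' Gaussian linear mixed model with fixed effects for age group, tissue type,
#' denoising method, and the age x method interaction, plus a subject-level
#' random intercept; one frequency band at a time.  F statistics use the
#' inner-outer (containment) denominator degrees of freedom of
#' \code{nlme::lme} by default; `ddf = "satterthwaite"` switches to a
#' lmerTest fit.
#'
#' @param table long-format data frame with columns `subject`, `group`,
#'   `source` (tissue), `method`, `band`, and the response column `value`
#'   (use [power_change_table()] to shape a [band_power_table()] output).
#' @param band which band to analyze (the design requires one at a time).
#' @param ddf `"containment"` (default) or `"satterthwaite"`.
#' @return an `anova_result` data frame: one row per factor with `F`,
#'   `num_df`, `den_df`, `p`.
#' @export
power_anova <- function(table, band, ddf = c("containment", "satterthwaite")) {
  ddf <- match.arg(ddf)
  d <- table[table$band == band, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for band ", band)
  d <- data.frame(subject = factor(d$subject), age = factor(d$group),
                  tissue = factor(d$source), method = factor(d$method),
                  value = d$value)
  check_balanced(d, c("tissue", "method"))
  fit_lmm_anova(value ~ age + tissue + method + age:method, d, ddf)
}

#' Mixed ANOVA on a connectivity metric
#'
#' Age group as the between-subject factor, denoising method as the
#' within-subject factor, plus their interaction; subject random intercept.
#'
#' @param table long-format data frame with columns `subject`, `group`,
#'   `method`, and `value` (one row per subject x method).
#' @inheritParams power_anova
#' @return an `anova_result` data frame.
#' @export
mixed_anova_metric <- function(table, ddf = c("containment", "satterthwaite")) {
  ddf <- match.arg(ddf)
  d <- data.frame(subject = factor(table$subject), age = factor(table$group),
                  method = factor(table$method), value = table$value)
  check_balanced(d, "method")
  fit_lmm_anova(value ~ age + method + age:method, d, ddf)
}

check_balanced <- function(d, within) {
  cells <- do.call(table, c(list(d$subject), lapply(within, function(w) d[[w]])))
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    stop(sprintf("unbalanced design: %d empty subject-level cell(s), e.g. %s",
                 sum(cells == 0),
                 paste(dimnames(cells)[[1]][bad[1, 1]], collapse = " / ")))
  }
  invisible(TRUE)
}

fit_lmm_anova <- function(formula, d, ddf) {
  if (!anyDuplicated(d$subject)) {
    # one observation per subject: the random intercept is confounded with
    # the residual and the model reduces to fixed-effects ANOVA
    fit <- stats::lm(formula, data = d)
    a <- stats::anova(fit)
    a <- a[rownames(a) != "Residuals", , drop = FALSE]
    res <- data.frame(factor = rownames(a), F = a$`F value`,
                      num_df = a$Df, den_df = stats::df.residual(fit),
                      p = a$`Pr(>F)`)
    rownames(res) <- NULL
    class(res) <- c("anova_result", class(res))
    return(res)
  }
  if (ddf == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE))
      stop("ddf = 'satterthwaite' requires the lmerTest package")
    f2 <- stats::update(formula, . ~ . + (1 | subject))
    fit <- lmerTest::lmer(f2, data = d, REML = TRUE)
    a <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
    res <- data.frame(factor = rownames(a), F = a$`F value`,
                      num_df = a$NumDF, den_df = a$DenDF,
                      p = a$`Pr(>F)`)
  } else {
    fit <- nlme::lme(formula, random = ~ 1 | subject, data = d,
                     method = "REML")
    # sequential table: for the balanced designs used here this is the
    # classical mixed-ANOVA decomposition (marginal + treatment contrasts
    # would test simple effects at the reference level instead)
    a <- stats::anova(fit)
    a <- a[rownames(a) != "(Intercept)", , drop = FALSE]
    res <- data.frame(factor = rownames(a), F = a$`F-value`,
                      num_df = a$numDF, den_df = a$denDF,
                      p = a$`p-value`)
  }
  rownames(res) <- NULL
  class(res) <- c("anova_result", class(res))
  res
}

#' Shape a band-power table for [power_anova()]
#'
#' Restricts a [band_power_table()] to the denoising methods (dropping the
#' `none` rows, whose fractional change is identically zero) and renames the
#' response.
#'
#' @param bp output of [band_power_table()].
#' @param sources which sources to keep (default the two tissues).
#' @return long-format data frame with a `value` column.
#' @export
power_change_table <- function(bp, sources = c("GM", "WM")) {
  d <- bp[bp$method != "none" & bp$source %in% sources, , drop = FALSE]
  d$value <- d$fractional_change
  d
}

#' Pairwise follow-up t-tests with Benjamini-Hochberg correction
#'
#' For `family = "method"`: paired t-tests between every pair of denoising
#' methods (pairing on subject).  For `family = "age"`: unpaired t-tests
#' between the age groups, one per method.  Raw p values are BH-adjusted
#' within the family; each comparison carries a direction mark (`">"` if the
#' first level's mean exceeds the second's).
#'
#' @param table long-format data frame with `subject`, `group`, `method`,
#'   `value`.
#' @param family `"method"` or `"age"`.
#' @return data frame with columns `level_1`, `level_2`, `t`, `p`,
#'   `p_adjusted`, `direction`.
#' @export
followup_tests <- function(table, family = c("method", "age")) {
  family <- match.arg(family)
  out <- list()
  if (family == "method") {
    methods <- unique(as.character(table$method))
    if (length(methods) < 2) stop("need at least two methods")
    for (i in seq_along(methods)) for (j in seq_len(i - 1L)) {
      a <- methods[j]; b <- methods[i]
      xa <- table$value[table$method == a][order(table$subject[table$method == a])]
      xb <- table$value[table$method == b][order(table$subject[table$method == b])]
      dd <- xa - xb
      if (stats::sd(dd) < .Machine$double.eps) {
        out[[length(out) + 1L]] <- data.frame(
          level_1 = a, level_2 = b, t = NA_real_, p = NA_real_,
          direction = "=", flag = "degenerate: zero within-pair variance")
        next
      }
      tt <- stats::t.test(xa, xb, paired = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        level_1 = a, level_2 = b, t = unname(tt$statistic), p = tt$p.value,
        direction = if (mean(dd) > 0) ">" else "<", flag = "")
    }
  } else {
    groups <- unique(as.character(table$group))
    if (length(groups) < 2) stop("need two age groups")
    for (m in unique(as.character(table$method))) {
      d <- table[table$method == m, ]
      xa <- d$value[d$group == groups[1]]
      xb <- d$value[d$group == groups[2]]
      tt <- stats::t.test(xa, xb, var.equal = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        level_1 = paste(m, groups[1], sep = ":"),
        level_2 = paste(m, groups[2], sep = ":"),
        t = unname(tt$statistic), p = tt$p.value,
        direction = if (mean(xa) > mean(xb)) ">" else "<", flag = "")
    }
  }
  res <- do.call(rbind, out)
  res$p_adjusted <- stats::p.adjust(res$p, method = "BH")
  res[, c("level_1", "level_2", "t", "p", "p_adjusted", "direction", "flag")]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, exposed so the
#' correction used across the package is a single named operation.
#'
#' @param p numeric vector of raw p values.
#' @return adjusted p values (monotone in the input order of significance).
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
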