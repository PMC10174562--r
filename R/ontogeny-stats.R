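#' One-way linear model for a metric across categorical age groups
#'
#' Fixed-effects cell-means model: the metric is regressed on age as a
#' factor. Returns the overall F test (`F = MS_between / MS_within` on
#' `(k - 1, n - k)` degrees of freedom), its p-value, and
#' `r2 = SS_between / SS_total`. With a covariate (typically body mass)
#' the model becomes an ANCOVA with a common slope: the group F is the
#' sequential test of the factor after the covariate on
#' `(k - 1, n - k - 1)` degrees of freedom, `r_squared` is the group sum
#' of squares over the total, and `group_means` are the covariate-adjusted
#' means evaluated at the grand covariate mean.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (coerced to factor), same length.
#' @param covariate Optional numeric covariate of the same length.
#' @return A list with `f_statistic`, `df` (between, within), `p_value`,
#'   `r_squared`, `n`, `k`, `group_means` (adjusted when a covariate is
#'   present), `ms_within` and the underlying `lm` fit.
#' @export
fit_group_lm <- function(values, groups, covariate = NULL) {
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values) & !is.na(groups)
  if (!is.null(covariate)) {
    stopifnot(length(covariate) == length(values))
    ok <- ok & is.finite(covariate)
    covariate <- covariate[ok]
  }
  values <- values[ok]
  g <- factor(groups[ok])
  sizes <- table(g)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  small <- names(sizes)[sizes < 2]
  if (length(small))
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  if (is.null(covariate)) {
    fit <- stats::lm(values ~ g)
    an <- stats::anova(fit)
    grow <- 1L
    means <- tapply(values, g, mean)
  } else {
    fit <- stats::lm(values ~ covariate + g)
    an <- stats::anova(fit)
    grow <- 2L
    nd <- data.frame(covariate = mean(covariate), g = levels(g))
    means <- stats::setNames(stats::predict(fit, nd), levels(g))
  }
  nres <- nrow(an)
  list(f_statistic = an$`F value`[grow],
       df = c(between = an$Df[grow], within = an$Df[nres]),
       p_value = an$`Pr(>F)`[grow],
       r_squared = an$`Sum Sq`[grow] / sum(an$`Sum Sq`),
       n = length(values), k = nlevels(g),
       group_means = means,
       ms_within = an$`Mean Sq`[nres],
       fit = fit)
}

#' Pairwise group contrasts with multiplicity adjustment
#'
#' All pairwise differences of group means, tested against the pooled
#' within-group variance on `n - k` degrees of freedom. With
#' `method = "tukey"` (default) each comparison's p-value comes from the
#' studentized range distribution (Tukey's HSD); with `method = "holm"`
#' two-sided pooled-t p-values are Holm-adjusted.
#'
#' With a covariate the contrasts are differences of covariate-adjusted
#' means (estimated-marginal-means style), with standard errors from the
#' model's coefficient covariance matrix.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (coerced to factor).
#' @param method Adjustment method, `"tukey"` or `"holm"`.
#' @param covariate Optional numeric covariate (see [fit_group_lm()]).
#' @return A data frame with one row per pair: `group_i`, `group_j`,
#'   `estimate` (mean_j - mean_i), `se`, `statistic`, `adjusted_p`.
#' @export
pairwise_contrasts <- function(values, groups, method = c("tukey", "holm"),
                               covariate = NULL) {
  method <- match.arg(method, c("tukey", "holm"))
  lmres <- fit_group_lm(values, groups, covariate)
  keep <- is.finite(values) & !is.na(groups)
  if (!is.null(covariate)) keep <- keep & is.finite(covariate)
  g <- factor(groups[keep])
  means <- lmres$group_means
  sizes <- table(g)
  lev <- levels(g)
  k <- length(lev)
  dfw <- unname(lmres$df["within"])
  mse <- lmres$ms_within
  pairs <- utils::combn(lev, 2)
  est <- se <- stat <- numeric(ncol(pairs))
  vc <- stats::vcov(lmres$fit)
  cf_names <- colnames(vc)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    est[p] <- means[[j]] - means[[i]]
    if (is.null(covariate)) {
      se[p] <- sqrt(mse * (1 / sizes[[i]] + 1 / sizes[[j]]))
    } else {
      # contrast of the two group dummies (treatment coding, common slope)
      L <- stats::setNames(numeric(length(cf_names)), cf_names)
      ni <- paste0("g", i); nj <- paste0("g", j)
      if (nj %in% cf_names) L[nj] <- 1
      if (ni %in% cf_names) L[ni] <- -1
      se[p] <- sqrt(drop(t(L) %*% vc %*% L))
    }
    stat[p] <- est[p] / se[p]
  }
  if (method == "tukey") {
    # studentized range statistic q = |diff| / (se / sqrt(2))
    adj <- stats::ptukey(abs(stat) * sqrt(2), nmeans = k, df = dfw,
                         lower.tail = FALSE)
  } else {
    adj <- stats::p.adjust(2 * stats::pt(abs(stat), dfw,
                                         lower.tail = FALSE),
                           method = "holm")
  }
  data.frame(group_i = pairs[1, ], group_j = pairs[2, ], estimate = est,
             se = se, statistic = stat, adjusted_p = pmin(adj, 1),
             stringsAsFactors = FALSE)
}

#' Compact letter display from pairwise comparisons
#'
#' Insert-and-absorb letter assignment: two groups share at least one
#' letter if and only if their adjusted pairwise p-value is at or above
#' `alpha`. Non-transitive significance patterns (A differs from C while
#' both equal B) yield multi-letter labels such as `a / ab / b`, never an
#' error.
#'
#' @param pairwise Data frame as returned by [pairwise_contrasts()]
#'   (columns `group_i`, `group_j`, `adjusted_p`).
#' @param alpha Significance level (default 0.05).
#' @param letters_pool Symbols to assign, in order (defaults to
#'   `letters`).
#' @return Named character vector mapping each group to its letter string.
#' @examples
#' pw <- data.frame(group_i = c("4", "4", "6"), group_j = c("6", "9", "9"),
#'                  adjusted_p = c(0.001, 0.001, 0.001))
#' compact_letter_display(pw)  # a, b, c
#' @export
compact_letter_display <- function(pairwise, alpha = 0.05,
                                   letters_pool = letters) {
  groups <- unique(c(pairwise$group_i, pairwise$group_j))
  ng <- length(groups)
  # columns are letters, entries logical membership
  cols <- list(rep(TRUE, ng))
  sig <- pairwise$adjusted_p < alpha
  for (p in which(sig)) {
    gi <- match(pairwise$group_i[p], groups)
    gj <- match(pairwise$group_j[p], groups)
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[gi] && col[gj]) {
        # duplicate the column, drop gi from one copy and gj from the other
        c1 <- col; c1[gi] <- FALSE
        c2 <- col; c2[gj] <- FALSE
        cols[[ci]] <- c1
        cols[[length(cols) + 1L]] <- c2
      }
    }
    # absorb: drop any column whose membership is a subset of another's
    drop <- rep(FALSE, length(cols))
    for (a in seq_along(cols)) {
      for (b in seq_along(cols)) {
        if (a != b && !drop[a] && !drop[b] &&
            all(cols[[a]] | !cols[[b]]) ) {
          # b subset of a
          if (all(cols[[b]] | !cols[[a]])) {
            # identical: drop the later one
            if (b > a) drop[b] <- TRUE
          } else {
            drop[b] <- TRUE
          }
        }
      }
    }
    cols <- cols[!drop]
  }
  # label columns in order of their first member so the first group reads 'a'
  cols <- cols[order(vapply(cols, function(cc) which(cc)[1], integer(1)))]
  if (length(cols) > length(letters_pool))
    letters_pool <- c(letters_pool,
                      as.vector(outer(letters_pool, letters_pool,
                                      paste0)))
  lab <- vapply(seq_len(ng), function(i) {
    paste0(letters_pool[which(vapply(cols, `[`, logical(1), i))],
           collapse = "")
  }, character(1))
  stats::setNames(lab, groups)
}

#' Select the best model by AIC
#'
#' `AIC = 2k - 2 lnL`; the candidate with the lowest AIC wins, with ties
#' broken toward the model with fewer estimated parameters.
#'
#' @param fits Named list of fitted model objects supporting
#'   [stats::logLik()] (e.g. `lm`, `nls`).
#' @return A list with `best` (name of the winning candidate), `aic`
#'   (named vector) and `df` (named parameter counts).
#' @export
aic_select <- function(fits) {
  if (!length(fits)) stop("no candidate models supplied")
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- paste0("model", seq_along(fits))
  ll <- lapply(fits, stats::logLik)
  k <- vapply(ll, function(x) attr(x, "df"), numeric(1))
  aic <- 2 * k - 2 * vapply(ll, as.numeric, numeric(1))
  ord <- order(aic, k)
  list(best = names(fits)[ord[1]],
       aic = stats::setNames(aic, names(fits)),
       df = stats::setNames(k, names(fits)))
}

#' Compare a physiological metric across age groups
#'
#' One-stop categorical-age comparison: one-way linear model, pairwise
#' contrasts, and a compact letter display, plus a simple residual
#' normality check (Shapiro-Wilk).
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector.
#' @param alpha Significance level for the letter display (default 0.05).
#' @param method Pairwise adjustment method (see [pairwise_contrasts()]).
#' @param covariate Optional numeric covariate (ANCOVA; see
#'   [fit_group_lm()]).
#' @return A `group_comparison` list: `anova` (from [fit_group_lm()]),
#'   `pairwise`, `letters`, `alpha`, `residual_normality_p`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05,
                           method = c("tukey", "holm"),
                           covariate = NULL) {
  method <- match.arg(method)
  an <- fit_group_lm(values, groups, covariate)
  pw <- pairwise_contrasts(values, groups, method, covariate)
  letters_map <- compact_letter_display(pw, alpha)
  res <- stats::residuals(an$fit)
  shap <- if (length(res) >= 3 && length(res) <= 5000 &&
              stats::sd(res) > 0)
    stats::shapiro.test(res)$p.value else NA_real_
  structure(list(anova = an, pairwise = pw, letters = letters_map,
                 alpha = alpha, residual_normality_p = shap),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  a <- x$anova
  cat(sprintf("One-way LM: F(%d,%d) = %.2f, p = %.3g, r2 = %.2f\n",
              a$df[1], a$df[2], a$f_statistic, a$p_value, a$r_squared))
  cat("Letters:",
      paste(names(x$letters), x$letters, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
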