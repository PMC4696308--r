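#' Pairwise variance-ratio tests across locus categories
#'
#' Compares the spread of per-locus variance percentages (or any per-locus
#' quantity) between locus categories with two-sample variance-ratio
#' F-tests: `F = s1^2 / s2^2` with the larger variance in the numerator,
#' degrees of freedom `(n1 - 1, n2 - 1)` and a two-tailed p-value, adjusted
#' across category pairs by Benjamini-Hochberg. Letter groupings (categories
#' sharing a letter are not significantly different at `alpha`) are derived
#' from the adjusted p-values.
#'
#' @param values Numeric vector of the per-locus quantity.
#' @param category Character/factor vector of the same length: the locus
#'   category of each value.
#' @param alpha Significance level for the letter grouping.
#' @return List of class `variance_test`: `pairs` (one row per category
#'   pair: F, df1, df2, p_value, p_adj), `letters` (named character vector),
#'   and `anova_p` (one-way ANOVA p-value across categories, as a companion
#'   mean-difference test).
#' @export
category_variance_test <- function(values, category, alpha = 0.05) {
  category <- as.character(category)
  keep <- !is.na(values) & !is.na(category)
  values <- values[keep]; category <- category[keep]
  cats <- unique(category)
  if (any(table(category) < 2L))
    stop("need at least two loci per category")
  vars <- tapply(values, category, var)
  ns <- tapply(values, category, length)
  prs <- combn(cats, 2)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    c1 <- prs[1, i]; c2 <- prs[2, i]
    v1 <- vars[[c1]]; v2 <- vars[[c2]]
    if (v1 == 0 && v2 == 0)
      return(data.frame(category1 = c1, category2 = c2, F = NA_real_,
                        df1 = NA_integer_, df2 = NA_integer_,
                        p_value = NA_real_, undefined = TRUE,
                        stringsAsFactors = FALSE))
    # larger variance over smaller, so F >= 1 and the order of the two
    # samples does not matter
    if (v1 >= v2) { num <- c1; den <- c2 } else { num <- c2; den <- c1 }
    f <- vars[[num]] / vars[[den]]
    df1 <- ns[[num]] - 1L; df2 <- ns[[den]] - 1L
    p <- min(1, 2 * pf(f, df1, df2, lower.tail = FALSE))
    data.frame(category1 = c1, category2 = c2, F = f, df1 = df1,
               df2 = df2, p_value = p, undefined = FALSE,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  pairs$p_adj <- p.adjust(pairs$p_value, method = "BH")
  anova_p <- if (length(cats) > 1L)
    summary(aov(values ~ factor(category)))[[1]][["Pr(>F)"]][1]
  else NA_real_
  structure(list(pairs = pairs,
                 letters = .letter_groups(cats, pairs, alpha),
                 anova_p = anova_p),
            class = "variance_test")
}

# greedy compact-letter display: categories not significantly different
# share a letter
.letter_groups <- function(cats, pairs, alpha) {
  differs <- function(a, b) {
    row <- pairs[(pairs$category1 == a & pairs$category2 == b) |
                   (pairs$category1 == b & pairs$category2 == a), ]
    isTRUE(row$p_adj[1] < alpha)
  }
  groups <- list()
  for (cat in cats) {
    placed <- FALSE
    for (k in seq_along(groups)) {
      if (!any(vapply(groups[[k]], differs, logical(1), a = cat))) {
        groups[[k]] <- c(groups[[k]], cat)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- cat
  }
  out <- setNames(rep("", length(cats)), cats)
  for (k in seq_along(groups))
    for (cat in groups[[k]])
      out[cat] <- paste0(out[cat], letters[k])
  out
}

#' @export
print.variance_test <- function(x, ...) {
  cat("Pairwise variance-ratio F-tests (two-tailed, BH-adjusted)\n")
  tab <- x$pairs
  tab$F <- round(tab$F, 3); tab$p_value <- signif(tab$p_value, 3)
  tab$p_adj <- signif(tab$p_adj, 3)
  print(tab[setdiff(names(tab), "undefined")], row.names = FALSE)
  cat("Letter groups:",
      paste(names(x$letters), x$letters, sep = ":", collapse = "  "), "\n")
  cat(sprintf("One-way ANOVA across categories: p = %.4g\n", x$anova_p))
  invisible(x)
}
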