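#' Rank-based group comparison
#'
#' Thin delegation to the standard nonparametric tests matched to the study
#' design, included so reports carry the same statistics as the imaging
#' literature:
#' \describe{
#'   \item{`independent-2`}{unpaired two-sided Mann-Whitney U
#'     ([stats::wilcox.test()]).}
#'   \item{`independent-k`}{Kruskal-Wallis ([stats::kruskal.test()]) with
#'     Bonferroni-corrected pairwise Mann-Whitney follow-ups.}
#'   \item{`repeated-k`}{Friedman test ([stats::friedman.test()]) on a
#'     complete block design (equal group lengths, blocks = positions) with
#'     Dunn's rank-sum follow-ups, Bonferroni-adjusted.}
#' }
#'
#' @param values_by_group Named list of numeric vectors, one per group, or a
#'   data frame with columns `value` and `group`.
#' @param design One of `independent-2`, `independent-k`, `repeated-k`.
#' @return A list of class `group_comparison`: `test`, `statistic`, `p_value`,
#'   `stars`, and (k-group designs) `pairwise`, a tibble of follow-ups.
#' @examples
#' compare_groups(list(a = c(1, 2, 3), b = c(4, 5, 6)), "independent-2")
#' @export
compare_groups <- function(values_by_group,
                           design = c("independent-2", "independent-k",
                                      "repeated-k")) {
  design <- match.arg(design)
  if (is.data.frame(values_by_group)) {
    values_by_group <- split(values_by_group$value, values_by_group$group)
  }
  k <- length(values_by_group)
  if (k < 2 || any(vapply(values_by_group, length, 1L) == 0)) {
    abort("need at least 2 non-empty groups")
  }
  if (design == "independent-2" && k != 2) {
    abort(sprintf("design 'independent-2' requires exactly 2 groups, got %d", k))
  }
  if (design != "independent-2" && k < 3) {
    abort(sprintf("design '%s' requires at least 3 groups", design))
  }
  res <- switch(design,
    "independent-2" = {
      w <- stats::wilcox.test(values_by_group[[1]], values_by_group[[2]],
                              alternative = "two.sided", exact = NULL)
      list(test = "Mann-Whitney U", statistic = unname(w$statistic),
           p_value = w$p.value, pairwise = NULL)
    },
    "independent-k" = {
      kw <- stats::kruskal.test(values_by_group)
      list(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
           p_value = kw$p.value,
           pairwise = pairwise_mw(values_by_group))
    },
    "repeated-k" = {
      lens <- vapply(values_by_group, length, 1L)
      if (length(unique(lens)) != 1) {
        abort("repeated-k design requires equal block counts in every group")
      }
      y <- do.call(cbind, values_by_group)
      fr <- stats::friedman.test(y)
      list(test = "Friedman", statistic = unname(fr$statistic),
           p_value = fr$p.value, pairwise = friedman_dunn(y))
    }
  )
  res$design <- design
  res$stars <- p_stars(res$p_value)
  if (!is.null(res$pairwise)) res$pairwise$stars <- p_stars(res$pairwise$p_adjusted)
  structure(res, class = "group_comparison")
}

pairwise_mw <- function(groups) {
  nm <- names(groups) %||% as.character(seq_along(groups))
  idx <- utils::combn(length(groups), 2)
  rows <- lapply(seq_len(ncol(idx)), function(j) {
    i1 <- idx[1, j]; i2 <- idx[2, j]
    # normal approximation under ties is intended for the follow-ups
    w <- suppressWarnings(
      stats::wilcox.test(groups[[i1]], groups[[i2]], alternative = "two.sided"))
    tibble(group1 = nm[i1], group2 = nm[i2],
           statistic = unname(w$statistic), p_value = w$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- pmin(1, out$p_value * nrow(out)) # Bonferroni
  out
}

# Dunn's post-hoc for the Friedman design: z on within-block rank sums,
# Bonferroni-adjusted ("Dunn's correction")
friedman_dunn <- function(y) {
  n <- nrow(y); k <- ncol(y)
  ranks <- t(apply(y, 1, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  nm <- colnames(y) %||% as.character(seq_len(k))
  idx <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(idx)), function(j) {
    i1 <- idx[1, j]; i2 <- idx[2, j]
    z <- (rbar[i1] - rbar[i2]) / se
    tibble(group1 = nm[i1], group2 = nm[i2], statistic = z,
           p_value = 2 * stats::pnorm(-abs(z)))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  out
}

#' Significance star banding
#'
#' `*` for 0.05 > p > 0.01, `**` for 0.01 > p > 0.001, `***` for
#' 0.001 > p > 0.0001, `****` for p < 0.0001, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$test, " (", x$design, ")\n",
      "  statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 4), " [", x$stars, "]\n", sep = "")
  if (!is.null(x$pairwise)) {
    cat("  pairwise follow-ups:\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  main <- tibble(group1 = NA_character_, group2 = NA_character_,
                 test = x$test, statistic = x$statistic,
                 p_value = x$p_value, p_adjusted = x$p_value, stars = x$stars)
  if (is.null(x$pairwise)) return(main)
  dplyr::bind_rows(main, dplyr::mutate(x$pairwise, test = paste0(x$test, " follow-up")))
}
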