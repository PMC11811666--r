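#' Assign four-group insomnia-severity labels from ISI totals
#'
#' Delegates to [classify_isi()] and tallies the groups.
#'
#' @param isi_totals ISI total scores in 0-28.
#' @return List with `groups` (factor, one label per participant) and
#'   `counts` (named integer vector over the four bands).
#' @export
assign_isi_groups <- function(isi_totals) {
  groups <- classify_isi(isi_totals)
  list(groups = groups, counts = table(groups))
}

#' Bonferroni-corrected pairwise significance threshold
#'
#' `family_alpha / choose(n_groups, 2)`: with 4 groups and a familywise
#' alpha of 0.05 the threshold is 0.05/6 = 0.00833..., conventionally
#' displayed as .0083.
#'
#' @param n_groups Number of groups compared pairwise (>= 2).
#' @param family_alpha Familywise error rate, default 0.05.
#' @return The per-pair threshold.
#' @export
bonferroni_threshold <- function(n_groups, family_alpha = 0.05) {
  if (n_groups < 2) stop("need at least 2 groups", call. = FALSE)
  family_alpha / choose(n_groups, 2)
}

# Null counts of the Mann-Whitney U statistic for sample sizes m and n,
# over u = 0..m*n, via subset-sum counting of the m ranks among 1..(m+n).
mw_null_counts <- function(m, n) {
  N <- m + n
  max_w <- sum((N - m + 1):N)
  dp <- matrix(0, nrow = m + 1, ncol = max_w + 1)
  dp[1, 1] <- 1
  for (v in seq_len(N)) {
    for (k in rev(seq_len(min(v, m)))) {
      cols <- (v + 1):(max_w + 1)
      dp[k + 1, cols] <- dp[k + 1, cols] + dp[k, cols - v]
    }
  }
  counts_w <- dp[m + 1, ]
  min_w <- m * (m + 1) / 2
  counts_w[(min_w:max_w) + 1]
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The statistic is the Mann-Whitney U of the first sample (identical to
#' `stats::wilcox.test`'s `W`). The exact null distribution (computed by
#' rank subset-sum counting) is used for combined samples of at most 20
#' observations without ties; otherwise the normal approximation with
#' mid-rank ties, tie-corrected variance, and continuity correction.
#'
#' @param x,y Numeric samples (both nonempty).
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact path;
#'   default `NULL` auto-selects as above. Exactness is unavailable under
#'   ties and falls back to the approximation.
#' @param correct Apply the continuity correction in the normal
#'   approximation (default `TRUE`).
#' @return List with `statistic` (U), `p.value`, and `method`.
#' @export
rank_sum_test <- function(x, y, exact = NULL, correct = TRUE) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  m <- length(x)
  n <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (is.null(exact)) exact <- (m + n <= 20)
  if (exact && ties) exact <- FALSE
  if (exact) {
    counts <- mw_null_counts(m, n)
    tot <- sum(counts)
    p_lo <- sum(counts[seq_len(u + 1)]) / tot
    p_hi <- sum(counts[(u + 1):length(counts)]) / tot
    p <- if (u > m * n / 2) 2 * p_hi else 2 * p_lo
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- m * n / 2
    tie_tab <- table(r)
    sigma2 <- m * n / 12 *
      ((m + n + 1) - sum(tie_tab^3 - tie_tab) / ((m + n) * (m + n - 1)))
    if (sigma2 <= 0) {
      return(list(statistic = u, p.value = 1,
                  method = "normal approximation (degenerate)"))
    }
    z <- u - mu
    if (correct) z <- z - sign(z) * 0.5
    z <- z / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = u, p.value = p, method = method)
}

# Per-group Shapiro-Wilk normality gate: a group counts as non-normal when
# it is too small for the test, has zero variance, or rejects at alpha.
groups_all_normal <- function(values, groups, alpha = 0.05) {
  for (lev in levels(groups)) {
    v <- values[groups == lev & !is.na(values)]
    if (length(v) == 0) next
    if (length(v) < 3 || stats::sd(v) == 0) return(FALSE)
    if (stats::shapiro.test(v[seq_len(min(length(v), 5000))])$p.value <
          alpha) {
      return(FALSE)
    }
  }
  TRUE
}

#' Compare one variable across severity groups
#'
#' Implements the study's test-selection policy. Continuous variables pass a
#' per-group Shapiro-Wilk normality gate: if any group is non-normal the
#' omnibus test is Kruskal-Wallis followed by all pairwise Wilcoxon
#' rank-sum tests flagged at the Bonferroni threshold
#' (`family_alpha / choose(k, 2)`); if every group is normal, one-way ANOVA
#' with Tukey HSD post hoc. Categorical variables use the chi-square test on
#' the group-by-level contingency table. Group summaries are median (IQR) on
#' the rank path, mean (SD) on the ANOVA path, and n (%) for categoricals.
#'
#' @param values The variable (numeric, or character/factor for
#'   `kind = "categorical"`).
#' @param groups Factor of group labels, same length as `values`.
#' @param variable Name used in reports.
#' @param kind `"continuous"` or `"categorical"`.
#' @param normality_alpha Alpha for the per-group Shapiro-Wilk gate.
#' @param family_alpha Familywise alpha for post hoc flagging.
#' @return An object of class `comparison_result`: list with `variable`,
#'   `kind`, `test_used`, `omnibus_p`, `threshold`, `pairwise` (tibble),
#'   and `summaries` (tibble).
#' @export
test_group_variable <- function(values, groups, variable = "variable",
                                kind = c("continuous", "categorical"),
                                normality_alpha = 0.05,
                                family_alpha = 0.05) {
  kind <- match.arg(kind)
  groups <- droplevels(as.factor(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  k <- nlevels(groups)
  empty_result <- function(reason) {
    structure(list(
      variable = variable, kind = kind, test_used = "none",
      omnibus_p = NA_real_, threshold = NA_real_,
      pairwise = tibble::tibble(group1 = character(), group2 = character(),
                                statistic = numeric(), p = numeric(),
                                significant = logical()),
      summaries = tibble::tibble(), reason = reason
    ), class = "comparison_result")
  }
  if (k < 2) {
    return(empty_result("fewer than 2 nonempty groups"))
  }
  if (kind == "categorical") {
    tab <- table(groups, values)
    ct <- suppressWarnings(stats::chisq.test(tab))
    if (any(ct$expected < 5)) {
      warning(variable, ": chi-square expected cell count below 5")
    }
    summaries <- as.data.frame(tab) |>
      dplyr::group_by(.data$groups) |>
      dplyr::mutate(pct = 100 * .data$Freq / sum(.data$Freq)) |>
      dplyr::ungroup() |>
      dplyr::transmute(
        group = as.character(.data$groups),
        level = as.character(.data$values),
        n = .data$Freq,
        cell = sprintf("%d (%.1f)", .data$Freq, .data$pct)
      )
    return(structure(list(
      variable = variable, kind = kind, test_used = "chi_square",
      omnibus_p = unname(ct$p.value), threshold = NA_real_,
      pairwise = tibble::tibble(group1 = character(), group2 = character(),
                                statistic = numeric(), p = numeric(),
                                significant = logical()),
      summaries = tibble::as_tibble(summaries)
    ), class = "comparison_result"))
  }
  values <- as.numeric(values)
  normal <- groups_all_normal(values, groups, normality_alpha)
  pairs <- utils::combn(levels(groups), 2)
  if (!normal) {
    kw <- stats::kruskal.test(values, groups)
    thr <- bonferroni_threshold(k, family_alpha)
    pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- values[groups == pairs[1, j]]
      b <- values[groups == pairs[2, j]]
      rs <- rank_sum_test(a, b)
      tibble::tibble(group1 = pairs[1, j], group2 = pairs[2, j],
                     statistic = rs$statistic, p = rs$p.value,
                     significant = rs$p.value < thr)
    })
    summaries <- tibble::tibble(
      group = levels(groups),
      n = as.integer(table(groups)),
      location = tapply(values, groups, stats::median),
      cell = vapply(levels(groups), function(lev) {
        v <- values[groups == lev]
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
        sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
      }, character(1))
    )
    res <- list(variable = variable, kind = kind,
                test_used = "kruskal_wallis",
                omnibus_p = unname(kw$p.value), threshold = thr,
                pairwise = pw, summaries = summaries)
  } else {
    fit <- stats::aov(values ~ groups)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$groups
    pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
    pw <- tibble::tibble(
      group1 = vapply(pair_names, `[`, character(1), 2),
      group2 = vapply(pair_names, `[`, character(1), 1),
      statistic = tk[, "diff"],
      p = tk[, "p adj"],
      significant = tk[, "p adj"] < family_alpha
    )
    summaries <- tibble::tibble(
      group = levels(groups),
      n = as.integer(table(groups)),
      location = tapply(values, groups, mean),
      cell = vapply(levels(groups), function(lev) {
        v <- values[groups == lev]
        sprintf("%.2f (%.2f)", mean(v), stats::sd(v))
      }, character(1))
    )
    res <- list(variable = variable, kind = kind, test_used = "anova",
                omnibus_p = unname(p), threshold = family_alpha,
                pairwise = pw, summaries = summaries)
  }
  structure(res, class = "comparison_result")
}

# Merge groups not separated by a significant pair (union-find), order the
# resulting clusters by group location, and render "a<b-to-c<d"-style
# narratives like the study tables' post hoc column.
posthoc_narrative <- function(res) {
  if (res$test_used %in% c("none", "chi_square") ||
      nrow(res$pairwise) == 0 || !any(res$pairwise$significant)) {
    return("-")
  }
  levs <- res$summaries$group
  parent <- stats::setNames(seq_along(levs), levs)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  ns <- res$pairwise[!res$pairwise$significant, , drop = FALSE]
  for (j in seq_len(nrow(ns))) {
    a <- find(match(ns$group1[j], levs))
    b <- find(match(ns$group2[j], levs))
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_along(levs), find, numeric(1))
  loc <- res$summaries$location
  cluster_ids <- unique(roots)
  cluster_label <- vapply(cluster_ids, function(cid) {
    members <- which(roots == cid)
    if (length(members) == 1) return(levs[members])
    if (all(diff(members) == 1)) {
      return(paste0(levs[members[1]], "-to-", levs[members[length(members)]]))
    }
    paste(levs[members], collapse = "/")
  }, character(1))
  cluster_loc <- vapply(cluster_ids, function(cid) {
    mean(loc[roots == cid])
  }, numeric(1))
  if (length(cluster_ids) == 1) {
    # non-transitive pattern: list the significant pairs directly
    sig <- res$pairwise[res$pairwise$significant, , drop = FALSE]
    return(paste(vapply(seq_len(nrow(sig)), function(j) {
      a <- sig$group1[j]
      b <- sig$group2[j]
      if (loc[match(a, levs)] <= loc[match(b, levs)]) {
        paste0(a, "<", b)
      } else {
        paste0(b, "<", a)
      }
    }, character(1)), collapse = "; "))
  }
  paste(cluster_label[order(cluster_loc)], collapse = "<")
}

#' Compare many variables across groups
#'
#' Applies [test_group_variable()] to each requested column of a feature
#' table.
#'
#' @param data Tibble with one row per participant, containing the group
#'   column and the variables.
#' @param group_col Name of the group column (factor or character).
#' @param variables Named character vector mapping variable column names to
#'   `"continuous"` or `"categorical"`.
#' @inheritParams test_group_variable
#' @return Named list of `comparison_result` objects.
#' @export
compare_groups <- function(data, group_col, variables,
                           normality_alpha = 0.05, family_alpha = 0.05) {
  groups <- data[[group_col]]
  out <- lapply(names(variables), function(v) {
    test_group_variable(data[[v]], groups, variable = v,
                        kind = variables[[v]],
                        normality_alpha = normality_alpha,
                        family_alpha = family_alpha)
  })
  stats::setNames(out, names(variables))
}

#' Assemble a study-style comparison report
#'
#' One row per variable with the per-group summary cells (median (IQR),
#' mean (SD), or n (%) depending on the test path), the omnibus test and
#' p-value, and an ordered post hoc narrative (groups not separated by a
#' significant pairwise test are merged, clusters ordered by location, e.g.
#' `"no_insomnia<mild-to-moderate<severe"`). Empty input gives an empty
#' report.
#'
#' @param results List of `comparison_result` objects (see
#'   [compare_groups()]).
#' @return Tibble with columns `variable`, one summary column per group (or
#'   a `cells` list-column for categoricals), `test`, `p`, `posthoc`.
#' @export
build_group_report <- function(results) {
  if (length(results) == 0) {
    return(tibble::tibble(variable = character(), test = character(),
                          p = numeric(), posthoc = character()))
  }
  purrr::map_dfr(results, function(res) {
    row <- tibble::tibble(
      variable = res$variable,
      test = res$test_used,
      p = res$omnibus_p,
      posthoc = posthoc_narrative(res)
    )
    if (res$kind == "continuous" && nrow(res$summaries) > 0) {
      cells <- stats::setNames(as.list(res$summaries$cell),
                               res$summaries$group)
      row <- dplyr::bind_cols(row, tibble::as_tibble(cells))
    } else if (nrow(res$summaries) > 0) {
      row$cells <- list(res$summaries)
    }
    row
  })
}
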