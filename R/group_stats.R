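#' Per-architecture summary of DOA / DOC values
#'
#' Mean and standard error of the mean per architecture and statistic.
#' Non-finite values (infinite-alignment / infinite-containment sentinels,
#' undefined DOC on flat samples) are excluded with a message; a group of
#' size 1 has an undefined SEM (`NA`).
#'
#' @param table long tibble with columns `architecture`, `replicate`,
#'   `statistic` (`"DOA"` or `"DOC"`) and `value`.
#' @return A tibble with `architecture`, `statistic`, `n`, `mean`, `sem`.
#' @export
summarize_groups <- function(table) {
  stopifnot(all(c("architecture", "statistic", "value") %in% names(table)))
  n_bad <- sum(!is.finite(table$value))
  if (n_bad > 0) {
    message(n_bad, " non-finite value(s) excluded from the summary")
    table <- dplyr::filter(table, is.finite(.data$value))
  }
  table |>
    dplyr::group_by(.data$architecture, .data$statistic) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sem = ifelse(dplyr::n() > 1,
                   stats::sd(.data$value) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop"
    )
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' Rank-based comparison of a statistic across architectures: the
#' Kruskal-Wallis omnibus test (with tie correction) followed by Dunn's
#' pairwise z tests on mean ranks. Pairwise p values are unadjusted by
#' default (`p_adjust = "holm"` applies Holm's correction). Results are
#' flagged at the conventional cutoffs 0.05 and 0.005. Non-finite values are
#' excluded with a message. If all values are identical the omnibus statistic
#' is zero and p = 1 by convention.
#'
#' With triplicate groups the chi-squared approximation of the omnibus
#' statistic is far too conservative, so for small samples (12 or fewer
#' observations, no ties) the omnibus p value is computed exactly by
#' enumerating all rank assignments (`method = "auto"`, the default;
#' `"asymptotic"` forces the chi-squared approximation).
#'
#' @param table long tibble with columns `architecture` and `value`
#'   (optionally `statistic`, filtered via `stat`).
#' @param stat statistic to test when a `statistic` column is present.
#' @param p_adjust `"none"` (default) or `"holm"` for the Dunn p values.
#' @param pairwise set `FALSE` to skip Dunn's comparisons.
#' @param method `"auto"`, `"exact"` or `"asymptotic"` omnibus p value.
#' @return A list of class `kruskal_dunn`: `omnibus` (one-row tibble with
#'   `statistic`, `df`, `p_value`, `method`), `pairwise` (tibble with
#'   `group1`, `group2`, `z`, `p_value`, `sig_05`, `sig_005`), `n_excluded`.
#' @export
kruskal_dunn <- function(table, stat = NULL, p_adjust = c("none", "holm"),
                         pairwise = TRUE,
                         method = c("auto", "exact", "asymptotic")) {
  p_adjust <- match.arg(p_adjust)
  method <- match.arg(method)
  stopifnot(all(c("architecture", "value") %in% names(table)))
  if (!is.null(stat) && "statistic" %in% names(table)) {
    table <- dplyr::filter(table, .data$statistic == stat)
  }
  n_bad <- sum(!is.finite(table$value))
  if (n_bad > 0) {
    message(n_bad, " non-finite value(s) excluded from testing")
    table <- dplyr::filter(table, is.finite(.data$value))
  }
  g <- factor(table$architecture)
  v <- table$value
  if (nlevels(g) < 3) stop("the omnibus test needs at least 3 groups")
  if (length(unique(v)) == 1) {
    omni <- tibble::tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                           method = "degenerate")
  } else {
    kt <- stats::kruskal.test(v, g)
    no_ties <- !any(duplicated(v))
    use_exact <- method == "exact" ||
      (method == "auto" && length(v) <= 12 && no_ties)
    if (use_exact) {
      if (!no_ties) stop("exact omnibus p value requires untied values")
      if (length(v) > 14) stop("exact enumeration limited to 14 observations")
      p <- exact_kw_pvalue(unname(kt$statistic), tabulate(g))
      omni <- tibble::tibble(statistic = unname(kt$statistic),
                             df = unname(kt$parameter), p_value = p,
                             method = "exact")
    } else {
      omni <- tibble::tibble(statistic = unname(kt$statistic),
                             df = unname(kt$parameter),
                             p_value = kt$p.value, method = "asymptotic")
    }
  }
  pw <- NULL
  if (pairwise) {
    pw <- dunn_pairwise(v, g, p_adjust)
  }
  structure(list(omnibus = omni, pairwise = pw, n_excluded = n_bad),
            class = "kruskal_dunn")
}

# exact null distribution of the (untied) Kruskal-Wallis statistic for the
# given group sizes, by enumeration of rank assignments; cached per signature
kw_null_cache <- new.env(parent = emptyenv())

exact_kw_pvalue <- function(h_obs, sizes) {
  key <- paste(sort(sizes), collapse = ",")
  if (is.null(kw_null_cache[[key]])) {
    kw_null_cache[[key]] <- kw_null_distribution(sizes)
  }
  hs <- kw_null_cache[[key]]
  mean(hs >= h_obs - 1e-9)
}

kw_null_distribution <- function(sizes) {
  N <- sum(sizes)
  out <- numeric(0)
  recurse <- function(remaining, rank_sums) {
    gi <- length(rank_sums) + 1
    if (gi == length(sizes)) {
      rs <- c(rank_sums, sum(remaining))
      h <- 12 / (N * (N + 1)) * sum(rs^2 / sizes) - 3 * (N + 1)
      out[length(out) + 1] <<- h
      return(invisible())
    }
    cmb <- utils::combn(remaining, sizes[gi])
    for (j in seq_len(ncol(cmb))) {
      recurse(setdiff(remaining, cmb[, j]), c(rank_sums, sum(cmb[, j])))
    }
  }
  recurse(seq_len(N), numeric(0))
  out
}

# Dunn's z statistics on mean ranks with tie correction
dunn_pairwise <- function(v, g, p_adjust = "none") {
  N <- length(v)
  rk <- rank(v)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  mr <- tapply(rk, g, mean)
  ns <- tapply(rk, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- vapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    (mr[[a]] - mr[[b]]) / sqrt(s2 * (1 / ns[[a]] + 1 / ns[[b]]))
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(z))
  if (p_adjust == "holm") p <- stats::p.adjust(p, "holm")
  tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ], z = z, p_value = p,
    sig_05 = p < 0.05, sig_005 = p < 0.005
  )
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi-squared = %.4g, df = %d, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value))
  if (!is.null(x$pairwise)) {
    cat("Dunn's pairwise comparisons:\n")
    print(x$pairwise)
  }
  invisible(x)
}
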