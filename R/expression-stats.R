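#' Relative gene expression by the delta-delta-Ct method
#'
#' For every sample and target gene, `dCt = Ct_target - Ct_housekeeping`
#' normalizes against the housekeeping gene; `ddCt = dCt - mean(dCt)` over
#' the control-group samples of that gene references the control; the fold
#' change is `2^(-ddCt)`. By construction the control group's geometric
#' mean fold change is exactly 1 for every gene, and the housekeeping
#' gene's own fold change is exactly 1 for every sample.
#'
#' @param table A `ct_table` data frame with columns `sample_id`, `group`,
#'   `gene`, `ct` (one row per sample-gene pair).
#' @param housekeeping Housekeeping gene name (default `"Gapdh"`).
#' @param control_group Control group label (default `"control"`).
#' @return An object of class `fold_change_result`: list with `per_sample`
#'   (data frame: `sample_id`, `group`, `gene`, `ct`, `dct`, `ddct`,
#'   `fold_change`) and `by_group` (data frame: `group`, `gene`, `n`,
#'   `geo_mean_fold` — geometric mean, i.e. `2^mean(log2 fold)` — and
#'   `sd_log2_fold`).
#' @export
delta_delta_ct <- function(table, housekeeping = "Gapdh",
                           control_group = "control") {
  stopifnot(is.data.frame(table),
            all(c("sample_id", "group", "gene", "ct") %in% names(table)))
  if (anyDuplicated(table[c("sample_id", "gene")]))
    stop("every (sample_id, gene) pair must be unique", call. = FALSE)
  if (any(!is.finite(table$ct)))
    stop("all Ct values must be finite", call. = FALSE)
  if (!control_group %in% table$group)
    stop(sprintf("control group '%s' has no samples", control_group),
         call. = FALSE)
  hk <- table[table$gene == housekeeping, ]
  hk_ct <- stats::setNames(hk$ct, hk$sample_id)
  missing_hk <- setdiff(unique(table$sample_id), hk$sample_id)
  if (length(missing_hk))
    stop("missing housekeeping Ct for sample(s): ",
         paste(missing_hk, collapse = ", "), call. = FALSE)

  per <- table[c("sample_id", "group", "gene", "ct")]
  per$dct <- per$ct - hk_ct[per$sample_id]
  ctrl_mean <- tapply(per$dct[per$group == control_group],
                      per$gene[per$group == control_group], mean)
  missing_ctrl <- setdiff(unique(per$gene), names(ctrl_mean))
  if (length(missing_ctrl))
    stop("no control samples for gene(s): ",
         paste(missing_ctrl, collapse = ", "), call. = FALSE)
  per$ddct <- per$dct - as.numeric(ctrl_mean[per$gene])
  per$fold_change <- 2^(-per$ddct)
  rownames(per) <- NULL

  key <- interaction(per$group, per$gene, drop = TRUE, lex.order = TRUE)
  agg <- do.call(rbind, lapply(split(per, key), function(d) {
    l2 <- -d$ddct
    data.frame(group = d$group[1], gene = d$gene[1], n = nrow(d),
               geo_mean_fold = 2^mean(l2),
               sd_log2_fold = if (nrow(d) > 1) sd(l2) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(list(per_sample = per, by_group = agg,
                 housekeeping = housekeeping, control_group = control_group),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("<fold_change_result> normalized to %s, control = %s\n",
              x$housekeeping, x$control_group))
  print(x$by_group)
  invisible(x)
}

new_test_result <- function(statistic, df, p, test_name) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_two_sided = unname(p), test_name = test_name),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("<group_test_result> %s: statistic = %.4g, df = %s, p = %.4g\n",
              x$test_name, x$statistic,
              paste(signif(x$df, 6), collapse = ", "), x$p_two_sided))
  invisible(x)
}

summ_stats <- function(v, name) {
  if (is.list(v)) {
    stopifnot(all(c("mean", "sd", "n") %in% names(v)))
    if (v$n < 2) stop(sprintf("`%s` must have n >= 2", name), call. = FALSE)
    list(m = v$mean, s = v$sd, n = v$n)
  } else {
    if (length(v) < 2)
      stop(sprintf("`%s` must have n >= 2", name), call. = FALSE)
    list(m = mean(v), s = sd(v), n = length(v))
  }
}

#' Two-sample t test (Student or Welch), from raw data or summaries
#'
#' Student's variant pools the variances with `df = n1 + n2 - 2`; Welch's
#' variant uses per-group variances with the Welch-Satterthwaite degrees of
#' freedom. Both accept either raw numeric vectors or summary statistics
#' given as `list(mean =, sd =, n =)`, which is how published group
#' summaries (mean, SD, n) can be tested without the raw data. The
#' two-sided p-value comes from the t distribution.
#'
#' @param x,y Numeric vectors (n >= 2 each) or `list(mean =, sd =, n =)`.
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @return A `group_test_result`: list with `statistic`, `df`,
#'   `p_two_sided`, `test_name`.
#' @export
two_sample_t <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- summ_stats(x, "x"); b <- summ_stats(y, "y")
  if (a$s == 0 && b$s == 0 && a$m == b$m)
    stop("undefined statistic: both samples have zero variance and equal ",
         "means", call. = FALSE)
  if (variant == "student") {
    sp2 <- ((a$n - 1) * a$s^2 + (b$n - 1) * b$s^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    va <- a$s^2 / a$n; vb <- b$s^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- (a$m - b$m) / se
  p <- 2 * pt(-abs(t), df)
  new_test_result(t, df, p, paste0(variant, "_t"))
}

#' One-way analysis of variance
#'
#' Classic between/within sum-of-squares decomposition:
#' `F = MSB / MSW` with `df = (k - 1, N - k)`; p-value from the F
#' distribution.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   n >= 2).
#' @return A `group_test_result` with `df = c(df_between, df_within)`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("`groups` must be a list of >= 2 numeric vectors", call. = FALSE)
  ns <- lengths(groups)
  if (any(ns < 2))
    stop("every group must have n >= 2", call. = FALSE)
  N <- sum(ns); k <- length(groups)
  means <- vapply(groups, mean, 0)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (ssw == 0 && ssb == 0)
    stop("undefined statistic: zero within- and between-group variation",
         call. = FALSE)
  if (ssw == 0)
    stop("undefined statistic: zero within-group variation", call. = FALSE)
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- pf(f, k - 1, N - k, lower.tail = FALSE)
  new_test_result(f, c(k - 1, N - k), p, "anova_F")
}
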