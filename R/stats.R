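#' Metric direction: is a higher value worse?
#'
#' Direction conventions for most-affected-side selection: higher is worse
#' for tremor intensity and reaction-time metrics; lower is worse for tap
#' frequencies (bradykinesia slows tapping).
#'
#' @param metric Metric name (`"TI"`, `"RT"`, `"RT_SD"`, `"MFT"`, ...).
#' @return Logical: `TRUE` if larger values indicate worse performance.
#' @export
higher_is_worse <- function(metric) {
  key <- sub(".*_(TI|RT_SD|RT|MFT_SD|MFT)$", "\\1", metric)
  if (!key %in% c("TI", "RT", "RT_SD", "MFT", "MFT_SD")) {
    stop_argument(sprintf(
      "no side-selection direction defined for metric '%s'", metric))
  }
  !key %in% c("MFT", "MFT_SD")
}

#' Most affected side for a bilateral metric
#'
#' Returns the side with the worse value under the metric's direction
#' convention (see [higher_is_worse()]). Ties are broken to the dominant
#' side and flagged; a missing side excludes itself and the remaining
#' side is returned with a flag.
#'
#' @param right,left Metric values per side (may be `NA`).
#' @param metric Metric name, for the direction convention.
#' @param dominant Dominant side, used only to break exact ties.
#' @return List: `side` (`"right"`/`"left"`/`NA`), `value`, `flagged`
#'   (TRUE when a tie was broken or a side was missing).
#' @export
most_affected_side <- function(right, left, metric = "TI",
                               dominant = "right") {
  if (is.na(right) && is.na(left)) {
    return(list(side = NA_character_, value = NA_real_, flagged = TRUE))
  }
  if (is.na(right)) return(list(side = "left", value = left, flagged = TRUE))
  if (is.na(left)) return(list(side = "right", value = right,
                               flagged = TRUE))
  hw <- higher_is_worse(metric)
  if (right == left) {
    return(list(side = dominant,
                value = right, flagged = TRUE))
  }
  worse_right <- if (hw) right > left else right < left
  if (worse_right) list(side = "right", value = right, flagged = FALSE)
  else list(side = "left", value = left, flagged = FALSE)
}

#' Mann-Whitney U comparison of two groups
#'
#' U statistic (first-group orientation) and two-sided p value: exact
#' enumeration when the smaller group has at most 10 observations and the
#' pooled data are tie-free, normal approximation with tie correction (and
#' continuity correction) otherwise.
#'
#' @param a,b Numeric vectors (NAs dropped); each group needs >= 2 values.
#' @param metric Optional metric label carried into the result.
#' @return Object of class `comparison_result`: `metric`, `U` (for `a`
#'   over `b`), `p`, `n`, group means/SDs, `direction` (which group has
#'   the larger values).
#' @export
mann_whitney <- function(a, b, metric = "metric") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) {
    stop_validation("each group needs >= 2 non-missing values")
  }
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = (min(n1, n2) <= 10 && !ties),
                       correct = TRUE))
  structure(
    list(metric = metric, U = U, p = wt$p.value, n = c(n1, n2),
         mean = c(mean(a), mean(b)),
         sd = c(sample_sd(a), sample_sd(b)),
         direction = if (U > n1 * n2 / 2) "first" else "second"),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: U = %.1f, p = %.4g (n = %d vs %d)\n",
              x$metric, x$U, x$p, x$n[1], x$n[2]))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Average ranks for ties, then the product-moment correlation of the
#' ranks; two-sided p value by the t approximation. Pairwise-complete
#' observations only.
#'
#' @param x,y Paired numeric vectors.
#' @param metric,item Optional labels carried into the result.
#' @return Object of class `correlation_result`: `rho`, `p`, `n`,
#'   `flagged` (TRUE when rho is undefined because an input is constant).
#' @export
spearman <- function(x, y, metric = "metric", item = "item") {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_validation("need >= 3 complete pairs")
  if (sample_sd(x) == 0 || sample_sd(y) == 0) {
    return(structure(list(metric = metric, item = item, rho = NA_real_,
                          p = NA_real_, n = n, flagged = TRUE),
                     class = "correlation_result"))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  structure(
    list(metric = metric, item = item, rho = unname(ct$estimate),
         p = ct$p.value, n = n, flagged = FALSE),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s ~ %s: rho = %.3f, p = %.4g (n = %d)\n",
              x$metric, x$item, x$rho, x$p, x$n))
  invisible(x)
}

## task -> (primary metric used to pick the side, secondary metrics that
## follow the chosen side)
task_reductions <- function() {
  list(
    rest_tremor = list(primary = "TI", also = c("F50", "SF50", "HI")),
    postural_tremor = list(primary = "TI", also = c("F50", "SF50", "HI")),
    pronation_supination = list(primary = "MFT", also = "MFT_SD"),
    finger_tapping = list(primary = "MFT", also = "MFT_SD"),
    reaction = list(primary = "RT", also = "RT_SD"))
}

#' Reduce bilateral metrics to the most affected side
#'
#' For each bilateral task, selects the worse side by the task's primary
#' metric (TI for tremor, MFT for plate tasks, RT for reaction; direction
#' per [higher_is_worse()]) and takes every metric of that task from the
#' selected side — applied identically to both groups. Also appends the
#' bilateral mean of pronation/supination frequency
#' (`pronation_supination_MFT_bilateral`), the reduction used when
#' correlating with the body-bradykinesia item. Sway metrics pass through
#' unchanged.
#'
#' @param tbl Cohort metric table from [cohort_metrics()].
#' @return Data frame with one column per reduced metric
#'   (`<task>_<metric>`), sway columns, and the id/group/clinical columns.
#' @export
reduce_most_affected <- function(tbl) {
  out <- tbl[, intersect(c("subject_id", "group", "dominant_side",
                           "updrs20_right", "updrs20_left",
                           "updrs21_right", "updrs21_left", "updrs31",
                           "hy_stage"), names(tbl)), drop = FALSE]
  red <- task_reductions()
  for (task in names(red)) {
    pr <- red[[task]]$primary
    rcol <- paste(task, "right", pr, sep = "_")
    lcol <- paste(task, "left", pr, sep = "_")
    if (!rcol %in% names(tbl)) next
    sides <- vapply(seq_len(nrow(tbl)), function(i) {
      most_affected_side(tbl[[rcol]][i], tbl[[lcol]][i], metric = pr,
                         dominant = tbl$dominant_side[i])$side
    }, character(1))
    for (m in c(pr, red[[task]]$also)) {
      rv <- tbl[[paste(task, "right", m, sep = "_")]]
      lv <- tbl[[paste(task, "left", m, sep = "_")]]
      out[[paste(task, m, sep = "_")]] <-
        ifelse(is.na(sides), NA_real_, ifelse(sides == "right", rv, lv))
    }
  }
  if ("pronation_supination_right_MFT" %in% names(tbl)) {
    out$pronation_supination_MFT_bilateral <-
      (tbl$pronation_supination_right_MFT +
         tbl$pronation_supination_left_MFT) / 2
  }
  for (m in sway_metric_names()) {
    col <- paste0("stance_", m)
    if (col %in% names(tbl)) out[[col]] <- tbl[[col]]
  }
  out
}

#' Group comparison over a cohort metric table
#'
#' One Mann-Whitney comparison per metric column, PD versus control, on
#' pairwise-complete observations (per-metric Ns may differ when
#' recordings are missing). Significance at `p <= alpha`; no multiplicity
#' correction by default (a Holm adjustment is available).
#'
#' @param tbl Reduced metric table from [reduce_most_affected()] (or any
#'   data frame with a `group` column and numeric metric columns).
#' @param alpha Significance level (default 0.05).
#' @param metrics Metric columns to compare; default: all numeric columns
#'   except identifiers and clinical items.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Data frame: metric, U, p, group Ns, means, SDs, direction
#'   (which group worse, by larger-value orientation), significant.
#' @export
compare_cohort <- function(tbl, alpha = 0.05, metrics = NULL,
                           adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (!"group" %in% names(tbl)) stop_validation("tbl needs a group column")
  if (!all(c("pd", "control") %in% tbl$group)) {
    stop_validation("both a pd and a control group are required")
  }
  if (is.null(metrics)) {
    skip <- c("subject_id", "group", "dominant_side", "updrs20_right",
              "updrs20_left", "updrs21_right", "updrs21_left", "updrs31",
              "hy_stage")
    metrics <- setdiff(names(tbl)[vapply(tbl, is.numeric, logical(1))],
                       skip)
  }
  rows <- lapply(metrics, function(m) {
    a <- tbl[[m]][tbl$group == "pd"]
    b <- tbl[[m]][tbl$group == "control"]
    cr <- mann_whitney(a, b, metric = m)
    data.frame(metric = m, U = cr$U, p = cr$p,
               n_pd = cr$n[1], n_control = cr$n[2],
               mean_pd = cr$mean[1], mean_control = cr$mean[2],
               sd_pd = cr$sd[1], sd_control = cr$sd[2],
               direction = ifelse(cr$direction == "first", "pd_higher",
                                  "control_higher"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (adjust == "holm") res$p <- stats::p.adjust(res$p, "holm")
  res$significant <- res$p <= alpha
  res
}

#' Clinical-item correlations of a cohort
#'
#' The standard pairings: per-side rest TI against the per-side
#' rest-tremor item, per-side postural TI against the per-side
#' action/postural-tremor item, and the bilateral mean of
#' pronation/supination frequency against the body-bradykinesia item
#' (computed over parkinsonian subjects, who carry item scores).
#'
#' @param tbl Full (unreduced) cohort metric table from
#'   [cohort_metrics()].
#' @return Data frame of [spearman()] results, one row per pairing.
#' @export
correlate_clinical <- function(tbl) {
  pd <- tbl[tbl$group == "pd", , drop = FALSE]
  pairs <- list(
    list("rest_tremor_right_TI", "updrs20_right"),
    list("rest_tremor_left_TI", "updrs20_left"),
    list("postural_tremor_right_TI", "updrs21_right"),
    list("postural_tremor_left_TI", "updrs21_left"))
  rows <- lapply(pairs, function(p) {
    cr <- spearman(pd[[p[[1]]]], pd[[p[[2]]]], metric = p[[1]],
                   item = p[[2]])
    data.frame(metric = cr$metric, item = cr$item, rho = cr$rho,
               p = cr$p, n = cr$n, stringsAsFactors = FALSE)
  })
  if (all(c("pronation_supination_right_MFT",
            "pronation_supination_left_MFT") %in% names(pd))) {
    bil <- (pd$pronation_supination_right_MFT +
              pd$pronation_supination_left_MFT) / 2
    cr <- spearman(bil, pd$updrs31,
                   metric = "pronation_supination_MFT_bilateral",
                   item = "updrs31")
    rows <- c(rows, list(data.frame(metric = cr$metric, item = cr$item,
                                    rho = cr$rho, p = cr$p, n = cr$n,
                                    stringsAsFactors = FALSE)))
  }
  do.call(rbind, rows)
}
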