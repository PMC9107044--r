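#' Rater quality control
#'
#' Crowdsourced rating panels need screening before any reliability
#' analysis: raters who abandoned the task, who straight-lined the scale,
#' or whose ratings degrade the panel's internal consistency contaminate
#' every downstream variance component. Three screens are applied in a
#' fixed order — incomplete raters, low response-range raters, and
#' leave-one-out reliability outliers — and a rater failing several rules
#' is attributed to the earliest one.
#'
#' @name rater_qc
NULL

# Cronbach-type internal-consistency coefficient with raters as "items"
# over a cells x raters score matrix. A panel of identical raters scores 1.
panel_alpha <- function(mat) {
  k <- ncol(mat)
  if (k < 2) return(NA_real_)
  total_var <- stats::var(rowSums(mat))
  if (total_var <= .Machine$double.eps) return(1)
  item_vars <- apply(mat, 2, stats::var)
  (k / (k - 1)) * (1 - sum(item_vars) / total_var)
}

# Mean pairwise Pearson correlation between rater columns; constant
# columns contribute nothing (their correlations are undefined).
panel_mean_cor <- function(mat) {
  if (ncol(mat) < 2) return(NA_real_)
  cm <- suppressWarnings(stats::cor(mat))
  vals <- cm[upper.tri(cm)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) return(1)
  mean(vals)
}

panel_statistic <- function(mat, statistic) {
  switch(statistic,
         alpha = panel_alpha(mat),
         mean_cor = panel_mean_cor(mat),
         stop("unknown panel statistic: ", statistic, call. = FALSE))
}

qc_fragment <- function(table, removed, rule, params) {
  list(table = table, removed = sort(unique(removed)), rule = rule,
       params = params)
}

#' Remove raters with incomplete ratings
#'
#' A rater is retained only if, for every physician they touched, they
#' rated every required vignette on every item in the table's item set.
#' Removed raters' records are dropped entirely — a partially complete
#' rater contributes nothing.
#'
#' @param table A [rating_table()].
#' @param required_vignettes Vignette ids every rater must have covered;
#'   defaults to all vignettes present in the table.
#' @return A list with elements `table` (the filtered [rating_table()]),
#'   `removed` (rater ids), `rule`, and `params`.
#' @export
filter_incomplete <- function(table, required_vignettes = NULL) {
  if (nrow(table) == 0) stop("empty rating table", call. = FALSE)
  if (is.null(required_vignettes)) {
    required_vignettes <- sort(unique(table$vignette_id))
  }
  required_vignettes <- as.integer(required_vignettes)
  if (length(required_vignettes) == 0) {
    stop("required vignette set is empty", call. = FALSE)
  }
  items <- sort(unique(table$item_id))
  need <- length(required_vignettes) * length(items)

  cover <- tibble::as_tibble(table) |>
    dplyr::group_by(.data$rater_id, .data$physician_id) |>
    dplyr::summarise(
      n_cells = sum(.data$vignette_id %in% required_vignettes),
      .groups = "drop_last"
    ) |>
    dplyr::summarise(complete = all(.data$n_cells == need), .groups = "drop")

  removed <- cover$rater_id[!cover$complete]
  kept <- restitch_table(
    dplyr::filter(tibble::as_tibble(table), !.data$rater_id %in% removed),
    table
  )
  qc_fragment(kept, removed, "incomplete",
              list(required_vignettes = required_vignettes))
}

#' Remove raters using too few response options
#'
#' Raters whose entire set of ratings uses fewer than `min_distinct`
#' distinct scale values are removed: using 2 or fewer of the 5 response
#' options is read as a sign of inattention (straight-lining).
#'
#' @param table A [rating_table()].
#' @param min_distinct Minimum number of distinct scale values a retained
#'   rater must have used (default 3, i.e. raters using 2 or fewer are
#'   dropped).
#' @return Same shape as [filter_incomplete()].
#' @export
filter_low_range <- function(table, min_distinct = 3L) {
  scale_size <- attr(table, "scale_max") - attr(table, "scale_min") + 1L
  if (min_distinct < 1L || min_distinct > scale_size) {
    stop("min_distinct must lie in [1, ", scale_size, "]", call. = FALSE)
  }
  usage <- tibble::as_tibble(table) |>
    dplyr::group_by(.data$rater_id) |>
    dplyr::summarise(n_used = dplyr::n_distinct(.data$rating),
                     .groups = "drop")
  removed <- usage$rater_id[usage$n_used < min_distinct]
  kept <- restitch_table(
    dplyr::filter(tibble::as_tibble(table), !.data$rater_id %in% removed),
    table
  )
  qc_fragment(kept, removed, "low_range", list(min_distinct = min_distinct))
}

# Raters are grouped by the set of physicians they rated: a crossed panel
# forms one group, batch-based panels one group per batch ("their task").
task_groups <- function(table) {
  tibble::as_tibble(table) |>
    dplyr::distinct(.data$rater_id, .data$physician_id) |>
    dplyr::group_by(.data$rater_id) |>
    dplyr::summarise(
      task = paste(sort(unique(.data$physician_id)), collapse = "|"),
      .groups = "drop"
    )
}

# Cells x raters matrix of raw item ratings over the cells shared by all
# raters in the group.
group_matrix <- function(records) {
  wide <- records |>
    dplyr::select("rater_id", "physician_id", "vignette_id", "item_id",
                  "rating") |>
    tidyr::pivot_wider(names_from = "rater_id", values_from = "rating") |>
    dplyr::select(-"physician_id", -"vignette_id", -"item_id")
  mat <- as.matrix(wide)
  mat[stats::complete.cases(mat), , drop = FALSE]
}

#' Remove raters who depress their task's inter-rater reliability
#'
#' For each task group (raters sharing the same set of physicians), the
#' panel consistency statistic is computed with all raters and then leave
#' one out for each rater. A rater whose removal raises the statistic by
#' at least `drop_threshold` is an outlier. Flagged raters are removed
#' sequentially, worst offender first, re-evaluating after each removal,
#' so the procedure is deterministic and does not over-delete. Groups left
#' with fewer than 3 raters cannot be evaluated and are retained as-is
#' (with a warning).
#'
#' @param table A [rating_table()].
#' @param drop_threshold Minimum leave-one-out increase in the statistic
#'   that flags a rater (default 0.1).
#' @param statistic Panel consistency statistic: `"alpha"` (default), a
#'   Cronbach-type coefficient treating raters as items over the group's
#'   (physician, vignette, item) score vectors, or `"mean_cor"`, the mean
#'   pairwise inter-rater correlation. Pluggable because different
#'   platforms report different "interrater reliability" statistics.
#' @return Same shape as [filter_incomplete()]; `params` records the
#'   statistic used.
#' @export
filter_irr_outliers <- function(table, drop_threshold = 0.1,
                                statistic = c("alpha", "mean_cor")) {
  statistic <- match.arg(statistic)
  if (drop_threshold <= 0) {
    stop("drop_threshold must be positive", call. = FALSE)
  }
  groups <- task_groups(table)
  records <- dplyr::left_join(tibble::as_tibble(table), groups,
                              by = "rater_id")
  removed <- character(0)
  small_groups <- FALSE

  for (task in sort(unique(groups$task))) {
    grp <- dplyr::filter(records, .data$task == !!task)
    active <- sort(unique(grp$rater_id))
    if (length(active) < 3) {
      small_groups <- TRUE
      next
    }
    repeat {
      if (length(active) < 3) break
      mat <- group_matrix(dplyr::filter(grp, .data$rater_id %in% active))
      mat <- mat[, active, drop = FALSE]
      stat_all <- panel_statistic(mat, statistic)
      deltas <- vapply(seq_along(active), function(j) {
        panel_statistic(mat[, -j, drop = FALSE], statistic) - stat_all
      }, numeric(1))
      if (all(!is.finite(deltas)) || max(deltas, na.rm = TRUE) < drop_threshold) {
        break
      }
      worst <- active[which.max(deltas)]  # ties: first in sorted id order
      removed <- c(removed, worst)
      active <- setdiff(active, worst)
    }
  }
  if (small_groups) {
    warning("some task groups had fewer than 3 raters; ",
            "leave-one-out screening skipped for them", call. = FALSE)
  }
  kept <- restitch_table(
    dplyr::filter(tibble::as_tibble(table), !.data$rater_id %in% removed),
    table
  )
  qc_fragment(kept, removed, "irr_outlier",
              list(drop_threshold = drop_threshold, statistic = statistic))
}

#' Run the full rater quality-control pass
#'
#' Applies the three screens in the fixed order incomplete -> low-range ->
#' reliability outlier, each operating on the survivors of the previous
#' one, and composes a [qc_report].
#'
#' @param table A [rating_table()].
#' @param required_vignettes Passed to [filter_incomplete()].
#' @param min_distinct Passed to [filter_low_range()].
#' @param drop_threshold,statistic Passed to [filter_irr_outliers()].
#' @return A list with `table` (the cleaned [rating_table()]) and `report`
#'   (a `qc_report`).
#' @export
run_qc <- function(table, required_vignettes = NULL, min_distinct = 3L,
                   drop_threshold = 0.1,
                   statistic = c("alpha", "mean_cor")) {
  statistic <- match.arg(statistic)
  n_recruited <- dplyr::n_distinct(table$rater_id)

  f1 <- filter_incomplete(table, required_vignettes)
  f2 <- filter_low_range(f1$table, min_distinct)
  f3 <- filter_irr_outliers(f2$table, drop_threshold, statistic)

  removed_all <- c(f1$removed, f2$removed, f3$removed)
  report <- structure(
    list(removed_incomplete = f1$removed,
         removed_low_range = f2$removed,
         removed_outlier = f3$removed,
         n_recruited = n_recruited,
         n_retained = n_recruited - length(removed_all),
         params = list(incomplete = f1$params, low_range = f2$params,
                       irr_outlier = f3$params)),
    class = "qc_report")
  list(table = f3$table, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  recruited: %d, retained: %d\n", x$n_recruited, x$n_retained))
  cat(sprintf("  removed incomplete:   %d %s\n",
              length(x$removed_incomplete),
              paste0("(", paste(x$removed_incomplete, collapse = ", "), ")")))
  cat(sprintf("  removed low-range:    %d %s\n", length(x$removed_low_range),
              paste0("(", paste(x$removed_low_range, collapse = ", "), ")")))
  cat(sprintf("  removed IRR outliers: %d %s\n", length(x$removed_outlier),
              paste0("(", paste(x$removed_outlier, collapse = ", "), ")")))
  cat(sprintf("  outlier statistic: %s, drop threshold: %g\n",
              x$params$irr_outlier$statistic,
              x$params$irr_outlier$drop_threshold))
  invisible(x)
}
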