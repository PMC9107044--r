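#' Aggregate item ratings to vignette-level scores
#'
#' The unit of all reliability analysis is the vignette-level score: the
#' arithmetic mean of a rater's item ratings for one physician on one
#' vignette, with every item weighted equally. Each (rater, physician,
#' vignette) cell must carry the table's complete item set; partially
#' rated cells are an error, never silently averaged (quality control
#' guarantees completeness upstream).
#'
#' @param table A [rating_table()].
#' @return A tibble with columns `rater_id`, `rater_group`,
#'   `physician_id`, `vignette_id`, `score`.
#' @export
vignette_scores <- function(table) {
  if (nrow(table) == 0) stop("empty rating table", call. = FALSE)
  items <- sort(unique(table$item_id))
  scored <- tibble::as_tibble(table) |>
    dplyr::group_by(.data$rater_id, .data$rater_group, .data$physician_id,
                    .data$vignette_id) |>
    dplyr::summarise(score = mean(.data$rating), n_items = dplyr::n(),
                     .groups = "drop")
  bad <- dplyr::filter(scored, .data$n_items != length(items))
  if (nrow(bad) > 0) {
    stop("incomplete item set (expected ", length(items), " items) in cell(s): ",
         paste(utils::head(
           paste0("(", bad$rater_id, ", ", bad$physician_id, ", v",
                  bad$vignette_id, ": ", bad$n_items, " items)"), 5),
           collapse = ", "),
         call. = FALSE)
  }
  dplyr::select(scored, -"n_items") |>
    dplyr::arrange(.data$rater_id, .data$physician_id, .data$vignette_id)
}

#' Aggregate vignette scores to overall communication scores
#'
#' At `level = "rater"`, each rater's overall score for a physician is the
#' mean of their vignette scores (every rated vignette must be present for
#' every (rater, physician) pair). At `level = "group"`, the physician's
#' score within a rater group is the mean of that group's raters' overall
#' scores — raters weighted equally, which matters for nested panels where
#' physicians have different rater counts.
#'
#' @param scores A vignette-score tibble from [vignette_scores()].
#' @param level `"rater"` or `"group"`.
#' @return A tibble of overall scores: per (rater, physician) or per
#'   (rater_group, physician).
#' @export
overall_scores <- function(scores, level = c("rater", "group")) {
  level <- match.arg(level)
  n_v <- dplyr::n_distinct(scores$vignette_id)
  by_rater <- scores |>
    dplyr::group_by(.data$rater_id, .data$rater_group, .data$physician_id) |>
    dplyr::summarise(score = mean(.data$score), n_v = dplyr::n(),
                     .groups = "drop")
  if (any(by_rater$n_v != n_v)) {
    bad <- dplyr::filter(by_rater, .data$n_v != n_v)
    stop("missing vignette score(s) for (rater, physician) pair(s): ",
         paste(utils::head(paste0("(", bad$rater_id, ", ", bad$physician_id,
                                  ")"), 5), collapse = ", "),
         call. = FALSE)
  }
  by_rater <- dplyr::select(by_rater, -"n_v")
  if (level == "rater") return(by_rater)
  by_rater |>
    dplyr::group_by(.data$rater_group, .data$physician_id) |>
    dplyr::summarise(score = mean(.data$score), n_raters = dplyr::n(),
                     .groups = "drop")
}
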