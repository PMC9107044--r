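#' Per-physician cell means for group comparison
#'
#' Collapses vignette-level scores to one mean per physician x vignette x
#' rater group (raters averaged within group) — the cell layout consumed
#' by [stringency_anova()]. Used because the two groups have different,
#' non-paired rater panels: the physician is the repeated-measures
#' subject, rated under every (vignette, group) condition.
#'
#' @param scores Vignette-level scores ([vignette_scores()]), possibly
#'   row-bound across groups.
#' @return A tibble with `physician_id`, `vignette_id`, `rater_group`,
#'   `score`.
#' @export
group_cell_means <- function(scores) {
  scores |>
    dplyr::group_by(.data$physician_id, .data$vignette_id,
                    .data$rater_group) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop")
}

# Greenhouse-Geisser epsilon for a within-subject effect: Y is the
# subjects x conditions matrix for that effect, C an orthonormal contrast
# basis (q x k). epsilon = tr(E)^2 / (q * tr(E %*% E)), E = C S C'.
gg_epsilon <- function(Y, C) {
  S <- stats::cov(Y)
  E <- C %*% S %*% t(C)
  q <- nrow(C)
  (sum(diag(E))^2) / (q * sum(E * E))
}

orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  C <- apply(C, 2, function(col) col / sqrt(sum(col^2)))
  t(C)
}

#' Compare rater-group stringency by repeated-measures factorial ANOVA
#'
#' Tests whether one rater group scores systematically lower than the
#' other: a vignette x rater-group factorial ANOVA with physicians as the
#' repeated-measures subjects (both factors within-subject, because every
#' physician is scored under every condition). The effect size `d` is the
#' absolute group mean difference divided by the pooled SD of the two
#' groups' physician-level overall scores.
#'
#' Sphericity correction is off by default; with
#' `sphericity = "greenhouse_geisser"`, effects with more than 1
#' numerator df get Greenhouse-Geisser-adjusted df and p-values.
#'
#' @param cell_scores Output of [group_cell_means()]: one mean score per
#'   physician x vignette x rater group, complete.
#' @param sphericity `"none"` (default) or `"greenhouse_geisser"`.
#' @return An object of class `stringency_result`: tibble `effects`
#'   (effect, df1, df2, statistic, p_value, and epsilon when corrected),
#'   tibble `group_stats` (per-group mean and SD of physician-level
#'   scores), and `d`.
#' @export
stringency_anova <- function(cell_scores,
                             sphericity = c("none", "greenhouse_geisser")) {
  sphericity <- match.arg(sphericity)
  d <- tibble::as_tibble(cell_scores)
  needed <- c("physician_id", "vignette_id", "rater_group", "score")
  if (length(setdiff(needed, names(d))) > 0) {
    stop("cell_scores needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  n_p <- dplyr::n_distinct(d$physician_id)
  n_v <- dplyr::n_distinct(d$vignette_id)
  n_g <- dplyr::n_distinct(d$rater_group)
  if (n_p < 3) stop("need at least 3 physicians", call. = FALSE)
  if (nrow(d) != n_p * n_v * n_g ||
      anyDuplicated(paste(d$physician_id, d$vignette_id, d$rater_group)) > 0) {
    stop("cell_scores must have exactly one score per ",
         "physician x vignette x group cell", call. = FALSE)
  }

  d$physician_id <- factor(d$physician_id)
  d$vignette_id <- factor(d$vignette_id)
  d$rater_group <- factor(d$rater_group)

  fit <- stats::aov(
    score ~ rater_group * vignette_id +
      Error(physician_id / (rater_group * vignette_id)),
    data = d
  )
  sm <- summary(fit)
  pull_effect <- function(stratum, term, label) {
    tab <- sm[[paste0("Error: physician_id:", stratum)]][[1]]
    row <- trimws(rownames(tab)) == term
    tibble::tibble(effect = label,
                   df1 = tab[row, "Df"],
                   df2 = tab[trimws(rownames(tab)) == "Residuals", "Df"],
                   statistic = tab[row, "F value"],
                   p_value = tab[row, "Pr(>F)"])
  }
  effects <- dplyr::bind_rows(
    pull_effect("rater_group", "rater_group", "rater_group"),
    pull_effect("vignette_id", "vignette_id", "vignette"),
    pull_effect("rater_group:vignette_id", "rater_group:vignette_id",
                "rater_group:vignette")
  )

  if (sphericity == "greenhouse_geisser") {
    wide <- d |>
      dplyr::arrange(.data$rater_group, .data$vignette_id) |>
      tidyr::pivot_wider(names_from = c("rater_group", "vignette_id"),
                         values_from = "score") |>
      dplyr::arrange(.data$physician_id)
    Y <- as.matrix(wide[, -1])
    Cg <- orthonormal_contrasts(n_g)
    Cv <- orthonormal_contrasts(n_v)
    avg_g <- kronecker(matrix(1 / n_g, 1, n_g), diag(n_v))
    eps <- c(rater_group = 1,  # 2-level factors: sphericity holds trivially
             vignette = if (n_v > 2) gg_epsilon(Y %*% t(avg_g), Cv) else 1,
             `rater_group:vignette` =
               if (n_v > 2 || n_g > 2)
                 gg_epsilon(Y, kronecker(Cg, Cv)) else 1)
    effects$epsilon <- unname(eps[effects$effect])
    effects$df1 <- effects$df1 * effects$epsilon
    effects$df2 <- effects$df2 * effects$epsilon
    effects$p_value <- stats::pf(effects$statistic, effects$df1,
                                 effects$df2, lower.tail = FALSE)
  }

  overall <- d |>
    dplyr::group_by(.data$rater_group, .data$physician_id) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop")
  group_stats <- overall |>
    dplyr::group_by(.data$rater_group) |>
    dplyr::summarise(mean = mean(.data$score), sd = stats::sd(.data$score),
                     .groups = "drop")
  if (n_g == 2) {
    pooled_sd <- sqrt(mean(group_stats$sd^2))
    eff_d <- abs(diff(group_stats$mean)) / pooled_sd
  } else {
    eff_d <- NA_real_
  }

  structure(list(effects = effects, group_stats = group_stats, d = eff_d,
                 sphericity = sphericity),
            class = "stringency_result")
}

#' @export
print.stringency_result <- function(x, ...) {
  cat("<stringency_result> repeated-measures factorial ANOVA",
      if (x$sphericity != "none") paste0("(", x$sphericity, ")"), "\n")
  print(as.data.frame(x$effects), row.names = FALSE)
  cat("group means (SD) of physician-level scores:\n")
  with(x$group_stats,
       cat(paste0("  ", rater_group, ": ", sprintf("%.2f (%.2f)", mean, sd),
                  collapse = "\n"), "\n"))
  cat(sprintf("effect size d = %.3f\n", x$d))
  invisible(x)
}

#' Rank agreement between two rater groups
#'
#' Pearson correlation of per-physician overall scores between two groups:
#' does a physician's standing relative to peers survive a change of
#' rating panel?
#'
#' @param scores_a,scores_b Tibbles with `physician_id` and `score`
#'   (group-level overall scores, e.g. from
#'   `overall_scores(..., level = "group")`); same physician set, n >= 3.
#' @return An object of class `agreement_result`: `r`, `n`, `p_value`.
#' @export
correlate_groups <- function(scores_a, scores_b) {
  a <- tibble::as_tibble(scores_a)[, c("physician_id", "score")]
  b <- tibble::as_tibble(scores_b)[, c("physician_id", "score")]
  if (!setequal(a$physician_id, b$physician_id)) {
    stop("the two groups must score the same physician set", call. = FALSE)
  }
  merged <- dplyr::inner_join(a, b, by = "physician_id",
                              suffix = c("_a", "_b"))
  if (nrow(merged) < 3) stop("need at least 3 physicians", call. = FALSE)
  if (stats::sd(merged$score_a) == 0 || stats::sd(merged$score_b) == 0) {
    stop("zero variance in one group's scores; correlation undefined",
         call. = FALSE)
  }
  ct <- stats::cor.test(merged$score_a, merged$score_b, method = "pearson")
  structure(list(r = unname(ct$estimate), n = nrow(merged),
                 p_value = ct$p.value),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> Pearson r = %.3f over %d physicians (p = %.3g)\n",
              x$r, x$n, x$p_value))
  invisible(x)
}
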