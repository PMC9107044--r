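#' Variance-component container
#'
#' Holds method-of-moments variance-component estimates for one of the two
#' supported facet designs. Negative raw estimates are truncated to zero
#' for reporting and for all decision-study projection (the standard
#' generalizability-theory convention, and what nonnegativity of variances
#' requires); the raw estimates are retained for diagnostics such as
#' unbiasedness checks.
#'
#' Effect labels are `p` (physician/person), `r` (rater), `v` (vignette),
#' their interactions, and `residual`, which conflates the highest-order
#' interaction with measurement error because the analysis unit is the
#' vignette-level score (one observation per cell, no replication):
#' * `crossed_pvr`: `p`, `r`, `v`, `pr`, `pv`, `rv`, `residual`
#' * `nested_rp_v`: `p`, `v`, `r:p`, `pv`, `residual`
#'
#' @param design `"crossed_pvr"` or `"nested_rp_v"`.
#' @param components Named numeric vector of variance estimates
#'   (score-scale squared units) whose names exactly match the design's
#'   effect labels. May contain negative raw estimates; they are truncated
#'   in the `components` slot and kept in `raw_components`.
#' @param n_physicians,n_vignettes,n_raters Facet sizes of the data the
#'   components were estimated from (optional, recorded for reference).
#' @return An object of class `variance_components` with elements
#'   `design`, `components` (truncated), `raw_components`, `percentages`
#'   (truncated component / truncated total, in percent) and the facet
#'   sizes.
#' @export
variance_components <- function(design = c("crossed_pvr", "nested_rp_v"),
                                components,
                                n_physicians = NA_integer_,
                                n_vignettes = NA_integer_,
                                n_raters = NA_integer_) {
  design <- match.arg(design)
  labels <- effect_labels(design)
  if (!setequal(names(components), labels)) {
    stop("component labels must be exactly {",
         paste(labels, collapse = ", "), "} for design ", design,
         call. = FALSE)
  }
  raw <- components[labels]
  trunc <- pmax(raw, 0)
  total <- sum(trunc)
  # a numerically-zero total (constant data) has no meaningful percentages
  pct <- if (total > 1e-12) 100 * trunc / total else trunc * 0
  structure(list(design = design,
                 components = trunc,
                 raw_components = raw,
                 percentages = pct,
                 n_physicians = as.integer(n_physicians),
                 n_vignettes = as.integer(n_vignettes),
                 n_raters = as.integer(n_raters)),
            class = "variance_components")
}

effect_labels <- function(design) {
  switch(design,
         crossed_pvr = c("p", "r", "v", "pr", "pv", "rv", "residual"),
         nested_rp_v = c("p", "v", "r:p", "pv", "residual"),
         stop("unknown design: ", design, call. = FALSE))
}

#' @export
print.variance_components <- function(x, digits = 3, ...) {
  cat("<variance_components>", x$design, "\n")
  tab <- data.frame(effect = names(x$components),
                    estimate = round(unname(x$components), digits),
                    percentage = round(unname(x$percentages), digits),
                    raw = round(unname(x$raw_components), digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
#' @rdname variance_components
#' @param x A `variance_components` object.
as.data.frame.variance_components <- function(x, ...) {
  data.frame(effect = names(x$components),
             estimate = unname(x$components),
             percentage = unname(x$percentages),
             raw = unname(x$raw_components))
}

check_score_columns <- function(scores) {
  needed <- c("rater_id", "physician_id", "vignette_id", "score")
  miss <- setdiff(needed, names(scores))
  if (length(miss) > 0) {
    stop("score table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

#' Estimate variance components for the fully crossed p x v x r design
#'
#' The G-study for a crossed panel: every rater scores every physician on
#' every vignette, giving a complete three-way random-effects layout with
#' one observation per cell. The seven mean squares of the three-way ANOVA
#' without replication are computed and the expected-mean-squares linear
#' system is solved in closed form:
#' \deqn{\hat\sigma^2_{res} = MS_{pvr}}
#' \deqn{\hat\sigma^2_{pr} = (MS_{pr} - MS_{res})/n_v, \quad
#'       \hat\sigma^2_{pv} = (MS_{pv} - MS_{res})/n_r, \quad
#'       \hat\sigma^2_{rv} = (MS_{rv} - MS_{res})/n_p}
#' \deqn{\hat\sigma^2_{p} = (MS_p - MS_{pr} - MS_{pv} + MS_{res})/(n_v n_r)}
#' and symmetrically for \eqn{\sigma^2_r} and \eqn{\sigma^2_v}.
#'
#' @param scores Vignette-level scores ([vignette_scores()]): one row per
#'   (rater, physician, vignette), complete and balanced.
#' @return A [variance_components()] object; the attribute
#'   `"sums_of_squares"` carries the seven ANOVA sums of squares plus the
#'   total, for diagnostics.
#' @export
estimate_crossed <- function(scores) {
  check_score_columns(scores)
  p <- factor(scores$physician_id)
  v <- factor(scores$vignette_id)
  r <- factor(scores$rater_id)
  n_p <- nlevels(p); n_v <- nlevels(v); n_r <- nlevels(r)
  if (min(n_p, n_v, n_r) < 2) {
    stop("every facet needs at least 2 levels to estimate its variance",
         call. = FALSE)
  }
  if (nrow(scores) != n_p * n_v * n_r ||
      anyDuplicated(paste(p, v, r)) > 0) {
    stop("crossed design requires exactly one score per ",
         "(physician, vignette, rater) cell", call. = FALSE)
  }

  x <- array(NA_real_, dim = c(n_p, n_v, n_r))
  x[cbind(as.integer(p), as.integer(v), as.integer(r))] <- scores$score

  m <- mean(x)
  m_p <- apply(x, 1, mean); m_v <- apply(x, 2, mean); m_r <- apply(x, 3, mean)
  m_pv <- apply(x, c(1, 2), mean)
  m_pr <- apply(x, c(1, 3), mean)
  m_vr <- apply(x, c(2, 3), mean)

  ss <- c(
    p  = n_v * n_r * sum((m_p - m)^2),
    r  = n_p * n_v * sum((m_r - m)^2),
    v  = n_p * n_r * sum((m_v - m)^2),
    pr = n_v * sum((m_pr - outer(m_p, m_r, "+") + m)^2),
    pv = n_r * sum((m_pv - outer(m_p, m_v, "+") + m)^2),
    rv = n_p * sum((m_vr - outer(m_v, m_r, "+") + m)^2),
    residual = sum((sweep(sweep(sweep(x, c(1, 2), m_pv), c(1, 3), m_pr),
                          c(2, 3), m_vr) +
                    outer(outer(m_p, m_v, "+"), m_r, "+") - m)^2)
  )
  df <- c(p = n_p - 1, r = n_r - 1, v = n_v - 1,
          pr = (n_p - 1) * (n_r - 1), pv = (n_p - 1) * (n_v - 1),
          rv = (n_r - 1) * (n_v - 1),
          residual = (n_p - 1) * (n_v - 1) * (n_r - 1))
  ms <- ss / df

  est <- c(
    p  = (ms[["p"]] - ms[["pr"]] - ms[["pv"]] + ms[["residual"]]) / (n_v * n_r),
    r  = (ms[["r"]] - ms[["pr"]] - ms[["rv"]] + ms[["residual"]]) / (n_p * n_v),
    v  = (ms[["v"]] - ms[["pv"]] - ms[["rv"]] + ms[["residual"]]) / (n_p * n_r),
    pr = (ms[["pr"]] - ms[["residual"]]) / n_v,
    pv = (ms[["pv"]] - ms[["residual"]]) / n_r,
    rv = (ms[["rv"]] - ms[["residual"]]) / n_p,
    residual = ms[["residual"]]
  )
  out <- variance_components("crossed_pvr", est,
                             n_physicians = n_p, n_vignettes = n_v,
                             n_raters = n_r)
  attr(out, "sums_of_squares") <- c(ss, total = sum((x - m)^2))
  out
}

# Coefficient of one variance component in the expectation of one T-term
# (uncorrected sum of quadratics): for grouping key g with group sizes m_g
# and component level key l, coef = sum_g sum_l n_{g,l}^2 / m_g.
t_coefficient <- function(gkey, lkey) {
  d <- dplyr::count(tibble::tibble(g = gkey, l = lkey), .data$g, .data$l)
  m <- tapply(d$n, d$g, sum)
  sum(d$n^2 / m[as.character(d$g)])
}

t_value <- function(gkey, y) {
  totals <- tapply(y, gkey, sum)
  sizes <- tapply(y, gkey, length)
  sum(totals^2 / sizes)
}

#' Estimate variance components for the nested (r:p) x v design
#'
#' The G-study for a batch-based panel in which each rater's scores attach
#' to one physician nest: rater nested within physician, crossed with
#' vignette. Estimation is analogous-ANOVA (Henderson Method 1), which
#' handles unequal numbers of raters per physician: the uncorrected sums
#' of quadratics (T-terms) for the groupings \{mean, p, v, r:p, pv,
#' observation\} are computed with unbalance-aware coefficients, the
#' analogous sums of squares are formed as the usual contrasts of
#' T-terms, and the resulting 5 x 5 linear system in the components
#' \{p, v, r:p, pv, residual\} is solved. On balanced data this reduces
#' exactly to the balanced-nested expected-mean-squares solution.
#'
#' When a table declared nested contains raters spanning several
#' physicians (batch designs where each rater scored a small batch), each
#' (rater, physician) pairing is treated as a distinct nested pseudo-rater,
#' with a warning — the only reading under which the (r:p) x v model
#' applies to batch data.
#'
#' @param scores Vignette-level scores: one row per (rater, physician,
#'   vignette); every (rater, physician) pair must cover every vignette.
#' @return A [variance_components()] object; the attribute
#'   `"sums_of_squares"` carries the five analogous sums of squares.
#' @export
estimate_nested <- function(scores) {
  check_score_columns(scores)
  scores <- tibble::as_tibble(scores)

  span <- dplyr::distinct(scores, .data$rater_id, .data$physician_id) |>
    dplyr::count(.data$rater_id)
  if (any(span$n > 1)) {
    warning("raters span multiple physicians; treating each ",
            "(rater, physician) pairing as a distinct nested pseudo-rater",
            call. = FALSE)
  }
  pr_id <- paste(scores$rater_id, scores$physician_id, sep = "\r")

  p <- factor(scores$physician_id)
  v <- factor(scores$vignette_id)
  r <- factor(pr_id)
  n_p <- nlevels(p); n_v <- nlevels(v)
  if (n_p < 2 || n_v < 2) {
    stop("need at least 2 physicians and 2 vignettes", call. = FALSE)
  }
  nests <- table(sub(".*\r", "", levels(r)))
  if (all(nests < 2)) {
    stop("all physician nests have a single rater; ",
         "the rater-within-physician component is not estimable",
         call. = FALSE)
  }
  per_pair <- table(r)
  if (any(per_pair != n_v) || nrow(scores) != nlevels(r) * n_v) {
    stop("every (rater, physician) pair must have exactly one score ",
         "per vignette", call. = FALSE)
  }

  y <- scores$score
  pv <- paste(p, v, sep = "\r")
  obs <- seq_along(y)
  one <- rep(1L, length(y))

  groupings <- list(mu = one, p = p, v = v, r = r, pv = pv, x = obs)
  comps <- list(p = p, v = v, `r:p` = r, pv = pv, residual = obs)

  tvals <- vapply(groupings, t_value, numeric(1), y = y)
  # coefficient matrix of E[T] in the components (plus an implicit mu^2
  # column equal to N in every row, which cancels in the SS contrasts)
  tcoef <- matrix(0, nrow = length(groupings), ncol = length(comps),
                  dimnames = list(names(groupings), names(comps)))
  n_obs <- length(y)
  for (gi in names(groupings)) {
    for (ci in names(comps)) {
      tcoef[gi, ci] <-
        if (gi == "x") n_obs
        else if (ci == "residual") length(unique(groupings[[gi]]))
        else t_coefficient(groupings[[gi]], comps[[ci]])
    }
  }

  # analogous sums of squares as contrasts of T-terms (rows sum to zero,
  # so the mu^2 term drops out)
  contrasts <- rbind(
    p        = c(mu = -1, p = 1,  v = 0,  r = 0,  pv = 0, x = 0),
    v        = c(mu = -1, p = 0,  v = 1,  r = 0,  pv = 0, x = 0),
    `r:p`    = c(mu = 0,  p = -1, v = 0,  r = 1,  pv = 0, x = 0),
    pv       = c(mu = 1,  p = -1, v = -1, r = 0,  pv = 1, x = 0),
    residual = c(mu = 0,  p = 1,  v = 0,  r = -1, pv = -1, x = 1)
  )
  ss <- drop(contrasts %*% tvals)
  coef_mat <- contrasts %*% tcoef

  est <- drop(solve(coef_mat, ss))
  names(est) <- colnames(coef_mat)

  out <- variance_components("nested_rp_v", est,
                             n_physicians = n_p, n_vignettes = n_v,
                             n_raters = nlevels(r))
  attr(out, "sums_of_squares") <- ss
  out
}

#' Estimate variance components, dispatching on the design
#'
#' Convenience wrapper: infers (or takes) the facet structure and calls
#' [estimate_crossed()] or [estimate_nested()].
#'
#' @param scores Vignette-level scores.
#' @param design `"crossed_pvr"`, `"nested_rp_v"`, or `NULL` to infer:
#'   crossed when every rater scored every physician.
#' @return A [variance_components()] object.
#' @export
estimate_components <- function(scores, design = NULL) {
  if (is.null(design)) {
    pairs <- dplyr::distinct(tibble::as_tibble(scores), .data$rater_id,
                             .data$physician_id)
    crossed <- nrow(pairs) ==
      dplyr::n_distinct(pairs$rater_id) * dplyr::n_distinct(pairs$physician_id)
    design <- if (crossed) "crossed_pvr" else "nested_rp_v"
  }
  switch(design,
         crossed_pvr = estimate_crossed(scores),
         nested_rp_v = estimate_nested(scores),
         stop("unknown design: ", design, call. = FALSE))
}
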