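#' Project reliability for a hypothetical panel design (D-study)
#'
#' A decision study asks: given the variance components estimated in a
#' G-study, how reliable would mean scores be if each physician were rated
#' by a panel of `n_raters` raters on `n_vignettes` vignettes? Two error
#' variances are projected:
#'
#' * relative error \eqn{\sigma^2(\delta)} — the facets that interact with
#'   the person, which disturb rank ordering. Crossed design:
#'   \eqn{\sigma^2_{pr}/n'_r + \sigma^2_{pv}/n'_v +
#'        \sigma^2_{res}/(n'_r n'_v)}. Nested design:
#'   \eqn{\sigma^2_{r:p}/n'_r + \sigma^2_{pv}/n'_v +
#'        \sigma^2_{res}/(n'_r n'_v)}.
#' * absolute error \eqn{\sigma^2(\Delta)} — adds the main effects of the
#'   measurement facets (crossed: \eqn{\sigma^2_r/n'_r + \sigma^2_v/n'_v +
#'   \sigma^2_{rv}/(n'_r n'_v)}; nested: \eqn{\sigma^2_v/n'_v}).
#'
#' The generalizability coefficient (for relative, rank-ordering
#' decisions) is \eqn{E\rho^2 = \sigma^2_p /(\sigma^2_p +
#' \sigma^2(\delta))} and the dependability coefficient (for absolute,
#' criterion-referenced decisions) is \eqn{\Phi = \sigma^2_p/(\sigma^2_p +
#' \sigma^2(\Delta))}; always \eqn{\Phi \le E\rho^2}. The projection keeps
#' the G-study's facet structure: a crossed study projects crossed panels,
#' a nested study nested panels.
#'
#' @param components A [variance_components()] object (truncated
#'   components are used).
#' @param n_raters,n_vignettes Hypothetical panel size and task length
#'   (positive integers).
#' @return A one-row tibble with the design, the panel sizes, both error
#'   variances, `g_coef` (\eqn{E\rho^2}) and `phi_coef` (\eqn{\Phi}).
#' @export
#' @examples
#' vc <- variance_components("crossed_pvr",
#'   c(p = 0.214, r = 0.311, v = 0.017, pr = 0.008, pv = 0.210,
#'     rv = 0.012, residual = 0.420))
#' g_coefficient(vc, n_raters = 8, n_vignettes = 3)
g_coefficient <- function(components, n_raters, n_vignettes) {
  stopifnot(inherits(components, "variance_components"))
  n_r <- as.numeric(n_raters)
  n_v <- as.numeric(n_vignettes)
  if (length(n_r) != 1 || length(n_v) != 1 || n_r < 1 || n_v < 1 ||
      n_r != round(n_r) || n_v != round(n_v)) {
    stop("n_raters and n_vignettes must be single positive integers",
         call. = FALSE)
  }
  s <- components$components
  if (components$design == "crossed_pvr") {
    rel <- s[["pr"]] / n_r + s[["pv"]] / n_v + s[["residual"]] / (n_r * n_v)
    abs_ <- rel + s[["r"]] / n_r + s[["v"]] / n_v + s[["rv"]] / (n_r * n_v)
  } else {
    rel <- s[["r:p"]] / n_r + s[["pv"]] / n_v + s[["residual"]] / (n_r * n_v)
    abs_ <- rel + s[["v"]] / n_v
  }
  sp <- s[["p"]]
  g <- if (sp + rel > 0) sp / (sp + rel) else 0
  phi <- if (sp + abs_ > 0) sp / (sp + abs_) else 0
  tibble::tibble(design = components$design,
                 n_raters = as.integer(n_r), n_vignettes = as.integer(n_v),
                 rel_error_var = rel, abs_error_var = abs_,
                 g_coef = g, phi_coef = phi)
}

#' Evaluate a D-study over a grid of panel designs
#'
#' Runs [g_coefficient()] on the full cartesian grid of rater and vignette
#' counts; both coefficients are non-decreasing along each axis.
#'
#' @param components A [variance_components()] object.
#' @param raters,vignettes Non-empty vectors of positive integers.
#' @return A tibble with one row per (n_raters, n_vignettes) combination.
#' @export
dstudy_grid <- function(components, raters, vignettes) {
  if (length(raters) == 0 || length(vignettes) == 0) {
    stop("rater and vignette ranges must be non-empty", call. = FALSE)
  }
  grid <- tidyr::expand_grid(n_raters = sort(unique(as.integer(raters))),
                             n_vignettes = sort(unique(as.integer(vignettes))))
  dplyr::bind_rows(
    mapply(function(r, v) g_coefficient(components, r, v),
           grid$n_raters, grid$n_vignettes, SIMPLIFY = FALSE)
  )
}

#' Plot a D-study grid
#'
#' Reliability projection curves: G coefficient against panel size, one
#' line per number of vignettes.
#'
#' @param grid Output of [dstudy_grid()].
#' @param coefficient `"g_coef"` or `"phi_coef"`.
#' @return A ggplot object.
#' @export
plot_dstudy_grid <- function(grid, coefficient = c("g_coef", "phi_coef")) {
  coefficient <- match.arg(coefficient)
  ggplot2::ggplot(grid,
                  ggplot2::aes(x = .data$n_raters,
                               y = .data[[coefficient]],
                               colour = factor(.data$n_vignettes))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "number of raters",
                  y = if (coefficient == "g_coef")
                    "G coefficient (relative)" else "dependability (absolute)",
                  colour = "vignettes") +
    ggplot2::theme_minimal()
}
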