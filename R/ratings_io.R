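#' Construct a validated rating table
#'
#' A rating table is the analysis substrate of the package: one row per
#' rater x physician x vignette x item, with an integer rating on a bounded
#' ordinal (Likert-type) scale. The constructor validates scale bounds,
#' integer-ness, and key uniqueness, and attaches the scale as attributes so
#' that every downstream computation knows the bounds without re-declaring
#' them.
#'
#' @param records A data frame with columns `rater_id`, `rater_group`,
#'   `physician_id`, `vignette_id`, `item_id`, `rating`. Identifier columns
#'   are coerced to character; `vignette_id`, `item_id` and `rating` must be
#'   coercible to integer without loss.
#' @param scale_min,scale_max Integer bounds of the rating scale
#'   (default 1--5, the five verbal anchors "Poor ... Excellent" /
#'   "Not at all ... Completely" stored as their ordinal positions).
#' @param provenance Free-text note recording where the records came from.
#' @return A tibble of class `rating_table` with attributes `scale_min`,
#'   `scale_max` and `provenance`.
#' @export
#' @examples
#' tab <- rating_table(data.frame(
#'   rater_id = "r1", rater_group = "advocate", physician_id = "p1",
#'   vignette_id = 1L, item_id = 1:6, rating = 3L
#' ))
#' tab
rating_table <- function(records, scale_min = 1L, scale_max = 5L,
                         provenance = "") {
  required <- c("rater_id", "rater_group", "physician_id",
                "vignette_id", "item_id", "rating")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("rating table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  scale_min <- as.integer(scale_min)
  scale_max <- as.integer(scale_max)
  if (scale_min >= scale_max) {
    stop("scale_min must be strictly below scale_max", call. = FALSE)
  }

  tab <- tibble::as_tibble(records[required])
  tab$rater_id <- as.character(tab$rater_id)
  tab$rater_group <- as.character(tab$rater_group)
  tab$physician_id <- as.character(tab$physician_id)
  for (col in c("vignette_id", "item_id")) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    if (anyNA(v) && !all(is.na(tab[[col]]) == is.na(v))) {
      stop(col, " must be integer-valued", call. = FALSE)
    }
    tab[[col]] <- v
  }

  raw_rating <- tab$rating
  num <- suppressWarnings(as.numeric(raw_rating))
  bad_numeric <- which(is.na(num) | num != round(num))
  if (length(bad_numeric) > 0) {
    stop("non-integer rating(s) at row(s): ",
         paste(utils::head(bad_numeric, 10), collapse = ", "),
         call. = FALSE)
  }
  tab$rating <- as.integer(round(num))
  out_of_range <- which(tab$rating < scale_min | tab$rating > scale_max)
  if (length(out_of_range) > 0) {
    stop("rating(s) outside the declared ", scale_min, "-", scale_max,
         " scale at row(s): ",
         paste(utils::head(out_of_range, 10), collapse = ", "),
         call. = FALSE)
  }

  key <- paste(tab$rater_id, tab$physician_id, tab$vignette_id, tab$item_id,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (rater, physician, vignette, item) key(s) at row(s): ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  }

  structure(tab,
            class = c("rating_table", class(tibble::tibble())),
            scale_min = scale_min, scale_max = scale_max,
            provenance = provenance)
}

#' @export
print.rating_table <- function(x, ...) {
  cat(sprintf("<rating_table> %d records | %d raters, %d physicians, %d vignettes, %d items | scale %d-%d\n",
              nrow(x), dplyr::n_distinct(x$rater_id),
              dplyr::n_distinct(x$physician_id),
              dplyr::n_distinct(x$vignette_id),
              dplyr::n_distinct(x$item_id),
              attr(x, "scale_min"), attr(x, "scale_max")))
  if (nzchar(attr(x, "provenance") %||% "")) {
    cat("provenance:", attr(x, "provenance"), "\n")
  }
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Scale bounds of a rating table
#'
#' @param table A [rating_table()].
#' @return Named integer vector `c(min = , max = )`.
#' @export
scale_bounds <- function(table) {
  c(min = attr(table, "scale_min"), max = attr(table, "scale_max"))
}

# Rebuild a rating_table around a plain tibble produced by dplyr verbs,
# keeping the template's scale and provenance. No re-validation: callers
# only subset rows.
restitch_table <- function(records, template) {
  structure(tibble::as_tibble(records),
            class = class(template),
            scale_min = attr(template, "scale_min"),
            scale_max = attr(template, "scale_max"),
            provenance = attr(template, "provenance"))
}

#' Read a long-format ratings file
#'
#' Reads the package's interchange format: UTF-8, comma-delimited, header
#' `rater_id,rater_group,physician_id,vignette_id,item_id,rating`. Extra
#' columns (for example a `comment` column holding free-text responses) are
#' accepted and ignored; only the six analytic columns are kept. Row order
#' carries no meaning: all downstream results are invariant to it.
#'
#' @param path Path to the CSV file.
#' @param scale_min,scale_max Declared bounds of the rating scale.
#' @return A validated [rating_table()].
#' @export
read_ratings <- function(path, scale_min = 1L, scale_max = 5L) {
  if (!file.exists(path)) {
    stop("ratings file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  rating_table(raw, scale_min = scale_min, scale_max = scale_max,
               provenance = path)
}

#' Write a rating table to a long-format CSV file
#'
#' Inverse of [read_ratings()]: the written file re-reads to an equal table.
#' Missing cells are represented by absent rows, never by sentinel values.
#'
#' @param table A [rating_table()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(table, path) {
  stopifnot(inherits(table, "rating_table"))
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' Declare a measurement design
#'
#' The two supported facet structures are the fully crossed
#' `crossed_pvr` design (every rater rates every physician on every
#' vignette, p x v x r) and the nested `nested_rp_v` design (each rater's
#' ratings attach to a single physician, crossed with vignette,
#' (r:p) x v). The structure determines which variance-component estimator
#' applies.
#'
#' @param structure `"crossed_pvr"` or `"nested_rp_v"`.
#' @param n_physicians,n_vignettes Facet sizes.
#' @param n_raters For the crossed design, the panel size; for the nested
#'   design, the total number of (pseudo-)raters across nests.
#' @param raters_per_physician For the nested design only: named integer
#'   vector of nest sizes, one entry per physician.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(structure = c("crossed_pvr", "nested_rp_v"),
                        n_physicians, n_vignettes, n_raters,
                        raters_per_physician = NULL) {
  structure <- match.arg(structure)
  spec <- list(structure = structure,
               n_physicians = as.integer(n_physicians),
               n_vignettes = as.integer(n_vignettes),
               n_raters = as.integer(n_raters),
               raters_per_physician = raters_per_physician)
  if (any(c(spec$n_physicians, spec$n_vignettes, spec$n_raters) < 1L)) {
    stop("all facet sizes must be positive", call. = FALSE)
  }
  class(spec) <- "design_spec"
  spec
}

#' @export
print.design_spec <- function(x, ...) {
  label <- switch(x$structure,
                  crossed_pvr = "fully crossed p x v x r",
                  nested_rp_v = "rater nested in physician, (r:p) x v")
  cat(sprintf("<design_spec> %s | %d physicians, %d vignettes, %d raters\n",
              label, x$n_physicians, x$n_vignettes, x$n_raters))
  if (!is.null(x$raters_per_physician)) {
    cat("raters per physician:",
        paste(x$raters_per_physician, collapse = " "), "\n")
  }
  invisible(x)
}

#' Infer the facet design from a rating table
#'
#' Returns the crossed design when every rater rated every physician in the
#' table, and the nested design otherwise (each rater linked to a subset of
#' physicians, e.g. one batch). Invariant to row order.
#'
#' @param table A [rating_table()].
#' @return A [design_spec()].
#' @export
infer_design <- function(table) {
  if (nrow(table) == 0) stop("cannot infer a design from an empty table",
                             call. = FALSE)
  pairs <- dplyr::distinct(tibble::as_tibble(table), .data$rater_id,
                           .data$physician_id)
  n_r <- dplyr::n_distinct(pairs$rater_id)
  n_p <- dplyr::n_distinct(pairs$physician_id)
  n_v <- dplyr::n_distinct(table$vignette_id)

  raters_per_phys <- table(pairs$physician_id)
  if (all(raters_per_phys < 2L)) {
    stop("design not estimable: no physician was rated by 2 or more raters",
         call. = FALSE)
  }

  if (nrow(pairs) == n_r * n_p) {
    design_spec("crossed_pvr", n_physicians = n_p, n_vignettes = n_v,
                n_raters = n_r)
  } else {
    rpp <- as.integer(raters_per_phys)
    names(rpp) <- names(raters_per_phys)
    design_spec("nested_rp_v", n_physicians = n_p, n_vignettes = n_v,
                n_raters = n_r, raters_per_physician = rpp)
  }
}

#' Read or write a design declaration as YAML
#'
#' The declaration carries keys `structure`, `scale: {min, max}` and
#' optional facet sizes (`n_physicians`, `n_vignettes`, `n_raters`).
#'
#' @param path YAML file path.
#' @return For `read_design`, a list with elements `spec` (a
#'   [design_spec()] or `NULL` when sizes are omitted), `structure` and
#'   `scale`.
#' @export
read_design <- function(path) {
  decl <- yaml::read_yaml(path)
  if (is.null(decl$structure) ||
      !decl$structure %in% c("crossed_pvr", "nested_rp_v")) {
    stop("design declaration needs structure 'crossed_pvr' or 'nested_rp_v'",
         call. = FALSE)
  }
  scale <- list(min = decl$scale$min %||% 1L, max = decl$scale$max %||% 5L)
  spec <- NULL
  if (!is.null(decl$n_physicians)) {
    spec <- design_spec(decl$structure, decl$n_physicians, decl$n_vignettes,
                        decl$n_raters)
  }
  list(structure = decl$structure, scale = scale, spec = spec)
}

#' @rdname read_design
#' @param spec A [design_spec()].
#' @param scale_min,scale_max Scale bounds to record alongside the design.
#' @export
write_design <- function(spec, path, scale_min = 1L, scale_max = 5L) {
  decl <- list(structure = spec$structure,
               scale = list(min = as.integer(scale_min),
                            max = as.integer(scale_max)),
               n_physicians = spec$n_physicians,
               n_vignettes = spec$n_vignettes,
               n_raters = spec$n_raters)
  yaml::write_yaml(decl, path)
  invisible(path)
}
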