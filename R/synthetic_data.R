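#' Reference variance components for the two panel designs
#'
#' The generator's default ground truth: variance-component maps typical
#' of communication-skill rating panels — a fully crossed advocate-style
#' panel (large rater stringency and residual variance, small vignette
#' effects) and a nested crowdsourced-layperson-style panel (large
#' rater-within-physician variance). These also serve as convenient inputs
#' for worked D-study examples.
#'
#' @param design `"crossed_pvr"` or `"nested_rp_v"`.
#' @return A named numeric vector matching [effect_labels()] for the design.
#' @export
default_true_components <- function(design = c("crossed_pvr", "nested_rp_v")) {
  design <- match.arg(design)
  switch(design,
         crossed_pvr = c(p = 0.214, r = 0.311, v = 0.017, pr = 0.008,
                         pv = 0.210, rv = 0.012, residual = 0.420),
         nested_rp_v = c(p = 0.121, v = 0.007, `r:p` = 0.368, pv = 0.074,
                         residual = 0.258))
}

#' Configure a synthetic rating panel
#'
#' Describes a panel to simulate: the facet design, its sizes, the true
#' variance components at the vignette-score level, the Likert
#' discretization, and an optional contamination spec injecting the rater
#' pathologies the QC screens target. Defaults emulate a communication
#' -assessment study layout: 20 physicians x 3 vignettes x 6 items; a
#' crossed panel of 8 raters, or a nested panel of 42 raters each rating
#' one batch of 4 physicians; grand mean 3.55 with a -0.36 stringency
#' shift for the crossed (advocate-style) panel.
#'
#' @param design `"crossed"` (p x v x r) or `"nested"` ((r:p) x v batch
#'   panel).
#' @param true_components Named numeric vector of generating variance
#'   components at the vignette-score level; defaults to
#'   [default_true_components()] for the design.
#' @param n_physicians,n_vignettes,n_items Facet sizes.
#' @param n_raters Number of genuine (uncontaminated) raters.
#' @param batch_size Nested design only: physicians per rater batch;
#'   physicians are partitioned into consecutive batches and raters
#'   assigned round-robin, so batch panels differ in size when counts do
#'   not divide evenly (a realistic source of unbalance).
#' @param grand_mean Latent grand mean, scale units.
#' @param group_shift Added to every latent score of this panel (a group
#'   stringency shift); default -0.36 for the crossed panel, 0 otherwise.
#' @param rater_group Group label stamped on the records.
#' @param item_sd SD of the independent item-level noise around the cell
#'   score. The configured `residual` component is the *total* residual at
#'   the vignette-score level, so the cell-level residual effect is drawn
#'   with variance `residual - item_sd^2 / n_items` (an error if
#'   negative): item noise is carved out of the residual, not added on
#'   top, and vignette scores carry exactly the configured components for
#'   any `item_sd`. Default 1.0 — the six items probe different
#'   constructs (honesty, empathy, accountability, ...), so a rater's
#'   item ratings within one vignette realistically spread about one
#'   scale point.
#' @param item_effect_sd SD of shared item main effects: the instrument's
#'   items probe different constructs and differ systematically in mean
#'   (every rater scores e.g. the empathy item lower than the overall
#'   item). Drawn once per panel and centered to sum to zero across the
#'   item set, so vignette-level scores — and therefore every variance
#'   component — are exactly unaffected. Default 0.7.
#' @param discretize If `TRUE` (default), item ratings are rounded to the
#'   nearest integer and clipped to the scale, mimicking Likert responses.
#' @param scale_min,scale_max Scale bounds used when discretizing.
#' @param n_incomplete,n_straightline,n_anticorrelated Counts of
#'   contaminated raters to inject on top of `n_raters`: raters missing
#'   one vignette entirely, raters giving one constant rating, and raters
#'   whose ratings are reflected about the scale midpoint.
#' @param seed Integer seed fixing the entire output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(design = c("crossed", "nested"),
                              true_components = NULL,
                              n_physicians = 20L, n_vignettes = 3L,
                              n_items = 6L,
                              n_raters = NULL, batch_size = 4L,
                              grand_mean = 3.55, group_shift = NULL,
                              rater_group = NULL,
                              item_sd = 1.0, item_effect_sd = 0.7,
                              discretize = TRUE,
                              scale_min = 1L, scale_max = 5L,
                              n_incomplete = 0L, n_straightline = 0L,
                              n_anticorrelated = 0L,
                              seed = 1L) {
  design <- match.arg(design)
  structure_name <- if (design == "crossed") "crossed_pvr" else "nested_rp_v"
  if (is.null(true_components)) {
    true_components <- default_true_components(structure_name)
  }
  labels <- effect_labels(structure_name)
  if (!setequal(names(true_components), labels)) {
    stop("true_components labels must be {", paste(labels, collapse = ", "),
         "} for the ", design, " design", call. = FALSE)
  }
  if (any(true_components < 0)) {
    stop("true variance components must be non-negative", call. = FALSE)
  }
  if (is.null(n_raters)) n_raters <- if (design == "crossed") 8L else 42L
  if (is.null(group_shift)) group_shift <- if (design == "crossed") -0.36 else 0
  if (is.null(rater_group)) {
    rater_group <- if (design == "crossed") "advocate" else "layperson"
  }
  counts <- c(n_physicians, n_vignettes, n_items, n_raters, batch_size)
  if (any(counts < 1)) stop("all counts must be positive", call. = FALSE)
  if (item_sd^2 / n_items > true_components[["residual"]] + 1e-12) {
    stop("item_sd^2 / n_items exceeds the residual component: the ",
         "item-level noise is carved out of the vignette-level residual ",
         "and cannot be larger than it", call. = FALSE)
  }

  cfg <- list(design = design, structure = structure_name,
              true_components = true_components[labels],
              n_physicians = as.integer(n_physicians),
              n_vignettes = as.integer(n_vignettes),
              n_items = as.integer(n_items),
              n_raters = as.integer(n_raters),
              batch_size = as.integer(batch_size),
              grand_mean = grand_mean, group_shift = group_shift,
              rater_group = rater_group,
              item_sd = item_sd, item_effect_sd = item_effect_sd,
              discretize = isTRUE(discretize),
              scale_min = as.integer(scale_min),
              scale_max = as.integer(scale_max),
              n_incomplete = as.integer(n_incomplete),
              n_straightline = as.integer(n_straightline),
              n_anticorrelated = as.integer(n_anticorrelated),
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

pad_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

#' Simulate a rating panel with known ground truth
#'
#' Draws independent zero-mean normal random effects with the configured
#' variances for every effect in the design's decomposition, sums them
#' with the grand mean (plus the group stringency shift) into a latent
#' cell score per (physician, vignette, rater), adds independent item
#' noise, and (optionally) discretizes to the Likert scale by
#' round-to-nearest then clipping. Contaminated raters are injected after
#' generation: incomplete raters lose one vignette entirely,
#' straight-liners are overwritten with a single constant response, and
#' anti-correlated raters have every rating reflected about the scale
#' midpoint. The whole table is a deterministic function of the config
#' (including its seed).
#'
#' @param config A [simulation_config()].
#' @param physician_effects Optional named numeric vector (names
#'   `P001`, `P002`, ...) of latent physician effects to condition on
#'   instead of drawing them — used to simulate several panels rating the
#'   same physicians (see [simulate_paired_panels()]).
#' @return A [rating_table()]; attributes `"truth"` (the config),
#'   `"contaminated"` (the injected rater ids by pathology) and
#'   `"physician_effects"` (the drawn or supplied effects).
#' @export
simulate_panel <- function(config, physician_effects = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(config$seed)
  }
  sc <- config$true_components
  n_p <- config$n_physicians; n_v <- config$n_vignettes
  n_extra <- config$n_incomplete + config$n_straightline +
    config$n_anticorrelated
  n_total_raters <- config$n_raters + n_extra

  phys <- pad_ids("P", n_p)
  raters <- pad_ids("R", n_total_raters)

  if (config$design == "crossed") {
    cells <- tidyr::expand_grid(rater_id = raters, physician_id = phys,
                                vignette_id = seq_len(n_v))
  } else {
    n_batches <- ceiling(n_p / config$batch_size)
    batch_of_phys <- rep(seq_len(n_batches),
                         each = config$batch_size)[seq_len(n_p)]
    batch_of_rater <- rep_len(seq_len(n_batches), n_total_raters)
    assignment <- tibble::tibble(
      rater_id = rep(raters, times = tabulate(batch_of_phys)[batch_of_rater]),
      physician_id = unlist(lapply(batch_of_rater,
                                   function(b) phys[batch_of_phys == b]))
    )
    cells <- assignment[rep(seq_len(nrow(assignment)), each = n_v), ]
    cells$vignette_id <- rep(seq_len(n_v), times = nrow(assignment))
  }

  draw <- function(keys, var) {
    u <- unique(keys)
    eff <- stats::rnorm(length(u), 0, sqrt(var))
    eff[match(keys, u)]
  }
  p_key <- cells$physician_id
  v_key <- cells$vignette_id
  r_key <- cells$rater_id
  pv_key <- paste(p_key, v_key)
  if (is.null(physician_effects)) {
    p_draw <- stats::rnorm(n_p, 0, sqrt(sc[["p"]]))
    names(p_draw) <- phys
  } else {
    if (!all(phys %in% names(physician_effects))) {
      stop("physician_effects must be named for every physician id",
           call. = FALSE)
    }
    p_draw <- physician_effects[phys]
  }
  # item noise is carved out of the vignette-level residual (see
  # simulation_config); the remainder is the cell-level residual effect
  cell_res_var <- max(sc[["residual"]] -
                        config$item_sd^2 / config$n_items, 0)
  consensus <- config$grand_mean + config$group_shift +
    unname(p_draw[p_key]) + draw(v_key, sc[["v"]]) +
    draw(pv_key, sc[["pv"]])
  latent <- consensus + draw(paste(r_key, p_key, v_key), cell_res_var)
  if (config$design == "crossed") {
    latent <- latent + draw(r_key, sc[["r"]]) +
      draw(paste(r_key, p_key), sc[["pr"]]) +
      draw(paste(r_key, v_key), sc[["rv"]])
  } else {
    latent <- latent + draw(paste(r_key, p_key), sc[["r:p"]])
  }
  cells$latent <- latent
  cells$consensus <- consensus

  # contamination: the last n_extra rater ids, in pathology blocks
  idx <- config$n_raters
  ids_incomplete <- raters[seq_len(config$n_incomplete) + idx]
  idx <- idx + config$n_incomplete
  ids_straight <- raters[seq_len(config$n_straightline) + idx]
  idx <- idx + config$n_straightline
  ids_anti <- raters[seq_len(config$n_anticorrelated) + idx]

  # anti-correlated raters track the panel consensus, not their own
  # idiosyncrasies, and are mirrored about the scale midpoint below:
  # a deliberate contrarian, the pathology the reliability screen targets
  if (length(ids_anti) > 0) {
    flip_cells <- cells$rater_id %in% ids_anti
    cells$latent[flip_cells] <- cells$consensus[flip_cells]
  }

  # shared item main effects, centered so vignette means are untouched
  item_eff <- stats::rnorm(config$n_items, 0, config$item_effect_sd)
  item_eff <- item_eff - mean(item_eff)

  records <- cells[rep(seq_len(nrow(cells)), each = config$n_items), ]
  records$item_id <- rep(seq_len(config$n_items), times = nrow(cells))
  item_noise <- if (config$item_sd > 0)
    stats::rnorm(nrow(records), 0, config$item_sd) else 0
  # contrarians mirror the consensus faithfully: no idiosyncratic noise
  if (length(ids_anti) > 0) {
    item_noise[records$rater_id %in% ids_anti] <- 0
  }
  records$rating <- records$latent + item_eff[records$item_id] + item_noise

  if (length(ids_straight) > 0) {
    const <- sample(seq(config$scale_min + 1L, config$scale_max - 1L),
                    length(ids_straight), replace = TRUE)
    pick <- match(records$rater_id, ids_straight)
    records$rating[!is.na(pick)] <- const[pick[!is.na(pick)]]
  }
  if (config$discretize) {
    records$rating <- pmin(pmax(round(records$rating), config$scale_min),
                           config$scale_max)
  }
  if (length(ids_anti) > 0) {
    flip <- records$rater_id %in% ids_anti
    records$rating[flip] <- config$scale_min + config$scale_max -
      records$rating[flip]
  }
  if (length(ids_incomplete) > 0) {
    dropped_v <- sample(seq_len(n_v), length(ids_incomplete), replace = TRUE)
    drop <- records$rater_id %in% ids_incomplete &
      records$vignette_id == dropped_v[match(records$rater_id, ids_incomplete)]
    records <- records[!drop, ]
  }

  records$rater_group <- config$rater_group
  if (!config$discretize) {
    # keep continuous scores: bypass the integer-scale validation by
    # storing the latent+noise value in a score table instead
    tab <- structure(
      tibble::as_tibble(records[, c("rater_id", "rater_group",
                                    "physician_id", "vignette_id",
                                    "item_id", "rating")]),
      class = c("rating_table", class(tibble::tibble())),
      scale_min = config$scale_min, scale_max = config$scale_max,
      provenance = "simulate_panel (continuous, not discretized)")
  } else {
    tab <- rating_table(records[, c("rater_id", "rater_group",
                                    "physician_id", "vignette_id",
                                    "item_id", "rating")],
                        scale_min = config$scale_min,
                        scale_max = config$scale_max,
                        provenance = "simulate_panel")
  }
  attr(tab, "truth") <- config
  attr(tab, "contaminated") <- list(incomplete = ids_incomplete,
                                    straightline = ids_straight,
                                    anticorrelated = ids_anti)
  attr(tab, "physician_effects") <- p_draw
  tab
}

#' Simulate two panels rating the same physicians
#'
#' Draws one set of latent physician effects and conditions both panels
#' on it, so the two rater groups score a common set of physician
#' abilities — the structure needed to study between-group agreement and
#' stringency. Both configs must declare the same number of physicians
#' and the same person variance (the shared component).
#'
#' @param config_a,config_b Two [simulation_config()]s.
#' @param seed Seed for the shared physician draw (each panel then uses
#'   its own config seed).
#' @return A list of two [rating_table()]s.
#' @export
simulate_paired_panels <- function(config_a, config_b, seed = 1L) {
  if (config_a$n_physicians != config_b$n_physicians) {
    stop("both panels must rate the same number of physicians",
         call. = FALSE)
  }
  if (config_a$true_components[["p"]] != config_b$true_components[["p"]]) {
    stop("the shared person variance must be equal in both configs",
         call. = FALSE)
  }
  set.seed(seed)
  phys <- pad_ids("P", config_a$n_physicians)
  p_eff <- stats::rnorm(config_a$n_physicians, 0,
                        sqrt(config_a$true_components[["p"]]))
  names(p_eff) <- phys
  list(simulate_panel(config_a, physician_effects = p_eff),
       simulate_panel(config_b, physician_effects = p_eff))
}

#' Write the canonical synthetic fixture suite
#'
#' Generates and writes three panels — a clean crossed panel, a clean
#' nested batch panel, and a contaminated nested panel of 59 recruited
#' raters (42 genuine + 8 incomplete + 8 straight-lining + 1
#' anti-correlated) — plus a YAML manifest recording the generating
#' variance components and the injected rater ids. Regenerating from the
#' same seed reproduces the files byte for byte.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Base seed; each panel derives its own fixed offset from it.
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 42L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_crossed <- simulation_config("crossed", seed = seed)
  cfg_nested <- simulation_config("nested", seed = seed + 1L)
  cfg_contam <- simulation_config("nested", n_raters = 42L,
                                  n_incomplete = 8L, n_straightline = 8L,
                                  n_anticorrelated = 1L, seed = seed + 2L)
  panels <- list(crossed_clean = cfg_crossed, nested_clean = cfg_nested,
                 nested_contaminated = cfg_contam)
  paths <- character(0)
  manifest <- list()
  for (nm in names(panels)) {
    tab <- simulate_panel(panels[[nm]])
    path <- file.path(out_dir, paste0(nm, ".csv"))
    write_ratings(tab, path)
    paths[nm] <- path
    cfg <- panels[[nm]]
    manifest[[nm]] <- list(
      design = cfg$structure,
      true_components = as.list(cfg$true_components),
      n_physicians = cfg$n_physicians, n_vignettes = cfg$n_vignettes,
      n_items = cfg$n_items, n_raters = cfg$n_raters,
      grand_mean = cfg$grand_mean, group_shift = cfg$group_shift,
      seed = cfg$seed,
      contaminated = lapply(attr(tab, "contaminated"), as.list)
    )
  }
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  paths["manifest"] <- manifest_path
  invisible(paths)
}
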