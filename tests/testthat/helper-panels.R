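# Small builders shared across tests.

# One rater, one physician, one vignette, the full 6-item set.
tiny_records <- function(rating = 3L) {
  data.frame(rater_id = "r1", rater_group = "advocate",
             physician_id = "p1", vignette_id = 1L, item_id = 1:6,
             rating = rating)
}

# Fully crossed item-level records from explicit rating values.
crossed_records <- function(raters, physicians, vignettes, items,
                            ratings, group = "g") {
  g <- expand.grid(item_id = seq_len(items), vignette_id = seq_len(vignettes),
                   physician_id = physicians, rater_id = raters,
                   stringsAsFactors = FALSE)
  g$rater_group <- group
  g$rating <- rep_len(ratings, nrow(g))
  g[, c("rater_id", "rater_group", "physician_id", "vignette_id",
        "item_id", "rating")]
}

estimate_nested_quietly <- function(scores) {
  suppressWarnings(estimate_nested(scores))
}

run_qc_quietly <- function(table, ...) {
  suppressWarnings(run_qc(table, ...))
}
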