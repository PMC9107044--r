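test_that("incomplete raters are removed, complete ones retained", {
  rec <- rbind(
    crossed_records("full", "p1", 3, 6, rep(3:4, 27)),
    {
      part <- crossed_records("partial", "p1", 3, 6, rep(2:3, 27))
      part[part$vignette_id != 3L, ]  # missing vignette 3 of {1,2,3}
    }
  )
  tab <- rating_table(rec)
  out <- filter_incomplete(tab)
  expect_equal(out$removed, "partial")
  expect_setequal(unique(out$table$rater_id), "full")
  expect_error(filter_incomplete(tab, integer(0)), "empty")
})

test_that("low-range rule drops raters using fewer than 3 response options", {
  rec <- rbind(
    crossed_records("const4", "p1", 3, 6, 4L),              # 1 distinct
    crossed_records("alt34", "p1", 3, 6, rep(3:4, 27)),     # 2 distinct
    crossed_records("three", "p1", 3, 6, rep(2:4, 18))      # 3 distinct
  )
  tab <- rating_table(rec)
  out <- filter_low_range(tab)
  expect_setequal(out$removed, c("const4", "alt34"))
  expect_setequal(unique(out$table$rater_id), "three")
  expect_error(filter_low_range(tab, min_distinct = 0), "min_distinct")
  expect_error(filter_low_range(tab, min_distinct = 6), "min_distinct")
})

test_that("leave-one-out screen removes exactly an anti-correlated rater", {
  # five raters share one task; four share a common signal, one is the
  # mirror image of it
  set.seed(41)
  base <- rep(1:5, each = 8) + rnorm(40, 0, 0.3)
  base <- pmin(pmax(round(base), 1), 5)
  recs <- do.call(rbind, lapply(1:4, function(i) {
    r <- crossed_records(paste0("clone", i), c("p1", "p2"), 4, 5, 3L)
    r$rating <- base
    r
  }))
  anti <- crossed_records("anti", c("p1", "p2"), 4, 5, 3L)
  anti$rating <- 6L - base
  tab <- rating_table(rbind(recs, anti))

  # direct leave-one-out computation confirms the construction: dropping
  # the mirror rater must raise alpha by more than 0.1
  mat <- cbind(base, base, base, base, 6L - base)
  alpha <- function(m) {
    k <- ncol(m); (k / (k - 1)) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
  }
  expect_gt(alpha(mat[, 1:4]) - alpha(mat), 0.1)

  out <- filter_irr_outliers(tab)
  expect_equal(out$removed, "anti")
})

test_that("clone panels and sub-threshold panels keep all raters", {
  set.seed(42)
  base <- pmin(pmax(round(rep(1:5, each = 6) + rnorm(30, 0, 0.4)), 1), 5)
  clones <- do.call(rbind, lapply(1:4, function(i) {
    r <- crossed_records(paste0("c", i), "p1", 5, 6, 3L)
    r$rating <- base
    r
  }))
  out <- filter_irr_outliers(rating_table(clones))
  expect_length(out$removed, 0)

  # mildly noisy panel: every leave-one-out change stays under 0.1
  noisy <- do.call(rbind, lapply(1:6, function(i) {
    r <- crossed_records(paste0("n", i), "p1", 5, 6, 3L)
    r$rating <- pmin(pmax(round(base + rnorm(30, 0, 0.4)), 1), 5)
    r
  }))
  out2 <- filter_irr_outliers(rating_table(noisy))
  expect_length(out2$removed, 0)

  # groups too small to evaluate are retained with a warning
  two <- rating_table(clones[clones$rater_id %in% c("c1", "c2"), ])
  expect_warning(res <- filter_irr_outliers(two), "fewer than 3")
  expect_length(res$removed, 0)
})

test_that("lowering the drop threshold never shrinks the outlier set", {
  tab <- simulate_panel(simulation_config(
    "nested", n_raters = 20L, n_anticorrelated = 2L, seed = 5))
  removed <- lapply(c(0.3, 0.1, 0.02),
                    function(th) filter_irr_outliers(tab, th)$removed)
  expect_true(all(removed[[1]] %in% removed[[2]]))
  expect_true(all(removed[[2]] %in% removed[[3]]))
})

test_that("the full QC pass mirrors an engineered contamination spec", {
  cfg <- simulation_config("nested", n_raters = 42L, n_incomplete = 8L,
                           n_straightline = 8L, n_anticorrelated = 1L,
                           seed = 7)
  tab <- simulate_panel(cfg)
  expect_equal(dplyr::n_distinct(tab$rater_id), 59L)
  res <- run_qc(tab)
  injected <- attr(tab, "contaminated")
  expect_setequal(res$report$removed_incomplete, injected$incomplete)
  expect_setequal(res$report$removed_low_range, injected$straightline)
  expect_setequal(res$report$removed_outlier, injected$anticorrelated)
  expect_equal(res$report$n_recruited, 59L)
  expect_equal(res$report$n_retained, 42L)

  # removal lists are disjoint and account for the retention count
  all_removed <- c(res$report$removed_incomplete,
                   res$report$removed_low_range,
                   res$report$removed_outlier)
  expect_equal(anyDuplicated(all_removed), 0L)
})

test_that("QC is idempotent and invariant to rater input order", {
  tab <- simulate_panel(simulation_config(
    "nested", n_raters = 20L, n_incomplete = 2L, n_straightline = 2L,
    n_anticorrelated = 1L, seed = 9))
  res <- run_qc(tab)

  again <- run_qc(res$table)
  expect_equal(again$report$n_retained, again$report$n_recruited)
  expect_equal(tibble::as_tibble(again$table), tibble::as_tibble(res$table))

  set.seed(2)
  shuffled <- rating_table(tibble::as_tibble(tab)[sample(nrow(tab)), ],
                           provenance = "shuffled")
  res2 <- run_qc(shuffled)
  expect_setequal(res2$report$removed_incomplete,
                  res$report$removed_incomplete)
  expect_setequal(res2$report$removed_low_range,
                  res$report$removed_low_range)
  expect_setequal(res2$report$removed_outlier, res$report$removed_outlier)
})

test_that("a clean panel passes QC untouched", {
  tab <- simulate_panel(simulation_config("crossed", seed = 10))
  res <- run_qc(tab)
  expect_equal(res$report$n_retained, res$report$n_recruited)
  expect_equal(nrow(res$table), nrow(tab))
})
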