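# Brute-force two-within-factor repeated-measures ANOVA by partitioned
# sums of squares, for cross-checking stringency_anova.
oracle_rm_anova <- function(cells) {
  s <- factor(cells$physician_id); a <- factor(cells$rater_group)
  b <- factor(cells$vignette_id); y <- cells$score
  n <- nlevels(s); ka <- nlevels(a); kb <- nlevels(b)
  m <- mean(y)
  m_s <- tapply(y, s, mean); m_a <- tapply(y, a, mean)
  m_b <- tapply(y, b, mean)
  m_as <- tapply(y, list(a, s), mean); m_bs <- tapply(y, list(b, s), mean)
  m_ab <- tapply(y, list(a, b), mean)
  ss_a <- n * kb * sum((m_a - m)^2)
  ss_as <- kb * sum((m_as - outer(m_a, m_s, "+") + m)^2)
  ss_b <- n * ka * sum((m_b - m)^2)
  ss_bs <- ka * sum((m_bs - outer(m_b, m_s, "+") + m)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, m_b, "+") + m)^2)
  resid <- y - m_ab[cbind(a, b)] - m_as[cbind(a, s)] - m_bs[cbind(b, s)] +
    m_a[a] + m_b[b] + m_s[s] - m
  ss_abs <- sum(resid^2)
  list(
    rater_group = (ss_a / (ka - 1)) / (ss_as / ((ka - 1) * (n - 1))),
    vignette = (ss_b / (kb - 1)) / (ss_bs / ((kb - 1) * (n - 1))),
    interaction = (ss_ab / ((ka - 1) * (kb - 1))) /
      (ss_abs / ((ka - 1) * (kb - 1) * (n - 1)))
  )
}

make_cells <- function(score_fun, n_p = 3, n_v = 3) {
  g <- expand.grid(physician_id = paste0("p", seq_len(n_p)),
                   vignette_id = seq_len(n_v),
                   rater_group = c("A", "B"), stringsAsFactors = FALSE)
  g$score <- score_fun(g)
  tibble::as_tibble(g)
}

test_that("equal group means give a null group effect and d = 0", {
  set.seed(61)
  base <- rnorm(9, 3.5, 0.4)
  delta <- rnorm(9, 0, 0.2)
  delta <- delta - mean(delta)  # groups differ per cell but not on average
  cells <- make_cells(function(g) {
    cell <- as.integer(factor(paste(g$physician_id, g$vignette_id)))
    base[cell] + ifelse(g$rater_group == "A", delta[cell], -delta[cell])
  })
  res <- stringency_anova(cells)
  f_group <- res$effects$statistic[res$effects$effect == "rater_group"]
  expect_equal(f_group, 0, tolerance = 1e-10)
  expect_equal(res$d, 0, tolerance = 1e-10)
})

test_that("F statistics match a brute-force partitioned-SS computation", {
  set.seed(62)
  for (i in 1:5) {
    cells <- make_cells(function(g) round(rnorm(nrow(g), 3.4, 0.5), 2),
                        n_p = 3 + i, n_v = 3)
    res <- stringency_anova(cells)
    oracle <- oracle_rm_anova(cells)
    expect_equal(res$effects$statistic[res$effects$effect == "rater_group"],
                 oracle$rater_group, tolerance = 1e-8)
    expect_equal(res$effects$statistic[res$effects$effect == "vignette"],
                 oracle$vignette, tolerance = 1e-8)
    expect_equal(
      res$effects$statistic[res$effects$effect == "rater_group:vignette"],
      oracle$interaction, tolerance = 1e-8)
    expect_equal(res$effects$df1, c(1, 2, 2))
    expect_equal(res$effects$df2,
                 c(nrow(cells) / 6 - 1, 2 * (nrow(cells) / 6 - 1),
                   2 * (nrow(cells) / 6 - 1)))
  }
})

test_that("a built-in stringency shift is detected and d recovered", {
  set.seed(60)
  lay <- default_true_components("nested_rp_v")
  lay["p"] <- default_true_components("crossed_pvr")[["p"]]
  ds <- replicate(20, {
    seed <- sample.int(1e6, 1)
    panels <- simulate_paired_panels(
      simulation_config("crossed", group_shift = -0.36, item_sd = 0,
                        n_items = 1L, discretize = FALSE, seed = seed),
      simulation_config("nested", true_components = lay, group_shift = 0,
                        item_sd = 0, n_items = 1L, discretize = FALSE,
                        seed = seed + 1L),
      seed = seed + 2L)
    scores <- dplyr::bind_rows(lapply(panels, vignette_scores))
    res <- stringency_anova(group_cell_means(scores))
    p_group <- res$effects$p_value[res$effects$effect == "rater_group"]
    c(d = res$d, p = p_group)
  })
  # construction: shift 0.36 over physician-level group variances near
  # 0.30, so d ~ 0.36 / sqrt(0.30) ~ 0.7; the band is ~3 Monte-Carlo
  # standard errors of the 20-replicate mean
  expect_lt(abs(mean(ds["d", ]) - 0.7), 0.3)
  expect_gt(mean(ds["p", ] < 0.05), 0.7)
})

test_that("stringency ANOVA is invariant to relabeling and location shifts", {
  set.seed(63)
  cells <- make_cells(function(g) round(rnorm(nrow(g), 3.3, 0.5), 2),
                      n_p = 6)
  res <- stringency_anova(cells)
  relabeled <- cells
  relabeled$physician_id <- paste0("zz_", relabeled$physician_id)
  shifted <- cells
  shifted$score <- shifted$score + 0.7
  for (variant in list(relabeled, shifted)) {
    res2 <- stringency_anova(variant)
    expect_equal(res2$effects$statistic, res$effects$statistic,
                 tolerance = 1e-10)
    expect_equal(res2$d, res$d, tolerance = 1e-10)
  }
})

test_that("sphericity correction shrinks df for multi-level effects only", {
  set.seed(64)
  cells <- make_cells(function(g) round(rnorm(nrow(g), 3.3, 0.5), 2),
                      n_p = 8)
  raw <- stringency_anova(cells)
  gg <- stringency_anova(cells, sphericity = "greenhouse_geisser")
  expect_equal(gg$effects$epsilon[gg$effects$effect == "rater_group"], 1)
  expect_lte(gg$effects$epsilon[gg$effects$effect == "vignette"], 1)
  expect_equal(gg$effects$statistic, raw$effects$statistic)
  v <- gg$effects$effect == "vignette"
  expect_gt(gg$effects$epsilon[v], 0)
  expect_equal(gg$effects$df1[v], raw$effects$df1[v] * gg$effects$epsilon[v])
  expect_equal(gg$effects$p_value[v],
               stats::pf(gg$effects$statistic[v], gg$effects$df1[v],
                         gg$effects$df2[v], lower.tail = FALSE))
})

test_that("stringency ANOVA validates its input layout", {
  cells <- make_cells(function(g) rnorm(nrow(g)))
  expect_error(stringency_anova(cells[-1, ]), "one score per")
  expect_error(stringency_anova(cells[cells$physician_id %in%
                                        c("p1", "p2"), ]),
               "at least 3 physicians")
})

test_that("group correlation hits the trivial boundary cases", {
  a <- tibble::tibble(physician_id = paste0("p", 1:6),
                      score = c(3.1, 3.4, 2.8, 4.0, 3.6, 3.3))
  same <- correlate_groups(a, a)
  expect_equal(same$r, 1)
  flipped <- a
  flipped$score <- -a$score + 7
  expect_equal(correlate_groups(a, flipped)$r, -1)
  expect_error(correlate_groups(a, a[1:5, ]), "same physician set")
  const <- a
  const$score <- 3
  expect_error(correlate_groups(a, const), "zero variance")
})

test_that("group correlation is invariant under positive affine transforms", {
  set.seed(65)
  a <- tibble::tibble(physician_id = paste0("p", 1:10), score = rnorm(10, 3.4, 0.5))
  b <- tibble::tibble(physician_id = paste0("p", 1:10),
                      score = a$score * 0.8 + rnorm(10, 0, 0.3))
  r0 <- correlate_groups(a, b)$r
  b2 <- b
  b2$score <- 2.5 * b$score + 1
  expect_equal(correlate_groups(a, b2)$r, r0, tolerance = 1e-12)
})

test_that("between-group correlation matches the attenuation implied by the components", {
  # groups share only the physician effect; with panel-mean error
  # variances Va and Vb, corr(score_a, score_b) = s2p / sqrt(Va * Vb)
  adv <- default_true_components("crossed_pvr")
  lay <- default_true_components("nested_rp_v")
  lay["p"] <- adv[["p"]]
  v_a <- adv[["p"]] + adv[["pv"]] / 3 + adv[["pr"]] / 8 + adv[["residual"]] / 24
  # nested panel: ~8-9 pseudo-raters per physician; use the average 42*4/20
  k <- 42 * 4 / 20
  v_b <- adv[["p"]] + lay[["pv"]] / 3 + lay[["r:p"]] / k +
    lay[["residual"]] / (3 * k)
  expected_r <- adv[["p"]] / sqrt(v_a * v_b)

  set.seed(66)
  rs <- replicate(25, {
    seed <- sample.int(1e6, 1)
    panels <- simulate_paired_panels(
      simulation_config("crossed", group_shift = 0, item_sd = 0,
                        n_items = 1L, discretize = FALSE, seed = seed),
      simulation_config("nested", true_components = lay, group_shift = 0,
                        item_sd = 0, n_items = 1L, discretize = FALSE,
                        seed = seed + 1L),
      seed = seed + 2L)
    overall <- lapply(panels, function(p)
      overall_scores(vignette_scores(p), level = "group"))
    correlate_groups(overall[[1]], overall[[2]])$r
  })
  mc_se <- stats::sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs) - expected_r), max(3 * mc_se, 0.03))
})
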