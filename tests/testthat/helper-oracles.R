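# Independent oracles used to cross-check the estimators. These
# deliberately take different computational routes from the package code:
# sums of squares come from stats::aov / explicit quadratic-form matrices,
# and expected-mean-square systems are built symbolically and solved
# numerically rather than via the closed forms.

# Crossed p x v x r design: SS from aov(), EMS coefficient matrix built
# from the balanced expectations, solved with solve().
oracle_crossed_ems <- function(scores) {
  d <- data.frame(p = factor(scores$physician_id),
                  v = factor(scores$vignette_id),
                  r = factor(scores$rater_id),
                  y = scores$score)
  n_p <- nlevels(d$p); n_v <- nlevels(d$v); n_r <- nlevels(d$r)
  fit <- stats::aov(y ~ p * v * r, data = d)
  ss <- summary(fit)[[1]][, "Sum Sq"]
  df <- summary(fit)[[1]][, "Df"]
  terms <- trimws(rownames(summary(fit)[[1]]))
  names(ss) <- names(df) <- terms
  ms <- ss / df
  # rows: MS for p, r, v, p:r, p:v, v:r, p:v:r; cols: sigma2 in same order
  # as the package's label set
  ems <- rbind(
    p     = c(p = n_v * n_r, r = 0, v = 0, pr = n_v, pv = n_r, rv = 0, residual = 1),
    r     = c(p = 0, r = n_p * n_v, v = 0, pr = n_v, pv = 0, rv = n_p, residual = 1),
    v     = c(p = 0, r = 0, v = n_p * n_r, pr = 0, pv = n_r, rv = n_p, residual = 1),
    pr    = c(p = 0, r = 0, v = 0, pr = n_v, pv = 0, rv = 0, residual = 1),
    pv    = c(p = 0, r = 0, v = 0, pr = 0, pv = n_r, rv = 0, residual = 1),
    rv    = c(p = 0, r = 0, v = 0, pr = 0, pv = 0, rv = n_p, residual = 1),
    pvr   = c(p = 0, r = 0, v = 0, pr = 0, pv = 0, rv = 0, residual = 1)
  )
  ms_vec <- c(ms[["p"]], ms[["r"]], ms[["v"]], ms[["p:r"]], ms[["p:v"]],
              ms[["v:r"]], ms[["p:v:r"]])
  est <- solve(ems, ms_vec)
  names(est) <- colnames(ems)
  est
}

# Nested (r:p) x v design, any balance: brute-force quadratic-forms solve.
# Each T-term is y' M y with M = G (G'G)^{-1} G' for the grouping's
# indicator matrix G; E[y' A y] = mu^2 1'A1 + sum_c sigma2_c tr(A Z_c Z_c').
oracle_nested_quadform <- function(scores) {
  p <- factor(scores$physician_id)
  v <- factor(scores$vignette_id)
  r <- factor(paste(scores$rater_id, scores$physician_id, sep = "/"))
  pv <- factor(paste(p, v, sep = "/"))
  n <- nrow(scores)
  y <- scores$score

  proj <- function(f) {
    G <- stats::model.matrix(~ f - 1)
    G %*% solve(crossprod(G)) %*% t(G)
  }
  M <- list(mu = matrix(1 / n, n, n), p = proj(p), v = proj(v),
            r = proj(r), pv = proj(pv), x = diag(n))
  K <- rbind(
    p        = c(mu = -1, p = 1, v = 0, r = 0, pv = 0, x = 0),
    v        = c(mu = -1, p = 0, v = 1, r = 0, pv = 0, x = 0),
    `r:p`    = c(mu = 0, p = -1, v = 0, r = 1, pv = 0, x = 0),
    pv       = c(mu = 1, p = -1, v = -1, r = 0, pv = 1, x = 0),
    residual = c(mu = 0, p = 1, v = 0, r = -1, pv = -1, x = 1)
  )
  A <- lapply(rownames(K), function(ss_name) {
    Reduce(`+`, Map(function(w, m) w * m, K[ss_name, ], M))
  })
  names(A) <- rownames(K)
  ZZ <- list(p = tcrossprod(stats::model.matrix(~ p - 1)),
             v = tcrossprod(stats::model.matrix(~ v - 1)),
             `r:p` = tcrossprod(stats::model.matrix(~ r - 1)),
             pv = tcrossprod(stats::model.matrix(~ pv - 1)),
             residual = diag(n))
  ss_vals <- vapply(A, function(a) drop(t(y) %*% a %*% y), numeric(1))
  C <- t(vapply(A, function(a) {
    vapply(ZZ, function(z) sum(a * z), numeric(1))  # tr(A Z Z')
  }, numeric(length(ZZ))))
  est <- solve(C, ss_vals)
  names(est) <- names(ZZ)
  est
}

# Balanced nested (r:p) x v closed form: mean squares by explicit loops,
# then the textbook EMS solution.
oracle_balanced_nested <- function(scores) {
  p <- factor(scores$physician_id)
  r <- factor(paste(scores$rater_id, scores$physician_id, sep = "/"))
  v <- factor(scores$vignette_id)
  n_p <- nlevels(p); n_v <- nlevels(v)
  r_per <- nlevels(r) / n_p
  stopifnot(r_per == round(r_per))
  y <- scores$score
  m <- mean(y)
  m_p <- tapply(y, p, mean)
  m_v <- tapply(y, v, mean)
  m_r <- tapply(y, r, mean)
  m_pv <- tapply(y, list(p, v), mean)
  r_of <- tapply(as.character(p), r, unique)

  ss_p <- r_per * n_v * sum((m_p - m)^2)
  ss_v <- r_per * n_p * sum((m_v - m)^2)
  ss_r <- n_v * sum((m_r - m_p[r_of])^2)
  ss_pv <- r_per * sum((m_pv - outer(m_p, m_v, "+") + m)^2)
  ss_res <- sum((y - m_r[r] - m_pv[cbind(p, v)] + m_p[p])^2)

  ms_p <- ss_p / (n_p - 1)
  ms_v <- ss_v / (n_v - 1)
  ms_r <- ss_r / (n_p * (r_per - 1))
  ms_pv <- ss_pv / ((n_p - 1) * (n_v - 1))
  ms_res <- ss_res / (n_p * (r_per - 1) * (n_v - 1))

  c(p = (ms_p - ms_pv - ms_r + ms_res) / (r_per * n_v),
    v = (ms_v - ms_pv) / (r_per * n_p),
    `r:p` = (ms_r - ms_res) / n_v,
    pv = (ms_pv - ms_res) / r_per,
    residual = ms_res)
}

# Random small crossed score table drawn from a random component set.
random_crossed_scores <- function(n_p, n_v, n_r) {
  comp <- stats::runif(7, 0, 1)
  names(comp) <- c("p", "r", "v", "pr", "pv", "rv", "residual")
  g <- expand.grid(physician_id = paste0("P", seq_len(n_p)),
                   vignette_id = seq_len(n_v),
                   rater_id = paste0("R", seq_len(n_r)),
                   stringsAsFactors = FALSE)
  eff <- function(key, s) {
    u <- unique(key)
    stats::rnorm(length(u), 0, sqrt(s))[match(key, u)]
  }
  g$score <- 3 + eff(g$physician_id, comp["p"]) + eff(g$rater_id, comp["r"]) +
    eff(g$vignette_id, comp["v"]) +
    eff(paste(g$physician_id, g$rater_id), comp["pr"]) +
    eff(paste(g$physician_id, g$vignette_id), comp["pv"]) +
    eff(paste(g$rater_id, g$vignette_id), comp["rv"]) +
    stats::rnorm(nrow(g), 0, sqrt(comp["residual"]))
  tibble::as_tibble(g)
}

# Random nested score table; rater counts per physician supplied.
random_nested_scores <- function(raters_per_physician, n_v) {
  n_p <- length(raters_per_physician)
  comp <- stats::runif(5, 0, 1)
  names(comp) <- c("p", "v", "r:p", "pv", "residual")
  rows <- list()
  rid <- 0
  for (i in seq_len(n_p)) {
    for (j in seq_len(raters_per_physician[i])) {
      rid <- rid + 1
      rows[[rid]] <- data.frame(physician_id = paste0("P", i),
                                rater_id = paste0("R", rid),
                                vignette_id = seq_len(n_v),
                                stringsAsFactors = FALSE)
    }
  }
  g <- do.call(rbind, rows)
  eff <- function(key, s) {
    u <- unique(key)
    stats::rnorm(length(u), 0, sqrt(s))[match(key, u)]
  }
  g$score <- 3 + eff(g$physician_id, comp["p"]) + eff(g$vignette_id, comp["v"]) +
    eff(paste(g$rater_id, g$physician_id), comp["r:p"]) +
    eff(paste(g$physician_id, g$vignette_id), comp["pv"]) +
    stats::rnorm(nrow(g), 0, sqrt(comp["residual"]))
  tibble::as_tibble(g)
}
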