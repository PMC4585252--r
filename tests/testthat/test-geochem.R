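test_that("oxygen-zone boxes classify canonical and off-box cases", {
  expect_equal(classify_zone(30, 210), "upper_oxic")
  expect_equal(classify_zone(250, 2), "core_omz")
  expect_equal(classify_zone(70, 50), "upper_oxycline")
  expect_equal(classify_zone(100, 6), "upper_omz")
  expect_equal(classify_zone(700, 20), "lower_oxycline")
  # anoxic water at an oxic-zone depth fits no box
  expect_equal(classify_zone(30, 3), "unclassified")
  expect_warning(z <- classify_zone(NA, 50), "missing")
  expect_equal(z, "unclassified")
})

test_that("zone labels partition the depth x O2 grid", {
  depth <- seq(0, 1100, by = 13)
  o2 <- seq(0, 300, by = 3.7)
  grid <- expand.grid(depth = depth, o2 = o2)
  z <- classify_zone(grid$depth, grid$o2)
  expect_true(all(z %in% c("upper_oxic", "upper_oxycline", "upper_omz",
                           "core_omz", "lower_oxycline", "unclassified")))
  # each box assigns only inside its own depth window, so no two labels
  # can claim the same point; rerunning gives identical labels
  expect_identical(z, classify_zone(grid$depth, grid$o2))
  # boundary conventions: O2 lower bound inclusive, upper exclusive
  expect_equal(classify_zone(80, 10), "upper_oxycline")
  expect_equal(classify_zone(80, 9.999), "upper_omz")
  expect_equal(classify_zone(25, 200), "unclassified") # needs > 200
})

test_that("OLS of Fe:Cu on O2 recovers exact and noisy lines", {
  # points exactly on the published-style line
  o2 <- seq(10, 280, length.out = 15)
  d <- data.frame(fe_cu_ratio = -0.006 * o2 + 1.8, o2 = o2)
  fit <- fit_fe_cu_vs_o2(d)
  expect_equal(fit$slope, -0.006, tolerance = 1e-12)
  expect_equal(fit$intercept, 1.8, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # constant response: slope 0, r^2 0
  dc <- data.frame(fe_cu_ratio = rep(1.2, 10), o2 = o2[1:10])
  fitc <- fit_fe_cu_vs_o2(dc)
  expect_equal(fitc$slope, 0)
  expect_equal(fitc$r_squared, 0)
  # noisy line against the closed-form normal equations
  set.seed(51)
  x <- runif(50, 0, 250)
  y <- -0.004 * x + 1.5 + rnorm(50, 0, 0.1)
  fitn <- fit_fe_cu_vs_o2(data.frame(fe_cu_ratio = y, o2 = x))
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fitn$slope, beta, tolerance = 1e-12)
  expect_equal(fitn$intercept, mean(y) - beta * mean(x), tolerance = 1e-12)
  # duplicating every point leaves the fit unchanged
  fitd <- fit_fe_cu_vs_o2(data.frame(fe_cu_ratio = rep(y, 3),
                                     o2 = rep(x, 3)))
  expect_equal(fitd$slope, fitn$slope, tolerance = 1e-12)
  expect_equal(fitd$intercept, fitn$intercept, tolerance = 1e-12)
  # degenerate design
  expect_error(fit_fe_cu_vs_o2(data.frame(fe_cu_ratio = c(1, 2),
                                          o2 = c(5, 5))), "degenerate")
})

test_that("the zero-oxygen prediction is the intercept, flagged by slope", {
  expect_equal(as.numeric(predict_zero_oxygen(linear_fit(-0.006, 1.8))),
               1.8)
  expect_equal(as.numeric(predict_zero_oxygen(linear_fit(-1, 0))), 0)
  f <- linear_fit(-0.5, 2.7)
  expect_true(attr(predict_zero_oxygen(f), "is_maximum"))
  expect_warning(up <- predict_zero_oxygen(linear_fit(0.2, 1.1)),
                 "not a predicted maximum")
  expect_false(attr(up, "is_maximum"))
})

test_that("Spearman rho and p match the oracles, with and without ties", {
  # perfect monotone cases
  expect_equal(spearman_rho_p(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_rho_p(1:5, 5:1)$rho, -1)
  # tied fixture vs the long-hand mid-rank Pearson
  x <- c(1, 2, 2, 3, 4, 4, 4, 5)
  y <- c(2, 1, 3, 3, 5, 4, 6, 7)
  r <- spearman_rho_p(x, y)
  expect_equal(r$rho, spearman_rho_oracle(x, y), tolerance = 1e-12)
  expect_equal(r$rho, suppressWarnings(
    cor.test(x, y, method = "spearman")$estimate[[1]]), tolerance = 1e-12)
  # exact permutation p at n = 6 vs full 720-enumeration
  x6 <- c(3, 1, 4, 1.5, 5, 9)
  y6 <- c(2, 7, 1, 8, 2.5, 8.5)
  r6 <- spearman_rho_p(x6, y6)
  expect_equal(r6$method, "exact permutation")
  rx <- rank(x6); ry <- rank(y6)
  obs <- spearman_rho_oracle(x6, y6)
  count <- 0L
  for (p in perms_oracle(seq_len(6))) {
    if (abs(cor(rx[p], ry)) >= abs(obs) - 1e-12) count <- count + 1L
  }
  expect_equal(r6$p_value, count / factorial(6))
  # large-n route uses the t approximation
  set.seed(52)
  xl <- rnorm(30); yl <- xl + rnorm(30)
  rl <- spearman_rho_p(xl, yl)
  expect_equal(rl$method, "t approximation")
  tt <- rl$rho * sqrt(28 / (1 - rl$rho^2))
  expect_equal(rl$p_value, 2 * pt(-abs(tt), 28), tolerance = 1e-12)
  expect_error(spearman_rho_p(rep(1, 6), 1:6), "constant")
})

test_that("the Spearman screen reports pairs, skips and BH q-values", {
  set.seed(53)
  inv <- cbind(fe_total = c(10, 8, 7, 5, 3, 1),
               flat = rep(2, 6),
               noise = rnorm(6))
  rownames(inv) <- paste0("s", 1:6)
  geo <- cbind(o2 = c(1, 3, 10, 60, 150, 220),
               depth = c(300, 250, 100, 80, 50, 20))
  rownames(geo) <- paste0("s", 1:6)
  scr <- spearman_screen(inv, geo)
  fe_o2 <- scr[scr$x_name == "o2" & scr$y_name == "fe_total", ]
  expect_equal(fe_o2$rho, -1)
  expect_equal(scr$note[scr$y_name == "flat"][1], "constant vector")
  tested <- !is.na(scr$p_value)
  expect_equal(scr$q_value[tested],
               p.adjust(scr$p_value[tested], "BH"))
})

test_that("rarefaction means converge to the hypergeometric expectation", {
  m <- matrix(c(10, 0), 1, 2, dimnames = list("s1", c("a", "b")))
  # depth equal to the total reproduces the sample every repetition
  expect_equal(rarefy_matrix(m, 10, reps = 5, seed = 1),
               matrix(c(10, 0), 1, 2, dimnames = dimnames(m)))
  # single-label certainty
  expect_equal(rarefy_matrix(m, 5, reps = 11, seed = 1)[1, "a"], 5)
  # {6,4} at depth 5: E[a] = 5 * 6/10 = 3, hypergeometric SE known
  m2 <- matrix(c(6, 4), 1, 2, dimnames = list("s1", c("a", "b")))
  rr <- rarefy_matrix(m2, 5, reps = 999, seed = 7)
  v <- 5 * (6 / 10) * (4 / 10) * (10 - 5) / (10 - 1)
  se <- sqrt(v / 999)
  expect_lt(abs(rr[1, "a"] - 3), 3 * se)
  # reproducible under the same seed, depth errors name the sample
  expect_identical(rarefy_matrix(m2, 5, reps = 99, seed = 3),
                   rarefy_matrix(m2, 5, reps = 99, seed = 3))
  expect_error(rarefy_matrix(m2, 11, seed = 1), "s1")
})

test_that("CCA identities hold: inertia, constant and single constraints", {
  set.seed(54)
  X <- matrix(rpois(6 * 5, 8) + 1, 6, 5,
              dimnames = list(paste0("s", 1:6), paste0("f", 1:5)))
  # total inertia equals chi-square / grand total
  z <- rnorm(6)
  res <- partial_cca(X, cbind(env = z))
  expect_equal(res$total_inertia, chisq_inertia_oracle(X), tolerance = 1e-10)
  # a constant constraint has no span
  resc <- partial_cca(X, cbind(const = rep(2, 6)))
  expect_equal(resc$constrained_inertia, 0)
  # one binary constraint: eigenvalue matches the dense projection oracle
  b <- c(0, 0, 0, 1, 1, 1)
  resb <- partial_cca(X, cbind(grp = b))
  expect_equal(resb$eigenvalues_constrained[1],
               cca_eig_oracle(X, b), tolerance = 1e-8)
  # conditions identical to constraints leave nothing to constrain
  resp <- partial_cca(X, cbind(env = z), conditions = cbind(env = z))
  expect_lt(resp$constrained_inertia, 1e-10)
  # collinear constraints error with the offending column named
  expect_error(partial_cca(X, cbind(a = z, b = 2 * z)), "collinear")
})

test_that("permuting samples permutes scores and preserves eigenvalues", {
  set.seed(55)
  X <- matrix(rpois(8 * 6, 6) + 1, 8, 6,
              dimnames = list(paste0("s", 1:8), paste0("f", 1:6)))
  env <- cbind(o2 = rnorm(8), no3 = rnorm(8))
  rownames(env) <- rownames(X)
  r1 <- partial_cca(X, env)
  perm <- sample(8)
  r2 <- partial_cca(X[perm, ], env[perm, ])
  expect_lt(max(abs(r1$eigenvalues_constrained -
                      r2$eigenvalues_constrained)), 1e-10)
  # site scores move with the samples (axis signs are arbitrary)
  s1 <- r1$site_scores[perm, , drop = FALSE]
  s2 <- r2$site_scores
  flip <- sign(colSums(s1 * s2))
  expect_lt(max(abs(sweep(s2, 2, flip, `*`) - s1)), 1e-8)
})

test_that("geochem assembly derives ratios and flags bad input", {
  df <- data.frame(sample_id = c("a", "b"), depth = c(30, 250),
                   o2 = c(210, 2), dfe = c(0.2, 1.8), dcu = c(1.0, 1.2))
  g <- geo_samples(df)
  expect_equal(g$fe_cu_ratio, c(0.2, 1.5))
  expect_equal(g$zone, c("upper_oxic", "core_omz"))
  expect_error(geo_samples(df[, -3]), "missing geochemistry column")
})
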