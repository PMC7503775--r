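make_pheno <- function(n_var = 8, n_reps = 2, treatments = "I", seed = 1,
                       traits = paste0("F", 1:15), noise = 1) {
  set.seed(seed)
  varieties <- default_varieties()[seq_len(n_var)]
  tab <- expand.grid(variety = varieties,
                     treatment = c("control", treatments),
                     replicate = seq_len(n_reps),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (tr in traits) tab[[tr]] <- 20 + rnorm(nrow(tab), sd = noise)
  tab
}

test_that("trait classification separates D from VD responses", {
  set.seed(2)
  ph <- make_pheno(n_var = 8, n_reps = 3, noise = 0.5)
  # F1: uniform -20% drought effect -> D
  dr <- ph$treatment == "I"
  ph$F1[dr] <- ph$F1[dr] - 4
  # F2: effect in half the varieties only -> VD
  hit <- ph$variety %in% default_varieties()[1:4]
  ph$F2[dr & hit] <- ph$F2[dr & hit] - 5
  cl <- classify_trait_effects(ph, alpha = 0.01)
  expect_equal(cl$class[cl$trait == "F1"], "D")
  expect_equal(cl$class[cl$trait == "F2"], "VD")
  expect_true(all(c("p_D", "p_VD") %in% names(cl)))
  # missing control errors
  expect_error(classify_trait_effects(ph[ph$treatment != "control", ]),
               "control")
})

test_that("trait F-tests hold their nominal type-I error", {
  n_seeds <- 400
  hits_D <- 0
  hits_VD <- 0
  total <- 0
  for (s in seq_len(n_seeds)) {
    ph <- make_pheno(n_var = 4, n_reps = 2, seed = s, traits = paste0("F", 1:5))
    cl <- classify_trait_effects(ph, alpha = 0.01)
    hits_D <- hits_D + sum(cl$p_D < 0.01)
    hits_VD <- hits_VD + sum(cl$p_VD < 0.01)
    total <- total + nrow(cl)
  }
  se <- sqrt(0.01 * 0.99 / total)
  expect_lt(abs(hits_D / total - 0.01), 4 * se)
  expect_lt(abs(hits_VD / total - 0.01), 4 * se)
})

test_that("trait effects and percent scaling are consistent", {
  ph <- make_pheno(noise = 0)
  dr <- ph$treatment == "I"
  ph$F1[dr] <- ph$F1[dr] - 2  # control 20, drought 18
  eff <- trait_effects(ph, as_percent_of_control = TRUE)
  row <- eff[eff$trait == "F1", ]
  expect_equal(row$effect, -2)
  expect_equal(row$percent, -10)
  # zero effect: 0 and 0%
  row2 <- eff[eff$trait == "F2", ]
  expect_equal(row2$effect, 0)
  expect_equal(row2$percent, 0)
  # consistency invariant percent * control / 100 = effect
  ctrl_mean <- mean(ph$F1[ph$treatment == "control"])
  expect_equal(row$percent * ctrl_mean / 100, row$effect, tolerance = 1e-10)
  # zero control mean errors under percent scaling
  ph$F3 <- ph$F3 - 20
  expect_error(trait_effects(ph, as_percent_of_control = TRUE), "zero control")
})

test_that("variety-specific trait effects recover planted percentages", {
  set.seed(7)
  n_seeds <- 50
  est <- replicate(n_seeds, {
    ph <- make_pheno(seed = sample.int(1e6, 1), noise = 0.4)
    dr <- ph$treatment == "I"
    ph$F1[dr] <- ph$F1[dr] - 4  # -20% of the baseline 20
    e <- trait_effects(ph, as_percent_of_control = TRUE)
    e$percent[e$trait == "F1"]
  })
  expect_lt(abs(mean(est) - (-20)), 3 * sd(est) / sqrt(n_seeds) + 0.5)
})

test_that("biplot coordinates factorize the centered effect matrix", {
  set.seed(4)
  # rank-1 matrix: first axis explains everything
  u <- rnorm(8)
  v <- rnorm(5)
  M1 <- outer(u, v)
  b1 <- biplot_coords(M1)
  expect_equal(b1$variance_explained[1], 1, tolerance = 1e-12)
  # rank-2 reconstruction is exact
  M2 <- outer(u, v) + outer(rnorm(8), rnorm(5))
  b2 <- biplot_coords(M2)
  C <- sweep(M2, 2, colMeans(M2))
  expect_equal(b2$scores %*% t(b2$loadings), C, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(b2$variance_explained), 1, tolerance = 1e-12)
  # duplicated variety rows get coincident scores
  M3 <- rbind(M2, M2[1, ])
  b3 <- biplot_coords(M3)
  expect_equal(b3$scores[9, ], b3$scores[1, ], ignore_attr = TRUE)
  # axes orthogonal; explained variance non-increasing
  expect_equal(sum(b2$scores[, 1] * b2$scores[, 2]), 0, tolerance = 1e-8)
  expect_gte(b2$variance_explained[1], b2$variance_explained[2])
  expect_error(biplot_coords(matrix(1, 4, 3)), "zero variance")
  expect_error(biplot_coords(matrix(1, 1, 3)), "at least 2")
})

test_that("effect correlations match the t-transform and flag degeneracy", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  # identical vectors: r = 1, p ~ 0
  out <- correlate_effects(cbind(M1 = x), cbind(F1 = x))
  expect_equal(out$r, 1)
  expect_lt(out$p, 1e-10)
  # against cor.test as the independent reference
  set.seed(5)
  y <- x + rnorm(8, sd = 2)
  out2 <- correlate_effects(cbind(M1 = x), cbind(F1 = y))
  ref <- cor.test(x, y)
  expect_equal(out2$r, unname(ref$estimate))
  expect_equal(out2$p, ref$p.value, tolerance = 1e-12)
  # zero variance flagged, not an error
  out3 <- correlate_effects(cbind(M1 = rep(1, 8)), cbind(F1 = y))
  expect_true(out3$degenerate)
  expect_true(is.na(out3$r))
  expect_error(correlate_effects(cbind(x[1:2]), cbind(y[1:2])), "at least 3")
})

test_that("the n = 8 significance threshold sits at |r| ~ 0.834", {
  # derived from the t quantile with 6 degrees of freedom
  t99 <- qt(0.995, 6)
  r_thr <- t99 / sqrt(6 + t99^2)
  expect_equal(r_thr, 0.8343, tolerance = 1e-4)
  x <- scale(1:8)[, 1]
  make_y <- function(r) {
    z <- scale(resid(lm(rnorm(8) ~ x)))[, 1]
    r * x + sqrt(1 - r^2) * z
  }
  set.seed(6)
  y_hi <- make_y(r_thr + 0.01)
  y_lo <- make_y(r_thr - 0.01)
  out <- correlate_effects(cbind(M1 = x), cbind(hi = y_hi, lo = y_lo))
  expect_true(out$sig01[out$trait == "hi"])
  expect_false(out$sig01[out$trait == "lo"])
  expect_true(all(out$sig05))
})

test_that("correlations are invariant to affine rescaling of either vector", {
  set.seed(8)
  x <- rnorm(8)
  y <- 0.7 * x + rnorm(8, sd = 0.5)
  base <- correlate_effects(cbind(M1 = x), cbind(F1 = y))
  resc <- correlate_effects(cbind(M1 = 3 * x - 10), cbind(F1 = -2 * y + 4))
  expect_equal(abs(resc$r), abs(base$r), tolerance = 1e-12)
  expect_equal(resc$p, base$p, tolerance = 1e-12)
})
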