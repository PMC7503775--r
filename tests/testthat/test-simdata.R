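test_that("design is a balanced factorial with matched controls", {
  d <- make_design(8, "I", list(I = c(3, 6, 10)), 4, seed = 1)
  expect_equal(nrow(d), 8 * 2 * 3 * 4)
  d2 <- make_design(8, "I+II", list("I+II" = c(1, 3, 6, 10)), 4, seed = 1)
  expect_equal(nrow(d2), 256)
  expect_true(all(d2$treatment == "I+II"))
  # every factor combination appears exactly n_reps times
  counts <- table(d$variety, d$condition, d$day)
  expect_true(all(counts == 4))
  # control rows matched per drought (variety, day)
  dr <- unique(d[d$condition == "drought", c("variety", "day")])
  co <- unique(d[d$condition == "control", c("variety", "day")])
  expect_equal(nrow(merge(dr, co)), nrow(dr))
  expect_false(anyDuplicated(d$sample_id) > 0)
  # determinism
  expect_identical(d, make_design(8, "I", list(I = c(3, 6, 10)), 4, seed = 1))
  # default study design: day 1 only under I+II
  full <- make_design(seed = 3)
  expect_true(all(full$treatment[full$day == 1] == "I+II"))
})

test_that("design rejects degenerate arguments", {
  expect_error(make_design(8, character(0), list(), 4), "non-empty")
  expect_error(make_design(8, "I", list(I = 3), 4, mass_range = c(-1, 2)),
               "positive")
  expect_error(make_design(1, "I", list(I = 3), 4), "n_varieties")
  expect_error(make_design(8, "I", list(I = integer(0)), 4), "day set")
  expect_error(make_design(8, "I", list(II = 3), 4), "no day set")
})

test_that("simulated chromatograms follow the peak model", {
  grid <- seq(0, 10, length.out = 1001)
  # no peaks, no baseline, no noise: all zero
  ch0 <- simulate_chromatogram(grid)
  expect_true(all(ch0$intensity == 0))
  # single gaussian: maximum at the grid point nearest the apex
  pk <- peak_spec(5.0, 0.1, 1)
  ch1 <- simulate_chromatogram(grid, pk)
  expect_equal(which.max(ch1$intensity), which.min(abs(grid - 5.0)))
  # piecewise-linear monotone warp, endpoints fixed, shifting the apex
  # region +0.2 min later
  w <- stats::approxfun(c(0, 2, 8, 10), c(0, 2 - 0.2, 8 - 0.2, 10))
  ch2 <- simulate_chromatogram(grid, pk, warp = w)
  dt <- grid[2] - grid[1]
  expect_lte(abs(grid[which.max(ch2$intensity)] - 5.2), 0.2 + dt + 1e-9)
  expect_error(simulate_chromatogram(grid, pk, warp = function(t) -t),
               "monotone")
  expect_error(simulate_chromatogram(c(1, 1, 2), pk), "increasing")
})

test_that("EMG peaks preserve area and gain a tail", {
  grid <- seq(0, 10, length.out = 4001)
  dt <- grid[2] - grid[1]
  g <- simulate_chromatogram(grid, peak_spec(5, 0.1, 2))$intensity
  e <- simulate_chromatogram(grid, peak_spec(5, 0.1, 2, "emg", 0.15))$intensity
  area_g <- sum((g[-1] + g[-length(g)]) / 2) * dt
  area_e <- sum((e[-1] + e[-length(e)]) / 2) * dt
  expect_equal(area_g, 2 * 0.1 * sqrt(2 * pi), tolerance = 1e-6)
  expect_equal(area_e, area_g, tolerance = 1e-4)
  # tailing: EMG mode sits later than the gaussian apex
  expect_gt(grid[which.max(e)], 5)
})

test_that("experiment generator plants areas multiplicatively and is deterministic", {
  des <- make_design(2, "I", list(I = c(3, 6)), n_reps = 2, seed = 9)
  probs <- setNames(c(0, 1, 0, 0, 0, 0), category_levels())  # all D
  cs <- simulate_experiment(des, n_metabolites = 3, category_probs = probs,
                            effect_size = 1, warp_magnitude = 0,
                            noise_sd = 0, baseline_magnitude = 0,
                            rt_range = c(0, 20), n_points = 2000,
                            peak_width = 0.08, seed = 9)
  gt <- cs$ground_truth
  expect_true(all(gt$categories$category == "D"))
  grid <- cs$grid
  # pick a matched drought/control pair (same variety, day, replicate)
  d <- cs$design
  i_dr <- which(d$condition == "drought")[1]
  i_co <- which(d$condition == "control" & d$variety == d$variety[i_dr] &
                  d$day == d$day[i_dr] & d$replicate == d$replicate[i_dr])[1]
  tr_dr <- cs$chromatograms[[paste0(d$sample_id[i_dr], "_280")]]$intensity
  tr_co <- cs$chromatograms[[paste0(d$sample_id[i_co], "_280")]]$intensity
  for (m in seq_len(3)) {
    rt_m <- gt$metabolites$rt[m]
    sel <- abs(grid - rt_m) < 4 * gt$metabolites$width[m]
    trapz <- function(y) sum((y[sel][-1] + y[sel][-sum(sel)]) / 2)
    eff <- gt$effects$effect[gt$effects$metabolite == gt$metabolites$metabolite[m] &
                               gt$effects$variety == d$variety[i_dr] &
                               gt$effects$day == d$day[i_dr]][1]
    expect_equal(trapz(tr_dr) / trapz(tr_co), 2^eff, tolerance = 1e-6)
  }
  # NoEffect everywhere, no noise/warp: drought equals control
  probs0 <- setNames(c(1, 0, 0, 0, 0, 0), category_levels())
  cs0 <- simulate_experiment(des, n_metabolites = 3, category_probs = probs0,
                             warp_magnitude = 0, noise_sd = 0,
                             baseline_magnitude = 0, rt_range = c(0, 20),
                             n_points = 1000, peak_width = 0.08, seed = 9)
  t_dr <- cs0$chromatograms[[paste0(d$sample_id[i_dr], "_280")]]$intensity
  t_co <- cs0$chromatograms[[paste0(d$sample_id[i_co], "_280")]]$intensity
  expect_equal(t_dr, t_co)
  # bit-identical reruns under a fixed seed
  cs_a <- simulate_experiment(des, n_metabolites = 3, seed = 4,
                              n_points = 500, rt_range = c(0, 20))
  cs_b <- simulate_experiment(des, n_metabolites = 3, seed = 4,
                              n_points = 500, rt_range = c(0, 20))
  expect_identical(lapply(cs_a$chromatograms, `[[`, "intensity"),
                   lapply(cs_b$chromatograms, `[[`, "intensity"))
  expect_error(simulate_experiment(des, n_metabolites = 0), "n_metabolites")
})

test_that("ground-truth categories constrain the planted effect maps", {
  des <- make_design(4, "I", list(I = c(3, 6, 10)), n_reps = 2, seed = 2)
  for (catg in c("D", "VD", "TD")) {
    probs <- setNames(as.numeric(category_levels() == catg), category_levels())
    cs <- simulate_experiment(des, n_metabolites = 4, category_probs = probs,
                              n_points = 500, rt_range = c(0, 20), seed = 3)
    for (m in cs$ground_truth$metabolites$metabolite) {
      em <- true_effect_matrix(cs$ground_truth, m, "I")
      if (catg == "D") {
        expect_equal(max(em) - min(em), 0)
      } else if (catg == "VD") {
        expect_true(all(apply(em, 1, function(r) diff(range(r)) == 0)))
        expect_gt(diff(range(em[, 1])), 0)
      } else {
        expect_true(all(apply(em, 2, function(cc) diff(range(cc)) == 0)))
        expect_gt(diff(range(em[1, ])), 0)
      }
    }
  }
})

test_that("phenotype simulation plants variety-specific links", {
  varieties <- default_varieties()
  des <- make_design(8, "I", list(I = c(3, 6, 10)), 2, seed = 5)
  gt <- link_ground_truth(varieties)
  # slope 0, no perturbation, no noise: every variety shares the trait effect
  link0 <- data.frame(trait = "F15", metabolite = "M001", treatment = "I",
                      slope = 0, perturb_sd = 0)
  sim0 <- simulate_phenotypes(des, gt, link = link0, noise_sd = 0, seed = 1)
  eff0 <- sim0$ground_truth$phenotype_effects
  f15 <- eff0[eff0$trait == "F15", ]
  expect_equal(diff(range(f15$effect)), 0)
  # positive slope, no perturbation: correlation of planted effects is 1
  link1 <- data.frame(trait = "F15", metabolite = "M001", treatment = "I",
                      slope = 0.5, perturb_sd = 0)
  sim1 <- simulate_phenotypes(des, gt, link = link1, noise_sd = 0, seed = 1)
  eff1 <- sim1$ground_truth$phenotype_effects
  f15 <- eff1[eff1$trait == "F15", ]
  met_v <- rowMeans(true_effect_matrix(gt, "M001", "I"))
  expect_equal(cor(met_v[f15$variety], f15$effect), 1)
  # unknown metabolite link errors
  bad <- data.frame(trait = "F15", metabolite = "M999", treatment = "I",
                    slope = 1, perturb_sd = 0)
  expect_error(simulate_phenotypes(des, gt, link = bad), "unknown linked")
})

test_that("warp construction is monotone with fixed endpoints", {
  w <- make_warp(c(0, 20), 0.05, seed = 3)
  g <- seq(0, 20, length.out = 500)
  expect_true(all(diff(w(g)) > 0))
  expect_equal(w(0), 0)
  expect_equal(w(20), 20)
  expect_error(make_warp(c(0, 1), 0.5, n_nodes = 6), "monotone")
})
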