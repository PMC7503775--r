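make_chrom <- function(intensity, rt = seq_along(intensity), mass = 100) {
  structure(list(rt = rt, intensity = intensity, wavelength = 280,
                 sample_id = "S0001", sample_mass = mass),
            class = "chromatogram")
}

test_that("mass normalization divides intensities and is idempotent", {
  ch <- make_chrom(c(2, 4, 6), mass = 100)
  n1 <- normalize_by_mass(ch)
  expect_equal(n1$intensity, c(0.02, 0.04, 0.06))
  expect_equal(normalize_by_mass(n1)$intensity, n1$intensity)
  ch1 <- make_chrom(c(2, 4), mass = 1)
  expect_equal(normalize_by_mass(ch1)$intensity, c(2, 4))
  expect_error(normalize_by_mass(make_chrom(1:3, mass = 0)), "positive")
})

test_that("differentiation removes constant and linear baselines", {
  expect_true(all(remove_baseline_by_differentiation(rep(5, 50)) == 0))
  lin <- remove_baseline_by_differentiation(0.3 * (1:50))
  expect_equal(lin[2:49], rep(0.3, 48))
  expect_error(remove_baseline_by_differentiation(c(1, 2)), "3 grid points")
  # gaussian on a linear baseline: derivative crosses the slope level at
  # the apex index +- 1
  i <- 1:1001
  apex <- 500
  y <- exp(-0.5 * ((i - apex) / 20)^2) + 0.001 * i
  d <- remove_baseline_by_differentiation(y)
  crossings <- which(diff(sign(d - 0.001)) < 0)
  expect_lte(min(abs(crossings - apex)), 1)
})

test_that("smoothed second derivative reproduces polynomials and locates apices", {
  n <- 1000
  a <- 0.003
  d1 <- remove_baseline_by_differentiation(a * (seq_len(n))^2)
  d2 <- smooth_second_derivative(d1, 200)
  expect_lt(max(abs(d2[50:950] - 2 * a)) / (2 * a), 1e-3)
  # noiseless gaussian: minimum of the smoothed second derivative at apex +- 2
  i <- seq_len(2000)
  g <- exp(-0.5 * ((i - 800) / 15)^2)
  d2g <- smooth_second_derivative(remove_baseline_by_differentiation(g), 400)
  expect_lte(abs(which.min(d2g) - 800), 2)
  expect_error(smooth_second_derivative(rnorm(100), 100), "below the signal")
  expect_error(smooth_second_derivative(rnorm(100), 3), ">= 4")
})

test_that("more knots leave more residual roughness under noise", {
  set.seed(2)
  i <- seq_len(2000)
  g <- exp(-0.5 * ((i - 800) / 15)^2)
  sig <- remove_baseline_by_differentiation(g) + rnorm(2000, sd = 0.002)
  rough <- vapply(c(50, 100, 520), function(k) {
    p <- smooth_second_derivative(sig, k)
    sum(diff(p, differences = 2)^2)
  }, numeric(1))
  expect_false(is.unsorted(rough))
})

test_that("peak detection keeps concave runs and filters irrelevant ones", {
  # flat profile: nothing
  empty <- detect_peaks(rep(0, 100), rep(0, 100))
  expect_equal(nrow(empty), 0)
  # single gaussian well above tolerance: exactly one interval with the apex
  i <- seq_len(2000)
  apex <- 900
  g <- 0.5 * exp(-0.5 * ((i - apex) / 12)^2)
  d1 <- remove_baseline_by_differentiation(g)
  d2 <- smooth_second_derivative(d1, 300)
  pk <- detect_peaks(d2, d1, 0.0005)
  expect_equal(nrow(pk), 1)
  expect_true(pk$start <= apex && apex < pk$end)
  expect_lte(abs(pk$apex - apex), 2)
  # same peak scaled so max |derivative| = 0.0004: filtered out
  scale <- 0.0004 / max(abs(d1))
  pk2 <- detect_peaks(smooth_second_derivative(d1 * scale, 300), d1 * scale,
                      0.0005)
  expect_equal(nrow(pk2), 0)
  # ...but kept at a tolerance below its maximum derivative
  pk3 <- detect_peaks(smooth_second_derivative(d1 * scale, 300), d1 * scale,
                      0.0003)
  expect_equal(nrow(pk3), 1)
})

test_that("detected intervals are disjoint with length at least 2", {
  set.seed(8)
  i <- seq_len(3000)
  sig <- rowSums(sapply(c(400, 900, 1500, 2200), function(a) {
    runif(1, 0.3, 1) * exp(-0.5 * ((i - a) / 14)^2)
  })) + rnorm(3000, sd = 0.003)
  d1 <- remove_baseline_by_differentiation(sig)
  d2 <- smooth_second_derivative(d1, 500)
  pk <- detect_peaks(d2, d1, 1e-4)
  expect_true(all(pk$end - pk$start >= 2))
  if (nrow(pk) > 1) {
    expect_true(all(pk$start[-1] >= pk$end[-nrow(pk)]))
    expect_false(is.unsorted(pk$start))
  }
})

test_that("common peaks merge by interval addition with support filtering", {
  iv <- function(s, e) data.frame(start = s, end = e, apex = s)
  # identical intervals in two samples
  cp <- build_common_peaks(list(a = iv(10, 20), b = iv(10, 20)), c1 = 2)
  expect_equal(nrow(cp), 1)
  expect_equal(cp$start, 10)
  expect_equal(cp$end, 20)
  expect_equal(cp$support, 2)
  # overlapping intervals: union
  cp2 <- build_common_peaks(list(a = iv(10, 20), b = iv(15, 25)), c1 = 1)
  expect_equal(cp2[, c("start", "end")], data.frame(start = 10, end = 25))
  # interval in 1 of 3 samples dropped at c1 = 2
  cp3 <- build_common_peaks(list(a = iv(10, 20), b = iv(100, 110),
                                 c = iv(101, 111)), c1 = 2)
  expect_equal(nrow(cp3), 1)
  expect_equal(cp3$start, 100)
  # c1 above the number of samples warns and yields nothing
  expect_warning(cp4 <- build_common_peaks(list(a = iv(1, 5)), c1 = 2),
                 "exceeds")
  expect_equal(nrow(cp4), 0)
  # half-open adjacency [10,20) + [20,30) does not merge
  cp5 <- build_common_peaks(list(a = iv(10, 20), b = iv(20, 30)), c1 = 1)
  expect_equal(nrow(cp5), 2)
})

test_that("common-peak construction is order-invariant and idempotent", {
  set.seed(3)
  ivs <- lapply(1:6, function(s) {
    st <- sort(sample(seq(1, 400, by = 7), 5))
    data.frame(start = st, end = st + sample(3:12, 5, replace = TRUE),
               apex = st)
  })
  names(ivs) <- paste0("s", 1:6)
  a <- build_common_peaks(ivs, c1 = 2)
  b <- build_common_peaks(rev(ivs), c1 = 2)
  expect_equal(a[, c("start", "end", "support")],
               b[, c("start", "end", "support")])
  # idempotent on its own output (support recomputation aside)
  again <- build_common_peaks(list(merged = a[, c("start", "end")]), c1 = 1)
  expect_equal(again[, c("start", "end")], a[, c("start", "end")])
})

test_that("integration is the rectified trapezoid times the grid step", {
  rt <- seq(0, 10, length.out = 101)  # dt = 0.1 min
  cp <- data.frame(peak_id = "P001", start = 21, end = 41, support = 1)
  # unit-height rectangle across the interval: value = rt width
  sig <- rep(0, 101)
  sig[21:40] <- 1
  v <- integrate_peaks(matrix(sig, 1), cp, rt)
  expect_equal(unname(v[1, 1]), rt[40] - rt[21])
  # zero signal integrates to zero
  expect_equal(unname(integrate_peaks(matrix(0, 1, 101), cp, rt)[1, 1]), 0)
  # rectification: negative lobes do not cancel the positive ones
  sig2 <- sig
  sig2[30:40] <- -1
  v2 <- integrate_peaks(matrix(sig2, 1), cp, rt)
  expect_equal(unname(v2[1, 1]), rt[29] - rt[21] + 0.05)
  expect_error(integrate_peaks(matrix(0, 1, 101),
                               data.frame(peak_id = "P", start = 90,
                                          end = 110, support = 1), rt),
               "outside")
})

test_that("rectified-derivative integral of a gaussian equals its height", {
  rt <- seq(0, 10, length.out = 2001)
  A <- 1.7
  sigma <- 0.12
  f <- A * exp(-0.5 * ((rt - 5) / sigma)^2)
  dfdt <- c(0, diff(f) / diff(rt))  # per-minute derivative
  cp <- data.frame(peak_id = "P001", start = 1, end = 2001, support = 1)
  v <- integrate_peaks(matrix(dfdt, 1), cp, rt)
  expect_equal(unname(v[1, 1]), A, tolerance = 0.01)
})

test_that("wavelength merging sums shared names and keeps co-elution labels", {
  vals <- function(x) matrix(x, 2, length(x) / 2,
                             dimnames = list(c("S1", "S2"), NULL))
  pt280 <- structure(list(
    values = vals(c(3, 3, 7, 7)),
    peaks = data.frame(peak_id = c("P001", "P002"), start = c(1, 10),
                       end = c(5, 15), support = 2, wavelength = 280),
    rt = 1:20, wavelength = 280), class = "peak_table")
  pt330 <- structure(list(
    values = vals(c(5, 5)),
    peaks = data.frame(peak_id = "P001", start = 2, end = 6, support = 2,
                       wavelength = 330),
    rt = 1:20, wavelength = 330), class = "peak_table")
  nm <- list("280" = list(P001 = "apigenin7OG", P002 = c("X", "Y")),
             "330" = list(P001 = "apigenin7OG"))
  mt <- merge_wavelengths(pt280, pt330, nm)
  expect_s3_class(mt, "metabolite_table")
  expect_equal(unname(mt$values[1, "apigenin7OG"]), 8)  # 3 + 5
  expect_true("X;Y" %in% colnames(mt$values))
  # no shared names: concatenation
  mt2 <- merge_wavelengths(pt280, pt330, NULL)
  expect_equal(ncol(mt2$values), 3)
  # ambiguous: one name on two peaks of the same wavelength
  nm_bad <- list("280" = list(P001 = "A", P002 = "A"), "330" = NULL)
  expect_error(merge_wavelengths(pt280, pt330, nm_bad), "more than one peak")
})

test_that("preprocessing recovers planted metabolites", {
  # noise 0, warp 0, c1 = all chromatograms: exactly the planted variables
  cs <- small_experiment(seed = 21, noise_sd = 0, warp_magnitude = 0)
  cfg <- preprocess_config(segment_len = 20, slack = 8, n_knots = 400,
                           c1 = nrow(cs$design))
  tab <- run_preprocessing(cs, cfg)
  expect_equal(sort(colnames(tab$values)),
               sort(cs$ground_truth$metabolites$metabolite))
  # moderate warp within slack: same variables, apexes within 2 grid steps
  cs2 <- small_experiment(seed = 22, warp_magnitude = 0.02)
  tab2 <- run_preprocessing(cs2, preprocess_config(segment_len = 20,
                                                   slack = 8, n_knots = 400))
  expect_equal(sort(colnames(tab2$values)),
               sort(cs2$ground_truth$metabolites$metabolite))
  pt <- attr(tab2, "peak_tables")[["280"]]
  planted_idx <- vapply(cs2$ground_truth$metabolites$rt, function(r) {
    which.min(abs(cs2$grid - r))
  }, integer(1))
  nearest <- vapply(planted_idx, function(i) min(abs(pt$peaks$apex - i)),
                    numeric(1))
  expect_true(all(nearest <= 2))
  # empty set errors
  empty <- cs
  empty$chromatograms <- list()
  expect_error(run_preprocessing(empty), "empty")
})

test_that("metabolite values are equivariant to joint intensity/mass scaling", {
  cs <- small_experiment(seed = 31, n_metabolites = 6, n_points = 1200)
  cs_scaled <- cs
  for (k in seq_along(cs_scaled$chromatograms)) {
    cs_scaled$chromatograms[[k]]$intensity <-
      cs_scaled$chromatograms[[k]]$intensity * 3
    cs_scaled$chromatograms[[k]]$sample_mass <-
      cs_scaled$chromatograms[[k]]$sample_mass * 3
  }
  cs_scaled$design$sample_mass <- cs_scaled$design$sample_mass * 3
  cfg <- preprocess_config(segment_len = 20, slack = 6, n_knots = 300)
  t1 <- run_preprocessing(cs, cfg)
  t2 <- run_preprocessing(cs_scaled, cfg)
  expect_equal(t1$values, t2$values)
})
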