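test_that("despike removes a single cosmic spike and nothing else", {
  ax <- seq(400, 1400, by = 2)
  clean <- 100 * exp(-((ax - 900)^2) / (2 * 30^2)) + 20
  set.seed(3)
  clean <- clean + rnorm(length(ax), sd = 0.5)
  spiked <- clean
  hit <- 260L
  spiked[hit] <- spiked[hit] + 1000
  r <- despike(raman_spectrum(ax, spiked), threshold = 8, window = 7L)
  expect_identical(r$corrected, hit)
  expect_lt(abs(r$spectrum$intensity[hit] - clean[hit]), 2)
  # every other channel is bit-identical to the input
  expect_identical(r$spectrum$intensity[-hit], spiked[-hit])
})

test_that("despike leaves spike-free and degenerate spectra untouched", {
  ax <- seq(400, 1400, by = 2)
  set.seed(4)
  smooth <- 50 * exp(-((ax - 700)^2) / (2 * 40^2)) + rnorm(length(ax), sd = 0.3)
  r <- despike(raman_spectrum(ax, smooth))
  expect_length(r$corrected, 0L)
  # all-constant spectrum: MAD floor avoids divide-by-zero, nothing flagged
  r2 <- despike(raman_spectrum(ax, rep(5, length(ax))))
  expect_length(r2$corrected, 0L)
  # flat zero with one spike: spike channel reset to ~0
  flat <- rep(0, length(ax)); flat[100L] <- 800
  r3 <- despike(raman_spectrum(ax, flat))
  expect_identical(r3$corrected, 100L)
  expect_lt(abs(r3$spectrum$intensity[100L]), 1e-9)
})

test_that("both baseline methods annihilate an exact quadratic", {
  ax <- seq(200, 3400, by = 3)
  u <- (ax - min(ax)) / diff(range(ax))
  q <- 3 + 2 * u - 1.5 * u^2
  for (m in c("poly2", "autopoly2")) {
    out <- baseline_correct(raman_spectrum(ax, q), m)
    expect_lt(max(abs(out$intensity)), 1e-8 * max(abs(q)))
  }
})

test_that("poly2 correction is linear: adding any quadratic changes nothing", {
  ax <- seq(200, 3400, by = 3)
  u <- (ax - min(ax)) / diff(range(ax))
  set.seed(6)
  for (i in 1:5) {
    s <- abs(rnorm(length(ax))) + 10 * exp(-((ax - 1450)^2) / (2 * 25^2))
    p <- rnorm(1) + rnorm(1) * u + rnorm(1) * u^2
    a <- baseline_correct(raman_spectrum(ax, s), "poly2")
    b <- baseline_correct(raman_spectrum(ax, s + p), "poly2")
    expect_lt(max(abs(a$intensity - b$intensity)), 1e-8 * max(abs(s)))
  }
})

test_that("autopoly2 recovers planted baseline coefficients under a narrow band", {
  # phantom with a single phenylalanine band (~1% of channels) on top of a
  # per-pixel random quadratic; coefficients bounded away from zero so the
  # relative error is well defined
  bands <- data.frame(component = "protein", center = 1007, sigma = 5,
                      amplitude = 0.3)
  cfg <- noiseless_config(width = 8L, height = 8L, n_planes = 2L,
                          bands = bands,
                          baseline_coeffs_range = rbind(c(0.3, 0.6),
                                                        c(0.1, 0.3),
                                                        c(-0.3, -0.1)),
                          seed = 7)
  g <- generate_stack(cfg, "control")
  p <- g$stack$planes[[1L]]
  fit <- ramanlayers:::fit_baseline_matrix(p$wavenumber, p$intensities,
                                           "autopoly2")
  rel <- abs(fit$coef - g$truth$planes[[1L]]$baseline_coeffs) /
    abs(g$truth$planes[[1L]]$baseline_coeffs)
  expect_lt(max(rel), 0.01)
})

test_that("autopoly2 preserves band peaks of a baseline-free spectrum", {
  ax <- seq(200, 3400, by = 3)
  s <- pure_component_spectrum("protein", ax, band_library())
  out <- baseline_correct(s, "autopoly2")
  i <- which.max(s$intensity)
  expect_lt(abs(out$intensity[i] - s$intensity[i]) / s$intensity[i], 0.02)
})

test_that("vector normalization yields unit in-region norm and is scale invariant", {
  ax <- seq(200, 3400, by = 3)
  set.seed(12)
  s <- raman_spectrum(ax, abs(rnorm(length(ax))) + 0.1)
  region <- c(450, 3200)
  inside <- ax >= region[1L] & ax <= region[2L]
  n1 <- vector_normalize(s, region)
  expect_equal(sqrt(sum(n1$intensity[inside]^2)), 1, tolerance = 1e-12)
  n2 <- vector_normalize(raman_spectrum(ax, 37.5 * s$intensity), region)
  expect_equal(n1$intensity, n2$intensity)
  # channels outside the region never influence the scale factor
  pert <- s$intensity
  pert[which(!inside)[1L]] <- pert[which(!inside)[1L]] + 1e6
  n3 <- vector_normalize(raman_spectrum(ax, pert), region)
  expect_equal(n3$intensity[inside], n1$intensity[inside])
  expect_error(vector_normalize(raman_spectrum(ax, rep(0, length(ax))), region),
               "450")
})

test_that("dialects pair the documented baseline method and normalization region", {
  fx <- preprocess_config("fixed")
  expect_identical(fx$baseline_method, "poly2")
  expect_equal(fx$region, c(450, 3200))
  un <- preprocess_config("unfixed")
  expect_identical(un$baseline_method, "autopoly2")
  expect_equal(un$region, c(200, 1500))
  g <- generate_stack(small_config(width = 3L, height = 3L), "control")
  log <- attr(preprocess_stack(g$stack), "preprocess_log")
  expect_identical(log$baseline_method, "poly2")
  expect_equal(log$normalization_region, c(450, 3200))
  expect_identical(log$order, c("despike", "baseline_correct", "vector_normalize"))
})

test_that("the preprocessing chain is idempotent to 1e-6 relative", {
  g <- generate_stack(small_config(width = 5L, height = 5L, seed = 11), "control")
  p1 <- preprocess_stack(g$stack)
  p2 <- preprocess_stack(p1)
  for (k in seq_along(p1$planes)) {
    a <- p1$planes[[k]]$intensities
    b <- p2$planes[[k]]$intensities
    expect_lt(max(abs(a - b)) / max(abs(a)), 1e-6)
  }
})

test_that("an all-zero stack fails with pixel coordinates in the message", {
  ax <- seq(400, 3400, by = 10)
  plane <- raman_plane(ax, matrix(0, length(ax), 4L), 2L, 2L, z = 0)
  plane2 <- raman_plane(ax, matrix(0, length(ax), 4L), 2L, 2L, z = 0.5)
  stack <- raman_stack(list(plane, plane2), dialect = "fixed")
  expect_error(preprocess_stack(stack), "plane 1, pixel \\(0, 0\\)")
})

test_that("despiking corrects injected phantom spikes without touching clean channels", {
  tot <- 0L; hitn <- 0L; false_alt <- 0L; clean <- 0
  for (s in 1:10) {
    cfg <- small_config(spike_rate = 0.2, seed = 100 + s)
    g <- generate_stack(cfg, "control")
    for (k in seq_along(g$stack$planes)) {
      p <- g$stack$planes[[k]]
      ds <- ramanlayers:::despike_matrix(p$intensities, 8, 7L)
      sp <- g$truth$planes[[k]]$spikes
      truth_keys <- paste(sp$pixel, sp$channel)
      corr_keys <- unlist(lapply(seq_along(ds$corrected), function(j) {
        if (length(ds$corrected[[j]])) paste(j, ds$corrected[[j]])
      }))
      tot <- tot + length(truth_keys)
      hitn <- hitn + sum(truth_keys %in% corr_keys)
      false_alt <- false_alt + sum(!(corr_keys %in% truth_keys))
      clean <- clean + length(p$intensities) - length(truth_keys)
    }
  }
  expect_gte(hitn / tot, 0.95)
  expect_lt(false_alt / clean, 0.001)
})
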