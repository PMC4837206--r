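test_that("Z = 0 designation maximizes total intensity with a low-z tiebreak", {
  st <- toy_stack(list(rep(1, 8), rep(5, 8), rep(3, 8)))
  expect_equal(designate_z0(st), 2L)
  st2 <- toy_stack(list(rep(5, 8), rep(5, 8), rep(1, 8)))
  expect_equal(designate_z0(st2), 1L)
  expect_error(designate_z0(toy_stack(list(rep(1, 8)))), "2 planes")
})

test_that("the brightest phantom plane lies in the media", {
  g <- generate_stack(noiseless_config(), "control")
  z0 <- designate_z0(g$stack)
  expect_identical(g$truth$labels[z0], "media")
  totals <- plane_totals(g$stack)
  expect_true(all(totals[-z0] < totals[z0]))
})

test_that("layer assignment splits retained planes into upper and lower", {
  st <- toy_stack(list(rep(10, 8), rep(8, 8), rep(6, 8)))
  a <- assign_layers(st, n_upper = 1L, signal_fraction_threshold = 0)
  expect_identical(a$labels, c("lower", "lower", "upper"))
  expect_equal(a$z0_index, 1L)
  expect_equal(a$z_rel, c(0, 1, 2))

  # a top plane at 1 % of the Z = 0 total is excluded at threshold 0.1 and
  # the next plane becomes the endothelium
  st5 <- toy_stack(list(rep(100, 8), rep(80, 8), rep(60, 8), rep(40, 8),
                        rep(1, 8)))
  a5 <- assign_layers(st5, n_upper = 1L, signal_fraction_threshold = 0.1)
  expect_identical(a5$labels,
                   c("lower", "lower", "lower", "upper", "excluded"))

  expect_error(assign_layers(st, n_upper = 3L), "retained")
  expect_error(assign_layers(st, signal_fraction_threshold = 2), "excluded")
})

test_that("average_spectrum is the channel-wise pixel mean", {
  ax <- 1:8
  m <- cbind(rep(0, 8), rep(2, 8))
  p <- raman_plane(ax, m, 2L, 1L, z = 0)
  expect_equal(average_spectrum(p)$intensity, rep(1, 8))
  p2 <- raman_plane(ax, cbind(ax, ax, ax), 3L, 1L, z = 0)
  expect_equal(average_spectrum(p2)$intensity, as.numeric(ax))
})

test_that("plane averaging suppresses noise as sigma over sqrt(N)", {
  cfg <- noiseless_config(width = 5L, height = 5L)
  truth <- render_plane(cfg, z = 0, "control", seed = 1)$truth$noiseless
  sd_target <- 0.05 / sqrt(25)
  cfg_n <- phantom_config(width = 5L, height = 5L, noise_sd = 0.05,
                          spike_rate = 0, baseline_coeffs_range = zero_baseline)
  keep <- seq(1, length(truth), by = 50)
  devs <- sapply(1:200, function(s) {
    r <- render_plane(cfg_n, z = 0, "control", seed = s)
    (average_spectrum(r$plane)$intensity - truth)[keep]
  })
  expect_equal(sd(as.vector(devs)), sd_target, tolerance = 0.2)
})

test_that("band integration matches the closed-form Gaussian integral", {
  ax <- seq(900, 1100, by = 1)
  A <- 1; s <- 4
  spec <- raman_spectrum(ax, A * exp(-((ax - 1007)^2) / (2 * s^2)))
  got <- integrate_band(spec, c(993, 1023))
  want <- A * s * sqrt(2 * pi) *
    (pnorm((1023 - 1007) / s) - pnorm((993 - 1007) / s))
  expect_equal(got, want, tolerance = 0.005)
  # window edges between channels: same closed form, shifted window
  got2 <- integrate_band(spec, c(993.5, 1022.5))
  want2 <- A * s * sqrt(2 * pi) *
    (pnorm((1022.5 - 1007) / s) - pnorm((993.5 - 1007) / s))
  expect_equal(got2, want2, tolerance = 0.005)
})

test_that("band integration is linear and exact on trivial input", {
  ax <- seq(900, 1100, by = 1)
  expect_equal(integrate_band(raman_spectrum(ax, rep(0, length(ax))),
                              c(993, 1023)), 0)
  set.seed(20)
  y <- abs(rnorm(length(ax)))
  a <- integrate_band(raman_spectrum(ax, y), c(993, 1023))
  b <- integrate_band(raman_spectrum(ax, 2 * y), c(993, 1023))
  expect_equal(b, 2 * a)
  expect_error(integrate_band(raman_spectrum(ax, y), c(2800, 3100)),
               "outside the axis span")
})

test_that("identical bands in both windows give unit lipid-to-protein ratio", {
  ax <- seq(400, 3400, by = 1)
  y <- exp(-((ax - 2940)^2) / (2 * 2^2)) + exp(-((ax - 1007)^2) / (2 * 2^2))
  r <- lipid_protein_ratio(raman_spectrum(ax, y), "fixed")
  expect_equal(r$R, 1, tolerance = 1e-6)
})

test_that("integration windows carry the dialect-specific bounds", {
  fx <- band_windows("fixed")
  expect_equal(fx[fx$name == "lipid_CH", c("lo", "hi")],
               data.frame(lo = 2825, hi = 3030), ignore_attr = TRUE)
  expect_equal(fx[fx$name == "protein_phe", c("lo", "hi")],
               data.frame(lo = 993, hi = 1023), ignore_attr = TRUE)
  un <- band_windows("unfixed")
  expect_equal(un[un$name == "lipid_CH", c("lo", "hi")],
               data.frame(lo = 2820, hi = 3012), ignore_attr = TRUE)
  expect_equal(un[un$name == "protein_phe", c("lo", "hi")],
               data.frame(lo = 997, hi = 1016), ignore_attr = TRUE)
})

test_that("a negative protein integral is rejected as an undefined ratio", {
  ax <- seq(400, 3400, by = 3)
  y <- rep(0, length(ax)) - 0.01
  expect_error(lipid_protein_ratio(raman_spectrum(ax, y), "fixed"),
               "undefined")
})

test_that("control endothelium shows the higher lipid-to-protein ratio", {
  g <- generate_stack(noiseless_config(), "control")
  prof <- profile_stack(g$stack, assignment = assign_layers(g$stack))
  up <- prof$planes$R[prof$planes$label == "upper"]
  lo <- prof$planes$R[prof$planes$label == "lower"]
  expect_true(all(up > lo))
})

test_that("compartment aggregates equal hand-computed means", {
  ax <- seq(400, 3400, by = 1)
  band <- function(a_ch, a_phe)
    a_ch * exp(-((ax - 2940)^2) / (2 * 20^2)) +
      a_phe * exp(-((ax - 1007)^2) / (2 * 4^2))
  st <- toy_stack(list(band(4, 2), band(3, 1), band(2, 1)),
                  wavenumber = ax, z = c(0, 0.5, 1))
  prof <- profile_stack(st, n_upper = 1L, signal_fraction_threshold = 0)
  w <- band_windows("fixed")
  I <- function(y, nm) integrate_band(raman_spectrum(ax, y), w[w$name == nm, ])
  hand <- sapply(list(band(4, 2), band(3, 1), band(2, 1)), function(y)
    c(I(y, "lipid_CH"), I(y, "protein_phe")))
  expect_equal(prof$planes$I_lipid, hand[1L, ])
  expect_equal(prof$planes$I_protein, hand[2L, ])
  comp <- prof$compartments
  expect_equal(comp$I_lipid[comp$compartment == "lower"], mean(hand[1L, 1:2]))
  expect_equal(comp$R[comp$compartment == "all"],
               mean(hand[1L, ] / hand[2L, ]))
  # `all` is independent of the upper/lower split
  prof2 <- profile_stack(st, n_upper = 2L, signal_fraction_threshold = 0)
  expect_equal(prof2$compartments[prof2$compartments$compartment == "all", ],
               comp[comp$compartment == "all", ], ignore_attr = TRUE)
})

test_that("the ratio is invariant to overall intensity scaling", {
  ax <- seq(400, 3400, by = 3)
  set.seed(30)
  y <- abs(rnorm(length(ax))) + 1
  r1 <- lipid_protein_ratio(raman_spectrum(ax, y), "fixed")
  r2 <- lipid_protein_ratio(raman_spectrum(ax, 123.4 * y), "fixed")
  expect_equal(r1$R, r2$R)
})

test_that("averaging and band integration commute", {
  ax <- seq(400, 3400, by = 3)
  set.seed(31)
  for (i in 1:5) {
    m <- matrix(abs(rnorm(length(ax) * 6)), ncol = 6L)
    p <- raman_plane(ax, m, 3L, 2L, z = 0)
    w <- band_windows("fixed")[1, ]
    avg_then_int <- integrate_band(average_spectrum(p), w)
    int_then_avg <- mean(apply(m, 2L, function(col)
      integrate_band(raman_spectrum(ax, col), w)))
    expect_equal(avg_then_int, int_then_avg, tolerance = 1e-10)
  }
})

test_that("noiseless profiling recovers the generator's mixture ratio exactly", {
  cfg <- noiseless_config()
  g <- generate_stack(cfg, "control")
  prof <- profile_stack(g$stack, assignment = assign_layers(g$stack))
  w <- band_windows("fixed")
  for (i in seq_len(nrow(prof$planes))) {
    k <- prof$planes$plane[i]
    truth_spec <- raman_spectrum(g$stack$planes[[k]]$wavenumber,
                                 g$truth$planes[[k]]$noiseless)
    R_truth <- integrate_band(truth_spec, w[1, ]) /
      integrate_band(truth_spec, w[2, ])
    expect_equal(prof$planes$R[i], R_truth, tolerance = 1e-6)
  }
})

test_that("a planted endothelial protein excess raises the upper protein integral", {
  ctl <- generate_stack(noiseless_config(), "control")
  met <- generate_stack(noiseless_config(), "metastasis")
  up <- function(g) {
    p <- profile_stack(g$stack, assignment = assign_layers(g$stack))
    p$compartments$I_protein[p$compartments$compartment == "upper"]
  }
  expect_gt(up(met), up(ctl))
})
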