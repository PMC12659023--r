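test_that("bin_density places a single particle in exactly one cell", {
  co <- array(0, c(1, 1, 3))
  co[1, 1, ] <- c(3.5, 7.2, 1.1)
  tr <- trajectory(co, c(10, 10, 10), 1)
  pt <- particle_table(1, "cation", 1)
  g <- bin_density(tr, pt, "cation", cell = 1)
  expect_equal(sum(g$density > 0), 1L)
  expect_equal(max(g$density), 1)            # 1 particle / 1 A^3
  expect_equal(g$density[4, 8, 2], 1)
})

test_that("bin_density conserves mass exactly and filters species", {
  run <- generate(electrolyte_spec(n = 30, duration = 400, seed = 12,
                                   water = 40))
  g <- bin_density(run$trajectory, run$particles, "cation", cell = 2)
  expect_equal(sum(g$density) * 2^3, 30)
  gw <- bin_density(run$trajectory, run$particles, "water_oxygen", cell = 2)
  expect_equal(sum(gw$density) * 2^3, 40)
  expect_error(bin_density(run$trajectory, run$particles, "nope"),
               "no particles")
})

test_that("out-of-grid particles error when wrapping is off", {
  co <- array(0, c(1, 1, 3)); co[1, 1, ] <- c(-5, 5, 5)
  tr <- trajectory(co, c(10, 10, 10), 1)
  pt <- particle_table(1, "cation", 1)
  expect_error(bin_density(tr, pt, "cation", wrap = FALSE),
               "outside the grid.*frame 1")
  expect_silent(bin_density(tr, pt, "cation", wrap = TRUE))
})

test_that("angular averaging maps exact uniform input to exact uniform output", {
  run <- generate(electrolyte_spec(n = 10, duration = 100, seed = 13))
  g <- bin_density(run$trajectory, run$particles, "all", cell = 2)
  g$density[] <- 0.25
  m <- to_cylindrical(g, r_bin = 3, z_bin = 7)
  expect_equal(max(abs(m$values - 0.25), na.rm = TRUE), 0)
  # empty annuli are NA, not zero: shrink r_max below the first bin
  m2 <- to_cylindrical(g, r_bin = 0.4, z_bin = 10)
  expect_true(anyNA(m2$values) || all(is.finite(m2$values)))
})

test_that("cylindrical conversion conserves mass with full radial coverage", {
  fx <- generate_density_fixture(radial_profile("uniform"), n = 500,
                                 frames = 8, box = c(40, 40, 40), seed = 14)
  g <- bin_density(fx$trajectory, fx$particles, "all", cell = 1)
  m <- to_cylindrical(g, r_bin = 2, z_bin = 4,
                      r_max = sqrt(2) * 20 + 1)
  expect_equal(sum(m$values * m$volume, na.rm = TRUE), 500)
})

test_that("sampled uniform density gives a flat map within 2%", {
  fx <- generate_density_fixture(radial_profile("uniform"), n = 20000,
                                 frames = 50, box = c(40, 40, 40),
                                 seed = 15)
  g <- bin_density(fx$trajectory, fx$particles, "all", cell = 1)
  m <- to_cylindrical(g, r_bin = 5, z_bin = 20)
  u <- 20000 / (40 * 40 * 40)     # uniform over the whole box
  expect_lt(max(abs(m$values / u - 1), na.rm = TRUE), 0.02)
})

test_that("annular Gaussian profile is recovered within 5%", {
  # >= 1e5 samples of a ring at r0 = 10
  fx <- generate_density_fixture(radial_profile("annular_gaussian",
                                                r0 = 10, width = 2),
                                 n = 20000, frames = 10,
                                 box = c(40, 40, 40), seed = 16)
  g <- bin_density(fx$trajectory, fx$particles, "all", cell = 1)
  m <- to_cylindrical(g, r_bin = 1, z_bin = 40)
  prof <- m$values[, 1]
  rc <- (m$r_edges[-1] + m$r_edges[-length(m$r_edges)]) / 2
  # peak within one bin of r0
  expect_lt(abs(rc[which.max(prof)] - 10), 1.5)
  # shape: compare to the bin-averaged analytic profile where the signal
  # is appreciable (>= 20% of peak)
  analytic <- exp(-(rc - 10)^2 / (2 * 2^2))
  pred <- analytic / max(analytic) * max(prof)
  sel <- analytic > 0.2
  expect_lt(max(abs(prof[sel] - pred[sel]) / max(prof)), 0.05)
})

test_that("map distance satisfies the closed-form constant-offset case", {
  a <- mk_map(matrix(0, 20, 70))
  b <- mk_map(matrix(1, 20, 70))
  region <- roi(c(0, 20), c(0, 70))
  # constant offset 1 over a full 40 x 70 ROI: d = sqrt(2800)
  expect_equal(map_distance(a, b, region), sqrt(2800))
  expect_equal(map_distance(a, a, region), 0)
  expect_equal(map_distance(a, b, region), map_distance(b, a, region))
  # missing cells drop their area pairwise
  b2 <- b; b2$values[1, 1] <- NA
  expect_equal(map_distance(a, b2, region), sqrt(2800 - 2))
  # mismatched binning refuses
  c <- mk_map(matrix(1, 10, 70))
  expect_error(map_distance(a, c), "mismatched bin geometry")
})

test_that("map distance obeys the metric axioms on random maps", {
  set.seed(200)
  for (k in 1:200) {
    x <- rand_map(); y <- rand_map(); z <- rand_map()
    dxy <- map_distance(x, y); dyx <- map_distance(y, x)
    dxz <- map_distance(x, z); dzy <- map_distance(z, y)
    expect_gte(dxy, 0)
    expect_identical(dxy, dyx)
    expect_lte(dxy, dxz + dzy + 1e-12)          # triangle inequality
    expect_equal(map_distance(x, x), 0)
  }
})

test_that("group_compare bookkeeping matches all-against-all counts", {
  set.seed(201)
  groups <- list(CT = lapply(1:10, function(i) rand_map()),
                 AO = lapply(1:10, function(i) rand_map()))
  gc <- group_compare(groups)
  intra <- gc[gc$kind == "intra", ]
  inter <- gc[gc$kind == "inter", ]
  expect_equal(intra$n_comparisons, c(45L, 45L))  # 10 choose 2
  expect_equal(inter$n_comparisons, 100L)         # 10 x 10
  expect_true(all(gc$error >= 0))
  # all maps identical -> all means zero
  same <- rand_map()
  gc0 <- group_compare(list(a = list(same, same), b = list(same, same)))
  expect_equal(gc0$mean, c(0, 0, 0))
})

test_that("distinct radial profiles separate inter above intra", {
  mk_group <- function(profile, seeds) lapply(seeds, function(s) {
    fx <- generate_density_fixture(profile, n = 3000, frames = 4,
                                   box = c(40, 40, 40), seed = s)
    g <- bin_density(fx$trajectory, fx$particles, "all", cell = 2)
    to_cylindrical(g, r_bin = 2, z_bin = 40)
  })
  hits <- vapply(1:20, function(rep) {
    base <- 1000 * rep
    A <- mk_group(radial_profile("annular_gaussian", r0 = 8, width = 3),
                  base + 1:3)
    B <- mk_group(radial_profile("annular_gaussian", r0 = 13, width = 3),
                  base + 11:13)
    gc <- group_compare(list(A = A, B = B))
    inter <- gc$mean[gc$kind == "inter"]
    all(inter > gc$mean[gc$kind == "intra"])
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("normalization and cylmap serialization round trip", {
  m <- rand_map()
  m$values <- abs(m$values) + 1
  nm <- normalize_map(m, bulk = 2)
  expect_equal(nm$values, m$values / 2)
  m$values[2, 3] <- NA
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cylmap(m, f)
  back <- read_cylmap(f)
  expect_equal(back$values, m$values, tolerance = 1e-12)
  expect_equal(back$r_edges, m$r_edges)
  expect_equal(back$z_edges, m$z_edges)
})
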