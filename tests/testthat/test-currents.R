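test_that("windowed current reproduces hand-evaluated displacement sums", {
  # A (+1 e) moves +1 A, B (-1 e) moves -1 A in one 20 ps window,
  # Lz = 100: I = (1*1 + (-1)*(-1))/(20*100) e/ps = 0.001 e/ps
  z <- rbind(c(50, 50), c(51, 49))
  tr <- traj_from_z(z)
  pt <- particle_table(1:2, c("cation", "anion"), c(1, -1))
  trace <- windowed_current(tr, pt, 20)
  expect_equal(trace$value, 0.001 * 160.2176634)
  expect_equal(nrow(trace), 1L)

  # static particles -> all zero
  zs <- matrix(30, 5, 3)
  pts <- particle_table(1:3, c("cation", "anion", "cation"), c(1, -1, 1))
  expect_true(all(windowed_current(traj_from_z(zs), pts)$value == 0))
})

test_that("minimum image treats a 99 -> 1 jump as +2, not -98", {
  z <- rbind(99, 1)
  tr <- traj_from_z(z)
  pt <- particle_table(1, "cation", 1)
  expect_equal(windowed_current(tr, pt, 20)$value,
               2 / (20 * 100) * 160.2176634)
})

test_that("tau must be commensurate with the frame spacing", {
  z <- matrix(runif(10 * 2, 0, 100), 10, 2)
  tr <- traj_from_z(z)
  pt <- particle_table(1:2, c("cation", "anion"), c(1, -1))
  expect_error(windowed_current(tr, pt, 30), "multiple")
  expect_error(windowed_current(tr, pt, -20), "multiple")
  # tau = 2 strides: windows are non-overlapping sums of pair displacements
  t40 <- windowed_current(tr, pt, 40)
  expect_equal(nrow(t40), 4L)
})

test_that("an exactly ambiguous Lz/2 displacement is refused", {
  z <- rbind(10, 60)    # dz = +50 = Lz/2
  tr <- traj_from_z(z)
  pt <- particle_table(1, "cation", 1)
  expect_error(windowed_current(tr, pt, 20), "ambiguous")
})

test_that("species decomposition is exact per window and warns when empty", {
  run <- generate(electrolyte_spec(n = 30, duration = 1000, seed = 8,
                                   water = 20))
  sc <- species_currents(run$trajectory, run$particles, 20)
  expect_equal(sc$all$value, sc$cation$value + sc$anion$value)

  # only water present -> ion traces zero, with a warning
  sp <- data.frame(name = "water_oxygen", count = 5, charge = 0,
                   D = 0.01, v = 0)
  wrun <- generate(synthetic_spec(c(50, 50, 100), sp, frame_interval = 20,
                                  duration = 200, seed = 2))
  expect_warning(tr <- windowed_current(wrun$trajectory, wrun$particles,
                                        20, "cation"),
                 "no particles")
  expect_true(all(tr$value == 0))
})

test_that("constant-drift current matches the closed form", {
  # v+ = +0.01, v- = -0.01 A/ps, 50 ions each, Lz = 100:
  # E[I_cation] = 50*0.01/100 e/ps = 0.801 nA
  run <- generate(electrolyte_spec(n = 50, v = 0.01, D = 0,
                                   duration = 2000, seed = 3))
  sc <- species_currents(run$trajectory, run$particles, 20)
  # exact against the lattice ground truth, and against the hand value
  # to the generator's drift-lattice precision (~1e-6 relative)
  expect_equal(mean(sc$cation$value), run$truth$current_nA[["cation"]],
               tolerance = 1e-12)
  expect_equal(mean(sc$cation$value), 0.005 * 160.2176634,
               tolerance = 1e-5)
  expect_equal(mean(sc$anion$value), run$truth$current_nA[["cation"]],
               tolerance = 1e-12)
})

test_that("water flux counts molecules, ignoring charge", {
  # 100 waters advancing +1 A per 20 ps window, Lz = 100:
  # 100*1/(20*100) = 0.05 molecules/ps = 50 molecules/ns
  z <- rbind(rep(10, 100), rep(11, 100))
  tr <- traj_from_z(z)
  pt <- particle_table(1:100, "water_oxygen", 0)
  expect_equal(water_flux(tr, pt, 20)$value, 50)
  expect_error(water_flux(tr, particle_table(1:100, "cation", 1), 20),
               "water_oxygen")
})

test_that("drift-diffusion water flux recovers N*v/Lz within 3 SE", {
  # N = 1000 waters at v = 0.002 A/ps, Lz = 100 -> 20 molecules/ns
  sp <- data.frame(name = "water_oxygen", count = 1000, charge = 0,
                   D = 0.04, v = 0.002)
  run <- generate(synthetic_spec(c(50, 50, 100), sp, frame_interval = 20,
                                 duration = 20000, seed = 4))
  est <- block_error(water_flux(run$trajectory, run$particles, 20),
                     block = 2000, discard = 0)
  expect_equal(est$units, "molecules/ns")
  expect_lt(abs(est$mean - 20), 3 * est$error)
})

test_that("telescoping: time-averaged current equals endpoint displacement sum", {
  run <- generate(electrolyte_spec(n = 40, duration = 2000, seed = 6))
  u <- attr(run$trajectory, "unwrapped")
  trace <- windowed_current(u, run$particles, 20)
  q <- run$particles$charge
  nf <- n_frames(u)
  total <- sum(q * (u$coords[nf, , 3] - u$coords[1, , 3]))
  Tdur <- u$times[nf] - u$times[1]
  expect_equal(mean(trace$value),
               total / (Tdur * 100) * 160.2176634, tolerance = 1e-12)
})

test_that("wrapped and unwrapped twins give bitwise-equal traces", {
  run <- generate(electrolyte_spec(n = 50, duration = 4000, seed = 10,
                                   water = 50))
  w <- run$trajectory; u <- attr(w, "unwrapped")
  expect_identical(windowed_current(w, run$particles, 20)$value,
                   windowed_current(u, run$particles, 20)$value)
  expect_identical(water_flux(w, run$particles, 20)$value,
                   water_flux(u, run$particles, 20)$value)
  # also at tau = 3 frames
  expect_identical(windowed_current(w, run$particles, 60)$value,
                   windowed_current(u, run$particles, 60)$value)
})

test_that("block_error averages retained windows and blocks correctly", {
  # constant trace -> zero error
  tr <- poreflux:::current_trace(seq(0, 980, 20), rep(2, 50), 20, "all",
                                 "nA")
  est <- block_error(tr, block = 200, discard = 0)
  expect_equal(est$mean, 2)
  expect_equal(est$error, 0)
  expect_equal(est$n, 5L)
  # discard drops early windows; short traces refuse
  est2 <- block_error(tr, block = 200, discard = 500)
  expect_equal(est2$n, 2L)
  expect_error(block_error(tr, block = 600, discard = 0), "2 complete blocks")
})

test_that("block error is consistent with the analytic SEM on iid noise", {
  # ratio of block error to sigma/sqrt(M*B) has expectation c4(B);
  # check the mean ratio over seeds against the analytic value
  B <- 10; M <- 20; sigma <- 1.5
  c4 <- sqrt(2 / (B - 1)) * gamma(B / 2) / gamma((B - 1) / 2)
  set.seed(100)
  ratios <- replicate(200, {
    v <- rnorm(B * M, 0, sigma)
    tr <- poreflux:::current_trace(seq_along(v) * 20 - 20, v, 20, "all",
                                   "nA")
    block_error(tr, block = M * 20, discard = 0)$error /
      (sigma / sqrt(M * B))
  })
  sd_ratio <- sqrt(1 - c4^2)
  expect_lt(abs(mean(ratios) - c4), 5 * sd_ratio / sqrt(200))
})

test_that("block error exceeds the naive SEM on AR(1) traces", {
  set.seed(101)
  phi <- 0.9
  wins <- 400
  hits <- replicate(100, {
    v <- as.vector(arima.sim(list(ar = phi), wins))
    tr <- poreflux:::current_trace(seq_len(wins) * 20 - 20, v, 20, "all",
                                   "nA")
    be <- block_error(tr, block = 40 * 20, discard = 0)$error
    naive <- sd(v) / sqrt(wins)
    be > naive
  })
  expect_gte(mean(hits), 0.95)
})

test_that("replica aggregation follows the sd/sqrt(n) rule", {
  # replica means 1, 2, 3 -> mean 2, error sd/sqrt(3) = 1/sqrt(3)
  agg <- replica_aggregate(list(fe(1), fe(2), fe(3)))
  expect_equal(agg$mean, 2)
  expect_equal(agg$error, 1 / sqrt(3))
  expect_equal(agg$n, 3L)
  # identical replicas -> zero error
  expect_equal(replica_aggregate(list(fe(5), fe(5)))$error, 0)
  # single replica falls back with a warning
  expect_warning(one <- replica_aggregate(list(fe(4, 0.3))), "single")
  expect_equal(one$error, 0.3)
  expect_error(replica_aggregate(list(fe(1), fe(1, units = "S/m"))),
               "mixed units")
})

test_that("synthetic replicas recover the ground truth within 3 SE", {
  s0 <- electrolyte_spec(n = 50, v = 0.01, D = 0.04, duration = 4000)
  truth <- ground_truth(s0)$current_nA[["total"]]
  ests <- lapply(1:10, function(k) {
    run <- generate(electrolyte_spec(n = 50, v = 0.01, D = 0.04,
                                     duration = 4000, seed = 300 + k))
    block_error(windowed_current(run$trajectory, run$particles, 20),
                block = 400, discard = 0)
  })
  agg <- replica_aggregate(ests)
  expect_lt(abs(agg$mean - truth), 3 * agg$error)
})

test_that("selectivity difference propagates in quadrature; ratio flags", {
  sel <- selectivity_indicator(fe(2, 0.1), fe(1, 0.1))
  expect_equal(sel$difference$mean, 1)
  expect_equal(sel$difference$error, sqrt(0.02))
  expect_true(sel$ratio$reliable)
  # equal currents -> zero difference
  expect_equal(selectivity_indicator(fe(1, 0.1), fe(1, 0.1))$difference$mean,
               0)
  # negligible anion current -> ratio unreliable
  sel2 <- selectivity_indicator(fe(2, 0.1), fe(0.01, 0.05))
  expect_false(sel2$ratio$reliable)
})
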