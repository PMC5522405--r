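test_that("built lipids realize their target inter-chain angles exactly", {
  cases <- list(
    list(spec = tg_spec("tuning_fork"), want = c(30, 135)),
    list(spec = tg_spec("trident"), want = c(30, 30)),
    list(spec = tg_spec("random"), want = c(75, 85)),
    list(spec = tg_spec("random", target_sn1sn3 = 0, target_sn2sn3 = 180),
         want = c(0, 180)),
    list(spec = tg_spec("tuning_fork",
                        representation = "coarse_grained"), want = c(30, 135))
  )
  for (cs in cases) {
    built <- build_tg(cs$spec, seed = 99)
    expect_lt(abs(built$realized[["sn1sn3"]] - cs$want[1]), 1e-6)
    expect_lt(abs(built$realized[["sn2sn3"]] - cs$want[2]), 1e-6)
  }
  expect_error(tg_spec("tuning_fork", target_sn1sn3 = 200), "0, 180")
})

test_that("atomistic lipids carry C=C pairs straddling the chain tip", {
  built <- build_tg(tg_spec("tuning_fork", representation = "atomistic"),
                    seed = 4)
  frame <- built$frame
  topo <- built$topology
  expect_equal(n_sites(frame), 10L)
  for (k in 1:3) {
    pair <- topo$chain_sites[[k]]
    a <- frame$coords[pair[1], ]
    b <- frame$coords[pair[2], ]
    expect_equal(sqrt(sum((a - b)^2)), 0.7, tolerance = 1e-9)
    mid <- (a + b) / 2
    expect_equal(sqrt(sum((mid - frame$coords[topo$central_site, ])^2)), 12,
                 tolerance = 1e-9)
  }
})

test_that("CG lipids emit the 13-bead layout with D-beads at the tips", {
  built <- build_tg(tg_spec("trident", representation = "coarse_grained"),
                    seed = 4)
  expect_equal(n_sites(built$frame), 13L)
  expect_setequal(
    built$frame$site_name,
    c("GLY", "ES1", "ES2", "ES3", "C1A", "D2A", "C3A", "C1B", "D2B", "C3B",
      "C1C", "D2C", "C3C"))
  raw <- compute_chain_vectors(built$frame, built$topology)
  expect_equal(unname(apply(raw, 1, function(v) sqrt(sum(v^2)))),
               rep(12, 3), tolerance = 1e-9)
})

test_that("pair arrangements place lipids on the tunnel half-axes", {
  built <- build_pair_arrangement("parallel_NN", axis_length = 60, seed = 1)
  cn <- built$frame$coords[built$topology_n$central_site, ]
  cc <- built$frame$coords[built$topology_c$central_site, ]
  expect_equal(sqrt(sum((cn - cc)^2)), 30, tolerance = 1e-9)
  expect_equal(cn, c(15, 0, 0), tolerance = 1e-9)
  expect_equal(cc, c(45, 0, 0), tolerance = 1e-9)
})

test_that("pair arrangements classify to their defining label", {
  axis <- c(1, 0, 0)
  want <- list(parallel_NN = c("HEAD_TO_LEGS", "HEAD_TO_LEGS"),
               antiparallel_NC = c("HEAD_TO_LEGS", "LEGS_TO_HEAD"),
               parallel_CC = c("LEGS_TO_HEAD", "LEGS_TO_HEAD"),
               antiparallel_CN = c("LEGS_TO_HEAD", "HEAD_TO_LEGS"))
  for (lab in names(want)) {
    built <- build_pair_arrangement(lab, seed = 3)
    for (i in 1:2) {
      topo <- list(built$topology_n, built$topology_c)[[i]]
      raw <- compute_chain_vectors(built$frame, topo)
      ang <- inter_chain_angles(assign_roles(raw, axis))
      expect_equal(classify_orientation(ang[["sn1sn3"]]), want[[lab]][i])
    }
  }
})

test_that("parallel_CC lipids point a single chain toward the C-terminal", {
  built <- build_pair_arrangement("parallel_CC", seed = 8)
  raw <- compute_chain_vectors(built$frame, built$topology_n)
  proj <- raw %*% c(1, 0, 0)
  # legs-to-head: exactly one chain (the head, role sn1) points C-ward
  expect_equal(sum(proj > 0), 1L)
  triple <- assign_roles(raw, c(1, 0, 0))
  expect_gt(sum(triple$sn1 * c(1, 0, 0)), 0)
})

test_that("scaffolds reproduce prescribed bend and twist to 1e-6 degree", {
  for (case in list(c(139, 8), c(118, -12), c(180, 0), c(90, 45))) {
    built <- build_scaffold(scaffold_spec(case[1], case[2]), seed = 21)
    expect_lt(abs(bending_angle(built$frame, built$domains) - case[1]), 1e-6)
    expect_lt(abs(twist_angle(built$frame, built$domains) - case[2]), 1e-6)
  }
})

test_that("unrealizable scaffold geometries raise geometry errors", {
  expect_error(build_scaffold(scaffold_spec(30, 60)), "geometry error")
  expect_error(build_scaffold(scaffold_spec(180, 5)), "geometry error")
  expect_error(scaffold_spec(0, 0), "bend_deg")
  expect_error(scaffold_spec(139, 95), "twist_deg")
})

test_that("zero noise reproduces the signature angles exactly", {
  ts <- trajectory_spec(20, state_sequence = rep("PARALLEL_NN", 20),
                        angular_noise_sigma = 0, seed = 5)
  gen <- generate_trajectory(ts)
  expect_true(all(abs(gen$truth$sn1sn3_n - 30) < 1e-9))
  expect_true(all(abs(gen$truth$sn2sn3_n - 135) < 1e-9))
  expect_true(all(abs(gen$truth$sn1sn3_c - 30) < 1e-9))
})

test_that("the same seed generates bit-identical trajectories", {
  ts <- trajectory_spec(50, state_sequence = rep(c("PARALLEL_NN", "RANDOM"),
                                                 25),
                        angular_noise_sigma = 12, noise_truncation = 25,
                        seed = 77)
  g1 <- generate_trajectory(ts)
  g2 <- generate_trajectory(ts)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)
  expect_identical(g1$truth, g2$truth)
})

test_that("truncated noise keeps head-to-legs angles under the threshold", {
  ts <- trajectory_spec(1000, state_sequence = rep("PARALLEL_NN", 1000),
                        angular_noise_sigma = 10, noise_truncation = 20,
                        seed = 42)
  gen <- generate_trajectory(ts)
  # each chain vector rotates by at most 20 deg, so 30 + 2*20 < 75
  expect_true(all(gen$truth$sn1sn3_n < 75))
  expect_true(all(gen$truth$sn1sn3_c < 75))
})

test_that("random-band lipids stay strictly inside the random band", {
  ts <- trajectory_spec(400, state_sequence = rep("RANDOM", 400),
                        angular_noise_sigma = 10, noise_truncation = 20,
                        seed = 6)
  gen <- generate_trajectory(ts)
  band <- pmax(gen$truth$sn1sn3_n * (gen$truth$orientation_n == "RANDOM"),
               gen$truth$sn1sn3_c * (gen$truth$orientation_c == "RANDOM"))
  band <- band[band > 0]
  expect_true(all(band > 75 & band < 105))
})

test_that("markov sequences converge to the stationary distribution", {
  pi0 <- c(PARALLEL_NN = 0.646, ANTIPARALLEL_NC = 0.199, PARALLEL_CC = 0,
           ANTIPARALLEL_CN = 0, RANDOM = 0.155)
  # sticky chain: stay with prob 1/2, else draw from pi0; stationary = pi0
  P <- 0.5 * diag(5) + 0.5 * matrix(pi0, 5, 5, byrow = TRUE)
  dimnames(P) <- list(names(pi0), names(pi0))
  n <- 10000L
  ts <- trajectory_spec(n, transition_matrix = P, seed = 31)
  gen <- generate_trajectory(ts)
  emp <- pair_distribution(gen$truth$state)
  # autocorrelation 0.5 -> effective sample size n/3
  se <- sqrt(pi0 * (1 - pi0) / (n / 3))
  for (s in names(pi0)) {
    expect_lt(abs(emp[[s]] - pi0[[s]]), 3 * se[[s]] + 1e-12)
  }
  expect_identical(unname(emp[c("PARALLEL_CC", "ANTIPARALLEL_CN")]), c(0, 0))
})

test_that("stationary_distribution solves pi = pi P", {
  P <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2, byrow = TRUE)
  dimnames(P) <- list(c("a", "b"), c("a", "b"))
  pi0 <- stationary_distribution(P)
  expect_equal(as.vector(pi0 %*% P), unname(pi0), tolerance = 1e-12)
  expect_equal(sum(pi0), 1, tolerance = 1e-12)
})

test_that("scaffold trajectories sweep the prescribed bend series", {
  sweep_vals <- seq(118, 147, length.out = 30)
  st <- scaffold_trajectory(scaffold_spec(139, 0), bend_series = sweep_vals,
                            twist_series = 0, seed = 9)
  bt <- bend_twist_series(st$trajectory, st$domains)
  expect_equal(min(bt$series$bend), 118, tolerance = 1e-6)
  expect_equal(max(bt$series$bend), 147, tolerance = 1e-6)
  expect_equal(bt$series$bend, sweep_vals, tolerance = 1e-6)
})
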