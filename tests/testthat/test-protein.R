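test_that("centre of mass weights by mass, geometric when forced", {
  fr <- point_frame(rbind(c(0, 0, 0), c(2, 0, 0)), mass = 1)
  expect_equal(center_of_mass(fr, sites = 1:2), c(1, 0, 0))
  fr$mass <- c(1, 3)
  expect_equal(center_of_mass(fr, sites = 1:2), c(1.5, 0, 0))
  expect_equal(center_of_mass(fr, sites = 1:2, weighting = "geometric"),
               c(1, 0, 0))
  fr$mass <- c(0, 3)
  expect_warning(com <- center_of_mass(fr, sites = 1:2), "mass-0")
  expect_equal(com, c(1, 0, 0))
  expect_error(center_of_mass(fr, sites = integer(0)), "empty selection")
})

test_that("bending angle handles collinear and right-angle geometries", {
  fr <- point_frame(rbind(c(-5, 0, 0), c(0, 0, 0), c(5, 0, 0)))
  dom <- domain_definition(n_barrel = 1L, central_sheet = 2L, c_barrel = 3L)
  expect_equal(bending_angle(fr, dom), 180)
  fr2 <- point_frame(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)))
  expect_equal(bending_angle(fr2, dom), 90)
  fr3 <- point_frame(rbind(c(0, 0, 0), c(0, 0, 0), c(5, 0, 0)))
  expect_error(bending_angle(fr3, dom), "degenerate")
})

test_that("twist angle is the signed azimuth between barrel planes", {
  # axis along +x from residues 2,3 (n_end) to 4,5 (c_end)
  mk <- function(pn, pc) {
    fr <- point_frame(rbind(pn, c(-5, 0, 0), c(-5, 0, 0), c(5, 0, 0),
                            c(5, 0, 0), pc))
    dom <- domain_definition(n_barrel = 1L, central_sheet = 2:5,
                             c_barrel = 6L, n_end = 2:3, c_end = 4:5)
    twist_angle(fr, dom)
  }
  expect_equal(mk(c(-10, 3, 0), c(10, 3, 0)), 0, tolerance = 1e-12)
  # C barrel rotated +90 about the axis (right-hand rule, N to C)
  expect_equal(mk(c(-10, 3, 0), c(10, 0, 3)), 90, tolerance = 1e-9)
  expect_equal(mk(c(-10, 3, 0), c(10, 0, -3)), -90, tolerance = 1e-9)
  expect_equal(mk(c(-10, 3, 0), c(10, -3, 1e-9)), 180, tolerance = 1e-6)
  expect_error(mk(c(-10, 0, 0), c(10, 3, 0)), "axis")
})

test_that("bend and twist are rigid-motion invariant, twist flips on mirror", {
  built <- build_scaffold(scaffold_spec(127, -17), seed = 5)
  bend0 <- bending_angle(built$frame, built$domains)
  twist0 <- twist_angle(built$frame, built$domains)
  set.seed(29)
  for (rep in 1:15) {
    moved <- transform_frame(built$frame, random_rotation(),
                             rnorm(3, sd = 50))
    expect_equal(bending_angle(moved, built$domains), bend0,
                 tolerance = 1e-9)
    expect_equal(twist_angle(moved, built$domains), twist0,
                 tolerance = 1e-9)
  }
  mirrored <- mirror_frame(built$frame)
  expect_equal(bending_angle(mirrored, built$domains), bend0,
               tolerance = 1e-9)
  expect_equal(twist_angle(mirrored, built$domains), -twist0,
               tolerance = 1e-9)
})

test_that("kabsch rmsd is zero iff frames are rigidly related", {
  set.seed(8)
  fr <- point_frame(matrix(rnorm(30, sd = 5), 10, 3))
  expect_equal(kabsch_rmsd(fr, fr)$rmsd, 0, tolerance = 1e-12)
  moved <- transform_frame(fr, random_rotation(), rnorm(3, sd = 20))
  expect_equal(kabsch_rmsd(fr, moved)$rmsd, 0, tolerance = 1e-9)
  bumped <- fr
  bumped$coords[4, ] <- bumped$coords[4, ] + c(3, 0, 0)
  expect_gt(kabsch_rmsd(fr, bumped)$rmsd, 0.5)
})

test_that("kabsch rmsd equals the quaternion-method oracle", {
  set.seed(9)
  for (rep in 1:25) {
    n <- sample(3:40, 1)
    A <- matrix(rnorm(3 * n, sd = 8), n, 3)
    B <- matrix(rnorm(3 * n, sd = 8), n, 3)
    fa <- point_frame(A)
    fb <- point_frame(B)
    got <- kabsch_rmsd(fa, fb)$rmsd
    expect_equal(got, horn_rmsd(A, B), tolerance = 1e-9)
    expect_equal(got, kabsch_rmsd(fb, fa)$rmsd, tolerance = 1e-9)
  }
  # the 3-site case with one displaced site, against the oracle
  A <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0))
  B <- A
  B[3, ] <- B[3, ] + c(0, 3, 0)
  expect_equal(kabsch_rmsd(point_frame(A), point_frame(B))$rmsd,
               horn_rmsd(A, B), tolerance = 1e-9)
})

test_that("kabsch never uses an improper rotation", {
  set.seed(14)
  fr <- point_frame(matrix(rnorm(24, sd = 5), 8, 3))
  reflected <- fr
  reflected$coords[, 1] <- -reflected$coords[, 1]
  fit <- kabsch_rmsd(fr, reflected)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.1)
})

test_that("average structure honours window and fit conventions", {
  set.seed(15)
  base <- point_frame(matrix(rnorm(18, sd = 6), 6, 3))
  single <- average_structure(as_trajectory(list(base)))
  expect_equal(single$coords, base$coords, tolerance = 1e-12)

  # frames differing only in one site, fit on the common sites: midpoint
  fa <- base
  fb <- base
  fa$coords[6, ] <- fa$coords[6, ] + c(2, 0, 0)
  fb$coords[6, ] <- fb$coords[6, ] - c(2, 0, 0)
  avg <- average_structure(as_trajectory(list(fa, fb)), selection = 1:5)
  expect_equal(avg$coords[6, ], base$coords[6, ], tolerance = 1e-9)
  expect_equal(avg$coords[1:5, ], base$coords[1:5, ], tolerance = 1e-9)

  # rigid-motion copies collapse back to the reference frame
  set.seed(16)
  copies <- lapply(1:6, function(i) {
    transform_frame(base, random_rotation(), rnorm(3, sd = 15))
  })
  avg2 <- average_structure(as_trajectory(copies))
  expect_equal(kabsch_rmsd(avg2, copies[[1]],
                           selection = 1:6)$rmsd, 0, tolerance = 1e-9)
  it <- average_structure(as_trajectory(copies), method = "iterative")
  expect_equal(kabsch_rmsd(it, copies[[1]], selection = 1:6)$rmsd, 0,
               tolerance = 1e-9)
  expect_error(average_structure(as_trajectory(copies),
                                 frame_window = integer(0)), "empty")
})

test_that("bend/twist series over a constant scaffold is constant", {
  st <- scaffold_trajectory(scaffold_spec(139, 8), bend_series = rep(139, 5),
                            twist_series = rep(8, 5), seed = 2)
  bt <- bend_twist_series(st$trajectory, st$domains)
  expect_equal(bt$series$bend, rep(139, 5), tolerance = 1e-6)
  expect_equal(bt$series$twist, rep(8, 5), tolerance = 1e-6)
  expect_equal(sum(bt$bend_hist$mass), 1, tolerance = 1e-12)
  expect_equal(sum(bt$twist_hist$mass), 1, tolerance = 1e-12)
})

test_that("window splits of a stationary series agree within 3 SE", {
  set.seed(44)
  nf <- 400
  bends <- pmin(pmax(rnorm(nf, 132, 4), 100), 170)
  st <- scaffold_trajectory(scaffold_spec(139, 0), bend_series = bends,
                            twist_series = 0, seed = 3)
  bt <- bend_twist_series(st$trajectory, st$domains, bin_width = 10,
                          n_windows = 4)
  expect_length(bt$window_bend_hists, 4L)
  overall <- bt$bend_hist$mass
  nw <- nf / 4
  for (h in bt$window_bend_hists) {
    se <- sqrt(pmax(overall * (1 - overall), 1e-12) / nw)
    expect_true(all(abs(h$mass - overall) <= 3 * se + 1e-9))
  }
})

test_that("domain definitions validate ranges and sub-ranges", {
  expect_error(domain_definition(1:5, 4:10, 11:20), "disjoint")
  expect_error(domain_definition(integer(0), 4:10, 11:20), "non-empty")
  expect_error(domain_definition(1:5, 6:10, 11:20, n_end = 1:2), "subsets")
  d <- domain_definition(1:30, 31:60, 61:90)
  expect_equal(d$n_end, 31:40)
  expect_equal(d$c_end, 51:60)
  d2 <- cetp_default_domains()
  expect_true(all(d2$n_end %in% d2$central_sheet))
})
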