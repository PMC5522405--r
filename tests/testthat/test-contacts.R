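test_that("contact counting respects the distance boundary", {
  fr <- point_frame(rbind(c(0, 0, 0), c(4.9, 0, 0), c(5.1, 0, 0)))
  expect_equal(site_contacts(fr, 1L, 2L, cutoff = 5)$count, 1L)
  expect_equal(site_contacts(fr, 1L, 3L, cutoff = 5)$count, 0L)
  expect_error(site_contacts(fr, 1:2, 2:3, cutoff = 5), "disjoint")
  expect_error(site_contacts(fr, 1L, 2L, cutoff = -1), "positive")
})

test_that("contact counts equal the exhaustive double-loop oracle", {
  set.seed(51)
  for (rep in 1:30) {
    na <- sample(5:45, 1)
    nb <- sample(5:45, 1)
    A <- matrix(runif(3 * na, 0, 20), na, 3)
    B <- matrix(runif(3 * nb, 0, 20), nb, 3)
    fr <- point_frame(rbind(A, B))
    got <- site_contacts(fr, seq_len(na), na + seq_len(nb), cutoff = 5)
    expect_identical(got$count, brute_force_contacts(A, B, 5))
    expect_equal(nrow(got$pairs), got$count)
    # symmetry
    expect_identical(site_contacts(fr, na + seq_len(nb), seq_len(na),
                                   cutoff = 5)$count, got$count)
  }
})

test_that("contact counts and residue sets grow monotonically in cutoff", {
  set.seed(52)
  A <- matrix(runif(90, 0, 15), 30, 3)
  B <- matrix(runif(45, 0, 15), 15, 3)
  fr <- point_frame(rbind(A, B))
  cutoffs <- c(1, 2.5, 5, 8, 12)
  counts <- vapply(cutoffs, function(cc) {
    site_contacts(fr, 1:30, 31:45, cc)$count
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  sets <- lapply(cutoffs, function(cc) residue_contacts(fr, 31:45, 1:30, cc))
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("residue-level contacts recover a constructed ground truth", {
  # 12 protein residues on a line next to a single lipid site
  prot <- cbind(seq(0, 44, by = 4), 0, 0)
  lip <- matrix(c(12, 3, 0), 1, 3)
  fr <- point_frame(rbind(prot, lip), resid = c(1:12, 99L))
  hit <- residue_contacts(fr, lipid_sites = 13L, protein_sites = 1:12,
                          cutoff = 5)
  truth <- which(sqrt((prot[, 1] - 12)^2 + 9) <= 5)
  expect_equal(length(truth), 3L)  # residues at x = 8, 12, 16
  expect_equal(unname(hit), truth)

  wide <- residue_contacts(fr, lipid_sites = 13L, protein_sites = 1:12,
                           cutoff = 12)
  expect_equal(unname(wide),
               which(sqrt((prot[, 1] - 12)^2 + 9) <= 12))
  tiny <- residue_contacts(fr, lipid_sites = 13L, protein_sites = 1:12,
                           cutoff = 0.1)
  expect_length(tiny, 0L)
})

test_that("occupancy mode keeps residues present in enough frames", {
  prot <- cbind(c(0, 40), 0, 0)
  lip <- matrix(c(3, 0, 0), 1, 3)
  base <- point_frame(rbind(prot, lip), resid = c(1L, 2L, 9L))
  far <- base
  far$coords[3, ] <- c(20, 0, 0)
  traj <- as_trajectory(list(base, base, far, far))
  keep <- residue_contacts(traj, lipid_sites = 3L, protein_sites = 1:2,
                           cutoff = 5, occupancy = 0.5)
  expect_equal(unname(keep), 1L)
  none <- residue_contacts(traj, lipid_sites = 3L, protein_sites = 1:2,
                           cutoff = 5, occupancy = 0.75)
  expect_length(none, 0L)
})

test_that("contact comparisons report both percent conventions", {
  ref <- paste0("R", 1:43)
  query <- paste0("R", 1:51)
  cmp <- compare_contacts(ref, query)
  expect_equal(cmp$n_ref, 43L)
  expect_equal(cmp$n_query, 51L)
  expect_equal(cmp$percent_change_ref_denom, 100 * 8 / 43, tolerance = 1e-12)
  expect_length(cmp$gained, 8L)
  expect_length(cmp$lost, 0L)

  cmp2 <- compare_contacts(paste0("R", 1:38), paste0("R", 1:48))
  expect_equal(cmp2$percent_change_query_denom, 100 * 10 / 48,
               tolerance = 1e-12)

  same <- compare_contacts(ref, ref)
  expect_equal(same$percent_change_ref_denom, 0)
  expect_equal(same$percent_change_query_denom, 0)
  expect_length(same$gained, 0L)
  expect_length(same$lost, 0L)
})

test_that("comparison count identity holds on random set pairs", {
  set.seed(53)
  for (rep in 1:25) {
    universe <- seq_len(80)
    ref <- sample(universe, sample(5:60, 1))
    query <- sample(universe, sample(5:60, 1))
    cmp <- compare_contacts(ref, query)
    expect_equal(cmp$n_query,
                 cmp$n_ref - length(cmp$lost) + length(cmp$gained))
    expect_length(intersect(cmp$gained, cmp$lost), 0L)
  }
})

test_that("contact time series track static and receding lipids", {
  built <- build_pair_arrangement("parallel_NN", seed = 61)
  scaf <- build_scaffold(scaffold_spec(139, 8), seed = 61)
  # merge scaffold and lipids into one frame
  ns <- n_sites(scaf$frame)
  merged <- molecular_frame(
    rbind(scaf$frame$coords, built$frame$coords),
    site_name = c(scaf$frame$site_name, built$frame$site_name),
    residue_id = c(scaf$frame$residue_id, built$frame$residue_id),
    residue_name = c(scaf$frame$residue_name, built$frame$residue_name),
    chain_id = c(scaf$frame$chain_id, built$frame$chain_id),
    mass = c(scaf$frame$mass, built$frame$mass))
  lipid_sites <- ns + seq_len(n_sites(built$frame))
  prot_sites <- seq_len(ns)

  static <- as_trajectory(list(merged, merged, merged))
  cts <- contact_timeseries(static, lipid_sites, prot_sites, cutoff = 25)
  expect_equal(length(unique(cts$n_contacts)), 1L)

  frames <- lapply(0:4, function(i) {
    f <- merged
    f$coords[lipid_sites, ] <- sweep(f$coords[lipid_sites, ], 2,
                                     c(0, 0, 10 * i), `+`)
    f
  })
  receding <- as_trajectory(frames)
  cts2 <- contact_timeseries(receding, lipid_sites, prot_sites, cutoff = 25)
  expect_true(all(diff(cts2$n_contacts) <= 0))
  # per-frame brute-force agreement
  for (f in 1:5) {
    fr <- traj_frame(receding, f)
    expect_identical(cts2$n_contacts[f],
                     brute_force_contacts_fast(fr$coords[prot_sites, ],
                                               fr$coords[lipid_sites, ], 25))
  }
})

test_that("hydrogen bonds require both distance and angle criteria", {
  # linear D-H...A at 2.9 A donor-acceptor
  fr <- point_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0)),
                    name = "N")
  hb <- detect_hbonds(fr, donor_sites = 1L, hydrogen_sites = 2L,
                      acceptor_sites = 3L)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$angle_dha, 180)

  far <- point_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(4, 0, 0)), name = "N")
  expect_equal(nrow(detect_hbonds(far, 1L, 2L, 3L)), 0L)

  # acceptor placed for a 100-degree D-H...A angle at short range
  # (D-H points along -x from H, so a 100-degree DHA angle puts A-H at
  # 80 degrees from +x)
  ang <- 80 * pi / 180
  acc <- c(1, 0, 0) + 1.9 * c(cos(ang), sin(ang), 0)
  bent <- point_frame(rbind(c(0, 0, 0), c(1, 0, 0), acc), name = "N")
  expect_equal(nrow(detect_hbonds(bent, 1L, 2L, 3L)), 0L)
  expect_equal(nrow(detect_hbonds(bent, 1L, 2L, 3L, angle_cut = 95)), 1L)

  expect_error(detect_hbonds(fr, 1L, c(2L, 3L), 3L), "mapping")
})
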