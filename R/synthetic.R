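# Synthetic generators: single triglycerides with prescribed inter-chain
# angles, two-lipid tunnel arrangements, three-domain protein scaffolds with
# prescribed bend/twist, and noisy labeled trajectories with known ground
# truth. These stand in for molecular-dynamics data so that every descriptor
# in the package can be validated against a construction-time truth.

#' Signature angles of the generator's lipid states
#'
#' The per-state (sn1-sn3, sn2-sn3) target angles, in degrees, used by the
#' trajectory generator: a head-to-legs tuning fork at (30, 135), a
#' legs-to-head tuning fork at (145, 30), and a random state whose sn1-sn3
#' angle is sampled uniformly inside the (76, 104) band with sn2-sn3 held
#' at 85. All values are configurable by passing a modified copy to
#' [generate_trajectory()].
#'
#' @return a named list of numeric signature parameters.
#' @export
tg_state_signatures <- function() {
  list(head = c(30, 135),
       legs = c(145, 30),
       random_band = c(76, 104),
       random_sn2sn3 = 85)
}

#' Specification of one synthetic triglyceride
#'
#' @param conformation `"tuning_fork"`, `"trident"` or `"random"`; sets the
#'   default target angles ((30, 135), (30, 30) and (75, 85) respectively).
#' @param target_sn1sn3,target_sn2sn3 target inter-chain angles in degrees,
#'   each in `[0, 180]`; override the conformation defaults.
#' @param chain_length distance in Angstrom from the central site to each
#'   chain's double-bond midpoint (default 12).
#' @param representation `"atomistic"` or `"coarse_grained"`.
#' @return an object of class `tg_spec`.
#' @export
tg_spec <- function(conformation = c("tuning_fork", "trident", "random"),
                    target_sn1sn3 = NULL, target_sn2sn3 = NULL,
                    chain_length = 12,
                    representation = c("atomistic", "coarse_grained")) {
  conformation <- match.arg(conformation)
  representation <- match.arg(representation)
  defaults <- switch(conformation,
                     tuning_fork = c(30, 135),
                     trident = c(30, 30),
                     random = c(75, 85))
  a13 <- if (is.null(target_sn1sn3)) defaults[1] else as.numeric(target_sn1sn3)
  a23 <- if (is.null(target_sn2sn3)) defaults[2] else as.numeric(target_sn2sn3)
  if (!is.finite(a13) || a13 < 0 || a13 > 180 ||
      !is.finite(a23) || a23 < 0 || a23 > 180) {
    stop("target angles must lie in [0, 180] degrees", call. = FALSE)
  }
  if (!is.finite(chain_length) || chain_length <= 0) {
    stop("chain_length must be positive", call. = FALSE)
  }
  structure(list(conformation = conformation, target_sn1sn3 = a13,
                 target_sn2sn3 = a23, chain_length = chain_length,
                 representation = representation),
            class = "tg_spec")
}

# Chain directions realized in a canonical local frame: chain 1 along the
# tunnel axis u, chains 3 and 2 at planar angles t13 and t13 + t23 in the
# half-plane spanned by u and (cos(spin) v + sin(spin) w). The planar
# construction realizes every (t13, t23) pair in [0,180]^2: the implied
# sn1-sn2 angle is |t13 + t23| folded into [0, 180], which always satisfies
# the spherical triangle inequality.
.tg_chain_dirs <- function(t13, t23, u, v, w, spin_deg = 0) {
  e <- cos(.rad(spin_deg)) * v + sin(.rad(spin_deg)) * w
  alpha <- .rad(c(0, t13 + t23, t13))  # chains 1, 2, 3
  t(vapply(alpha, function(a) cos(a) * u + sin(a) * e, numeric(3)))
}

# Site layout for one TG given its three unit chain directions.
# Returns coords + metadata + topology index map (1-based, relative).
.tg_sites <- function(dirs, center, chain_length, representation,
                      residue_id = 1L, chain_id = "L") {
  L <- chain_length
  suf <- c("A", "B", "C")
  if (representation == "atomistic") {
    # central glycerol carbon, per chain an ester carbonyl carbon and the
    # two C=C carbons straddling the chain-vector tip 0.7 A apart
    coords <- matrix(0, 10, 3)
    names <- character(10)
    coords[1, ] <- center
    names[1] <- "C2"
    chain_sites <- vector("list", 3)
    ester_sites <- integer(3)
    k <- 2L
    for (i in 1:3) {
      d <- dirs[i, ]
      tip <- center + L * d
      p <- .any_perp(d)
      coords[k, ] <- center + 0.35 * L * d
      names[k] <- paste0("C1", suf[i])
      ester_sites[i] <- k
      coords[k + 1L, ] <- tip - 0.35 * p
      names[k + 1L] <- paste0("C9", suf[i])
      coords[k + 2L, ] <- tip + 0.35 * p
      names[k + 2L] <- paste0("C10", suf[i])
      chain_sites[[i]] <- c(k + 1L, k + 2L)
      k <- k + 3L
    }
    mass <- rep(12.011, 10)
    resname <- "TRI"
  } else {
    # 12-bead mapping plus the central GLY bead: GLY, ES1-3, and per chain
    # C1x, D2x (double bond, at the chain-vector tip), C3x
    coords <- matrix(0, 13, 3)
    names <- character(13)
    coords[1, ] <- center
    names[1] <- "GLY"
    chain_sites <- vector("list", 3)
    ester_sites <- integer(3)
    k <- 2L
    for (i in 1:3) {
      d <- dirs[i, ]
      coords[k, ] <- center + 0.35 * L * d
      names[k] <- paste0("ES", i)
      ester_sites[i] <- k
      coords[k + 1L, ] <- center + 0.6 * L * d
      names[k + 1L] <- paste0("C1", suf[i])
      coords[k + 2L, ] <- center + L * d
      names[k + 2L] <- paste0("D2", suf[i])
      coords[k + 3L, ] <- center + 1.4 * L * d
      names[k + 3L] <- paste0("C3", suf[i])
      chain_sites[[i]] <- k + 2L
      k <- k + 4L
    }
    mass <- rep(72, 13)
    resname <- "TOG"
  }
  n <- nrow(coords)
  list(coords = coords, site_name = names,
       residue_id = rep(as.integer(residue_id), n),
       residue_name = rep(resname, n),
       chain_id = rep(chain_id, n), mass = mass,
       central_site = 1L, chain_sites = chain_sites,
       ester_sites = ester_sites)
}

.bind_site_sets <- function(sets) {
  coords <- do.call(rbind, lapply(sets, `[[`, "coords"))
  molecular_frame(coords,
                  site_name = unlist(lapply(sets, `[[`, "site_name")),
                  residue_id = unlist(lapply(sets, `[[`, "residue_id")),
                  residue_name = unlist(lapply(sets, `[[`, "residue_name")),
                  chain_id = unlist(lapply(sets, `[[`, "chain_id")),
                  mass = unlist(lapply(sets, `[[`, "mass")))
}

.offset_topology <- function(sites, offset, representation) {
  tg_topology(central_site = sites$central_site + offset,
              chain_sites = lapply(sites$chain_sites, function(s) s + offset),
              ester_sites = sites$ester_sites + offset,
              representation = representation)
}

#' Build one synthetic triglyceride
#'
#' Realizes a triglyceride whose inter-chain angles equal the spec's targets
#' exactly (to floating-point precision): chain 1 along `axis`, chains 3 and
#' 2 placed at the target angles in a fixed half-plane, the whole triple then
#' rotated about the axis by a seeded random spin so that repeated builds are
#' reproducible yet not axis-aligned in a degenerate way.
#'
#' @param spec a [tg_spec].
#' @param seed integer seed for the azimuthal spin; `NULL` leaves the RNG
#'   stream untouched and uses spin 0.
#' @param center 3-vector position of the central site (Angstrom).
#' @param axis tunnel axis direction (N- to C-terminal), default `+x`.
#' @param residue_id,chain_id identifiers for the emitted sites.
#' @return a list with elements `frame` ([molecular_frame]), `topology`
#'   ([tg_topology]) and `realized` (named sn1-sn3, sn2-sn3, sn1-sn2 angles).
#' @export
build_tg <- function(spec, seed = NULL, center = c(0, 0, 0),
                     axis = c(1, 0, 0), residue_id = 1L, chain_id = "L") {
  stopifnot(inherits(spec, "tg_spec"))
  u <- .unit(axis)
  v <- .any_perp(u)
  w <- .cross3(u, v)
  spin <- 0
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    spin <- stats::runif(1, 0, 360)
  }
  dirs <- .tg_chain_dirs(spec$target_sn1sn3, spec$target_sn2sn3, u, v, w, spin)
  sites <- .tg_sites(dirs, center, spec$chain_length, spec$representation,
                     residue_id, chain_id)
  frame <- .bind_site_sets(list(sites))
  topo <- .offset_topology(sites, 0L, spec$representation)
  raw <- compute_chain_vectors(frame, topo)
  realized <- c(
    sn1sn3 = angle_between(raw[1, ], raw[3, ]),
    sn2sn3 = angle_between(raw[2, ], raw[3, ]),
    sn1sn2 = angle_between(raw[1, ], raw[2, ])
  )
  list(frame = frame, topology = topo, realized = realized)
}

.pair_orientation_map <- list(
  parallel_NN = c("head", "head"),
  antiparallel_NC = c("head", "legs"),
  parallel_CC = c("legs", "legs"),
  antiparallel_CN = c("legs", "head")
)

#' Build a two-lipid tunnel arrangement
#'
#' Places two triglycerides on a tunnel axis of the given length, TG_N at the
#' centre of the N-terminal half and TG_C at the centre of the C-terminal
#' half (central sites `axis_length / 2` apart), each in the single-lipid
#' orientation the pair label implies: head-to-legs lipids use the
#' tuning-fork signature (30, 135), legs-to-head lipids its reflection
#' (145, 30).
#'
#' @param pair_label one of `"parallel_NN"`, `"antiparallel_NC"`,
#'   `"parallel_CC"`, `"antiparallel_CN"`.
#' @param axis_length tunnel length in Angstrom (default 60, the length of
#'   the CETP core tunnel).
#' @param seed integer seed for the azimuthal spins.
#' @param representation `"atomistic"` or `"coarse_grained"`.
#' @param chain_length chain-vector length in Angstrom.
#' @return a list with `frame`, `topology_n`, `topology_c`, `axis_start`,
#'   `axis_end`.
#' @export
build_pair_arrangement <- function(pair_label = c("parallel_NN",
                                                  "antiparallel_NC",
                                                  "parallel_CC",
                                                  "antiparallel_CN"),
                                   axis_length = 60, seed = NULL,
                                   representation = c("coarse_grained",
                                                      "atomistic"),
                                   chain_length = 12) {
  pair_label <- match.arg(pair_label)
  representation <- match.arg(representation)
  if (!is.finite(axis_length) || axis_length <= 0) {
    stop("axis_length must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  sig <- tg_state_signatures()
  u <- c(1, 0, 0)
  v <- .any_perp(u)
  w <- .cross3(u, v)
  orient <- .pair_orientation_map[[pair_label]]
  centers <- list(c(axis_length / 4, 0, 0), c(3 * axis_length / 4, 0, 0))
  sets <- vector("list", 2)
  for (i in 1:2) {
    targets <- sig[[orient[i]]]
    spin <- if (is.null(seed)) 0 else stats::runif(1, 0, 360)
    dirs <- .tg_chain_dirs(targets[1], targets[2], u, v, w, spin)
    sets[[i]] <- .tg_sites(dirs, centers[[i]], chain_length, representation,
                           residue_id = 9000L + i, chain_id = "L")
  }
  frame <- .bind_site_sets(sets)
  off <- nrow(sets[[1]]$coords)
  list(frame = frame,
       topology_n = .offset_topology(sets[[1]], 0L, representation),
       topology_c = .offset_topology(sets[[2]], off, representation),
       axis_start = c(0, 0, 0), axis_end = c(axis_length, 0, 0))
}

#' Specification of a synthetic three-domain protein scaffold
#'
#' @param bend_deg bending angle in degrees, in `(0, 180]`.
#' @param twist_deg signed twist angle in degrees, in `(-90, 90)`.
#' @param domain_site_counts integer vector of 3 positive site counts for the
#'   N-terminal barrel, central sheet and C-terminal barrel point clouds.
#' @param arm_length distance in Angstrom from the central-sheet COM to each
#'   barrel COM (default 25).
#' @return an object of class `scaffold_spec`.
#' @export
scaffold_spec <- function(bend_deg, twist_deg = 0,
                          domain_site_counts = c(24L, 40L, 24L),
                          arm_length = 25) {
  bend_deg <- as.numeric(bend_deg)
  twist_deg <- as.numeric(twist_deg)
  if (!is.finite(bend_deg) || bend_deg <= 0 || bend_deg > 180) {
    stop("bend_deg must lie in (0, 180]", call. = FALSE)
  }
  if (!is.finite(twist_deg) || twist_deg <= -90 || twist_deg >= 90) {
    stop("twist_deg must lie in (-90, 90)", call. = FALSE)
  }
  domain_site_counts <- as.integer(domain_site_counts)
  if (length(domain_site_counts) != 3L || any(domain_site_counts < 1L)) {
    stop("domain_site_counts must be 3 positive integers", call. = FALSE)
  }
  if (domain_site_counts[2] < 2L) {
    stop("the central sheet needs >= 2 sites for its axis sub-ranges",
         call. = FALSE)
  }
  if (!is.finite(arm_length) || arm_length <= 0) {
    stop("arm_length must be positive", call. = FALSE)
  }
  structure(list(bend_deg = bend_deg, twist_deg = twist_deg,
                 domain_site_counts = domain_site_counts,
                 arm_length = arm_length),
            class = "scaffold_spec")
}

# Domain COM geometry for a (bend, twist) pair. Axis along +x. Central-sheet
# COM c sits on the axis at the origin; barrel COMs at polar angles
# 90 +/- delta from +x and azimuths -/+ twist/2 about the axis, with
# sin^2(delta) = (cos t - cos beta) / (1 + cos t). Bend = 180 is special:
# the arms must be antiparallel through c, which forces the barrels onto the
# axis unless c itself moves off-axis; only twist = 0 is then realizable.
.scaffold_coms <- function(bend_deg, twist_deg, arm_length) {
  r <- arm_length
  a <- arm_length  # separation of the two axis-defining sub-range COMs
  if (bend_deg >= 180 - 1e-12) {
    if (abs(twist_deg) > 1e-12) {
      stop("geometry error: bend 180 forces both barrel centres into one ",
           "axial plane; twist must be 0", call. = FALSE)
    }
    h <- arm_length / 5
    return(list(n_end = c(-a / 2, 0, 0), c_end = c(a / 2, 0, 0),
                central = c(0, h, 0),
                n_barrel = c(-r, h, 0), c_barrel = c(r, h, 0),
                off_axis = TRUE, h = h))
  }
  beta <- .rad(bend_deg)
  t <- .rad(twist_deg)
  s2 <- (cos(t) - cos(beta)) / (1 + cos(t))
  if (s2 < -1e-12 || s2 > 1 + 1e-12) {
    stop("geometry error: no scaffold realizes bend ", bend_deg,
         " with twist ", twist_deg, " (|twist| must not exceed bend)",
         call. = FALSE)
  }
  delta <- asin(sqrt(max(0, min(1, s2))))
  g1 <- pi / 2 + delta  # polar angle of the N arm from +x
  g2 <- pi / 2 - delta  # polar angle of the C arm from +x
  p1 <- -t / 2
  p2 <- t / 2
  list(n_end = c(-a / 2, 0, 0), c_end = c(a / 2, 0, 0),
       central = c(0, 0, 0),
       n_barrel = r * c(cos(g1), sin(g1) * cos(p1), sin(g1) * sin(p1)),
       c_barrel = r * c(cos(g2), sin(g2) * cos(p2), sin(g2) * sin(p2)),
       off_axis = FALSE)
}

# Zero-mean point cloud offsets (k x 3), seeded by the caller's RNG stream.
.cloud_offsets <- function(k, spread = 1.5) {
  if (k == 1L) return(matrix(0, 1, 3))
  off <- matrix(stats::rnorm(3 * k, sd = spread), k, 3)
  sweep(off, 2, colMeans(off))
}

#' Build a synthetic three-domain protein scaffold
#'
#' Realizes the three domains as small rigid point clouds whose centres of
#' mass sit at a closed-form geometry with the prescribed bending angle
#' (angle at the central-sheet COM between the two barrel arms) and signed
#' twist angle (azimuthal separation of the barrel COMs about the axis
#' through the central sheet's N-end and C-end sub-range COMs). Descriptor
#' functions applied to the result recover the inputs to better than 1e-6
#' degrees.
#'
#' @param spec a [scaffold_spec].
#' @param seed integer seed for the point-cloud offsets.
#' @return a list with `frame` ([molecular_frame]), `domains`
#'   ([domain_definition]), `axis_start`, `axis_end` (the two axis sub-range
#'   COMs).
#' @export
build_scaffold <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scaffold_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  coms <- .scaffold_coms(spec$bend_deg, spec$twist_deg, spec$arm_length)
  k <- spec$domain_site_counts
  .scaffold_from_offsets(spec, coms,
                         offs = list(n = .cloud_offsets(k[1]),
                                     central = .cloud_offsets(k[2]),
                                     c = .cloud_offsets(k[3])))
}

# Assemble the scaffold frame from COM geometry + fixed cloud offsets.
# The central sheet is split into sub-clouds so that its n_end / c_end
# sub-range COMs land exactly on the axis anchors, and (for the off-axis
# bend-180 case) a middle sub-cloud displaces the whole-domain COM off the
# axis. Cloud offsets are re-centred per sub-cloud, so COMs are exact.
.scaffold_from_offsets <- function(spec, coms, offs) {
  k <- spec$domain_site_counts
  kc <- k[2]
  if (isTRUE(coms$off_axis)) {
    # middle sub-cloud pulls the whole-domain COM off the axis to (0, h, 0):
    # anchor chosen so the weighted mean of the three sub-cloud COMs is exact
    ke <- kc %/% 3
    km <- kc - 2L * ke
    if (km < 1L || ke < 1L) {
      stop("central sheet too small for the off-axis layout (needs >= 3 sites)",
           call. = FALSE)
    }
    anchors <- list(coms$n_end, c(0, coms$h * kc / km, 0), coms$c_end)
    sizes <- c(ke, km, ke)
  } else {
    ke <- kc %/% 2
    anchors <- list(coms$n_end, coms$c_end)
    sizes <- c(ke, kc - ke)
  }
  # slice the central cloud offsets into sub-clouds and re-centre each
  central_parts <- list()
  pos <- 0L
  for (j in seq_along(sizes)) {
    rows <- offs$central[(pos + 1L):(pos + sizes[j]), , drop = FALSE]
    rows <- sweep(rows, 2, colMeans(rows))
    central_parts[[j]] <- sweep(rows, 2, anchors[[j]], `+`)
    pos <- pos + sizes[j]
  }
  central_coords <- do.call(rbind, central_parts)
  n_coords <- sweep(offs$n, 2, coms$n_barrel, `+`)
  c_coords <- sweep(offs$c, 2, coms$c_barrel, `+`)
  coords <- rbind(n_coords, central_coords, c_coords)
  n_total <- nrow(coords)
  resid <- seq_len(n_total)
  frame <- molecular_frame(coords, site_name = rep("CA", n_total),
                           residue_id = resid,
                           residue_name = rep("ALA", n_total),
                           chain_id = "A", mass = rep(12.011, n_total))
  n1 <- k[1]
  central_ids <- (n1 + 1L):(n1 + kc)
  if (isTRUE(coms$off_axis)) {
    n_end_ids <- central_ids[seq_len(sizes[1])]
    c_end_ids <- central_ids[(sizes[1] + sizes[2] + 1L):kc]
  } else {
    n_end_ids <- central_ids[seq_len(sizes[1])]
    c_end_ids <- central_ids[(sizes[1] + 1L):kc]
  }
  domains <- domain_definition(n_barrel = seq_len(n1),
                               central_sheet = central_ids,
                               c_barrel = (n1 + kc + 1L):n_total,
                               n_end = n_end_ids, c_end = c_end_ids)
  list(frame = frame, domains = domains,
       axis_start = coms$n_end, axis_end = coms$c_end)
}

#' Scaffold trajectory with prescribed per-frame bend/twist
#'
#' Builds one rigid point-cloud realization of the scaffold and re-poses it
#' frame by frame at the given bend and twist angles (recycled to the longer
#' of the two series). Useful for validating the bend/twist descriptor
#' series against a known sweep.
#'
#' @param spec a [scaffold_spec] (its `bend_deg`/`twist_deg` give defaults).
#' @param bend_series,twist_series numeric vectors of per-frame angles in
#'   degrees.
#' @param seed integer seed for the cloud offsets.
#' @return a list with `trajectory`, `domains`, `bend_series`, `twist_series`.
#' @export
scaffold_trajectory <- function(spec, bend_series = spec$bend_deg,
                                twist_series = spec$twist_deg, seed = NULL) {
  stopifnot(inherits(spec, "scaffold_spec"))
  nf <- max(length(bend_series), length(twist_series))
  bend_series <- rep_len(as.numeric(bend_series), nf)
  twist_series <- rep_len(as.numeric(twist_series), nf)
  if (!is.null(seed)) set.seed(as.integer(seed))
  k <- spec$domain_site_counts
  offs <- list(n = .cloud_offsets(k[1]), central = .cloud_offsets(k[2]),
               c = .cloud_offsets(k[3]))
  frames <- vector("list", nf)
  domains <- NULL
  for (i in seq_len(nf)) {
    coms <- .scaffold_coms(bend_series[i], twist_series[i], spec$arm_length)
    built <- .scaffold_from_offsets(spec, coms, offs)
    frames[[i]] <- built$frame
    if (is.null(domains)) domains <- built$domains
  }
  list(trajectory = as_trajectory(frames), domains = domains,
       bend_series = bend_series, twist_series = twist_series)
}

.pair_states <- c("PARALLEL_NN", "ANTIPARALLEL_NC", "PARALLEL_CC",
                  "ANTIPARALLEL_CN", "RANDOM")
.single_states <- c("HEAD_TO_LEGS", "LEGS_TO_HEAD", "RANDOM")

#' Specification of a synthetic labeled trajectory
#'
#' Exactly one of `state_sequence` (explicit per-frame labels) or
#' `transition_matrix` (row-stochastic; 5x5 over the pair states
#' PARALLEL_NN, ANTIPARALLEL_NC, PARALLEL_CC, ANTIPARALLEL_CN, RANDOM, or
#' 3x3 over the single-lipid states HEAD_TO_LEGS, LEGS_TO_HEAD, RANDOM) must
#' be given. Markov sequences start from the chain's stationary
#' distribution.
#'
#' @param n_frames positive frame count.
#' @param state_sequence character vector of per-frame labels.
#' @param transition_matrix row-stochastic matrix (rows sum to 1 within
#'   1e-12), with state names as dimnames or in the canonical order above.
#' @param angular_noise_sigma Gaussian noise width (degrees) applied as a
#'   rotation of each chain vector about a random perpendicular axis.
#' @param noise_truncation hard upper bound on each rotation (degrees);
#'   `Inf` disables truncation.
#' @param seed integer RNG seed; the same spec generates bit-identical
#'   trajectories.
#' @return an object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_frames, state_sequence = NULL,
                            transition_matrix = NULL,
                            angular_noise_sigma = 0,
                            noise_truncation = Inf, seed = 1L) {
  if (!.is_count(n_frames)) stop("n_frames must be a positive integer",
                                 call. = FALSE)
  if (is.null(state_sequence) == is.null(transition_matrix)) {
    stop("give exactly one of state_sequence or transition_matrix",
         call. = FALSE)
  }
  mode <- NULL
  if (!is.null(state_sequence)) {
    state_sequence <- as.character(state_sequence)
    if (length(state_sequence) != n_frames) {
      stop("state_sequence must have length n_frames", call. = FALSE)
    }
    if (all(state_sequence %in% .pair_states)) {
      mode <- "pair"
    } else if (all(state_sequence %in% .single_states)) {
      mode <- "single"
    } else {
      stop("unknown state label(s): ",
           paste(setdiff(state_sequence, c(.pair_states, .single_states)),
                 collapse = ", "), call. = FALSE)
    }
  } else {
    transition_matrix <- as.matrix(transition_matrix)
    d <- nrow(transition_matrix)
    if (ncol(transition_matrix) != d || !(d %in% c(3L, 5L))) {
      stop("transition_matrix must be 3x3 (single-lipid states) or 5x5 ",
           "(pair states)", call. = FALSE)
    }
    if (any(abs(rowSums(transition_matrix) - 1) > 1e-12) ||
        any(transition_matrix < 0)) {
      stop("transition_matrix rows must be non-negative and sum to 1 ",
           "within 1e-12", call. = FALSE)
    }
    states <- if (d == 5L) .pair_states else .single_states
    if (!is.null(rownames(transition_matrix))) {
      if (!setequal(rownames(transition_matrix), states)) {
        stop("transition_matrix dimnames must be the canonical state names",
             call. = FALSE)
      }
      transition_matrix <- transition_matrix[states, states]
    } else {
      dimnames(transition_matrix) <- list(states, states)
    }
    mode <- if (d == 5L) "pair" else "single"
  }
  if (!is.finite(angular_noise_sigma) || angular_noise_sigma < 0) {
    stop("angular_noise_sigma must be >= 0", call. = FALSE)
  }
  if (!(is.infinite(noise_truncation) || noise_truncation > 0)) {
    stop("noise_truncation must be positive (or Inf)", call. = FALSE)
  }
  structure(list(n_frames = as.integer(n_frames),
                 state_sequence = state_sequence,
                 transition_matrix = transition_matrix,
                 angular_noise_sigma = angular_noise_sigma,
                 noise_truncation = noise_truncation,
                 seed = as.integer(seed), mode = mode),
            class = "trajectory_spec")
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized to
#' a probability vector.
#'
#' @param P row-stochastic square matrix.
#' @return named numeric probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(P))
}

.simulate_states <- function(spec) {
  if (!is.null(spec$state_sequence)) return(spec$state_sequence)
  P <- spec$transition_matrix
  states <- rownames(P)
  pi0 <- stationary_distribution(P)
  s <- character(spec$n_frames)
  s[1] <- sample(states, 1, prob = pi0)
  for (i in seq_len(spec$n_frames - 1L)) {
    s[i + 1L] <- sample(states, 1, prob = P[s[i], ])
  }
  s
}

# |N(0, sigma)| with hard truncation by rejection; sigma 0 gives 0.
.noise_angle <- function(sigma, trunc) {
  if (sigma == 0) return(0)
  repeat {
    eta <- abs(stats::rnorm(1, 0, sigma))
    if (eta <= trunc) return(eta)
  }
}

# Apply chain-vector noise: rotate each unit direction by |N(0,sigma)|
# (truncated) about a uniformly random perpendicular axis. Chain lengths
# are unaffected because only directions rotate.
.perturb_dirs <- function(dirs, sigma, trunc) {
  if (sigma == 0) return(dirs)
  for (i in seq_len(nrow(dirs))) {
    eta <- .noise_angle(sigma, trunc)
    ax <- .random_perp(dirs[i, ])
    dirs[i, ] <- as.vector(.rotmat(ax, eta) %*% dirs[i, ])
  }
  dirs
}

# Draw the per-TG state targets for one frame. Returns for each TG a list
# with target angles, whether noise applies, and the truth orientation.
.frame_tg_states <- function(state, mode, sig) {
  single_of <- function(lab) {
    switch(lab,
           head = list(targets = sig$head, noisy = TRUE,
                       orientation = "HEAD_TO_LEGS"),
           legs = list(targets = sig$legs, noisy = TRUE,
                       orientation = "LEGS_TO_HEAD"),
           random = list(targets = c(stats::runif(1, sig$random_band[1],
                                                  sig$random_band[2]),
                                     sig$random_sn2sn3),
                         noisy = FALSE, orientation = "RANDOM"))
  }
  if (mode == "single") {
    lab <- switch(state, HEAD_TO_LEGS = "head", LEGS_TO_HEAD = "legs",
                  RANDOM = "random")
    return(list(single_of(lab)))
  }
  if (state == "RANDOM") {
    which_random <- sample(1:2, 1)
    other <- sample(c("head", "legs"), 1)
    labs <- c(other, other)
    labs[which_random] <- "random"
  } else {
    labs <- .pair_orientation_map[[c(PARALLEL_NN = "parallel_NN",
                                     ANTIPARALLEL_NC = "antiparallel_NC",
                                     PARALLEL_CC = "parallel_CC",
                                     ANTIPARALLEL_CN = "antiparallel_CN")[state]]]
  }
  lapply(labs, single_of)
}

#' Generate a synthetic labeled trajectory
#'
#' Emits a trajectory of one triglyceride (single mode) or a TG_N/TG_C pair
#' on a tunnel axis (pair mode), optionally together with a rigid protein
#' scaffold, plus per-frame ground truth. Per-frame chain geometry is the
#' state's signature angles plus truncated Gaussian rotational noise of each
#' chain vector; lipids in the random band are built exactly at their
#' sampled sn1-sn3 angle so their truth label cannot be invalidated by
#' noise. Everything is driven by the spec's seed: the same spec reproduces
#' the trajectory bit for bit.
#'
#' @param traj_spec a [trajectory_spec].
#' @param tg_specs optional list of [tg_spec]s; the first element's
#'   `representation` and `chain_length` are used for all lipids.
#' @param scaffold_spec optional [scaffold_spec]; when given, the rigid
#'   scaffold sites are prepended to every frame and its domain definition
#'   is returned.
#' @param axis_length tunnel axis length in Angstrom (default 60).
#' @param signatures state signature parameters, see [tg_state_signatures()].
#' @return a list with `trajectory`, `truth` (data.frame of per-frame labels
#'   and realized angles), `topologies` (list of [tg_topology]), `axis_start`,
#'   `axis_end`, and `domains` (or `NULL`).
#' @export
generate_trajectory <- function(traj_spec, tg_specs = NULL,
                                scaffold_spec = NULL, axis_length = 60,
                                signatures = tg_state_signatures()) {
  stopifnot(inherits(traj_spec, "trajectory_spec"))
  representation <- "coarse_grained"
  chain_length <- 12
  if (!is.null(tg_specs)) {
    s1 <- if (inherits(tg_specs, "tg_spec")) tg_specs else tg_specs[[1]]
    representation <- s1$representation
    chain_length <- s1$chain_length
  }
  set.seed(traj_spec$seed)
  states <- .simulate_states(traj_spec)
  mode <- traj_spec$mode
  n_tg <- if (mode == "pair") 2L else 1L
  nf <- traj_spec$n_frames

  u <- c(1, 0, 0)
  v <- .any_perp(u)
  w <- .cross3(u, v)
  centers <- if (n_tg == 2L) {
    list(c(axis_length / 4, 0, 0), c(3 * axis_length / 4, 0, 0))
  } else {
    list(c(axis_length / 2, 0, 0))
  }

  scaffold <- NULL
  scaffold_sets <- list()
  domains <- NULL
  if (!is.null(scaffold_spec)) {
    built <- .scaffold_from_offsets(
      scaffold_spec,
      .scaffold_coms(scaffold_spec$bend_deg, scaffold_spec$twist_deg,
                     scaffold_spec$arm_length),
      offs = list(n = .cloud_offsets(scaffold_spec$domain_site_counts[1]),
                  central = .cloud_offsets(scaffold_spec$domain_site_counts[2]),
                  c = .cloud_offsets(scaffold_spec$domain_site_counts[3])))
    # centre the scaffold on the tunnel axis midpoint
    shift <- c(axis_length / 2, 0, 0)
    built$frame$coords <- sweep(built$frame$coords, 2, shift, `+`)
    scaffold <- built
    domains <- built$domains
  }

  # template sites to get the layout/metadata once
  tpl <- lapply(seq_len(n_tg), function(i) {
    .tg_sites(.tg_chain_dirs(30, 135, u, v, w, 0), centers[[i]], chain_length,
              representation, residue_id = 9000L + i, chain_id = "L")
  })
  n_scaf <- if (is.null(scaffold)) 0L else n_sites(scaffold$frame)
  sets <- if (is.null(scaffold)) tpl else c(list(.frame_as_set(scaffold$frame)), tpl)
  topo_frame <- .bind_site_sets(sets)
  offsets <- n_scaf + c(0L, if (n_tg == 2L) nrow(tpl[[1]]$coords))
  topologies <- lapply(seq_len(n_tg), function(i) {
    .offset_topology(tpl[[i]], offsets[i], representation)
  })

  coords <- array(0, c(n_sites(topo_frame), 3L, nf))
  truth <- data.frame(frame = seq_len(nf), state = states,
                      stringsAsFactors = FALSE)
  or_mat <- matrix(NA_character_, nf, n_tg)
  conf_mat <- matrix(NA_character_, nf, n_tg)
  a13_mat <- matrix(NA_real_, nf, n_tg)
  a23_mat <- matrix(NA_real_, nf, n_tg)

  sigma <- traj_spec$angular_noise_sigma
  trunc <- traj_spec$noise_truncation
  for (f in seq_len(nf)) {
    if (n_scaf > 0L) coords[1:n_scaf, , f] <- scaffold$frame$coords
    tg_states <- .frame_tg_states(states[f], mode, signatures)
    for (i in seq_len(n_tg)) {
      st <- tg_states[[i]]
      spin <- stats::runif(1, 0, 360)
      dirs <- .tg_chain_dirs(st$targets[1], st$targets[2], u, v, w, spin)
      if (st$noisy) dirs <- .perturb_dirs(dirs, sigma, trunc)
      sites <- .tg_sites(dirs, centers[[i]], chain_length, representation,
                         residue_id = 9000L + i, chain_id = "L")
      rows <- (offsets[i] + 1L):(offsets[i] + nrow(sites$coords))
      coords[rows, , f] <- sites$coords
      # realized role-assigned angles (what a classifier sees)
      raw <- chain_length * dirs
      triple <- assign_roles(raw, u)
      ang <- inter_chain_angles(triple)
      or_mat[f, i] <- st$orientation
      conf_mat[f, i] <- if (st$orientation == "RANDOM") "RANDOM" else "FORK_LIKE"
      a13_mat[f, i] <- ang[["sn1sn3"]]
      a23_mat[f, i] <- ang[["sn2sn3"]]
    }
  }

  if (n_tg == 2L) {
    truth$orientation_n <- or_mat[, 1]
    truth$orientation_c <- or_mat[, 2]
    truth$conformation_n <- conf_mat[, 1]
    truth$conformation_c <- conf_mat[, 2]
    truth$sn1sn3_n <- a13_mat[, 1]
    truth$sn2sn3_n <- a23_mat[, 1]
    truth$sn1sn3_c <- a13_mat[, 2]
    truth$sn2sn3_c <- a23_mat[, 2]
    truth$pair_label <- states
  } else {
    truth$orientation <- or_mat[, 1]
    truth$conformation <- conf_mat[, 1]
    truth$sn1sn3 <- a13_mat[, 1]
    truth$sn2sn3 <- a23_mat[, 1]
  }

  list(trajectory = trajectory(topo_frame, coords), truth = truth,
       topologies = topologies, axis_start = c(0, 0, 0),
       axis_end = c(axis_length, 0, 0), domains = domains)
}

# view a molecular_frame as a site-set list for .bind_site_sets
.frame_as_set <- function(frame) {
  list(coords = frame$coords, site_name = frame$site_name,
       residue_id = frame$residue_id, residue_name = frame$residue_name,
       chain_id = frame$chain_id, mass = frame$mass,
       central_site = NA_integer_, chain_sites = list(), ester_sites = integer(0))
}
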