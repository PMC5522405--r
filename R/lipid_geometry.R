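# Chain-vector construction and inter-chain angle analysis for a bound
# triglyceride: the three vectors run from the central glycerol site to each
# oleoyl chain's C=C double-bond midpoint (atomistic) or D-bead (CG), and
# are role-labeled sn1/sn2/sn3 by their projection on the protein's N-to-C
# tunnel axis.

#' Raw chain vectors of one triglyceride
#'
#' For each of the three chains, the vector from the central site to the
#' unweighted midpoint of the two C=C atoms (atomistic) or to the D-bead
#' (coarse-grained). Raises a broken-molecule error when the two C=C atoms
#' of a pair are more than 10 Angstrom apart (no periodic unwrapping is
#' performed: analyses assume whole molecules), and a degenerate-geometry
#' error when a chain vector is shorter than 0.1 Angstrom.
#'
#' @param frame a [molecular_frame].
#' @param topo a [tg_topology] valid in `frame`.
#' @return a 3 x 3 matrix; row k is the raw vector of chain k, Angstrom.
#' @export
compute_chain_vectors <- function(frame, topo) {
  stopifnot(inherits(frame, "molecular_frame"), inherits(topo, "tg_topology"))
  .check_topology_in_frame(frame, topo)
  origin <- frame$coords[topo$central_site, ]
  raw <- matrix(0, 3, 3)
  for (k in 1:3) {
    idx <- topo$chain_sites[[k]]
    if (length(idx) == 2L) {
      a <- frame$coords[idx[1], ]
      b <- frame$coords[idx[2], ]
      if (.norm3(a - b) > 10) {
        stop("broken molecule: C=C atoms of chain ", k, " are ",
             round(.norm3(a - b), 1), " Angstrom apart", call. = FALSE)
      }
      tip <- (a + b) / 2
    } else {
      tip <- frame$coords[idx, ]
    }
    v <- tip - origin
    if (.norm3(v) <= 0.1) {
      stop("degenerate geometry: chain ", k,
           " vector is shorter than 0.1 Angstrom", call. = FALSE)
    }
    raw[k, ] <- v
  }
  raw
}

#' Assign sn1/sn2/sn3 roles to raw chain vectors
#'
#' The chain pointing most toward the C-terminal domain (largest projection
#' on the N-to-C axis) is sn1, the chain pointing most toward the N-terminal
#' domain (smallest projection) is sn2, and the remaining chain is sn3. Ties
#' are broken toward the lower raw chain index.
#'
#' @param raw_vectors 3 x 3 matrix of raw chain vectors (rows).
#' @param protein_axis N-to-C axis direction (any nonzero 3-vector).
#' @return an object of class `chain_vector_triple`: list with `sn1`, `sn2`,
#'   `sn3` and `role_permutation` (named integer vector of raw chain
#'   indices).
#' @export
assign_roles <- function(raw_vectors, protein_axis) {
  raw_vectors <- as.matrix(raw_vectors)
  stopifnot(nrow(raw_vectors) == 3L, ncol(raw_vectors) == 3L)
  u <- .unit(protein_axis)
  proj <- as.vector(raw_vectors %*% u)
  ord <- order(-proj, seq_len(3L))  # descending projection, ties by index
  perm <- c(sn1 = ord[1], sn3 = ord[2], sn2 = ord[3])[c("sn1", "sn2", "sn3")]
  structure(list(sn1 = raw_vectors[perm[["sn1"]], ],
                 sn2 = raw_vectors[perm[["sn2"]], ],
                 sn3 = raw_vectors[perm[["sn3"]], ],
                 role_permutation = perm),
            class = "chain_vector_triple")
}

#' Inter-chain angles of a role-assigned triple
#'
#' @param triple a `chain_vector_triple` from [assign_roles()].
#' @return named numeric vector `sn1sn3`, `sn2sn3`, `sn1sn2`, degrees in
#'   `[0, 180]`.
#' @export
inter_chain_angles <- function(triple) {
  stopifnot(inherits(triple, "chain_vector_triple"))
  c(sn1sn3 = angle_between(triple$sn1, triple$sn3),
    sn2sn3 = angle_between(triple$sn2, triple$sn3),
    sn1sn2 = angle_between(triple$sn1, triple$sn2))
}

#' Per-frame inter-chain angle series for one triglyceride
#'
#' Applies [compute_chain_vectors()], [assign_roles()] and
#' [inter_chain_angles()] to every frame. Roles are re-assigned every frame
#' by default (the third chain genuinely migrates between the two ends of
#' the tunnel); `roles = "first_frame"` locks the frame-1 permutation for
#' sensitivity checks.
#'
#' @param traj a [trajectory].
#' @param topo a [tg_topology].
#' @param axis N-to-C axis 3-vector, or `NULL` to derive it from `domains`.
#' @param domains optional [domain_definition]; when given, the axis is
#'   COM(C-terminal barrel) - COM(N-terminal barrel) recomputed per frame.
#' @param roles `"per_frame"` or `"first_frame"`.
#' @return data.frame with columns `frame`, `sn1sn3`, `sn2sn3`, `sn1sn2`,
#'   `sn1_chain`, `sn2_chain`, `sn3_chain` (raw indices of the role
#'   assignment).
#' @export
tg_angle_series <- function(traj, topo, axis = NULL, domains = NULL,
                            roles = c("per_frame", "first_frame")) {
  roles <- match.arg(roles)
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(axis) && is.null(domains)) {
    stop("give either axis or domains to orient the role assignment",
         call. = FALSE)
  }
  nf <- n_frames(traj)
  out <- data.frame(frame = seq_len(nf), sn1sn3 = NA_real_,
                    sn2sn3 = NA_real_, sn1sn2 = NA_real_,
                    sn1_chain = NA_integer_, sn2_chain = NA_integer_,
                    sn3_chain = NA_integer_)
  locked_perm <- NULL
  for (f in seq_len(nf)) {
    fr <- traj_frame(traj, f)
    raw <- compute_chain_vectors(fr, topo)
    ax <- if (is.null(domains)) axis else {
      center_of_mass(fr, residues = domains$c_barrel) -
        center_of_mass(fr, residues = domains$n_barrel)
    }
    triple <- assign_roles(raw, ax)
    if (roles == "first_frame") {
      if (is.null(locked_perm)) {
        locked_perm <- triple$role_permutation
      } else {
        triple <- structure(list(sn1 = raw[locked_perm[["sn1"]], ],
                                 sn2 = raw[locked_perm[["sn2"]], ],
                                 sn3 = raw[locked_perm[["sn3"]], ],
                                 role_permutation = locked_perm),
                            class = "chain_vector_triple")
      }
    }
    ang <- inter_chain_angles(triple)
    out$sn1sn3[f] <- ang[["sn1sn3"]]
    out$sn2sn3[f] <- ang[["sn2sn3"]]
    out$sn1sn2[f] <- ang[["sn1sn2"]]
    out$sn1_chain[f] <- triple$role_permutation[["sn1"]]
    out$sn2_chain[f] <- triple$role_permutation[["sn2"]]
    out$sn3_chain[f] <- triple$role_permutation[["sn3"]]
  }
  out
}

#' Normalized angle histogram over [0, 180] degrees
#'
#' Probability-mass histogram: bin masses sum to 1. Bins are half-open
#' `[lo, hi)` except the last, which is closed at 180.
#'
#' @param series numeric vector of angles in degrees, all in `[0, 180]`.
#' @param bin_width bin width in degrees; must divide 180 evenly (default 5).
#' @return data.frame with columns `lo`, `hi`, `mass`.
#' @export
angle_histogram <- function(series, bin_width = 5) {
  series <- as.numeric(series)
  if (length(series) == 0L) stop("empty angle series", call. = FALSE)
  if (any(!is.finite(series) | series < 0 | series > 180)) {
    stop("angles must lie in [0, 180] degrees", call. = FALSE)
  }
  nb <- 180 / bin_width
  if (!is.finite(nb) || abs(nb - round(nb)) > 1e-9 || nb < 1) {
    stop("bin_width must divide 180 evenly", call. = FALSE)
  }
  nb <- as.integer(round(nb))
  idx <- pmin(floor(series / bin_width) + 1L, nb)  # 180 joins the last bin
  counts <- tabulate(idx, nbins = nb)
  data.frame(lo = bin_width * (seq_len(nb) - 1L),
             hi = bin_width * seq_len(nb),
             mass = counts / length(series))
}
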