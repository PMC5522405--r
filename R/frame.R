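#' Molecular frame
#'
#' A single-frame container for a set of interaction sites: Cartesian
#' coordinates in Angstrom plus per-site metadata (name, residue id/name,
#' chain, mass). It is deliberately representation-agnostic: atomistic atoms
#' and coarse-grained beads are both "sites"; a CG bead may carry mass 0, in
#' which case every centre-of-mass operation on a selection containing it
#' falls back to geometric (unweighted) averaging.
#'
#' @param coords numeric matrix, n x 3, coordinates in Angstrom.
#' @param site_name character vector of site (atom/bead) names.
#' @param residue_id integer vector of residue ids, as in the source file
#'   (1-based PDB numbering is preserved verbatim).
#' @param residue_name character vector of residue names.
#' @param chain_id character vector of chain identifiers (recycled if length 1).
#' @param mass numeric vector of site masses in amu, or `NULL` to infer from
#'   the leading characters of `site_name` (unknown element gives mass 0 and
#'   a warning).
#' @param box optional numeric length-3 box edge lengths in Angstrom.
#' @return an object of class `molecular_frame`.
#' @export
molecular_frame <- function(coords, site_name, residue_id, residue_name,
                            chain_id = "A", mass = NULL, box = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix", call. = FALSE)
  n <- nrow(coords)
  if (n == 0L) stop("empty input: frame has zero sites", call. = FALSE)
  if (!all(is.finite(coords))) {
    stop("all coordinate components must be finite", call. = FALSE)
  }
  storage.mode(coords) <- "double"
  site_name <- as.character(site_name)
  residue_id <- as.integer(residue_id)
  residue_name <- as.character(residue_name)
  if (length(chain_id) == 1L) chain_id <- rep(as.character(chain_id), n)
  chain_id <- as.character(chain_id)
  lens <- c(length(site_name), length(residue_id), length(residue_name),
            length(chain_id))
  if (any(lens != n)) {
    stop("site arrays must all have length ", n, call. = FALSE)
  }
  if (is.null(mass)) {
    mass <- infer_site_mass(site_name)
  } else {
    mass <- as.numeric(mass)
    if (length(mass) == 1L) mass <- rep(mass, n)
    if (length(mass) != n) stop("mass must have length ", n, call. = FALSE)
    if (any(!is.finite(mass) | mass < 0)) {
      stop("masses must be finite and >= 0", call. = FALSE)
    }
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box) | box <= 0)) {
      stop("box must be 3 positive lengths in Angstrom", call. = FALSE)
    }
  }
  structure(
    list(coords = unname(coords), site_name = site_name,
         residue_id = residue_id, residue_name = residue_name,
         chain_id = chain_id, mass = mass, box = box),
    class = "molecular_frame"
  )
}

#' @export
print.molecular_frame <- function(x, ...) {
  cat("molecular_frame:", n_sites(x), "sites,",
      length(unique(paste(x$chain_id, x$residue_id))), "residues\n")
  invisible(x)
}

#' Number of sites in a frame or trajectory
#' @param x a `molecular_frame` or `trajectory`.
#' @return integer site count.
#' @export
n_sites <- function(x) {
  if (inherits(x, "trajectory")) x <- x$topology
  nrow(x$coords)
}

# Masses (amu) keyed by element symbol; covers the elements that occur in
# protein/lipid structures. CG bead names will typically not match and give 0.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, K = 39.098, B = 10.81, I = 126.904,
  CL = 35.45, MG = 24.305, FE = 55.845, ZN = 65.38,
  BR = 79.904, MN = 54.938, CU = 63.546, SE = 78.971
)

#' Infer site masses from site names
#'
#' Takes the leading alphabetic characters of each site name, tries a
#' two-letter element match first (e.g. "CL"), then one letter. Unknown
#' elements get mass 0 with a warning; downstream centre-of-mass operations
#' then use geometric weighting for any selection containing such a site.
#'
#' Note that PDB atom names like "CA" are read as carbon, not calcium: the
#' two-letter codes for calcium and sodium are only matched when the full
#' name equals the element symbol plus a charge sign (ion naming convention).
#'
#' @param site_name character vector.
#' @return numeric masses in amu.
#' @export
infer_site_mass <- function(site_name) {
  lead <- toupper(sub("^([A-Za-z]*).*$", "\\1", site_name))
  two_letter <- c("CL", "MG", "FE", "ZN", "BR", "MN", "CU", "SE")
  m <- numeric(length(site_name))
  unknown <- character(0)
  for (i in seq_along(lead)) {
    nm <- lead[i]
    one <- substr(nm, 1, 1)
    if (nm %in% two_letter) {
      m[i] <- .element_masses[[nm]]
    } else if (one %in% names(.element_masses)) {
      m[i] <- .element_masses[[one]]
    } else {
      m[i] <- 0
      unknown <- c(unknown, site_name[i])
    }
  }
  if (length(unknown) > 0) {
    warning("unknown element for site name(s) ",
            paste(unique(unknown), collapse = ", "),
            "; mass set to 0 (geometric COM will be used)", call. = FALSE)
  }
  m
}

#' Trajectory
#'
#' An ordered sequence of frames sharing one topology (site identity and
#' count). Coordinates are stored as an `n_sites x 3 x n_frames` array; the
#' per-site metadata lives once in `topology` (a [molecular_frame] whose
#' coordinates are those of the first frame).
#'
#' @param topology a `molecular_frame` providing site identities.
#' @param coords an `n_sites x 3 x n_frames` array, Angstrom.
#' @param time_per_frame frame spacing in ns (metadata only).
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, time_per_frame = NA_real_) {
  stopifnot(inherits(topology, "molecular_frame"))
  coords <- as.array(coords)
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("coords must be an n_sites x 3 x n_frames array", call. = FALSE)
  }
  if (dim(coords)[1] != n_sites(topology)) {
    stop("coords site count does not match topology", call. = FALSE)
  }
  if (dim(coords)[3] < 1L) stop("trajectory needs >= 1 frame", call. = FALSE)
  if (!all(is.finite(coords))) {
    stop("all coordinates must be finite", call. = FALSE)
  }
  structure(list(topology = topology, coords = coords,
                 time_per_frame = time_per_frame),
            class = "trajectory")
}

#' Build a trajectory from a list of frames
#'
#' @param frames list of `molecular_frame`s with identical site identity.
#' @param time_per_frame frame spacing in ns (metadata only).
#' @return a `trajectory`.
#' @export
as_trajectory <- function(frames, time_per_frame = NA_real_) {
  stopifnot(length(frames) >= 1L)
  topo <- frames[[1L]]
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!inherits(f, "molecular_frame") || n_sites(f) != n_sites(topo) ||
        !identical(f$site_name, topo$site_name)) {
      stop("frame ", i, " does not share the trajectory topology",
           call. = FALSE)
    }
  }
  coords <- array(0, c(n_sites(topo), 3L, length(frames)))
  for (i in seq_along(frames)) coords[, , i] <- frames[[i]]$coords
  trajectory(topo, coords, time_per_frame)
}

#' Number of frames
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  dim(traj$coords)[3]
}

#' Extract one frame of a trajectory
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return a `molecular_frame`.
#' @export
traj_frame <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory"))
  if (!.is_count(i) || i > n_frames(traj)) {
    stop("frame index out of range: ", i, call. = FALSE)
  }
  f <- traj$topology
  f$coords <- traj$coords[, , i, drop = TRUE]
  if (is.null(dim(f$coords))) f$coords <- matrix(f$coords, ncol = 3)
  f
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", n_frames(x), "frames x", n_sites(x), "sites\n")
  invisible(x)
}

#' Triglyceride topology
#'
#' Index map from one triglyceride molecule in a frame to the sites the
#' chain-vector construction needs: the central site (atomistic central
#' glycerol carbon; CG GLY bead), and per acyl chain either the two
#' double-bond carbon indices (atomistic C=C) or the single double-bond
#' D-bead index (CG). Ester site indices are carried as metadata.
#'
#' @param central_site integer site index of the central glycerol site.
#' @param chain_sites list of 3 integer vectors, each of length 2 (atomistic
#'   C=C pair) or 1 (CG D-bead).
#' @param ester_sites integer vector of 3 ester site indices (metadata).
#' @param representation `"atomistic"` or `"coarse_grained"`.
#' @return an object of class `tg_topology`.
#' @export
tg_topology <- function(central_site, chain_sites, ester_sites = integer(0),
                        representation = c("atomistic", "coarse_grained")) {
  representation <- match.arg(representation)
  central_site <- as.integer(central_site)
  if (length(chain_sites) != 3L) {
    stop("a triglyceride has exactly 3 chains", call. = FALSE)
  }
  chain_sites <- lapply(chain_sites, as.integer)
  want <- if (representation == "atomistic") 2L else 1L
  for (k in 1:3) {
    if (length(chain_sites[[k]]) != want) {
      stop(sprintf("chain %d must map to %d site(s) for %s representation",
                   k, want, representation), call. = FALSE)
    }
  }
  all_idx <- c(central_site, unlist(chain_sites))
  if (anyDuplicated(all_idx)) {
    stop("topology site indices must be distinct", call. = FALSE)
  }
  if (any(all_idx < 1L)) stop("site indices must be >= 1", call. = FALSE)
  structure(list(central_site = central_site, chain_sites = chain_sites,
                 ester_sites = as.integer(ester_sites),
                 representation = representation),
            class = "tg_topology")
}

.check_topology_in_frame <- function(frame, topo) {
  idx <- c(topo$central_site, unlist(topo$chain_sites), topo$ester_sites)
  if (any(idx > n_sites(frame))) {
    stop("topology site index out of range for frame with ", n_sites(frame),
         " sites", call. = FALSE)
  }
  invisible(TRUE)
}
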