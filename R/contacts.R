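# Protein-lipid contact accounting under a distance cutoff: site-pair
# counts, residue-level contact sets, gained/lost/common comparisons
# between two lipid systems, and geometric hydrogen-bond detection.
# Distances are plain Euclidean: no periodic minimum-image convention
# (whole-molecule post-processed frames are assumed).

#' Site-site contacts between two selections
#'
#' Counts unordered site pairs (a in A, b in B) whose Euclidean distance is
#' at most `cutoff`. The returned pair list is explicit, so the count always
#' equals its length.
#'
#' @param frame a [molecular_frame].
#' @param set_a,set_b disjoint integer site-index vectors.
#' @param cutoff distance threshold in Angstrom (default 5, the usual
#'   hydrophobic-contact criterion).
#' @return an object of class `contact_result`: list with `count`, `pairs`
#'   (m x 2 matrix of site indices), `residues` (sorted residue ids of the
#'   contacting `set_a` sites) and `cutoff`.
#' @export
site_contacts <- function(frame, set_a, set_b, cutoff = 5) {
  stopifnot(inherits(frame, "molecular_frame"))
  set_a <- as.integer(set_a)
  set_b <- as.integer(set_b)
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("empty site selection", call. = FALSE)
  }
  if (max(set_a, set_b) > n_sites(frame) || min(set_a, set_b) < 1L) {
    stop("site index out of range", call. = FALSE)
  }
  if (length(intersect(set_a, set_b))) {
    stop("site sets must be disjoint", call. = FALSE)
  }
  if (!is.finite(cutoff) || cutoff <= 0) {
    stop("cutoff must be positive", call. = FALSE)
  }
  A <- frame$coords[set_a, , drop = FALSE]
  B <- frame$coords[set_b, , drop = FALSE]
  d2 <- outer(A[, 1], B[, 1], `-`)^2 +
    outer(A[, 2], B[, 2], `-`)^2 +
    outer(A[, 3], B[, 3], `-`)^2
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  pairs <- cbind(a = set_a[hit[, 1]], b = set_b[hit[, 2]])
  structure(list(count = nrow(pairs), pairs = pairs,
                 residues = sort(unique(frame$residue_id[pairs[, 1]])),
                 cutoff = cutoff),
            class = "contact_result")
}

#' @export
print.contact_result <- function(x, ...) {
  cat("contact_result:", x$count, "site pairs within", x$cutoff,
      "Angstrom;", length(x$residues), "set-A residues involved\n")
  invisible(x)
}

#' Residue-level contact set
#'
#' A protein residue is in contact when at least one of its sites lies
#' within `cutoff` of at least one lipid site. Following the usual
#' procedure this is applied to a single (typically time-averaged) frame;
#' passing a [trajectory] instead switches to per-frame evaluation with an
#' occupancy criterion (residue retained when in contact in at least
#' `occupancy` of the frames).
#'
#' @param x a [molecular_frame] or [trajectory].
#' @param lipid_sites integer site indices of the lipid.
#' @param protein_sites integer site indices partitioned by residue id
#'   (default: all sites not in `lipid_sites`).
#' @param cutoff distance threshold in Angstrom.
#' @param occupancy minimum fraction of frames (trajectory input only).
#' @return named character vector: residue names keyed by residue id
#'   (names attribute holds residue names; values are sorted residue ids).
#' @export
residue_contacts <- function(x, lipid_sites, protein_sites = NULL,
                             cutoff = 5, occupancy = 0.5) {
  lipid_sites <- as.integer(lipid_sites)
  if (inherits(x, "trajectory")) {
    nf <- n_frames(x)
    hits <- table(unlist(lapply(seq_len(nf), function(f) {
      .residue_contact_ids(traj_frame(x, f), lipid_sites, protein_sites,
                           cutoff)
    })))
    ids <- sort(as.integer(names(hits)[hits / nf >= occupancy]))
    frame <- x$topology
  } else {
    frame <- x
    ids <- .residue_contact_ids(frame, lipid_sites, protein_sites, cutoff)
  }
  nm <- frame$residue_name[match(ids, frame$residue_id)]
  stats::setNames(ids, nm)
}

.residue_contact_ids <- function(frame, lipid_sites, protein_sites, cutoff) {
  stopifnot(inherits(frame, "molecular_frame"))
  if (is.null(protein_sites)) {
    protein_sites <- setdiff(seq_len(n_sites(frame)), lipid_sites)
  }
  if (length(protein_sites) == 0L) {
    stop("empty protein partition", call. = FALSE)
  }
  res <- site_contacts(frame, protein_sites, lipid_sites, cutoff)
  res$residues
}

#' Compare two residue-level contact sets
#'
#' `common` is the intersection, `gained` the residues only the query lipid
#' contacts, `lost` the residues only the reference lipid contacts. Both
#' percent-change conventions are reported because published percentages
#' use each: `percent_change_ref_denom = 100 (|query| - |ref|) / |ref|` and
#' `percent_change_query_denom = 100 (|query| - |ref|) / |query|`.
#'
#' @param ref_set,query_set vectors of residue ids (or labels) over the
#'   same residue universe.
#' @return an object of class `contact_comparison`.
#' @export
compare_contacts <- function(ref_set, query_set) {
  ref_set <- unique(ref_set)
  query_set <- unique(query_set)
  n_ref <- length(ref_set)
  n_query <- length(query_set)
  if (n_ref == 0L) stop("empty reference set", call. = FALSE)
  structure(list(common = sort(intersect(ref_set, query_set)),
                 gained = sort(setdiff(query_set, ref_set)),
                 lost = sort(setdiff(ref_set, query_set)),
                 n_ref = n_ref, n_query = n_query,
                 percent_change_ref_denom = 100 * (n_query - n_ref) / n_ref,
                 percent_change_query_denom =
                   100 * (n_query - n_ref) / n_query),
            class = "contact_comparison")
}

#' @export
print.contact_comparison <- function(x, ...) {
  cat(sprintf(paste0("contact_comparison: %d ref vs %d query residues ",
                     "(%d common, %d gained, %d lost)\n"),
              x$n_ref, x$n_query, length(x$common), length(x$gained),
              length(x$lost)))
  cat(sprintf("  change: %+.1f%% of reference, %+.1f%% of query\n",
              x$percent_change_ref_denom, x$percent_change_query_denom))
  invisible(x)
}

#' Per-frame contact count time series
#'
#' @param traj a [trajectory].
#' @param lipid_sites,protein_sites disjoint site-index vectors.
#' @param cutoff distance threshold in Angstrom.
#' @return data.frame with columns `frame`, `n_contacts`.
#' @export
contact_timeseries <- function(traj, lipid_sites, protein_sites, cutoff = 5) {
  stopifnot(inherits(traj, "trajectory"))
  counts <- vapply(seq_len(n_frames(traj)), function(f) {
    site_contacts(traj_frame(traj, f), protein_sites, lipid_sites,
                  cutoff)$count
  }, integer(1))
  data.frame(frame = seq_len(n_frames(traj)), n_contacts = counts)
}

#' Geometric hydrogen-bond detection
#'
#' Reports donor-hydrogen-acceptor triples with donor-acceptor distance at
#' most `d_cut` (default 3.5 Angstrom) and donor-H...acceptor angle (at the
#' hydrogen) at least `angle_cut` (default 120 degrees; 180 is linear).
#' Hydrogens are mapped to donors positionally: `hydrogen_sites[i]` is
#' bonded to `donor_sites[i]`.
#'
#' @param frame a [molecular_frame].
#' @param donor_sites,hydrogen_sites equal-length integer site vectors.
#' @param acceptor_sites integer site vector.
#' @param d_cut donor-acceptor distance cutoff, Angstrom.
#' @param angle_cut minimum D-H...A angle, degrees.
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `dist_da`, `angle_dha`.
#' @export
detect_hbonds <- function(frame, donor_sites, hydrogen_sites, acceptor_sites,
                          d_cut = 3.5, angle_cut = 120) {
  stopifnot(inherits(frame, "molecular_frame"))
  donor_sites <- as.integer(donor_sites)
  hydrogen_sites <- as.integer(hydrogen_sites)
  acceptor_sites <- as.integer(acceptor_sites)
  if (length(donor_sites) != length(hydrogen_sites)) {
    stop("hydrogen without donor mapping: donor_sites and hydrogen_sites ",
         "must be parallel vectors", call. = FALSE)
  }
  out <- list()
  for (i in seq_along(donor_sites)) {
    d <- frame$coords[donor_sites[i], ]
    h <- frame$coords[hydrogen_sites[i], ]
    for (a_idx in setdiff(acceptor_sites, donor_sites[i])) {
      a <- frame$coords[a_idx, ]
      dist_da <- .norm3(d - a)
      if (dist_da > d_cut) next
      ang <- angle_between(d - h, a - h)
      if (ang < angle_cut) next
      out[[length(out) + 1L]] <- data.frame(donor = donor_sites[i],
                                            hydrogen = hydrogen_sites[i],
                                            acceptor = a_idx,
                                            dist_da = dist_da,
                                            angle_dha = ang)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), dist_da = numeric(0),
                      angle_dha = numeric(0)))
  }
  do.call(rbind, out)
}
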