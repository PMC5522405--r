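# State classification: map sn angles to single-lipid orientation and
# conformation labels, combine two lipids into a pair-orientation label,
# and summarize a label sequence as a probability distribution.

.orientation_levels <- c("HEAD_TO_LEGS", "LEGS_TO_HEAD", "RANDOM")
.conformation_levels <- c("FORK_LIKE", "TRIDENT", "RANDOM")
.pair_levels <- c("PARALLEL_NN", "ANTIPARALLEL_NC", "PARALLEL_CC",
                  "ANTIPARALLEL_CN", "RANDOM")

#' Single-lipid orientation from the sn1-sn3 angle
#'
#' A lipid whose sn1-sn3 angle is below `head_max` (default 75 degrees) rests
#' head-to-legs from the N- to the C-terminal end of the tunnel; above
#' `legs_min` (default 105) it rests legs-to-head; intermediate angles are
#' random. Both thresholds themselves fall in the RANDOM band (half-open
#' convention), so the three labels partition `[0, 180]` exactly.
#'
#' @param sn1sn3 numeric vector of angles in degrees, each in `[0, 180]`.
#' @param head_max,legs_min thresholds in degrees.
#' @return character vector of labels `HEAD_TO_LEGS`, `LEGS_TO_HEAD`,
#'   `RANDOM`.
#' @export
classify_orientation <- function(sn1sn3, head_max = 75, legs_min = 105) {
  sn1sn3 <- as.numeric(sn1sn3)
  if (any(!is.finite(sn1sn3) | sn1sn3 < 0 | sn1sn3 > 180)) {
    stop("sn1-sn3 angle out of range [0, 180]", call. = FALSE)
  }
  if (!(head_max < legs_min)) {
    stop("thresholds must satisfy head_max < legs_min", call. = FALSE)
  }
  ifelse(sn1sn3 < head_max, "HEAD_TO_LEGS",
         ifelse(sn1sn3 > legs_min, "LEGS_TO_HEAD", "RANDOM"))
}

#' Single-lipid conformation from the (sn1-sn3, sn2-sn3) angle pair
#'
#' Thresholds interpolate the observed signature peaks: a fork-like lipid
#' (tuning fork or chair; the two are not distinguished) has one small and
#' one large inter-chain angle, a trident has both small, anything else is
#' random. Defaults: small means `<= 60`, large means `>= 105`.
#'
#' @param sn1sn3,sn2sn3 numeric vectors of angles in degrees.
#' @param small_max,large_min classification thresholds in degrees.
#' @return character vector of labels `FORK_LIKE`, `TRIDENT`, `RANDOM`.
#' @export
classify_conformation <- function(sn1sn3, sn2sn3, small_max = 60,
                                  large_min = 105) {
  sn1sn3 <- as.numeric(sn1sn3)
  sn2sn3 <- as.numeric(sn2sn3)
  if (any(!is.finite(c(sn1sn3, sn2sn3)) | c(sn1sn3, sn2sn3) < 0 |
          c(sn1sn3, sn2sn3) > 180)) {
    stop("angles out of range [0, 180]", call. = FALSE)
  }
  lo <- pmin(sn1sn3, sn2sn3)
  hi <- pmax(sn1sn3, sn2sn3)
  ifelse(lo <= small_max & hi >= large_min, "FORK_LIKE",
         ifelse(hi <= small_max, "TRIDENT", "RANDOM"))
}

#' Pair-orientation label from two single-lipid orientations
#'
#' `(HEAD, HEAD)` is parallel N-N, `(HEAD, LEGS)` antiparallel N-C,
#' `(LEGS, LEGS)` parallel C-C, `(LEGS, HEAD)` antiparallel C-N; a pair with
#' either lipid individually random is a random pair.
#'
#' @param orientation_n,orientation_c labels of TG_N and TG_C (character
#'   vectors, values from [classify_orientation()]).
#' @return character vector of pair labels.
#' @export
classify_pair <- function(orientation_n, orientation_c) {
  orientation_n <- as.character(orientation_n)
  orientation_c <- as.character(orientation_c)
  ok <- orientation_n %in% .orientation_levels &
    orientation_c %in% .orientation_levels
  if (!all(ok)) stop("invalid orientation label(s)", call. = FALSE)
  key <- paste(orientation_n, orientation_c, sep = "|")
  map <- c("HEAD_TO_LEGS|HEAD_TO_LEGS" = "PARALLEL_NN",
           "HEAD_TO_LEGS|LEGS_TO_HEAD" = "ANTIPARALLEL_NC",
           "LEGS_TO_HEAD|LEGS_TO_HEAD" = "PARALLEL_CC",
           "LEGS_TO_HEAD|HEAD_TO_LEGS" = "ANTIPARALLEL_CN")
  out <- unname(map[key])
  out[is.na(out)] <- "RANDOM"
  out
}

#' Probability distribution over pair-orientation states
#'
#' Empirical probabilities (frame counts over total) of the five pair
#' states. Masses are non-negative and sum to exactly 1.
#'
#' @param labels character vector of per-frame pair labels.
#' @return named numeric vector over `PARALLEL_NN`, `ANTIPARALLEL_NC`,
#'   `PARALLEL_CC`, `ANTIPARALLEL_CN`, `RANDOM`, with attribute `n_frames`.
#' @export
pair_distribution <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("empty label sequence", call. = FALSE)
  if (!all(labels %in% .pair_levels)) {
    stop("invalid pair label(s): ",
         paste(unique(setdiff(labels, .pair_levels)), collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(labels, levels = .pair_levels))
  out <- as.numeric(counts) / length(labels)
  names(out) <- .pair_levels
  attr(out, "n_frames") <- length(labels)
  out
}

#' Exact-match classification accuracy
#'
#' @param inferred,truth equal-length label vectors.
#' @return fraction of positions where the labels agree, in `[0, 1]`.
#' @export
classification_accuracy <- function(inferred, truth) {
  if (length(inferred) != length(truth)) {
    stop("length mismatch: ", length(inferred), " inferred vs ",
         length(truth), " truth labels", call. = FALSE)
  }
  if (length(inferred) == 0L) stop("empty label sequences", call. = FALSE)
  mean(as.character(inferred) == as.character(truth))
}

#' Classify a two-lipid trajectory frame by frame
#'
#' Convenience wrapper: computes both lipids' angle series, classifies each
#' frame's orientations and the pair state, and returns the per-frame label
#' table. Pass the output's `pair` column to [pair_distribution()] for the
#' trajectory-level summary.
#'
#' @param traj a [trajectory].
#' @param topology_n,topology_c [tg_topology] of TG_N and TG_C.
#' @param axis N-to-C axis 3-vector.
#' @param head_max,legs_min orientation thresholds in degrees.
#' @return data.frame with columns `frame`, `sn1sn3_n`, `sn2sn3_n`,
#'   `sn1sn3_c`, `sn2sn3_c`, `orientation_n`, `orientation_c`, `pair`.
#' @export
classify_pair_trajectory <- function(traj, topology_n, topology_c, axis,
                                     head_max = 75, legs_min = 105) {
  ser_n <- tg_angle_series(traj, topology_n, axis = axis)
  ser_c <- tg_angle_series(traj, topology_c, axis = axis)
  orientation_n <- classify_orientation(ser_n$sn1sn3, head_max, legs_min)
  orientation_c <- classify_orientation(ser_c$sn1sn3, head_max, legs_min)
  data.frame(frame = ser_n$frame,
             sn1sn3_n = ser_n$sn1sn3, sn2sn3_n = ser_n$sn2sn3,
             sn1sn3_c = ser_c$sn1sn3, sn2sn3_c = ser_c$sn2sn3,
             orientation_n = orientation_n, orientation_c = orientation_c,
             pair = classify_pair(orientation_n, orientation_c),
             stringsAsFactors = FALSE)
}
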