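# Independent oracles and geometry helpers used across the test files.

# uniform random proper rotation matrix from a random unit quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# apply a rigid motion (rows are points: x' = x R^T + t)
transform_coords <- function(coords, R, t = c(0, 0, 0)) {
  sweep(coords %*% t(R), 2, t, `+`)
}

transform_frame <- function(frame, R, t = c(0, 0, 0)) {
  frame$coords <- transform_coords(frame$coords, R, t)
  frame
}

transform_trajectory <- function(traj, R, t = c(0, 0, 0)) {
  for (f in seq_len(dim(traj$coords)[3])) {
    traj$coords[, , f] <- transform_coords(traj$coords[, , f], R, t)
  }
  traj
}

mirror_frame <- function(frame) {
  frame$coords[, 1] <- -frame$coords[, 1]
  frame
}

# Horn's quaternion method for the minimal superposition RMSD; an
# independent route to the same quantity as the SVD-based Kabsch fit.
horn_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  S <- crossprod(Ac, Bc)
  N <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2], S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3], S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1], -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3], S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]),
    nrow = 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Ac^2) + sum(Bc^2) - 2 * lambda) / nrow(A)
  sqrt(max(0, msd))
}

# exhaustive double-loop contact count (per-pair sqrt distance test)
brute_force_contacts <- function(A, B, cutoff) {
  count <- 0L
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      if (sqrt(sum((A[i, ] - B[j, ])^2)) <= cutoff) count <- count + 1L
    }
  }
  count
}

# same enumeration with the inner loop vectorized (for larger instances)
brute_force_contacts_fast <- function(A, B, cutoff) {
  count <- 0L
  for (i in seq_len(nrow(A))) {
    d <- sqrt((A[i, 1] - B[, 1])^2 + (A[i, 2] - B[, 2])^2 +
                (A[i, 3] - B[, 3])^2)
    count <- count + sum(d <= cutoff)
  }
  count
}

# a minimal hand-built frame: n points, one residue per site
point_frame <- function(coords, mass = 12, resid = seq_len(nrow(coords)),
                        name = "CA", resname = "ALA") {
  molecular_frame(coords, site_name = rep(name, nrow(coords)),
                  residue_id = resid,
                  residue_name = rep(resname, nrow(coords)),
                  chain_id = "A", mass = rep(mass, nrow(coords)))
}

# a hand-built atomistic TG frame: central site at `center`, chain tips at
# center + tips[k,], C=C atoms straddling each tip along `perp`
toy_tg_frame <- function(center, tips, perp = c(0, 0, 1), sep = 0.7) {
  coords <- matrix(0, 1 + 2 * nrow(tips), 3)
  coords[1, ] <- center
  for (k in seq_len(nrow(tips))) {
    tip <- center + tips[k, ]
    coords[2 * k, ] <- tip - sep / 2 * perp
    coords[2 * k + 1, ] <- tip + sep / 2 * perp
  }
  frame <- point_frame(coords, resid = rep(1L, nrow(coords)),
                       name = "C", resname = "TRI")
  topo <- tg_topology(central_site = 1L,
                      chain_sites = list(c(2L, 3L), c(4L, 5L), c(6L, 7L)),
                      representation = "atomistic")
  list(frame = frame, topology = topo)
}
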