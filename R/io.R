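#' Read a structure file into a molecular frame
#'
#' PDB files are parsed with \pkg{bio3d}; residue numbering is preserved
#' verbatim and records carrying insertion codes are rejected rather than
#' silently renumbered. GRO files (fixed-column, nm units) are parsed
#' directly and converted to Angstrom on read: all internal units are
#' Angstrom.
#'
#' @param path file path.
#' @param format `"pdb"` or `"gro"`.
#' @return a [molecular_frame].
#' @export
read_structure <- function(path, format = c("pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format, pdb = .read_pdb_frame(path), gro = .read_gro_frame(path))
}

.read_pdb_frame <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) {
                    stop("format error reading PDB '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  at <- pdb$atom
  if (nrow(at) == 0L) stop("empty input: no ATOM/HETATM records in ", path,
                           call. = FALSE)
  ins <- at$insert
  if (any(!is.na(ins) & nzchar(trimws(ins)))) {
    bad <- which(!is.na(ins) & nzchar(trimws(ins)))[1]
    stop("PDB insertion codes are not supported (first at atom record ", bad,
         "); renumber the structure instead", call. = FALSE)
  }
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))[1]
    stop("format error: non-numeric coordinates at atom record ", bad,
         call. = FALSE)
  }
  chain <- at$chain
  chain[is.na(chain)] <- ""
  molecular_frame(cbind(at$x, at$y, at$z), site_name = at$elety,
                  residue_id = at$resno, residue_name = at$resid,
                  chain_id = chain)
}

# GRO fixed columns: resid(1:5) resname(6:10) atomname(11:15) atomno(16:20)
# then x, y, z in nm as %8.3f. Velocities, if present, are ignored.
.read_gro_frame <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("format error: GRO file too short: ", path,
                               call. = FALSE)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || natoms < 1L) {
    stop("format error at line 2 of ", path, ": bad atom count", call. = FALSE)
  }
  if (length(lines) < 2L + natoms) {
    stop("format error: GRO file declares ", natoms, " atoms but has only ",
         length(lines) - 3L, " atom lines", call. = FALSE)
  }
  al <- lines[3:(2 + natoms)]
  num <- function(s, lineno) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v))) {
      stop("format error at line ", lineno[which(is.na(v))[1]], " of ", path,
           ": bad coordinate field", call. = FALSE)
    }
    v
  }
  linenos <- 3:(2 + natoms)
  resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
  if (any(is.na(resid))) {
    stop("format error at line ", linenos[which(is.na(resid))[1]], " of ",
         path, ": bad residue number", call. = FALSE)
  }
  resname <- trimws(substr(al, 6, 10))
  atname <- trimws(substr(al, 11, 15))
  x <- num(substr(al, 21, 28), linenos)
  y <- num(substr(al, 29, 36), linenos)
  z <- num(substr(al, 37, 44), linenos)
  boxline <- trimws(lines[3 + natoms])
  box <- suppressWarnings(as.numeric(strsplit(boxline, "\\s+")[[1]]))
  box <- if (length(box) >= 3 && all(is.finite(box[1:3])) && all(box[1:3] > 0)) {
    box[1:3] * 10
  } else {
    NULL
  }
  molecular_frame(cbind(x, y, z) * 10, site_name = atname, residue_id = resid,
                  residue_name = resname, chain_id = "", box = box)
}

#' Read a multi-frame trajectory
#'
#' Supported formats are multi-model PDB (parsed with \pkg{bio3d}) and the
#' plain-text `xyzcsv` dialect: a header line `frame,site,x,y,z` followed by
#' one row per site per frame, coordinates in Angstrom, frames contiguous
#' and 0-based, sites 0-based in topology order within each frame.
#'
#' @param path file path.
#' @param format `"multimodel_pdb"` or `"xyzcsv"`.
#' @param topology a [molecular_frame] giving the site identities the frames
#'   must match.
#' @return a [trajectory].
#' @export
read_trajectory <- function(path, format = c("multimodel_pdb", "xyzcsv"),
                            topology) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(inherits(topology, "molecular_frame"))
  switch(format,
         multimodel_pdb = .read_multimodel_pdb(path, topology),
         xyzcsv = .read_xyzcsv(path, topology))
}

.read_multimodel_pdb <- function(path, topology) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  n_expected <- n_sites(topology)
  if (length(starts) == 0L) {
    # single implicit model
    frame <- .read_pdb_frame(path)
    if (n_sites(frame) != n_expected) {
      stop("shape error at frame 1: ", n_sites(frame), " sites, expected ",
           n_expected, call. = FALSE)
    }
    return(trajectory(topology, array(frame$coords, c(n_expected, 3, 1))))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) {
    stop("shape error at frame ", length(starts),
         ": truncated model (missing ENDMDL)", call. = FALSE)
  }
  for (i in seq_along(starts)) {
    natom <- sum(grepl("^(ATOM  |HETATM)", lines[starts[i]:ends[i]]))
    if (natom != n_expected) {
      stop("shape error at frame ", i, ": ", natom, " sites, expected ",
           n_expected, call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  coords <- array(0, c(n_expected, 3, nf))
  for (i in seq_len(nf)) {
    coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  }
  trajectory(topology, coords)
}

.read_xyzcsv <- function(path, topology) {
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "frame,site,x,y,z")) {
    stop("format error at line 1: xyzcsv header must be 'frame,site,x,y,z'",
         call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = c("integer", "integer", "numeric",
                                             "numeric", "numeric"))
  n <- n_sites(topology)
  if (nrow(df) == 0L) stop("empty input: no rows in ", path, call. = FALSE)
  if (nrow(df) %% n != 0L) {
    stop("shape error at frame ", nrow(df) %/% n + 1L,
         ": truncated frame (", nrow(df) %% n, " of ", n, " sites)",
         call. = FALSE)
  }
  nf <- nrow(df) %/% n
  expect_frame <- rep(0:(nf - 1L), each = n)
  expect_site <- rep(0:(n - 1L), times = nf)
  if (!identical(df$frame, as.integer(expect_frame))) {
    bad <- which(df$frame != expect_frame)[1]
    stop("format error: frames must be contiguous and 0-based (row ", bad + 1L,
         ")", call. = FALSE)
  }
  if (!identical(df$site, as.integer(expect_site))) {
    bad <- which(df$site != expect_site)[1]
    stop("format error: sites must be 0-based in topology order (row ",
         bad + 1L, ")", call. = FALSE)
  }
  coords <- array(0, c(n, 3, nf))
  xyz <- as.matrix(df[, c("x", "y", "z")])
  for (i in seq_len(nf)) coords[, , i] <- xyz[((i - 1L) * n + 1L):(i * n), ]
  trajectory(topology, coords)
}

#' Write a trajectory
#'
#' `xyzcsv` writes coordinates with 17 significant digits so a
#' read/write round trip is exact; multi-model PDB is written via
#' \pkg{bio3d} and rounds to the format's 1e-3 Angstrom precision.
#'
#' @param traj a [trajectory].
#' @param path output path.
#' @param format `"multimodel_pdb"` or `"xyzcsv"`.
#' @return invisibly, `path`.
#' @export
write_trajectory <- function(traj, path, format = c("multimodel_pdb",
                                                    "xyzcsv")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "trajectory"))
  if (format == "xyzcsv") {
    n <- n_sites(traj)
    nf <- n_frames(traj)
    rows <- character(n * nf + 1L)
    rows[1] <- "frame,site,x,y,z"
    k <- 2L
    for (i in seq_len(nf)) {
      xyz <- traj$coords[, , i, drop = TRUE]
      if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
      rows[k:(k + n - 1L)] <- sprintf("%d,%d,%.17g,%.17g,%.17g",
                                      i - 1L, 0:(n - 1L),
                                      xyz[, 1], xyz[, 2], xyz[, 3])
      k <- k + n
    }
    con <- tryCatch(file(path, "w"),
                    error = function(e) stop("cannot write to ", path,
                                             call. = FALSE))
    on.exit(close(con))
    writeLines(rows, con)
  } else {
    topo <- traj$topology
    nf <- n_frames(traj)
    xyz <- matrix(0, nf, 3L * n_sites(traj))
    for (i in seq_len(nf)) {
      xyz[i, ] <- as.vector(t(traj$coords[, , i]))
    }
    chain <- substr(topo$chain_id, 1, 1)
    chain[!nzchar(chain)] <- " "
    tryCatch(
      bio3d::write.pdb(file = path, xyz = xyz, resno = topo$residue_id,
                       resid = substr(topo$residue_name, 1, 3),
                       eleno = seq_len(n_sites(traj)),
                       elety = substr(topo$site_name, 1, 4), chain = chain),
      error = function(e) stop("cannot write PDB to ", path, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  invisible(path)
}
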