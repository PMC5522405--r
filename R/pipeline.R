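# End-to-end pipeline: a validated configuration object, a deterministic
# run over synthetic or file-based inputs, and a report bundle (per-frame
# CSVs, distribution JSON, manifest with checksums).

#' Pipeline run configuration
#'
#' Collects every tunable parameter of the analysis in one validated
#' object. Either a simulation block (a [trajectory_spec] plus optional
#' scaffold) or input file paths must be supplied.
#'
#' @param simulate optional list passed to the generator: fields
#'   `trajectory_spec` ([trajectory_spec]), optional `scaffold_spec`,
#'   optional `axis_length`.
#' @param input optional list describing file inputs: `trajectory_path`,
#'   `trajectory_format`, `topology_path`, `topology_format`, plus
#'   `topologies` (list of [tg_topology]) and either `axis` or `domains`.
#' @param orientation_head_max,orientation_legs_min single-lipid
#'   orientation thresholds, degrees.
#' @param conformation_small_max,conformation_large_min conformation
#'   thresholds, degrees.
#' @param contact_cutoff contact distance cutoff, Angstrom.
#' @param hbond_d_cut,hbond_angle_cut hydrogen-bond criteria.
#' @param bin_width histogram bin width, degrees (must divide 180).
#' @param n_windows window count for convergence splits.
#' @param seed integer seed controlling all randomness of the run.
#' @return an object of class `run_config`.
#' @export
run_config <- function(simulate = NULL, input = NULL,
                       orientation_head_max = 75,
                       orientation_legs_min = 105,
                       conformation_small_max = 60,
                       conformation_large_min = 105,
                       contact_cutoff = 5,
                       hbond_d_cut = 3.5, hbond_angle_cut = 120,
                       bin_width = 5, n_windows = 1L, seed = 1L) {
  if (is.null(simulate) == is.null(input)) {
    stop("config validation error: give exactly one of simulate or input",
         call. = FALSE)
  }
  if (!(orientation_head_max < orientation_legs_min)) {
    stop("config validation error: orientation thresholds must be ordered ",
         "head_max < legs_min", call. = FALSE)
  }
  if (!(conformation_small_max < conformation_large_min)) {
    stop("config validation error: conformation thresholds must be ordered",
         call. = FALSE)
  }
  if (!is.finite(contact_cutoff) || contact_cutoff <= 0) {
    stop("config validation error: contact cutoff must be > 0", call. = FALSE)
  }
  if (!is.finite(hbond_d_cut) || hbond_d_cut <= 0 ||
      !is.finite(hbond_angle_cut) || hbond_angle_cut < 0 ||
      hbond_angle_cut > 180) {
    stop("config validation error: bad hydrogen-bond criteria", call. = FALSE)
  }
  nb <- 180 / bin_width
  if (!is.finite(nb) || abs(nb - round(nb)) > 1e-9) {
    stop("config validation error: bin_width must divide 180", call. = FALSE)
  }
  if (!is.null(simulate) && !inherits(simulate$trajectory_spec,
                                      "trajectory_spec")) {
    stop("config validation error: simulate$trajectory_spec must be a ",
         "trajectory_spec", call. = FALSE)
  }
  structure(list(simulate = simulate, input = input,
                 orientation_head_max = orientation_head_max,
                 orientation_legs_min = orientation_legs_min,
                 conformation_small_max = conformation_small_max,
                 conformation_large_min = conformation_large_min,
                 contact_cutoff = contact_cutoff,
                 hbond_d_cut = hbond_d_cut,
                 hbond_angle_cut = hbond_angle_cut,
                 bin_width = bin_width, n_windows = as.integer(n_windows),
                 seed = as.integer(seed)),
            class = "run_config")
}

.write_csv_fixed <- function(df, path) {
  # fixed formatting so identical runs produce byte-identical files
  is_num <- vapply(df, is.double, logical(1))
  for (j in which(is_num)) df[[j]] <- sprintf("%.10g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Wires the stages together: obtain a trajectory (synthetic or from
#' files), compute both lipids' angle series and histograms, classify
#' per-frame orientation and pair states, summarize the pair distribution,
#' compute bend/twist series when domains are available, count
#' protein-lipid contacts when protein sites are present, and write the
#' report bundle: per-frame CSVs, histogram CSVs, a distribution JSON, and
#' a manifest with the package version, a config hash, the seed and an
#' md5 checksum for every emitted file. Deterministic for a fixed config.
#'
#' @param config a [run_config].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emitted <- character(0)
  emit <- function(name) {
    path <- file.path(out_dir, name)
    emitted <<- c(emitted, path)
    path
  }

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    ts <- sim$trajectory_spec
    ts$seed <- config$seed
    gen <- generate_trajectory(ts, tg_specs = sim$tg_specs,
                               scaffold_spec = sim$scaffold_spec,
                               axis_length = if (is.null(sim$axis_length)) 60
                                             else sim$axis_length)
    traj <- gen$trajectory
    topologies <- gen$topologies
    axis <- gen$axis_end - gen$axis_start
    domains <- gen$domains
    truth <- gen$truth
  } else {
    inp <- config$input
    topo_frame <- read_structure(inp$topology_path, inp$topology_format)
    traj <- read_trajectory(inp$trajectory_path, inp$trajectory_format,
                            topo_frame)
    topologies <- inp$topologies
    domains <- inp$domains
    axis <- if (!is.null(inp$axis)) inp$axis else NULL
    truth <- NULL
  }
  if (is.null(axis) && !is.null(domains)) {
    f1 <- traj_frame(traj, 1L)
    axis <- center_of_mass(f1, residues = domains$c_barrel) -
      center_of_mass(f1, residues = domains$n_barrel)
  }

  results <- list()
  series <- lapply(topologies, function(tp) {
    tg_angle_series(traj, tp, axis = axis)
  })
  tg_names <- if (length(series) == 2L) c("tg_n", "tg_c") else "tg"
  for (i in seq_along(series)) {
    .write_csv_fixed(series[[i]], emit(sprintf("angles_%s.csv", tg_names[i])))
    .write_csv_fixed(angle_histogram(series[[i]]$sn1sn3, config$bin_width),
                     emit(sprintf("hist_sn1sn3_%s.csv", tg_names[i])))
    .write_csv_fixed(angle_histogram(series[[i]]$sn2sn3, config$bin_width),
                     emit(sprintf("hist_sn2sn3_%s.csv", tg_names[i])))
  }
  results$angle_series <- series

  labels <- lapply(series, function(s) {
    classify_orientation(s$sn1sn3, config$orientation_head_max,
                         config$orientation_legs_min)
  })
  conf_labels <- lapply(series, function(s) {
    classify_conformation(s$sn1sn3, s$sn2sn3, config$conformation_small_max,
                          config$conformation_large_min)
  })
  label_df <- data.frame(frame = series[[1]]$frame)
  for (i in seq_along(labels)) {
    label_df[[paste0("orientation_", tg_names[i])]] <- labels[[i]]
    label_df[[paste0("conformation_", tg_names[i])]] <- conf_labels[[i]]
  }
  if (length(labels) == 2L) {
    label_df$pair <- classify_pair(labels[[1]], labels[[2]])
    dist <- pair_distribution(label_df$pair)
    results$pair_distribution <- dist
    jsonlite::write_json(list(probabilities = as.list(dist),
                              n_frames = attr(dist, "n_frames")),
                         emit("pair_distribution.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  .write_csv_fixed(label_df, emit("labels.csv"))
  results$labels <- label_df

  if (!is.null(domains)) {
    bt <- tryCatch(bend_twist_series(traj, domains, config$bin_width,
                                     config$n_windows),
                   error = function(e) NULL)
    if (!is.null(bt)) {
      .write_csv_fixed(bt$series, emit("bend_twist.csv"))
      results$bend_twist <- bt
    }
    lipid_sites <- sort(unlist(lapply(topologies, function(tp) {
      c(tp$central_site, unlist(tp$chain_sites), tp$ester_sites)
    })))
    protein_sites <- setdiff(
      .sites_for_residues(traj$topology, c(domains$n_barrel,
                                           domains$central_sheet,
                                           domains$c_barrel)),
      lipid_sites)
    if (length(protein_sites) && length(lipid_sites)) {
      cts <- contact_timeseries(traj, lipid_sites, protein_sites,
                                config$contact_cutoff)
      .write_csv_fixed(cts, emit("contacts.csv"))
      results$contacts <- cts
    }
  }
  if (!is.null(truth)) {
    .write_csv_fixed(truth, emit("ground_truth.csv"))
    results$truth <- truth
  }

  manifest <- list(
    package = "tgtunnel",
    version = as.character(utils::packageVersion("tgtunnel")),
    seed = config$seed,
    config_hash = .config_hash(config),
    files = lapply(stats::setNames(emitted, basename(emitted)), function(p) {
      list(md5 = unname(tools::md5sum(p)), bytes = file.size(p))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

.config_hash <- function(config) {
  dump <- paste(utils::capture.output(utils::str(config, digits.d = 15)),
                collapse = "\n")
  tf <- tempfile()
  writeLines(dump, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}
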