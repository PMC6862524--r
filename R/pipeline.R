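# Run orchestration: plain-text configuration, the simulate stage (generator
# + ground-truth ledger) and the analyze stage (all analysis modules, TSV
# tables plus a JSON summary). Every output table carries a header with the
# package version, a configuration hash and the seed.

.default_config <- function() {
  list(
    sequence = "IIGPVLGLVGSALGGLLKKI",
    n_chains = 27L,
    box_nm = 15,
    spacing_nm = 5,
    frame_interval_ns = 1,
    duration_ns = 100,
    noise_sigma_nm = 0.005,
    bend_angle_deg = 120,
    hinge = c(10L, 11L),
    contact_cutoff_nm = 0.5,
    cluster_cutoff_nm = 0.3,
    persistence_ns = 50,
    min_occupancy = 0.8,
    window_ns = 10,
    sasa_probe_nm = 0.14,
    sasa_n_points = 960L,
    sasa_frames = 10L,
    cluster_frames = 40L,
    merges = NULL,
    straightenings = NULL,
    seed = 1L,
    deterministic = TRUE
  )
}

#' Load a run configuration
#'
#' Reads a YAML configuration file (or takes a list of overrides) and fills
#' unset fields with package defaults, which correspond to the standard
#' 27-chain study conditions. Event tables (\code{merges},
#' \code{straightenings}) are given as lists of records with \code{time_ns}
#' and chain fields.
#'
#' @param path YAML file path, or NULL.
#' @param overrides named list applied on top of the file values.
#' @return named list of class \code{run_config}.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- .default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  bad <- c("contact_cutoff_nm", "cluster_cutoff_nm", "persistence_ns",
           "window_ns", "sasa_probe_nm")
  for (k in bad) if (cfg[[k]] <= 0) stop(k, " must be positive")
  for (k in c("merges", "straightenings")) {
    if (!is.null(cfg[[k]]) && !is.data.frame(cfg[[k]])) {
      cfg[[k]] <- do.call(rbind, lapply(cfg[[k]], as.data.frame))
    }
  }
  class(cfg) <- "run_config"
  cfg
}

# short content hash (FNV-1a over the serialised configuration)
.config_hash <- function(cfg) {
  s <- utf8ToInt(paste(utils::capture.output(utils::str(unclass(cfg))),
                       collapse = "\n"))
  h <- 2166136261
  for (b in s) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296   # exact below 2^53
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.table_header <- function(cfg) {
  c(sprintf("# aggfold %s",
            as.character(utils::packageVersion("aggfold"))),
    sprintf("# config_hash: %s", .config_hash(cfg)),
    sprintf("# seed: %d", as.integer(cfg$seed)))
}

.write_tsv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.table_header(cfg), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.scenario_from_config <- function(cfg) {
  scenario(
    seq = parse_sequence(cfg$sequence),
    n_chains = cfg$n_chains, box_nm = cfg$box_nm,
    spacing_nm = cfg$spacing_nm,
    frame_interval_ns = cfg$frame_interval_ns,
    duration_ns = cfg$duration_ns,
    merges = cfg$merges, straightenings = cfg$straightenings,
    noise_sigma_nm = cfg$noise_sigma_nm,
    bend_angle_deg = cfg$bend_angle_deg, hinge = cfg$hinge,
    seed = cfg$seed
  )
}

#' Simulate stage: generate and write a scripted trajectory
#'
#' @param cfg a \code{run_config}.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the trajectory object and the paths
#'   written (\code{trajectory.pdb}, \code{ledger.tsv}, \code{config.yaml}).
#' @export
run_simulate <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  traj <- generate_trajectory(.scenario_from_config(cfg))
  paths <- list(
    trajectory = file.path(outdir, "trajectory.pdb"),
    ledger = file.path(outdir, "ledger.tsv"),
    config = file.path(outdir, "config.yaml")
  )
  write_trajectory(traj, paths$trajectory,
                   deterministic = isTRUE(cfg$deterministic))
  write_ledger(traj, paths$ledger)
  yaml::write_yaml(unclass(cfg), paths$config)
  invisible(list(trajectory = traj, paths = paths))
}

#' Analyze stage: run all analysis modules and write the report bundle
#'
#' Emits per-chain gyration-radius and RMSF tables, class-decomposed SASA
#' with the polar/hydrophobic ratio, state strips with windowed occupancy
#' and helix masks, GROMOS clusters and Cartesian PCA of the first chain,
#' the aggregate series, per-residue intermolecular contacts by state, the
#' transition table and the sigmoid fit, plus a JSON summary.
#'
#' @param cfg a \code{run_config}.
#' @param traj a \code{trajectory} or path to a multi-model PDB file.
#' @param outdir output directory.
#' @param stages character vector of stages to run; any of
#'   \code{"geometry"}, \code{"sasa"}, \code{"states"}, \code{"ensemble"},
#'   \code{"aggregation"}, \code{"kinetics"} (default all).
#' @return invisibly, a list with the computed objects and the JSON summary.
#' @export
run_analyze <- function(cfg, traj, outdir,
                        stages = c("geometry", "sasa", "states", "ensemble",
                                   "aggregation", "kinetics")) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.character(traj)) traj <- read_trajectory(traj)
  stopifnot(inherits(traj, "trajectory"))
  if (!identical(paste(traj$sequence$residues, collapse = ""),
                 gsub("\\s", "", toupper(cfg$sequence)))) {
    stop("trajectory sequence does not match the configuration")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  chains <- trajectory_chains(traj)
  nf <- n_frames(traj)
  out <- list()
  summary <- list(n_chains = length(chains), n_frames = nf,
                  duration_ns = max(traj$times))

  if ("geometry" %in% stages) {
    rg <- do.call(rbind, lapply(chains, function(ch) {
      idx <- which(traj$atoms$chain == ch)
      data.frame(chain = ch, time_ns = traj$times,
                 rg_nm = vapply(seq_len(nf), function(f) {
                   radius_of_gyration(traj$coords[idx, , f],
                                      traj$atoms$mass[idx])
                 }, 0), stringsAsFactors = FALSE)
    }))
    .write_tsv(rg, file.path(outdir, "rg.tsv"), cfg)
    out$rg <- rg
    if (nf >= 2L) {
      rmsf <- do.call(rbind, lapply(chains, function(ch) {
        cbind(chain = ch, rmsf_per_residue(traj, ch))
      }))
      .write_tsv(rmsf, file.path(outdir, "rmsf.tsv"), cfg)
      out$rmsf <- rmsf
    }
  }

  if ("sasa" %in% stages) {
    sf <- unique(round(seq(1, nf, length.out = min(nf, cfg$sasa_frames))))
    sasa <- polar_hydrophobic_ratio(
      sasa_by_class(traj, probe_radius = cfg$sasa_probe_nm,
                    n_points = cfg$sasa_n_points, frames = sf))
    .write_tsv(sasa, file.path(outdir, "sasa.tsv"), cfg)
    out$sasa <- sasa
  }

  states <- NULL
  if (any(c("states", "aggregation", "kinetics") %in% stages)) {
    states <- state_series(traj)
    strip <- data.frame(
      chain = rep(rownames(states$labels), each = nf),
      frame = rep(seq_len(nf), length(chains)),
      time_ns = rep(states$times, length(chains)),
      state = as.vector(t(states$labels)),
      stringsAsFactors = FALSE
    )
    .write_tsv(strip, file.path(outdir, "states.tsv"), cfg)
    occ <- occupancy_windows(states, window_ns = cfg$window_ns)
    .write_tsv(occ, file.path(outdir, "occupancy.tsv"), cfg)
    mask <- do.call(rbind, lapply(chains, function(ch) {
      data.frame(chain = ch, frame = seq_len(nf), time_ns = traj$times,
                 helix_mask = vapply(seq_len(nf), function(f) {
                   hel <- assign_helix(get_conformation(traj, ch, f))
                   paste(ifelse(hel, "H", "-"), collapse = "")
                 }, ""), stringsAsFactors = FALSE)
    }))
    .write_tsv(mask, file.path(outdir, "helix_mask.tsv"), cfg)
    out$states <- states
    out$occupancy <- occ
  }

  if ("ensemble" %in% stages && nf >= 2L) {
    cf <- unique(round(seq(1, nf, length.out = min(nf, cfg$cluster_frames))))
    idx1 <- which(traj$atoms$chain == chains[1] &
                    traj$atoms$name %in% c("N", "CA", "C"))
    frames_list <- lapply(cf, function(f) traj$coords[idx1, , f])
    clus <- gromos_cluster(frames_list, cutoff_nm = cfg$cluster_cutoff_nm)
    ctab <- data.frame(
      cluster = seq_along(clus$clusters),
      size = lengths(clus$clusters),
      centroid_frame = cf[clus$centroids],
      members = vapply(clus$clusters,
                       function(m) paste(cf[m], collapse = ","), "")
    )
    .write_tsv(ctab, file.path(outdir, "clusters.tsv"), cfg)
    pca <- cartesian_pca(traj, chains[1])
    .write_tsv(data.frame(component = seq_along(pca$values),
                          eigenvalue_nm2 = pca$values),
               file.path(outdir, "pca_eigenvalues.tsv"), cfg)
    .write_tsv(data.frame(frame = seq_len(nf), time_ns = traj$times,
                          pc1_nm = pca$projections[, 1],
                          pc2_nm = pca$projections[, 2]),
               file.path(outdir, "pca_projections.tsv"), cfg)
    .write_tsv(eigen_rmsf(pca, 1), file.path(outdir, "pca_rmsf_pc1.tsv"), cfg)
    out$clusters <- clus
    out$pca <- pca
    summary$top_cluster_sizes <- utils::head(lengths(clus$clusters), 5)
    summary$pc1_variance_share <-
      if (sum(pca$values) > 0) pca$values[1] / sum(pca$values) else NA
  }

  if ("aggregation" %in% stages) {
    agg <- aggregate_series(traj, cutoff_nm = cfg$contact_cutoff_nm)
    .write_tsv(agg$summary, file.path(outdir, "aggregates.tsv"), cfg)
    out$aggregates <- agg
    summary$n_aggregates_first <- agg$summary$n_aggregates[1]
    summary$n_aggregates_last <- agg$summary$n_aggregates[nf]
    summary$max_size_last <- agg$summary$max_size[nf]
    if (!is.null(states)) {
      contacts <- intermolecular_contacts(traj, states,
                                          cutoff_nm = cfg$contact_cutoff_nm)
      .write_tsv(contacts, file.path(outdir, "contacts.tsv"), cfg)
      out$contacts <- contacts
    }
  }

  if ("kinetics" %in% stages && !is.null(states)) {
    trans <- detect_transitions(states, persistence_ns = cfg$persistence_ns,
                                min_occupancy = cfg$min_occupancy,
                                traj = traj, cutoff_nm = cfg$contact_cutoff_nm)
    .write_tsv(trans, file.path(outdir, "transitions.tsv"), cfg)
    nh <- folded_count(trans, traj$times)
    .write_tsv(data.frame(time_ns = traj$times, n_h = nh),
               file.path(outdir, "folded_count.tsv"), cfg)
    out$transitions <- trans
    summary$n_h_terminal <- nh[nf]
    fit <- tryCatch(fit_sigmoid(traj$times, nh), error = function(e) NULL)
    if (!is.null(fit)) {
      summary$sigmoid <- list(h_max = fit$h_max, t_half_ns = fit$t_half,
                              k_per_ns = fit$k, lambda_per_ns = fit$lambda,
                              rss = fit$rss)
      out$sigmoid <- fit
    }
  }

  summary_path <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  out$summary <- summary
  invisible(out)
}
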