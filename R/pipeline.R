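#' Run the full analysis pipeline from a config
#'
#' Orchestrates the analysis stages end to end from a single YAML config
#' (or an equivalent named list), writing one JSON summary plus per-stage
#' CSV files into the output directory. Stages run in dependency order:
#' `gen` (synthetic input), `diffusion`, `rdf`, `angles`, `zprofile`,
#' `clusters`; when the cluster cutoff is `"auto"` the COR-COR RDF stage
#' must run first, and its first minimum supplies the cutoff.
#'
#' Config keys: `trajectory`, `group_file` (or stage `gen` with a
#' `generator` name and its parameters), `stages` (character vector),
#' `outdir`, `seed`, `skip_time` (ns of initial equilibration dropped
#' before every analysis, default 0), and one optional block per stage
#' with its parameters (`diffusion`, `rdf`, `angles`, `zprofile`,
#' `clusters`). The resolved config — defaults included — is embedded in
#' the summary for provenance.
#'
#' @param config path to a YAML config file, or a named list.
#' @return invisibly, the summary list (also written to
#'   `<outdir>/summary.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% stop("config needs a 'stages' field")
  known <- c("gen", "diffusion", "rdf", "angles", "zprofile", "clusters")
  bad <- setdiff(stages, known)
  if (length(bad))
    abort_validation("unknown stage(s): %s", paste(bad, collapse = ", "))
  outdir <- config$outdir %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  summary <- list(config = config, decisions = list(), results = list())

  traj <- NULL; groups <- NULL
  if ("gen" %in% stages) {
    gen <- config$gen %||% list()
    gen_fun <- switch(gen$generator %||% "brownian2d",
                      brownian2d = gen_brownian2d,
                      cluster = gen_cluster_frames,
                      rod = gen_rod_frames,
                      slab = gen_bilayer_slab,
                      abort_validation("unknown generator '%s'", gen$generator))
    args <- gen[setdiff(names(gen), "generator")]
    args$seed <- args$seed %||% seed
    out <- do.call(gen_fun, args)
    traj <- out$trajectory; groups <- out$groups
    xyz_path <- file.path(outdir, "generated.xyz")
    write_xyz(traj, xyz_path)
    write_group_file(groups, file.path(outdir, "generated.groups.yaml"))
    summary$results$gen <- list(file = xyz_path, seed = args$seed,
                                n_frames = traj$n_frames,
                                n_particles = traj$n_particles)
  } else {
    if (is.null(config$trajectory))
      abort_validation("config needs 'trajectory' (or a 'gen' stage)")
    loaded <- load_trajectory(config$trajectory,
                              topology = config$topology,
                              group_file = config$group_file)
    traj <- loaded$trajectory; groups <- loaded$groups
  }

  skip_time <- config$skip_time %||% 0
  if (skip_time > 0) {
    skip_frames <- floor(skip_time / traj$dt)
    if (skip_frames >= traj$n_frames)
      abort_validation("skip_time discards the whole trajectory")
    keep <- (skip_frames + 1L):traj$n_frames
    traj <- trajectory(traj$coords[keep, , , drop = FALSE],
                       box = traj$box[keep, , drop = FALSE], dt = traj$dt,
                       wrapped = traj$wrapped, masses = traj$masses)
    summary$decisions$skip_time <- skip_time
  }

  utraj <- if (traj$wrapped) unwrap(traj) else traj
  all_idx <- seq_len(traj$n_particles)
  rdf_cache <- NULL

  for (stage in setdiff(stages, "gen")) {
    pars <- config[[stage]] %||% list()
    if (stage == "diffusion") {
      grp <- resolve_group(pars$group %||% "lipids", groups, all_idx)
      ref <- resolve_group(pars$reference %||% "lipids", groups, all_idx)
      est <- block_diffusion(utraj, grp, ref,
                             n_blocks = pars$blocks %||% 5L,
                             max_lag = pars$max_lag,
                             fit_window = pars$fit_window,
                             lateral = pars$lateral %||% TRUE)
      curve <- compute_msd(utraj, grp, ref, max_lag = pars$max_lag)
      utils::write.csv(data.frame(lag_ns = curve$lags, msd_A2 = curve$msd),
                       file.path(outdir, "msd.csv"), row.names = FALSE)
      summary$results$diffusion <- list(
        d_value = est$d_value, d_uncertainty = est$d_uncertainty,
        n_blocks = est$n_blocks, fit_window = est$fit_window)
      summary$decisions$diffusion_fit_window <- est$fit_window
    } else if (stage == "rdf") {
      cor <- cor_positions(utraj, groups)
      mode <- pars$mode %||% "lateral"
      rdf <- compute_rdf(cor, box = traj$box[1, ],
                         r_max = pars$r_max %||% 30,
                         dr = pars$dr %||% 0.2, mode = mode)
      rdf_cache <- rdf
      peaks <- find_peaks(rdf)
      utils::write.csv(data.frame(r_A = rdf$bin_centers, g = rdf$g),
                       file.path(outdir, "rdf_cor.csv"), row.names = FALSE)
      summary$results$rdf <- list(mode = mode, peaks = peaks$positions,
                                  heights = peaks$heights)
      summary$decisions$rdf_mode <- mode
    } else if (stage == "angles") {
      ang <- backbone_angles(utraj, groups)
      utils::write.csv(ang, file.path(outdir, "backbone_angles.csv"),
                       row.names = FALSE)
      summary$results$angles <- list(
        alpha1_mean = mean(ang$alpha1), alpha2_mean = mean(ang$alpha2),
        beta_mean = mean(ang$beta))
    } else if (stage == "zprofile") {
      grp <- resolve_group(pars$group %||% "headgroup_atoms", groups, all_idx)
      ref <- resolve_group(pars$reference %||% "all", groups, all_idx)
      prof <- z_profile(utraj, grp, ref,
                        bin_width = pars$bin_width %||% 1,
                        z_range = pars$z_range %||% 34)
      utils::write.csv(data.frame(z_A = prof$z_bin_centers,
                                  density = prof$density),
                       file.path(outdir, "zprofile.csv"), row.names = FALSE)
      thick <- tryCatch(bilayer_thickness(prof), error = function(e) NA_real_)
      summary$results$zprofile <- list(
        thickness = thick, midplane_ratio = midplane_ratio(prof))
    } else if (stage == "clusters") {
      cutoff <- pars$cutoff %||% "auto"
      if (identical(cutoff, "auto")) {
        if (is.null(rdf_cache))
          abort_validation(
            "clusters with cutoff = 'auto' needs the rdf stage to run first")
        cutoff <- tryCatch(first_minimum(rdf_cache),
                           error = function(e) 9.5)
      }
      cts <- cluster_timeseries(utraj, groups, cutoff = cutoff,
                                mode = pars$mode %||% "lateral")
      utils::write.csv(
        data.frame(frame = seq_len(nrow(cts$labels)),
                   largest = vapply(cts$sizes, max, integer(1)),
                   trimer = cts$trimer_indicator),
        file.path(outdir, "clusters.csv"), row.names = FALSE)
      res <- list(cutoff_used = cutoff,
                  trimer_fraction = mean(cts$trimer_indicator),
                  n_exchanges = exchange_events(cts)$n_exchanges)
      if (stats::var(cts$trimer_indicator) > 0) {
        ts <- characteristic_timescale(cts$trimer_indicator, traj$dt,
                                       max_lag = pars$max_lag)
        res$tau <- ts$tau
      }
      summary$results$clusters <- res
      summary$decisions$cluster_cutoff <- cutoff
    }
  }
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(summary)
}

resolve_group <- function(name, groups, all_idx) {
  if (is.numeric(name)) return(as.integer(name))
  if (identical(name, "all")) return(all_idx)
  if (identical(name, "additives") && !is.null(groups) &&
      length(groups$additives) == 0L && length(groups$molecules) > 0L) {
    return(unique(unlist(lapply(groups$molecules, unlist))))
  }
  idx <- groups[[name]]
  if (is.null(idx) || length(idx) == 0L)
    abort_validation("group '%s' is empty or undefined", name)
  as.integer(idx)
}
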