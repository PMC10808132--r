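# Pipeline front end: a single hierarchical YAML config drives every
# analysis step; each run echoes the resolved config, the seed and the
# package version to a log file. A thin Rscript wrapper around
# run_pipeline() lives in inst/scripts/dmcpull-cli.R.

.cfg_error <- function(msg) stop(errorCondition(msg, class = c("dmc_config_error", "error")))
.io_error <- function(msg) stop(errorCondition(msg, class = c("dmc_io_error", "error")))

.load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) .io_error(paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .cfg_error("config must be a YAML file path or a list")
  config
}

.cfg_get <- function(config, key, default = NULL, required = FALSE) {
  val <- config[[key]]
  if (is.null(val)) {
    if (required) .cfg_error(paste("missing config key:", key))
    return(default)
  }
  val
}

.open_log <- function(out_dir, subcommand, config) {
  log_path <- file.path(out_dir, paste0(subcommand, ".log"))
  ver <- tryCatch(as.character(utils::packageVersion("dmcpull")), error = function(e) "dev")
  writeLines(c(sprintf("dmcpull %s | subcommand: %s | %s", ver, subcommand,
                       format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               "resolved config:",
               strsplit(yaml::as.yaml(config), "\n")[[1]]), log_path)
  log_path
}

.model_from_config <- function(config) {
  d <- .cfg_get(config, "design", list())
  build_tetrahedron(tetra_design(
    edge_bp = .cfg_get(d, "edge_bp", 20L),
    rise = .cfg_get(d, "rise", 0.34),
    fb_bp = .cfg_get(d, "fb_bp", 12L)))
}

.params_from_config <- function(config) {
  s <- .cfg_get(config, "sim", list())
  seed <- .cfg_get(config, "seed", required = TRUE)
  defaults <- formals(sim_params)
  args <- list(seed = seed)
  for (key in setdiff(names(defaults), "seed"))
    if (!is.null(s[[key]])) args[[key]] <- s[[key]]
  do.call(sim_params, args)
}

.read_inputs <- function(config) {
  top_path <- .cfg_get(config, "topology", required = TRUE)
  traj_path <- .cfg_get(config, "trajectory", required = TRUE)
  if (!file.exists(top_path)) .io_error(paste("topology file not found:", top_path))
  if (!file.exists(traj_path)) .io_error(paste("trajectory file not found:", traj_path))
  topo <- read_topology(top_path)
  list(topology = topo, trajectory = read_trajectory(traj_path, topo))
}

.protocol_from_config <- function(config, n_nt) {
  p <- .cfg_get(config, "protocol", required = TRUE)
  trap_protocol(.cfg_get(p, "index_a", required = TRUE),
                .cfg_get(p, "index_b", required = TRUE),
                k_a = .cfg_get(p, "k_a", 11.42), k_b = .cfg_get(p, "k_b", 11.42),
                anchor_a = unlist(.cfg_get(p, "anchor_a", required = TRUE)),
                start_b = unlist(.cfg_get(p, "start_b", required = TRUE)),
                rate = .cfg_get(p, "rate", 1.4e4),
                axis = unlist(.cfg_get(p, "axis", required = TRUE)))
}

#' Run a pipeline subcommand
#'
#' Subcommands: `simulate` (build the tetrahedron analog, run the pulling
#' simulation, write `.top`/`.dat` plus the bond-event CSV and a protocol
#' block usable by the analysis subcommands), `force-curve`, `rupture`,
#' `pores`, `denaturation`, `distances`, `assay-qe`, `assay-density`,
#' `assay-spacing`, `assay-halflife`, and `fixtures` (write the small
#' hand-written demonstration fixtures). Every run writes
#' `<subcommand>.log` with the resolved config and package version.
#'
#' @param subcommand one of the names above.
#' @param config YAML file path or an equivalent nested list.
#' @return Invisibly, a named list of output file paths (and key results).
#' @export
run_pipeline <- function(subcommand, config) {
  config <- .load_config(config)
  out_dir <- .cfg_get(config, "output_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- .open_log(out_dir, subcommand, config)
  out <- switch(subcommand,
    "simulate" = {
      model <- .model_from_config(config)
      params <- .params_from_config(config)
      pcfg <- .cfg_get(config, "protocol", list())
      protocol <- default_protocol(model,
                                   k = .cfg_get(pcfg, "k", 11.42),
                                   rate = .cfg_get(pcfg, "rate", 1.4e4))
      run <- run_pulling(model, params, protocol)
      top <- file.path(out_dir, "model.top")
      dat <- file.path(out_dir, "trajectory.dat")
      ev <- file.path(out_dir, "bond_events.csv")
      write_topology(model$topology, top)
      write_trajectory(run$trajectory, dat)
      write_bond_events_csv(run, ev)
      meta <- file.path(out_dir, "run.yaml")
      yaml::write_yaml(list(
        topology = top, trajectory = dat,
        protocol = list(index_a = protocol$index_a, index_b = protocol$index_b,
                        k_a = protocol$k_a, k_b = protocol$k_b,
                        anchor_a = protocol$anchor_a, start_b = protocol$start_b,
                        rate = protocol$rate, axis = protocol$axis),
        pore_faces = apply(model$pore$faces, 1, as.list),
        pairs = apply(model$pairs, 1, as.list),
        fb_pairs = model$fb_pairs,
        sites = run$model$sites, seed = params$seed), meta)
      list(topology = top, trajectory = dat, events = ev, meta = meta)
    },
    "force-curve" = ,
    "rupture" = {
      inp <- .read_inputs(config)
      protocol <- .protocol_from_config(config, inp$topology$n_nucleotides)
      curve <- force_extension_curve(inp$trajectory, protocol,
                                     convention = .cfg_get(config, "extension_convention",
                                                           "nucleotide"))
      csv <- file.path(out_dir, "force_curve.csv")
      write_force_curve_csv(curve, csv)
      res <- list(curve = csv)
      if (subcommand == "rupture") {
        rup <- detect_rupture(curve,
                              drop_fraction = .cfg_get(config, "drop_fraction", 0.5),
                              window_fraction = .cfg_get(config, "window_fraction", 0.1))
        rcsv <- file.path(out_dir, "rupture.csv")
        utils::write.csv(data.frame(rupture_force = rup$rupture_force,
                                    rupture_frame = rup$rupture_frame,
                                    valid = rup$valid,
                                    drop_observed = rup$drop_observed),
                         rcsv, row.names = FALSE)
        res$rupture <- rcsv
        res$result <- rup
      }
      res
    },
    "pores" = {
      inp <- .read_inputs(config)
      faces <- do.call(rbind, lapply(.cfg_get(config, "pore_faces", required = TRUE), unlist))
      series <- pore_series(inp$trajectory, pore_spec(faces, inp$topology$n_nucleotides))
      csv <- file.path(out_dir, "pores.csv")
      utils::write.csv(as.data.frame(series), csv, row.names = FALSE)
      res <- list(pores = csv)
      cargo <- .cfg_get(config, "cargo_radius")
      if (!is.null(cargo)) {
        leaky <- leakage_frames(series, cargo)
        lcsv <- file.path(out_dir, "leaky_frames.csv")
        utils::write.csv(data.frame(frame = leaky), lcsv, row.names = FALSE)
        res$leaky <- lcsv
      }
      res
    },
    "denaturation" = {
      inp <- .read_inputs(config)
      pairs <- do.call(rbind, lapply(.cfg_get(config, "pairs", required = TRUE), unlist))
      frac <- denatured_fraction(inp$trajectory, pairs, inp$topology,
                                 distance_cutoff = .cfg_get(config, "distance_cutoff", 0.4))
      csv <- file.path(out_dir, "denaturation.csv")
      utils::write.csv(frac, csv, row.names = FALSE)
      list(denaturation = csv, end_fraction = attr(frac, "end_fraction"))
    },
    "distances" = {
      inp <- .read_inputs(config)
      i <- .cfg_get(config, "site_i", required = TRUE)
      j <- .cfg_get(config, "site_j", required = TRUE)
      d <- site_distance_series(inp$trajectory, i, j)
      csv <- file.path(out_dir, "distances.csv")
      utils::write.csv(data.frame(frame = seq_along(d), distance_nm = d),
                       csv, row.names = FALSE)
      list(distances = csv)
    },
    "assay-qe" = {
      a <- .cfg_get(config, "assay", required = TRUE)
      qe <- quenching_efficiency(.cfg_get(a, "i_quenched", required = TRUE),
                                 .cfg_get(a, "i_unquenched", required = TRUE))
      csv <- file.path(out_dir, "quenching.csv")
      utils::write.csv(data.frame(quenching_efficiency = qe,
                                  fold_enhancement = fold_enhancement(qe)),
                       csv, row.names = FALSE)
      list(quenching = csv, qe = qe)
    },
    "assay-density" = {
      a <- .cfg_get(config, "assay", required = TRUE)
      pts_path <- .cfg_get(a, "calibration_csv", required = TRUE)
      if (!file.exists(pts_path)) .io_error(paste("calibration file not found:", pts_path))
      curve <- fit_density_calibration(utils::read.csv(pts_path),
                                       footprint = .cfg_get(a, "footprint", 0.72),
                                       leaflet_factor = .cfg_get(a, "leaflet_factor", 2))
      dens <- intensity_to_density(.cfg_get(a, "i_probe", required = TRUE), curve,
                                   .cfg_get(a, "f_factor", 1))
      csv <- file.path(out_dir, "density.csv")
      utils::write.csv(data.frame(slope = curve$slope, intercept = curve$intercept,
                                  r_squared = curve$r_squared,
                                  density_per_um2 = dens,
                                  spacing_nm = mean_spacing(dens)),
                       csv, row.names = FALSE)
      list(density = csv, density_per_um2 = dens)
    },
    "assay-spacing" = {
      a <- .cfg_get(config, "assay", required = TRUE)
      sp <- mean_spacing(.cfg_get(a, "density", required = TRUE))
      csv <- file.path(out_dir, "spacing.csv")
      utils::write.csv(data.frame(spacing_nm = sp), csv, row.names = FALSE)
      list(spacing = csv, spacing_nm = sp)
    },
    "assay-halflife" = {
      a <- .cfg_get(config, "assay", required = TRUE)
      decay_path <- .cfg_get(a, "decay_csv", required = TRUE)
      if (!file.exists(decay_path)) .io_error(paste("decay file not found:", decay_path))
      tab <- utils::read.csv(decay_path)
      fit <- decay_halflife(tab[[1]], tab[[2]],
                            fit_offset = isTRUE(.cfg_get(a, "fit_offset", FALSE)))
      csv <- file.path(out_dir, "halflife.csv")
      utils::write.csv(data.frame(amplitude = fit$amplitude, rate = fit$rate,
                                  offset = fit$offset, half_life = fit$half_life,
                                  valid = fit$valid), csv, row.names = FALSE)
      list(halflife = csv, fit = fit)
    },
    "fixtures" = {
      list(dir = write_demo_fixtures(out_dir))
    },
    .cfg_error(paste("unknown subcommand:", subcommand))
  )
  out$log <- log_path
  invisible(out)
}

#' Write the small hand-written demonstration fixtures
#'
#' An 8-nucleotide two-strand duplex topology and matching one-frame
#' configurations in the 15-column (with velocities) and 9-column dialects.
#'
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_demo_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("8 2",
               "1 A -1 1", "1 C 0 2", "1 G 1 3", "1 T 2 -1",
               "2 A -1 5", "2 C 4 6", "2 G 5 7", "2 T 6 -1"),
             file.path(dir, "duplex.top"))
  rows <- character(8)
  for (i in 1:8) {
    side <- if (i <= 4) 1 else 2
    k <- if (i <= 4) i else 9 - i
    y <- if (side == 1) 0.3 else -0.3
    by <- if (side == 1) -1 else 1
    rows[i] <- sprintf("%.4f %.4f %.4f %.4f %.4f %.4f %.4f %.4f %.4f 0.0100 0.0200 0.0300 0.0000 0.0000 0.0000",
                       k * 0.4, y, 0, 0, by, 0, 1, 0, 0)
  }
  hdr <- c("t = 0", "b = 20 20 20", "E = 0 0 0")
  writeLines(c(hdr, rows), file.path(dir, "duplex15.dat"))
  rows9 <- vapply(strsplit(rows, " "), function(f) paste(f[1:9], collapse = " "), "")
  writeLines(c(hdr, rows9), file.path(dir, "duplex9.dat"))
  invisible(dir)
}
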