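#!/usr/bin/env Rscript

# Thin command-line interface over the vtloc package.
#
# Usage:
#   Rscript scripts/vtloc.R <subcommand> [--config <file>] [--seed <int>]
#                           [--out-dir <dir>] [--snr-list "5,10,15,20,30"]
#
# Subcommands:
#   simulate         build geometry and simulate the paced-beat signals
#   build-dataset    split + augment the simulated beats
#   train            train the networks of the configured schemes
#   localize         localize the held-out beats with the trained models
#   evaluate         print the reference report of a finished run
#   sweep-noise      noise sensitivity sweep on a finished run
#   sweep-electrodes electrode-placement sweep on a finished run
#
# `simulate`, `build-dataset`, `train` and `localize` are stages of
# run_pipeline(); each stage loads the previous stage's artifact from
# --out-dir and saves its own, so they can be run separately or in one go.

suppressMessages({
  library(optparse)
  library(vtloc)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) stop("missing subcommand; see header of scripts/vtloc.R")
cmd <- args[[1L]]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out-dir", dest = "out_dir", type = "character", default = "vtloc_out"),
  make_option("--snr-list", dest = "snr_list", type = "character",
              default = "5,10,15,20,30")
)), args = args[-1L])

dir.create(opts$out_dir, recursive = TRUE, showWarnings = FALSE)
cfg <- if (is.null(opts$config)) default_config() else read_config(opts$config)
art <- function(name) file.path(opts$out_dir, paste0(name, ".rds"))

log_msg <- function(...) message(sprintf(...))

run_stage_pipeline <- function() {
  # stages share run_pipeline for exact provenance; a finished pipeline
  # artifact contains everything downstream stages need
  if (file.exists(art("pipeline"))) return(readRDS(art("pipeline")))
  pl <- run_pipeline(cfg, seed = opts$seed, progress = TRUE)
  saveRDS(pl, art("pipeline"))
  write_report_csv(pl$report, file.path(opts$out_dir, "report_reference.csv"))
  pl
}

if (cmd %in% c("simulate", "build-dataset", "train", "localize", "evaluate")) {
  pl <- run_stage_pipeline()
  if (cmd == "simulate") {
    write_mesh_vtk(pl$mesh, file.path(opts$out_dir, "lv_mesh.vtk"),
                   uvc = pl$uvc, segmodel = pl$seg17)
    write_electrodes_csv(pl$electrodes, file.path(opts$out_dir, "electrodes.csv"))
    log_msg("wrote mesh + electrodes under %s", opts$out_dir)
  } else if (cmd == "build-dataset") {
    write_dataset(pl$dataset, file.path(opts$out_dir, "dataset"))
    log_msg("wrote dataset under %s", opts$out_dir)
  } else if (cmd == "train") {
    for (nm in names(pl$models)) save_model(pl$models[[nm]], art(paste0("model_", nm)))
    log_msg("saved %d model checkpoints", length(pl$models))
  } else {
    print(as.data.frame(pl$report))
  }
} else if (cmd == "sweep-noise") {
  pl <- run_stage_pipeline()
  snrs <- as.numeric(strsplit(opts$snr_list, ",")[[1L]])
  sw <- noise_sweep(pl, snr_list = snrs, seed = opts$seed)
  write_report_csv(sw, file.path(opts$out_dir, "report_noise_sweep.csv"))
  print(as.data.frame(sw))
} else if (cmd == "sweep-electrodes") {
  pl <- run_stage_pipeline()
  scenarios <- list(
    scenario_identity(),
    scenario_ecg_shift(c(0, 0, 50)), scenario_ecg_shift(c(0, 0, -50)),
    scenario_ecg_shift(c(50, 0, 0)), scenario_ecg_shift(c(-50, 0, 0)),
    scenario_lv_spacing(10), scenario_lv_spacing(20),
    scenario_tip_cloud(2), scenario_septal_coil()
  )
  sw <- electrode_sweep(pl, scenarios, seed = opts$seed)
  write_report_csv(sw, file.path(opts$out_dir, "report_electrode_sweep.csv"))
  print(as.data.frame(sw))
} else {
  stop(sprintf("unknown subcommand `%s`", cmd))
}
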