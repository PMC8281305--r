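#' Default experiment configuration
#'
#' A nested list driving the full pipeline: geometry, electrophysiology,
#' electrodes, signal encoding, dataset sizes, network settings, and the
#' schemes/modalities to evaluate. All values can be overridden via
#' [read_config()] or by editing the returned list.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    geometry = list(epi_long = 90, epi_short = 35, wall = 10, edge = 2.5,
                    fiber_endo = 60, fiber_epi = -60, z_cap = 0.1),
    ep = list(cv_long = 0.5455, cv_trans = 0.1802, bcl = 400,
              sigma_bath = 0.2, sigma_intra = 0.1845),
    electrodes = list(lv_tip_spacing = 7.5),
    signal = list(dt = 0.5, upstroke = 1, apd = 300, margin = 2),
    dataset = list(n_train = 2767, n_test = 1000,
                   proportions = c(endo = 0.32, mid = 0.36, epi = 0.32),
                   augmentation = 10, snr_db = 25, test_snr_db = 25),
    network = list(conv1 = 16, conv2 = 32, fc = 128, lr = 0.001, batch = 23,
                   epochs_classification = 10, epochs_regression = 15),
    experiment = list(schemes = c("cartesian17", "uvc"),
                      modalities = c("ecg", "egm"))
  )
}

#' Read a YAML configuration file, merged over the defaults
#' @param path YAML file with any subset of the [default_config()] entries.
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_cfg(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  merge_cfg(default_config(), user)
}

config_hash <- function(config) rlang::hash(config)

net_spec_from_config <- function(task, cfg) {
  nw <- cfg$network
  epochs <- if (task == "uvc_regression") nw$epochs_regression else nw$epochs_classification
  build_network(task, conv1 = nw$conv1, conv2 = nw$conv2, fc = nw$fc,
                lr = nw$lr, batch = nw$batch, epochs = epochs)
}

#' Run the full localization pipeline
#'
#' Geometry -> pacing sites -> eikonal beats -> lead-field signals ->
#' dataset (split + augmentation) -> network training -> localization ->
#' report. Every stage is deterministic given `(config, seed)`.
#'
#' @param config Configuration list (see [default_config()]).
#' @param seed Integer master seed.
#' @param progress Emit stage messages.
#' @return A `vt_pipeline` object holding all artifacts, with `$report`
#'   (a `vt_sweep` tibble: one row per scheme x modality) and `$results`
#'   (per-beat `vt_results`).
#' @export
run_pipeline <- function(config = default_config(), seed = 1L, progress = FALSE) {
  say <- function(...) if (progress) inform(sprintf(...))
  ch <- config_hash(config)
  g <- config$geometry

  say("stage geometry: building mesh")
  mesh <- build_lv_mesh(geometry_params(g$epi_long, g$epi_short, g$wall, g$edge))
  mesh <- assign_fibers(mesh, g$fiber_endo, g$fiber_epi)
  uvc <- compute_uvc(mesh)
  seg17 <- build_segment_model(mesh, uvc, 17, z_cap = g$z_cap)
  seg68 <- build_segment_model(mesh, uvc, 68, z_cap = g$z_cap)
  electrodes <- place_electrodes(mesh, config$electrodes$lv_tip_spacing)

  ep <- ep_params(config$ep$cv_long, config$ep$cv_trans, config$ep$bcl,
                  config$ep$sigma_bath, config$ep$sigma_intra)
  cond <- prepare_conduction(mesh, ep)
  lf <- compute_lead_field(mesh, electrodes, ep$sigma_bath)
  template <- ap_template(upstroke = config$signal$upstroke,
                          apd = config$signal$apd, dt = config$signal$dt)

  say("stage simulate: %d beats", config$dataset$n_train + config$dataset$n_test)
  n_beats <- config$dataset$n_train + config$dataset$n_test
  sites <- sample_pacing_sites(mesh, uvc, n_beats, config$dataset$proportions,
                               seed = seed)
  beats <- simulate_beats(sites, cond, lf, seg17, template,
                          margin = config$signal$margin, progress = progress)

  say("stage dataset: split %d/%d, augment x%d at %g dB",
      config$dataset$n_train, config$dataset$n_test,
      config$dataset$augmentation, config$dataset$snr_db)
  ds <- build_dataset(beats, config$dataset$n_train, config$dataset$n_test,
                      seed = seed + 1L)
  ds_aug <- augment(ds, k = config$dataset$augmentation,
                    snr_db = config$dataset$snr_db, seed = seed + 2L)

  schemes <- config$experiment$schemes
  modalities <- config$experiment$modalities
  models <- list()
  results <- list()
  test_snr <- config$dataset$test_snr_db %||% Inf
  for (mod in modalities) {
    say("stage train: modality %s", mod)
    if (any(c("cartesian17", "cartesian68") %in% schemes)) {
      ee_spec <- net_spec_from_config("epiendo", config)
      models[[paste0("epiendo_", mod)]] <-
        train_network(ee_spec, epiendo_training_view(ds_aug), mod, seed = seed + 3L)
    }
    if ("cartesian17" %in% schemes) {
      sp <- net_spec_from_config("segment17", config)
      m <- train_network(sp, ds_aug, mod, seed = seed + 4L)
      models[[paste0("segment17_", mod)]] <- m
      results[[paste0("cartesian17_", mod)]] <-
        localize_cartesian(m, models[[paste0("epiendo_", mod)]], seg17, ds_aug,
                           snr_db = test_snr, seed = seed + 5L)
    }
    if ("cartesian68" %in% schemes) {
      sp <- net_spec_from_config("segment68", config)
      m <- train_network(sp, ds_aug, mod, seed = seed + 6L)
      models[[paste0("segment68_", mod)]] <- m
      results[[paste0("cartesian68_", mod)]] <-
        localize_cartesian(m, models[[paste0("epiendo_", mod)]], seg68, ds_aug,
                           snr_db = test_snr, seed = seed + 5L)
    }
    if ("uvc" %in% schemes) {
      reg <- train_network(net_spec_from_config("uvc_regression", config),
                           ds_aug, mod, seed = seed + 7L)
      cls <- train_network(net_spec_from_config("phi_classification", config),
                           ds_aug, mod, seed = seed + 8L)
      models[[paste0("uvc_reg_", mod)]] <- reg
      models[[paste0("uvc_cls_", mod)]] <- cls
      results[[paste0("uvc_", mod)]] <-
        localize_uvc(reg, cls, mesh, uvc, ds_aug, snr_db = test_snr, seed = seed + 5L)
    }
  }

  report <- sweep_report(results, condition = "reference", ch, seed)
  structure(list(config = config, seed = seed, config_hash = ch,
                 mesh = mesh, uvc = uvc, seg17 = seg17, seg68 = seg68,
                 electrodes = electrodes, ep = ep, cond = cond, lf = lf,
                 template = template, dataset = ds_aug, models = models,
                 results = results, report = report),
            class = "vt_pipeline")
}

sweep_report <- function(results, condition, config_hash, seed) {
  rows <- lapply(results, function(r) {
    gl <- glance(r)
    acc <- if ("pred_class" %in% names(r)) {
      mean(r$pred_class == r$truth_class) * 100
    } else NA_real_
    tibble(condition = condition, scheme = gl$scheme, modality = gl$modality,
           n = gl$n, mean_error_mm = gl$mean_error_mm, sd_error_mm = gl$sd_error_mm,
           accuracy_pct = acc, config_hash = config_hash, seed = seed)
  })
  structure(dplyr::bind_rows(rows), class = c("vt_sweep", class(tibble())))
}

#' @export
print.vt_pipeline <- function(x, ...) {
  cat(sprintf("<vt_pipeline> seed %d, config %s\n", x$seed, x$config_hash))
  print(x$report)
  invisible(x)
}

#' Noise sensitivity sweep on frozen models
#'
#' Test matrices are re-noised from the clean traces at each SNR; the
#' trained models are reused unchanged (frozen-model protocol).
#'
#' @param pipeline A `vt_pipeline`.
#' @param snr_list SNR levels in dB (default 5, 10, 15, 20, 30).
#' @param seed Seed for the evaluation noise.
#' @return A `vt_sweep` tibble, one row per SNR x scheme x modality.
#' @export
noise_sweep <- function(pipeline, snr_list = c(5, 10, 15, 20, 30), seed = 1L) {
  stopifnot(inherits(pipeline, "vt_pipeline"))
  if (length(pipeline$models) == 0L) abort("missing trained models")
  out <- list()
  for (snr in snr_list) {
    res <- evaluate_frozen(pipeline, pipeline$dataset, snr_db = snr, seed = seed)
    out[[as.character(snr)]] <-
      sweep_report(res, condition = sprintf("snr_%g_dB", snr),
                   pipeline$config_hash, seed)
  }
  structure(dplyr::bind_rows(out), class = c("vt_sweep", class(tibble())))
}

# Evaluate all trained scheme x modality combinations on a dataset whose
# test split may have been re-rendered; models stay frozen.
evaluate_frozen <- function(pipeline, dataset, snr_db, seed,
                            mesh = pipeline$mesh, uvc = pipeline$uvc) {
  res <- list()
  for (mod in pipeline$config$experiment$modalities) {
    m17 <- pipeline$models[[paste0("segment17_", mod)]]
    ee <- pipeline$models[[paste0("epiendo_", mod)]]
    if (!is.null(m17) && !is.null(ee)) {
      res[[paste0("cartesian17_", mod)]] <-
        localize_cartesian(m17, ee, pipeline$seg17, dataset, snr_db = snr_db, seed = seed)
    }
    m68 <- pipeline$models[[paste0("segment68_", mod)]]
    if (!is.null(m68) && !is.null(ee)) {
      res[[paste0("cartesian68_", mod)]] <-
        localize_cartesian(m68, ee, pipeline$seg68, dataset, snr_db = snr_db, seed = seed)
    }
    reg <- pipeline$models[[paste0("uvc_reg_", mod)]]
    cls <- pipeline$models[[paste0("uvc_cls_", mod)]]
    if (!is.null(reg) && !is.null(cls)) {
      res[[paste0("uvc_", mod)]] <-
        localize_uvc(reg, cls, mesh, uvc, dataset, snr_db = snr_db, seed = seed)
    }
  }
  res
}

#' Electrode-placement scenarios
#'
#' Helpers building scenario descriptors for [electrode_sweep()]:
#' identity, rigid ECG displacement (mm), LV-lead inter-tip spacing, finite
#' 2-mm sensing tips (cloud averaging), and a septal RV coil reposition.
#'
#' @param name Scenario label.
#' @return A scenario list.
#' @export
scenario_identity <- function(name = "identity") list(name = name, type = "identity")

#' @rdname scenario_identity
#' @param shift Length-3 translation in mm applied to all ECG electrodes.
#' @export
scenario_ecg_shift <- function(shift, name = NULL) {
  list(name = name %||% sprintf("ecg_shift_%+g_%+g_%+g", shift[1], shift[2], shift[3]),
       type = "ecg_shift", shift = shift)
}

#' @rdname scenario_identity
#' @param spacing LV tip spacing in mm.
#' @export
scenario_lv_spacing <- function(spacing, name = NULL) {
  list(name = name %||% sprintf("lv_spacing_%g_mm", spacing),
       type = "lv_spacing", spacing = spacing)
}

#' @rdname scenario_identity
#' @param radius Cloud radius in mm.
#' @export
scenario_tip_cloud <- function(radius = 2, name = NULL) {
  list(name = name %||% sprintf("tip_cloud_%g_mm", radius),
       type = "tip_cloud", radius = radius)
}

#' @rdname scenario_identity
#' @export
scenario_septal_coil <- function(name = "septal_rv_coil") {
  list(name = name, type = "septal_coil")
}

#' Electrode-placement sensitivity sweep on frozen models
#'
#' For each scenario the lead field is recomputed, the test beats'
#' signals re-rendered (activation maps are unchanged: they do not depend
#' on the electrodes), and the frozen models re-evaluated. Training data
#' and models are never touched.
#'
#' @param pipeline A `vt_pipeline`.
#' @param scenarios List of scenario descriptors (see
#'   [scenario_identity()]).
#' @param seed Seed for the evaluation noise.
#' @return A `vt_sweep` tibble, one row per scenario x scheme x modality.
#' @export
electrode_sweep <- function(pipeline, scenarios, seed = 1L) {
  stopifnot(inherits(pipeline, "vt_pipeline"))
  if (length(pipeline$models) == 0L) abort("missing trained models")
  cfg <- pipeline$config
  test <- pipeline$dataset[pipeline$dataset$split == "test", ]
  test_snr <- cfg$dataset$test_snr_db %||% Inf
  out <- list()
  for (sc in scenarios) {
    lf <- scenario_leadfield(pipeline, sc)
    ds_sc <- if (sc$type == "identity") pipeline$dataset else {
      rerender_test(pipeline, test, lf)
    }
    res <- evaluate_frozen(pipeline, ds_sc, snr_db = test_snr, seed = seed)
    out[[sc$name]] <- sweep_report(res, condition = sc$name,
                                   pipeline$config_hash, seed)
  }
  structure(dplyr::bind_rows(out), class = c("vt_sweep", class(tibble())))
}

scenario_leadfield <- function(pipeline, sc) {
  mesh <- pipeline$mesh
  if (sc$type == "identity") return(pipeline$lf)
  if (sc$type == "ecg_shift") {
    es <- displace_electrodes(pipeline$electrodes, sc$shift, which = "ecg")
  } else if (sc$type == "lv_spacing") {
    es <- place_electrodes(mesh, lv_tip_spacing = sc$spacing)
  } else if (sc$type == "septal_coil") {
    es <- pipeline$electrodes
    i <- which(es$name == "RVcoil")
    # move the coil onto the septal wall proxy near the mid cavity level
    es$x[i] <- mesh$params$epi_short + 3; es$y[i] <- 0
    es$z[i] <- -0.45 * mesh$params$epi_long
  } else if (sc$type == "tip_cloud") {
    lf <- pipeline$lf
    for (nm in c("RVtip", paste0("LVtip", 1:4))) {
      lf <- average_tip_cloud(mesh, lf, nm, radius = sc$radius)
    }
    return(lf)
  } else {
    abort(sprintf("unknown scenario type `%s`", sc$type))
  }
  check_electrodes_clear(mesh, es)
  compute_lead_field(mesh, es, pipeline$ep$sigma_bath)
}

check_electrodes_clear <- function(mesh, es) {
  pos <- as.matrix(es[, c("x", "y", "z")])
  for (i in seq_len(nrow(pos))) {
    d <- min(row_norms(sweep(mesh$centroid, 2L, pos[i, ])))
    if (d <= 0.5) {
      abort(sprintf("scenario places electrode `%s` inside/too close to the myocardium", es$name[i]))
    }
  }
  invisible(es)
}

# Re-render the test beats' matrices under a new lead field; labels,
# splits and the train half are reused untouched.
rerender_test <- function(pipeline, test, lf) {
  cfg <- pipeline$config
  template <- pipeline$template
  taus <- solve_activation_many(pipeline$cond, test$node)
  for (i in seq_len(nrow(test))) {
    tau <- taus[i, ]
    tr <- beat_traces(lf, tau, template,
                      duration = max(tau) + template$upstroke + cfg$signal$margin,
                      sigma_intra = pipeline$ep$sigma_intra)
    ecg <- resample_16(extract_qrs(derive_ecg_channels(tr), max(tau),
                                   template$upstroke, cfg$signal$margin))
    egm <- resample_16(extract_qrs(derive_egm_channels(tr), max(tau),
                                   template$upstroke, cfg$signal$margin))
    test$ecg[[i]] <- signal_matrix(unclass_mat(ecg), "ecg")
    test$egm[[i]] <- signal_matrix(unclass_mat(egm), "egm")
  }
  train <- pipeline$dataset[pipeline$dataset$split == "train", ]
  out <- dplyr::bind_rows(train, test)
  structure(out, class = class(pipeline$dataset))
}

#' @exportS3Method ggplot2::autoplot
autoplot.vt_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$condition, y = .data$mean_error_mm,
                               colour = .data$modality, group = .data$modality)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_error_mm - .data$sd_error_mm,
                                        ymax = .data$mean_error_mm + .data$sd_error_mm),
                           width = 0.2, position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::labs(x = NULL, y = "localization error (mm)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write a sweep report as a delimited table
#' @param report A `vt_sweep` tibble.
#' @param path CSV path.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
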