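#' Compute lead-field weights in an infinite homogeneous medium
#'
#' For electrode `e` and element centroid `x` the scalar kernel is the
#' point-source transfer function `Z_e(x) = 1 / (4 pi sigma_bath |x - x_e|)`
#' (mm/mV/S-consistent units) and its spatial gradient
#' `grad Z_e(x) = -(x - x_e) / (4 pi sigma_bath |x - x_e|^3)`.
#' Alongside the per-element kernel the constructor assembles, once per
#' electrode configuration, the per-node weight vector
#' `w_e[n] = sum_el vol_el * grad(N_n)|_el . grad Z_e(x_el)` so that the
#' pseudo-ECG source integral reduces to an inner product with the nodal
#' transmembrane voltages (see [compute_extracellular()]).
#'
#' @param mesh A `vt_mesh`.
#' @param electrodes A `vt_electrodes` tibble.
#' @param sigma_bath Bath conductivity, S/m.
#' @return A `vt_leadfield`: `Z` (elements x electrodes), `grad`
#'   (elements x 3 x electrodes), `W` (nodes x electrodes), electrode table,
#'   element volumes, `sigma_bath`.
#' @export
compute_lead_field <- function(mesh, electrodes, sigma_bath = 0.2) {
  stopifnot(inherits(mesh, "vt_mesh"), inherits(electrodes, "vt_electrodes"))
  assert_scalar_num(sigma_bath, "sigma_bath", positive = TRUE)
  cen <- mesh$centroid
  m <- nrow(cen); En <- nrow(electrodes)
  Z <- matrix(0, m, En); G <- array(0, dim = c(m, 3L, En))
  dimnames(Z) <- list(NULL, electrodes$name)
  for (e in seq_len(En)) {
    pos <- c(electrodes$x[e], electrodes$y[e], electrodes$z[e])
    rv <- sweep(cen, 2L, pos)
    r <- row_norms(rv)
    if (min(r) <= 0.5) {
      abort(sprintf("electrode `%s` is within 0.5 mm of an element centroid (singular kernel)",
                    electrodes$name[e]))
    }
    Z[, e] <- 1 / (4 * pi * sigma_bath * r)
    G[, , e] <- -rv / (4 * pi * sigma_bath * r^3)
  }
  W <- assemble_node_weights(mesh, G)
  dimnames(W) <- list(NULL, electrodes$name)
  structure(list(Z = Z, grad = G, W = W, electrodes = electrodes,
                 vol = mesh$vol, sigma_bath = sigma_bath,
                 n_nodes = nrow(mesh$nodes)),
            class = "vt_leadfield")
}

# Accumulate vol * gradN_i . g_e into per-node weights, for all electrodes.
assemble_node_weights <- function(mesh, G) {
  gr <- elem_gradients(mesh)
  n <- nrow(mesh$nodes); En <- dim(G)[3L]
  W <- matrix(0, n, En)
  for (e in seq_len(En)) {
    ge <- G[, , e]
    for (k in 1:4) {
      gk <- gr[[k]]
      contrib <- mesh$vol * (gk[, 1L] * ge[, 1L] + gk[, 2L] * ge[, 2L] + gk[, 3L] * ge[, 3L])
      acc <- rowsum(contrib, mesh$elems[, k])
      ids <- as.integer(rownames(acc))
      W[ids, e] <- W[ids, e] + acc[, 1L]
    }
  }
  W
}

#' Extracellular potential traces at every electrode
#'
#' Pseudo-ECG source integration:
#' `phi_e(t) = sum_el sigma_intra * grad Vm(t)|_el . grad Z_e(x_el) * vol_el`,
#' with per-element linear-shape-function gradients. Implemented as the
#' algebraically identical inner product `sigma_intra * W^T Vm(t)` with the
#' precomputed nodal weights; linear in Vm, and exactly zero for spatially
#' uniform Vm.
#'
#' @param lf A `vt_leadfield`.
#' @param vm A `vt_vm_movie` (or plain nodes x times matrix).
#' @param mesh The mesh the movie lives on.
#' @param sigma_intra Intracellular conductivity, S/m.
#' @return A `vt_traces`: matrix electrodes x times (mV) with a `times`
#'   attribute.
#' @export
compute_extracellular <- function(lf, vm, mesh, sigma_intra = 0.1845) {
  stopifnot(inherits(lf, "vt_leadfield"))
  vmat <- if (inherits(vm, "vt_vm_movie")) vm$vm else vm
  times <- if (inherits(vm, "vt_vm_movie")) vm$times else seq_len(ncol(vmat)) - 1
  if (nrow(vmat) != lf$n_nodes) abort("Vm movie and lead field live on different meshes")
  out <- sigma_intra * crossprod(lf$W, vmat)
  rownames(out) <- lf$electrodes$name
  structure(out, times = times, class = c("vt_traces", "matrix", "array"))
}

#' Fast trace synthesis for one beat (activation map + template)
#'
#' Exploits the piecewise-linear template: before repolarization every node
#' contributes `amp * ramp((t - tau)/upstroke)`, so the electrode potential
#' is a pair of cumulative sums over nodes sorted by activation time.
#' Identical (to rounding) to running [vm_movie()] +
#' [compute_extracellular()], at a fraction of the memory.
#'
#' @param lf A `vt_leadfield`.
#' @param tau Activation times per node (ms).
#' @param template An `vt_ap_template`.
#' @param duration Trace duration (ms); defaults to
#'   `max(tau) + upstroke`; must not exceed `min(tau) + apd`.
#' @param sigma_intra Intracellular conductivity, S/m.
#' @return A `vt_traces` matrix (electrodes x times).
#' @export
beat_traces <- function(lf, tau, template, duration = NULL, sigma_intra = 0.1845) {
  stopifnot(inherits(lf, "vt_leadfield"), inherits(template, "vt_ap_template"))
  if (length(tau) != lf$n_nodes) abort("tau and lead field live on different meshes")
  up <- template$upstroke
  duration <- duration %||% (max(tau) + up)
  # time grid covers `duration` fully (last sample may overshoot by < dt)
  times <- seq(0, by = template$dt,
               length.out = ceiling(duration / template$dt) + 1L)
  if (max(times) > min(tau) + template$apd) {
    abort("duration extends into repolarization; use compute_extracellular()")
  }
  ord <- order(tau)
  ts <- tau[ord]
  Wo <- lf$W[ord, , drop = FALSE]
  cw <- apply(Wo, 2L, cumsum)
  cwt <- apply(Wo * ts, 2L, cumsum)
  i2 <- findInterval(times, ts)
  i1 <- findInterval(times - up, ts)
  pick <- function(cs, idx) rbind(0, cs)[idx + 1L, , drop = FALSE]
  full <- pick(cw, i1)
  partial <- (times * (pick(cw, i2) - pick(cw, i1)) -
                (pick(cwt, i2) - pick(cwt, i1))) / up
  out <- t(full + partial) * (sigma_intra * template$amplitude)
  rownames(out) <- lf$electrodes$name
  structure(out, times = times, class = c("vt_traces", "matrix", "array"))
}

#' Average an electrode's lead field over a cloud of points
#'
#' Replaces a point electrode with the mean kernel over `n_points`
#' quasi-uniform points (Fibonacci sphere, cube-root radial profile) inside
#' a sphere of radius `radius` about it, emulating a finite-size sensing
#' tip. Cloud points that fall within 0.5 mm of an element centroid are
#' excluded with a warning.
#'
#' @param mesh The mesh the lead field was built on.
#' @param lf A `vt_leadfield`.
#' @param electrode Electrode name.
#' @param radius Cloud radius, mm (> 0; the point kernel is the radius -> 0
#'   limit).
#' @param n_points Points in the cloud.
#' @return The lead field with that electrode's rows replaced.
#' @export
average_tip_cloud <- function(mesh, lf, electrode, radius = 2, n_points = 20) {
  stopifnot(inherits(lf, "vt_leadfield"))
  if (radius <= 0) abort("`radius` must be > 0")
  e <- match(electrode, lf$electrodes$name)
  if (is.na(e)) abort(sprintf("electrode `%s` missing", electrode))
  pos <- c(lf$electrodes$x[e], lf$electrodes$y[e], lf$electrodes$z[e])

  i <- seq_len(n_points)
  golden <- pi * (3 - sqrt(5))
  zs <- 1 - 2 * (i - 0.5) / n_points
  rad_xy <- sqrt(pmax(0, 1 - zs^2))
  dirs <- cbind(rad_xy * cos(golden * i), rad_xy * sin(golden * i), zs)
  rr <- radius * ((i - 0.5) / n_points)^(1 / 3)
  pts <- sweep(dirs * rr, 2L, pos, `+`)

  cen <- mesh$centroid
  m <- nrow(cen)
  Zacc <- numeric(m); Gacc <- matrix(0, m, 3L); used <- 0L
  for (q in seq_len(n_points)) {
    rv <- sweep(cen, 2L, pts[q, ])
    r <- row_norms(rv)
    if (min(r) <= 0.5) {
      warn(sprintf("tip-cloud point %d of `%s` within 0.5 mm of a centroid; excluded", q, electrode))
      next
    }
    Zacc <- Zacc + 1 / (4 * pi * lf$sigma_bath * r)
    Gacc <- Gacc - rv / (4 * pi * lf$sigma_bath * r^3)
    used <- used + 1L
  }
  if (used == 0L) abort("all cloud points excluded")
  lf$Z[, e] <- Zacc / used
  lf$grad[, , e] <- Gacc / used
  W_e <- assemble_node_weights(mesh, lf$grad[, , e, drop = FALSE])
  lf$W[, e] <- W_e[, 1L]
  lf
}

#' Scale lead-field weights per region (surrogate conductivity hook)
#'
#' A surrogate for torso-composition scenarios that would need a
#' heterogeneous-volume forward solve: rows of the weight matrices belonging
#' to each element region are scaled multiplicatively. Always labelled a
#' surrogate in reports.
#'
#' @param mesh The mesh the lead field was built on.
#' @param lf A `vt_leadfield`.
#' @param factors Either a single positive factor (global) or a vector of
#'   per-element positive factors.
#' @param seed Ignored unless factors are sampled by the caller; kept so the
#'   operation is a pure function of its arguments.
#' @return The scaled `vt_leadfield`, flagged with `attr(, "surrogate")`.
#' @export
perturb_leadfield <- function(mesh, lf, factors, seed = NULL) {
  stopifnot(inherits(lf, "vt_leadfield"))
  m <- nrow(lf$Z)
  f <- if (length(factors) == 1L) rep(factors, m) else as.numeric(factors)
  if (length(f) != m) abort("`factors` must be scalar or one per element")
  if (any(f <= 0)) abort("all perturbation factors must be > 0")
  lf$Z <- lf$Z * f
  lf$grad <- lf$grad * as.vector(f)
  lf$W <- assemble_node_weights(mesh, lf$grad)
  dimnames(lf$W) <- list(NULL, lf$electrodes$name)
  attr(lf, "surrogate") <- TRUE
  inform("perturb_leadfield: surrogate lead-field perturbation (not a torso conductivity model)")
  lf
}

#' Cache a lead field on disk, keyed by its configuration
#'
#' Lead fields depend only on (mesh, electrode set, bath conductivity), so
#' they are stored in an RDS container named by a hash of that triple;
#' [cached_lead_field()] returns the cached object when the key matches and
#' recomputes (then caches) otherwise.
#'
#' @param mesh A `vt_mesh`.
#' @param electrodes A `vt_electrodes`.
#' @param sigma_bath Bath conductivity, S/m.
#' @param cache_dir Directory for the cache files.
#' @return The `vt_leadfield` (computed or loaded).
#' @export
cached_lead_field <- function(mesh, electrodes, sigma_bath = 0.2,
                              cache_dir = tempdir()) {
  key <- rlang::hash(list(nodes = mesh$nodes, elems = mesh$elems,
                          electrodes = as.data.frame(electrodes),
                          sigma_bath = sigma_bath))
  path <- file.path(cache_dir, sprintf("leadfield_%s.rds", key))
  if (file.exists(path)) return(readRDS(path))
  lf <- compute_lead_field(mesh, electrodes, sigma_bath)
  saveRDS(lf, path)
  lf
}

#' Export traces as a delimited table (time in ms, one column per electrode)
#' @param traces A `vt_traces` matrix.
#' @param path Output CSV path.
#' @export
write_traces_csv <- function(traces, path) {
  df <- data.frame(time_ms = attr(traces, "times"), t(unclass(traces)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
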