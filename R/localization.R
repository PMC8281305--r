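#' Cartesian source estimate from segment and endo/epi probabilities
#'
#' The probability-weighted center-of-gravity combination: the candidate
#' set S is the highest-probability segment plus its adjacent segments; the
#' segment probabilities are renormalized over S and combined with the
#' endo/epi probabilities and the per-segment surface centers of gravity:
#' `x_hat = sum_{i in S} P_i (P_endo CoG_i,endo + P_epi CoG_i,epi)`.
#' The renormalization makes the output a convex combination of the
#' participating CoGs, so the estimate always lies in their convex hull.
#'
#' @param p_seg Probability vector over segments (sums to 1 within 1e-6).
#' @param p_epiendo Length-2 probability vector `(endo, epi)`.
#' @param segmodel A `vt_segments` whose mode matches `length(p_seg)`.
#' @return xyz estimate in mm (length-3 numeric).
#' @export
cartesian_combine <- function(p_seg, p_epiendo, segmodel) {
  stopifnot(inherits(segmodel, "vt_segments"))
  if (length(p_seg) != segmodel$mode) {
    abort(sprintf("p_seg has length %d but the segment model has %d segments",
                  length(p_seg), segmodel$mode))
  }
  if (abs(sum(p_seg) - 1) > 1e-6 || abs(sum(p_epiendo) - 1) > 1e-6 ||
      any(p_seg < -1e-9) || any(p_epiendo < -1e-9)) {
    abort("probability vectors must be nonnegative and sum to 1 (within 1e-6)")
  }
  top <- which.max(p_seg)
  S <- sort(unique(c(top, segmodel$adjacency[[top]])))
  w <- p_seg[S] / sum(p_seg[S])
  cog_endo <- cog_matrix(segmodel, "endo")[S, , drop = FALSE]
  cog_epi <- cog_matrix(segmodel, "epi")[S, , drop = FALSE]
  per_seg <- p_epiendo[1L] * cog_endo + p_epiendo[2L] * cog_epi
  as.numeric(colSums(per_seg * w))
}

#' Invert ventricular coordinates to Cartesian space (nearest mesh node)
#'
#' Finds the mesh node minimizing the scaled UVC metric
#' `d^2 = w_z (dz)^2 + w_rho (drho)^2 + (r_node wrap(dphi))^2`, where the
#' weights convert each normalized coordinate to approximate millimetres:
#' `w_z = (long axis)^2`, `w_rho = (wall thickness)^2`, and the phi
#' mismatch is charged its actual arc length at the candidate node's radius
#' `r_node` (so an azimuthal error near the apex, where phi is nearly
#' degenerate, costs what it is worth spatially). Exact on mesh nodes (the
#' node's own coordinates give metric zero).
#'
#' @param uvc A list/tibble row with `z`, `rho`, `phi` (or a 3-column
#'   matrix/tibble for a batch).
#' @param mesh A `vt_mesh`.
#' @param node_uvc The per-node `vt_uvc` table of `mesh`.
#' @return xyz in mm: a length-3 vector for one query, or an n x 3 matrix.
#' @export
uvc_to_cartesian <- function(uvc, mesh, node_uvc) {
  stopifnot(inherits(mesh, "vt_mesh"), inherits(node_uvc, "vt_uvc"))
  if (nrow(mesh$nodes) == 0L) abort("empty mesh")
  q <- if (is.numeric(uvc) && is.null(dim(uvc))) {
    if (length(uvc) != 3L) abort("numeric uvc query must be length 3 (z, rho, phi)")
    matrix(uvc, nrow = 1L)
  } else if (is.data.frame(uvc)) {
    as.matrix(as.data.frame(uvc)[, c("z", "rho", "phi")])
  } else if (is.list(uvc)) {
    matrix(c(uvc$z, uvc$rho, uvc$phi), nrow = 1L)
  } else {
    as.matrix(uvc)
  }
  w <- uvc_metric_weights(mesh)
  nz <- node_uvc$z; nr <- node_uvc$rho; np <- node_uvc$phi
  r_node <- sqrt(mesh$nodes[, 1L]^2 + mesh$nodes[, 2L]^2)
  idx <- vapply(seq_len(nrow(q)), function(i) {
    d2 <- w[1L] * (nz - q[i, 1L])^2 + w[2L] * (nr - q[i, 2L])^2 +
      (r_node * angle_diff(np, q[i, 3L]))^2
    which.min(d2)
  }, integer(1))
  out <- mesh$nodes[idx, , drop = FALSE]
  if (nrow(out) == 1L) as.numeric(out) else out
}

uvc_metric_weights <- function(mesh) {
  r_mid <- mean(sqrt(mesh$nodes[, 1L]^2 + mesh$nodes[, 2L]^2))
  c(z = mesh$params$epi_long^2, rho = mesh$params$wall^2, phi = r_mid^2)
}

#' Euclidean localization error in millimetres
#' @param pred,truth xyz coordinates (length-3, or n x 3 matrices).
#' @return Distance(s) in mm.
#' @export
localization_error <- function(pred, truth) {
  p <- rbind(pred); t_ <- rbind(truth)
  if (any(!is.finite(p)) || any(!is.finite(t_))) abort("coordinates must be finite")
  as.numeric(sqrt(rowSums((p - t_)^2)))
}

#' Accuracy and per-segment precision of a segment classifier
#'
#' Accuracy is the percentage of beats classified into their true segment.
#' Precision of segment s is the fraction of beats predicted as s that
#' truly originate there; segments never predicted get `NA` (reported as
#' missing, not zero).
#'
#' @param predictions,truths Integer class vectors of equal length.
#' @param n_classes Number of classes.
#' @return List with `accuracy` (percent) and `precision` tibble.
#' @export
score_segment_classifier <- function(predictions, truths, n_classes) {
  if (length(predictions) != length(truths)) abort("length mismatch")
  acc <- mean(predictions == truths) * 100
  prec <- vapply(seq_len(n_classes), function(s) {
    hit <- predictions == s
    if (!any(hit)) NA_real_ else mean(truths[hit] == s)
  }, numeric(1))
  list(accuracy = acc,
       precision = tibble(segment = seq_len(n_classes), precision = prec))
}

#' Bull's-eye display coordinates from ventricular coordinates
#'
#' Maps z to the radius (apex at the center, base at the rim; the
#' apical/mid/basal z thirds map linearly onto the radial thirds) and phi
#' to the display angle. rho is carried along as a color attribute; two
#' points differing only in rho share the same position.
#'
#' @param uvc A `vt_uvc`-like tibble (columns `z`, `rho`, `phi`).
#' @return Tibble `r`, `theta`, `rho`.
#' @export
bullseye_coords <- function(uvc) {
  df <- as.data.frame(uvc)
  tibble(r = df$z, theta = df$phi, rho = df$rho)
}

#' Localize test beats with the Cartesian probability scheme
#'
#' @param seg_model Trained segment classifier (`vt_model`).
#' @param epiendo_model Trained endo/epi classifier.
#' @param segmodel A `vt_segments` matching the classifier's class count.
#' @param dataset A `vt_dataset`; its test split is evaluated.
#' @param snr_db Optional noise added to the test matrices before
#'   prediction (the evaluation protocol noises held-out beats too).
#' @param seed Seed for the evaluation noise.
#' @return A `vt_results` tibble with per-beat errors (mm).
#' @export
localize_cartesian <- function(seg_model, epiendo_model, segmodel, dataset,
                               snr_db = Inf, seed = 1L) {
  test <- dataset[dataset$split == "test", ]
  modality <- seg_model$modality
  x <- test_inputs(test, modality, snr_db, seed)
  p_seg <- predict_proba(seg_model, x)
  p_ee <- predict_proba(epiendo_model, x)
  pred <- t(vapply(seq_len(nrow(test)), function(i) {
    cartesian_combine(p_seg[i, ], p_ee[i, ], segmodel)
  }, numeric(3)))
  truth <- as.matrix(test[, c("x", "y", "z")])
  scheme <- paste0("cartesian", segmodel$mode)
  pred_cls <- max.col(p_seg, ties.method = "first")
  truth_cls <- if (segmodel$mode == 17L) test$seg17 else test$seg68
  structure(tibble(beat = test$beat, scheme = scheme, modality = modality,
                   pred_x = pred[, 1L], pred_y = pred[, 2L], pred_z = pred[, 3L],
                   truth_x = truth[, 1L], truth_y = truth[, 2L], truth_z = truth[, 3L],
                   pred_class = pred_cls, truth_class = truth_cls,
                   error_mm = localization_error(pred, truth)),
            class = c("vt_results", class(tibble())))
}

#' Localize test beats with the UVC regression + wedge classification scheme
#'
#' @param regressor,classifier Trained `vt_model`s (`uvc_regression`,
#'   `phi_classification`) on the same modality.
#' @param mesh,node_uvc Mesh and its per-node coordinates for the
#'   nearest-node inversion.
#' @param dataset A `vt_dataset`; its test split is evaluated.
#' @param snr_db,seed Evaluation noise as in [localize_cartesian()].
#' @return A `vt_results` tibble.
#' @export
localize_uvc <- function(regressor, classifier, mesh, node_uvc, dataset,
                         snr_db = Inf, seed = 1L) {
  test <- dataset[dataset$split == "test", ]
  modality <- regressor$modality
  x <- test_inputs(test, modality, snr_db, seed)
  uvc_hat <- predict_uvc(regressor, classifier, x)
  pred <- uvc_to_cartesian(uvc_hat, mesh, node_uvc)
  pred <- rbind(pred)
  truth <- as.matrix(test[, c("x", "y", "z")])
  structure(tibble(beat = test$beat, scheme = "uvc", modality = modality,
                   pred_x = pred[, 1L], pred_y = pred[, 2L], pred_z = pred[, 3L],
                   truth_x = truth[, 1L], truth_y = truth[, 2L], truth_z = truth[, 3L],
                   pred_uvc_z = uvc_hat$z, pred_uvc_rho = uvc_hat$rho,
                   pred_uvc_phi = uvc_hat$phi,
                   error_mm = localization_error(pred, truth)),
            class = c("vt_results", class(tibble())))
}

test_inputs <- function(test, modality, snr_db, seed) {
  mats <- test[[modality]]
  if (is.finite(snr_db)) {
    mats <- with_seed(seed, lapply(mats, add_noise, snr_db = snr_db))
  }
  t(vapply(mats, function(m) as.vector(m$values), numeric(256L)))
}

#' @exportS3Method generics::glance
glance.vt_results <- function(x, ...) {
  tibble(scheme = x$scheme[1L], modality = x$modality[1L], n = nrow(x),
         mean_error_mm = mean(x$error_mm), sd_error_mm = stats::sd(x$error_mm),
         median_error_mm = stats::median(x$error_mm))
}

#' @exportS3Method generics::tidy
tidy.vt_results <- function(x, ...) as_tibble(x)

#' Histogram of localization errors
#' @param object A `vt_results` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.vt_results <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$error_mm)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "localization error (mm)", y = "beats",
                  title = sprintf("%s / %s localization", object$scheme[1L],
                                  toupper(object$modality[1L])))
}

#' Bull's-eye plot of predicted vs true sources
#'
#' Diamonds mark ground truths, circles the network estimates; the radius
#' encodes z (apex at the center), the angle encodes phi, and color the
#' transmural coordinate rho.
#'
#' @param results A `vt_results` from [localize_uvc()].
#' @param dataset The dataset the results came from (for true UVCs).
#' @return A ggplot object.
#' @export
plot_bullseye <- function(results, dataset) {
  test <- dataset[match(results$beat, dataset$beat), ]
  truth <- bullseye_coords(tibble(z = test$uvc_z, rho = test$uvc_rho, phi = test$uvc_phi))
  est <- bullseye_coords(tibble(z = results$pred_uvc_z, rho = results$pred_uvc_rho,
                                phi = results$pred_uvc_phi))
  df <- dplyr::bind_rows(
    dplyr::mutate(truth, kind = "truth"),
    dplyr::mutate(est, kind = "estimate")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$r,
                                   colour = .data$rho, shape = .data$kind)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(truth = 18, estimate = 1)) +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::scale_x_continuous(limits = c(-pi, pi)) +
    ggplot2::labs(x = expression(phi), y = "z (apex 0, base 1)")
}
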