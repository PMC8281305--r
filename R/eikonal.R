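#' Electrophysiology parameters
#'
#' Conduction velocities are the reaction-eikonal values along and transverse
#' to the fiber direction; the two bulk conductivities parameterize the
#' forward model (bath for the lead-field kernel, intracellular for the
#' source term). The tissue conductivity tensor values and the basic cycle
#' length are carried as metadata only (single-beat simulations).
#'
#' @param cv_long,cv_trans Conduction velocity along/transverse fiber, m/s
#'   (numerically equal to mm/ms).
#' @param bcl Basic cycle length, ms (metadata).
#' @param sigma_bath Bath conductivity for the lead-field kernel, S/m.
#' @param sigma_intra Intracellular conductivity in the source term, S/m.
#'
#' @return An `vt_ep_params` list.
#' @export
ep_params <- function(cv_long = 0.5455, cv_trans = 0.1802, bcl = 400,
                      sigma_bath = 0.2, sigma_intra = 0.1845) {
  assert_scalar_num(cv_long, "cv_long", positive = TRUE)
  assert_scalar_num(cv_trans, "cv_trans", positive = TRUE)
  if (cv_long <= cv_trans) abort("require cv_long > cv_trans > 0")
  assert_scalar_num(sigma_bath, "sigma_bath", positive = TRUE)
  assert_scalar_num(sigma_intra, "sigma_intra", positive = TRUE)
  structure(list(cv_long = cv_long, cv_trans = cv_trans, bcl = bcl,
                 sigma_bath = sigma_bath, sigma_intra = sigma_intra,
                 meta = list(intra_long = 0.1845, extra_long = 0.6628)),
            class = "vt_ep_params")
}

#' Precompute the anisotropic conduction graph
#'
#' Each mesh edge of direction `d` (unit) and length `L` costs
#' `L / v(d)` with the elliptical velocity profile
#' `v(d) = sqrt(cv_long^2 (d.f)^2 + cv_trans^2 (1 - (d.f)^2))`, `f` being the
#' local fiber direction (averaged over the elements incident to the edge).
#' Activation times are shortest arrival times over this weighted graph.
#'
#' @param mesh A `vt_mesh` with fibers assigned.
#' @param ep An `vt_ep_params`.
#' @return A `vt_conduction` object (igraph graph + edge table).
#' @export
prepare_conduction <- function(mesh, ep) {
  stopifnot(inherits(mesh, "vt_mesh"), inherits(ep, "vt_ep_params"))
  if (is.null(mesh$fiber)) abort("mesh has no fibers; call assign_fibers() first")
  ed <- mesh_edges(mesh)
  dvec <- (mesh$nodes[ed$j, , drop = FALSE] - mesh$nodes[ed$i, , drop = FALSE]) / ed$len
  proj <- rowSums(dvec * ed$fiber)
  v <- sqrt(ep$cv_long^2 * proj^2 + ep$cv_trans^2 * (1 - proj^2))
  wts <- ed$len / v
  g <- igraph::make_empty_graph(n = nrow(mesh$nodes), directed = FALSE)
  g <- igraph::add_edges(g, rbind(ed$i, ed$j))
  igraph::E(g)$weight <- wts
  structure(list(graph = g, edges = list(i = ed$i, j = ed$j, w = wts, len = ed$len),
                 n_nodes = nrow(mesh$nodes), ep = ep),
            class = "vt_conduction")
}

#' Solve for the activation-time map of one focal source
#'
#' @param x A `vt_conduction` (preferred; reusable across sources) or a
#'   `vt_mesh` with fibers.
#' @param source Node id of the pacing site.
#' @param ep Required when `x` is a mesh.
#' @return A `vt_activation` object with `tau` (ms per node, 0 at the
#'   source) and `source_node`.
#' @export
solve_activation <- function(x, source, ep = NULL) {
  cond <- if (inherits(x, "vt_conduction")) x else prepare_conduction(x, ep)
  tau <- solve_activation_many(cond, source)[1L, ]
  structure(list(tau = tau, source_node = as.integer(source), ep = cond$ep),
            class = "vt_activation")
}

#' Activation times for many sources at once
#' @param cond A `vt_conduction`.
#' @param sources Integer node ids.
#' @return Matrix `length(sources)` x n_nodes of arrival times (ms).
#' @export
solve_activation_many <- function(cond, sources) {
  stopifnot(inherits(cond, "vt_conduction"))
  sources <- as.integer(sources)
  if (any(sources < 1L | sources > cond$n_nodes)) abort("source is not a mesh node")
  tau <- igraph::distances(cond$graph, v = sources, algorithm = "dijkstra")
  if (any(!is.finite(tau))) abort("unreachable nodes: mesh must be connected")
  unname(tau)
}

#' Action-potential template (the reaction half of the reaction-eikonal surrogate)
#'
#' Piecewise waveform: resting potential until local activation, a linear
#' upstroke of `upstroke` ms to the plateau, a flat plateau for `apd` ms,
#' then a linear return to rest over `repol` ms. Only the QRS window is
#' consumed downstream, so the repolarization shape is irrelevant by
#' construction.
#'
#' @param upstroke Upstroke duration, ms.
#' @param v_rest,v_plateau Resting and plateau potentials, mV.
#' @param apd Action-potential duration (plateau end), ms.
#' @param repol Repolarization ramp duration, ms.
#' @param dt Sampling interval, ms.
#' @return A `vt_ap_template` with a vectorized evaluator `$value(t_rel)`.
#' @export
ap_template <- function(upstroke = 1, v_rest = -85, v_plateau = 25,
                        apd = 300, repol = 50, dt = 0.5) {
  assert_scalar_num(upstroke, "upstroke", positive = TRUE)
  assert_scalar_num(apd, "apd", positive = TRUE)
  assert_scalar_num(dt, "dt", positive = TRUE)
  amp <- v_plateau - v_rest
  value <- function(t_rel) {
    up <- pmin(pmax(t_rel / upstroke, 0), 1)
    down <- pmin(pmax((t_rel - apd) / repol, 0), 1)
    v_rest + amp * (up - down)
  }
  structure(list(upstroke = upstroke, v_rest = v_rest, v_plateau = v_plateau,
                 amplitude = amp, apd = apd, repol = repol, dt = dt, value = value),
            class = "vt_ap_template")
}

#' Expand an activation map into a transmembrane-voltage movie
#'
#' `Vm_node(t) = template(t - tau(node))`: every node plays the same
#' action-potential waveform shifted by its activation time.
#'
#' @param activation A `vt_activation`.
#' @param template An `vt_ap_template`.
#' @param duration Total duration in ms; must cover
#'   `max(tau) + upstroke`.
#' @return A `vt_vm_movie`: matrix nodes x times plus the time grid.
#' @export
vm_movie <- function(activation, template, duration) {
  stopifnot(inherits(activation, "vt_activation"), inherits(template, "vt_ap_template"))
  if (duration < max(activation$tau) + template$upstroke) {
    abort("`duration` too short: must cover max(tau) + upstroke")
  }
  times <- seq(0, duration, by = template$dt)
  vm <- outer(-activation$tau, times, `+`)
  vm[] <- template$value(vm)
  structure(list(vm = vm, times = times, dt = template$dt,
                 template = template, source_node = activation$source_node),
            class = "vt_vm_movie")
}
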