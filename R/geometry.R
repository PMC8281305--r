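#' Geometry parameters for the synthetic left ventricle
#'
#' The synthetic LV is a truncated-ellipsoid shell: the myocardium lies
#' between an endocardial and an epicardial half-ellipsoid of revolution,
#' cut by the base plane `z = 0`. The long axis is the z axis, the apex
#' points towards negative z, and `septal_dir` (the +x axis by default)
#' fixes the phi = 0 reference direction of the ventricular coordinate
#' system (the "septal" direction, where the virtual RV would sit).
#'
#' @param epi_long Epicardial long-axis length (apex to base), mm.
#' @param epi_short Epicardial short-axis radius at the base, mm.
#' @param wall Wall thickness, mm (uniform in the parametric sense).
#' @param edge Target edge length of the mesh, mm.
#' @param septal_dir Unit-ish 3-vector in the base plane marking phi = 0.
#'
#' @return A list of validated geometry parameters.
#' @export
geometry_params <- function(epi_long = 90, epi_short = 35, wall = 10,
                            edge = 2.5, septal_dir = c(1, 0, 0)) {
  assert_scalar_num(epi_long, "epi_long", positive = TRUE)
  assert_scalar_num(epi_short, "epi_short", positive = TRUE)
  assert_scalar_num(wall, "wall", positive = TRUE)
  assert_scalar_num(edge, "edge", positive = TRUE)
  if (epi_long - wall <= 0 || epi_short - wall <= 0) {
    abort("degenerate dimensions: endocardial ellipsoid must be strictly inside the epicardial one (endo >= epi)")
  }
  sd <- as.numeric(septal_dir)
  if (length(sd) != 3L || sqrt(sum(sd^2)) < 1e-9) abort("`septal_dir` must be a nonzero 3-vector")
  sd[3] <- 0
  if (sqrt(sum(sd^2)) < 1e-9) abort("`septal_dir` must have a component in the base plane")
  list(epi_long = epi_long, epi_short = epi_short, wall = wall,
       edge = edge, septal_dir = sd / sqrt(sum(sd^2)))
}

# Quarter-ellipse arc length from apex (psi = 0) to base (psi = pi/2) for a
# surface of revolution with short radius a and long semi-axis c.
quarter_arc <- function(a, c_) {
  f <- function(psi) sqrt(a^2 * cos(psi)^2 + c_^2 * sin(psi)^2)
  stats::integrate(f, 0, pi / 2, rel.tol = 1e-8)$value
}

#' Build the synthetic truncated-ellipsoid LV mesh
#'
#' Generates a structured tetrahedral mesh of the half-ellipsoid shell.
#' Nodes are laid out on `n_u` transmural layers between the endocardial
#' (`u = 0`) and epicardial (`u = 1`) surfaces, `n_v` latitude rings between
#' apex and base, and `n_w` azimuthal sectors; every hexahedral cell is cut
#' into six tetrahedra (Kuhn subdivision, conformal across the structured
#' grid), apex wedges into three. The construction is fully deterministic.
#'
#' @param params A list from [geometry_params()].
#'
#' @return A `vt_mesh` object: node coordinates (mm), tetrahedral
#'   connectivity, element centroids/volumes, per-node parametric
#'   coordinates, surface masks (`endo`, `epi`, `base_plane`), an exclusive
#'   per-boundary-node `surface_label`, apex/base landmarks, and per-element
#'   local wall frames used for fiber assignment.
#' @export
build_lv_mesh <- function(params = geometry_params()) {
  p <- params
  a_epi <- p$epi_short; c_epi <- p$epi_long
  a_endo <- a_epi - p$wall; c_endo <- c_epi - p$wall
  h <- p$edge

  n_u <- max(3L, as.integer(round(p$wall / h)) + 1L)
  arc <- quarter_arc(a_epi, c_epi)
  n_v <- max(4L, as.integer(round(arc / h)))
  n_w <- max(8L, as.integer(round(2 * pi * a_epi / h)))

  u_frac <- seq(0, 1, length.out = n_u)
  psi <- seq(0, pi / 2, length.out = n_v + 1L)  # psi[1] = pole
  w <- 2 * pi * (seq_len(n_w) - 1L) / n_w

  a_u <- a_endo + p$wall * u_frac        # short radius per layer
  c_u <- c_endo + p$wall * u_frac        # long semi-axis per layer

  # node ids: for layer l (1..n_u): pole node, then rings j = 1..n_v each with
  # n_w nodes ordered by sector k.
  per_layer <- 1L + n_v * n_w
  n_nodes <- n_u * per_layer
  pole_id <- function(l) (l - 1L) * per_layer + 1L
  ring_id <- function(l, j, k) {
    # k may exceed n_w (wraps); j in 1..n_v
    kk <- ((k - 1L) %% n_w) + 1L
    (l - 1L) * per_layer + 1L + (j - 1L) * n_w + kk
  }

  nodes <- matrix(0, n_nodes, 3L)
  par_u <- numeric(n_nodes); par_psi <- numeric(n_nodes); par_w <- numeric(n_nodes)
  for (l in seq_len(n_u)) {
    nodes[pole_id(l), ] <- c(0, 0, -c_u[l])
    par_u[pole_id(l)] <- u_frac[l]; par_psi[pole_id(l)] <- 0; par_w[pole_id(l)] <- 0
    for (j in seq_len(n_v)) {
      s <- sin(psi[j + 1L]); cz <- cos(psi[j + 1L])
      ids <- ring_id(l, j, seq_len(n_w))
      nodes[ids, 1L] <- a_u[l] * s * cos(w)
      nodes[ids, 2L] <- a_u[l] * s * sin(w)
      nodes[ids, 3L] <- -c_u[l] * cz
      par_u[ids] <- u_frac[l]; par_psi[ids] <- psi[j + 1L]; par_w[ids] <- w
    }
  }

  # --- elements -------------------------------------------------------------
  # Kuhn subdivision of each hex cell; axis order (u, j, k). The 6 tets share
  # the main diagonal v(0,0,0)-v(1,1,1); identical treatment of every cell
  # makes the subdivision conformal, including across the azimuthal seam.
  perms <- list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L), c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L))
  elems_list <- vector("list", 64L); eli <- 0L
  add_elems <- function(m) { eli <<- eli + 1L; elems_list[[eli]] <<- m }

  # hex bands j = 1..n_v-1 (between ring j and j+1)
  if (n_v >= 2L) {
    for (l in seq_len(n_u - 1L)) {
      for (j in seq_len(n_v - 1L)) {
        k <- seq_len(n_w)
        corner <- function(du, dj, dk) ring_id(l + du, j + dj, k + dk)
        v <- array(0L, dim = c(n_w, 2L, 2L, 2L))
        for (du in 0:1) for (dj in 0:1) for (dk in 0:1) {
          v[, du + 1L, dj + 1L, dk + 1L] <- corner(du, dj, dk)
        }
        for (pm in perms) {
          steps <- rbind(c(0L,0L,0L), diag(3L)[pm[1L], , drop = FALSE])
          s2 <- steps[2L, ] + diag(3L)[pm[2L], ]
          idx <- rbind(c(0L,0L,0L), steps[2L, ], s2, c(1L,1L,1L))
          tet <- cbind(
            v[cbind(k, idx[1,1]+1L, idx[1,2]+1L, idx[1,3]+1L)],
            v[cbind(k, idx[2,1]+1L, idx[2,2]+1L, idx[2,3]+1L)],
            v[cbind(k, idx[3,1]+1L, idx[3,2]+1L, idx[3,3]+1L)],
            v[cbind(k, idx[4,1]+1L, idx[4,2]+1L, idx[4,3]+1L)]
          )
          add_elems(tet)
        }
      }
    }
  }

  # apex wedges between pole and ring 1: split into 3 tets with quad-face
  # diagonals matching the Kuhn rule of the adjacent cells.
  for (l in seq_len(n_u - 1L)) {
    k <- seq_len(n_w)
    P0 <- rep(pole_id(l), n_w); P1 <- rep(pole_id(l + 1L), n_w)
    A0 <- ring_id(l, 1L, k);      B0 <- ring_id(l, 1L, k + 1L)
    A1 <- ring_id(l + 1L, 1L, k); B1 <- ring_id(l + 1L, 1L, k + 1L)
    add_elems(cbind(P0, A0, B0, B1))
    add_elems(cbind(P0, A0, B1, A1))
    add_elems(cbind(P0, P1, A1, B1))
  }

  elems <- do.call(rbind, elems_list[seq_len(eli)])
  dimnames(elems) <- NULL
  storage.mode(elems) <- "integer"

  # centroids and volumes
  p1 <- nodes[elems[, 1L], , drop = FALSE]; p2 <- nodes[elems[, 2L], , drop = FALSE]
  p3 <- nodes[elems[, 3L], , drop = FALSE]; p4 <- nodes[elems[, 4L], , drop = FALSE]
  d1 <- p2 - p1; d2 <- p3 - p1; d3 <- p4 - p1
  cx <- d2[, 2L] * d3[, 3L] - d2[, 3L] * d3[, 2L]
  cy <- d2[, 3L] * d3[, 1L] - d2[, 1L] * d3[, 3L]
  cz <- d2[, 1L] * d3[, 2L] - d2[, 2L] * d3[, 1L]
  vol <- abs(d1[, 1L] * cx + d1[, 2L] * cy + d1[, 3L] * cz) / 6
  keep <- vol > 1e-9
  elems <- elems[keep, , drop = FALSE]; vol <- vol[keep]
  centroid <- (p1 + p2 + p3 + p4)[keep, , drop = FALSE] / 4

  # surface masks and exclusive labels (precedence endo > epi > base)
  endo_nodes <- which(par_u <= u_frac[1L] + 1e-12)
  epi_nodes <- which(par_u >= u_frac[n_u] - 1e-12)
  base_plane <- which(abs(par_psi - pi / 2) < 1e-12)
  surface_label <- rep(NA_character_, n_nodes)
  surface_label[base_plane] <- "base"
  surface_label[epi_nodes] <- "epi"
  surface_label[endo_nodes] <- "endo"

  # per-element local wall frame from mean parametric coordinates
  e_u <- (par_u[elems[, 1L]] + par_u[elems[, 2L]] + par_u[elems[, 3L]] + par_u[elems[, 4L]]) / 4
  e_psi <- (par_psi[elems[, 1L]] + par_psi[elems[, 2L]] + par_psi[elems[, 3L]] + par_psi[elems[, 4L]]) / 4
  sw <- (sin(par_w[elems[, 1L]]) + sin(par_w[elems[, 2L]]) + sin(par_w[elems[, 3L]]) + sin(par_w[elems[, 4L]])) / 4
  cw <- (cos(par_w[elems[, 1L]]) + cos(par_w[elems[, 2L]]) + cos(par_w[elems[, 3L]]) + cos(par_w[elems[, 4L]])) / 4
  # circular mean of azimuth; near the pole use the centroid's azimuth instead
  e_w <- atan2(sw, cw)
  near_pole <- sqrt(centroid[, 1L]^2 + centroid[, 2L]^2) > 1e-9 &
    (sw^2 + cw^2) < 0.25
  e_w[near_pole] <- atan2(centroid[near_pole, 2L], centroid[near_pole, 1L])

  a_e <- a_endo + p$wall * e_u; c_e <- c_endo + p$wall * e_u
  circ <- cbind(-sin(e_w), cos(e_w), 0)
  longi <- cbind(a_e * cos(e_psi) * cos(e_w), a_e * cos(e_psi) * sin(e_w), c_e * sin(e_psi))
  # guard the pole where the longitudinal tangent degenerates in w
  longi <- normalize_rows(longi + 1e-12)
  nrm <- cbind(circ[, 2L] * longi[, 3L] - circ[, 3L] * longi[, 2L],
               circ[, 3L] * longi[, 1L] - circ[, 1L] * longi[, 3L],
               circ[, 1L] * longi[, 2L] - circ[, 2L] * longi[, 1L])
  nrm <- normalize_rows(nrm)

  mesh <- structure(list(
    nodes = nodes, elems = elems, vol = vol, centroid = centroid,
    param = list(u = par_u, psi = par_psi, w = par_w),
    frames = list(circ = circ, longi = longi, normal = nrm, rho = e_u),
    fiber = NULL,
    surface = list(endo = endo_nodes, epi = epi_nodes, base_plane = base_plane),
    surface_label = surface_label,
    apex_node = pole_id(n_u),
    apex_axis = vapply(seq_len(n_u), pole_id, integer(1)),
    apex_point = nodes[pole_id(n_u), ],
    base_plane = list(point = c(0, 0, 0), normal = c(0, 0, 1)),
    dims = list(n_u = n_u, n_v = n_v, n_w = n_w),
    params = p
  ), class = "vt_mesh")
  mesh
}

#' @export
print.vt_mesh <- function(x, ...) {
  cat(sprintf("<vt_mesh> %d nodes, %d tetrahedra (target edge %.2f mm)\n",
              nrow(x$nodes), nrow(x$elems), x$params$edge))
  cat(sprintf("  epi long axis %.0f mm, short radius %.0f mm, wall %.0f mm; fibers %s\n",
              x$params$epi_long, x$params$epi_short, x$params$wall,
              if (is.null(x$fiber)) "unset" else "set"))
  invisible(x)
}

#' Assign rule-based fibers with linear transmural helix-angle rotation
#'
#' The fiber of each element lies in the local wall tangent plane (spanned by
#' the circumferential and apex-base tangent directions) at a helix angle
#' that varies linearly across the wall from `endo_angle` at the endocardium
#' to `epi_angle` at the epicardium.
#'
#' @param mesh A `vt_mesh`.
#' @param endo_angle,epi_angle Helix angles in degrees at rho = 0 and rho = 1.
#'
#' @return The mesh with a unit `fiber` matrix (elements x 3).
#' @export
assign_fibers <- function(mesh, endo_angle = 60, epi_angle = -60) {
  stopifnot(inherits(mesh, "vt_mesh"))
  assert_scalar_num(endo_angle, "endo_angle"); assert_scalar_num(epi_angle, "epi_angle")
  rho <- mesh$frames$rho
  alpha <- (endo_angle + (epi_angle - endo_angle) * rho) * pi / 180
  f <- mesh$frames$circ * cos(alpha) + mesh$frames$longi * sin(alpha)
  mesh$fiber <- normalize_rows(f)
  mesh$fiber_angles <- c(endo = endo_angle, epi = epi_angle)
  mesh
}

# Unique undirected edge list of the tetrahedral mesh with lengths and (when
# fibers are present) a per-edge fiber direction averaged over the incident
# elements. Cached on first use.
mesh_edges <- function(mesh) {
  if (!is.null(mesh$custom_edges)) return(mesh$custom_edges)
  if (!is.null(mesh$edges_cache)) return(mesh$edges_cache)
  el <- mesh$elems
  pairs <- rbind(el[, c(1L, 2L)], el[, c(1L, 3L)], el[, c(1L, 4L)],
                 el[, c(2L, 3L)], el[, c(2L, 4L)], el[, c(3L, 4L)])
  i <- pmin(pairs[, 1L], pairs[, 2L]); j <- pmax(pairs[, 1L], pairs[, 2L])
  key <- (as.double(i) - 1) * nrow(mesh$nodes) + as.double(j)
  eid <- rep(seq_len(nrow(el)), times = 6L)
  first <- !duplicated(key)
  ukey <- key[first]
  ei <- i[first]; ej <- j[first]
  len <- row_norms(mesh$nodes[ej, , drop = FALSE] - mesh$nodes[ei, , drop = FALSE])
  fiber <- NULL
  if (!is.null(mesh$fiber)) {
    grp <- match(key, ukey)
    fx <- rowsum(mesh$fiber[eid, 1L], grp); fy <- rowsum(mesh$fiber[eid, 2L], grp)
    fz <- rowsum(mesh$fiber[eid, 3L], grp)
    fiber <- normalize_rows(cbind(fx, fy, fz) + 1e-12)
  }
  list(i = ei, j = ej, len = len, fiber = fiber)
}

#' Element-connectivity graph of the mesh (geometric edge lengths as weights)
#' @param mesh A `vt_mesh`.
#' @return An igraph graph whose vertices are mesh nodes.
#' @keywords internal
mesh_graph <- function(mesh) {
  ed <- mesh_edges(mesh)
  g <- igraph::make_empty_graph(n = nrow(mesh$nodes), directed = FALSE)
  g <- igraph::add_edges(g, rbind(ed$i, ed$j))
  igraph::E(g)$weight <- ed$len
  g
}

# Per-element gradient operator of linear (P1) shape functions.
# Returns four m x 3 matrices g1..g4 with grad(u)|el = sum_i gi * u[node_i].
elem_gradients <- function(mesh) {
  if (!is.null(mesh$grad_cache)) return(mesh$grad_cache)
  el <- mesh$elems; nd <- mesh$nodes
  p1 <- nd[el[, 1L], , drop = FALSE]; p2 <- nd[el[, 2L], , drop = FALSE]
  p3 <- nd[el[, 3L], , drop = FALSE]; p4 <- nd[el[, 4L], , drop = FALSE]
  a <- p2 - p1; b <- p3 - p1; c_ <- p4 - p1
  # inverse transpose of the Jacobian via cross products:
  # det = a . (b x c); grad N2 = (b x c)/det etc.
  bxc <- cbind(b[,2]*c_[,3]-b[,3]*c_[,2], b[,3]*c_[,1]-b[,1]*c_[,3], b[,1]*c_[,2]-b[,2]*c_[,1])
  cxa <- cbind(c_[,2]*a[,3]-c_[,3]*a[,2], c_[,3]*a[,1]-c_[,1]*a[,3], c_[,1]*a[,2]-c_[,2]*a[,1])
  axb <- cbind(a[,2]*b[,3]-a[,3]*b[,2], a[,3]*b[,1]-a[,1]*b[,3], a[,1]*b[,2]-a[,2]*b[,1])
  det <- rowSums(a * bxc)
  g2 <- bxc / det; g3 <- cxa / det; g4 <- axb / det
  g1 <- -(g2 + g3 + g4)
  list(g1 = g1, g2 = g2, g3 = g3, g4 = g4)
}
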