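test_that("mesh construction satisfies its postconditions", {
  mesh <- small_mesh()
  expect_gte(nrow(mesh$nodes), 1000)
  expect_setequal(unique(na.omit(mesh$surface_label)), c("endo", "epi", "base"))
  # boundary nodes carry exactly one label
  boundary <- unique(c(mesh$surface$endo, mesh$surface$epi, mesh$surface$base_plane))
  expect_true(all(!is.na(mesh$surface_label[boundary])))
  # connected element graph
  g <- vtloc:::mesh_graph(mesh)
  expect_equal(igraph::components(g)$no, 1L)
  # all element volumes positive
  expect_true(all(mesh$vol > 0))
})

test_that("mesh generation is deterministic and scales ~8x when edge halves", {
  m1 <- build_lv_mesh(geometry_params(edge = 8))
  m2 <- build_lv_mesh(geometry_params(edge = 8))
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elems, m2$elems)

  coarse <- nrow(build_lv_mesh(geometry_params(edge = 5))$nodes)
  fine <- nrow(build_lv_mesh(geometry_params(edge = 2.5))$nodes)
  ratio <- fine / coarse
  expect_gt(ratio, 8 * 0.7)
  expect_lt(ratio, 8 * 1.3)
})

test_that("degenerate geometry is rejected", {
  expect_error(geometry_params(epi_long = 9, wall = 10), "degenerate")
  expect_error(geometry_params(wall = 0), "wall")
})

test_that("fibers are unit, tangent to the wall, with linear helix angle", {
  mesh <- small_mesh()  # +60 endo -> -60 epi
  expect_equal(sqrt(rowSums(mesh$fiber^2)), rep(1, nrow(mesh$fiber)),
               tolerance = 1e-9)
  # tangency to the local wall surface
  expect_lt(max(abs(rowSums(mesh$fiber * mesh$frames$normal))), 0.05)

  # helix angle is linear in rho across the whole wall: every element's
  # angle matches 60 - 120 * rho within 2 degrees (covers the rho = 0 and
  # rho = 1 surface limits and the zero crossing at mid-wall)
  ang <- asin(pmin(pmax(rowSums(mesh$fiber * mesh$frames$longi), -1), 1)) * 180 / pi
  rho <- mesh$frames$rho
  expect_lt(max(abs(ang - (60 - 120 * rho))), 2)

  # constant zero angle -> purely circumferential fibers
  m0 <- assign_fibers(build_lv_mesh(geometry_params(edge = 8)), 0, 0)
  expect_lt(max(abs(rowSums(m0$fiber * m0$frames$longi))), 1e-9)
  expect_lt(max(abs(rowSums(m0$fiber * m0$frames$normal))), 0.05)
})

test_that("UVC anchors and monotonicity hold", {
  mesh <- small_mesh(); uvc <- small_uvc()
  expect_equal(uvc$z[mesh$apex_node], 0)
  expect_equal(uvc$z[mesh$surface$base_plane], rep(1, length(mesh$surface$base_plane)))
  expect_equal(uvc$rho[mesh$surface$endo], rep(0, length(mesh$surface$endo)))
  expect_equal(uvc$rho[mesh$surface$epi], rep(1, length(mesh$surface$epi)))
  expect_true(all(uvc$phi > -pi - 1e-12 & uvc$phi <= pi + 1e-12))

  # straight transmural ray: a structured-grid node column across the wall
  pu <- mesh$param$u; ppsi <- mesh$param$psi; pw <- mesh$param$w
  tgt_psi <- sort(unique(ppsi))[5]; tgt_w <- sort(unique(pw))[3]
  col <- which(abs(ppsi - tgt_psi) < 1e-12 & abs(pw - tgt_w) < 1e-12)
  col <- col[order(pu[col])]
  expect_gte(length(col), 3)
  expect_true(all(diff(uvc$rho[col]) >= -1e-12))
})

test_that("UVC computation reports missing surface classes", {
  mesh <- small_mesh()
  mesh$surface$endo <- integer(0)
  expect_error(compute_uvc(mesh), "endo")
})

test_that("segment models partition the myocardium with nesting 68 -> 17", {
  seg17 <- small_seg17(); seg68 <- small_seg68()
  expect_setequal(unique(seg17$labels), 1:17)
  expect_setequal(unique(seg68$labels), 1:68)
  expect_true(all(seg17$labels == ceiling(seg68$labels / 4)))
  expect_equal(length(seg17$labels), nrow(small_mesh()$nodes))
})

test_that("CoGs equal brute-force surface means and lie in their bounding boxes", {
  mesh <- small_mesh(); seg17 <- small_seg17()
  ids <- intersect(which(seg17$labels == 1L), mesh$surface$endo)
  brute <- colMeans(mesh$nodes[ids, , drop = FALSE])
  row <- seg17$cog[seg17$cog$segment == 1 & seg17$cog$surface == "endo", ]
  expect_equal(c(row$x, row$y, row$z), unname(brute))

  for (s in c(3, 9, 17)) {
    for (surf in c("endo", "epi")) {
      ids <- intersect(which(seg17$labels == s), mesh$surface[[surf]])
      bb <- apply(mesh$nodes[ids, , drop = FALSE], 2, range)
      row <- seg17$cog[seg17$cog$segment == s & seg17$cog$surface == surf, ]
      xyz <- c(row$x, row$y, row$z)
      expect_true(all(xyz >= bb[1, ] - 1e-9 & xyz <= bb[2, ] + 1e-9))
    }
  }
})

test_that("segment adjacency is symmetric and irreflexive", {
  for (seg in list(small_seg17(), small_seg68())) {
    for (s in seq_len(seg$mode)) {
      expect_false(s %in% seg$adjacency[[s]])
      for (t_ in seg$adjacency[[s]]) {
        expect_true(s %in% seg$adjacency[[t_]])
      }
    }
  }
})

test_that("electrode placement honors the device geometry", {
  mesh <- small_mesh()
  es <- place_electrodes(mesh)
  expect_equal(nrow(es), 18L)
  tips <- as.matrix(es[match(paste0("LVtip", 1:4), es$name), c("x", "y", "z")])
  gaps <- sqrt(rowSums(diff(tips)^2))
  expect_equal(gaps, rep(7.5, 3))
  # collinear
  d1 <- diff(tips)[1, ] / sqrt(sum(diff(tips)[1, ]^2))
  for (r in 2:3) {
    dr <- diff(tips)[r, ] / sqrt(sum(diff(tips)[r, ]^2))
    expect_equal(abs(sum(d1 * dr)), 1, tolerance = 1e-9)
  }
  # CAN = LA
  expect_equal(unlist(es[es$name == "CAN", c("x", "y", "z")]),
               unlist(es[es$name == "LA", c("x", "y", "z")]),
               ignore_attr = TRUE)
  expect_error(place_electrodes(mesh, lv_tip_spacing = 0), "lv_tip_spacing")
})

test_that("electrode displacement is an exact invertible translation", {
  es <- place_electrodes(small_mesh())
  up <- displace_electrodes(es, c(0, 0, 50), which = "ecg")
  ecg <- es$type == "ecg"
  expect_equal(up$z[ecg], es$z[ecg] + 50)
  expect_equal(up$z[!ecg], es$z[!ecg])
  back <- displace_electrodes(up, c(0, 0, -50), which = "ecg")
  expect_equal(as.data.frame(back), as.data.frame(es))
})

test_that("pacing-site sampling is stratified, valid and reproducible", {
  mesh <- small_mesh(); uvc <- small_uvc()
  sites <- sample_pacing_sites(mesh, uvc, 100, c(0.32, 0.36, 0.32), seed = 11)
  expect_equal(as.vector(table(factor(sites$wall_class, c("endo", "mid", "epi")))),
               c(32, 36, 32))
  expect_true(all(sites$node %in% seq_len(nrow(mesh$nodes))))
  expect_true(all(is.finite(sites$uvc_z) & is.finite(sites$uvc_rho)))
  expect_true(all(sites$uvc_rho[sites$wall_class == "endo"] == 0))
  expect_true(all(sites$uvc_rho[sites$wall_class == "epi"] == 1))

  again <- sample_pacing_sites(mesh, uvc, 100, c(0.32, 0.36, 0.32), seed = 11)
  expect_identical(sites$node, again$node)
  other <- sample_pacing_sites(mesh, uvc, 100, c(0.32, 0.36, 0.32), seed = 12)
  expect_false(identical(sites$node, other$node))
})
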