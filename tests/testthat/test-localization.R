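test_that("probability-CoG combination handles degenerate and soft cases", {
  seg <- small_seg17()
  one_hot <- rep(0, 17); one_hot[5] <- 1

  # pure epicardial one-hot: exactly the epi CoG of segment 5
  out <- cartesian_combine(one_hot, c(0, 1), seg)
  cg <- seg$cog[seg$cog$segment == 5 & seg$cog$surface == "epi", ]
  expect_equal(out, c(cg$x, cg$y, cg$z))

  # 50/50 endo-epi: midpoint of the two CoGs
  out2 <- cartesian_combine(one_hot, c(0.5, 0.5), seg)
  ce <- seg$cog[seg$cog$segment == 5 & seg$cog$surface == "endo", ]
  expect_equal(out2, (c(cg$x, cg$y, cg$z) + c(ce$x, ce$y, ce$z)) / 2)

  expect_error(cartesian_combine(rep(1 / 68, 68), c(0.5, 0.5), seg), "17")
  bad <- one_hot; bad[5] <- 0.8
  expect_error(cartesian_combine(bad, c(0.5, 0.5), seg), "sum to 1")
})

test_that("probability-CoG combination equals an independent double sum", {
  seg <- small_seg17()
  set.seed(8)
  for (rep_ in 1:5) {
    p_seg <- rep(0, 17)
    top <- sample(17, 1)
    S <- sort(unique(c(top, seg$adjacency[[top]])))
    p_seg[S] <- runif(length(S))
    p_seg[top] <- max(p_seg) + 0.5   # ensure `top` is the argmax
    p_seg <- p_seg / sum(p_seg)
    p_ee <- runif(2); p_ee <- p_ee / sum(p_ee)

    got <- cartesian_combine(p_seg, p_ee, seg)

    # brute-force Eq. 1 over the restricted, renormalized candidate set
    brute <- c(0, 0, 0)
    for (i in S) {
      pi_ <- p_seg[i] / sum(p_seg[S])
      for (j in 1:2) {
        surf <- c("endo", "epi")[j]
        cg <- seg$cog[seg$cog$segment == i & seg$cog$surface == surf, ]
        brute <- brute + pi_ * p_ee[j] * c(cg$x, cg$y, cg$z)
      }
    }
    expect_equal(got, brute, tolerance = 1e-12)
  }
})

test_that("combined estimates stay inside the convex hull of participating CoGs", {
  seg <- small_seg17()
  set.seed(21)
  for (rep_ in 1:200) {
    p_seg <- runif(17)^3; p_seg <- p_seg / sum(p_seg)
    p_ee <- runif(2); p_ee <- p_ee / sum(p_ee)
    out <- cartesian_combine(p_seg, p_ee, seg)
    top <- which.max(p_seg)
    S <- sort(unique(c(top, seg$adjacency[[top]])))
    pts <- as.matrix(seg$cog[seg$cog$segment %in% S, c("x", "y", "z")])
    # convex-hull membership via its bounding-box + support-function check:
    # out must be a convex combination, so for every direction d,
    # min(d.p) <= d.out <= max(d.p)
    for (k in 1:10) {
      d <- rnorm(3)
      proj <- pts %*% d
      expect_gte(sum(out * d), min(proj) - 1e-9)
      expect_lte(sum(out * d), max(proj) + 1e-9)
    }
  }
})

test_that("UVC inversion is exact on mesh nodes and matches exhaustive search", {
  mesh <- small_mesh(); uvc <- small_uvc()
  # round trip on every mesh node
  pred <- uvc_to_cartesian(uvc, mesh, uvc)
  expect_equal(unname(pred), unname(mesh$nodes), tolerance = 1e-12)

  # z = 0 queries land within an edge length of the apex axis
  for (rho_q in c(0, 0.5, 1)) {
    p <- uvc_to_cartesian(c(0, rho_q, 1.2), mesh, uvc)
    d_axis <- sqrt(p[1]^2 + p[2]^2)
    expect_lt(d_axis, 1.5 * mesh$params$edge)
  }

  # brute-force metric scan agreement on random queries
  w <- vtloc:::uvc_metric_weights(mesh)
  r_node <- sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2)
  set.seed(13)
  for (rep_ in 1:20) {
    q <- c(runif(1), runif(1), runif(1, -pi, pi))
    got <- uvc_to_cartesian(q, mesh, uvc)
    d2 <- w[1] * (uvc$z - q[1])^2 + w[2] * (uvc$rho - q[2])^2 +
      (r_node * vtloc:::angle_diff(uvc$phi, q[3]))^2
    expect_equal(got, unname(mesh$nodes[which.min(d2), ]))
  }
})

test_that("localization error is the Euclidean distance, symmetric, zero at identity", {
  expect_equal(localization_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(localization_error(c(0, 0, 0), c(3, 4, 0)), 5)
  a <- c(-2, 7, 1); b <- c(4, 0, -5)
  expect_equal(localization_error(a, b), localization_error(b, a))
  expect_error(localization_error(c(NA, 0, 0), c(0, 0, 0)), "finite")
})

test_that("classifier scoring reproduces a hand-counted toy case", {
  sc <- score_segment_classifier(c(1, 2, 2), c(1, 1, 2), n_classes = 3)
  expect_equal(sc$accuracy, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(sc$precision$precision[1], 1)
  expect_equal(sc$precision$precision[2], 0.5)
  expect_true(is.na(sc$precision$precision[3]))  # never predicted -> missing

  perm <- sample(3)
  sc2 <- score_segment_classifier(c(1, 2, 2)[perm], c(1, 1, 2)[perm], 3)
  expect_equal(sc2$accuracy, sc$accuracy)
  expect_equal(sc2$precision, sc$precision)
  expect_error(score_segment_classifier(1:3, 1:4, 4), "length")
})

test_that("bull's-eye coordinates map apex to center, base to rim, rho to color", {
  b <- bullseye_coords(tibble::tibble(z = c(0, 1, 0.5, 0.5),
                                      rho = c(0, 1, 0.2, 0.9),
                                      phi = c(0, 1, -2, -2)))
  expect_equal(b$r[1], 0)
  expect_equal(b$r[2], 1)
  # two points differing only in rho share a position
  expect_equal(b$r[3], b$r[4]); expect_equal(b$theta[3], b$theta[4])
  expect_false(b$rho[3] == b$rho[4])
})
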