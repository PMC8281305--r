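# Shared fixtures, memoized so expensive geometry is built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# Coarse LV testbed used by most module tests (~1k nodes).
small_mesh <- function() memo("small_mesh", function() {
  assign_fibers(build_lv_mesh(geometry_params(edge = 8)))
})

small_uvc <- function() memo("small_uvc", function() compute_uvc(small_mesh()))

small_seg17 <- function() memo("small_seg17", function() {
  build_segment_model(small_mesh(), small_uvc(), 17)
})

small_seg68 <- function() memo("small_seg68", function() {
  build_segment_model(small_mesh(), small_uvc(), 68)
})

small_cond <- function() memo("small_cond", function() {
  prepare_conduction(small_mesh(), ep_params())
})

small_lf <- function() memo("small_lf", function() {
  compute_lead_field(small_mesh(), place_electrodes(small_mesh()), 0.2)
})

# Medium mesh for resolution/convergence checks.
medium_mesh <- function() memo("medium_mesh", function() {
  assign_fibers(build_lv_mesh(geometry_params(edge = 4)))
})

# A straight rod along +x as a pure 1-D chain graph (node k at (k*spacing,
# 0, 0), edges only between consecutive nodes), with a constant fiber
# direction. The chain has no oblique edges, so travel times across it probe
# the anisotropic velocity profile in a single direction.
rod_mesh <- function(n_seg = 10, spacing = 1, fiber_dir = c(1, 0, 0)) {
  nodes <- cbind(seq(0, n_seg) * spacing, 0, 0)
  f <- fiber_dir / sqrt(sum(fiber_dir^2))
  edges <- list(i = seq_len(n_seg), j = seq_len(n_seg) + 1L,
                len = rep(spacing, n_seg),
                fiber = matrix(rep(f, n_seg), ncol = 3L, byrow = TRUE))
  structure(list(nodes = nodes, elems = matrix(integer(0), 0, 4),
                 fiber = matrix(f, 1, 3), custom_edges = edges),
            class = "vt_mesh")
}

# Independent O(n^2) Dijkstra on an undirected edge list; the oracle for the
# eikonal solver.
oracle_dijkstra <- function(n, ei, ej, w, source) {
  adj <- vector("list", n)
  for (k in seq_along(ei)) {
    adj[[ei[k]]] <- rbind(adj[[ei[k]]], c(ej[k], w[k]))
    adj[[ej[k]]] <- rbind(adj[[ej[k]]], c(ei[k], w[k]))
  }
  dist <- rep(Inf, n); dist[source] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1L]
      if (dist[u] + nb[r, 2L] < dist[v]) dist[v] <- dist[u] + nb[r, 2L]
    }
  }
  dist
}

# Random electrode traces keyed by name, for channel-arithmetic tests.
random_traces <- function(names, n_t = 40, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(length(names) * n_t), length(names), n_t,
              dimnames = list(names, NULL))
  structure(m, times = seq(0, by = 0.5, length.out = n_t),
            class = c("vt_traces", "matrix", "array"))
}

# Tiny simulated beat set shared by dataset/network/experiment tests.
small_beats <- function() memo("small_beats", function() {
  mesh <- small_mesh(); uvc <- small_uvc()
  sites <- sample_pacing_sites(mesh, uvc, 120, seed = 7)
  simulate_beats(sites, small_cond(), small_lf(), small_seg17())
})
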