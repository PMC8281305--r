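#' Sample focal pacing sites stratified by wall depth
#'
#' Sites are mesh nodes. Wall classes follow the transmural coordinate:
#' endocardial surface nodes (`rho = 0`), epicardial surface nodes
#' (`rho = 1`), and intramural/mid-wall nodes (everything in between).
#' Within each class, nodes are drawn without replacement with probability
#' proportional to their lumped volume share (sum of adjacent element
#' volumes), which makes the spatial coverage approximately uniform even
#' where the structured mesh crowds nodes (near the apex pole).
#'
#' @param mesh A `vt_mesh`.
#' @param uvc Output of [compute_uvc()].
#' @param n Total number of sites (>= 3).
#' @param proportions Named or positional fractions `(endo, mid, epi)`
#'   summing to 1. Counts are allocated by largest remainder so they sum to
#'   `n` exactly.
#' @param seed Integer seed (mandatory for reproducibility).
#'
#' @return A tibble: `site`, `node`, `x`, `y`, `z`, `uvc_z`, `uvc_rho`,
#'   `uvc_phi`, `wall_class`.
#' @export
sample_pacing_sites <- function(mesh, uvc, n, proportions = c(endo = 0.32, mid = 0.36, epi = 0.32),
                                seed = 1L) {
  stopifnot(inherits(mesh, "vt_mesh"), inherits(uvc, "vt_uvc"))
  if (n < 3) abort("`n` must be >= 3")
  pr <- as.numeric(proportions)
  if (length(pr) != 3L || abs(sum(pr) - 1) > 1e-8 || any(pr < 0)) {
    abort("`proportions` must be three nonnegative fractions (endo, mid, epi) summing to 1")
  }

  cls <- rep("mid", nrow(mesh$nodes))
  cls[mesh$surface$endo] <- "endo"
  cls[mesh$surface$epi] <- "epi"

  # largest-remainder allocation
  raw <- n * pr
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    order_rem <- order(raw - cnt, decreasing = TRUE)
    cnt[order_rem[seq_len(rem)]] <- cnt[order_rem[seq_len(rem)]] + 1
  }
  names(cnt) <- c("endo", "mid", "epi")

  # lumped nodal volume weights
  wt <- numeric(nrow(mesh$nodes))
  for (k in 1:4) {
    acc <- rowsum(mesh$vol / 4, mesh$elems[, k])
    wt[as.integer(rownames(acc))] <- wt[as.integer(rownames(acc))] + acc[, 1L]
  }

  with_seed(seed, {
    rows <- lapply(c("endo", "mid", "epi"), function(cl) {
      pool <- which(cls == cl)
      need <- cnt[[cl]]
      if (need == 0L) return(integer(0))
      if (length(pool) == 0L) abort(sprintf("no candidate nodes for wall class `%s`", cl))
      if (length(pool) < need) abort(sprintf("wall class `%s` has %d nodes, %d requested",
                                             cl, length(pool), need))
      sample(pool, need, prob = wt[pool])
    })
    nodes_sel <- unlist(rows)
    tibble(
      site = seq_along(nodes_sel),
      node = nodes_sel,
      x = mesh$nodes[nodes_sel, 1L], y = mesh$nodes[nodes_sel, 2L],
      z = mesh$nodes[nodes_sel, 3L],
      uvc_z = uvc$z[nodes_sel], uvc_rho = uvc$rho[nodes_sel],
      uvc_phi = uvc$phi[nodes_sel],
      wall_class = rep(c("endo", "mid", "epi"), times = c(cnt[["endo"]], cnt[["mid"]], cnt[["epi"]]))
    )
  })
}
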