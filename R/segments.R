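#' Build the AHA 17- or 68-segment model of the LV
#'
#' Seventeen segments follow the standard AHA layout expressed in ventricular
#' coordinates: basal ring `z in [2/3, 1]` and mid ring `z in [1/3, 2/3)` are
#' each cut into six 60-degree sectors, the apical ring `z in [z_cap, 1/3)`
#' into four 90-degree sectors, and `z < z_cap` forms the apex cap
#' (segment 17). The 68-segment variant quarters every segment by halving
#' its z range and its phi range (the cap is split into four phi quadrants),
#' so that `seg17 = ceiling(seg68 / 4)`.
#'
#' The phi origin sits at the configured septal reference direction; sector
#' boundaries are fixed at multiples of 60 degrees (90 for apical) from
#' `phi = -pi`. Centers of gravity (CoG) are plain means of each segment's
#' endocardial and epicardial surface-node coordinates; adjacency links
#' segments that share a mesh edge.
#'
#' @param mesh A `vt_mesh`.
#' @param uvc Output of [compute_uvc()] for `mesh`.
#' @param mode 17 or 68.
#' @param z_cap Apex-cap boundary in z (default 0.1).
#'
#' @return A `vt_segments` object: `labels` (per node, for `mode`), the
#'   underlying `seg17`/`seg68` vectors, a `cog` tibble
#'   (`segment`, `surface`, `x`, `y`, `z`), and an `adjacency` list.
#' @export
build_segment_model <- function(mesh, uvc, mode = 17, z_cap = 0.1) {
  stopifnot(inherits(mesh, "vt_mesh"), inherits(uvc, "vt_uvc"))
  mode <- as.integer(mode)
  if (!mode %in% c(17L, 68L)) abort("`mode` must be 17 or 68")
  z <- uvc$z; phi <- uvc$phi
  n <- length(z)

  sector <- function(phi, k) {  # k equal sectors over (-pi, pi], 1-based
    s <- 1L + as.integer(floor((phi + pi) / (2 * pi / k)))
    pmin(pmax(s, 1L), k)
  }
  ring <- ifelse(z >= 2 / 3, "basal", ifelse(z >= 1 / 3, "mid",
                 ifelse(z >= z_cap, "apical", "cap")))
  seg17 <- integer(n)
  seg17[ring == "basal"] <- sector(phi[ring == "basal"], 6L)
  seg17[ring == "mid"] <- 6L + sector(phi[ring == "mid"], 6L)
  seg17[ring == "apical"] <- 12L + sector(phi[ring == "apical"], 4L)
  seg17[ring == "cap"] <- 17L

  # quarter each segment: z lower/upper half x phi lower/upper half
  z_lo <- ifelse(ring == "basal", 2 / 3, ifelse(ring == "mid", 1 / 3,
                 ifelse(ring == "apical", z_cap, 0)))
  z_hi <- ifelse(ring == "basal", 1, ifelse(ring == "mid", 2 / 3,
                 ifelse(ring == "apical", 1 / 3, z_cap)))
  z_upper <- as.integer(z >= (z_lo + z_hi) / 2)
  n_sec <- ifelse(ring == "basal" | ring == "mid", 6L, 4L)
  sec_width <- 2 * pi / n_sec
  sec_idx <- ifelse(ring == "cap", sector(phi, 4L),
                    ifelse(ring %in% c("basal", "mid"), sector(phi, 6L), sector(phi, 4L)))
  phi_lo <- -pi + (sec_idx - 1L) * sec_width
  phi_upper <- as.integer(phi >= phi_lo + sec_width / 2)
  quarter <- ifelse(ring == "cap",
                    sector(phi, 4L),                      # cap: 4 phi quadrants
                    1L + phi_upper + 2L * z_upper)
  seg68 <- (seg17 - 1L) * 4L + as.integer(quarter)

  labels <- if (mode == 17L) seg17 else seg68
  n_seg <- mode

  missing <- setdiff(seq_len(n_seg), unique(labels))
  if (length(missing) > 0L) {
    abort(sprintf("empty segment label(s) at mode %d (mesh too coarse): %s",
                  mode, paste(missing, collapse = ", ")))
  }

  cog_rows <- list()
  for (s in seq_len(n_seg)) {
    for (surf in c("endo", "epi")) {
      ids <- intersect(which(labels == s), mesh$surface[[surf]])
      if (length(ids) == 0L) {
        abort(sprintf("segment %d has no %scardial surface nodes (mesh too coarse)", s, surf))
      }
      xyz <- colMeans(mesh$nodes[ids, , drop = FALSE])
      cog_rows[[length(cog_rows) + 1L]] <-
        tibble(segment = s, surface = surf, x = xyz[1L], y = xyz[2L], z = xyz[3L])
    }
  }
  cog <- dplyr::bind_rows(cog_rows)

  ed <- mesh_edges(mesh)
  li <- labels[ed$i]; lj <- labels[ed$j]
  diffp <- li != lj
  pairs <- unique(cbind(pmin(li[diffp], lj[diffp]), pmax(li[diffp], lj[diffp])))
  adjacency <- lapply(seq_len(n_seg), function(s) {
    sort(unique(c(pairs[pairs[, 1L] == s, 2L], pairs[pairs[, 2L] == s, 1L])))
  })

  structure(list(mode = n_seg, labels = labels, seg17 = seg17, seg68 = seg68,
                 cog = cog, adjacency = adjacency, z_cap = z_cap),
            class = "vt_segments")
}

#' @export
print.vt_segments <- function(x, ...) {
  cat(sprintf("<vt_segments> AHA %d-segment model; %d labelled nodes\n",
              x$mode, length(x$labels)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.vt_segments <- function(x, ...) x$cog

# CoG lookup as matrices keyed by segment, one row per segment.
cog_matrix <- function(segmodel, surface) {
  sub <- segmodel$cog[segmodel$cog$surface == surface, ]
  sub <- sub[order(sub$segment), ]
  as.matrix(sub[, c("x", "y", "z")])
}
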