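#' Write the mesh (with optional point data) as legacy ASCII VTK
#'
#' Unstructured grid with tetrahedral cells. Point-data arrays written by
#' default: `uvc_z`, `uvc_rho`, `uvc_phi` (when `uvc` is supplied),
#' `seg17`, `seg68` (when `segmodel` is supplied), `surface_label` coded as
#' integers (0 interior, 1 endo, 2 epi, 3 base), and any extra named arrays
#' in `point_data` (e.g. an activation map).
#'
#' @param mesh A `vt_mesh`.
#' @param path Output `.vtk` path.
#' @param uvc Optional `vt_uvc`.
#' @param segmodel Optional `vt_segments`.
#' @param point_data Optional named list of per-node numeric vectors.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, uvc = NULL, segmodel = NULL, point_data = list()) {
  stopifnot(inherits(mesh, "vt_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "synthetic truncated-ellipsoid LV",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(mesh$nodes, digits = 15, scientific = FALSE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  utils::write.table(cbind(4L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)

  arrays <- point_data
  if (!is.null(uvc)) {
    arrays$uvc_z <- uvc$z; arrays$uvc_rho <- uvc$rho; arrays$uvc_phi <- uvc$phi
  }
  if (!is.null(segmodel)) {
    arrays$seg17 <- segmodel$seg17; arrays$seg68 <- segmodel$seg68
  }
  lab <- match(mesh$surface_label, c("endo", "epi", "base"))
  lab[is.na(lab)] <- 0L
  arrays$surface_label <- lab
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in names(arrays)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(format(arrays[[nm]], digits = 15, scientific = FALSE, trim = TRUE), con)
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid written by [write_mesh_vtk()]
#'
#' @param path `.vtk` file path.
#' @return List with `nodes`, `elems`, and `point_data` (named list).
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  ipt <- grep("^POINTS", lines)[1L]
  n <- as.integer(strsplit(lines[ipt], "\\s+")[[1L]][2L])
  nodes <- matrix(scan(text = lines[(ipt + 1L):(ipt + n)], quiet = TRUE),
                  ncol = 3L, byrow = TRUE)
  icl <- grep("^CELLS", lines)[1L]
  m <- as.integer(strsplit(lines[icl], "\\s+")[[1L]][2L])
  cells <- matrix(scan(text = lines[(icl + 1L):(icl + m)], quiet = TRUE),
                  ncol = 5L, byrow = TRUE)
  elems <- cells[, 2:5, drop = FALSE] + 1L
  storage.mode(elems) <- "integer"
  point_data <- list()
  isc <- grep("^SCALARS", lines)
  for (i in isc) {
    nm <- strsplit(lines[i], "\\s+")[[1L]][2L]
    point_data[[nm]] <- scan(text = lines[(i + 2L):(i + 1L + n)], quiet = TRUE)
  }
  list(nodes = nodes, elems = elems, point_data = point_data)
}

#' Save / load a trained model with a metadata sidecar
#'
#' The weights go into an RDS container; a small YAML sidecar records the
#' task, modality, seed and training configuration so checkpoints are
#' self-describing.
#'
#' @param model A `vt_model`.
#' @param path Base path; writes `<path>.rds` and `<path>.yaml`.
#' @return `path` (writer) / the model (reader), invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "vt_model"))
  saveRDS(model, paste0(path, ".rds"))
  yaml::write_yaml(list(task = model$task, modality = model$modality,
                        seed = model$seed,
                        spec = model$spec[c("conv1", "conv2", "fc", "lr", "batch", "epochs", "loss")],
                        final_loss = utils::tail(model$history$loss, 1L)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_model
#' @param path Base path used by [save_model()].
#' @export
load_model <- function(path) readRDS(paste0(path, ".rds"))
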