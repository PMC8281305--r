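#' Place the ECG and implanted-device (CIED) electrodes
#'
#' Nine ECG electrodes (limb RA/LA/LL plus precordial V1-V6) are laid out at
#' torso scale around the LV mesh (the heart sits with its base at z = 0 and
#' apex at negative z; +x is septal, +y anterior). Nine CIED sensing points
#' comprise an RV lead (tip, ring, coil) near the septal wall, an SVC coil
#' above the base, the device can (CAN, coincident with LA by convention),
#' and four collinear LV lead tips along the lateral epicardium spaced
#' `lv_tip_spacing` millimetres apart.
#'
#' All coordinates are deterministic functions of the parameters.
#'
#' @param mesh A `vt_mesh` used to anchor the CIED lead positions.
#' @param lv_tip_spacing Spacing of the four LV tips in mm (default 7.5).
#'
#' @return A `vt_electrodes` tibble with columns `name`, `x`, `y`, `z`,
#'   `type` (`"ecg"` or `"cied"`), carrying `lv_tip_spacing` as an attribute.
#' @export
place_electrodes <- function(mesh, lv_tip_spacing = 7.5) {
  stopifnot(inherits(mesh, "vt_mesh"))
  if (!is.numeric(lv_tip_spacing) || lv_tip_spacing <= 0) {
    abort("`lv_tip_spacing` must be > 0")
  }
  a_epi <- mesh$params$epi_short; c_epi <- mesh$params$epi_long

  # precordial arc, anterior chest; angles from the septal (+x) axis
  ang <- c(25, 45, 65, 85, 105, 125) * pi / 180
  rad <- 115
  prec <- tibble(
    name = paste0("V", 1:6),
    x = rad * cos(ang), y = rad * sin(ang),
    z = -35 - 5 * seq(0, 5), type = "ecg"
  )
  limb <- tibble(
    name = c("RA", "LA", "LL"),
    x = c(-170, 170, 80), y = c(40, 40, 30), z = c(80, 80, -350),
    type = "ecg"
  )

  la <- c(170, 40, 80)
  epi_radius <- function(z) a_epi * sqrt(pmax(0, 1 - (z / c_epi)^2))
  radial <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180), 0)
  # RV lead stands in for the RV cavity: it hugs the septal wall but runs
  # slightly anterior (+y), as a transvenous apical lead does
  z_tip <- -0.60 * c_epi; z_ring <- -0.50 * c_epi; z_coil <- -0.35 * c_epi
  rv_pt <- function(z, deg, clear) (epi_radius(z) + clear) * radial(deg) + c(0, 0, z)
  p_tip <- rv_pt(z_tip, 20, 4); p_ring <- rv_pt(z_ring, 20, 4); p_coil <- rv_pt(z_coil, 10, 6)
  # LV lead reaches the posterolateral wall through a coronary-sinus branch:
  # a straight line of four tips at azimuth ~215 deg, tilted toward the apex
  # so the clearance to the wall stays roughly constant
  u_lv <- radial(215)
  lv_anchor <- (epi_radius(-0.45 * c_epi) + 5) * u_lv + c(0, 0, -0.45 * c_epi)
  lv_dir <- 0.25 * u_lv + c(0, 0, -1); lv_dir <- lv_dir / sqrt(sum(lv_dir^2))
  tips <- t(vapply(0:3, function(i) lv_anchor + i * lv_tip_spacing * lv_dir,
                   numeric(3)))
  cied <- tibble(
    name = c("RVtip", "RVring", "RVcoil", "SVC", "CAN",
             paste0("LVtip", 1:4)),
    x = c(p_tip[1], p_ring[1], p_coil[1], 20, la[1], tips[, 1]),
    y = c(p_tip[2], p_ring[2], p_coil[2], 10, la[2], tips[, 2]),
    z = c(p_tip[3], p_ring[3], p_coil[3], 60, la[3], tips[, 3]),
    type = "cied"
  )

  es <- dplyr::bind_rows(limb, prec, cied)
  structure(es, lv_tip_spacing = lv_tip_spacing,
            class = c("vt_electrodes", class(tibble())))
}

electrode_xyz <- function(electrodes, name) {
  row <- electrodes[electrodes$name == name, ]
  if (nrow(row) != 1L) abort(sprintf("electrode `%s` missing", name))
  c(row$x, row$y, row$z)
}

#' Displace a subset of electrodes by a fixed translation
#'
#' Used by the placement-sensitivity scenarios; a displacement followed by
#' its inverse restores the original coordinates exactly.
#'
#' @param electrodes A `vt_electrodes` tibble.
#' @param shift Numeric length-3 translation in mm.
#' @param which `"ecg"`, `"cied"`, `"all"`, or a character vector of names.
#' @return The displaced `vt_electrodes`.
#' @export
displace_electrodes <- function(electrodes, shift, which = "ecg") {
  stopifnot(inherits(electrodes, "vt_electrodes"), length(shift) == 3L)
  sel <- if (identical(which, "all")) rep(TRUE, nrow(electrodes))
  else if (length(which) == 1L && which %in% c("ecg", "cied")) electrodes$type == which
  else electrodes$name %in% which
  electrodes$x[sel] <- electrodes$x[sel] + shift[1L]
  electrodes$y[sel] <- electrodes$y[sel] + shift[2L]
  electrodes$z[sel] <- electrodes$z[sel] + shift[3L]
  electrodes
}

#' Write an electrode set as a delimited table (name, x, y, z in mm)
#' @param electrodes A `vt_electrodes` tibble.
#' @param path Output CSV path.
#' @export
write_electrodes_csv <- function(electrodes, path) {
  utils::write.csv(as.data.frame(electrodes[, c("name", "x", "y", "z")]),
                   path, row.names = FALSE)
  invisible(path)
}

ecg_names <- function() c("RA", "LA", "LL", paste0("V", 1:6))
cied_names <- function() c("RVtip", "RVring", "RVcoil", "SVC", "CAN", paste0("LVtip", 1:4))
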