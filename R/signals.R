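# Fixed, documented channel orders of the two 16-channel modalities.

#' Channel order of the ECG modality
#' @return Character vector of the 16 ECG channel names.
#' @export
ecg_channel_order <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6),
    "LL-RA-LA", "LA-RA-LL", "RA-LA-LL", "avg(RA,LA,LL)")
}

#' Channel order of the EGM modality
#' @return Character vector of the 16 EGM channel names.
#' @export
egm_channel_order <- function() {
  c("CAN-SVC", "CAN-RVcoil", "SVC-RVcoil", "RVtip-RVring",
    paste0("LVtip", 1:4, "-RVtip"),
    paste0("CAN-LVtip", 1:4),
    paste0("SVC-LVtip", 1:4))
}

trace_row <- function(traces, name) {
  if (!name %in% rownames(traces)) abort(sprintf("missing electrode `%s` in traces", name))
  traces[name, ]
}

#' Derive the 16 ECG channels from the nine electrode potentials
#'
#' Channels 1-12 are the standard leads (Einthoven I/II/III, Goldberger
#' augmented leads, V1-V6 referenced to the Wilson central terminal
#' `(RA + LA + LL)/3`). Channels 13-16 are the four extra combinations
#' completing the square matrix, implemented as literal electrode
#' arithmetic: `LL - RA - LA`, `LA - RA - LL`, `RA - LA - LL`, and
#' `(RA + LA + LL)/2`.
#'
#' @param traces A `vt_traces` matrix containing RA, LA, LL, V1-V6.
#' @return A 16 x n_times matrix in [ecg_channel_order()].
#' @export
derive_ecg_channels <- function(traces) {
  ra <- trace_row(traces, "RA"); la <- trace_row(traces, "LA"); ll <- trace_row(traces, "LL")
  wct <- (ra + la + ll) / 3
  ch <- rbind(
    I = la - ra, II = ll - ra, III = ll - la,
    aVR = ra - (la + ll) / 2, aVL = la - (ra + ll) / 2, aVF = ll - (ra + la) / 2,
    V1 = trace_row(traces, "V1") - wct, V2 = trace_row(traces, "V2") - wct,
    V3 = trace_row(traces, "V3") - wct, V4 = trace_row(traces, "V4") - wct,
    V5 = trace_row(traces, "V5") - wct, V6 = trace_row(traces, "V6") - wct,
    `LL-RA-LA` = ll - ra - la, `LA-RA-LL` = la - ra - ll,
    `RA-LA-LL` = ra - la - ll, `avg(RA,LA,LL)` = (ra + la + ll) / 2
  )
  structure(ch, times = attr(traces, "times"), class = c("vt_channels", "matrix", "array"))
}

#' Derive the 16 EGM channels from the nine CIED sensing points
#'
#' Far-field vectors CAN-SVC, CAN-RVcoil, SVC-RVcoil; near-field
#' RVtip-RVring and LVtip_i-RVtip; plus the additional CAN-LVtip_i and
#' SVC-LVtip_i combinations — 16 channels in total.
#'
#' @param traces A `vt_traces` matrix containing the CIED electrodes.
#' @return A 16 x n_times matrix in [egm_channel_order()].
#' @export
derive_egm_channels <- function(traces) {
  g <- function(nm) trace_row(traces, nm)
  can <- g("CAN"); svc <- g("SVC"); rvt <- g("RVtip")
  ch <- rbind(
    `CAN-SVC` = can - svc, `CAN-RVcoil` = can - g("RVcoil"),
    `SVC-RVcoil` = svc - g("RVcoil"), `RVtip-RVring` = rvt - g("RVring"),
    `LVtip1-RVtip` = g("LVtip1") - rvt, `LVtip2-RVtip` = g("LVtip2") - rvt,
    `LVtip3-RVtip` = g("LVtip3") - rvt, `LVtip4-RVtip` = g("LVtip4") - rvt,
    `CAN-LVtip1` = can - g("LVtip1"), `CAN-LVtip2` = can - g("LVtip2"),
    `CAN-LVtip3` = can - g("LVtip3"), `CAN-LVtip4` = can - g("LVtip4"),
    `SVC-LVtip1` = svc - g("LVtip1"), `SVC-LVtip2` = svc - g("LVtip2"),
    `SVC-LVtip3` = svc - g("LVtip3"), `SVC-LVtip4` = svc - g("LVtip4")
  )
  structure(ch, times = attr(traces, "times"), class = c("vt_channels", "matrix", "array"))
}

#' Extract the QRS window from channel traces
#'
#' Simulated beats need no QRS detector: ventricular activation spans
#' `[0, max(tau) + upstroke]`, so the window is
#' `[0, max(tau) + upstroke + margin]`, applied identically to all channels
#' of a beat.
#'
#' @param channels A channels matrix (rows = channels) with a `times` attribute.
#' @param max_tau Latest activation time of the beat (ms), or a
#'   `vt_activation`.
#' @param upstroke Template upstroke duration (ms).
#' @param margin Extra window padding (ms, >= 0).
#' @return The windowed channels matrix.
#' @export
extract_qrs <- function(channels, max_tau, upstroke = 1, margin = 2) {
  if (inherits(max_tau, "vt_activation")) max_tau <- max(max_tau$tau)
  if (margin < 0) abort("`margin` must be >= 0")
  times <- attr(channels, "times")
  t_end <- max_tau + upstroke + margin
  if (t_end > max(times) + 1e-9) {
    abort("QRS window exceeds the simulated duration")
  }
  keep <- times <= t_end + 1e-9
  out <- channels[, keep, drop = FALSE]
  structure(out, times = times[keep], class = class(channels))
}

#' Resample each channel to 16 uniformly spaced time points
#'
#' Linear interpolation at 16 points spanning the window inclusive of both
#' endpoints. A 16-sample trace already on the uniform grid is returned
#' unchanged.
#'
#' @param channels Channels matrix with `times` attribute (>= 2 samples).
#' @return Channels x 16 matrix.
#' @export
resample_16 <- function(channels) {
  times <- attr(channels, "times")
  if (is.null(times) || length(times) < 2L) abort("trace must have >= 2 samples")
  grid <- seq(times[1L], times[length(times)], length.out = 16L)
  out <- t(apply(channels, 1L, function(y) approx(times, y, xout = grid)$y))
  rownames(out) <- rownames(channels)
  structure(out, times = grid, class = class(channels))
}

#' Assemble a 16 x 16 signal matrix
#'
#' Stores both the raw (pre-normalization) values and the max-abs-normalized
#' values (`max(abs(values)) == 1`). Noise, when requested later, is added
#' to the raw values and the matrix re-normalized, matching the contract
#' that noise precedes normalization.
#'
#' @param values16 16 x 16 numeric matrix (channels x time samples).
#' @param modality `"ecg"` or `"egm"`.
#' @param snr_db Noise level already applied, or `NULL` for clean.
#' @return A `vt_signal_matrix`.
#' @export
signal_matrix <- function(values16, modality, snr_db = NULL) {
  if (!all(dim(values16) == c(16L, 16L))) abort("signal matrix must be 16 x 16")
  modality <- match.arg(modality, c("ecg", "egm"))
  peak <- max(abs(values16))
  if (peak == 0) abort("signal matrix is identically zero")
  structure(list(values = values16 / peak, raw = values16, normalization = peak,
                 modality = modality,
                 channel_order = if (modality == "ecg") ecg_channel_order() else egm_channel_order(),
                 snr_db = snr_db),
            class = "vt_signal_matrix")
}

#' @export
print.vt_signal_matrix <- function(x, ...) {
  cat(sprintf("<vt_signal_matrix> %s, 16 x 16, %s\n", x$modality,
              if (is.null(x$snr_db)) "clean" else sprintf("SNR %g dB", x$snr_db)))
  invisible(x)
}

#' Add per-channel white Gaussian noise at a target SNR
#'
#' Noise variance per channel is `signal_power / 10^(snr_db/10)` with the
#' signal power taken as the mean square of the clean channel. Zero-power
#' channels receive no noise. `snr_db = Inf` returns the input unchanged.
#'
#' @param x A `vt_signal_matrix`, a channels matrix, or a plain matrix
#'   (rows = channels).
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param seed Optional integer seed (the operation otherwise consumes the
#'   caller's RNG stream).
#' @return Noisy copy of `x` (re-normalized when `x` is a
#'   `vt_signal_matrix`).
#' @export
add_noise <- function(x, snr_db, seed = NULL) {
  if (inherits(x, "vt_signal_matrix")) {
    noisy <- add_noise(x$raw, snr_db, seed)
    out <- signal_matrix(noisy, x$modality, snr_db = snr_db)
    return(out)
  }
  if (is.infinite(snr_db)) return(x)
  pw <- rowMeans(x^2)
  if (any(pw == 0)) inform("add_noise: zero-power channel(s) left noise-free")
  sd_noise <- sqrt(pw / 10^(snr_db / 10))
  noise_mat <- with_seed(seed, {
    matrix(rnorm(length(x)), nrow(x), ncol(x)) * sd_noise
  })
  out <- x + noise_mat
  attributes(out) <- attributes(x)
  out
}

#' Map the rotational coordinate phi to one of 68 equal wedges (and back)
#'
#' Wedge `k` covers `[-pi + (k-1) d, -pi + k d)` with `d = 2 pi / 68`
#' (0.09 rad to two decimals); `phi = pi` belongs to wedge 68.
#' `wedge_to_phi()` returns the interval midpoint.
#'
#' @param phi Angles in `[-pi, pi]`.
#' @return Integer classes 1..68.
#' @export
phi_to_wedge <- function(phi) {
  if (any(phi < -pi - 1e-9 | phi > pi + 1e-9)) abort("phi outside [-pi, pi]")
  d <- 2 * pi / 68
  k <- 1L + as.integer(floor((phi + pi) / d))
  pmin(pmax(k, 1L), 68L)
}

#' @rdname phi_to_wedge
#' @param wedge Integer classes 1..68.
#' @export
wedge_to_phi <- function(wedge) {
  if (any(wedge < 1L | wedge > 68L)) abort("wedge class outside 1..68")
  d <- 2 * pi / 68
  -pi + (wedge - 0.5) * d
}
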