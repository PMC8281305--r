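#' Simulate paced beats and encode them as 16 x 16 signal matrices
#'
#' For every pacing site: solve the anisotropic eikonal activation, render
#' the electrode potentials through the lead field, derive the 16 ECG and
#' 16 EGM channels, window the QRS, resample to 16 time points and store
#' both modality matrices together with the site's labels (AHA segments,
#' wall class, phi wedge).
#'
#' @param sites Pacing sites from [sample_pacing_sites()].
#' @param cond A `vt_conduction` (mesh + EP parameters).
#' @param lf A `vt_leadfield` built on the same mesh.
#' @param segmodel A `vt_segments` (provides both seg17 and seg68 labels).
#' @param template An `vt_ap_template`.
#' @param margin QRS window padding, ms.
#' @param chunk Number of sources per multi-source eikonal batch.
#' @param progress Emit a message every chunk.
#'
#' @return A `vt_beats` tibble: one row per beat with site coordinates,
#'   labels and list-columns `ecg`/`egm` of `vt_signal_matrix`.
#' @export
simulate_beats <- function(sites, cond, lf, segmodel, template = ap_template(),
                           margin = 2, chunk = 200L, progress = FALSE) {
  stopifnot(inherits(cond, "vt_conduction"), inherits(lf, "vt_leadfield"),
            inherits(segmodel, "vt_segments"))
  n <- nrow(sites)
  ecg_list <- vector("list", n); egm_list <- vector("list", n)
  max_tau <- numeric(n)
  idx_chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  for (ch in idx_chunks) {
    taus <- solve_activation_many(cond, sites$node[ch])
    for (q in seq_along(ch)) {
      i <- ch[q]
      tau <- taus[q, ]
      max_tau[i] <- max(tau)
      tr <- beat_traces(lf, tau, template,
                        duration = max(tau) + template$upstroke + margin,
                        sigma_intra = cond$ep$sigma_intra)
      ecg_ch <- resample_16(extract_qrs(derive_ecg_channels(tr), max(tau),
                                        template$upstroke, margin))
      egm_ch <- resample_16(extract_qrs(derive_egm_channels(tr), max(tau),
                                        template$upstroke, margin))
      ecg_list[[i]] <- signal_matrix(unclass_mat(ecg_ch), "ecg")
      egm_list[[i]] <- signal_matrix(unclass_mat(egm_ch), "egm")
    }
    if (progress) inform(sprintf("simulated %d / %d beats", max(ch), n))
  }
  out <- sites
  out$beat <- seq_len(n)
  out$seg17 <- segmodel$seg17[sites$node]
  out$seg68 <- segmodel$seg68[sites$node]
  out$wedge <- phi_to_wedge(sites$uvc_phi)
  out$max_tau <- max_tau
  out$ecg <- ecg_list
  out$egm <- egm_list
  structure(out, class = c("vt_beats", class(tibble())))
}

unclass_mat <- function(x) {
  attr(x, "times") <- NULL
  class(x) <- NULL
  x
}

#' Split simulated beats into train and test sets
#'
#' Random disjoint split, reproducible per seed. Use
#' [epiendo_training_view()] to obtain the surface-only subset required for
#' training the endo/epi classifier.
#'
#' @param beats A `vt_beats` tibble.
#' @param n_train,n_test Split sizes (`n_train + n_test <= nrow(beats)`).
#' @param seed Integer seed.
#' @return A `vt_dataset` tibble with a `split` column.
#' @export
build_dataset <- function(beats, n_train, n_test, seed = 1L) {
  if (n_train + n_test > nrow(beats)) abort("insufficient beats for the requested split")
  idx <- with_seed(seed, sample(nrow(beats), n_train + n_test))
  out <- beats[idx, ]
  out$split <- rep(c("train", "test"), times = c(n_train, n_test))
  out$parent <- out$beat
  attr(out, "seed") <- seed
  attr(out, "augmentation") <- 1L
  structure(out, class = c("vt_dataset", class(tibble())))
}

#' Surface-only training view for the endo/epi classifier
#'
#' The binary endo/epi network is trained on surface beats only; mid-wall
#' beats are excluded from its training data (they are still evaluated at
#' test time).
#'
#' @param dataset A `vt_dataset`.
#' @return The dataset with mid-wall rows removed from the train split.
#' @export
epiendo_training_view <- function(dataset) {
  stopifnot(inherits(dataset, "vt_dataset"))
  keep <- dataset$split != "train" | dataset$wall_class != "mid"
  out <- dataset[keep, ]
  attr(out, "seed") <- attr(dataset, "seed")
  attr(out, "augmentation") <- attr(dataset, "augmentation")
  structure(out, class = class(dataset))
}

#' Augment the training split with noisy copies
#'
#' Each training record is replaced by `k` independently noised copies
#' (white Gaussian noise at `snr_db` added to the raw matrices, which are
#' then re-normalized). Copies inherit the parent's labels and split, so
#' augmentation never crosses the train/test boundary. The test split is
#' untouched.
#'
#' @param x A `vt_dataset`.
#' @param k Number of noisy repetitions (>= 1).
#' @param snr_db Noise level in dB.
#' @param seed Integer seed.
#' @param split Must be `"train"`; requesting augmentation of the test
#'   split is a contract violation and errors.
#' @param ... Unused.
#' @return The augmented `vt_dataset`.
#' @exportS3Method generics::augment
augment.vt_dataset <- function(x, k = 10, snr_db = 25, seed = 1L, split = "train", ...) {
  if (!identical(split, "train")) abort("augmentation applies to the train split only")
  if (k < 1) abort("`k` must be >= 1")
  tr <- x[x$split == "train", ]
  te <- x[x$split == "test", ]
  aug <- with_seed(seed, {
    reps <- tr[rep(seq_len(nrow(tr)), each = k), ]
    reps$ecg <- lapply(reps$ecg, add_noise, snr_db = snr_db)
    reps$egm <- lapply(reps$egm, add_noise, snr_db = snr_db)
    reps
  })
  aug$beat <- seq_len(nrow(aug)) + max(x$beat)
  out <- dplyr::bind_rows(aug, te)
  attr(out, "seed") <- attr(x, "seed")
  attr(out, "augmentation") <- as.integer(k)
  attr(out, "snr_db") <- snr_db
  structure(out, class = class(x))
}

#' Extract model tensors from a dataset
#'
#' Flattens each 16 x 16 normalized matrix of the requested modality into a
#' 256-vector (column-major) and assembles the target for the requested
#' task.
#'
#' @param dataset A `vt_dataset` (or any `vt_beats`-like tibble).
#' @param modality `"ecg"` or `"egm"`.
#' @param task One of `"segment17"`, `"segment68"`, `"epiendo"`,
#'   `"uvc_regression"`, `"phi_classification"`.
#' @param split Optional split filter (`"train"`/`"test"`).
#' @return List with `x` (n x 256 matrix), `y` (targets), `classes`
#'   (levels for classification tasks, `NULL` otherwise).
#' @export
dataset_tensors <- function(dataset, modality, task, split = NULL) {
  modality <- match.arg(modality, c("ecg", "egm"))
  if (!is.null(split)) dataset <- dataset[dataset$split == split, ]
  mats <- dataset[[modality]]
  x <- t(vapply(mats, function(m) as.vector(m$values), numeric(256L)))
  if (task == "segment17") {
    y <- dataset$seg17; classes <- 1:17
  } else if (task == "segment68") {
    y <- dataset$seg68; classes <- 1:68
  } else if (task == "epiendo") {
    if (any(dataset$wall_class == "mid")) {
      abort("epiendo task given mid-wall records; use epiendo_training_view()")
    }
    y <- match(dataset$wall_class, c("endo", "epi")); classes <- c("endo", "epi")
  } else if (task == "uvc_regression") {
    y <- cbind(z = dataset$uvc_z, rho = dataset$uvc_rho); classes <- NULL
  } else if (task == "phi_classification") {
    y <- dataset$wedge; classes <- 1:68
  } else {
    abort(sprintf("unknown task `%s`", task))
  }
  list(x = x, y = y, classes = classes)
}

#' Persist / restore a dataset
#'
#' The dataset is stored as an RDS container (arrays and labels) plus a
#' delimited manifest (one row per beat: id, split, labels, site
#' coordinates). Reloading round-trips the object bit-exactly.
#'
#' @param dataset A `vt_dataset`.
#' @param path Base path; writes `<path>.rds` and `<path>_manifest.csv`.
#' @return `path`, invisibly (writer) / the dataset (reader).
#' @export
write_dataset <- function(dataset, path) {
  saveRDS(dataset, paste0(path, ".rds"))
  manifest <- as.data.frame(dataset[, c("beat", "split", "wall_class", "seg17", "seg68",
                                        "wedge", "node", "x", "y", "z",
                                        "uvc_z", "uvc_rho", "uvc_phi")])
  utils::write.csv(manifest, paste0(path, "_manifest.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  readRDS(paste0(path, ".rds"))
}
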