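#' Build a nuisance regressor set
#'
#' Six rigid-body motion parameters plus mean white-matter and CSF series,
#' all sampled once per volume.
#'
#' @param motion T x 6 numeric matrix, or `NULL`.
#' @param wm_mean,csf_mean Length-T numeric vectors, or `NULL`.
#' @return A `nuisance_set` (list of the non-NULL components).
#' @export
nuisance_set <- function(motion = NULL, wm_mean = NULL, csf_mean = NULL) {
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6) stop("motion must have 6 columns")
  }
  structure(list(motion = motion, wm_mean = wm_mean, csf_mean = csf_mean),
            class = "nuisance_set")
}

nuisance_design <- function(tt, nuisance = NULL) {
  X <- cbind(intercept = rep(1, tt),
             drift = seq_len(tt) / tt)
  if (!is.null(nuisance)) {
    stopifnot(inherits(nuisance, "nuisance_set"))
    if (!is.null(nuisance$motion)) {
      if (nrow(nuisance$motion) != tt)
        stop("motion parameters have ", nrow(nuisance$motion),
             " rows but the series has ", tt, " timepoints")
      m <- nuisance$motion
      colnames(m) <- paste0("motion", 1:6)
      X <- cbind(X, m)
    }
    for (nm in c("wm_mean", "csf_mean")) {
      v <- nuisance[[nm]]
      if (!is.null(v)) {
        if (length(v) != tt)
          stop(nm, " has length ", length(v), " but the series has ",
               tt, " timepoints")
        X <- cbind(X, stats::setNames(data.frame(v), nm))
      }
    }
    X <- as.matrix(X)
  }
  X
}

#' Regress nuisance signals out of a regional time series
#'
#' Least-squares residualization of every region on a design holding an
#' intercept, a linear drift term and — when supplied — six motion
#' parameters and the mean white-matter and CSF series (10 columns in the
#' full design). Residuals are orthogonal to every regressor, so applying
#' the operation twice equals applying it once. With no nuisance set the
#' operation degrades to intercept + drift removal and says so via
#' `message()` (the usual mode for synthetic regional data).
#'
#' @param ts A `subject_ts` (T x N).
#' @param nuisance A [nuisance_set()], or `NULL`.
#' @return Residual `subject_ts` of the same shape.
#' @export
regress_nuisance <- function(ts, nuisance = NULL) {
  v <- as.matrix(ts)
  tt <- nrow(v)
  X <- nuisance_design(tt, nuisance)
  if (is.null(nuisance))
    message("no nuisance set supplied; removing intercept + linear drift only")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("nuisance design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qrX, v)
  dimnames(res) <- dimnames(v)
  subject_ts(res, attr(ts, "sampling_interval") %||% 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Zero-phase band-pass filter
#'
#' Second-order Butterworth filter applied forward and backward
#' (zero phase) with odd-reflection padding at both ends, retaining the
#' canonical resting-state band 0.01–0.08 Hz by default.
#'
#' @param ts A `subject_ts`; the sampling interval sets the Nyquist limit.
#' @param low,high Band edges in Hz; `high` must be below Nyquist.
#' @param order Butterworth order (per pass).
#' @return Filtered `subject_ts`.
#' @export
bandpass <- function(ts, low = 0.01, high = 0.08, order = 2) {
  v <- as.matrix(ts)
  dt <- attr(ts, "sampling_interval") %||% 2
  nyq <- 1 / (2 * dt)
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  if (high >= nyq)
    stop("high edge ", high, " Hz is at or above Nyquist (", nyq, " Hz)")
  tt <- nrow(v)
  min_pad <- 3 * (2 * order + 1)
  if (tt <= min_pad + 1)
    stop("series too short (", tt, " timepoints) for stable filtering; ",
         "need more than ", min_pad + 1)
  # pad out the slow low-edge transient (~3 periods of the low cutoff)
  pad <- min(tt - 1, max(min_pad, ceiling(3 / (low * dt))))
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- apply(v, 2, function(x) {
    # odd reflection about the end samples stabilizes the transient
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[tt] - x[(tt - 1):(tt - pad)])
    y <- signal::filtfilt(bf, xp)
    y[(pad + 1):(pad + tt)]
  })
  dimnames(out) <- dimnames(v)
  subject_ts(out, dt)
}

#' Condition a regional time series
#'
#' The documented two-step order: nuisance regression first, band-pass
#' filtering second.
#'
#' @inheritParams regress_nuisance
#' @inheritParams bandpass
#' @return Conditioned `subject_ts`.
#' @export
preprocess_series <- function(ts, nuisance = NULL, low = 0.01, high = 0.08) {
  bandpass(regress_nuisance(ts, nuisance), low = low, high = high)
}

#' Extract regional mean time series from a labeled 4D image
#'
#' Column k of the output is the unweighted mean, at each timepoint, over
#' all voxels whose label equals region k's `label_value`; column order is
#' atlas order. Label codes absent from the atlas are ignored with a
#' warning (background 0 is always ignored); an atlas region with no voxels
#' is an error.
#'
#' @param image 4D numeric array (x, y, z, t) or a path to a NIfTI file.
#' @param labels 3D integer array of label codes or a path to a NIfTI file.
#' @param atlas A `brain_atlas`.
#' @param sampling_interval Seconds between volumes of the output series.
#' @return A `subject_ts` (T x N).
#' @export
extract_regional_series <- function(image, labels, atlas,
                                    sampling_interval = 2) {
  stopifnot(inherits(atlas, "brain_atlas"))
  if (is.character(image)) image <- as.array(RNifti::readNifti(image))
  if (is.character(labels)) labels <- as.array(RNifti::readNifti(labels))
  if (length(dim(image)) != 4) stop("image must be a 4D array")
  if (!all(dim(image)[1:3] == dim(labels)))
    stop("spatial dimensions of image and labels disagree")
  tt <- dim(image)[4]
  nv <- prod(dim(labels))
  flat <- matrix(image, nrow = nv, ncol = tt)
  lab <- as.integer(labels)
  known <- atlas$regions$label_value
  stray <- setdiff(unique(lab), c(0L, known))
  if (length(stray) > 0)
    warning("ignoring label code(s) absent from atlas: ",
            paste(stray, collapse = ", "))
  missing <- known[!known %in% lab]
  if (length(missing) > 0)
    stop("no voxels found for atlas region(s): ",
         paste(atlas$regions$abbreviation[match(missing, known)],
               collapse = ", "))
  out <- vapply(known, function(code) {
    rows <- lab == code
    colMeans(flat[rows, , drop = FALSE])
  }, numeric(tt))
  colnames(out) <- region_names(atlas)
  subject_ts(out, sampling_interval)
}
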