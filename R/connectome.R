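#' Interregional Pearson correlation matrix
#'
#' @param ts A `subject_ts` (T x N).
#' @return Symmetric N x N correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(ts) {
  v <- as.matrix(ts)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(v)[sds == 0] %||% which(sds == 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  stats::cor(v)
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r)` elementwise. To keep z finite for degenerate inputs
#' (duplicate signals), |r| is clipped to `1 - 1e-7` first; any clipped
#' entry is reported via `message()`. For square matrix input the diagonal
#' is forced to 0 — the self-edge carries no information and is excluded
#' from all downstream statistics.
#'
#' @param r Correlation scalar, vector or matrix with |r| <= 1.
#' @return Same shape as `r`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12)) stop("correlation outside [-1, 1]")
  clip <- 1 - 1e-7
  is_sq <- is.matrix(r) && nrow(r) == ncol(r)
  chk <- if (is_sq) r[upper.tri(r)] else r
  n_clip <- sum(abs(chk) > clip)
  if (n_clip > 0)
    message(n_clip, " correlation(s) at |r| ~ 1 clipped before atanh")
  z <- atanh(pmax(pmin(r, clip), -clip))
  if (is_sq) diag(z) <- 0
  z
}

#' Per-subject Fisher-z connectivity matrix
#'
#' @param ts A `subject_ts`.
#' @param subject_id Optional identifier stored as an attribute.
#' @return N x N Fisher-z matrix (diagonal 0) of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(ts, subject_id = NULL) {
  z <- fisher_z(correlation_matrix(ts))
  structure(z, subject_id = subject_id,
            class = c("connectivity_matrix", "matrix", "array"))
}

#' Assemble a cohort stack
#'
#' Aligns per-subject Fisher-z matrices with their covariates; the central
#' container for all group-level statistics.
#'
#' @param z A list of N x N Fisher-z matrices (one per covariate row) or an
#'   N x N x S array.
#' @param covariates Data frame with columns `subject_id`, `group`, `mmse`;
#'   `group` must take values in `groups`.
#' @param atlas The shared `brain_atlas`.
#' @param groups Allowed group vocabulary, in display order.
#' @return A `cohort_stack`: list with `z` (N x N x S array), `covariates`,
#'   `atlas`, `edges` (the canonical [edge_table()]).
#' @export
cohort_stack <- function(z, covariates, atlas,
                         groups = c("NC", "MCI", "AD")) {
  stopifnot(inherits(atlas, "brain_atlas"))
  n <- atlas$n_regions
  if (is.list(z)) {
    stopifnot(all(vapply(z, function(m) all(dim(m) == n), logical(1))))
    z <- array(unlist(z, use.names = FALSE), dim = c(n, n, length(z)))
  }
  if (length(dim(z)) != 3 || dim(z)[1] != n || dim(z)[2] != n)
    stop("z must be an N x N x S array matching the atlas")
  covariates <- as.data.frame(covariates)
  req <- c("subject_id", "group", "mmse")
  if (!all(req %in% names(covariates)))
    stop("covariates must have columns ", paste(req, collapse = ", "))
  if (dim(z)[3] != nrow(covariates))
    stop("one matrix per covariate row required: ", dim(z)[3],
         " matrices vs ", nrow(covariates), " rows")
  if (anyDuplicated(covariates$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(covariates$subject_id[duplicated(covariates$subject_id)]),
               collapse = ", "))
  bad <- !covariates$group %in% groups
  if (any(bad))
    stop("unknown group label(s): ",
         paste(unique(covariates$group[bad]), collapse = ", "))
  covariates$group <- factor(covariates$group, levels = groups)
  dimnames(z) <- list(region_names(atlas), region_names(atlas),
                      covariates$subject_id)
  structure(list(z = z, covariates = covariates, atlas = atlas,
                 edges = edge_table(atlas)),
            class = "cohort_stack")
}

#' Compute a cohort stack from time series
#'
#' Runs [connectivity_matrix()] on every subject of a simulated or loaded
#' cohort, optionally conditioning each series first.
#'
#' @param cohort A `synthetic_cohort`, or a named list of `subject_ts`.
#' @param covariates Covariate table (taken from the cohort if omitted).
#' @param atlas Atlas (taken from the cohort if omitted).
#' @param preprocess Apply [preprocess_series()] to each subject first.
#' @param low,high Band edges used when `preprocess = TRUE`.
#' @return A `cohort_stack`.
#' @export
compute_connectivity <- function(cohort, covariates = NULL, atlas = NULL,
                                 preprocess = FALSE,
                                 low = 0.01, high = 0.08) {
  if (inherits(cohort, "synthetic_cohort")) {
    covariates <- covariates %||% cohort$covariates
    atlas <- atlas %||% cohort$atlas
    series <- cohort$series
  } else {
    series <- cohort
    if (is.null(covariates) || is.null(atlas))
      stop("covariates and atlas are required for a plain series list")
  }
  zs <- lapply(names(series), function(sid) {
    ts <- series[[sid]]
    if (preprocess)
      ts <- suppressMessages(preprocess_series(ts, low = low, high = high))
    unclass(connectivity_matrix(ts, sid))
  })
  cohort_stack(zs, covariates, atlas)
}

#' @export
print.cohort_stack <- function(x, ...) {
  cat("cohort_stack:", dim(x$z)[3], "subjects x",
      x$atlas$n_regions, "regions (",
      paste(sprintf("%s=%d", levels(x$covariates$group),
                    as.integer(table(x$covariates$group))), collapse = ", "),
      ")\n")
  invisible(x)
}

stack_group_index <- function(stack, group) {
  idx <- which(stack$covariates$group == group)
  if (length(idx) == 0) stop("no subjects in group ", group)
  idx
}

#' Group mean connectivity matrix
#'
#' Elementwise mean of the group's Fisher-z matrices; with
#' `absolute = TRUE`, the mean of |z| (the usual display for cohort-level
#' connectivity strength).
#'
#' @param stack A `cohort_stack`.
#' @param group Group label.
#' @param absolute Average |z| instead of signed z.
#' @return N x N matrix.
#' @export
group_mean_matrix <- function(stack, group, absolute = FALSE) {
  idx <- stack_group_index(stack, group)
  z <- stack$z[, , idx, drop = FALSE]
  if (absolute) z <- abs(z)
  apply(z, c(1, 2), mean)
}

#' Group difference matrix
#'
#' `mean(groupA) - mean(groupB)` on signed Fisher z; antisymmetric in its
#' group arguments.
#'
#' @param stack A `cohort_stack`.
#' @param group_a,group_b Group labels (former minus latter).
#' @return N x N signed matrix.
#' @export
group_difference_matrix <- function(stack, group_a, group_b) {
  group_mean_matrix(stack, group_a) - group_mean_matrix(stack, group_b)
}

#' Mean connectivity strength of one matrix
#'
#' Mean over the N(N-1)/2 upper-triangle entries (4005 for 90 regions);
#' absolute z by default, matching the usual "mean absolute z-score"
#' summary. The signed variant is available because group-level strength
#' comparisons may be run on either.
#'
#' @param z N x N Fisher-z matrix.
#' @param absolute Use |z|.
#' @return Scalar.
#' @export
mean_connectivity_strength <- function(z, absolute = TRUE) {
  v <- z[upper.tri(z)]
  if (absolute) v <- abs(v)
  mean(v)
}

#' Per-subject mean connectivity strengths
#'
#' @param stack A `cohort_stack`.
#' @param absolute Use |z|.
#' @return Numeric vector, one value per subject, named by subject id.
#' @export
subject_strengths <- function(stack, absolute = TRUE) {
  s <- apply(stack$z, 3, mean_connectivity_strength, absolute = absolute)
  stats::setNames(s, stack$covariates$subject_id)
}
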