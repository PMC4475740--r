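#' Covariance specification for a synthetic cohort
#'
#' Describes the group-wise target correlation structure the generator
#' emulates: strong interhemispheric homologue edges, moderately strong
#' intralobe edges, weak generic background edges, and a set of "affected"
#' edges whose correlation is attenuated in patient groups (NC >= MCI >= AD).
#'
#' Effect sizes are package conventions (no effect-size estimates exist for
#' the emulated disease contrasts); defaults plant a 0.15 / 0.30 drop from a
#' 0.5 baseline in MCI / AD.
#'
#' @param atlas A `brain_atlas` defining node order.
#' @param base_correlation Correlation of generic region pairs, in `[0, 1)`.
#' @param homologue_correlation Correlation of left/right homologous pairs.
#' @param intralobe_correlation Correlation of same-lobe pairs.
#' @param affected_edges Data frame `i`, `j` (`i < j`) of edges carrying a
#'   group effect; defaults to [default_affected_edges()].
#' @param affected_baseline Pre-attenuation correlation at affected edges.
#' @param effect_size_by_group Named numeric, subtraction applied to the
#'   affected-edge correlation per group; must be ordered
#'   `NC <= MCI <= AD` so that planted strength satisfies NC >= MCI >= AD.
#' @return A `cov_spec` object.
#' @export
cov_spec <- function(atlas,
                     base_correlation = 0.1,
                     homologue_correlation = 0.6,
                     intralobe_correlation = 0.3,
                     affected_edges = NULL,
                     affected_baseline = 0.5,
                     effect_size_by_group = c(NC = 0, MCI = 0.15, AD = 0.3)) {
  stopifnot(inherits(atlas, "brain_atlas"))
  rs <- c(base_correlation, homologue_correlation, intralobe_correlation,
          affected_baseline)
  if (any(abs(rs) >= 1)) stop("all specified correlations must lie in (-1, 1)")
  groups <- c("NC", "MCI", "AD")
  if (!all(groups %in% names(effect_size_by_group)))
    stop("effect_size_by_group must name NC, MCI and AD")
  eff <- effect_size_by_group[groups]
  if (eff["NC"] > eff["MCI"] || eff["MCI"] > eff["AD"])
    stop("effect sizes must satisfy NC <= MCI <= AD ",
         "(so affected-edge correlation is NC >= MCI >= AD)")
  if (any(abs(affected_baseline - eff) >= 1))
    stop("affected_baseline minus an effect size leaves |r| >= 1")
  if (is.null(affected_edges)) affected_edges <- default_affected_edges(atlas)
  affected_edges <- validate_edges(affected_edges, atlas$n_regions)
  structure(list(atlas = atlas,
                 n_regions = atlas$n_regions,
                 base_correlation = base_correlation,
                 homologue_correlation = homologue_correlation,
                 intralobe_correlation = intralobe_correlation,
                 affected_edges = affected_edges,
                 affected_baseline = affected_baseline,
                 effect_size_by_group = eff),
            class = "cov_spec")
}

validate_edges <- function(edges, n) {
  edges <- as.data.frame(edges)
  if (!all(c("i", "j") %in% names(edges)))
    stop("edges must be a data frame with columns i and j")
  i <- pmin(edges$i, edges$j); j <- pmax(edges$i, edges$j)
  if (any(i == j)) stop("self-edges (i == j) are not allowed")
  if (any(i < 1 | j > n)) stop("edge index out of range 1..", n)
  out <- unique(data.frame(i = as.integer(i), j = as.integer(j)))
  rownames(out) <- NULL
  out
}

#' Default set of affected edges
#'
#' A deterministic selection of long-distance interlobe edges, anchored on
#' default-mode and temporal nodes when the atlas carries the standard
#' abbreviations (posterior cingulate, medial superior frontal, precuneus,
#' parahippocampal, mid-cingulate, superior occipital, paracentral nodes and
#' temporal-to-frontal/parietal pairs), topped up with evenly spaced
#' interlobe pairs for atlases without them.
#'
#' @param atlas A `brain_atlas`.
#' @param n_edges Number of edges to select.
#' @return Data frame `i`, `j` with `n_edges` rows.
#' @export
default_affected_edges <- function(atlas, n_edges = 20) {
  r <- atlas$regions
  find <- function(ab, hemi) which(r$abbreviation == ab & r$hemisphere == hemi)
  curated <- list(
    c("PCG", "left", "SFGmed", "right"), c("PCG", "right", "SFGmed", "right"),
    c("PCG", "left", "SFGmed", "left"),  c("PCUN", "left", "SFGmed", "left"),
    c("PCUN", "right", "MFG", "right"),  c("PHG", "left", "SFGdor", "left"),
    c("PHG", "right", "MFG", "left"),    c("PHG", "left", "IPL", "left"),
    c("DCG", "left", "PCUN", "right"),   c("DCG", "right", "STG", "left"),
    c("SOG", "left", "STG", "left"),     c("SOG", "right", "MTG", "right"),
    c("PCL", "left", "MTG", "left"),     c("PCL", "right", "STG", "right"),
    c("MTG", "left", "SFGdor", "right"), c("MTG", "right", "IPL", "right"),
    c("ITG", "left", "MFG", "left"),     c("ITG", "right", "SPG", "right"),
    c("STG", "left", "SFGmed", "left"),  c("TPOsup", "left", "ACG", "left")
  )
  edges <- list()
  for (cc in curated) {
    a <- find(cc[1], cc[2]); b <- find(cc[3], cc[4])
    if (length(a) == 1 && length(b) == 1)
      edges[[length(edges) + 1]] <- c(min(a, b), max(a, b))
    if (length(edges) >= n_edges) break
  }
  have <- if (length(edges) > 0) do.call(rbind, edges) else
    matrix(integer(0), 0, 2)
  if (nrow(have) < n_edges) {
    # fall back to evenly spaced interlobe pairs
    et <- edge_table(atlas)
    cls <- classify_edge(atlas, et$i, et$j)
    cand <- et[cls$lobe_class == "interlobe", , drop = FALSE]
    if (nrow(cand) == 0) cand <- et
    take <- unique(round(seq(1, nrow(cand), length.out = n_edges)))
    have <- unique(rbind(have, as.matrix(cand[take, c("i", "j")])))
  }
  out <- data.frame(i = as.integer(have[, 1]), j = as.integer(have[, 2]))
  validate_edges(utils::head(out, n_edges), atlas$n_regions)
}

#' Cohort generation configuration
#'
#' Defaults emulate a three-group clinical cohort of 27 controls, 27 MCI
#' and 35 AD subjects scanned with a 2-second sampling interval for
#' 6 min 40 s (200 volumes).
#'
#' @param group_sizes Named integer vector for groups NC, MCI, AD.
#' @param n_timepoints Volumes per subject.
#' @param sampling_interval Seconds between volumes.
#' @param ar_coefficient Temporal AR(1) coefficient shared by all regions,
#'   in `[0, 1)`; emulates the slow autocorrelated character of BOLD.
#' @param mmse_intercept Named numeric per group, baseline MMSE points.
#' @param mmse_slope Points of MMSE per unit of mean affected-edge Fisher z.
#' @param mmse_noise_sd Standard deviation of the MMSE noise term.
#' @param seed Integer master seed; each subject draws from its own derived
#'   stream so changing one group's size leaves other subjects unchanged.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(group_sizes = c(NC = 27, MCI = 27, AD = 35),
                          n_timepoints = 200,
                          sampling_interval = 2,
                          ar_coefficient = 0.3,
                          mmse_intercept = c(NC = 23, MCI = 22.5, AD = 18.5),
                          mmse_slope = 10,
                          mmse_noise_sd = 1.5,
                          seed = 1L) {
  groups <- c("NC", "MCI", "AD")
  if (!all(groups %in% names(group_sizes)))
    stop("group_sizes must name NC, MCI and AD")
  gs <- group_sizes[groups]
  if (any(gs < 0) || sum(gs) < 1)
    stop("group sizes must be non-negative with at least one subject")
  gs <- gs[gs > 0]   # a zero-sized group is simply absent from the cohort
  if (!all(names(gs) %in% names(mmse_intercept)))
    stop("mmse_intercept must cover every simulated group")
  stopifnot(n_timepoints >= 10, sampling_interval > 0,
            ar_coefficient >= 0, ar_coefficient < 1, mmse_noise_sd >= 0)
  structure(list(group_sizes = gs,
                 n_timepoints = as.integer(n_timepoints),
                 sampling_interval = sampling_interval,
                 ar_coefficient = ar_coefficient,
                 mmse_intercept = mmse_intercept[names(gs)],
                 mmse_slope = mmse_slope,
                 mmse_noise_sd = mmse_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Build a group's target correlation matrix
#'
#' Applies the spec's rules in increasing precedence — background, intralobe,
#' interhemispheric homologue, affected-edge baseline — then subtracts the
#' group's effect size at affected edges, and (by default) projects the
#' result to the nearest positive-definite correlation matrix so it can
#' drive a Gaussian simulator.
#'
#' @param spec A `cov_spec`.
#' @param group `"NC"`, `"MCI"` or `"AD"`.
#' @param project Project to positive definite via [nearest_pd()] (default
#'   `TRUE`). With `project = FALSE` the raw rule-based matrix is returned.
#' @return N x N correlation matrix with unit diagonal; attribute
#'   `"target_raw"` carries the pre-projection matrix.
#' @export
build_group_correlation <- function(spec, group, project = TRUE) {
  stopifnot(inherits(spec, "cov_spec"))
  group <- match.arg(group, names(spec$effect_size_by_group))
  atlas <- spec$atlas
  n <- spec$n_regions
  r <- atlas$regions
  R <- matrix(spec$base_correlation, n, n)
  same_lobe <- outer(r$lobe, r$lobe, "==")
  R[same_lobe] <- spec$intralobe_correlation
  hp <- homologous_pairs(atlas)
  if (nrow(hp) > 0) {
    R[cbind(hp$i, hp$j)] <- spec$homologue_correlation
    R[cbind(hp$j, hp$i)] <- spec$homologue_correlation
  }
  ae <- spec$affected_edges
  val <- spec$affected_baseline - spec$effect_size_by_group[[group]]
  if (nrow(ae) > 0) {
    R[cbind(ae$i, ae$j)] <- val
    R[cbind(ae$j, ae$i)] <- val
  }
  diag(R) <- 1
  if (any(abs(R[upper.tri(R)]) >= 1))
    stop("specified rules produce |r| >= 1 at some edge")
  raw <- R
  if (project) R <- nearest_pd(R)
  attr(R, "target_raw") <- raw
  dimnames(R) <- list(region_names(atlas), region_names(atlas))
  R
}

#' Nearest positive-definite correlation matrix
#'
#' Eigenvalue clipping: eigenvalues below `epsilon` are raised to `epsilon`,
#' the matrix is rebuilt and its diagonal renormalized to 1; repeated until
#' the smallest eigenvalue is at least `epsilon` (renormalization can
#' slightly deflate it). Already-PD input is returned unchanged.
#'
#' @param m Symmetric matrix.
#' @param epsilon Floor for the smallest eigenvalue.
#' @return Symmetric positive-definite matrix with unit diagonal.
#' @export
nearest_pd <- function(m, epsilon = 1e-6) {
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("input matrix is not symmetric")
  m <- (m + t(m)) / 2
  for (iter in 1:100) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) >= epsilon) return(m)
    vals <- pmax(e$values, epsilon)
    m <- e$vectors %*% (vals * t(e$vectors))
    m <- (m + t(m)) / 2
    d <- sqrt(diag(m))
    m <- m / outer(d, d)
    diag(m) <- 1
  }
  stop("positive-definite projection did not converge")
}

#' Simulate one subject's regional time series
#'
#' Stationary first-order autoregressive process with correlated Gaussian
#' innovations: `x_t = phi * x_(t-1) + sqrt(1 - phi^2) * L %*% e_t`, with
#' `L` the Cholesky factor of the target correlation matrix. Because the
#' AR coefficient is shared across regions, the stationary lag-0
#' cross-correlation equals the target matrix exactly, so the sample
#' correlation converges to the target as T grows.
#'
#' @param correlation Positive-definite target correlation matrix.
#' @param config A `cohort_config` (supplies T, interval, AR coefficient).
#' @return T x N matrix of class `subject_ts` with attribute
#'   `sampling_interval`; column names are taken from the target matrix.
#' @export
simulate_subject <- function(correlation, config) {
  stopifnot(inherits(config, "cohort_config"))
  ch <- tryCatch(chol(correlation),
                 error = function(e) stop("target matrix is not positive definite"))
  n <- ncol(correlation)
  tt <- config$n_timepoints
  phi <- config$ar_coefficient
  innov <- matrix(stats::rnorm(tt * n), tt, n) %*% ch
  if (phi > 0) {
    innov[1, ] <- innov[1, ]                      # stationary start
    innov[-1, ] <- sqrt(1 - phi^2) * innov[-1, ]
    x <- stats::filter(innov, phi, method = "recursive")
    x <- matrix(as.numeric(x), tt, n)
  } else {
    x <- innov
  }
  colnames(x) <- colnames(correlation)
  subject_ts(x, config$sampling_interval)
}

#' Construct a subject time-series object
#'
#' @param values T x N numeric matrix (timepoints by regions).
#' @param sampling_interval Seconds between rows.
#' @return The matrix with class `subject_ts` and the interval attached.
#' @export
subject_ts <- function(values, sampling_interval = 2) {
  values <- as.matrix(values)
  if (nrow(values) < 10) stop("time series must have at least 10 timepoints")
  if (anyNA(values)) stop("time series contains missing values")
  structure(values, sampling_interval = sampling_interval,
            class = c("subject_ts", "matrix", "array"))
}

#' Simulate an MMSE score
#'
#' `round(intercept_group + slope * strength + noise)` clamped to the
#' instrument's 0–30 range.
#'
#' @param strength Latent connectivity strength (mean affected-edge Fisher z).
#' @param group Group label.
#' @param config A `cohort_config`.
#' @return Integer score in `[0, 30]`.
#' @export
simulate_mmse <- function(strength, group, config) {
  mu <- config$mmse_intercept[[group]] + config$mmse_slope * strength
  score <- round(mu + stats::rnorm(1, sd = config$mmse_noise_sd))
  as.integer(pmin(30, pmax(0, score)))
}

subject_seed <- function(master, group, index) {
  gcode <- match(group, c("NC", "MCI", "AD")) - 1L
  as.integer((as.double(master) * 7919 + gcode * 104729 + index * 13) %%
               .Machine$integer.max)
}

#' Simulate a full three-group cohort
#'
#' One time series per subject plus a covariate table and a ground-truth
#' record (planted edges, per-group target correlations, per-subject latent
#' strengths and MMSE scores) for recovery testing. Each subject has its own
#' seed derived from `(master seed, group, within-group index)`, so
#' resizing one group does not reshuffle the others.
#'
#' @param spec A `cov_spec`.
#' @param config A `cohort_config`.
#' @return A `synthetic_cohort`: list with `series` (named list of
#'   `subject_ts`), `covariates` (data frame `subject_id`, `group`, `mmse`),
#'   `ground_truth`, `atlas`.
#' @export
simulate_cohort <- function(spec, config = cohort_config()) {
  stopifnot(inherits(spec, "cov_spec"), inherits(config, "cohort_config"))
  if (config$n_timepoints < 2 * spec$n_regions)
    warning("n_timepoints < 2 * n_regions; per-subject correlation ",
            "estimates will be noisy")
  targets <- lapply(names(config$group_sizes), function(g)
    build_group_correlation(spec, g))
  names(targets) <- names(config$group_sizes)
  ae <- spec$affected_edges
  series <- list()
  cov_rows <- list()
  latent <- numeric(0)
  for (g in names(config$group_sizes)) {
    for (k in seq_len(config$group_sizes[[g]])) {
      sid <- sprintf("%s_%02d", g, k)
      set.seed(subject_seed(config$seed, g, k))
      ts <- simulate_subject(targets[[g]], config)
      z <- fisher_z(stats::cor(ts))
      strength <- if (nrow(ae) > 0) mean(z[cbind(ae$i, ae$j)]) else 0
      mmse <- simulate_mmse(strength, g, config)
      series[[sid]] <- ts
      latent[sid] <- strength
      cov_rows[[sid]] <- data.frame(subject_id = sid, group = g, mmse = mmse)
    }
  }
  covariates <- do.call(rbind, cov_rows)
  rownames(covariates) <- NULL
  gt <- list(
    affected_edges = ae,
    target_by_group = vapply(names(targets), function(g)
      spec$affected_baseline - spec$effect_size_by_group[[g]], numeric(1)),
    latent_strength = latent,
    mmse = stats::setNames(covariates$mmse, covariates$subject_id)
  )
  structure(list(series = series, covariates = covariates,
                 ground_truth = gt, atlas = spec$atlas),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$covariates), "subjects (",
      paste(sprintf("%s=%d", names(table(x$covariates$group)),
                    as.integer(table(x$covariates$group))), collapse = ", "),
      "),", x$atlas$n_regions, "regions\n")
  invisible(x)
}

#' Render a toy labeled 4D image from regional series
#'
#' Builds a small 3D label volume assigning `voxels_per_region` voxels to
#' each atlas region and a 4D volume whose voxels carry the region's series
#' plus independent Gaussian noise — the round-trip input for
#' [extract_regional_series()].
#'
#' @param atlas A `brain_atlas`.
#' @param series A `subject_ts` with one column per region.
#' @param voxels_per_region Voxels allocated to each region (>= 1).
#' @param noise_sd Voxel-level noise standard deviation.
#' @return List with `image` (4D array x,y,z,t) and `labels` (3D integer
#'   array of `label_value` codes, 0 = background).
#' @export
render_toy_image <- function(atlas, series, voxels_per_region = 3,
                             noise_sd = 0) {
  stopifnot(inherits(atlas, "brain_atlas"))
  series <- as.matrix(series)
  if (ncol(series) != atlas$n_regions)
    stop("series has ", ncol(series), " columns but atlas has ",
         atlas$n_regions, " regions")
  if (voxels_per_region < 1) stop("every region needs at least one voxel")
  n <- atlas$n_regions
  tt <- nrow(series)
  nv <- n * voxels_per_region
  nx <- ceiling(sqrt(nv)); ny <- ceiling(nv / nx); nz <- 2
  labels <- array(0L, dim = c(nx, ny, nz))
  flat <- rep(atlas$regions$label_value, each = voxels_per_region)
  labels[seq_along(flat)] <- as.integer(flat)
  img <- array(0, dim = c(nx, ny, nz, tt))
  vox_region <- rep(seq_len(n), each = voxels_per_region)
  for (v in seq_along(flat)) {
    coord <- arrayInd(v, dim(labels))
    img[coord[1], coord[2], coord[3], ] <-
      series[, vox_region[v]] +
      if (noise_sd > 0) stats::rnorm(tt, sd = noise_sd) else 0
  }
  list(image = img, labels = labels)
}
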