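#' Write / read a numeric matrix as delimited text
#'
#' Tab-separated with a header row of region names; values carry 17
#' significant digits so a write/read round trip is exact to double
#' precision.
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @export
write_matrix_txt <- function(m, path) {
  df <- as.data.frame(signif_format(m))
  names(df) <- colnames(m) %||% paste0("V", seq_len(ncol(m)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

signif_format <- function(m) {
  apply(m, c(1, 2), function(x) sprintf("%.17g", x))
}

#' @rdname write_matrix_txt
#' @return `read_matrix_txt`: the numeric matrix.
#' @export
read_matrix_txt <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  as.matrix(df)
}

#' Write / read a subject time series as delimited text
#'
#' T rows by N columns, header = region names; the sampling interval is
#' recorded on a comment line.
#'
#' @param ts A `subject_ts`.
#' @param path Output path.
#' @export
write_timeseries <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_interval=%g",
                     attr(ts, "sampling_interval") %||% 2), con)
  df <- as.data.frame(signif_format(as.matrix(ts)))
  names(df) <- colnames(ts) %||% paste0("V", seq_len(ncol(ts)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param default_interval Sampling interval used when the file carries no
#'   comment line.
#' @return `read_timeseries`: a `subject_ts`.
#' @export
read_timeseries <- function(path, default_interval = 2) {
  first <- readLines(path, n = 1)
  interval <- default_interval
  skip <- 0
  if (grepl("^# sampling_interval=", first)) {
    interval <- as.numeric(sub("^# sampling_interval=", "", first))
    skip <- 1
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                          check.names = FALSE)
  subject_ts(as.matrix(df), interval)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `subject_id`, `group`, `mmse`,
#' `timeseries_path` (paths relative to the manifest's directory unless
#' absolute). All subjects must share the atlas's column count and one
#' timepoint count.
#'
#' @param path Manifest CSV.
#' @param atlas A `brain_atlas`.
#' @param groups Allowed group vocabulary.
#' @return List with `series` (named list of `subject_ts`) and
#'   `covariates`.
#' @export
read_manifest <- function(path, atlas, groups = c("NC", "MCI", "AD")) {
  stopifnot(inherits(atlas, "brain_atlas"))
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "mmse", "timeseries_path")
  if (!all(req %in% names(mf)))
    stop("manifest must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(mf$subject_id))
    stop("duplicate subject_id in manifest: ",
         paste(unique(mf$subject_id[duplicated(mf$subject_id)]),
               collapse = ", "))
  bad <- !mf$group %in% groups
  if (any(bad))
    stop("unknown group label(s) in manifest: ",
         paste(unique(mf$group[bad]), collapse = ", "))
  base <- dirname(path)
  series <- list()
  tt <- NULL
  for (k in seq_len(nrow(mf))) {
    f <- mf$timeseries_path[k]
    if (!file.exists(f)) f <- file.path(base, mf$timeseries_path[k])
    if (!file.exists(f))
      stop("time-series file not found for subject ", mf$subject_id[k],
           ": ", mf$timeseries_path[k])
    ts <- read_timeseries(f)
    if (ncol(ts) != atlas$n_regions)
      stop("subject ", mf$subject_id[k], " has ", ncol(ts),
           " regions but the atlas has ", atlas$n_regions)
    if (is.null(tt)) tt <- nrow(ts)
    if (nrow(ts) != tt)
      stop("subject ", mf$subject_id[k], " has ", nrow(ts),
           " timepoints; expected ", tt)
    series[[mf$subject_id[k]]] <- ts
  }
  list(series = series,
       covariates = mf[c("subject_id", "group", "mmse")])
}

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end workflow. `run_config()` builds
#' one from arguments; `read_run_config()` loads a YAML file with the same
#' field names (fields omitted from the file keep their defaults).
#'
#' @param atlas_path Atlas table path; `NULL` uses the bundled 90-region
#'   atlas.
#' @param manifest_path Cohort manifest CSV; `NULL` simulates a synthetic
#'   cohort instead.
#' @param low_hz,high_hz Band-pass edges (Hz).
#' @param preprocess Condition each series (drift removal + band-pass)
#'   before correlation; defaults to `FALSE` for already-conditioned or
#'   synthetic regional data.
#' @param control,patient Groups contrasted for altered-edge selection.
#' @param alpha_one,q_two,alpha_mmse Thresholds of the dual criterion and
#'   the cognition correlations.
#' @param var_equal Pooled (TRUE) or Welch two-sample tests.
#' @param absolute_strength Use |z| for mean-strength summaries.
#' @param seed Master seed for simulation.
#' @param group_sizes,n_timepoints Simulated cohort dimensions (used only
#'   when no manifest is given); defaults are those of [cohort_config()].
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(atlas_path = NULL, manifest_path = NULL,
                       low_hz = 0.01, high_hz = 0.08, preprocess = FALSE,
                       control = "NC", patient = "AD",
                       alpha_one = 0.05, q_two = 0.05, alpha_mmse = 0.05,
                       var_equal = TRUE, absolute_strength = TRUE,
                       seed = 1L, group_sizes = c(NC = 27, MCI = 27, AD = 35),
                       n_timepoints = 200, out_dir = "connectograph_out") {
  for (a in c(alpha_one, q_two, alpha_mmse))
    if (a <= 0 || a >= 1) stop("thresholds must lie in (0, 1)")
  structure(list(atlas_path = atlas_path, manifest_path = manifest_path,
                 low_hz = low_hz, high_hz = high_hz, preprocess = preprocess,
                 control = control, patient = patient,
                 alpha_one = alpha_one, q_two = q_two,
                 alpha_mmse = alpha_mmse, var_equal = var_equal,
                 absolute_strength = absolute_strength,
                 seed = as.integer(seed),
                 group_sizes = unlist(group_sizes),
                 n_timepoints = n_timepoints, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()   # empty file -> all defaults
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the full simulate/load -> connectome -> edges -> cognition workflow
#'
#' Writes, under `config$out_dir`: per-subject Fisher-z matrices, group
#' mean and difference matrices, the altered-edge table
#' (`altered_edges.csv`), a topology summary (`summary.json`), the
#' cognition report (`cognition.csv` + rows in the summary), and a
#' provenance record (`provenance.json`: config, seed, package version).
#' Identical config and seed reproduce byte-identical numeric outputs.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the in-memory results (`stack`,
#'   `altered`, `summary`, `cognition`, `anova`, `paths`).
#' @export
run_full_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  atlas <- if (is.null(config$atlas_path)) aal90_atlas() else
    load_atlas(config$atlas_path)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config$manifest_path)) {
    cohort <- simulate_cohort(cov_spec(atlas),
                              cohort_config(group_sizes = config$group_sizes,
                                            n_timepoints = config$n_timepoints,
                                            seed = config$seed))
    series <- cohort$series
    covariates <- cohort$covariates
  } else {
    loaded <- read_manifest(config$manifest_path, atlas)
    series <- loaded$series
    covariates <- loaded$covariates
  }
  if (config$preprocess)
    series <- lapply(series, function(ts)
      suppressMessages(preprocess_series(ts, low = config$low_hz,
                                         high = config$high_hz)))
  stack <- compute_connectivity(series, covariates, atlas)

  mat_dir <- file.path(config$out_dir, "matrices")
  dir.create(mat_dir, showWarnings = FALSE)
  for (k in seq_len(dim(stack$z)[3]))
    write_matrix_txt(stack$z[, , k],
                     file.path(mat_dir,
                               paste0(covariates$subject_id[k], "_z.tsv")))
  present <- levels(droplevels(stack$covariates$group))
  for (g in present)
    write_matrix_txt(group_mean_matrix(stack, g,
                                       absolute = config$absolute_strength),
                     file.path(config$out_dir, paste0("mean_", g, ".tsv")))
  if (all(c(config$control, config$patient) %in% present))
    write_matrix_txt(group_difference_matrix(stack, config$control,
                                             config$patient),
                     file.path(config$out_dir,
                               paste0("diff_", config$control, "_minus_",
                                      config$patient, ".tsv")))

  altered <- select_altered_edges(stack, config$control, config$patient,
                                  alpha_one = config$alpha_one,
                                  q_two = config$q_two,
                                  var_equal = config$var_equal)
  utils::write.csv(as.data.frame(altered),
                   file.path(config$out_dir, "altered_edges.csv"),
                   row.names = FALSE)
  summ <- summarize_altered(altered, atlas)
  anova <- group_strength_anova(stack, absolute = config$absolute_strength)

  patient_groups <- setdiff(present, config$control)
  cognition <- lapply(c(as.list(patient_groups),
                        if (length(patient_groups) > 1) list(patient_groups)),
                      function(gs) edge_mmse_correlation(stack, altered,
                                                         group_set = gs,
                                                         alpha = config$alpha_mmse))
  cog_tab <- do.call(rbind, lapply(cognition, as.data.frame))
  utils::write.csv(cog_tab, file.path(config$out_dir, "cognition.csv"),
                   row.names = FALSE)
  report <- correlation_report(cognition)

  summary_json <- list(
    n_subjects = nrow(covariates),
    n_regions = atlas$n_regions,
    n_edges = edge_count(atlas),
    altered_total = summ$total,
    critical_p = attr(altered, "critical_p"),
    class_tally = as.list(as.data.frame(summ$class_tally)),
    lobe_counts = as.list(summ$lobe_counts),
    top_nodes = utils::head(summ$node_degree, 10),
    anova = anova[c("F", "df1", "df2", "p")],
    cognition_report = report
  )
  jsonlite::write_json(summary_json,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  provenance <- list(package = "connectograph",
                     version = as.character(utils::packageVersion("connectograph")),
                     seed = config$seed,
                     config = unclass(config))
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(stack = stack, altered = altered, summary = summ,
                 cognition = report, anova = anova,
                 paths = list(out_dir = config$out_dir)))
}
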