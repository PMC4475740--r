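#' Load a brain atlas table
#'
#' Reads a delimited region catalogue and validates it. The atlas fixes the
#' node order of every matrix in the pipeline: matrix row/column k is the
#' k-th row of the atlas file.
#'
#' @param path Path to a TSV/CSV file with header columns `index`,
#'   `label_value`, `abbreviation`, `hemisphere`, `lobe`. `index` must be
#'   contiguous starting at 0 or 1 (normalized to 1-based internally);
#'   `label_value` is the positive integer code used in label images;
#'   `hemisphere` is `"left"` or `"right"`; `lobe` is an open vocabulary
#'   (any non-empty token), so alternative parcellations work.
#' @param sep Field separator; guessed from the file extension by default.
#' @return A `brain_atlas` object: a list with `regions` (data frame in node
#'   order) and `n_regions`.
#' @seealso [aal90_atlas()] for the bundled 90-region default.
#' @export
load_atlas <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  required <- c("index", "label_value", "abbreviation", "hemisphere", "lobe")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("atlas table is missing column(s): ", paste(missing, collapse = ", "))
  new_atlas(df[required])
}

#' The bundled 90-region anatomical atlas
#'
#' Ninety cortical and subcortical regions (45 per hemisphere) following the
#' standard automated-anatomical-labeling parcellation, with a conventional
#' six-lobe grouping (frontal, limbic, occipital, parietal, subcortical,
#' temporal; the insula is grouped with the limbic lobe). Lobe assignments
#' are a package convention; supply your own table via [load_atlas()] to
#' override them.
#'
#' @return A `brain_atlas` with 90 regions.
#' @export
aal90_atlas <- function() {
  load_atlas(system.file("extdata", "aal90_atlas.tsv",
                         package = "connectograph", mustWork = TRUE))
}

new_atlas <- function(df) {
  n <- nrow(df)
  if (n < 1) stop("atlas must contain at least one region")
  idx <- df$index
  if (anyDuplicated(idx))
    stop("duplicate region index at row(s): ",
         paste(which(duplicated(idx)), collapse = ", "))
  # accept 0- or 1-based contiguous indices; store 1-based
  if (all(sort(idx) == 0:(n - 1))) {
    df$index <- idx + 1L
  } else if (!all(sort(idx) == 1:n)) {
    stop("region indices must be contiguous from 0 (or 1); got range ",
         min(idx), "..", max(idx))
  }
  if (anyDuplicated(df$label_value))
    stop("duplicate label_value at row(s): ",
         paste(which(duplicated(df$label_value)), collapse = ", "))
  if (any(df$label_value <= 0)) stop("label_value must be positive")
  bad_hemi <- !df$hemisphere %in% c("left", "right")
  if (any(bad_hemi))
    stop("unknown hemisphere token(s): ",
         paste(unique(df$hemisphere[bad_hemi]), collapse = ", "),
         " (row ", paste(which(bad_hemi), collapse = ", "), ")")
  if (any(is.na(df$lobe) | df$lobe == ""))
    stop("empty lobe label at row(s): ",
         paste(which(is.na(df$lobe) | df$lobe == ""), collapse = ", "))
  # keep file order as node order
  df <- df[order(df$index), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(regions = df, n_regions = n), class = "brain_atlas")
}

#' @export
print.brain_atlas <- function(x, ...) {
  cat("brain_atlas:", x$n_regions, "regions,",
      sum(x$regions$hemisphere == "left"), "left /",
      sum(x$regions$hemisphere == "right"), "right\n")
  cat("lobes:", paste(names(table(x$regions$lobe)), collapse = ", "), "\n")
  invisible(x)
}

#' Region display names
#'
#' Abbreviation plus hemisphere suffix (e.g. `"PCG.L"`), used as column
#' headers in serialized matrices and time series.
#'
#' @param atlas A `brain_atlas`.
#' @return Character vector of length `n_regions` in node order.
#' @export
region_names <- function(atlas) {
  stopifnot(inherits(atlas, "brain_atlas"))
  paste0(atlas$regions$abbreviation, ".",
         ifelse(atlas$regions$hemisphere == "left", "L", "R"))
}

#' Number of unique edges of an atlas
#'
#' All unordered region pairs, excluding the diagonal: N(N-1)/2. For the
#' bundled 90-region atlas this is 4005.
#'
#' @param atlas A `brain_atlas`, or an integer region count.
#' @return Integer edge count.
#' @export
edge_count <- function(atlas) {
  n <- if (inherits(atlas, "brain_atlas")) atlas$n_regions else as.integer(atlas)
  stopifnot(length(n) == 1, n >= 0)
  n * (n - 1) / 2
}

#' Enumerate the unique edges of an atlas
#'
#' Upper-triangle (i < j) pairs in column-major order, the canonical edge
#' order used by every edge-wise vector in the package (it matches
#' `M[upper.tri(M)]` for an N x N matrix `M`).
#'
#' @param atlas A `brain_atlas` or an integer region count.
#' @return Data frame with integer columns `i`, `j` (1-based node indices,
#'   `i < j`), one row per edge.
#' @export
edge_table <- function(atlas) {
  n <- if (inherits(atlas, "brain_atlas")) atlas$n_regions else as.integer(atlas)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0)))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
}

#' Classify edges by lobe and hemisphere
#'
#' An edge is *interlobe* when its endpoints' lobe labels differ and
#' *interhemispheric* when the hemisphere labels differ; classification is
#' symmetric in (i, j).
#'
#' @param atlas A `brain_atlas`.
#' @param i,j Integer vectors of node indices (1-based, recycled).
#' @return Data frame with columns `lobe_class`
#'   (`"interlobe"`/`"intralobe"`) and `hemisphere_class`
#'   (`"interhemispheric"`/`"intrahemispheric"`).
#' @export
classify_edge <- function(atlas, i, j) {
  stopifnot(inherits(atlas, "brain_atlas"))
  n <- atlas$n_regions
  if (any(i < 1 | i > n | j < 1 | j > n))
    stop("edge index out of range 1..", n)
  r <- atlas$regions
  data.frame(
    lobe_class = ifelse(r$lobe[i] != r$lobe[j], "interlobe", "intralobe"),
    hemisphere_class = ifelse(r$hemisphere[i] != r$hemisphere[j],
                              "interhemispheric", "intrahemispheric")
  )
}

#' Homologous interhemispheric region pairs
#'
#' Pairs sharing an abbreviation but lying in opposite hemispheres
#' (left/right counterparts of the same anatomical region).
#'
#' @param atlas A `brain_atlas`.
#' @return Data frame with columns `i`, `j` (`i < j`).
#' @export
homologous_pairs <- function(atlas) {
  stopifnot(inherits(atlas, "brain_atlas"))
  r <- atlas$regions
  out <- list()
  for (ab in unique(r$abbreviation)) {
    l <- which(r$abbreviation == ab & r$hemisphere == "left")
    h <- which(r$abbreviation == ab & r$hemisphere == "right")
    if (length(l) == 1 && length(h) == 1)
      out[[ab]] <- c(min(l, h), max(l, h))
  }
  if (length(out) == 0) return(data.frame(i = integer(0), j = integer(0)))
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]))
}
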