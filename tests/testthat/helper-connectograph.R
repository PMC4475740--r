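# Shared fixtures, all built in code.

# Small atlas: `pairs` homologous left/right pairs, lobes cycled from `lobes`.
toy_atlas <- function(pairs = 5, lobes = c("frontal", "temporal")) {
  ab <- paste0("R", seq_len(pairs))
  df <- data.frame(
    index = seq_len(2 * pairs),
    label_value = seq_len(2 * pairs) * 10L,
    abbreviation = rep(ab, each = 2),
    hemisphere = rep(c("left", "right"), pairs),
    lobe = rep(rep_len(lobes, pairs), each = 2)
  )
  atlas_from_df(df)
}

atlas_from_df <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  load_atlas(f)
}

# Stack with prescribed per-edge z values: `z_by_group` is a list
# group -> matrix (subjects x edges, canonical upper-triangle order).
stack_from_edges <- function(atlas, z_by_group) {
  n <- atlas$n_regions
  ut <- upper.tri(matrix(0, n, n))
  mats <- list(); rows <- list(); k <- 0
  for (g in names(z_by_group)) {
    E <- z_by_group[[g]]
    for (s in seq_len(nrow(E))) {
      k <- k + 1
      m <- matrix(0, n, n)
      m[ut] <- E[s, ]
      m <- m + t(m)
      mats[[k]] <- m
      rows[[k]] <- data.frame(subject_id = sprintf("%s_%d", g, s),
                              group = g, mmse = NA_real_)
    }
  }
  cohort_stack(mats, do.call(rbind, rows), atlas)
}

# Independent Benjamini-Hochberg oracle: check every k explicitly.
brute_bh <- function(p, q) {
  m <- length(p)
  if (m == 0) return(logical(0))
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0) return(rep(FALSE, m))
  p[] <- p <= ps[max(ok)]
  as.logical(p)
}

# One shared small simulated cohort, computed once per test run.
.shared <- new.env()
shared_cohort <- function() {
  if (is.null(.shared$cohort)) {
    atlas <- aal90_atlas()
    spec <- cov_spec(atlas)
    cfg <- cohort_config(group_sizes = c(NC = 8, MCI = 8, AD = 10),
                         n_timepoints = 150, seed = 42)
    .shared$cohort <- suppressWarnings(simulate_cohort(spec, cfg))
    .shared$stack <- compute_connectivity(.shared$cohort)
  }
  list(cohort = .shared$cohort, stack = .shared$stack)
}
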