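#' Correlate altered-edge strengths with MMSE
#'
#' For every altered edge, Pearson's correlation (with two-tailed p from
#' `stats::cor.test`) between the subjects' Fisher-z values at that edge
#' and their MMSE scores, over the pooled subjects of `group_set`
#' (patients combined by default). These relationships are exploratory, so
#' p-values are uncorrected; the significance flag uses `alpha` as-is.
#'
#' @param stack A `cohort_stack`; every subject in `group_set` must carry
#'   an MMSE value.
#' @param edges An `altered_edges` table (or data frame with `i`, `j`).
#' @param group_set Character vector of groups to pool (e.g. `"AD"`,
#'   `c("MCI", "AD")`).
#' @param alpha Uncorrected two-tailed significance level.
#' @return A `cognition_correlations` data frame: `i`, `j`, `region_i`,
#'   `region_j`, `group_set`, `r`, `p`, `n`, `significant`,
#'   `significant_positive`. Constant MMSE makes r undefined; such rows are
#'   flagged not significant and reported via `message()`.
#' @export
edge_mmse_correlation <- function(stack, edges, group_set = c("MCI", "AD"),
                                  alpha = 0.05) {
  idx <- which(stack$covariates$group %in% group_set)
  if (length(idx) < 3) stop("fewer than 3 subjects in group set ",
                            paste(group_set, collapse = "+"))
  mmse <- stack$covariates$mmse[idx]
  if (anyNA(mmse))
    stop("missing MMSE for subject(s): ",
         paste(stack$covariates$subject_id[idx][is.na(mmse)], collapse = ", "))
  label <- paste(group_set, collapse = "+")
  nm <- region_names(stack$atlas)
  constant_mmse <- stats::var(mmse) == 0
  if (constant_mmse)
    message("MMSE constant in group set ", label,
            "; correlations undefined, flagged not significant")
  rows <- lapply(seq_len(nrow(edges)), function(k) {
    z <- stack$z[edges$i[k], edges$j[k], idx]
    if (constant_mmse || stats::var(z) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(z, mmse)
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(i = edges$i[k], j = edges$j[k],
               region_i = nm[edges$i[k]], region_j = nm[edges$j[k]],
               group_set = label, r = r, p = p, n = length(idx))
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(i = integer(0), j = integer(0), region_i = character(0),
               region_j = character(0), group_set = character(0),
               r = numeric(0), p = numeric(0), n = integer(0))
  out$significant <- !is.na(out$p) & out$p < alpha
  out$significant_positive <- out$significant & out$r > 0
  rownames(out) <- NULL
  structure(out, alpha = alpha,
            class = c("cognition_correlations", "data.frame"))
}

#' Tabulate cognition correlations per group set
#'
#' Bookkeeping over one or more [edge_mmse_correlation()] results: how many
#' altered edges, how many significantly positive / negative correlations,
#' and the headline edge (largest |r|) per group set.
#'
#' @param correlations A `cognition_correlations` data frame, or a list of
#'   them (e.g. MCI, AD, MCI+AD).
#' @return Data frame with one row per group set: `group_set`, `total`,
#'   `significant_positive`, `significant_negative`, `headline_edge`,
#'   `headline_r`.
#' @export
correlation_report <- function(correlations) {
  if (is.data.frame(correlations)) correlations <- list(correlations)
  rows <- lapply(correlations, function(cc) {
    if (nrow(cc) == 0)
      return(data.frame(group_set = NA_character_, total = 0L,
                        significant_positive = 0L, significant_negative = 0L,
                        headline_edge = NA_character_, headline_r = NA_real_))
    best <- which.max(abs(cc$r))
    data.frame(
      group_set = cc$group_set[1],
      total = nrow(cc),
      significant_positive = sum(cc$significant & cc$r > 0, na.rm = TRUE),
      significant_negative = sum(cc$significant & cc$r < 0, na.rm = TRUE),
      headline_edge = if (length(best) == 1 && !all(is.na(cc$r)))
        paste(cc$region_i[best], cc$region_j[best], sep = "--") else
          NA_character_,
      headline_r = if (length(best) == 1) cc$r[best] else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
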