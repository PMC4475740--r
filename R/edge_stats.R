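edge_matrix <- function(stack, idx) {
  # subjects x edges matrix of Fisher z, canonical upper-triangle order
  n <- stack$atlas$n_regions
  ut <- upper.tri(matrix(0, n, n))
  out <- matrix(0, length(idx), sum(ut))
  for (k in seq_along(idx)) out[k, ] <- stack$z[, , idx[k]][ut]
  out
}

two_tailed_p <- function(t, df) 2 * stats::pt(-abs(t), df)

degenerate_p <- function(means) {
  # limit p-values for zero-variance edges: 0 if the mean is away from 0
  ifelse(means == 0, 1, 0)
}

#' One-sample edge-wise t-tests within a group
#'
#' For every edge, tests whether the group's Fisher-z values differ from
#' zero: `t = mean(z) / (sd(z) / sqrt(n))`, `df = n - 1`, two-tailed p.
#' Edges with zero variance across subjects get the limit p-value (0 for a
#' nonzero mean, 1 otherwise) and are reported via `message()`.
#'
#' @param stack A `cohort_stack`.
#' @param group Group label.
#' @return Data frame with one row per edge: `i`, `j`, `t`, `df`, `p`,
#'   `mean_z`, `comparison`.
#' @export
one_sample_edge_tests <- function(stack, group) {
  idx <- stack_group_index(stack, group)
  if (length(idx) < 3) stop("group ", group, " has fewer than 3 subjects")
  E <- edge_matrix(stack, idx)
  n <- nrow(E)
  m <- colMeans(E)
  s <- apply(E, 2, stats::sd)
  t <- m / (s / sqrt(n))
  p <- two_tailed_p(t, n - 1)
  degen <- s == 0
  if (any(degen)) {
    message(sum(degen), " zero-variance edge(s) in group ", group,
            "; limit p-values substituted")
    p[degen] <- degenerate_p(m[degen])
    t[degen] <- ifelse(m[degen] == 0, 0, sign(m[degen]) * Inf)
  }
  cbind(stack$edges,
        data.frame(t = t, df = n - 1, p = p, mean_z = m,
                   comparison = paste0("one_sample:", group)))
}

#' Two-sample edge-wise t-tests between groups
#'
#' Classical pooled-variance Student's t by default (`df = nA + nB - 2`);
#' Welch's unequal-variance form is available via `var_equal = FALSE`. The
#' sign of t encodes direction (group A minus group B). Zero pooled
#' variance is handled as in [one_sample_edge_tests()].
#'
#' @param stack A `cohort_stack`.
#' @param group_a,group_b Group labels.
#' @param var_equal Pooled-variance Student's t (`TRUE`, default) or Welch.
#' @return Data frame with one row per edge: `i`, `j`, `t`, `df`, `p`,
#'   `mean_a`, `mean_b`, `comparison`.
#' @export
two_sample_edge_tests <- function(stack, group_a, group_b, var_equal = TRUE) {
  ia <- stack_group_index(stack, group_a)
  ib <- stack_group_index(stack, group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("both groups need at least 2 subjects")
  A <- edge_matrix(stack, ia); B <- edge_matrix(stack, ib)
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- apply(A, 2, stats::var); vb <- apply(B, 2, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  diff <- ma - mb
  t <- diff / se
  p <- two_tailed_p(t, df)
  degen <- se == 0
  if (any(degen)) {
    message(sum(degen), " zero-pooled-variance edge(s) in ",
            group_a, " vs ", group_b, "; limit p-values substituted")
    p[degen] <- degenerate_p(diff[degen])
    t[degen] <- ifelse(diff[degen] == 0, 0, sign(diff[degen]) * Inf)
    df[degen] <- na + nb - 2
  }
  cbind(stack$edges,
        data.frame(t = t, df = df, p = p, mean_a = ma, mean_b = mb,
                   comparison = paste0("two_sample:", group_a, "_vs_", group_b)))
}

#' Bonferroni rejection mask
#'
#' Rejects where `p < alpha / m`; by default m is the number of tests
#' supplied (the full edge count when tests cover every edge).
#'
#' @param tests Data frame from an edge-test function, or a numeric p-vector.
#' @param alpha Familywise level.
#' @param m Number of comparisons.
#' @return Logical vector.
#' @export
bonferroni_mask <- function(tests, alpha = 0.05, m = NULL) {
  p <- if (is.data.frame(tests)) tests$p else tests
  m <- m %||% length(p)
  stopifnot(m >= 1)
  p < alpha / m
}

#' Benjamini-Hochberg step-up rejection mask
#'
#' Controls the false discovery rate at level `q`: with the p-values sorted
#' ascending, find the largest k with `p(k) <= k * q / m` and reject all
#' p-values at or below that critical p (ties share their fate). Computed
#' via `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return List with `mask` (logical) and `critical_p` (largest rejected
#'   p-value; `NA` when nothing is rejected).
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) return(list(mask = logical(0), critical_p = NA_real_))
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  mask <- stats::p.adjust(p, method = "BH") <= q
  list(mask = mask,
       critical_p = if (any(mask)) max(p[mask]) else NA_real_)
}

#' Select group-altered edges by the dual criterion
#'
#' An edge is *altered* iff (a) its Fisher-z values differ significantly
#' from zero in at least one of the two groups (one-sample two-tailed
#' t-test, Bonferroni-corrected over all edges within each group), AND
#' (b) the z values differ significantly between the groups (two-sample
#' two-tailed t-test, Benjamini-Hochberg FDR-corrected). Direction is
#' `"decreased"` when the control mean exceeds the patient mean.
#'
#' @param stack A `cohort_stack`.
#' @param control,patient Group labels to compare.
#' @param alpha_one Level of criterion (a) before Bonferroni division.
#' @param q_two FDR level of criterion (b).
#' @param var_equal Passed to [two_sample_edge_tests()].
#' @return An `altered_edges` data frame (one row per selected edge) with
#'   node abbreviations, t, p, direction, the groups that passed criterion
#'   (a), and lobe/hemisphere classes; attributes `critical_p`, `params`,
#'   and `n_candidates` (edges passing criterion (a)).
#' @export
select_altered_edges <- function(stack, control = "NC", patient = "AD",
                                 alpha_one = 0.05, q_two = 0.05,
                                 var_equal = TRUE) {
  one_c <- one_sample_edge_tests(stack, control)
  one_p <- one_sample_edge_tests(stack, patient)
  m <- nrow(stack$edges)
  mask_c <- bonferroni_mask(one_c, alpha_one, m)
  mask_p <- bonferroni_mask(one_p, alpha_one, m)
  crit_a <- mask_c | mask_p
  two <- two_sample_edge_tests(stack, control, patient, var_equal = var_equal)
  fdr <- bh_fdr(two$p, q_two)
  sel <- crit_a & fdr$mask
  ed <- stack$edges[sel, , drop = FALSE]
  r <- stack$atlas$regions
  nm <- region_names(stack$atlas)
  cls <- if (nrow(ed) > 0) classify_edge(stack$atlas, ed$i, ed$j) else
    data.frame(lobe_class = character(0), hemisphere_class = character(0))
  out <- data.frame(
    i = ed$i, j = ed$j,
    region_i = nm[ed$i], region_j = nm[ed$j],
    t = two$t[sel], p = two$p[sel], df = two$df[sel],
    mean_control = two$mean_a[sel], mean_patient = two$mean_b[sel],
    direction = ifelse(two$mean_a[sel] > two$mean_b[sel],
                       "decreased", "increased"),
    passed_one_sample = paste0(ifelse(mask_c[sel], control, ""),
                               ifelse(mask_c[sel] & mask_p[sel], "+", ""),
                               ifelse(mask_p[sel], patient, "")),
    lobe_class = cls$lobe_class,
    hemisphere_class = cls$hemisphere_class
  )
  rownames(out) <- NULL
  structure(out,
            critical_p = fdr$critical_p,
            n_candidates = sum(crit_a),
            params = list(control = control, patient = patient,
                          alpha_one = alpha_one, q_two = q_two,
                          var_equal = var_equal),
            class = c("altered_edges", "data.frame"))
}

#' Summarize altered edges by node, lobe and class
#'
#' @param edges An `altered_edges` table (or any data frame with `i`, `j`).
#' @param atlas The `brain_atlas` the edges refer to.
#' @return List with `node_degree` (data frame ranked by degree among
#'   altered edges), `lobe_counts` (edge endpoints per lobe), and
#'   `class_tally` (interlobe/intralobe x interhemispheric/intrahemispheric
#'   counts plus `total`).
#' @export
summarize_altered <- function(edges, atlas) {
  stopifnot(inherits(atlas, "brain_atlas"))
  n <- atlas$n_regions
  nm <- region_names(atlas)
  deg <- integer(n)
  lobe_levels <- sort(unique(atlas$regions$lobe))
  lobes <- stats::setNames(integer(length(lobe_levels)), lobe_levels)
  tally <- matrix(0L, 2, 2,
                  dimnames = list(c("interlobe", "intralobe"),
                                  c("interhemispheric", "intrahemispheric")))
  if (nrow(edges) > 0) {
    tab <- table(factor(c(edges$i, edges$j), levels = 1:n))
    deg <- as.integer(tab)
    lt <- table(factor(atlas$regions$lobe[c(edges$i, edges$j)],
                       levels = lobe_levels))
    lobes[] <- as.integer(lt)
    cls <- classify_edge(atlas, edges$i, edges$j)
    ct <- table(factor(cls$lobe_class, levels = rownames(tally)),
                factor(cls$hemisphere_class, levels = colnames(tally)))
    tally[] <- as.integer(ct)
  }
  node_degree <- data.frame(region = nm,
                            lobe = atlas$regions$lobe,
                            degree = deg)
  node_degree <- node_degree[order(-node_degree$degree, node_degree$region), ]
  rownames(node_degree) <- NULL
  list(node_degree = node_degree,
       lobe_counts = lobes,
       class_tally = tally,
       total = nrow(edges))
}

#' One-way ANOVA on per-subject mean connectivity strength
#'
#' Compares the groups' mean connectivity strengths (per-subject mean of
#' |z| by default) with `stats::aov`, plus pairwise two-sample t-tests as
#' post hoc contrasts. With three groups of 27/35/27 subjects the error
#' degrees of freedom are 86.
#'
#' @param stack A `cohort_stack`.
#' @param absolute Use |z| for per-subject strength.
#' @param var_equal Pooled post hoc t-tests when `TRUE`.
#' @return List with `F`, `df1`, `df2`, `p`, `group_means`, `strengths`,
#'   and `pairwise` (data frame of post hoc contrasts).
#' @export
group_strength_anova <- function(stack, absolute = TRUE, var_equal = TRUE) {
  s <- subject_strengths(stack, absolute = absolute)
  g <- droplevels(stack$covariates$group)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 subjects")
  if (stats::var(s) == 0) {
    message("all subjects have identical strength; F undefined, p set to 1")
    aov_row <- c(F = 0, df1 = nlevels(g) - 1, df2 = length(s) - nlevels(g),
                 p = 1)
  } else {
    fit <- stats::aov(s ~ g)
    sm <- summary(fit)[[1]]
    aov_row <- c(F = sm$`F value`[1], df1 = sm$Df[1], df2 = sm$Df[2],
                 p = sm$`Pr(>F)`[1])
  }
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    a <- s[g == pr[1]]; b <- s[g == pr[2]]
    if (stats::var(a) + stats::var(b) == 0) {
      # degenerate contrast: no spread in either group
      return(data.frame(group_a = pr[1], group_b = pr[2],
                        t = if (mean(a) == mean(b)) 0 else
                          sign(mean(a) - mean(b)) * Inf,
                        df = length(a) + length(b) - 2,
                        p = if (mean(a) == mean(b)) 1 else 0))
    }
    ht <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(group_a = pr[1], group_b = pr[2],
               t = unname(ht$statistic), df = unname(ht$parameter),
               p = ht$p.value)
  }))
  list(F = unname(aov_row["F"]), df1 = unname(aov_row["df1"]),
       df2 = unname(aov_row["df2"]), p = unname(aov_row["p"]),
       group_means = tapply(s, g, mean),
       strengths = s, pairwise = pw)
}
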