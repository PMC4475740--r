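test_that("one-sample edge t matches the hand formula", {
  atlas <- toy_atlas(pairs = 1)
  z <- matrix(c(0.1, 0.2, 0.3, 0.4), 4, 1)
  stack <- stack_from_edges(atlas, list(NC = z))
  res <- one_sample_edge_tests(stack, "NC")
  expect_equal(res$t, 0.25 / (sd(z) / 2), tolerance = 1e-12)
  expect_equal(res$t, 3.872983, tolerance = 1e-6)
  expect_equal(res$df, 3)
  expect_equal(res$p, unname(t.test(z)$p.value), tolerance = 1e-12)

  zero <- stack_from_edges(atlas, list(NC = matrix(0, 4, 1)))
  r0 <- one_sample_edge_tests(zero, "NC")
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)

  const <- stack_from_edges(atlas, list(NC = matrix(0.3, 4, 1)))
  expect_message(rc <- one_sample_edge_tests(const, "NC"), "zero-variance")
  expect_equal(rc$p, 0)
})

test_that("two-sample pooled t matches hand and reference computations", {
  atlas <- toy_atlas(pairs = 1)
  stack <- stack_from_edges(atlas, list(NC = matrix(c(1, 2, 3), 3, 1),
                                        AD = matrix(c(2, 3, 4), 3, 1)))
  res <- two_sample_edge_tests(stack, "NC", "AD")
  expect_equal(res$t, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  ht <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(res$t, unname(ht$statistic), tolerance = 1e-12)
  expect_equal(res$p, ht$p.value, tolerance = 1e-12)

  same <- stack_from_edges(atlas, list(NC = matrix(c(1, 2, 3), 3, 1),
                                       AD = matrix(c(1, 2, 3), 3, 1)))
  rs <- two_sample_edge_tests(same, "NC", "AD")
  expect_equal(rs$t, 0); expect_equal(rs$p, 1)
})

test_that("edge-wise tests agree with stats::t.test across random edges", {
  atlas <- toy_atlas(pairs = 3)   # 6 regions, 15 edges
  set.seed(9)
  A <- matrix(rnorm(8 * 15, sd = 0.4), 8, 15)
  B <- matrix(rnorm(11 * 15, mean = 0.1, sd = 0.5), 11, 15)
  stack <- stack_from_edges(atlas, list(NC = A, AD = B))
  for (ve in c(TRUE, FALSE)) {
    res <- two_sample_edge_tests(stack, "NC", "AD", var_equal = ve)
    for (e in c(1, 7, 15)) {
      ht <- t.test(A[, e], B[, e], var.equal = ve)
      expect_equal(res$t[e], unname(ht$statistic), tolerance = 1e-10)
      expect_equal(res$df[e], unname(ht$parameter), tolerance = 1e-10)
      expect_equal(res$p[e], ht$p.value, tolerance = 1e-10)
    }
  }
  one <- one_sample_edge_tests(stack, "AD")
  for (e in c(2, 9)) {
    ht <- t.test(B[, e])
    expect_equal(one$t[e], unname(ht$statistic), tolerance = 1e-10)
    expect_equal(one$p[e], ht$p.value, tolerance = 1e-10)
  }
})

test_that("two-sample df follows the pooled contract at study sizes", {
  atlas <- toy_atlas(pairs = 1)
  set.seed(10)
  stack <- stack_from_edges(atlas, list(NC = matrix(rnorm(27), 27, 1),
                                        AD = matrix(rnorm(35), 35, 1)))
  expect_equal(two_sample_edge_tests(stack, "NC", "AD")$df, 60)
})

test_that("bonferroni mask thresholds at alpha / m", {
  expect_equal(0.05 / 4005, 1.248439e-5, tolerance = 1e-6)
  p <- c(1e-6, 1e-5, 1e-4, 0.04)
  expect_equal(bonferroni_mask(p, 0.05, m = 4005),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(bonferroni_mask(p, 0.05, m = 1), p < 0.05)
  expect_false(any(bonferroni_mask(rep(1, 10), 0.05)))
})

test_that("bh_fdr implements the step-up rule", {
  # step-up by hand: thresholds k*q/m = .01, .02, .03, .04, .05;
  # p(1)=.001 and p(2)=.008 pass, p(3)=.039 > .03 and p(4)=.041 > .04 fail,
  # so the largest passing rank is 2 and only the first two are rejected
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27)
  res <- bh_fdr(p, 0.05)
  expect_identical(res$mask, brute_bh(p, 0.05))
  expect_equal(res$mask, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$critical_p, 0.008)
  # a relaxed q admits the tied cluster at ranks 3-4
  expect_equal(bh_fdr(p, 0.06)$mask, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bh_fdr(rep(1, 8), 0.05)$mask))
  expect_true(bh_fdr(0.04, 0.05)$mask)
  expect_equal(bh_fdr(numeric(0), 0.05)$mask, logical(0))
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("bh_fdr agrees with brute-force enumeration; Bonferroni is stricter", {
  set.seed(11)
  for (k in 1:200) {
    n <- sample(1:50, 1)
    p <- round(runif(n), sample(c(1, 2, 3, 6), 1))  # rounding makes ties
    res <- bh_fdr(p, 0.05)
    expect_identical(res$mask, brute_bh(p, 0.05))
    bon <- bonferroni_mask(p, 0.05, m = n)
    expect_true(all(res$mask[bon]))
  }
})

test_that("dual-criterion selection requires both criteria", {
  atlas <- toy_atlas(pairs = 2, lobes = c("frontal", "temporal"))  # 6 edges
  n_e <- nrow(edge_table(atlas))
  # deterministic samples with exact means and sd 0.02:
  # edge 1: strong in both groups, different means -> selected, decreased
  # edge 2: significant group difference but z ~ 0 in both -> rejected by (a)
  # edge 3: strong in both groups, same mean -> rejected by (b)
  v <- as.numeric(scale(1:12))
  mk <- function(means) outer(v, rep(0.02, n_e)) +
    matrix(means, 12, n_e, byrow = TRUE)
  mean_nc <- c(0.8, 0.013, 0.6, 0, 0, 0)
  mean_ad <- c(0.3, -0.013, 0.6, 0, 0, 0)
  stack <- stack_from_edges(atlas, list(NC = mk(mean_nc),
                                        AD = mk(mean_ad)))
  sel <- select_altered_edges(stack, "NC", "AD")
  et <- edge_table(atlas)
  expect_equal(nrow(sel), 1)
  expect_equal(c(sel$i, sel$j), c(et$i[1], et$j[1]))
  expect_equal(sel$direction, "decreased")
  expect_match(sel$passed_one_sample, "NC")
  expect_gte(attr(sel, "n_candidates"), 2)

  # flipping the group means flips the direction label
  stack_up <- stack_from_edges(atlas, list(NC = mk(mean_ad),
                                           AD = mk(mean_nc)))
  expect_equal(select_altered_edges(stack_up, "NC", "AD")$direction,
               "increased")
})

test_that("summaries partition altered edges by node, lobe and class", {
  atlas <- aal90_atlas()
  empty <- summarize_altered(data.frame(i = integer(0), j = integer(0)),
                             atlas)
  expect_equal(empty$total, 0)
  expect_true(all(empty$node_degree$degree == 0))
  expect_true(all(empty$class_tally == 0))

  r <- atlas$regions
  pcc_l <- which(r$abbreviation == "PCG" & r$hemisphere == "left")
  others <- c(which(r$abbreviation == "SFGmed" & r$hemisphere == "right"),
              which(r$abbreviation == "PCUN" & r$hemisphere == "left"),
              which(r$abbreviation == "MTG" & r$hemisphere == "left"))
  edges <- data.frame(i = pmin(pcc_l, others), j = pmax(pcc_l, others))
  s <- summarize_altered(edges, atlas)
  expect_equal(s$total, 3)
  expect_equal(s$node_degree$region[1], "PCG.L")
  expect_equal(s$node_degree$degree[1], 3)
  expect_equal(sum(s$class_tally), s$total)
  expect_equal(sum(s$class_tally["interlobe", ]) +
                 sum(s$class_tally["intralobe", ]), 3)
})

test_that("group strength ANOVA has the right dfs and post hocs", {
  atlas <- toy_atlas(pairs = 2)
  set.seed(13)
  sizes <- c(NC = 27, MCI = 27, AD = 35)
  zg <- lapply(sizes, function(n) matrix(rnorm(n * 6, sd = 0.3), n, 6))
  stack <- stack_from_edges(atlas, zg)
  an <- group_strength_anova(stack)
  expect_equal(an$df1, 2)
  expect_equal(an$df2, 86)
  # cross-check against oneway.test with pooled variance
  ow <- oneway.test(subject_strengths(stack) ~ stack$covariates$group,
                    var.equal = TRUE)
  expect_equal(an$F, unname(ow$statistic), tolerance = 1e-10)
  expect_equal(an$p, ow$p.value, tolerance = 1e-10)
  expect_equal(nrow(an$pairwise), 3)
  expect_equal(an$pairwise$df[an$pairwise$group_a == "NC" &
                                an$pairwise$group_b == "AD"], 60)

  flat <- stack_from_edges(atlas, list(NC = matrix(0.2, 3, 6),
                                       AD = matrix(0.2, 3, 6)))
  expect_message(anf <- group_strength_anova(flat), "identical strength")
  expect_equal(anf$p, 1)
})
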