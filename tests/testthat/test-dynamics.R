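test_that("replicate fold change follows the imputation rule", {
  expect_equal(replicate_fold_change(c(10, 10), c(30, 30), 1)$median_fc, 3)
  expect_false(replicate_fold_change(c(10, 10), c(30, 30), 1)$imputed)
  ## zeros replaced by the dataset minimum, then recomputed
  r <- replicate_fold_change(c(0, 10), c(20, 20), dataset_min = 5)
  expect_equal(r$median_fc, 3)   # ratios (20/5, 20/10) = (4, 2)
  expect_true(r$imputed)
  expect_equal(replicate_fold_change(c(10, 10), c(5, 5), 1)$median_fc, 0.5)
  expect_error(replicate_fold_change(numeric(0), numeric(0), 1), "nonempty")
})

test_that("welch_t matches the closed-form df=2 worked example", {
  res <- welch_t(c(4, 6), c(9, 11))
  expect_equal(res$t, -5 / sqrt(2), tolerance = 1e-12)
  expect_equal(res$df, 2, tolerance = 1e-12)
  expect_equal(res$p, oracle_p_t_df2(res$t), tolerance = 1e-12)
  expect_equal(res$p, 0.0715, tolerance = 1e-3)
})

test_that("welch_t degenerate conventions are deterministic", {
  expect_equal(welch_t(c(2, 4), c(2, 4))$p, 1)   # identical groups -> t = 0
  expect_equal(welch_t(c(2, 4), c(2, 4))$t, 0)
  expect_equal(welch_t(c(1, 1), c(1, 1))$p, 1)   # both constant, equal
  expect_equal(welch_t(c(1, 1), c(2, 2))$p, 0)   # both constant, unequal
})

test_that("welch_t agrees with t.test on random samples", {
  set.seed(101)
  for (i in 1:1000) {
    a <- rnorm(sample(2:6, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(2:6, 1), mean = runif(1, -1, 1))
    ours <- welch_t(a, b)
    ref <- t.test(a, b)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-9)
  }
})

test_that("differential categories follow the FC-and-p rule", {
  d <- make_design()
  cl <- chans(d, "PE")
  m <- rbind(
    big_up  = c(10, 10, 10, 10, 10, 10, 10, 10),
    small   = c(10, 14, 10, 10, 10, 14, 10, 10),
    rescue  = c(0, 7, 10, 10, 0, 9, 10, 10))
  colnames(m) <- cl
  m["big_up", c(2, 6)] <- c(30, 31)   # FC ~3 at t45, consistent reps
  cmp <- timecourse_comparisons(d, "wild_type", "PE")
  calls <- call_differential(m, cmp, analysis_config(), dataset_min = 1)
  t45 <- calls[calls$comparison == "wild_type:t0-vs-t45", ]
  expect_equal(t45$category[t45$feature == "big_up"], "increased")
  ## FC 1.4 stays below threshold everywhere
  expect_true(all(calls$category[calls$feature == "small"] == "no_change"))
  ## 0-vs->0: qualifies by rule iff the t test is significant
  r45 <- t45[t45$feature == "rescue", ]
  expect_true(r45$zero_rescue == (r45$p_value < 0.05))
  expect_true(r45$imputed)
  expect_error(call_differential(m, list(list(label = "x", ref = "nope",
                                              test = cl[1])),
                                 analysis_config()), "unknown channel")
})

test_that("category assignment is scale invariant and direction-symmetric", {
  ## three replicates: the median of an odd number of ratios inverts
  ## exactly under a ref/test swap (with two, the median is a mean and
  ## inversion holds only approximately)
  d <- make_design(reps = 3L)
  cl <- chans(d, "PE")
  set.seed(21)
  m <- matrix(rexp(10 * length(cl), 1 / 50) + 1, 10, length(cl),
              dimnames = list(sprintf("s%d", 1:10), cl))
  cmp <- timecourse_comparisons(d, "wild_type", "PE")
  a <- call_differential(m, cmp, analysis_config(), dataset_min = min(m))
  b <- call_differential(m * 37.5, cmp, analysis_config(),
                         dataset_min = min(m) * 37.5)
  expect_equal(a$category, b$category)
  expect_equal(a$median_fc, b$median_fc, tolerance = 1e-12)
  ## swapping ref and test inverts fold changes and swaps categories
  swap <- lapply(cmp, function(x) list(label = x$label, ref = x$test,
                                       test = x$ref))
  s <- call_differential(m, swap, analysis_config(), dataset_min = min(m))
  expect_equal(s$median_fc, 1 / a$median_fc, tolerance = 1e-12)
  map <- c(increased = "decreased", decreased = "increased",
           no_change = "no_change")
  expect_equal(s$category, unname(map[a$category]))
})

test_that("imputed fold changes equal fold changes on substituted data", {
  d <- make_design()
  cl <- chans(d, "PE")
  set.seed(33)
  m <- matrix(rexp(20 * 8, 1 / 50), 20, 8,
              dimnames = list(sprintf("s%d", 1:20), cl))
  m[m < 15] <- 0
  dm <- min(m[m > 0])
  cmp <- timecourse_comparisons(d, "wild_type", "PE")
  with_zeros <- call_differential(m, cmp, analysis_config(), dm)
  m2 <- m; m2[m2 == 0] <- dm
  substituted <- call_differential(m2, cmp, analysis_config(), dm)
  ## the imputation path is exactly dataset-minimum substitution
  expect_equal(with_zeros$median_fc, substituted$median_fc,
               tolerance = 1e-12)
  ## and the rescue rule can only add calls relative to the FC criterion
  ## of the substituted data (the FC criterion is identical, the p value
  ## differs because zeros enter the t test literally)
  fc_pass <- with_zeros$median_fc > 1.5 | with_zeros$median_fc < 1 / 1.5
  rescued <- with_zeros$zero_rescue
  expect_true(all(with_zeros$category[!fc_pass & !rescued] == "no_change"))
})

test_that("dynamic summary flags any significant comparison", {
  calls <- data.frame(
    feature = c("a", "a", "b", "b"),
    comparison = c("c1", "c2", "c1", "c2"),
    category = c("no_change", "increased", "no_change", "no_change"),
    stringsAsFactors = FALSE)
  s <- summarize_calls(calls)
  expect_true(s$dynamic[s$feature == "a"])
  expect_false(s$dynamic[s$feature == "b"])
  expect_equal(s$direction[s$feature == "a"], "increased")
})

test_that("metaphase transition classification uses the anchor timepoint", {
  tps <- c(0L, seq(45L, 165L, by = 15L))
  d <- make_design(timepoints = tps)
  cl <- chans(d, "PE")
  stopifnot(length(cl) == 20)
  base <- rep(10, 20)
  m <- rbind(doubles = base, flat = base)
  colnames(m) <- cl
  ## rep channel layout: 10 timepoints rep1 then rep2; t90 is index 5
  i90 <- which(rep(tps, 2) == 90)
  m["doubles", i90] <- c(20, 21)
  cfg <- analysis_config()
  res <- classify_transition(m, d, "wild_type", "PE", "I", cfg,
                             dataset_min = 1)
  expect_equal(res$category[res$feature == "doubles"], "increased")
  expect_equal(res$category[res$feature == "flat"], "no_change")
  ## metaphase II anchor is 120 min (135 min is the anaphase-II peak)
  expect_equal(cfg$metaphase_II, 120L)
})

test_that("profile scaling behaves in mean and reference modes", {
  m <- rbind(a = c(1, 2, 3, 6), b = c(0, 2, 0, 6))
  s <- scale_profile(m, "mean")
  expect_equal(rowMeans(s), c(a = 1, b = 1))
  ## zeros enter the mean and stay zero
  expect_equal(unname(s["b", c(1, 3)]), c(0, 0))
  expect_equal(unname(s["b", 2]), 2 / 2)
  r <- scale_profile(m, "reference_tp", reference_col = 2)
  expect_equal(unname(r[, 2]), c(1, 1))
  expect_message(scale_profile(rbind(c(0, 0, 0, 0), c(1, 1, 1, 1)), "mean"),
                 "excluded")
  ## combined scope: uniform 2x offset between strain blocks is preserved
  comb <- rbind(x = c(2, 4, 2, 4, 1, 2, 1, 2))  # wt = 2 x mut
  sc <- scale_profile(comb, "mean")
  expect_equal(unname(sc[1, 1:4] / sc[1, 5:8]), rep(2, 4))
})

test_that("replicate averaging includes zeros", {
  expect_equal(average_replicates(rbind(c(10, 0)), rbind(c(0, 0)))[1, ],
               c(5, 0))
  a <- matrix(1:4, 2)
  expect_equal(average_replicates(a, a), a)
  expect_error(average_replicates(a, matrix(1:6, 2)), "dimension")
})
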