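make_phospho_obj <- function(m, design, loc = NULL, windows = NULL) {
  n <- nrow(m)
  ids <- rownames(m) %||% sprintf("s%d", seq_len(n))
  rownames(m) <- ids
  structure(list(
    features = data.frame(site_id = ids, protein_id = sprintf("P%03d", seq_len(n)),
                          position = seq_len(n), residue = "S",
                          localization_prob = loc %||% rep(0.99, n),
                          window = windows %||% replicate(n, make_window()),
                          is_contaminant = FALSE, is_reverse = FALSE,
                          row.names = ids, stringsAsFactors = FALSE),
    intensities = m), class = "phospho_data")
}

make_protein_obj <- function(m, cont = NULL, rev = NULL) {
  n <- nrow(m)
  ids <- rownames(m) %||% sprintf("P%03d", seq_len(n))
  rownames(m) <- ids
  structure(list(
    features = data.frame(protein_id = ids, gene_name = ids,
                          is_contaminant = cont %||% rep(FALSE, n),
                          is_reverse = rev %||% rep(FALSE, n),
                          row.names = ids, stringsAsFactors = FALSE),
    intensities = m), class = "protein_data")
}

test_that("flagged features are dropped with per-flag tallies", {
  m <- matrix(1, 5, 4)
  x <- make_protein_obj(m, cont = c(TRUE, FALSE, FALSE, FALSE, TRUE),
                        rev = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  out <- drop_flagged_features(x)
  expect_equal(nrow(out$features), 2)
  audit <- attr(out, "audit")
  ## the doubly-flagged record counts once in removal, twice in tallies
  expect_equal(unname(audit["n_contaminant"]), 2)
  expect_equal(unname(audit["n_reverse"]), 2)
  expect_equal(unname(audit["n_removed"]), 3)
  clean <- drop_flagged_features(make_protein_obj(m))
  expect_equal(nrow(clean$features), 5)
})

test_that("protein detection rule: >=1 timepoint per replicate per strain", {
  d <- make_design()  # 4 timepoints x 2 reps
  m <- matrix(0, 3, 8, dimnames = list(NULL, chans(d, "N")))
  m[1, c(1, 5)] <- 10           # detected once in each replicate -> keep
  m[2, 1:4] <- 10               # only replicate 1 -> drop
  m[3, ] <- 10                  # everywhere -> keep
  x <- make_protein_obj(m)
  out <- detection_filter(x, d, kind = "protein")
  expect_equal(rownames(out$intensities), c("P001", "P003"))
  audit <- attr(out, "audit")
  expect_equal(nrow(audit), 3)  # every input feature appears exactly once
  expect_equal(audit$first_failing_rule[2], "detection")
})

test_that("phospho rule requires a consecutive detected pair in every replicate", {
  d <- make_design()  # timepoints 0,45,60,75
  cl <- chans(d, "PE")
  m <- matrix(0, 3, 8, dimnames = list(NULL, cl))
  ## rep1 channels are t0,t45,t60,t75 = cl[1:4]; rep2 = cl[5:8]
  m[1, c(2, 3, 6, 7)] <- 5      # t45+t60 in both reps -> sequential pair
  m[2, c(2, 4, 6, 8)] <- 5      # t45 and t75 only (gap) -> fails
  m[3, c(1, 2, 6, 7)] <- 5      # t0+t45 counts as sequential
  x <- make_phospho_obj(m, d)
  out <- detection_filter(x, d, kind = "phospho",
                          config = filter_config(require_normalizable = FALSE))
  expect_setequal(out$features$site_id, c("s1", "s3"))
  expect_match(attr(out, "audit")$first_failing_rule[2], "sequential")
})

test_that("localization cutoff is strict at 0.75", {
  d <- make_design()
  m <- matrix(5, 2, 8, dimnames = list(NULL, chans(d, "PE")))
  x <- make_phospho_obj(m, d, loc = c(0.75, 0.76))
  out <- detection_filter(x, d, kind = "phospho",
                          config = filter_config(require_normalizable = FALSE))
  expect_equal(out$features$site_id, "s2")
})

test_that("not-normalizable sites are excluded when required", {
  d <- make_design()
  m <- matrix(5, 2, 8, dimnames = list(NULL, chans(d, "PE")))
  m[1, 3] <- NA  # protein missing at one timepoint
  x <- make_phospho_obj(m, d)
  out <- detection_filter(x, d, kind = "phospho",
                          config = filter_config(require_normalizable = TRUE))
  expect_equal(out$features$site_id, "s2")
  expect_equal(attr(out, "audit")$first_failing_rule[1], "not_normalizable")
})

test_that("arrest filter keeps features in >= min_reps of every strain", {
  g <- expand.grid(enrichment = c("N", "PE"), replicate = 1:4,
                   strain = c("a", "b", "c"), stringsAsFactors = FALSE)
  g$timepoint_min <- 75L
  g$channel_label <- sprintf("%s_r%d_%s", g$strain, g$replicate, g$enrichment)
  d <- sample_design(g)
  cl <- chans(d, "N")
  m <- matrix(1, 3, 12, dimnames = list(NULL, cl))
  m[1, 1] <- 0                    # 3/4, 4/4, 4/4 -> kept
  m[2, c(1, 2, 3)] <- 0           # 1/4 in strain a -> dropped
  x <- make_protein_obj(m)
  out <- arrest_detection_filter(x, d, min_reps = 3)
  expect_setequal(rownames(out$intensities), c("P001", "P003"))
  ## min_reps = 1 on a fully observed matrix is the identity
  full <- make_protein_obj(matrix(1, 2, 12, dimnames = list(NULL, cl)))
  expect_equal(nrow(arrest_detection_filter(full, d, 1)$features), 2)
  expect_error(arrest_detection_filter(x, d, min_reps = 5), "min_reps")
})

test_that("filters are monotone in added observations", {
  d <- make_design()
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(rbinom(8, 1, 0.5) * 10, 1, 8,
                dimnames = list("s1", chans(d, "PE")))
    x <- make_phospho_obj(m, d)
    cfg <- filter_config(require_normalizable = FALSE)
    pass0 <- nrow(detection_filter(x, d, cfg, "phospho")$features) == 1
    ## add one observation at a random missing position
    zero <- which(m[1, ] == 0)
    if (!length(zero)) next
    m2 <- m; m2[1, sample(zero, 1)] <- 10
    pass1 <- nrow(detection_filter(make_phospho_obj(m2, d), d, cfg,
                                   "phospho")$features) == 1
    expect_true(pass1 >= pass0)
  }
})

test_that("detection is invariant to design-consistent channel permutations", {
  d <- make_design()
  set.seed(9)
  m <- matrix(rbinom(40, 1, 0.6) * 7, 5, 8,
              dimnames = list(NULL, chans(d, "PE")))
  x <- make_phospho_obj(m, d)
  cfg <- filter_config(require_normalizable = FALSE)
  a <- detection_filter(x, d, cfg, "phospho")
  perm <- sample(8)
  xp <- make_phospho_obj(m[, perm], d)
  b <- detection_filter(xp, d, cfg, "phospho")
  expect_setequal(a$features$site_id, b$features$site_id)
})
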