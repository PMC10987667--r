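test_that("motif grammar parses offsets relative to the starred token", {
  p <- parse_motif("[ST]*Px[KR]")
  expect_equal(p$constraints[["0"]], c("S", "T"))
  expect_equal(p$constraints[["1"]], "P")
  expect_equal(p$constraints[["3"]], c("K", "R"))
  expect_null(p$constraints[["2"]])

  q <- parse_motif("RPx[ST]*")
  expect_equal(q$constraints[["-3"]], "R")
  expect_equal(q$constraints[["-2"]], "P")
  expect_equal(q$constraints[["0"]], c("S", "T"))

  atg1 <- parse_motif("[LM]xx[ST]*x[STVILMFYW][YIFM]")
  expect_setequal(names(atg1$constraints), c("-3", "0", "2", "3"))

  cdc5 <- parse_motif("[DEN]x[ST]*")
  expect_equal(cdc5$constraints[["-2"]], c("D", "E", "N"))
})

test_that("grammar errors are specific", {
  expect_error(parse_motif("[ST]P"), "exactly one")
  expect_error(parse_motif("[ST]*P[ST]*"), "exactly one")
  expect_error(parse_motif("[]*P"), "empty bracket")
  expect_error(parse_motif("[ST]*B"), "illegal")
  expect_error(parse_motif("x*P"), "wildcard")
  expect_error(parse_motif("[AB]*P"), "illegal")
  expect_error(parse_motif("[DE]*P"), "phospho-acceptor")
})

test_that("site matching honors constraints, star set, and padding", {
  w_cdk <- make_window("S", list(`1` = "P", `3` = "K"))
  expect_true(match_site(w_cdk, "[ST]*Px[KR]"))
  w_polo <- make_window("S", list(`-2` = "N"))
  expect_true(match_site(w_polo, "[DEN]x[ST]*"))
  expect_false(match_site(make_window("Y", list(`1` = "P")), "[ST]*P"))
  ## padding at a constrained offset fails the match
  w_pad <- paste0(strrep("_", 13), "NAS", strrep("A", 15))
  expect_true(nchar(w_pad) == 31 && substr(w_pad, 16, 16) == "S")
  expect_true(match_site(w_pad, "[DEN]x[ST]*"))
  w_pad2 <- paste0(strrep("_", 15), "S", strrep("A", 15))
  expect_false(match_site(w_pad2, "[DEN]x[ST]*"))
})

test_that("matcher agrees exactly with the regex oracle", {
  set.seed(41)
  wins <- random_windows(2000)
  pats <- c(vapply(kinase_motifs(), `[[`, character(1), "pattern_text"),
            "[DEN]x[ST]*F", "[DEN]x[ST]*G", "[DEN]x[ST]*[FG]",
            "[DEN]x[ST]*[LIMYF]", "S[ST]*P")
  for (pt in pats) {
    expect_identical(match_site(wins, pt), oracle_match_site(wins, pt),
                     label = pt)
  }
})

test_that("vectorized Fisher p agrees with fisher.test and enumeration", {
  set.seed(51)
  tabs <- matrix(sample(0:25, 4 * 200, replace = TRUE), ncol = 4)
  p_ours <- fisher_exact_p(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])
  p_ref <- apply(tabs, 1, function(r)
    fisher.test(matrix(r, 2, byrow = TRUE))$p.value)
  p_orc <- apply(tabs, 1, function(r)
    oracle_fisher_p(r[1], r[2], r[3], r[4]))
  expect_equal(p_ours, p_ref, tolerance = 1e-9)
  expect_equal(p_ours, p_orc, tolerance = 1e-9)
})

test_that("motif enrichment builds the cluster-versus-total table", {
  wins <- c(replicate(20, make_window("S", list(`-2` = "D"))),
            replicate(30, make_window("S")),
            replicate(50, make_window("S", list(`-2` = "E"))))
  names(wins) <- sprintf("s%03d", seq_along(wins))
  mt <- motif_match_table(wins, list(parse_motif("[DEN]x[ST]*", "Cdc5")))
  groups <- list(g1 = names(wins)[1:20], g2 = names(wins)[21:50])
  res <- motif_enrichment(groups, names(wins), mt)
  g1 <- res[res$group == "g1", ]
  expect_equal(c(g1$a, g1$b, g1$c, g1$d), c(20, 0, 70, 30))
  expect_equal(g1$p_value, oracle_fisher_p(20, 0, 70, 30), tolerance = 1e-9)
  expect_equal(g1$direction, "enriched")
  g2 <- res[res$group == "g2", ]
  expect_equal(g2$direction, "depleted")
  ## disjoint mode removes the group from the background
  res2 <- motif_enrichment(groups, names(wins), mt, mode = "rest")
  g1r <- res2[res2$group == "g1", ]
  expect_equal(c(g1r$c, g1r$d), c(50, 30))
  ## a group drawn from background proportions is not significant
  expect_error(motif_enrichment(list(g = character(0)), names(wins), mt),
               "empty")
})

test_that("residue logo computes percent differences with exact tests", {
  fg <- replicate(30, make_window("S", list(`1` = "F")))
  bg <- random_windows(200)
  set.seed(12)
  logo <- residue_logo(fg, bg)
  cell <- logo[logo$offset == 1 & logo$residue == "F", ]
  expect_equal(cell$fg_pct, 100)
  expect_true(cell$significant && cell$diff_pct > 80)
  ## identical sets: no significant cells, zero differences
  null_logo <- residue_logo(bg, bg)
  expect_true(all(abs(null_logo$diff_pct) < 1e-12))
  expect_true(all(!null_logo$significant))
  ## antisymmetry under fg/bg swap
  l1 <- residue_logo(fg, bg); l2 <- residue_logo(bg, fg)
  expect_equal(l1$diff_pct, -l2$diff_pct)
  expect_equal(l1$p_value, l2$p_value, tolerance = 1e-12)
  ## per-offset foreground percentages total 100 over observed residues
  sums <- tapply(logo$fg_pct, logo$offset, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_error(residue_logo(fg, substr(bg, 1, 29)), "length")
})

test_that("sub-motif discovery recovers planted +1 preferences", {
  set.seed(77)
  base <- parse_motif("[DEN]x[ST]*")
  ## foreground: 60% F at +1; background: uniform residues
  fg_f <- replicate(60, make_window("S", list(`-2` = "D", `1` = "F")))
  fg_rest <- vapply(1:40, function(i)
    make_window("S", list(`-2` = "D",
                          `1` = sample(c("A", "C", "E", "G", "H"), 1))),
    character(1))
  ## background: ~10% F at +1
  bg_plus1 <- sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"),
                     400, replace = TRUE,
                     prob = c(rep(0.1, 4), 0.1, rep(0.1, 5)))
  bg <- vapply(1:400, function(i)
    make_window("S", list(`-2` = sample(c("D", "E", "N"), 1),
                          `1` = bg_plus1[i])),
    character(1))
  res <- discover_submotif(base, 1L, c(fg_f, fg_rest), bg)
  expect_equal(res$residue[1], "F")
  expect_lt(res$p_value[1], 0.01)
  ## exact p against the enumeration oracle
  ok <- res[res$residue == "F", ]
  expect_equal(ok$p_value,
               oracle_fisher_p(ok$fg_count, 100 - ok$fg_count,
                               ok$bg_count, 400 - ok$bg_count),
               tolerance = 1e-9)
  ## equal distributions return nothing
  expect_equal(nrow(discover_submotif(base, 1L, bg, bg)), 0)
  ## two planted residues come back ranked by p value
  fg2 <- c(replicate(50, make_window("S", list(`-2` = "D", `1` = "F"))),
           replicate(30, make_window("S", list(`-2` = "D", `1` = "G"))),
           replicate(20, make_window("S", list(`-2` = "D", `1` = "A"))))
  res2 <- discover_submotif(base, 1L, fg2, bg)
  expect_setequal(intersect(res2$residue, c("F", "G")), c("F", "G"))
  expect_true(which(res2$residue == "F") < which(res2$residue == "G"))
  expect_error(discover_submotif(base, -2L, fg2, bg), "already constrained")
})

test_that("protein-sequence scanning returns all overlapping starts", {
  expect_equal(scan_protein_sequence("STSTP"), 3L)
  expect_equal(scan_protein_sequence("TTTTP"), integer(0))
  expect_equal(scan_protein_sequence("SSPSTP"), c(1L, 4L))
  ## brute-force oracle on random sequences
  set.seed(123)
  sets <- list("S", c("S", "T"), "P")
  for (i in 1:25) {
    seq <- paste(sample(c("S", "T", "P", "A"), 40, replace = TRUE),
                 collapse = "")
    expect_equal(scan_protein_sequence(seq), oracle_scan(seq, sets))
  }
  expect_error(scan_protein_sequence("ACDS", "S[ST]*P"), "plain")
})
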