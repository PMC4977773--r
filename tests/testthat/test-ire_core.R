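# Anchor patterns, candidate scanning, score ladder and retention filter.

test_that("the apical loop H position excludes G and the modes nest", {
  ps_can <- build_pattern_set("canonical")
  ps_all <- build_pattern_set("all")
  # loop CAGUGG must not match; CAGUGU must
  bad <- "CCCCCCCAGUGG"
  good <- "CCCCCCCAGUGU"
  expect_length(irescout:::regex_starts(bad, ps_can$regex[["canonical"]]), 0L)
  expect_length(irescout:::regex_starts(good, ps_can$regex[["canonical"]]), 1L)
  # mode "all" anchors are a strict superset of the canonical language
  expect_true(all(ps_can$anchors %in% ps_all$anchors))
  expect_gt(length(ps_all$anchors), length(ps_can$anchors))
  u_start <- "UCCCCCCAGUGU"
  expect_length(irescout:::regex_starts(u_start, ps_can$regex[["canonical"]]), 0L)
  expect_length(
    irescout:::regex_starts(u_start,
                            ps_all$regex[["selex_pyrimidine_bulge"]]), 1L)
  expect_error(build_pattern_set("bogus"))
})

test_that("a planted IRE yields exactly one candidate at its offset", {
  m <- make_ire_sequence("canonical", seed = 3)
  set.seed(91)
  repeat {  # background free of accidental anchors
    bgseq <- random_rna_str(1000)
    if (length(oracle_iupac_scan(bgseq, "CAGUGH")) == 0L) break
  }
  off <- 400L
  substr(bgseq, off, off + nchar(m$rna) - 1L) <- m$rna
  utr <- make_utr_row(bgseq)
  cands <- scan_candidates(utr)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$anchor, off + m$anchor - 1L)

  # poly-A never matches
  expect_equal(nrow(scan_candidates(make_utr_row(strrep("A", 200)))), 0L)
})

test_that("overlapping anchors are both reported, sorted 5' to 3'", {
  # loop words at offsets 13 and 18 share context; both carry a C8-role C
  core <- paste0(strrep("G", 6), "CCCCCC", "CAGUG", "CAGUGA",
                 strrep("C", 10))
  utr <- make_utr_row(core)
  cands <- scan_candidates(utr)
  expect_equal(nrow(cands), 2L)
  expect_equal(cands$anchor, c(13L, 18L))
})

test_that("candidates whose hairpin extent contains N are dropped", {
  m <- make_ire_sequence("canonical", seed = 5)
  win <- paste0(strrep("A", 50), m$rna, strrep("A", 30), "N",
                strrep("A", 19))
  # N is 30 nt beyond the hairpin end: kept
  expect_message(
    expect_equal(nrow(scan_candidates(make_utr_row(win))), 1L), NA)
  win_n <- paste0(strrep("A", 50), sub("^.", "N", m$rna), strrep("A", 50))
  expect_message(
    expect_equal(nrow(scan_candidates(make_utr_row(win_n))), 0L),
    "dropped")
})

test_that("the score ladder follows the High/Medium/Low rules", {
  grammar <- ire_grammar()
  # canonical, zero defects
  m0 <- make_ire_sequence("canonical", seed = 1)
  expect_equal(score_ire_geometry(m0$rna, m0$anchor)$score, "HIGH")
  expect_equal(score_call(m0$geometry, grammar), "HIGH")
  # canonical core with one bulge or one mismatch stays HIGH
  mb <- make_ire_sequence("nc_bulge3p", seed = 2)
  expect_equal(score_ire_geometry(mb$rna, mb$anchor)$score, "HIGH")
  mm <- make_ire_sequence("nc_mismatch", seed = 2)
  expect_equal(score_ire_geometry(mm$rna, mm$anchor)$score, "HIGH")
  # SELEX-like short lower stem, zero mismatches -> MEDIUM
  short <- substr(m0$rna, 4, nchar(m0$rna) - 3L)  # lower stem cut to 2 bp
  sc <- score_ire_geometry(short, m0$anchor - 3L)
  expect_equal(sc$score, "MEDIUM")
  expect_equal(sc$geometry$mismatches, 0L)
  # two mismatches -> LOW
  # break a second upper pair: set a 3'-strand base equal to its partner
  g <- mm$geometry
  x <- strsplit(mm$rna, "")[[1]]
  ok_pair <- apply(g$upper_stem_pairs, 1, function(p)
    irescout:::can_pair_base(x[p[1]], x[p[2]]))
  target <- g$upper_stem_pairs[which(ok_pair)[1], ]
  x[target[2]] <- x[target[1]]  # same base never pairs with itself
  low <- score_ire_geometry(paste(x, collapse = ""), mm$anchor)
  expect_equal(low$score, "LOW")
  expect_gte(low$geometry$mismatches, 2L)
})

test_that("the retention filter keeps HIGH and mismatch-free MEDIUM only", {
  calls <- expand.grid(score = c("HIGH", "MEDIUM", "LOW"),
                       mismatches = 0:1, bulges = 0:1,
                       stringsAsFactors = FALSE)
  calls$gene_id <- sprintf("g%02d", seq_len(nrow(calls)))
  kept <- apply_filters(calls)
  expect_setequal(
    kept$gene_id,
    calls$gene_id[calls$score == "HIGH" |
                    (calls$score == "MEDIUM" & calls$mismatches == 0)])
  expect_true(all(kept$retained))
  # spot rules from the matrix
  expect_true("HIGH" %in% kept$score)
  expect_true(any(kept$score == "MEDIUM" & kept$bulges == 1))
  expect_false(any(kept$score == "MEDIUM" & kept$mismatches == 1))
  expect_false(any(kept$score == "LOW"))
})

test_that("gene-level summary de-duplicates genes across sides", {
  template <- data.frame(
    gene_id = c("gA", "gA", "gB", "gC"),
    side = c("five_prime", "three_prime", "five_prime", "three_prime"),
    score = "HIGH", canonical = c(TRUE, FALSE, TRUE, FALSE),
    mismatches = c(0L, 1L, 0L, 0L), bulges = c(0L, 0L, 0L, 1L),
    anchor = c(100L, 200L, 50L, 60L), stringsAsFactors = FALSE)
  s <- summarize_calls(template)
  expect_equal(s$n_genes_total, 3L)
  tab <- s$table
  expect_equal(tab$n_genes[tab$side == "five_prime"], 2L)
  expect_equal(tab$n_genes[tab$side == "three_prime"], 2L)
  expect_equal(tab$n_canonical[tab$side == "five_prime"], 2L)
  expect_equal(tab$n_noncanonical[tab$side == "three_prime"], 2L)
  # empty input: all-zero table
  s0 <- summarize_calls(template[0, ])
  expect_equal(s0$n_genes_total, 0L)
  expect_true(all(s0$table$n_genes == 0L))
})

test_that("retained calls re-validate with identical defect counts", {
  ds <- generate_dataset(synthetic_config(n_genes = 12, seed = 77))
  utrs <- extract_utrs(ds$contigs, ds$genes, 1000)
  ret <- apply_filters(scan_ire(utrs))
  expect_gt(nrow(ret), 0L)
  for (i in seq_len(nrow(ret))) {
    cl <- ret[i, ]
    u <- utrs[utrs$gene_id == cl$gene_id & utrs$side == cl$side, ]
    again <- score_ire_geometry(u$rna_sequence, cl$anchor)
    expect_equal(again$score, cl$score)
    expect_equal(again$geometry$mismatches, cl$mismatches)
    expect_equal(again$geometry$bulges, cl$bulges)
  }
})
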