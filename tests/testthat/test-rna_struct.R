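# Nussinov maximum pairing, exhaustive enumeration oracle, IRE geometry.

test_that("nussinov_fold reproduces enumeration-derived maxima", {
  expect_equal(nussinov_fold("GGGAAACCC")$max_pairs, 3L)
  expect_equal(nussinov_fold("ACGU")$max_pairs, 0L)  # loop would be 2 < 3
  expect_equal(nussinov_fold("GGGAAAUUU")$max_pairs, 3L)
  expect_equal(nussinov_fold("GGGAAAUUU",
                             fold_params(allow_gu = FALSE))$max_pairs, 1L)
  expect_equal(nussinov_fold("")$max_pairs, 0L)
  # N never pairs
  expect_equal(nussinov_fold("GGGAAANNN")$max_pairs, 0L)
})

test_that("enumeration is exhaustive, duplicate-free and guarded", {
  expect_length(enumerate_structures(""), 1L)
  expect_length(enumerate_structures("GCGC"), 1L)  # all pairs violate loop
  structs <- enumerate_structures("GGGAAACCC")
  keys <- vapply(structs, to_dotbracket, character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_equal(max(vapply(structs, function(p) nrow(p$pairs), 0L)),
               oracle_max_pairs("GGGAAACCC"))
  expect_error(enumerate_structures(strrep("A", 17)), "16")
})

test_that("folding agrees with the brute-force oracle on random RNA", {
  set.seed(421)
  for (rep in 1:60) {
    s <- random_rna_str(sample(2:12, 1))
    for (gu in c(TRUE, FALSE)) {
      fp <- fold_params(allow_gu = gu)
      nf <- nussinov_fold(s, fp)
      expect_equal(nf$max_pairs, oracle_max_pairs(s, allow_gu = gu),
                   info = paste(s, "gu:", gu))
      # returned structure attains the reported count and is valid
      expect_equal(nrow(nf$pair_table$pairs), nf$max_pairs)
      expect_true(irescout:::pair_table_valid(nf$pair_table, s, fp))
    }
  }
})

test_that("GU wobble and min-loop act monotonically on max pairs", {
  set.seed(77)
  for (rep in 1:25) {
    s <- random_rna_str(sample(4:12, 1))
    with_gu <- nussinov_fold(s, fold_params(allow_gu = TRUE))$max_pairs
    no_gu <- nussinov_fold(s, fold_params(allow_gu = FALSE))$max_pairs
    expect_gte(with_gu, no_gu)
    loose <- nussinov_fold(s, fold_params(min_loop = 2))$max_pairs
    tight <- nussinov_fold(s, fold_params(min_loop = 4))$max_pairs
    expect_gte(loose, nussinov_fold(s)$max_pairs)
    expect_lte(tight, nussinov_fold(s)$max_pairs)
  }
})

test_that("pair tables reject pseudoknots and serialize to dot-bracket", {
  expect_error(pair_table(8, rbind(c(1, 5), c(3, 7))), "pseudoknot")
  pt <- pair_table(9, rbind(c(1, 9), c(2, 8)))
  expect_equal(to_dotbracket(pt), "((.....))")
})

test_that("the worked canonical hairpin is recognised exactly", {
  g <- check_ire_geometry(WORKED_IRE, WORKED_IRE_ANCHOR)
  expect_false(is.null(g))
  expect_true(g$canonical)
  expect_equal(g$mismatches, 0L)
  expect_equal(g$bulges, 0L)
  expect_equal(g$lower_stem_bp, 5L)
  expect_true(g$pseudo_triloop)
  expect_equal(g$loop_seq, "CAGUGA")
  expect_equal(g$c_bulge_offset, 6L)
  expect_equal(g$span, c(1L, 27L))
})

test_that("single substitutions register as one mismatch, deletion kills it", {
  # break the (10,19) upper-stem pair: G.C -> G.A
  mut <- WORKED_IRE
  substr(mut, 19, 19) <- "A"
  g <- check_ire_geometry(mut, WORKED_IRE_ANCHOR)
  expect_equal(g$mismatches, 1L)
  expect_equal(g$bulges, 0L)
  expect_false(g$canonical)

  # deleting the C8 bulge removes any admissible layout
  no_bulge <- paste0(substr(WORKED_IRE, 1, 5), substr(WORKED_IRE, 7, 27))
  expect_null(check_ire_geometry(no_bulge, WORKED_IRE_ANCHOR - 1L))
})

test_that("a 3'-strand insertion is scored as a single bulge", {
  m <- make_ire_sequence("nc_bulge3p", seed = 31)
  g <- check_ire_geometry(m$rna, m$anchor)
  expect_equal(g$bulges, 1L)
  expect_equal(g$mismatches, 0L)
  expect_equal(g$bulge_side, "three_prime_upper")
})

test_that("returned geometries re-validate as pair tables on their window", {
  set.seed(5)
  for (cl in c("canonical", "nc_mismatch", "nc_bulge3p")) {
    for (rep in 1:5) {
      m <- make_ire_sequence(cl)
      g <- check_ire_geometry(m$rna, m$anchor, ire_grammar())
      expect_false(is.null(g))
      pt <- pair_table(nchar(m$rna), g$pairs)
      expect_true(irescout:::pair_table_valid(pt, m$rna, fold_params()))
      # loop positions (other than the pseudo-triloop closure) are unpaired
      loop_inner <- (g$anchor + 1L):(g$anchor + 3L)
      expect_false(any(loop_inner %in% as.vector(g$pairs)))
    }
  }
})

test_that("windows too short for any layout return NULL, not an error", {
  expect_null(check_ire_geometry("CAGUGA", 1L))
  expect_null(check_ire_geometry("CCAGUGA", 2L))
})
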