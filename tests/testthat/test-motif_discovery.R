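# Markov background estimation/sampling and ZOOPS EM motif discovery.

test_that("hand-counted conditionals are reproduced without smoothing", {
  bg0 <- estimate_markov_background(c("AAAA", "AAAA"), order = 0,
                                    pseudocount = 0)
  expect_equal(unname(bg0$cond[[1]][1, ]), c(1, 0, 0, 0))

  bg_sym <- estimate_markov_background("ACGU", order = 0, pseudocount = 0)
  expect_equal(unname(bg_sym$cond[[1]][1, ]), rep(0.25, 4))

  bg1 <- estimate_markov_background("AACC", order = 1, pseudocount = 0)
  expect_equal(bg1$cond[[2]]["A", "A"], 0.5)
  expect_equal(bg1$cond[[2]]["A", "C"], 0.5)
  expect_equal(bg1$cond[[2]]["C", "C"], 1)
  # unseen context falls back to uniform
  expect_equal(unname(bg1$cond[[2]]["G", ]), rep(0.25, 4))
})

test_that("conditionals normalize for every context at orders 0 to 3", {
  set.seed(31)
  corpus <- replicate(5, random_rna_str(400, gc = 0.55))
  for (ord in 0:3) {
    bg <- estimate_markov_background(corpus, order = ord)
    for (j in 0:ord) {
      sums <- rowSums(bg$cond[[j + 1]])
      expect_true(all(abs(sums - 1) < 1e-12), info = paste("order", ord))
    }
  }
  expect_error(estimate_markov_background(character(0), 1), "empty")
})

test_that("sampled text re-estimates the generating model", {
  # moderate length here; the large-corpus version runs in the acceptance
  # suite at 1e6 bases
  set.seed(42)
  gen <- estimate_markov_background(replicate(4, random_rna_str(500, 0.6)),
                                    order = 1)
  text <- sample_markov(gen, 2e5)
  re <- estimate_markov_background(text, order = 1, pseudocount = 0)
  for (ctx in rownames(gen$cond[[2]])) {
    n_ctx <- sum(strsplit(substr(text, 1, nchar(text) - 1), "")[[1]] == ctx)
    for (b in colnames(gen$cond[[2]])) {
      p <- gen$cond[[2]][ctx, b]
      se <- sqrt(p * (1 - p) / n_ctx)
      expect_lt(abs(re$cond[[2]][ctx, b] - p), 5 * se + 1e-9)
    }
  }
})

test_that("a planted 8-mer is recovered with its sites and significance", {
  corp <- make_motif_corpus(n_seqs = 50, len = 200, rate = 0.9, seed = 404)
  bg <- estimate_markov_background(corp$seqs, order = 2)
  motifs <- em_discover(corp$seqs, 8, 8, background = bg, seed = 9,
                        width_step = 1)
  expect_gte(length(motifs), 1L)
  m <- motifs[[1]]
  expect_lte(hamming(m$consensus, "GACGAUCG"), 1)
  expect_lt(m$p_value, 1e-4)
  expect_true(all(abs(rowSums(m$pwm) - 1) < 1e-12))
  # site offsets line up with the planted truth
  planted <- corp$truth[!is.na(corp$truth$offset), ]
  found <- merge(m$sites, planted, by = "seq_id")
  expect_gt(nrow(found), 0.8 * nrow(planted))
  expect_true(mean(found$offset.x == found$offset.y) > 0.9)
})

test_that("discovery is bit-reproducible for a fixed seed", {
  corp <- make_motif_corpus(n_seqs = 20, len = 100, rate = 0.9, seed = 55)
  bg <- estimate_markov_background(corp$seqs, order = 2)
  a <- em_discover(corp$seqs, 8, 8, background = bg, seed = 123,
                   width_step = 1, null_B = 4, p_cut = 1)
  b <- em_discover(corp$seqs, 8, 8, background = bg, seed = 123,
                   width_step = 1, null_B = 4, p_cut = 1)
  expect_identical(a, b)
  expect_gte(length(a), 1L)
})

test_that("sequences containing N are dropped with a warning", {
  corp <- make_motif_corpus(n_seqs = 12, len = 80, rate = 1, seed = 8)
  seqs <- corp$seqs
  substr(seqs[1], 5, 5) <- "N"
  expect_warning(
    em_discover(seqs, 8, 8, seed = 3, width_step = 1, null_B = 3),
    "N dropped")
})

test_that("motif annotation ranks a perfect consensus first", {
  one_hot <- function(word) {
    x <- match(strsplit(word, "")[[1]], c("A", "C", "G", "U"))
    pwm <- matrix(0.01, length(x), 4, dimnames = list(NULL,
                                                      c("A", "C", "G", "U")))
    pwm[cbind(seq_along(x), x)] <- 0.97
    pwm
  }
  pas_motif <- structure(list(width = 6L, pwm = one_hot("AAUAAA"),
                              consensus = "AAUAAA"), class = "motif_model")
  ann <- annotate_motifs(list(pas_motif), seed = 4)
  best <- ann[ann$best, ]
  expect_equal(best$element, "PAS")
  expect_lt(best$q, 0.05)

  # an uninformative PWM is its own permutation null: nothing significant
  flat <- structure(list(width = 6L,
                         pwm = matrix(0.25, 6, 4,
                                      dimnames = list(NULL,
                                                      c("A", "C", "G", "U"))),
                         consensus = "NNNNNN"), class = "motif_model")
  ann_flat <- annotate_motifs(list(flat), seed = 4)
  expect_true(all(ann_flat$q > 0.05))
  # q-values are exactly BH over the pair p-values
  expect_equal(ann$q, stats::p.adjust(ann$p, "BH"))
})

test_that("MEME-format output round-trips the probability matrix", {
  corp <- make_motif_corpus(n_seqs = 15, len = 90, rate = 0.95, seed = 21)
  motifs <- em_discover(corp$seqs, 8, 8, seed = 2, width_step = 1,
                        null_B = 4, p_cut = 1)
  expect_gte(length(motifs), 1L)
  path <- tempfile(fileext = ".meme")
  write_meme_motifs(motifs, path)
  lines <- readLines(path)
  expect_equal(lines[1], "MEME version 4")
  mat_start <- grep("letter-probability matrix", lines)[1]
  vals <- as.numeric(strsplit(lines[mat_start + 1], " ")[[1]])
  expect_equal(vals, unname(motifs[[1]]$pwm[1, ]), tolerance = 1e-4)
})
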