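# The synthetic-genome generator and its truth-table guarantees.

test_that("constructed IREs round-trip through the geometry checker", {
  for (cl in c("canonical", "nc_mismatch", "nc_bulge3p")) {
    m <- make_ire_sequence(cl, seed = 7)
    expect_equal(m$class, cl)
    g <- check_ire_geometry(m$rna, m$anchor)
    expect_false(is.null(g))
    expect_equal(g$mismatches + g$bulges, m$defects)
    expect_equal(g$canonical, cl == "canonical")
  }
  # determinism per seed, variation across seeds
  expect_identical(make_ire_sequence("canonical", seed = 7)$rna,
                   make_ire_sequence("canonical", seed = 7)$rna)
  expect_false(identical(make_ire_sequence("canonical", seed = 7)$rna,
                         make_ire_sequence("canonical", seed = 8)$rna))
  expect_error(make_ire_sequence("canonical", defects = 1))
})

test_that("dataset bookkeeping matches the configuration", {
  cfg <- synthetic_config(n_genes = 10, seed = 42)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$genes), 10L)
  expect_equal(length(ds$contigs), 4L)
  utrs <- extract_utrs(ds$contigs, ds$genes, cfg$flank_len)
  expect_lte(nrow(utrs), 20L)
  ire_truth <- ds$truth[ds$truth$kind == "ire", ]
  expect_equal(nrow(ire_truth), 10L)  # one canonical plant per gene
  # different seeds give different bytes under an identical schema
  ds2 <- generate_dataset(synthetic_config(n_genes = 10, seed = 43))
  expect_false(identical(as.character(ds$contigs),
                         as.character(ds2$contigs)))
  expect_identical(names(ds), names(ds2))
})

test_that("emitted files parse back through the genome_io surface", {
  dir <- tempfile("synds")
  ds <- generate_dataset(synthetic_config(n_genes = 6, seed = 99),
                         out_dir = dir)
  g <- load_genome(ds$paths$genome)
  expect_equal(sort(names(g)), sort(names(ds$contigs)))
  genes <- load_gene_models(ds$paths$gff)
  expect_equal(sort(genes$gene_id), sort(ds$genes$gene_id))
  expect_equal(genes[order(genes$gene_id), c("cds_start", "cds_end")],
               ds$genes[order(ds$genes$gene_id),
                        c("cds_start", "cds_end")],
               ignore_attr = TRUE)
  tss <- load_tss_table(ds$paths$tss)
  expect_true(all(tss$gene_id %in% ds$genes$gene_id))
})

test_that("background composition honours the GC setting", {
  cfg <- synthetic_config(n_genes = 8, gc_fraction = 0.4, seed = 5)
  ds <- generate_dataset(cfg)
  seqs <- paste(as.character(ds$contigs), collapse = "")
  # exclude planted intervals crudely by overall tolerance: plants occupy
  # well under 2% of the genome, so a binomial interval on the whole
  # genome still applies
  n <- nchar(seqs)
  gc <- sum(strsplit(seqs, "")[[1]] %in% c("G", "C")) / n
  se <- sqrt(0.4 * 0.6 / n)
  expect_lt(abs(gc - 0.4), 3 * se + 0.02)
})

test_that("planted elements and motifs sit at their recorded offsets", {
  cfg <- synthetic_config(n_genes = 15, seed = 64)
  ds <- generate_dataset(cfg)
  utrs <- extract_utrs(ds$contigs, ds$genes, cfg$flank_len)
  plants <- ds$truth[ds$truth$kind %in% c("element", "motif"), ]
  expect_gt(nrow(plants), 0L)
  for (i in seq_len(nrow(plants))) {
    tr <- plants[i, ]
    u <- utrs[utrs$gene_id == tr$gene_id & utrs$side == tr$side, ]
    expect_equal(substr(u$rna_sequence, tr$window_offset,
                        tr$window_offset + nchar(tr$seq) - 1L), tr$seq)
  }
  # planted uORFs are found by the scanner at their offsets
  uorf_truth <- plants[plants$name == "uORF", ]
  for (i in seq_len(nrow(uorf_truth))) {
    tr <- uorf_truth[i, ]
    u <- utrs[utrs$gene_id == tr$gene_id & utrs$side == tr$side, ]
    hits <- find_uorfs(u)
    expect_true(tr$window_offset %in% hits$start)
  }
})

test_that("an end-to-end scan recovers exactly the planted canonical set", {
  ds <- generate_dataset(synthetic_config(n_genes = 25, seed = 7))
  bundle_calls <- apply_filters(
    scan_ire(extract_utrs(ds$contigs, ds$genes, 1000)))
  truth <- ds$truth[ds$truth$kind == "ire", ]
  got <- paste(bundle_calls$gene_id, bundle_calls$side,
               bundle_calls$anchor)
  want <- paste(truth$gene_id, truth$side, truth$anchor)
  expect_setequal(got, want)
  expect_true(all(bundle_calls$score == "HIGH"))
  expect_true(all(bundle_calls$canonical))
})

test_that("dinucleotide shuffling preserves doublet composition", {
  doublets <- function(s) {
    x <- strsplit(s, "")[[1]]
    table(paste0(x[-length(x)], x[-1]))
  }
  set.seed(3)
  for (rep in 1:5) {
    s <- random_rna_str(300)
    sh <- dinucleotide_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(doublets(sh), doublets(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
  }
  s <- random_rna_str(300)
  expect_false(identical(dinucleotide_shuffle(s, seed = 1), s))
})
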