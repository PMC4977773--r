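# TSS-boundary validation and cross-species ortholog support.

mk_call <- function(gene_id, gstart, gend, side = "five_prime",
                    anchor = 100L) {
  data.frame(gene_id = gene_id, side = side, anchor = anchor,
             genomic_start = gstart, genomic_end = gend,
             stringsAsFactors = FALSE)
}

test_that("worked TSS containment example classifies both ways", {
  genes <- make_gene_row("g1", "c1", "+", 5000, 5900)
  tss <- data.frame(gene_id = "g1", contig_id = "c1", position = 4700,
                    source = "cage", stringsAsFactors = FALSE)
  inside <- tss_support(mk_call("g1", 4850, 4876), tss, genes)
  expect_equal(inside$status, "within_boundary")
  expect_gte(inside$distance_to_tss, 0)

  outside <- tss_support(mk_call("g1", 4200, 4226), tss, genes)
  expect_equal(outside$status, "outside_boundary")
  expect_lt(outside$distance_to_tss, -200)

  no_tss <- tss_support(mk_call("g2", 4850, 4876), tss,
                        rbind(genes, make_gene_row("g2", "c1", "+",
                                                   5000, 5900)))
  expect_equal(no_tss$status, "no_tss")
})

test_that("minus-strand boundaries mirror the plus-strand rule", {
  genes <- make_gene_row("gm", "c1", "-", 1000, 1900)
  tss <- data.frame(gene_id = "gm", contig_id = "c1", position = 2200,
                    source = "cage", stringsAsFactors = FALSE)
  # five-prime flank of a minus gene lies genomically right of the CDS
  inside <- tss_support(mk_call("gm", 2050, 2080), tss, genes)
  expect_equal(inside$status, "within_boundary")
  outside <- tss_support(mk_call("gm", 2500, 2530), tss, genes)
  expect_equal(outside$status, "outside_boundary")
})

test_that("tolerance extends boundaries outward and acts monotonically", {
  genes <- make_gene_row("g1", "c1", "+", 5000, 5900)
  tss <- data.frame(gene_id = "g1", contig_id = "c1", position = 4700,
                    source = "cage", stringsAsFactors = FALSE)
  call <- mk_call("g1", 4550, 4580)  # 150 nt upstream of the TSS
  expect_equal(tss_support(call, tss, genes, tolerance = 0)$status,
               "outside_boundary")
  expect_equal(tss_support(call, tss, genes, tolerance = 200)$status,
               "within_boundary")
  # enlarging the tolerance never flips a call back outside
  for (tol in c(0, 50, 100, 151, 400)) {
    st <- tss_support(call, tss, genes, tolerance = tol)$status
    if (tol >= 150) expect_equal(st, "within_boundary")
  }
  # TSS on a foreign contig is a hard error
  bad <- data.frame(gene_id = "g1", contig_id = "cX", position = 4700,
                    source = "cage", stringsAsFactors = FALSE)
  expect_error(tss_support(call, bad, genes), "contig")
})

test_that("the printed multi- and single-ortholog examples categorize", {
  map <- load_ortholog_map(
    system.file("extdata", "tsetse_ortholog_map.tsv",
                package = "irescout"))
  calls <- load_species_calls(
    system.file("extdata", "tsetse_species_ire_calls.tsv",
                package = "irescout"))
  res <- ortholog_support(c("GMOY008502", "GMOY000853", "GMOY000103",
                            "GMOY999999"), calls, map)
  res <- res[match(c("GMOY008502", "GMOY000853", "GMOY000103",
                     "GMOY999999"), res$gene_id), ]
  expect_equal(res$category,
               c("multi", "multi", "single", "none"))
  expect_equal(res$n_support, c(6L, 3L, 1L, 0L))
  # ferritin support spans non-Glossina insects; ACE support is
  # exclusively from other Glossina species
  expect_false(res$glossina_only[1])
  expect_true(res$glossina_only[2])
  expect_true(res$glossina_only[3])
  expect_false(res$glossina_only[4])
})

test_that("categories partition the focal set and missing species warn", {
  set.seed(10)
  ds <- generate_dataset(synthetic_config(n_genes = 40, seed = 23))
  focal <- ds$genes$gene_id
  res <- ortholog_support(focal, ds$species_calls, ds$ortholog_map)
  expect_equal(nrow(res), length(focal))
  expect_equal(sum(res$category == "multi") +
                 sum(res$category == "single") +
                 sum(res$category == "none"), length(focal))
  truth <- ds$truth[ds$truth$kind == "ortholog", ]
  expect_equal(res$category[match(truth$gene_id, res$gene_id)],
               truth$class)

  map2 <- data.frame(gene_id = "gX", species = "GHOST",
                     ortholog_id = "GHOST123", stringsAsFactors = FALSE)
  expect_warning(r2 <- ortholog_support("gX", ds$species_calls, map2),
                 "GHOST")
  expect_equal(r2$category, "none")
})
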