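# Independent oracles and small builders shared across the test files.
# Oracles are deliberately naive (position-by-position, brute-force,
# closed-form) and never call the implementation paths they check.

rna_alphabet <- c("A", "C", "G", "U")

random_rna_str <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(rna_alphabet, n, replace = TRUE, prob = p), collapse = "")
}

# Brute-force count of maximum pairs by recursive enumeration, independent
# of both nussinov_fold and enumerate_structures.
oracle_max_pairs <- function(rna, min_loop = 3, allow_gu = TRUE) {
  x <- strsplit(rna, "")[[1]]
  ok <- function(a, b) {
    p <- paste0(a, b)
    p %in% c("AU", "UA", "CG", "GC") ||
      (allow_gu && p %in% c("GU", "UG"))
  }
  rec <- function(i, j) {
    if (i >= j || j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (ok(x[i], x[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  n <- length(x)
  if (n < 2L) 0L else rec(1L, n)
}

# Naive IUPAC scanner: checks every window position against the allowed
# base sets, character by character.
iupac_sets <- list(
  A = "A", C = "C", G = "G", U = "U", T = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U"))

oracle_iupac_scan <- function(seq, pattern) {
  sx <- strsplit(seq, "")[[1]]
  px <- strsplit(pattern, "")[[1]]
  w <- length(px)
  hits <- integer(0)
  if (length(sx) < w) return(hits)
  for (i in seq_len(length(sx) - w + 1L)) {
    match_all <- TRUE
    for (k in seq_len(w)) {
      if (!sx[i + k - 1L] %in% iupac_sets[[px[k]]]) {
        match_all <- FALSE
        break
      }
    }
    if (match_all) hits <- c(hits, i)
  }
  hits
}

# Brute-force uORF finder: every AUG, walk codons until the first in-frame
# stop inside the window; report if the span is at least 9 nt.
oracle_uorfs <- function(seq) {
  sx <- strsplit(seq, "")[[1]]
  n <- length(sx)
  res <- NULL
  for (i in seq_len(max(n - 2L, 0L))) {
    if (paste(sx[i:(i + 2L)], collapse = "") != "AUG") next
    j <- i + 3L
    while (j + 2L <= n) {
      cod <- paste(sx[j:(j + 2L)], collapse = "")
      if (cod %in% c("UAA", "UAG", "UGA")) {
        if (j + 2L - i + 1L >= 9L) res <- rbind(res, c(i, j + 2L))
        break
      }
      j <- j + 3L
    }
  }
  res
}

# Exact two-sided Fisher p-value by direct hypergeometric tail summation
# (sum of all table probabilities not exceeding the observed one).
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Minimal in-memory genome builders.
make_test_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

make_gene_row <- function(gene_id, contig_id, strand, cds_start, cds_end) {
  data.frame(gene_id = gene_id, contig_id = contig_id, strand = strand,
             cds_start = cds_start, cds_end = cds_end,
             stringsAsFactors = FALSE)
}

make_utr_row <- function(rna, gene_id = "g1", side = "five_prime",
                         contig_id = "c1", start = 1L,
                         strand = "+") {
  data.frame(gene_id = gene_id, side = side, contig_id = contig_id,
             start = start, end = start + nchar(rna) - 1L, strand = strand,
             rna_sequence = rna, clipped = FALSE, overlaps_gene = FALSE,
             stringsAsFactors = FALSE)
}

# Write a small FASTA / GFF3 pair to tempfiles; returns the two paths.
write_test_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(nm)
    c(paste0(">", nm), seqs[[nm]]))), path)
  path
}

write_test_gff <- function(rows) {
  # rows: data.frame contig, source, type, start, end, strand, attributes
  path <- tempfile(fileext = ".gff3")
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(rows)), function(i)
               paste(rows$contig[i], "test", rows$type[i], rows$start[i],
                     rows$end[i], ".", rows$strand[i], ".",
                     rows$attributes[i], sep = "\t"), character(1)))
  writeLines(lines, path)
  path
}

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# The canonical worked IRE hairpin used across structure tests:
# lower stem GGGGG/CCCCC, C8 bulge, upper stem UCUGC/GCAGA, loop CAGUGA.
WORKED_IRE <- "GGGGGCUCUGCCAGUGAGCAGACCCCC"
WORKED_IRE_ANCHOR <- 12L
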