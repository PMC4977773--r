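# Seeded synthetic-genome generator with a machine-readable truth table.
# Every planted feature (IRE, UTR element instance, over-represented motif,
# TSS, ortholog support category) is registered with its window offset and
# genomic span, so the truth table is the oracle for every pipeline stage.

#' Synthetic dataset configuration
#'
#' Defaults describe the standard validation conditions used throughout the
#' package: 200 single-CDS genes on 4 contigs with an even strand mix,
#' 1000-nt flank windows, one canonical IRE planted per gene in a randomly
#' chosen window, common UTR elements planted at moderate rates, one
#' over-represented 8-mer planted in three-prime windows, and TSS positions
#' for half the genes at 100-900 nt upstream of the CDS.
#'
#' @param n_genes Number of genes (default 200).
#' @param n_contigs Number of contigs (default 4).
#' @param contig_length Minimum contig length; contigs grow as needed to
#'   hold their genes (default 0).
#' @param gc_fraction Background GC fraction (default 0.4).
#' @param flank_len UTR window length (default 1000).
#' @param cds_len CDS length (default 300).
#' @param spacer Spacer between gene blocks (default 50).
#' @param strand_minus_fraction Fraction of minus-strand genes (default 0.5).
#' @param ire List of planted-IRE specs, each a list with `class`
#'   (`canonical`/`nc_mismatch`/`nc_bulge3p`), `defects`, `count`, `side`
#'   (`five_prime`/`three_prime`/`random`).
#' @param elements Named numeric vector of per-window planting rates for
#'   IUPAC elements of [element_db()] plus `uORF`.
#' @param motif List with `consensus` (RNA string) and `rate` (per-window
#'   occurrence probability in three-prime windows).
#' @param tss_fraction Fraction of genes given a TSS record (default 0.5).
#' @param tss_range TSS distance range upstream of the CDS start
#'   (default `c(100, 900)`).
#' @param ortholog_probs Probabilities of the `multi`/`single`/`none`
#'   ortholog-support categories (default `c(0.2, 0.2, 0.6)`).
#' @param seed Mandatory RNG seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 200, n_contigs = 4,
                             contig_length = 0, gc_fraction = 0.4,
                             flank_len = 1000, cds_len = 300, spacer = 50,
                             strand_minus_fraction = 0.5,
                             ire = list(list(class = "canonical",
                                             defects = 0, count = 1,
                                             side = "random")),
                             elements = c(PAS = 0.3, ARE = 0.2,
                                          uORF = 0.3),
                             motif = list(consensus = "GACGAUCG",
                                          rate = 0.9),
                             tss_fraction = 0.5, tss_range = c(100, 900),
                             ortholog_probs = c(0.2, 0.2, 0.6),
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_genes >= 0, n_contigs >= 1, flank_len >= 1, cds_len >= 1,
            gc_fraction > 0, gc_fraction < 1,
            abs(sum(ortholog_probs) - 1) < 1e-9)
  structure(as.list(environment()), class = "synthetic_config")
}

# Watson-Crick complement of an RNA string, reversed (for stem strands).
wc_rev_comp_rna <- function(rna) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", rna), "")[[1]]), collapse = "")
}

#' Construct an IRE sequence of a requested structural class
#'
#' Builds a hairpin (5 lower-stem pairs, C8 bulge, 5-pair upper stem,
#' CAGUGH loop) and, for the non-canonical classes, introduces exactly one
#' upper-stem mismatch or one bulged nt on the 3' upper-stem strand. The
#' construction inverts the geometry checker: the emitted sequence is
#' verified to score with exactly the requested class and defect counts and
#' to contain a single anchor, and is deterministic for a given RNG state.
#'
#' @param class `"canonical"`, `"nc_mismatch"` or `"nc_bulge3p"`.
#' @param defects 0 for canonical, 1 for the non-canonical classes.
#' @param grammar The strict [ire_grammar()] used for verification.
#' @param seed Optional seed; when given the construction runs in its own
#'   RNG scope.
#' @return A list: `rna` (27 or 28 nt), `anchor` (1-based loop offset,
#'   always 12), `class`, `defects`, `geometry` (the verified
#'   [check_ire_geometry()] result).
#' @export
make_ire_sequence <- function(class = c("canonical", "nc_mismatch",
                                        "nc_bulge3p"),
                              defects = if (class == "canonical") 0 else 1,
                              grammar = ire_grammar(), seed = NULL) {
  class <- match.arg(class)
  expected_defects <- if (class == "canonical") 0L else 1L
  if (defects != expected_defects)
    stop("class ", class, " requires defects == ", expected_defects)
  build <- function() {
    for (attempt in seq_len(1000L)) {
      lower5 <- random_rna(5)
      upper5 <- random_rna(5)
      loop <- paste0("CAGUG", sample(c("A", "C", "U"), 1))
      upper3 <- strsplit(wc_rev_comp_rna(upper5), "")[[1]]
      if (class == "nc_mismatch") {
        j <- sample.int(5L, 1L)
        partner <- strsplit(upper5, "")[[1]][6L - j]
        bad <- RNA_BASES[!vapply(RNA_BASES, can_pair_base, TRUE,
                                 a = partner, allow_gu = grammar$allow_gu)]
        upper3[j] <- sample(bad, 1L)
      } else if (class == "nc_bulge3p") {
        pos <- sample.int(6L, 1L)
        upper3 <- append(upper3, sample(RNA_BASES, 1L), after = pos - 1L)
      }
      rna <- paste0(lower5, "C", upper5, loop,
                    paste(upper3, collapse = ""),
                    wc_rev_comp_rna(lower5))
      if (length(regex_starts(rna, "CAGUG[ACU]")) != 1L) next
      sc <- score_ire_geometry(rna, 12L, grammar)
      if (is.null(sc)) next
      g <- sc$geometry
      ok <- switch(class,
        canonical = g$canonical && sc$score == "HIGH",
        nc_mismatch = g$mismatches == 1L && g$bulges == 0L &&
          sc$score == "HIGH",
        nc_bulge3p = g$bulges == 1L && g$mismatches == 0L &&
          sc$score == "HIGH")
      if (ok && g$span[1] == 1L && g$span[2] == nchar(rna))
        return(list(rna = rna, anchor = 12L, class = class,
                    defects = expected_defects, geometry = g))
    }
    stop("could not construct a ", class, " IRE in 1000 attempts")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Synthetic corpus with one planted motif occurrence per chosen sequence
#'
#' Generates i.i.d. background sequences and plants the given consensus at
#' a random offset in each sequence with probability `rate` — the standard
#' corpus for validating motif discovery.
#'
#' @param n_seqs,len Corpus shape (default 50 x 200 nt).
#' @param consensus Planted RNA word (default an 8-mer).
#' @param rate Per-sequence occurrence probability (default 0.9).
#' @param gc Background GC fraction.
#' @param seed Optional seed for a self-contained RNG scope.
#' @return List: `seqs` (character), `truth` (data.frame `seq_id`, `offset`;
#'   offset `NA` for sequences without a plant).
#' @export
make_motif_corpus <- function(n_seqs = 50, len = 200,
                              consensus = "GACGAUCG", rate = 0.9,
                              gc = 0.5, seed = NULL) {
  build <- function() {
    w <- nchar(consensus)
    seqs <- character(n_seqs)
    offs <- rep(NA_integer_, n_seqs)
    for (i in seq_len(n_seqs)) {
      s <- random_rna(len, gc)
      if (stats::runif(1) < rate) {
        off <- sample.int(len - w + 1L, 1L)
        substr(s, off, off + w - 1L) <- consensus
        offs[i] <- off
      }
      seqs[i] <- s
    }
    list(seqs = seqs, truth = data.frame(seq_id = seq_len(n_seqs),
                                         offset = offs))
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

# Plant a literal RNA word into a window at a random free offset.
# occupied: two-column matrix of taken intervals. Returns list(seq, off).
plant_word <- function(window, word, occupied, tries = 100L) {
  w <- nchar(word)
  n <- nchar(window)
  if (n < w) return(NULL)
  for (t in seq_len(tries)) {
    off <- sample.int(n - w + 1L, 1L)
    iv <- c(off, off + w - 1L)
    clash <- nrow(occupied) > 0L &&
      any(iv[1] <= occupied[, 2] & iv[2] >= occupied[, 1])
    if (!clash) {
      substr(window, off, off + w - 1L) <- word
      return(list(seq = window, off = off, interval = iv))
    }
  }
  NULL
}

# Instantiate an IUPAC element definition as a literal RNA word.
instantiate_iupac <- function(pattern) {
  paste(vapply(strsplit(toupper(pattern), "")[[1]], function(ch) {
    sample(IUPAC_RNA[[ch]], 1L)
  }, character(1)), collapse = "")
}

# A random uORF: AUG + n_codons non-stop codons + UAA.
random_uorf_word <- function(n_codons = 2L) {
  stops <- c("UAA", "UAG", "UGA")
  mid <- vapply(seq_len(n_codons), function(i) {
    repeat {
      cod <- random_rna(3)
      if (!cod %in% stops) return(cod)
    }
  }, character(1))
  paste0("AUG", paste(mid, collapse = ""), "UAA")
}

#' Generate a synthetic genome dataset with planted truth
#'
#' Builds a multi-contig genome of strand-mixed single-CDS genes whose
#' flank windows carry planted IREs, UTR element instances and an
#' over-represented motif; emits TSS records and an ortholog map with
#' per-species call sets; and registers every planted feature in a truth
#' table. Each window is rejection-sampled until it contains no accidental
#' loop anchor within 30 nt of a plant and no unplanted anchor that would
#' survive the retention filter, so pipeline calls on the output can be
#' compared exactly against the truth table. Truth coordinates are verified
#' against the assembled genome before return.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `genes.gff3`, `tss.tsv`, `ortholog_map.tsv`, `species_calls.tsv` and
#'   `truth.tsv` there.
#' @return A list of class `synthetic_dataset`: `contigs`
#'   ([Biostrings::DNAStringSet]), `genes`, `truth`, `tss`, `ortholog_map`,
#'   `species_calls`, `config`, and `paths` when `out_dir` was given.
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  grammar <- ire_grammar()
  patterns <- build_pattern_set("all")
  db <- element_db()
  with_seed(config$seed, {
    flank <- config$flank_len
    genes <- data.frame(
      gene_id = sprintf("SYNG%05d", seq_len(config$n_genes)),
      contig_id = sprintf("ctg%02d",
                          rep_len(seq_len(config$n_contigs),
                                  config$n_genes)),
      strand = ifelse(stats::runif(config$n_genes) <
                        config$strand_minus_fraction, "-", "+"),
      cds_start = NA_integer_, cds_end = NA_integer_,
      stringsAsFactors = FALSE)
    truth <- list()
    blocks <- stats::setNames(vector("list", config$n_contigs),
                              sprintf("ctg%02d", seq_len(config$n_contigs)))

    build_window <- function(gene_id, side) {
      # decide plants for this window first, then rejection-sample layout
      ire_specs <- list()
      for (spec in config$ire) {
        spec_side <- spec$side
        if (spec_side == "random")
          spec_side <- attr(config, paste0(".side_", gene_id))
        if (identical(spec_side, side))
          for (k in seq_len(spec$count))
            ire_specs[[length(ire_specs) + 1L]] <- spec
      }
      for (attempt in seq_len(1000L)) {
        window <- random_rna(flank, config$gc_fraction)
        occupied <- matrix(integer(0), ncol = 2)
        plants <- list()
        ok <- TRUE
        for (spec in ire_specs) {
          ire <- make_ire_sequence(spec$class, spec$defects, grammar)
          pl <- plant_word(window, ire$rna, occupied)
          if (is.null(pl)) { ok <- FALSE; break }
          window <- pl$seq
          occupied <- rbind(occupied, pl$interval)
          plants[[length(plants) + 1L]] <-
            list(kind = "ire", name = spec$class, off = pl$off,
                 len = nchar(ire$rna), anchor = pl$off + 11L,
                 class = spec$class, defects = spec$defects,
                 seq = ire$rna)
        }
        if (ok) for (el in names(config$elements)) {
          rate <- config$elements[[el]]
          el_row <- db[db$name == el, , drop = FALSE]
          el_side <- if (el == "uORF") "five_prime" else el_row$region
          if (!identical(el_side, side) && !identical(el_side, "both")) next
          if (stats::runif(1) >= rate) next
          word <- if (el == "uORF") random_uorf_word() else
            instantiate_iupac(el_row$definition)
          pl <- plant_word(window, word, occupied)
          if (is.null(pl)) next
          window <- pl$seq
          occupied <- rbind(occupied, pl$interval)
          plants[[length(plants) + 1L]] <-
            list(kind = "element", name = el, off = pl$off,
                 len = nchar(word), anchor = NA_integer_,
                 class = el, defects = NA_integer_, seq = word)
        }
        if (ok && side == "three_prime" && !is.null(config$motif) &&
            config$motif$rate > 0 &&
            stats::runif(1) < config$motif$rate) {
          pl <- plant_word(window, config$motif$consensus, occupied)
          if (!is.null(pl)) {
            window <- pl$seq
            occupied <- rbind(occupied, pl$interval)
            plants[[length(plants) + 1L]] <-
              list(kind = "motif", name = "planted_motif", off = pl$off,
                   len = nchar(config$motif$consensus),
                   anchor = NA_integer_, class = "motif",
                   defects = NA_integer_, seq = config$motif$consensus)
          }
        }
        if (!ok) next
        # rejection checks: accidental anchors near plants, spurious calls
        planted_anchors <- vapply(plants, function(p) p$anchor, 0L)
        planted_anchors <- planted_anchors[!is.na(planted_anchors)]
        anchors <- regex_starts(window, "CAGUG[ACU]")  # loop starts
        stray <- setdiff(anchors, planted_anchors)
        if (length(planted_anchors) &&
            any(vapply(stray, function(a)
              any(abs(a - planted_anchors) <= 30L), TRUE))) next
        spurious <- FALSE
        for (a in stray) {
          sc <- score_ire_geometry(window, a, grammar)
          if (!is.null(sc) &&
              (sc$score == "HIGH" ||
               (sc$score == "MEDIUM" &&
                sc$geometry$mismatches == 0L))) {
            spurious <- TRUE
            break
          }
        }
        if (spurious) next
        return(list(window = window, plants = plants))
      }
      stop("window rejection sampling failed for ", gene_id, "/", side)
    }

    # choose each gene's random IRE side up-front (stable across retries)
    for (g in genes$gene_id)
      attr(config, paste0(".side_", g)) <-
        sample(c("five_prime", "three_prime"), 1L)

    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      w5 <- build_window(g$gene_id, "five_prime")
      w3 <- build_window(g$gene_id, "three_prime")
      cds <- random_dna(config$cds_len, config$gc_fraction)
      blocks[[g$contig_id]][[length(blocks[[g$contig_id]]) + 1L]] <-
        list(gene_id = g$gene_id, strand = g$strand, w5 = w5, w3 = w3,
             cds = cds)
    }

    # assemble contigs and assign genomic coordinates
    contig_seqs <- character(config$n_contigs)
    names(contig_seqs) <- names(blocks)
    for (ctg in names(blocks)) {
      pos <- 1L
      parts <- character(0)
      add <- function(s) {
        parts[[length(parts) + 1L]] <<- s
        pos <<- pos + nchar(s)
      }
      add(random_dna(config$spacer, config$gc_fraction))
      for (blk in blocks[[ctg]]) {
        left_rna <- if (blk$strand == "+") blk$w5$window else blk$w3$window
        right_rna <- if (blk$strand == "+") blk$w3$window else blk$w5$window
        left_dna <- if (blk$strand == "+") chartr("U", "T", left_rna) else
          revcomp_dna(chartr("U", "T", left_rna))
        right_dna <- if (blk$strand == "+") chartr("U", "T", right_rna) else
          revcomp_dna(chartr("U", "T", right_rna))
        add(left_dna)
        cds_start <- pos
        add(blk$cds)
        cds_end <- pos - 1L
        add(right_dna)
        add(random_dna(config$spacer, config$gc_fraction))
        genes[genes$gene_id == blk$gene_id,
              c("cds_start", "cds_end")] <- list(cds_start, cds_end)
        # truth rows with genomic spans via the window coordinate map
        for (side in c("five_prime", "three_prime")) {
          w <- if (side == "five_prime") blk$w5 else blk$w3
          win_start <- if ((side == "five_prime") == (blk$strand == "+"))
            cds_start - config$flank_len else cds_end + 1L
          win_end <- win_start + config$flank_len - 1L
          fake_utr <- data.frame(start = win_start, end = win_end,
                                 strand = blk$strand)
          for (p in w$plants) {
            gp <- utr_genomic_position(fake_utr, c(p$off,
                                                   p$off + p$len - 1L))
            truth[[length(truth) + 1L]] <- data.frame(
              kind = p$kind, name = p$name, gene_id = blk$gene_id,
              side = side, window_offset = p$off,
              anchor = p$anchor, contig_id = ctg,
              genomic_start = min(gp), genomic_end = max(gp),
              strand = blk$strand, class = p$class, defects = p$defects,
              seq = p$seq, stringsAsFactors = FALSE)
          }
        }
      }
      seqs <- paste(parts, collapse = "")
      if (nchar(seqs) < config$contig_length)
        seqs <- paste0(seqs, random_dna(config$contig_length - nchar(seqs),
                                        config$gc_fraction))
      contig_seqs[[ctg]] <- seqs
    }
    contigs <- Biostrings::DNAStringSet(contig_seqs)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(kind = character(0), name = character(0),
                 gene_id = character(0), side = character(0),
                 window_offset = integer(0), anchor = integer(0),
                 contig_id = character(0), genomic_start = integer(0),
                 genomic_end = integer(0), strand = character(0),
                 class = character(0), defects = integer(0),
                 seq = character(0))

    # TSS records
    tss_rows <- list()
    for (i in seq_len(nrow(genes))) {
      if (stats::runif(1) >= config$tss_fraction) next
      g <- genes[i, ]
      d <- sample(config$tss_range[1]:config$tss_range[2], 1L)
      pos <- if (g$strand == "+") g$cds_start - d else g$cds_end + d
      tss_rows[[length(tss_rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, contig_id = g$contig_id, position = pos,
        source = "synthetic", distance = d, stringsAsFactors = FALSE)
    }
    tss <- if (length(tss_rows)) do.call(rbind, tss_rows) else
      data.frame(gene_id = character(0), contig_id = character(0),
                 position = integer(0), source = character(0),
                 distance = integer(0))

    # ortholog map and per-species call sets with planted categories
    species_pool <- c(glossina_species(), "FBgn", "AGAP", "MDOA")
    map_rows <- list()
    call_rows <- list()
    ortho_truth <- list()
    for (i in seq_len(nrow(genes))) {
      g <- genes$gene_id[i]
      cat <- sample(c("multi", "single", "none"), 1L,
                    prob = config$ortholog_probs)
      n_sup <- switch(cat, multi = sample(2:4, 1L), single = 1L, none = 0L)
      sp_sup <- sample(species_pool, n_sup)
      for (sp in sp_sup) {
        oid <- sprintf("%s_%s", sp, g)
        map_rows[[length(map_rows) + 1L]] <-
          data.frame(gene_id = g, species = sp, ortholog_id = oid)
        call_rows[[length(call_rows) + 1L]] <-
          data.frame(species = sp, gene_id = oid)
      }
      if (stats::runif(1) < 0.3) {  # a mapped ortholog without an IRE call
        sp <- sample(setdiff(species_pool, sp_sup), 1L)
        map_rows[[length(map_rows) + 1L]] <-
          data.frame(gene_id = g, species = sp,
                     ortholog_id = sprintf("%s_%s_noire", sp, g))
      }
      ortho_truth[[length(ortho_truth) + 1L]] <- data.frame(
        kind = "ortholog", name = cat, gene_id = g, side = NA_character_,
        window_offset = NA_integer_, anchor = NA_integer_,
        contig_id = NA_character_, genomic_start = NA_integer_,
        genomic_end = NA_integer_, strand = NA_character_, class = cat,
        defects = NA_integer_,
        seq = if (n_sup) paste(sp_sup, collapse = ",") else "",
        stringsAsFactors = FALSE)
    }
    ortholog_map <- if (length(map_rows)) do.call(rbind, map_rows) else
      data.frame(gene_id = character(0), species = character(0),
                 ortholog_id = character(0))
    species_calls_df <- if (length(call_rows)) do.call(rbind, call_rows) else
      data.frame(species = character(0), gene_id = character(0))
    species_calls <- lapply(
      stats::setNames(species_pool, species_pool),
      function(sp)
        unique(species_calls_df$gene_id[species_calls_df$species == sp]))
    truth <- rbind(truth, do.call(rbind, ortho_truth))

    # internal verification: every planted window feature is re-locatable
    utrs <- extract_utrs(contigs, genes, flank)
    seq_truth <- truth[!is.na(truth$window_offset), , drop = FALSE]
    for (r in seq_len(nrow(seq_truth))) {
      tr <- seq_truth[r, ]
      u <- utrs[utrs$gene_id == tr$gene_id & utrs$side == tr$side, ]
      found <- substr(u$rna_sequence, tr$window_offset,
                      tr$window_offset + nchar(tr$seq) - 1L)
      if (!identical(found, tr$seq))
        stop("truth verification failed for ", tr$gene_id, "/", tr$side)
    }

    out <- structure(list(contigs = contigs, genes = genes, truth = truth,
                          tss = tss, ortholog_map = ortholog_map,
                          species_calls = species_calls,
                          species_calls_df = species_calls_df,
                          config = config),
                     class = "synthetic_dataset")
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(
        genome = file.path(out_dir, "genome.fa"),
        gff = file.path(out_dir, "genes.gff3"),
        tss = file.path(out_dir, "tss.tsv"),
        ortholog_map = file.path(out_dir, "ortholog_map.tsv"),
        species_calls = file.path(out_dir, "species_calls.tsv"),
        truth = file.path(out_dir, "truth.tsv"))
      Biostrings::writeXStringSet(contigs, paths$genome)
      gr <- GenomicRanges::GRanges(
        genes$contig_id,
        IRanges::IRanges(genes$cds_start, genes$cds_end),
        strand = genes$strand)
      gr$type <- "CDS"
      gr$ID <- paste0("cds-", genes$gene_id)
      gr$gene_id <- genes$gene_id
      gr$phase <- 0L
      rtracklayer::export(gr, paths$gff, format = "gff3")
      write_tsv_file(tss, paths$tss)
      write_tsv_file(ortholog_map, paths$ortholog_map)
      write_tsv_file(species_calls_df, paths$species_calls)
      write_tsv_file(truth, paths$truth)
      out$paths <- paths
    }
    out
  })
}

#' Dinucleotide-preserving shuffle of a sequence
#'
#' Altschul-Erickson style doublet shuffle: the shuffled sequence has
#' exactly the original dinucleotide composition. Used as a negative
#' control for false-positive calibration.
#'
#' @param seq A DNA or RNA string.
#' @param seed Optional seed for a self-contained RNG scope.
#' @return A shuffled string over the same alphabet.
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  run <- function() {
    x <- strsplit(seq, "")[[1]]
    n <- length(x)
    if (n <= 2L) return(seq)
    verts <- unique(x)
    edges <- lapply(stats::setNames(verts, verts),
                    function(v) x[which(x[-n] == v) + 1L])
    last <- x[n]
    # pick per-vertex last edges forming a tree into the terminal vertex
    repeat {
      last_edge <- vapply(verts, function(v) {
        if (v == last) NA_character_ else sample(edges[[v]], 1L)
      }, character(1))
      ok <- TRUE
      for (v in setdiff(verts, last)) {
        seen <- character(0)
        cur <- v
        while (cur != last) {
          if (cur %in% seen) { ok <- FALSE; break }
          seen <- c(seen, cur)
          cur <- last_edge[[cur]]
        }
        if (!ok) break
      }
      if (ok) break
    }
    pools <- lapply(stats::setNames(verts, verts), function(v) {
      pool <- edges[[v]]
      if (!is.na(last_edge[[v]])) {
        drop <- match(last_edge[[v]], pool)
        pool <- pool[-drop]
      }
      c(sample(pool), if (!is.na(last_edge[[v]])) last_edge[[v]])
    })
    used <- stats::setNames(integer(length(verts)), verts)
    out <- character(n)
    out[1] <- x[1]
    cur <- x[1]
    for (i in 2:n) {
      used[[cur]] <- used[[cur]] + 1L
      nxt <- pools[[cur]][used[[cur]]]
      out[i] <- nxt
      cur <- nxt
    }
    paste(out, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
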