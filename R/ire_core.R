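# IRE candidate generation and scoring. A fast IUPAC anchor prescreen finds
# potential apical loops; each anchor is then evaluated by the hairpin
# geometry checker under a ladder of grammars which determines the
# High/Medium/Low score class, and the retention filter keeps High calls plus
# Medium calls free of mismatches.

#' Build the IRE anchor pattern set
#'
#' Anchors are IUPAC-degenerate strings for the conserved core: a C8-role
#' base, five upper-stem nt, and the apical loop `CAGUGH` (H = A/C/U;
#' G is never admitted at the sixth loop position). Mode `"canonical"`
#' requires the literal C at the C8 position; mode `"all"` additionally
#' admits a U there, covering SELEX-derived pyrimidine-bulge variants, so
#' its anchor language strictly contains the canonical one.
#'
#' @param mode `"canonical"` or `"all"`.
#' @return A list of class `ire_pattern_set` with the IUPAC anchors, their
#'   compiled regexes and class labels.
#' @export
build_pattern_set <- function(mode = c("all", "canonical")) {
  mode <- match.arg(mode)
  anchors <- c(canonical = "CNNNNNCAGUGH")
  if (mode == "all")
    anchors <- c(anchors, selex_pyrimidine_bulge = "UNNNNNCAGUGH")
  structure(list(mode = mode,
                 loop_consensus = "CAGUGH",
                 anchors = anchors,
                 regex = vapply(anchors, iupac_to_regex, character(1))),
            class = "ire_pattern_set")
}

#' Scan one UTR window for IRE anchor candidates
#'
#' Reports every anchor match (overlapping matches included) whose flanking
#' context can host a minimal stem layout: at least `grammar$min_lower_bp` nt
#' 5' of the anchor and `5 + grammar$min_lower_bp` nt 3' of the loop.
#' Candidates whose potential hairpin extent contains `N` are dropped with a
#' message. Matches are reported 5' to 3'.
#'
#' @param utr One window row from [extract_utrs()] (or any list/row with
#'   `gene_id`, `side`, `rna_sequence`).
#' @param pattern_set An [build_pattern_set()] object.
#' @param grammar An [ire_grammar()]; supplies the context margins.
#' @return data.frame: `gene_id`, `side`, `anchor` (1-based loop start in
#'   the window), `anchor_class`, `subsequence` (maximal hairpin extent).
#' @export
scan_candidates <- function(utr, pattern_set = build_pattern_set(),
                            grammar = ire_grammar()) {
  seq <- utr$rna_sequence
  stopifnot(nzchar(seq))
  n <- nchar(seq)
  cap <- grammar$lower_bp_cap
  out <- list()
  for (cls in names(pattern_set$regex)) {
    starts <- regex_starts(seq, pattern_set$regex[[cls]])
    for (m in starts) {
      anchor <- m + 6L
      # context margins for a minimal layout
      if (m - 1L < grammar$min_lower_bp) next
      if (anchor + 10L + grammar$min_lower_bp > n) next
      lo <- max(1L, anchor - 6L - cap)
      hi <- min(n, anchor + 12L + cap)
      sub <- substr(seq, lo, hi)
      if (grepl("N", sub, fixed = TRUE)) {
        message("candidate at ", utr$gene_id, "/", utr$side, " offset ",
                anchor, " dropped: contains N")
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id = utr$gene_id, side = utr$side, anchor = anchor,
        anchor_class = cls, subsequence = sub, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), side = character(0),
                      anchor = integer(0), anchor_class = character(0),
                      subsequence = character(0)))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res$anchor), , drop = FALSE]  # canonical wins ties
  res <- res[order(res$anchor), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Grammar ladder: strict (HIGH), relaxed (MEDIUM), loose (LOW).
grammar_ladder <- function(grammar) {
  med <- grammar
  med$min_lower_bp <- 1L
  med$bulge_base <- union(grammar$bulge_base, c("C", "U"))
  low <- med
  low$max_defects <- max(2L, grammar$max_defects)
  list(HIGH = grammar, MEDIUM = med, LOW = low)
}

#' Score the hairpin geometry at one anchor
#'
#' Applies the grammar ladder: a layout admissible under the strict grammar
#' (canonical core, at most one defect) scores `HIGH`; failing that, a layout
#' under the relaxed grammar (pyrimidine bulge allowed, any lower-stem
#' support) scores `MEDIUM`; failing that, a layout tolerating two defects
#' scores `LOW`; otherwise no call is made.
#'
#' @param rna The window RNA sequence.
#' @param anchor 1-based loop-start offset.
#' @param grammar The strict [ire_grammar()].
#' @return `NULL`, or a list with `score` and `geometry`.
#' @export
score_ire_geometry <- function(rna, anchor, grammar = ire_grammar()) {
  for (lvl in names(ladder <- grammar_ladder(grammar))) {
    geom <- check_ire_geometry(rna, anchor, ladder[[lvl]])
    if (!is.null(geom)) return(list(score = lvl, geometry = geom))
  }
  NULL
}

#' Score a geometry object into High/Medium/Low
#'
#' Classifies an already-evaluated [check_ire_geometry()] result by the same
#' deterministic rules as [score_ire_geometry()]: a canonical core (literal C
#' bulge, lower stem meeting the strict minimum) with at most one defect is
#' `HIGH`; a layout only admissible under the relaxed grammar with at most
#' one defect is `MEDIUM`; anything else surviving with two defects is
#' `LOW`.
#'
#' @param geometry An `ire_geometry` object.
#' @param grammar The strict [ire_grammar()].
#' @return `"HIGH"`, `"MEDIUM"` or `"LOW"`.
#' @export
score_call <- function(geometry, grammar = ire_grammar()) {
  defects <- geometry$mismatches + geometry$bulges
  strict_core <- geometry$c_bulge_base == "C" &&
    geometry$lower_stem_bp >= grammar$min_lower_bp
  if (strict_core && defects <= grammar$max_defects) return("HIGH")
  if (defects <= grammar$max_defects) return("MEDIUM")
  "LOW"
}

#' Scan and score IRE calls over a set of UTR windows
#'
#' Runs the anchor prescreen and the geometry ladder over every window and
#' assembles the call table with window and genomic coordinates.
#'
#' @param utrs Window data.frame from [extract_utrs()].
#' @param pattern_set A [build_pattern_set()] object.
#' @param grammar The strict [ire_grammar()].
#' @return data.frame, one row per scored call: identification
#'   (`gene_id`, `side`), score fields (`score`, `canonical`, `mismatches`,
#'   `bulges`, `lower_stem_bp`, `pseudo_triloop`), window coordinates
#'   (`anchor`, `window_start`, `window_end`, 1-based in the window),
#'   `subsequence`, `dot_bracket`, and the genomic span (`contig_id`,
#'   `genomic_start`, `genomic_end`, `strand`).
#' @export
scan_ire <- function(utrs, pattern_set = build_pattern_set(),
                     grammar = ire_grammar()) {
  rows <- list()
  for (i in seq_len(nrow(utrs))) {
    utr <- utrs[i, ]
    if (!nzchar(utr$rna_sequence)) next
    cands <- scan_candidates(utr, pattern_set, grammar)
    for (j in seq_len(nrow(cands))) {
      sc <- score_ire_geometry(utr$rna_sequence, cands$anchor[j], grammar)
      if (is.null(sc)) next
      g <- sc$geometry
      gpos <- utr_genomic_position(utr, g$span)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = utr$gene_id, side = utr$side, score = sc$score,
        canonical = g$canonical, mismatches = g$mismatches,
        bulges = g$bulges, lower_stem_bp = g$lower_stem_bp,
        pseudo_triloop = g$pseudo_triloop,
        anchor = g$anchor, window_start = g$span[1], window_end = g$span[2],
        subsequence = substr(utr$rna_sequence, g$span[1], g$span[2]),
        dot_bracket = g$dot_bracket,
        contig_id = utr$contig_id, genomic_start = min(gpos),
        genomic_end = max(gpos), strand = utr$strand,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_call_table())
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

empty_call_table <- function() {
  data.frame(gene_id = character(0), side = character(0),
             score = character(0), canonical = logical(0),
             mismatches = integer(0), bulges = integer(0),
             lower_stem_bp = integer(0), pseudo_triloop = logical(0),
             anchor = integer(0), window_start = integer(0),
             window_end = integer(0), subsequence = character(0),
             dot_bracket = character(0), contig_id = character(0),
             genomic_start = integer(0), genomic_end = integer(0),
             strand = character(0))
}

#' Apply the retention filter to scored calls
#'
#' Retains every `HIGH` call, retains `MEDIUM` calls only when they carry no
#' mismatch (bulges do not disqualify), and drops `LOW` calls.
#'
#' @param calls Call table from [scan_ire()].
#' @return The retained subset of `calls`, with a `retained` column (all
#'   `TRUE`); the full annotated table is available as attribute
#'   `"all_calls"`.
#' @export
apply_filters <- function(calls) {
  retained <- calls$score == "HIGH" |
    (calls$score == "MEDIUM" & calls$mismatches == 0L)
  calls$retained <- retained
  out <- calls[retained, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_calls") <- calls
  out
}

#' Summarize retained IRE calls per gene and side
#'
#' Gene-level rollup: per side, the number of distinct genes with a call and
#' their canonical / non-canonical split (judged on each gene-side's best
#' call: HIGH before MEDIUM, then fewer defects, then the 5'-most anchor);
#' a gene with calls on both sides counts once in the gene total.
#'
#' @param calls Retained call table from [apply_filters()].
#' @return A list with `table` (one row per side: `side`, `n_genes`,
#'   `n_canonical`, `n_noncanonical`), `n_genes_total`, and `per_gene`
#'   (the best retained call per gene and side).
#' @export
summarize_calls <- function(calls) {
  sides <- c("five_prime", "three_prime")
  if (nrow(calls) == 0L) {
    return(list(table = data.frame(side = sides, n_genes = 0L,
                                   n_canonical = 0L, n_noncanonical = 0L),
                n_genes_total = 0L,
                per_gene = calls))
  }
  score_rank <- match(calls$score, c("HIGH", "MEDIUM", "LOW"))
  ord <- order(calls$gene_id, calls$side, score_rank,
               calls$mismatches + calls$bulges, calls$anchor)
  best <- calls[ord, , drop = FALSE]
  best <- best[!duplicated(best[, c("gene_id", "side")]), , drop = FALSE]
  tab <- do.call(rbind, lapply(sides, function(s) {
    b <- best[best$side == s, , drop = FALSE]
    data.frame(side = s, n_genes = length(unique(b$gene_id)),
               n_canonical = sum(b$canonical),
               n_noncanonical = sum(!b$canonical))
  }))
  rownames(best) <- NULL
  list(table = tab, n_genes_total = length(unique(calls$gene_id)),
       per_gene = best)
}

#' Write an IRE call table and its BED6 companion
#'
#' @param calls Call table ([scan_ire()] / [apply_filters()]).
#' @param path TSV output path; the BED companion replaces the extension
#'   with `.bed`.
#' @return The TSV path, invisibly.
#' @export
write_ire_calls <- function(calls, path) {
  write_tsv_file(calls, path)
  bed <- data.frame(calls$contig_id, calls$genomic_start - 1L,
                    calls$genomic_end,
                    paste0(calls$gene_id, "|", calls$side, "|", calls$score),
                    ifelse(calls$score == "HIGH", 1000L, 500L), calls$strand)
  utils::write.table(bed, sub("\\.[^.]+$", ".bed", path), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
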