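# Genome and annotation input, and strand-aware extraction of fixed-length
# gene-flanking windows used as proxy UTRs when no UTR annotation exists.

#' Load a genome from a FASTA file
#'
#' Reads a (multi-record) FASTA file into a `DNAStringSet`, uppercasing
#' soft-masked sequence. Record identifiers are the first whitespace-delimited
#' token of each header and must be unique.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig id.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGTACGT", ">c2", "ggcc"), fa)
#' load_genome(fa)
load_genome <- function(fasta_path) {
  contigs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(contigs) == 0L) {
    warning("no sequences found in ", fasta_path)
    return(contigs)
  }
  ids <- sub("\\s.*$", "", names(contigs))
  if (anyDuplicated(ids))
    stop("duplicate contig id(s) in ", fasta_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(contigs) <- ids
  # toupper() on a DNAStringSet folds soft-masked lowercase to uppercase
  Biostrings::DNAStringSet(toupper(contigs))
}

#' Load gene models from a GFF3 file
#'
#' Collects `CDS` features and collapses them per gene to the outermost CDS
#' extent. The gene identifier is taken from the first available of the
#' `gene_id`, `Parent`, `ID` or `locus_tag` attributes; CDS records carrying
#' none are skipped with a warning. Features with strand `.`/`*` are treated
#' as plus strand with a warning.
#'
#' @param gff_path Path to a GFF3 file containing CDS features.
#' @return A data.frame with columns `gene_id`, `contig_id`, `strand`
#'   (`"+"`/`"-"`), `cds_start`, `cds_end` (1-based inclusive).
#' @export
load_gene_models <- function(gff_path) {
  gr <- rtracklayer::import(gff_path)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  if (length(gr) == 0L)
    return(data.frame(gene_id = character(0), contig_id = character(0),
                      strand = character(0), cds_start = integer(0),
                      cds_end = integer(0)))
  meta <- S4Vectors::mcols(gr)
  pick_attr <- function(i) {
    for (field in c("gene_id", "Parent", "ID", "locus_tag")) {
      if (!field %in% names(meta)) next
      v <- meta[[field]][i]
      if (methods::is(v, "List") || is.list(v)) v <- unlist(v)
      v <- as.character(v)
      if (length(v) >= 1L && !is.na(v[1]) && nzchar(v[1])) return(v[1])
    }
    NA_character_
  }
  gene_ids <- vapply(seq_along(gr), pick_attr, character(1))
  if (anyNA(gene_ids)) {
    warning(sum(is.na(gene_ids)), " CDS feature(s) without a gene identifier",
            " skipped")
    gr <- gr[!is.na(gene_ids)]
    gene_ids <- gene_ids[!is.na(gene_ids)]
  }
  strands <- as.character(BiocGenerics::strand(gr))
  if (any(strands == "*")) {
    warning("CDS feature(s) with undefined strand treated as '+'")
    strands[strands == "*"] <- "+"
  }
  df <- data.frame(gene_id = gene_ids,
                   contig_id = as.character(GenomicRanges::seqnames(gr)),
                   strand = strands,
                   start = BiocGenerics::start(gr),
                   end = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(df, df$gene_id), function(d) {
    if (length(unique(d$contig_id)) > 1L)
      stop("gene ", d$gene_id[1], " has CDS on multiple contigs")
    data.frame(gene_id = d$gene_id[1], contig_id = d$contig_id[1],
               strand = d$strand[1],
               cds_start = min(d$start), cds_end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$contig_id, out$cds_start), , drop = FALSE]
}

#' Extract strand-aware UTR proxy windows flanking each CDS
#'
#' For each gene, cuts up to one five-prime and one three-prime window of at
#' most `flank_len` nt immediately flanking the CDS, clips them at contig
#' bounds, orients them 5'->3' on the coding strand (reverse-complementing
#' minus-strand genes) and transcribes them to the RNA alphabet. Windows
#' reduced to zero length at a contig edge are omitted. Overlap of a window
#' with another gene's CDS is reported in the `overlaps_gene` QC column, not
#' masked.
#'
#' @param contigs A named [Biostrings::DNAStringSet] (see [load_genome()]).
#' @param genes Gene model data.frame (see [load_gene_models()]).
#' @param flank_len Window length in nt (default 1000).
#' @param ignore_strand If `TRUE`, both windows are cut as naive plus-strand
#'   slices (compatibility mode); the five-prime window is always the
#'   left flank.
#' @return A data.frame, one row per window: `gene_id`, `side`
#'   (`"five_prime"`/`"three_prime"`), `contig_id`, `start`, `end` (1-based
#'   genomic, inclusive), `strand`, `rna_sequence`, `clipped`,
#'   `overlaps_gene`.
#' @export
extract_utrs <- function(contigs, genes, flank_len = 1000,
                         ignore_strand = FALSE) {
  stopifnot(flank_len >= 1)
  missing_contigs <- setdiff(genes$contig_id, names(contigs))
  if (length(missing_contigs))
    stop("contig(s) absent from genome: ",
         paste(missing_contigs, collapse = ", "))
  clens <- stats::setNames(Biostrings::width(contigs), names(contigs))
  bad <- genes$cds_start < 1 | genes$cds_end > clens[genes$contig_id]
  if (any(bad))
    stop("gene(s) with coordinates outside their contig: ",
         paste(genes$gene_id[bad], collapse = ", "))

  contig_chars <- stats::setNames(as.character(contigs), names(contigs))
  rows <- vector("list", 2L * nrow(genes))
  k <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    clen <- clens[[g$contig_id]]
    eff_strand <- if (ignore_strand) "+" else g$strand
    left <- c(max(1L, g$cds_start - flank_len), g$cds_start - 1L)
    right <- c(g$cds_end + 1L, min(clen, g$cds_end + flank_len))
    for (block in list(left, right)) {
      if (block[2] < block[1]) next  # zero-width window at contig edge
      is_left <- identical(block, left)
      side <- if (eff_strand == "+") {
        if (is_left) "five_prime" else "three_prime"
      } else {
        if (is_left) "three_prime" else "five_prime"
      }
      dna <- substr(contig_chars[[g$contig_id]], block[1], block[2])
      if (eff_strand == "-") dna <- revcomp_dna(dna)
      k <- k + 1L
      rows[[k]] <- data.frame(
        gene_id = g$gene_id, side = side, contig_id = g$contig_id,
        start = block[1], end = block[2], strand = eff_strand,
        rna_sequence = dna_to_rna(dna),
        clipped = (block[2] - block[1] + 1L) < flank_len,
        stringsAsFactors = FALSE)
    }
  }
  utrs <- do.call(rbind, rows[seq_len(k)])
  if (is.null(utrs))
    return(data.frame(gene_id = character(0), side = character(0),
                      contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      rna_sequence = character(0), clipped = logical(0),
                      overlaps_gene = logical(0)))
  # QC: does the window intersect any OTHER gene's CDS span?
  cds <- GenomicRanges::GRanges(genes$contig_id,
                                IRanges::IRanges(genes$cds_start,
                                                 genes$cds_end))
  win <- GenomicRanges::GRanges(utrs$contig_id,
                                IRanges::IRanges(utrs$start, utrs$end))
  ov <- GenomicRanges::findOverlaps(win, cds)
  other <- genes$gene_id[S4Vectors::subjectHits(ov)] !=
    utrs$gene_id[S4Vectors::queryHits(ov)]
  utrs$overlaps_gene <- FALSE
  utrs$overlaps_gene[unique(S4Vectors::queryHits(ov)[other])] <- TRUE
  rownames(utrs) <- NULL
  utrs
}

#' Map a window offset to its genomic position
#'
#' Inverts the window coordinate map: offset `i` (1-based within
#' `rna_sequence`) of a window row maps to a 1-based genomic position on the
#' window's contig. For plus-strand windows positions ascend with the offset;
#' for minus-strand windows they descend.
#'
#' @param utr A single-row window data.frame (one row of [extract_utrs()]).
#' @param offset Integer vector of 1-based offsets into `rna_sequence`.
#' @return Integer vector of genomic positions.
#' @export
utr_genomic_position <- function(utr, offset) {
  len <- utr$end - utr$start + 1L
  stopifnot(all(offset >= 1L & offset <= len))
  if (utr$strand == "+") utr$start + offset - 1L else utr$end - offset + 1L
}

#' Write UTR windows to FASTA
#'
#' Headers follow `geneID|side|contig:start-end(strand)`.
#' @param utrs Window data.frame from [extract_utrs()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_utr_fasta <- function(utrs, path) {
  headers <- sprintf("%s|%s|%s:%d-%d(%s)", utrs$gene_id, utrs$side,
                     utrs$contig_id, utrs$start, utrs$end, utrs$strand)
  seqs <- Biostrings::RNAStringSet(utrs$rna_sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write UTR windows as BED6
#'
#' BED uses 0-based half-open genomic intervals; the name column is
#' `geneID|side`.
#' @inheritParams write_utr_fasta
#' @export
write_utr_bed <- function(utrs, path) {
  bed <- data.frame(utrs$contig_id, utrs$start - 1L, utrs$end,
                    paste0(utrs$gene_id, "|", utrs$side), 0L, utrs$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
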