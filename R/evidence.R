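# Post-hoc support layers for retained IRE calls: validation of five-prime
# calls against experimentally determined transcription start sites, and
# categorisation of cross-species ortholog IRE support.

#' Load a TSS table
#'
#' @param path TSV with columns `gene_id`, `contig_id`, `position`
#'   (1-based genomic) and optionally `source`.
#' @return data.frame of TSS records.
#' @export
load_tss_table <- function(path) {
  tss <- read_tsv_file(path)
  stopifnot(all(c("gene_id", "contig_id", "position") %in% names(tss)))
  if (!"source" %in% names(tss)) tss$source <- "unknown"
  tss
}

#' Validate five-prime IRE calls against TSS positions
#'
#' A call is `within_boundary` when its genomic span lies inside the
#' transcribed region upstream of the CDS, i.e. strand-oriented between the
#' TSS and the CDS start, with `tolerance` extending the TSS boundary
#' outward (the default 200 nt absorbs approximate TSS mapping). Genes with
#' no TSS record yield `no_tss`. Three-prime calls are not evaluated. A TSS
#' on a different contig than its gene is a hard error. When a gene has
#' several TSS records the call is judged against each and the most
#' favourable status is kept.
#'
#' @param calls Retained call table ([apply_filters()]).
#' @param tss TSS data.frame ([load_tss_table()] layout).
#' @param genes Gene models ([load_gene_models()]).
#' @param tolerance Outward boundary extension in nt (default 200).
#' @return data.frame: `gene_id`, `anchor`, `genomic_start`, `genomic_end`,
#'   `status` (`within_boundary`/`outside_boundary`/`no_tss`),
#'   `distance_to_tss` (strand-oriented nt from the TSS to the call's
#'   upstream edge; negative means the call lies upstream of the TSS).
#' @export
tss_support <- function(calls, tss, genes, tolerance = 200) {
  calls <- calls[calls$side == "five_prime", , drop = FALSE]
  gidx <- match(tss$gene_id, genes$gene_id)
  known <- !is.na(gidx)
  if (any(known & tss$contig_id != genes$contig_id[gidx]))
    stop("TSS on a different contig than its gene: ",
         paste(tss$gene_id[known & tss$contig_id != genes$contig_id[gidx]],
               collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    g <- genes[genes$gene_id == cl$gene_id, ]
    positions <- tss$position[tss$gene_id == cl$gene_id]
    if (length(positions) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = cl$gene_id, anchor = cl$anchor,
        genomic_start = cl$genomic_start, genomic_end = cl$genomic_end,
        status = "no_tss", distance_to_tss = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    status <- "outside_boundary"
    dist <- -Inf
    for (pos in positions) {
      if (g$strand == "+") {
        d <- cl$genomic_start - pos
        inside <- d >= -tolerance && cl$genomic_end <= g$cds_start - 1L
      } else {
        d <- pos - cl$genomic_end
        inside <- d >= -tolerance && cl$genomic_start >= g$cds_end + 1L
      }
      if (inside && status != "within_boundary") {
        status <- "within_boundary"
        dist <- d
      } else if (status != "within_boundary" && d > dist) {
        dist <- d
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = cl$gene_id, anchor = cl$anchor,
      genomic_start = cl$genomic_start, genomic_end = cl$genomic_end,
      status = status, distance_to_tss = dist, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), anchor = integer(0),
                      genomic_start = integer(0), genomic_end = integer(0),
                      status = character(0), distance_to_tss = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load an ortholog map
#'
#' @param path TSV with columns `gene_id` (focal gene), `species`,
#'   `ortholog_id`.
#' @return data.frame.
#' @export
load_ortholog_map <- function(path) {
  m <- read_tsv_file(path)
  stopifnot(all(c("gene_id", "species", "ortholog_id") %in% names(m)))
  m
}

#' Load per-species IRE call sets
#'
#' @param path TSV with columns `species`, `gene_id` listing, per species,
#'   the genes whose UTRs carry a retained IRE call in that species.
#' @return Named list: species -> character vector of gene ids.
#' @export
load_species_calls <- function(path) {
  d <- read_tsv_file(path)
  stopifnot(all(c("species", "gene_id") %in% names(d)))
  lapply(split(d$gene_id, d$species), unique)
}

#' Default tsetse-group species tags
#' @return Character vector of the Glossina species tags used by
#'   [ortholog_support()]'s `glossina_only` flag.
#' @export
glossina_species <- function() c("GAUT", "GBRI", "GFUI", "GPAI", "GPPI")

#' Cross-species ortholog IRE support
#'
#' For each focal gene, a (species, ortholog) pair from the ortholog map is
#' supporting when that ortholog appears in that species' retained IRE call
#' set. Genes are categorised `multi` (two or more supporting pairs),
#' `single` (exactly one) or `none`; `glossina_only` flags genes whose
#' support comes exclusively from Glossina species. Species present in the
#' map but absent from `calls_by_species` are treated as giving no support,
#' with a warning.
#'
#' @param focal_genes Character vector of focal gene ids (genes absent from
#'   the map get category `none`).
#' @param calls_by_species Named list: species -> gene ids with retained
#'   IRE calls ([load_species_calls()]).
#' @param ortholog_map data.frame ([load_ortholog_map()]).
#' @param glossina Species tags counted as Glossina
#'   (default [glossina_species()]).
#' @return data.frame: `gene_id`, `n_support`, `category`, `glossina_only`,
#'   `supporting` (comma-joined `species:ortholog` pairs).
#' @export
ortholog_support <- function(focal_genes, calls_by_species, ortholog_map,
                             glossina = glossina_species()) {
  missing_sp <- setdiff(unique(ortholog_map$species),
                        names(calls_by_species))
  if (length(missing_sp))
    warning("species without call sets treated as no support: ",
            paste(missing_sp, collapse = ", "))
  rows <- lapply(unique(focal_genes), function(g) {
    m <- ortholog_map[ortholog_map$gene_id == g, , drop = FALSE]
    supp <- logical(nrow(m))
    for (j in seq_len(nrow(m))) {
      sp_calls <- calls_by_species[[m$species[j]]]
      supp[j] <- !is.null(sp_calls) && m$ortholog_id[j] %in% sp_calls
    }
    sup <- m[supp, , drop = FALSE]
    n <- nrow(sup)
    data.frame(
      gene_id = g, n_support = n,
      category = if (n >= 2L) "multi" else if (n == 1L) "single" else "none",
      glossina_only = n >= 1L && all(sup$species %in% glossina),
      supporting = paste(sprintf("%s:%s", sup$species, sup$ortholog_id),
                         collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), n_support = integer(0),
                      category = character(0), glossina_only = logical(0),
                      supporting = character(0))
  rownames(out) <- NULL
  out
}
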