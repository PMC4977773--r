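# End-to-end orchestration: extract windows, scan and score IRE candidates,
# filter, scan known elements, discover motifs in retained-gene UTRs, and
# attach TSS / ortholog evidence, under one configuration with a
# reproducibility manifest.

#' Pipeline configuration
#'
#' Defaults reproduce the method's stated settings: 1000-nt flank windows,
#' motif widths 6-30 with significance cutoff 1e-4, order-2 Markov
#' background, and a 200-nt TSS boundary tolerance.
#'
#' @param flank_len Flank window length (default 1000).
#' @param mode Anchor pattern mode, `"all"` or `"canonical"`.
#' @param min_lower_bp,max_defects,allow_gu Strict grammar parameters
#'   (see [ire_grammar()]).
#' @param w_min,w_max,p_cut,background_order Motif discovery parameters.
#' @param run_discovery Run de novo motif discovery (default `TRUE`;
#'   the slowest stage).
#' @param tss_tolerance TSS boundary tolerance in nt (default 200).
#' @param element_db_path Optional TSV overriding the built-in element DB.
#' @param seed RNG seed for the stochastic stages (default 1).
#' @param ignore_strand Naive plus-strand window slicing (default `FALSE`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(flank_len = 1000, mode = "all",
                            min_lower_bp = 3, max_defects = 1,
                            allow_gu = TRUE, w_min = 6, w_max = 30,
                            p_cut = 1e-4, background_order = 2,
                            run_discovery = TRUE, tss_tolerance = 200,
                            element_db_path = NULL, seed = 1,
                            ignore_strand = FALSE) {
  if (flank_len < 1) stop("flank_len must be >= 1")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#' @param path JSON file whose fields override [pipeline_config()] defaults.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, args)
}

#' Run the IRE discovery pipeline end to end
#'
#' Stages: window extraction, anchor scan + geometry scoring, retention
#' filtering, per-side summary, known-element scan over retained-gene
#' windows with enrichment against all windows, de novo motif discovery in
#' retained three-prime windows (annotated against the element DB), and —
#' when TSS / ortholog inputs are given — the evidence layers. Per-stage
#' attrition counts are logged with `message()`.
#'
#' @param contigs A [Biostrings::DNAStringSet] or FASTA path.
#' @param genes Gene model data.frame or GFF3 path.
#' @param config A [pipeline_config()].
#' @param tss Optional TSS data.frame or TSV path ([load_tss_table()]).
#' @param ortholog_map Optional ortholog map data.frame or TSV path.
#' @param species_calls Optional named list or TSV path
#'   ([load_species_calls()]).
#' @param out_dir Optional directory for the TSV/BED/FASTA outputs and the
#'   run manifest.
#' @return A list of class `report_bundle`: `utrs`, `calls` (all scored),
#'   `retained`, `summary`, `element_hits`, `enrichment`, `motifs`,
#'   `motif_annotation`, `tss_support`, `ortholog_support`, `manifest`.
#' @export
run_pipeline <- function(contigs, genes, config = pipeline_config(),
                         tss = NULL, ortholog_map = NULL,
                         species_calls = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(contigs)) contigs <- load_genome(contigs)
  if (is.character(genes)) genes <- load_gene_models(genes)
  if (is.character(tss)) tss <- load_tss_table(tss)
  if (is.character(ortholog_map)) ortholog_map <- load_ortholog_map(ortholog_map)
  if (is.character(species_calls)) species_calls <- load_species_calls(species_calls)
  grammar <- ire_grammar(min_lower_bp = config$min_lower_bp,
                         max_defects = config$max_defects,
                         allow_gu = config$allow_gu)
  patterns <- build_pattern_set(config$mode)
  db <- if (is.null(config$element_db_path)) element_db() else
    load_element_db(config$element_db_path)

  utrs <- extract_utrs(contigs, genes, config$flank_len,
                       ignore_strand = config$ignore_strand)
  message("stage extract: ", nrow(utrs), " windows from ",
          nrow(genes), " genes")

  calls <- scan_ire(utrs, patterns, grammar)
  retained <- apply_filters(calls)
  message("stage scan: ", nrow(calls), " scored candidates, ",
          nrow(retained), " retained")
  summary <- summarize_calls(retained)
  message("stage summary: ", summary$n_genes_total,
          " genes with retained IREs (5': ", summary$table$n_genes[1],
          ", 3': ", summary$table$n_genes[2], ")")

  ret_genes <- unique(retained$gene_id)
  fg <- utrs[utrs$gene_id %in% ret_genes, , drop = FALSE]
  element_hits <- if (nrow(fg)) scan_elements(fg, db) else
    scan_elements(utrs[0, ], db)
  enrichment <- if (nrow(fg) && nrow(utrs) > nrow(fg))
    element_enrichment(fg, utrs[!utrs$gene_id %in% ret_genes, , drop = FALSE],
                       db) else NULL
  message("stage elements: ", nrow(element_hits), " hits in ",
          nrow(fg), " retained-gene windows")

  motifs <- list()
  motif_annotation <- NULL
  disc <- fg[fg$side == "three_prime", , drop = FALSE]
  if (config$run_discovery && nrow(disc) >= 2L) {
    bg <- estimate_markov_background(disc$rna_sequence,
                                     order = config$background_order)
    motifs <- em_discover(disc$rna_sequence, config$w_min, config$w_max,
                          background = bg, seed = config$seed,
                          p_cut = config$p_cut)
    if (length(motifs))
      motif_annotation <- annotate_motifs(motifs, db,
                                          seed = config$seed)
    message("stage discovery: ", length(motifs),
            " significant motif(s) at p < ", config$p_cut)
  }

  tsup <- if (!is.null(tss) && nrow(retained))
    tss_support(retained, tss, genes, tolerance = config$tss_tolerance)
  osup <- if (!is.null(ortholog_map) && !is.null(species_calls) &&
              length(ret_genes))
    ortholog_support(ret_genes, species_calls, ortholog_map)

  manifest <- list(
    package_version = as.character(utils::packageVersion("irescout")),
    config = unclass(config),
    seed = config$seed,
    n_contigs = length(contigs), n_genes = nrow(genes),
    counts = list(windows = nrow(utrs), candidates = nrow(calls),
                  retained = nrow(retained),
                  genes_with_ire = summary$n_genes_total))

  bundle <- structure(list(
    utrs = utrs, calls = attr(retained, "all_calls"), retained = retained,
    summary = summary, element_hits = element_hits,
    enrichment = enrichment, motifs = motifs,
    motif_annotation = motif_annotation, tss_support = tsup,
    ortholog_support = osup, manifest = manifest),
    class = "report_bundle")

  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' Write a report bundle's tables to a directory
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_utr_fasta(bundle$utrs, file.path(out_dir, "utrs.fa"))
  write_utr_bed(bundle$utrs, file.path(out_dir, "utrs.bed"))
  write_ire_calls(bundle$calls, file.path(out_dir, "calls.tsv"))
  write_ire_calls(bundle$retained, file.path(out_dir, "retained.tsv"))
  write_tsv_file(bundle$summary$table, file.path(out_dir, "summary.tsv"))
  write_tsv_file(bundle$element_hits,
                 file.path(out_dir, "element_hits.tsv"))
  if (!is.null(bundle$enrichment))
    write_tsv_file(bundle$enrichment, file.path(out_dir, "enrichment.tsv"))
  if (length(bundle$motifs))
    write_meme_motifs(bundle$motifs, file.path(out_dir, "motifs.meme"))
  if (!is.null(bundle$motif_annotation))
    write_tsv_file(bundle$motif_annotation,
                   file.path(out_dir, "motif_annotation.tsv"))
  if (!is.null(bundle$tss_support))
    write_tsv_file(bundle$tss_support,
                   file.path(out_dir, "tss_support.tsv"))
  if (!is.null(bundle$ortholog_support))
    write_tsv_file(bundle$ortholog_support,
                   file.path(out_dir, "ortholog_support.tsv"))
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("IRE discovery report\n")
  cat("  windows:    ", nrow(x$utrs), "\n")
  cat("  candidates: ", nrow(x$calls), "\n")
  cat("  retained:   ", nrow(x$retained), "\n")
  cat("  genes with retained IREs:", x$summary$n_genes_total,
      sprintf("(5': %d, 3': %d)\n", x$summary$table$n_genes[1],
              x$summary$table$n_genes[2]))
  if (length(x$motifs))
    cat("  motifs:     ",
        paste(vapply(x$motifs, `[[`, "", "consensus"), collapse = ", "),
        "\n")
  invisible(x)
}
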