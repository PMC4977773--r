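# Known UTR regulatory element scanning (UTRScan role): a built-in database
# of simplified IUPAC consensus descriptors plus a procedural uORF detector,
# and Fisher-exact element enrichment of a foreground UTR set against a
# background set.

#' Built-in database of known UTR regulatory elements
#'
#' Simplified consensus encodings of commonly annotated UTR elements:
#' polyadenylation signal (PAS), AU-rich element (ARE), the miRNA seed
#' boxes (K-box, Brd-box, GY-box), cytoplasmic polyadenylation element
#' (CPE), Sex-lethal and UNR binding sites, and the procedural upstream-ORF
#' detector. Structural elements whose published descriptors are secondary
#' structure models (IRES, GAIT, FIE3) are deliberately absent; supply them
#' via [load_element_db()] with your own approximate descriptors if needed.
#'
#' @return data.frame with columns `name`, `region`
#'   (`five_prime`/`three_prime`/`both`), `matcher`
#'   (`iupac_pattern`/`procedural`), `definition`.
#' @export
element_db <- function() {
  db <- rbind(
    c("PAS",     "three_prime", "iupac_pattern", "AAUAAA"),
    c("PAS_var", "three_prime", "iupac_pattern", "AUUAAA"),
    c("ARE",     "three_prime", "iupac_pattern", "AUUUA"),
    c("K-box",   "three_prime", "iupac_pattern", "UGUGAU"),
    c("Brd-box", "three_prime", "iupac_pattern", "AGCUUUA"),
    c("GY-box",  "three_prime", "iupac_pattern", "GUCUUCC"),
    c("CPE",     "three_prime", "iupac_pattern", "UUUUUAU"),
    c("SXL-bs",  "both",        "iupac_pattern", "UUUUUUU"),
    c("UNR-bs",  "both",        "iupac_pattern", "RRAAGUAR"),
    c("uORF",    "five_prime",  "procedural",    "uorf"))
  out <- data.frame(name = db[, 1], region = db[, 2], matcher = db[, 3],
                    definition = db[, 4], stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(out$name))
  out
}

#' Load a UTR element database from a TSV file
#'
#' Expects the four columns of [element_db()]; names must be unique, region
#' one of `five_prime`, `three_prime`, `both`, matcher one of
#' `iupac_pattern`, `procedural`.
#'
#' @param path TSV path.
#' @return Element data.frame.
#' @export
load_element_db <- function(path) {
  db <- read_tsv_file(path)
  needed <- c("name", "region", "matcher", "definition")
  if (!all(needed %in% names(db)))
    stop("element DB must have columns: ", paste(needed, collapse = ", "))
  stopifnot(!anyDuplicated(db$name),
            all(db$region %in% c("five_prime", "three_prime", "both")),
            all(db$matcher %in% c("iupac_pattern", "procedural")))
  db[needed]
}

#' Scan one UTR window for a known element
#'
#' IUPAC-pattern elements are matched position by position with overlaps
#' allowed; the procedural `uORF` element dispatches to [find_uorfs()]. An
#' element whose region is incompatible with the window's side yields an
#' empty result by contract (the 5' and 3' sets are searched in separate
#' runs).
#'
#' @param utr One window row from [extract_utrs()].
#' @param element One row of the element database, or an element name to
#'   look up in [element_db()].
#' @param db Element database used when `element` is a name.
#' @return data.frame: `element`, `gene_id`, `side`, `start`, `end`
#'   (1-based inclusive window offsets), `matched`.
#' @export
scan_element <- function(utr, element, db = element_db()) {
  if (is.character(element)) {
    hit <- db[db$name == element, , drop = FALSE]
    if (nrow(hit) == 0L) stop("unknown element name: ", element)
    element <- hit
  }
  empty <- data.frame(element = character(0), gene_id = character(0),
                      side = character(0), start = integer(0),
                      end = integer(0), matched = character(0))
  if (element$region != "both" && element$region != utr$side) return(empty)
  if (element$matcher == "procedural") {
    if (element$definition != "uorf")
      stop("unknown procedural matcher: ", element$definition)
    return(find_uorfs(utr))
  }
  w <- nchar(element$definition)
  starts <- regex_starts(utr$rna_sequence, iupac_to_regex(element$definition))
  if (!length(starts)) return(empty)
  data.frame(element = element$name, gene_id = utr$gene_id, side = utr$side,
             start = starts, end = starts + w - 1L,
             matched = substring(utr$rna_sequence, starts, starts + w - 1L),
             stringsAsFactors = FALSE)
}

#' Detect upstream open reading frames in a 5' window
#'
#' Reports every AUG whose first in-frame stop codon (UAA/UAG/UGA) lies
#' fully inside the window, as one uORF spanning AUG through the stop codon.
#' A uORF must encode at least one codon between start and stop (minimum
#' span 9 nt); AUGs lacking an in-frame stop within the window are not
#' uORFs. No Kozak-context filtering is applied.
#'
#' @param utr One `five_prime` window row.
#' @return data.frame in the [scan_element()] hit layout, element `"uORF"`.
#' @export
find_uorfs <- function(utr) {
  stopifnot(utr$side == "five_prime")
  seq <- utr$rna_sequence
  n <- nchar(seq)
  stops <- c("UAA", "UAG", "UGA")
  augs <- regex_starts(seq, "AUG")
  rows <- list()
  for (a in augs) {
    s <- a + 3L
    while (s + 2L <= n) {
      codon <- substr(seq, s, s + 2L)
      if (codon %in% stops) {
        if (s + 2L - a + 1L >= 9L)
          rows[[length(rows) + 1L]] <- data.frame(
            element = "uORF", gene_id = utr$gene_id, side = utr$side,
            start = a, end = s + 2L,
            matched = substr(seq, a, s + 2L), stringsAsFactors = FALSE)
        break
      }
      s <- s + 3L
    }
  }
  if (!length(rows))
    return(data.frame(element = character(0), gene_id = character(0),
                      side = character(0), start = integer(0),
                      end = integer(0), matched = character(0)))
  do.call(rbind, rows)
}

#' Scan a set of UTR windows against an element database
#'
#' @param utrs Window data.frame from [extract_utrs()].
#' @param db Element database ([element_db()] layout).
#' @return Combined hit data.frame over all windows and elements.
#' @export
scan_elements <- function(utrs, db = element_db()) {
  hits <- list()
  for (i in seq_len(nrow(utrs)))
    for (j in seq_len(nrow(db)))
      hits[[length(hits) + 1L]] <- scan_element(utrs[i, ], db[j, ], db)
  out <- do.call(rbind, hits)
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(element = character(0), gene_id = character(0),
                      side = character(0), start = integer(0),
                      end = integer(0), matched = character(0)))
  rownames(out) <- NULL
  out
}

#' Element enrichment of a foreground UTR set against a background
#'
#' The counting unit is UTRs-with-at-least-one-hit (not hit totals), which
#' avoids window-length bias. Each element is tested with a two-sided Fisher
#' exact test on the 2x2 table (hit/no-hit x foreground/background) and
#' p-values are Benjamini-Hochberg adjusted across the elements tested.
#'
#' @param fg_utrs Foreground window data.frame.
#' @param bg_utrs Background window data.frame.
#' @param db Element database.
#' @return data.frame: `element`, `fg_hits`, `fg_n`, `bg_hits`, `bg_n`,
#'   `p`, `q`.
#' @export
element_enrichment <- function(fg_utrs, bg_utrs, db = element_db()) {
  if (nrow(fg_utrs) == 0L) stop("empty foreground set")
  count_hit_utrs <- function(utrs, el) {
    hits <- 0L
    for (i in seq_len(nrow(utrs)))
      if (nrow(scan_element(utrs[i, ], el, db)) > 0L) hits <- hits + 1L
    hits
  }
  rows <- lapply(seq_len(nrow(db)), function(j) {
    el <- db[j, ]
    fh <- count_hit_utrs(fg_utrs, el)
    bh <- count_hit_utrs(bg_utrs, el)
    fn <- nrow(fg_utrs); bn <- nrow(bg_utrs)
    p <- stats::fisher.test(matrix(c(fh, fn - fh, bh, bn - bh), 2L))$p.value
    data.frame(element = el$name, fg_hits = fh, fg_n = fn,
               bg_hits = bh, bg_n = bn, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
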