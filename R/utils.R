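# Shared low-level helpers: alphabet handling, IUPAC expansion, seeded RNG
# scoping, TSV writers. All coordinates in this package are 1-based inclusive.

RNA_BASES <- c("A", "C", "G", "U")

# IUPAC-IUB degenerate nucleotide codes, RNA alphabet (T folded into U).
IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U", T = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' Convert a DNA string to its strand-oriented RNA transcript
#'
#' Uppercases, and substitutes T with U. Reverse-complementation (for minus
#' strand features) is done by the caller on the DNA side.
#'
#' @param dna Character scalar over `{A,C,G,T,N}` (case-insensitive).
#' @return Character scalar over `{A,C,G,U,N}`.
#' @keywords internal
dna_to_rna <- function(dna) {
  chartr("Tt", "Uu", toupper(dna))
}

#' Reverse-complement a DNA string
#' @param dna Character scalar; N maps to N.
#' @return Character scalar.
#' @keywords internal
revcomp_dna <- function(dna) {
  paste(rev(strsplit(chartr("ACGTacgtN", "TGCAtgcaN", dna), "")[[1]]),
        collapse = "")
}

# Expand an IUPAC RNA pattern into a PCRE character-class regex.
iupac_to_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  paste0(vapply(chars, function(ch) {
    allowed <- IUPAC_RNA[[ch]]
    if (is.null(allowed)) stop("unknown IUPAC code: ", ch)
    if (length(allowed) == 1L) allowed else
      paste0("[", paste(allowed, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# All match start positions of a regex, overlapping matches included.
regex_starts <- function(x, regex) {
  hits <- gregexpr(paste0("(?=", regex, ")"), x, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

# Evaluate an expression under a temporary, fully-specified RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Random RNA string with the given GC fraction (i.i.d. bases).
random_rna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(RNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

random_dna <- function(n, gc = 0.5) chartr("U", "T", random_rna(n, gc))

# Uniform TSV writer used by every module's output surface.
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "")
}

# Integer base codes 1..4 for A,C,G,U (N and anything else -> NA).
encode_rna <- function(seq) {
  match(strsplit(seq, "")[[1]], RNA_BASES)
}

decode_rna <- function(codes) paste(RNA_BASES[codes], collapse = "")
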