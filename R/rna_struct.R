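# Combinatorial RNA pairing engine. A maximum base-pairing dynamic program
# (Nussinov) and an exhaustive enumerator over nested structures stand in for
# thermodynamic folding; an IRE-specific geometry checker evaluates hairpin
# layouts (lower stem, C8 bulge, five-pair upper stem, CAGUGH apical loop)
# directly instead of minimising free energy.

#' Folding parameters
#'
#' @param min_loop Minimum number of unpaired nt enclosed by a pair
#'   (hairpin-loop size), default 3.
#' @param allow_gu Allow G.U wobble pairs (default `TRUE`).
#' @return A list of class `fold_params`.
#' @export
fold_params <- function(min_loop = 3, allow_gu = TRUE) {
  stopifnot(min_loop >= 0)
  structure(list(min_loop = as.integer(min_loop),
                 allow_gu = isTRUE(allow_gu)),
            class = "fold_params")
}

# Watson-Crick (+ optional wobble) pairing predicate; N never pairs.
can_pair_base <- function(a, b, allow_gu = TRUE) {
  p <- paste0(a, b)
  p %in% c("AU", "UA", "CG", "GC") || (allow_gu && p %in% c("GU", "UG"))
}

#' Construct a pair table (nested RNA secondary structure)
#'
#' @param length Sequence length.
#' @param pairs Two-column integer matrix of 1-based index pairs `i < j`;
#'   may have zero rows. Pairs must be disjoint and nested (no pseudoknots).
#' @return A list of class `pair_table` with elements `length` and `pairs`
#'   (pairs sorted by first index).
#' @export
pair_table <- function(length, pairs = matrix(integer(0), ncol = 2)) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs)) {
    stopifnot(all(pairs[, 1] < pairs[, 2]),
              all(pairs >= 1L), all(pairs <= length),
              !anyDuplicated(as.vector(pairs)))
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    # nestedness: no two pairs may cross
    if (nrow(pairs) > 1L) {
      for (r in seq_len(nrow(pairs) - 1L)) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        rest <- pairs[-seq_len(r), , drop = FALSE]
        crossing <- (rest[, 1] > i & rest[, 1] < j & rest[, 2] > j)
        if (any(crossing)) stop("crossing pairs (pseudoknot) not allowed")
      }
    }
  }
  structure(list(length = as.integer(length), pairs = pairs),
            class = "pair_table")
}

#' Serialize a pair table to dot-bracket notation
#' @param pt A `pair_table`.
#' @return Character scalar of `(`, `)` and `.`.
#' @export
to_dotbracket <- function(pt) {
  db <- rep(".", pt$length)
  if (nrow(pt$pairs)) {
    db[pt$pairs[, 1]] <- "("
    db[pt$pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}

# Check that every pair of a pair_table is base-pair valid for `rna` and
# respects the min-loop constraint. Used by tests and by geometry assembly.
pair_table_valid <- function(pt, rna, params = fold_params()) {
  x <- strsplit(rna, "")[[1]]
  if (pt$length != length(x)) return(FALSE)
  if (!nrow(pt$pairs)) return(TRUE)
  all(pt$pairs[, 2] - pt$pairs[, 1] - 1L >= params$min_loop) &&
    all(mapply(can_pair_base, x[pt$pairs[, 1]], x[pt$pairs[, 2]],
               MoreArgs = list(allow_gu = params$allow_gu)))
}

#' Maximum base-pairing structure (Nussinov dynamic program)
#'
#' Computes a nested structure with the maximum number of base pairs under
#' the pairing rules in `params`. `N` never pairs. Ties are broken by the
#' traceback's preference for leaving the 5'-most base unpaired.
#'
#' @param rna RNA string over `{A,C,G,U,N}`.
#' @param params A [fold_params()] object.
#' @return A list with `max_pairs`, `pair_table` and `dot_bracket`.
#' @export
#' @examples
#' nussinov_fold("GGGAAACCC")$max_pairs  # 3
nussinov_fold <- function(rna, params = fold_params()) {
  x <- strsplit(toupper(rna), "")[[1]]
  n <- length(x)
  empty <- list(max_pairs = 0L, pair_table = pair_table(n),
                dot_bracket = paste(rep(".", n), collapse = ""))
  if (n == 0L) return(empty)
  ml <- params$min_loop
  M <- matrix(0L, n, n)
  for (span in (ml + 1L):max(ml + 1L, n - 1L)) {
    if (span > n - 1L) break
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i + 1L, j]  # i unpaired
      for (k in (i + ml + 1L):j) {
        if (!can_pair_base(x[i], x[k], params$allow_gu)) next
        inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
        outer <- if (k + 1L <= j) M[k + 1L, j] else 0L
        cand <- 1L + inner + outer
        if (cand > best) best <- cand
      }
      M[i, j] <- best
    }
  }
  # traceback
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || j - i <= ml) next
    if (M[i, j] == M[i + 1L, j]) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
      next
    }
    for (k in (i + ml + 1L):j) {
      if (!can_pair_base(x[i], x[k], params$allow_gu)) next
      inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
      outer <- if (k + 1L <= j) M[k + 1L, j] else 0L
      if (M[i, j] == 1L + inner + outer) {
        pairs <- rbind(pairs, c(i, k))
        if (k - 1L > i + 1L) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        if (k + 1L < j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
        break
      }
    }
  }
  pt <- pair_table(n, pairs)
  list(max_pairs = if (n > 1L) M[1L, n] else 0L, pair_table = pt,
       dot_bracket = to_dotbracket(pt))
}

#' Enumerate every nested structure of a short RNA
#'
#' Exhaustive, duplicate-free enumeration of all valid pair tables, used as
#' the independent oracle for [nussinov_fold()]. Guarded to sequences of at
#' most 16 nt.
#'
#' @inheritParams nussinov_fold
#' @return A list of `pair_table` objects (always contains the empty
#'   structure).
#' @export
enumerate_structures <- function(rna, params = fold_params()) {
  x <- strsplit(toupper(rna), "")[[1]]
  n <- length(x)
  if (n > 16L) stop("enumerate_structures is limited to sequences <= 16 nt")
  ml <- params$min_loop
  # decomposition on the leftmost index yields each structure exactly once
  enum <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2)))
    out <- enum(i + 1L, j)  # i unpaired
    if (j - i > ml) {
      for (k in (i + ml + 1L):j) {
        if (!can_pair_base(x[i], x[k], params$allow_gu)) next
        inner <- enum(i + 1L, k - 1L)
        outer <- enum(k + 1L, j)
        for (s1 in inner) for (s2 in outer)
          out[[length(out) + 1L]] <- rbind(c(i, k), s1, s2)
      }
    }
    out
  }
  lapply(enum(1L, n), function(p) pair_table(n, p))
}

#' IRE geometry grammar
#'
#' Structural thresholds for the hairpin layout search. The strict defaults
#' describe the canonical iron-responsive element: an apical CAGUGH loop, a
#' five-pair upper stem, an unpaired C immediately 5' of it (the C8 bulge)
#' and at least `min_lower_bp` contiguous lower-stem pairs, tolerating at
#' most `max_defects` defects (an upper-stem mismatch or one extra unpaired
#' nt on the 3' upper-stem strand).
#'
#' @param min_lower_bp Minimum contiguous lower-stem pairs (default 3,
#'   sensible range 1-10).
#' @param max_defects Maximum upper-stem defects, mismatches plus bulges
#'   (default 1).
#' @param allow_gu Count G.U wobble as a pair in both stems (default `TRUE`).
#' @param bulge_base Bases accepted at the C8-bulge position (default `"C"`;
#'   relaxed grammars also admit `"U"`).
#' @param lower_bp_cap Reporting cap on the lower-stem length (default 10).
#' @return A list of class `ire_grammar`.
#' @export
ire_grammar <- function(min_lower_bp = 3, max_defects = 1, allow_gu = TRUE,
                        bulge_base = "C", lower_bp_cap = 10) {
  stopifnot(min_lower_bp >= 1, min_lower_bp <= 10, max_defects >= 0)
  structure(list(min_lower_bp = as.integer(min_lower_bp),
                 max_defects = as.integer(max_defects),
                 allow_gu = isTRUE(allow_gu),
                 bulge_base = toupper(bulge_base),
                 lower_bp_cap = as.integer(lower_bp_cap)),
            class = "ire_grammar")
}

#' Evaluate IRE hairpin geometry at a loop anchor
#'
#' Searches every admissible layout around the anchored apical loop: the
#' loop hexamer must match `CAGUGH` (H = A/C/U), the five upper-stem position
#' pairs may carry at most `grammar$max_defects` defects (a mismatch, or one
#' bulged nt on the 3' strand of the upper stem), the C8-role base
#' immediately 5' of the upper stem must be in `grammar$bulge_base` and stay
#' unpaired, and the lower stem must stack at least `grammar$min_lower_bp`
#' contiguous pairs. Among admissible layouts the one with fewest defects,
#' then longest lower stem, then the bulge placed closest to the loop wins.
#'
#' @param rna RNA string (a UTR window or candidate subsequence).
#' @param anchor 1-based offset of the loop's first nt (the loop C).
#' @param grammar An [ire_grammar()].
#' @return A list of class `ire_geometry` (fields: `anchor`, `loop_seq`,
#'   `c_bulge_offset`, `upper_stem_pairs`, `mismatches`, `bulges`,
#'   `bulge_side`, `bulge_offset`, `lower_stem_bp`, `pseudo_triloop`,
#'   `canonical`, `span`, `pairs`, `dot_bracket`), or `NULL` when no layout
#'   satisfies the grammar (including windows too short for any layout).
#' @export
check_ire_geometry <- function(rna, anchor, grammar = ire_grammar()) {
  x <- strsplit(toupper(rna), "")[[1]]
  n <- length(x)
  anchor <- as.integer(anchor)
  if (anchor < 7L || anchor + 5L > n) return(NULL)
  loop <- x[anchor:(anchor + 5L)]
  if (!(loop[1] == "C" && loop[2] == "A" && loop[3] == "G" &&
        loop[4] == "U" && loop[5] == "G" && loop[6] %in% c("A", "C", "U")))
    return(NULL)
  if (!x[anchor - 6L] %in% grammar$bulge_base) return(NULL)
  p5 <- (anchor - 5L):(anchor - 1L)
  layouts <- list()
  for (b in 0:6) {  # 0: no bulge; 1..6: 3'-strand nt anchor+5+b bulged out
    span3_end <- anchor + 5L + if (b == 0L) 5L else 6L
    if (span3_end > n) next
    q_all <- (anchor + 6L):span3_end
    q <- if (b == 0L) q_all else q_all[-b]
    upper <- cbind(rev(p5), q)  # innermost pair first
    ok <- mapply(can_pair_base, x[upper[, 1]], x[upper[, 2]],
                 MoreArgs = list(allow_gu = grammar$allow_gu))
    mism <- sum(!ok)
    defects <- mism + (b > 0L)
    if (defects > grammar$max_defects) next
    r0 <- span3_end + 1L
    lower <- 0L
    while (lower < grammar$lower_bp_cap) {
      li <- anchor - 7L - lower
      ri <- r0 + lower
      if (li < 1L || ri > n ||
          !can_pair_base(x[li], x[ri], grammar$allow_gu)) break
      lower <- lower + 1L
    }
    if (lower < grammar$min_lower_bp) next
    layouts[[length(layouts) + 1L]] <-
      list(b = b, mism = mism, defects = defects, lower = lower,
           upper = upper, upper_ok = ok, r0 = r0)
  }
  if (!length(layouts)) return(NULL)
  ord <- order(vapply(layouts, `[[`, 0L, "defects"),
               -vapply(layouts, `[[`, 0L, "lower"),
               vapply(layouts, `[[`, 0L, "b"))
  L <- layouts[[ord[1]]]
  pseudo <- loop[1] == "C" && loop[5] == "G"
  pairs <- L$upper[L$upper_ok, , drop = FALSE]
  if (L$lower > 0L)
    pairs <- rbind(pairs,
                   cbind((anchor - 7L):(anchor - 6L - L$lower),
                         L$r0:(L$r0 + L$lower - 1L)))
  if (pseudo) pairs <- rbind(pairs, c(anchor, anchor + 4L))
  span <- c(anchor - 6L - L$lower, L$r0 + L$lower - 1L)
  pt <- pair_table(n, pairs)
  structure(list(
    anchor = anchor,
    loop_seq = paste(loop, collapse = ""),
    c_bulge_offset = anchor - 6L,
    c_bulge_base = x[anchor - 6L],
    upper_stem_pairs = L$upper,
    mismatches = as.integer(L$mism),
    bulges = as.integer(L$b > 0L),
    bulge_side = if (L$b > 0L) "three_prime_upper" else "none",
    bulge_offset = if (L$b > 0L) anchor + 5L + L$b else NA_integer_,
    lower_stem_bp = L$lower,
    pseudo_triloop = pseudo,
    canonical = (L$mism == 0L && L$b == 0L),
    span = as.integer(span),
    pairs = pt$pairs,
    dot_bracket = substr(to_dotbracket(pt), span[1], span[2])
  ), class = "ire_geometry")
}
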