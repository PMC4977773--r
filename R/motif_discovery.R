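# De novo motif discovery: k-order Markov background estimation, ZOOPS
# (zero-or-one-occurrence-per-sequence) EM over a width range, a seeded
# shuffle-based significance calibration, and annotation of discovered
# motifs against the known UTR element database.

#' Estimate a k-order Markov background model
#'
#' Counts context -> base transitions over the corpus with add-pseudocount
#' smoothing, together with all lower-order models (used for the first k
#' positions of a sequence). Contexts never observed fall back to the
#' uniform distribution. Counting is single-strand: UTR windows are
#' oriented RNA.
#'
#' @param seqs Character vector of RNA sequences (`N` positions are skipped).
#' @param order Markov order `k` (0-3).
#' @param pseudocount Added to every context cell (default 0.1).
#' @return A list of class `markov_background`: `order`, `pseudocount`,
#'   `cond` (per order 0..k, a `4^j x 4` matrix of conditional
#'   probabilities, rows named by context, `""` for order 0).
#' @export
estimate_markov_background <- function(seqs, order = 2, pseudocount = 0.1) {
  stopifnot(order >= 0, order <= 3, pseudocount >= 0)
  seqs <- seqs[nzchar(seqs)]
  if (length(seqs) == 0L) stop("empty corpus")
  cond <- vector("list", order + 1L)
  for (j in 0:order) {
    ctx <- if (j == 0L) "" else
      apply(do.call(expand.grid, rep(list(RNA_BASES), j))[, j:1, drop = FALSE],
            1, paste, collapse = "")
    counts <- matrix(pseudocount, nrow = length(ctx), ncol = 4L,
                     dimnames = list(ctx, RNA_BASES))
    for (s in seqs) {
      n <- nchar(s)
      if (n <= j) next
      pos <- (j + 1L):n
      bases <- substring(s, pos, pos)
      keys <- if (j == 0L) rep("", length(pos)) else
        substring(s, pos - j, pos - 1L)
      keep <- bases %in% RNA_BASES & !grepl("N", keys, fixed = TRUE)
      if (!any(keep)) next
      tab <- table(factor(keys[keep], levels = ctx),
                   factor(bases[keep], levels = RNA_BASES))
      counts <- counts + as.matrix(tab)
    }
    rs <- rowSums(counts)
    probs <- counts / rs
    probs[rs == 0, ] <- 0.25  # pseudocount 0 and context unseen -> uniform
    cond[[j + 1L]] <- probs
  }
  structure(list(order = as.integer(order), pseudocount = pseudocount,
                 cond = cond),
            class = "markov_background")
}

#' Sample a sequence from a Markov background
#'
#' @param bg A `markov_background`.
#' @param n Sequence length.
#' @return RNA string of length `n` drawn from the model (lower-order
#'   conditionals seed the first `order` positions). Uses the current RNG
#'   state; wrap in a seeded context for reproducibility.
#' @export
sample_markov <- function(bg, n) {
  if (n <= 0L) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    j <- min(i - 1L, bg$order)
    key <- if (j == 0L) 1L else paste(out[(i - j):(i - 1L)], collapse = "")
    out[i] <- sample(RNA_BASES, 1L, prob = bg$cond[[j + 1L]][key, ])
  }
  paste(out, collapse = "")
}

# Per-position log background probability of a sequence (N -> log 0.25).
bg_logprob_positions <- function(seq, bg) {
  n <- nchar(seq)
  if (n == 0L) return(numeric(0))
  out <- rep(log(0.25), n)
  pos_all <- seq_len(n)
  bidx <- match(substring(seq, pos_all, pos_all), RNA_BASES)
  # first `order` positions use their lower-order conditionals
  for (i in seq_len(min(bg$order, n))) {
    j <- i - 1L
    if (is.na(bidx[i])) next
    key <- if (j == 0L) 1L else substr(seq, 1L, j)
    ri <- if (j == 0L) 1L else match(key, rownames(bg$cond[[j + 1L]]))
    if (!is.na(ri)) out[i] <- log(bg$cond[[j + 1L]][ri, bidx[i]])
  }
  if (n > bg$order) {
    k <- bg$order
    pos <- (k + 1L):n
    ri <- if (k == 0L) rep(1L, length(pos)) else
      match(substring(seq, pos - k, pos - 1L), rownames(bg$cond[[k + 1L]]))
    ok <- !is.na(ri) & !is.na(bidx[pos])
    out[pos[ok]] <- log(bg$cond[[k + 1L]][cbind(ri[ok], bidx[pos[ok]])])
  }
  out
}

# One ZOOPS EM fit at a fixed width from one seeded start.
# X: n x Lmax integer code matrix (padded with 1); lens: true lengths;
# BGW: n x m matrix of log background probabilities of each w-window;
# valid: n x m logical matrix of admissible motif starts.
zoops_em_fit <- function(X, lens, w, BGW, valid, pre, pseudocount = 0.1,
                         max_iter = 100, tol = 1e-6, init_theta = NULL,
                         init_gamma = 0.5) {
  n <- nrow(X)
  m <- ncol(BGW)
  mi <- pmax(lens - w + 1L, 0L)
  if (is.null(init_theta)) {
    # seed the PWM from one random admissible site
    cand <- which(valid, arr.ind = TRUE)
    pick <- cand[sample.int(nrow(cand), 1L), ]
    seed_codes <- X[pick[1], pick[2]:(pick[2] + w - 1L)]
    theta <- matrix(0.1, nrow = w, ncol = 4L,
                    dimnames = list(NULL, RNA_BASES))
    theta[cbind(seq_len(w), seed_codes)] <- 0.7
  } else {
    theta <- init_theta
  }
  gamma <- init_gamma
  ll_prev <- -Inf
  pll_prev <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ltheta <- log(theta)
    llw <- numeric(n * m)
    for (k in seq_len(w)) llw <- llw + ltheta[k, pre$codes[[k]]]
    A <- llw - BGW + log(gamma) - log(pmax(mi, 1L))
    dim(A) <- c(n, m)
    if (!all(valid)) A[!valid] <- -Inf
    z0 <- log(1 - gamma)
    rowmax <- pmax(A[cbind(seq_len(n), max.col(A, ties.method = "first"))],
                   z0)
    E <- exp(A - rowmax)
    denom <- exp(z0 - rowmax) + rowSums(E)
    lse <- rowmax + log(denom)
    ll <- sum(lse)  # log-likelihood relative to the background-only model
    # the pseudocount M-step is a MAP update under a Dirichlet prior, so
    # the monotone quantity is the penalized (posterior) log-likelihood
    pll <- ll + pseudocount * sum(ltheta)
    if (pll < pll_prev - 1e-6 * (abs(pll_prev) + 1))
      stop("EM penalized log-likelihood decreased: ", pll_prev, " -> ", pll)
    pll_prev <- pll
    Z <- E / denom
    z0p <- exp(z0 - rowmax) / denom
    gamma <- min(max(mean(1 - z0p), 1e-6), 1 - 1e-6)
    cnt <- matrix(0, w, 4L)
    zvec <- as.vector(Z)
    for (k in seq_len(w)) for (b in 1:4)
      cnt[k, b] <- sum(zvec[pre$idx[[k]][[b]]])
    theta <- (cnt + pseudocount) / (rowSums(cnt) + 4 * pseudocount)
    dimnames(theta) <- list(NULL, RNA_BASES)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < tol * (abs(ll_prev) + tol)) break
    if (iter >= max_iter) break
    ll_prev <- ll
  }
  site_idx <- max.col(A, ties.method = "first")
  has_site <- (1 - z0p) > 0.5 & mi > 0L
  list(theta = theta, gamma = gamma, llr = ll, n_iter = iter,
       sites = data.frame(seq = which(has_site),
                          offset = site_idx[has_site]))
}

# Hill-climb over +-1 column shifts of the converged model (vacated columns
# reset to uniform), re-running EM from each shifted start and keeping the
# best LLR until no shift improves. Corrects the phase drift EM is prone to
# when seeded off-register from an embedded word.
refine_phase <- function(fit, X, lens, w, BGW, valid, pre, max_iter, tol,
                         max_rounds = 4L) {
  best <- fit
  for (round in seq_len(max_rounds)) {
    improved <- FALSE
    for (d in c(-1L, 1L)) {
      th <- matrix(0.25, w, 4L, dimnames = list(NULL, RNA_BASES))
      src <- seq_len(w) - d
      keep <- src >= 1L & src <= w
      th[keep, ] <- best$theta[src[keep], ]
      f2 <- zoops_em_fit(X, lens, w, BGW, valid, pre, max_iter = max_iter,
                         tol = tol, init_theta = th,
                         init_gamma = best$gamma)
      if (f2$llr > best$llr + 1e-6) {
        best <- f2
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  best
}

# Best-of-restarts ZOOPS fit on a coded corpus at one width.
zoops_em_width <- function(seqs, w, bg, n_starts, max_iter, tol) {
  lens <- nchar(seqs)
  usable <- lens >= w
  if (sum(usable) < 2L) return(NULL)
  seqs <- seqs[usable]
  lens <- lens[usable]
  n <- length(seqs)
  Lmax <- max(lens)
  X <- matrix(1L, n, Lmax)
  B <- matrix(0, n, Lmax)
  for (i in seq_len(n)) {
    X[i, seq_len(lens[i])] <- encode_rna(seqs[i])
    B[i, seq_len(lens[i])] <- bg_logprob_positions(seqs[i], bg)
  }
  m <- Lmax - w + 1L
  if (m < 1L) return(NULL)
  CS <- cbind(0, t(apply(B, 1, cumsum)))
  BGW <- CS[, (w + 1L):(Lmax + 1L), drop = FALSE] -
    CS[, 1L:m, drop = FALSE]
  if (n == 1L) BGW <- matrix(BGW, 1L)
  valid <- outer(lens, seq_len(m), function(L, j) j <= L - w + 1L)
  # window code layout is fixed across iterations and restarts:
  # pre$codes[[k]] is the base code of window position k for every window,
  # pre$idx[[k]][[b]] the flat window indices where that code equals b
  pre <- list(codes = vector("list", w), idx = vector("list", w))
  for (k in seq_len(w)) {
    codes <- as.vector(X[, k:(k + m - 1L), drop = FALSE])
    pre$codes[[k]] <- codes
    pre$idx[[k]] <- lapply(1:4, function(b) which(codes == b))
  }
  # data-driven seeding: the most over-represented exact w-mers make the
  # strongest EM starts; remaining restarts seed from random sites
  kmers <- unlist(lapply(seq_len(n), function(i) {
    starts <- seq_len(lens[i] - w + 1L)
    substring(seqs[i], starts, starts + w - 1L)
  }))
  counts <- sort(table(kmers), decreasing = TRUE)
  top <- names(counts)[counts >= 2L]
  top <- top[seq_len(min(length(top), max(n_starts - 1L, 1L)))]
  seed_thetas <- lapply(top, function(km) {
    th <- matrix(0.1, w, 4L, dimnames = list(NULL, RNA_BASES))
    th[cbind(seq_len(w), match(strsplit(km, "")[[1]], RNA_BASES))] <- 0.7
    th
  })
  n_random <- max(n_starts - length(seed_thetas), 1L)
  seed_thetas <- c(seed_thetas, vector("list", n_random))  # NULL = random
  best <- NULL
  for (s in seq_along(seed_thetas)) {
    fit <- zoops_em_fit(X, lens, w, BGW, valid, pre,
                        max_iter = max_iter, tol = tol,
                        init_theta = seed_thetas[[s]])
    if (is.null(best) || fit$llr > best$llr) best <- fit
  }
  best <- refine_phase(best, X, lens, w, BGW, valid, pre, max_iter, tol)
  best$seq_index <- which(usable)
  best
}

# Within-sequence letter shuffle preserving composition.
shuffle_seqs <- function(seqs) {
  vapply(seqs, function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Discover over-represented motifs by ZOOPS EM
#'
#' For each width in the search set, fits a ZOOPS motif model by
#' expectation-maximisation from `n_starts` seeded restarts and scores it by
#' its log-likelihood ratio (LLR) against the Markov background. The LLR is
#' calibrated against a null distribution obtained by re-running the same
#' discovery on `null_B` within-sequence shuffled copies of the corpus; the
#' reported p-value is the fitted t-tail of that null. Only motifs with
#' `p < p_cut` are reported, best (smallest p, then largest LLR) first.
#' The run is deterministic given `seed`.
#'
#' @param seqs Character vector of RNA sequences (>= 2; sequences containing
#'   `N` are dropped with a warning).
#' @param w_min,w_max Width range (6-30). The search is decimated to every
#'   second width by default; set `width_step = 1` for the full range.
#' @param background A `markov_background`; estimated from `seqs` at order 2
#'   when `NULL`.
#' @param n_motifs Maximum number of motifs reported (default 3).
#' @param seed RNG seed (mandatory).
#' @param p_cut Significance cutoff on the calibrated p-value
#'   (default 1e-4).
#' @param n_starts EM restarts per width (default 3; phase-shift
#'   hill-climbing follows each best-of-restarts fit).
#' @param null_B Number of shuffled corpora for the null (default 10).
#' @param width_step Width decimation step (default 2).
#' @param max_iter,tol EM iteration cap and relative LLR tolerance.
#' @return List of `motif_model` objects: `width`, `pwm` (w x 4, rows sum
#'   to 1), `consensus`, `sites` (`seq_id`, `offset`), `llr`, `gamma`,
#'   `p_value`, `null_mean`, `null_sd`, `seed`, `n_iter`.
#' @export
em_discover <- function(seqs, w_min = 6, w_max = 30, background = NULL,
                        n_motifs = 3, seed, p_cut = 1e-4, n_starts = 3,
                        null_B = 10, width_step = 2, max_iter = 60,
                        tol = 1e-6) {
  stopifnot(w_min >= 6, w_max <= 30, w_min <= w_max)
  if (missing(seed)) stop("seed is mandatory")
  has_n <- grepl("N", seqs, fixed = TRUE)
  if (any(has_n)) {
    warning(sum(has_n), " sequence(s) containing N dropped from discovery")
    seqs <- seqs[!has_n]
  }
  if (length(seqs) < 2L) stop("need at least 2 usable sequences")
  if (is.null(background))
    background <- estimate_markov_background(seqs, order = 2)
  widths <- seq(as.integer(w_min), as.integer(w_max), by = width_step)
  with_seed(seed, {
    motifs <- list()
    for (w in widths) {
      fit <- zoops_em_width(seqs, w, background, n_starts, max_iter, tol)
      if (is.null(fit)) next
      null_llr <- numeric(null_B)
      for (b in seq_len(null_B)) {
        nfit <- zoops_em_width(shuffle_seqs(seqs), w, background,
                               n_starts, max_iter, tol)
        null_llr[b] <- if (is.null(nfit)) 0 else nfit$llr
      }
      mu <- mean(null_llr)
      sdv <- stats::sd(null_llr)
      p <- if (sdv < 1e-9) as.numeric(fit$llr <= mu + 1e-6) else
        stats::pt((fit$llr - mu) / sdv, df = null_B - 1L,
                  lower.tail = FALSE)
      consensus <- paste(RNA_BASES[apply(fit$theta, 1, which.max)],
                         collapse = "")
      sites <- data.frame(
        seq_id = fit$seq_index[fit$sites$seq],
        offset = fit$sites$offset)
      motifs[[length(motifs) + 1L]] <- structure(
        list(width = w, pwm = fit$theta, consensus = consensus,
             sites = sites, llr = fit$llr, gamma = fit$gamma,
             p_value = p, null_mean = mu, null_sd = sdv,
             seed = seed, n_iter = fit$n_iter),
        class = "motif_model")
    }
    motifs <- Filter(function(m) m$p_value < p_cut, motifs)
    ord <- order(vapply(motifs, `[[`, 0, "p_value"),
                 -vapply(motifs, `[[`, 0, "llr"))
    motifs[ord][seq_len(min(n_motifs, length(motifs)))]
  })
}

# Log-odds alignment score of a PWM against an element's IUPAC pattern:
# per overlapping column log( sum(theta[allowed]) / sum(pi[allowed]) ),
# averaged over the overlap, maximised over full-containment alignments.
pwm_element_score <- function(pwm, pattern, base_freq = rep(0.25, 4)) {
  allowed <- lapply(strsplit(toupper(pattern), "")[[1]], function(ch) {
    a <- IUPAC_RNA[[ch]]
    if (is.null(a)) stop("unknown IUPAC code in element pattern: ", ch)
    match(a, RNA_BASES)
  })
  w <- nrow(pwm)
  L <- length(allowed)
  col_score <- function(theta_row, idx)
    log(max(sum(theta_row[idx]), 1e-9) / sum(base_freq[idx]))
  scores <- c()
  if (w >= L) {
    for (off in 0:(w - L))
      scores <- c(scores, mean(vapply(seq_len(L), function(k)
        col_score(pwm[off + k, ], allowed[[k]]), 0)))
  } else {
    for (off in 0:(L - w))
      scores <- c(scores, mean(vapply(seq_len(w), function(k)
        col_score(pwm[k, ], allowed[[off + k]]), 0)))
  }
  max(scores)
}

#' Annotate discovered motifs against the known-element database
#'
#' Each motif is scored against each IUPAC-pattern element by the best
#' log-odds alignment of its PWM to the element descriptor. Significance is
#' empirical: the observed score is compared with `n_null` null scores in
#' which the PWM's columns are order-shuffled and each column's four
#' probabilities are randomly permuted (so an uninformative PWM is its own
#' null). p-values are Benjamini-Hochberg adjusted across all
#' motif x element pairs; the best match per motif is the minimum q.
#'
#' @param motifs List of `motif_model` objects.
#' @param db Element database ([element_db()]); procedural entries are
#'   skipped.
#' @param n_null Null permutations per pair (default 499).
#' @param seed RNG seed for the permutation null.
#' @return data.frame: `motif` (index), `consensus`, `element`, `score`,
#'   `p`, `q`, `best` (logical, minimum q within the motif).
#' @export
annotate_motifs <- function(motifs, db = element_db(), n_null = 499,
                            seed = 1) {
  db <- db[db$matcher == "iupac_pattern", , drop = FALSE]
  if (nrow(db) == 0L) stop("element database has no scannable descriptors")
  if (length(motifs) == 0L)
    return(data.frame(motif = integer(0), consensus = character(0),
                      element = character(0), score = numeric(0),
                      p = numeric(0), q = numeric(0), best = logical(0)))
  with_seed(seed, {
    rows <- list()
    for (mi in seq_along(motifs)) {
      pwm <- motifs[[mi]]$pwm
      for (j in seq_len(nrow(db))) {
        obs <- pwm_element_score(pwm, db$definition[j])
        null_scores <- vapply(seq_len(n_null), function(b) {
          perm <- pwm[sample.int(nrow(pwm)), , drop = FALSE]
          for (r in seq_len(nrow(perm)))
            perm[r, ] <- perm[r, sample.int(4L)]
          pwm_element_score(perm, db$definition[j])
        }, 0)
        p <- (1 + sum(null_scores >= obs)) / (n_null + 1)
        rows[[length(rows) + 1L]] <- data.frame(
          motif = mi, consensus = motifs[[mi]]$consensus,
          element = db$name[j], score = obs, p = p,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out$best <- FALSE
    for (mi in unique(out$motif)) {
      sel <- which(out$motif == mi)
      best <- sel[order(out$q[sel], -out$score[sel])][1]
      out$best[best] <- TRUE
    }
    out
  })
}

#' Write motifs in minimal MEME text format
#'
#' Emits the version header, alphabet, background frequencies and one
#' letter-probability matrix per motif, readable by MEME-suite tools.
#'
#' @param motifs List of `motif_model` objects.
#' @param path Output path.
#' @param base_freq Background base frequencies (A, C, G, U).
#' @return The path, invisibly.
#' @export
write_meme_motifs <- function(motifs, path, base_freq = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", RNA_BASES, base_freq),
                     collapse = " "), ""), con)
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    writeLines(sprintf("MOTIF m%d %s", i, m$consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= %.3g",
      m$width, nrow(m$sites), m$p_value), con)
    for (r in seq_len(m$width))
      writeLines(paste(sprintf("%.6f", m$pwm[r, ]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}
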