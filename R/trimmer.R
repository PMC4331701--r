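#' Parameters for the two-stage trimming algorithm
#'
#' The algorithm scans the reverse complement of the first `L` bases of each
#' mate along the other mate. Each tolerance `e` is a maximum mismatch
#' fraction: a comparison of length `len` passes when its mismatch count is
#' at most `floor(len * e)`. Setting a tolerance to 1 disables its check
#' (the budget equals the length). Defaults are the recommended operating
#' point for 101-nt Illumina pairs.
#'
#' @param L Prefix length in bases for the stage-1 scan (default 30); choose
#'   it at or below the minimum insert size of interest. Pairs with mates
#'   shorter than `L` are passed through untrimmed.
#' @param e1 Stage-1 mismatch tolerance for the sliding prefix comparison
#'   (default 0.4).
#' @param e2 Stage-2 tolerance for reverse-complementarity of the inferred
#'   DNA portions (default 0.6).
#' @param e3 Stage-2 tolerance for equality of the inferred adapter portions
#'   (default 0.4). Set to 1 for libraries whose forward and reverse
#'   adapters differ in sequence.
#' @param strict_singleton Also validate a candidate that is the sole
#'   element of the stage-1 intersection (default `FALSE`: a unique doubly
#'   supported site is accepted as-is).
#' @return A list of class `trimmer_params`.
#' @export
trimmer_params <- function(L = 30L, e1 = 0.4, e2 = 0.6, e3 = 0.4,
                           strict_singleton = FALSE) {
  L <- as.integer(L)
  stopifnot(length(L) == 1, L >= 1,
            e1 >= 0, e1 <= 1, e2 >= 0, e2 <= 1, e3 >= 0, e3 <= 1)
  structure(list(L = L, e1 = e1, e2 = e2, e3 = e3,
                 strict_singleton = isTRUE(strict_singleton)),
            class = "trimmer_params")
}

#' @export
print.trimmer_params <- function(x, ...) {
  cat(sprintf(
    "<trimmer_params> L=%d e1=%g e2=%g e3=%g strict_singleton=%s\n",
    x$L, x$e1, x$e2, x$e3, x$strict_singleton))
  invisible(x)
}

#' Reverse complement of nucleotide strings
#'
#' Watson-Crick complement, reversed; `N` is self-complementary. Vectorized
#' over strings.
#'
#' @param seq Character vector over the alphabet `{A,C,G,T,N}` (case kept).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement(c("ACGT", "AAGATC", "AAAN"))
#' @export
reverse_complement <- function(seq) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", seq))
}

#' Hamming distance with N counted as a mismatch
#'
#' Counts positions where the two strings differ or where either character
#' is `N` (an undetermined base can never support a match). Vectorized over
#' pairs of equal-length strings.
#'
#' @param a,b Character vectors of equal-length nucleotide strings.
#' @return Integer vector of mismatch counts.
#' @export
count_mismatches <- function(a, b) {
  .hamming_n_cpp(as.character(a), as.character(b))
}

#' Stage-1 scan: candidate insert lengths from one mate against the other
#'
#' Takes the first `L` bases of `template_seq`, reverse complements them,
#' and slides the result along `target_seq`. Every 0-based start `p` whose
#' window mismatch count is within `floor(L * e1)` contributes candidate
#' insert length `p + L`. With `e1 = 1` every position qualifies.
#'
#' @param template_seq,target_seq Nucleotide strings (single reads).
#' @param params A [trimmer_params()] object.
#' @return Ascending integer vector of candidate insert lengths, with the
#'   number of character comparisons performed in attribute `"comparisons"`.
#'   A read shorter than `L` yields an empty set with a warning.
#' @examples
#' scan_candidates("ACGTTGAGAT", "CAACGTAGAT", trimmer_params(L = 4, e1 = 0))
#' @export
scan_candidates <- function(template_seq, target_seq,
                            params = trimmer_params()) {
  if (nchar(template_seq) < params$L || nchar(target_seq) < params$L) {
    warn(sprintf("read shorter than L=%d; no candidates", params$L))
    return(structure(integer(), comparisons = 0))
  }
  res <- .scan_candidates_cpp(template_seq, target_seq, params$L, params$e1)
  structure(res$candidates, comparisons = res$comparisons)
}

#' Intersect the two directional candidate sets
#'
#' Candidate insert lengths supported by both scan directions (G1: mate 1's
#' prefix against mate 2; G2: the reverse) are the doubly supported
#' trimming sites the decision logic works from. Both scans emit ascending
#' sets, so the intersection is returned ascending.
#'
#' @param g1,g2 Integer vectors of candidate insert lengths.
#' @return Ascending integer vector.
#' @export
candidate_intersection <- function(g1, g2) {
  sort(intersect(as.integer(g1), as.integer(g2)))
}

#' Stage-2 validation of a candidate insert length
#'
#' A candidate `n` splits each mate into an inferred DNA portion (first `n`
#' bases) and an inferred adapter portion (the rest). The DNA portions must
#' be mutual reverse complements within `floor(n * e2)` mismatches and the
#' adapter portions equal within `floor((N - n) * e3)` mismatches (vacuous
#' when `n = N`). Either check is disabled by a tolerance of 1.
#'
#' @param seq1,seq2 Mate sequences of equal length `N`.
#' @param n Candidate insert length(s), each in `[L, N]`.
#' @inheritParams scan_candidates
#' @return Logical vector.
#' @export
validate_candidate <- function(seq1, seq2, n, params = trimmer_params()) {
  N <- nchar(seq1)
  if (nchar(seq2) != N) abort("mates must have equal length")
  if (any(n < params$L | n > N)) {
    abort(sprintf("candidate insert length outside [L=%d, N=%d]",
                  params$L, N))
  }
  .validate_candidate_cpp(seq1, seq2, as.integer(n), params$e2, params$e3)
}

#' Trim adapter read-through from paired-end reads
#'
#' Applies the two-stage algorithm to every pair. Stage 1 scans each mate's
#' reverse-complemented `L`-prefix along the other mate, producing candidate
#' sets G1 and G2 whose intersection I holds the doubly supported insert
#' lengths. An empty I leaves the pair untrimmed; a singleton is accepted
#' directly (unless `strict_singleton`); otherwise candidates are validated
#' largest-first by [validate_candidate()] and the first to pass wins. An
#' accepted insert length `n < N` trims both mates (and their qualities) to
#' their first `n` bases; `n = N` means a zero-length adapter, so nothing is
#' removed and the pair is reported untrimmed.
#'
#' Pairs with unequal mate lengths or mates shorter than `L` are passed
#' through untrimmed and flagged in the `skipped` column, with one summary
#' warning.
#'
#' @param pairs A tibble of read pairs (columns `seq1`, `qual1`, `seq2`,
#'   `qual2`, optionally `pair_id`, `id1`, `id2`), as from
#'   [read_paired_fastq()].
#' @inheritParams scan_candidates
#' @return A tibble of class `trim_result`: the identifier columns, trimmed
#'   `seq1`/`qual1`/`seq2`/`qual2`, plus `trimmed` (logical),
#'   `insert_length` (integer, `NA` when untrimmed), `candidates`
#'   (list-column: the stage-1 intersection, ascending),
#'   `validated_candidate` (the accepted element, `NA` if none),
#'   `n_candidates`, `n_validated` (stage-2 validations performed),
#'   `comparisons` (stage-1 character comparisons) and `skipped`.
#' @examples
#' pairs <- tibble::tibble(pair_id = "p1",
#'                         seq1 = "ACGTTGAGAT", qual1 = "IIIIIIIIII",
#'                         seq2 = "CAACGTAGAT", qual2 = "IIIIIIIIII")
#' trim_pairs(pairs, trimmer_params(L = 4))
#' @export
trim_pairs <- function(pairs, params = trimmer_params()) {
  stopifnot(all(c("seq1", "qual1", "seq2", "qual2") %in% names(pairs)))
  res <- .trim_pairs_cpp(pairs$seq1, pairs$seq2, params$L,
                         params$e1, params$e2, params$e3,
                         params$strict_singleton)
  n_skipped <- sum(res$skipped)
  if (n_skipped > 0) {
    warn(sprintf(
      "%d pair(s) skipped (unequal mate lengths or shorter than L=%d); passed through untrimmed",
      n_skipped, params$L))
  }
  out <- pairs
  cut <- which(res$trimmed)
  if (length(cut) > 0) {
    n <- res$insert_length[cut]
    out$seq1[cut] <- substr(out$seq1[cut], 1L, n)
    out$qual1[cut] <- substr(out$qual1[cut], 1L, n)
    out$seq2[cut] <- substr(out$seq2[cut], 1L, n)
    out$qual2[cut] <- substr(out$qual2[cut], 1L, n)
  }
  out$trimmed <- res$trimmed
  out$insert_length <- res$insert_length
  out$candidates <- res$candidates
  out$validated_candidate <- res$validated_candidate
  out$n_candidates <- lengths(res$candidates)
  out$n_validated <- res$n_validated
  out$comparisons <- res$comparisons
  out$skipped <- res$skipped
  out <- as_tibble(out)
  class(out) <- c("trim_result", class(out))
  attr(out, "params") <- params
  out
}

#' Summarize a trimming run
#'
#' @param x A `trim_result` tibble from [trim_pairs()].
#' @param ... Unused.
#' @return A one-row tibble: pairs processed, trimmed, untrimmed, skipped,
#'   and the trimmed/untrimmed ratio.
#' @importFrom generics glance
#' @export
generics::glance

#' @export
glance.trim_result <- function(x, ...) {
  n_trim <- sum(x$trimmed)
  n_untrim <- sum(!x$trimmed)
  tibble(n_pairs = nrow(x), n_trimmed = n_trim, n_untrimmed = n_untrim,
         n_skipped = sum(x$skipped),
         trimmed_untrimmed_ratio = if (n_untrim > 0) n_trim / n_untrim
                                   else NA_real_)
}

#' Exhaustive reference trimmer (quadratic-time oracle)
#'
#' Independent re-derivation of the trimming decision used to cross-check
#' [trim_pairs()]: for every insert length `n` in `[L, N]` it recomputes the
#' stage-1 criterion directly in both directions (no scanning shortcuts),
#' forms the candidate set, and applies the identical acceptance logic in
#' pure R. It must agree with [trim_pairs()] on every input.
#'
#' @inheritParams trim_pairs
#' @return A tibble with `pair_id` (when present), `trimmed`,
#'   `insert_length`, `candidates` (list-column) and `skipped`.
#' @export
brute_force_trim <- function(pairs, params = trimmer_params()) {
  n_pairs <- nrow(pairs)
  trimmed <- logical(n_pairs)
  insert_length <- rep(NA_integer_, n_pairs)
  skipped <- logical(n_pairs)
  candidates <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    d <- brute_force_one(pairs$seq1[i], pairs$seq2[i], params)
    trimmed[i] <- d$trimmed
    insert_length[i] <- d$insert_length
    skipped[i] <- d$skipped
    candidates[[i]] <- d$candidates
  }
  out <- tibble(trimmed = trimmed, insert_length = insert_length,
                candidates = candidates, skipped = skipped)
  if ("pair_id" %in% names(pairs)) {
    out <- dplyr::bind_cols(tibble(pair_id = pairs$pair_id), out)
  }
  out
}

# Pure-R decision for one pair: character vectors and direct sums only.
brute_force_one <- function(s1, s2, params) {
  L <- params$L
  N <- nchar(s1)
  none <- list(trimmed = FALSE, insert_length = NA_integer_,
               candidates = integer(), skipped = FALSE)
  if (nchar(s2) != N || N < L) {
    none$skipped <- TRUE
    return(none)
  }
  a1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  a2 <- strsplit(s2, "", fixed = TRUE)[[1]]
  comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  q1 <- rev(unname(comp_map[a1[seq_len(L)]]))   # revcomp of r1's L-prefix
  q2 <- rev(unname(comp_map[a2[seq_len(L)]]))
  b1 <- mismatch_budget(L, params$e1)

  mm <- function(x, y) sum(x != y | x == "N" | y == "N")
  cand <- integer()
  for (n in L:N) {
    win <- (n - L + 1L):n
    if (mm(q1, a2[win]) <= b1 && mm(q2, a1[win]) <= b1) {
      cand <- c(cand, n)
    }
  }

  validate <- function(n) {
    dna <- mm(rev(unname(comp_map[a1[seq_len(n)]])), a2[seq_len(n)])
    if (dna > mismatch_budget(n, params$e2)) return(FALSE)
    if (n < N) {
      ad <- mm(a1[(n + 1L):N], a2[(n + 1L):N])
      if (ad > mismatch_budget(N - n, params$e3)) return(FALSE)
    }
    TRUE
  }

  accepted <- NA_integer_
  if (length(cand) == 1L && !params$strict_singleton) {
    accepted <- cand
  } else if (length(cand) >= 1L) {
    for (n in rev(cand)) {
      if (validate(n)) { accepted <- n; break }
    }
  }
  if (!is.na(accepted) && accepted < N) {
    return(list(trimmed = TRUE, insert_length = accepted,
                candidates = cand, skipped = FALSE))
  }
  list(trimmed = FALSE, insert_length = NA_integer_,
       candidates = cand, skipped = FALSE)
}

# floor(len * e) with an epsilon against IEEE products like 10 * 0.3 that
# land a hair below the mathematically integral value.
mismatch_budget <- function(len, e) {
  as.integer(floor(len * e + 1e-9))
}
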