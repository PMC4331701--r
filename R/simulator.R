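#' Built-in adapter sequence pairs
#'
#' `"illumina"` is the standard TruSeq-style forward/reverse adapter pair;
#' `"distinct"` is a deliberately unrelated pair used to benchmark libraries
#' whose 5' and 3' adapters differ in sequence (the case where the
#' adapter-equality check must be disabled with `e3 = 1`).
#'
#' @param name `"illumina"` or `"distinct"`, or omit both in favour of
#'   `forward`/`reverse` to supply custom sequences.
#' @param forward,reverse Custom adapter sequences (alphabet `{A,C,G,T}`).
#' @return A list of class `adapter_set` with fields `forward`, `reverse`,
#'   `name`.
#' @export
adapter_set <- function(name = c("illumina", "distinct"),
                        forward = NULL, reverse = NULL) {
  if (!is.null(forward) || !is.null(reverse)) {
    stopifnot(is.character(forward), is.character(reverse),
              nchar(forward) > 0, nchar(reverse) > 0,
              !grepl("[^ACGT]", forward), !grepl("[^ACGT]", reverse))
    label <- if (is.character(name) && length(name) == 1 &&
                 !name[1] %in% c("illumina", "distinct")) name else "custom"
    return(structure(list(forward = forward, reverse = reverse,
                          name = label), class = "adapter_set"))
  }
  name <- match.arg(name)
  seqs <- switch(name,
    illumina = list(
      forward = "AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAGACCGATCTCGTATGCCGTCTTCTGCTTG",
      reverse = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTAGATCTCGGTGGTCGCCGTATCATT"),
    distinct = list(
      forward = "CTAGAGTCAGTCCGGTTAATCCGGATCAGTCGTAGGAATCCAAAAGGTCCGTACGTACCTT",
      reverse = "ATGGGCCCCTTTTAGTCAGTCAGTGGTTGGCCCTTTAAAATTTTCTCTTGAAGTCCCC"))
  structure(c(seqs, list(name = name)), class = "adapter_set")
}

#' Simulation parameters for benchmark dataset generation
#'
#' Describes one benchmark condition: fixed-length mates, a set fraction of
#' pairs carrying appended adapter (read-through contamination) with adapter
#' length drawn from a Gaussian, per-base substitution errors driven by
#' simulated Phred qualities, and an overall error-rate multiplier.
#'
#' @param n_pairs Number of read pairs.
#' @param read_length Length of every mate in bases (default 101).
#' @param contaminated_fraction Fraction of pairs that are adapter-appended
#'   (default 0.5); the contaminated count is exactly
#'   `round(n_pairs * contaminated_fraction)`.
#' @param adapter_mu,adapter_sigma Mean and SD of the Gaussian adapter
#'   length (defaults 20 and 5); draws are rounded and clamped to
#'   `[1, min(read_length - 1, adapter sequence length)]`.
#' @param error_scale Multiplier on every per-base error probability
#'   (default 1; use `10^-0.5` / `10^0.5` for low/high-error conditions,
#'   0 for error-free data). Effective probabilities are capped at 1.
#' @param adapters An [adapter_set()].
#' @param overlap_mode When `TRUE`, clean pairs are built from a single
#'   fragment of `clean_fragment_length` bases so the mates overlap
#'   (default fragment `2 * read_length - 50`, i.e. a 50-base overlap);
#'   when `FALSE`, clean mates come from two independent windows.
#' @param clean_fragment_length Fragment length for overlap-mode clean
#'   pairs.
#' @param quality_model A `quality_model`, or `NULL` for the default
#'   [quality_model_parametric()] profile.
#' @param reference A reference nucleotide string to sample windows from,
#'   a path to a FASTA file, or `NULL` to generate a uniform-random
#'   synthetic reference of `reference_length` bases.
#' @param reference_length Length of the synthetic reference.
#' @param seed RNG seed for reproducible generation (`NULL` leaves the RNG
#'   state alone).
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(n_pairs = 10000L, read_length = 101L,
                              contaminated_fraction = 0.5,
                              adapter_mu = 20, adapter_sigma = 5,
                              error_scale = 1,
                              adapters = adapter_set("illumina"),
                              overlap_mode = FALSE,
                              clean_fragment_length = 2L * read_length - 50L,
                              quality_model = NULL,
                              reference = NULL,
                              reference_length = 200000L,
                              seed = NULL) {
  stopifnot(n_pairs >= 0, read_length >= 2,
            contaminated_fraction >= 0, contaminated_fraction <= 1,
            adapter_mu > 0, adapter_sigma > 0, error_scale >= 0,
            inherits(adapters, "adapter_set"),
            clean_fragment_length >= read_length)
  if (is.null(quality_model)) {
    quality_model <- quality_model_parametric(read_length)
  }
  stopifnot(quality_model$read_length == read_length)
  structure(list(
    n_pairs = as.integer(n_pairs), read_length = as.integer(read_length),
    contaminated_fraction = contaminated_fraction,
    adapter_mu = adapter_mu, adapter_sigma = adapter_sigma,
    error_scale = error_scale, adapters = adapters,
    overlap_mode = isTRUE(overlap_mode),
    clean_fragment_length = as.integer(clean_fragment_length),
    quality_model = quality_model, reference = reference,
    reference_length = as.integer(reference_length), seed = seed),
    class = "simulation_params")
}

#' Benchmark condition presets
#'
#' Eight standard conditions: low / middle / high error rate (`LED`, `MED`,
#' `HED`; error scales `10^-0.5`, 1, `10^0.5`) with the Illumina adapter
#' pair; the same three with the distinct adapter pair (`dLED`, `dMED`,
#' `dHED`); and overlap variants (`MED-o`, `dMED-o`) whose clean pairs
#' share a 50-base mate overlap.
#'
#' @param preset Preset name.
#' @param ... Overrides passed to [simulation_params()] (e.g. `n_pairs`,
#'   `seed`).
#' @return A `simulation_params` object.
#' @export
preset_params <- function(preset = c("LED", "MED", "HED", "dLED", "dMED",
                                     "dHED", "MED-o", "dMED-o"), ...) {
  preset <- match.arg(preset)
  distinct <- startsWith(preset, "d")
  core <- sub("-o$", "", sub("^d", "", preset))
  scale <- switch(core, LED = 10^-0.5, MED = 1, HED = 10^0.5)
  simulation_params(
    error_scale = scale,
    adapters = adapter_set(if (distinct) "distinct" else "illumina"),
    overlap_mode = endsWith(preset, "-o"),
    ...)
}

#' Generate or load a reference sequence
#'
#' With no FASTA, returns a uniform-random string over `{A,C,G,T}`. With a
#' FASTA path, concatenates its contigs separated by single `N` characters
#' (so sampled windows never span a contig boundary); window sampling later
#' rejects any window containing `N`.
#'
#' @param length Length of the synthetic reference (ignored when `fasta`
#'   is given).
#' @param fasta Optional path to a FASTA file.
#' @return A single nucleotide string.
#' @export
generate_reference <- function(length = 200000L, fasta = NULL) {
  if (!is.null(fasta)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("reading a FASTA reference requires the Biostrings package")
    }
    contigs <- as.character(Biostrings::readDNAStringSet(fasta))
    if (length(contigs) == 0) abort(sprintf("no sequences in '%s'", fasta))
    return(toupper(paste(contigs, collapse = "N")))
  }
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
        collapse = "")
}

#' Sample appended adapter lengths
#'
#' Draws from `Normal(mu, sigma)`, rounds to the nearest integer, and
#' clamps into `[1, min(read_length - 1, adapter_len)]`: an appended
#' adapter is at least one base, cannot fill the whole read, and cannot be
#' longer than the adapter sequence it is cropped from.
#'
#' @param n Number of draws.
#' @param mu,sigma Gaussian mean and SD (defaults 20, 5).
#' @param read_length Read length in bases.
#' @param adapter_len Length of the adapter sequence being cropped.
#' @return Integer vector of adapter lengths.
#' @export
sample_adapter_length <- function(n, mu = 20, sigma = 5,
                                  read_length = 101L, adapter_len = 58L) {
  raw <- round(rnorm(n, mu, sigma))
  upper <- min(read_length - 1L, adapter_len)
  as.integer(pmin(pmax(raw, 1), upper))
}

#' Apply quality-driven substitution errors to sequences
#'
#' Each base mutates independently with probability
#' `min(1, error_prob * error_scale)`; a mutated base is replaced by one of
#' the three other bases, uniformly. No indels are introduced.
#'
#' @param seqs Character vector of equal-length nucleotide sequences.
#' @param error_probs Numeric matrix of per-base error probabilities,
#'   `length(seqs)` rows by sequence-length columns.
#' @param error_scale Multiplier on the probabilities (capped at 1).
#' @return A list: `sequences` (mutated), `positions` (list of integer
#'   vectors of mutated positions per sequence), `n_mutations` (integer
#'   vector).
#' @export
mutate_sequences <- function(seqs, error_probs, error_scale = 1) {
  n <- length(seqs)
  if (n == 0L) {
    return(list(sequences = character(), positions = list(),
                n_mutations = integer()))
  }
  len <- nchar(seqs[1])
  stopifnot(all(nchar(seqs) == len),
            is.matrix(error_probs), nrow(error_probs) == n,
            ncol(error_probs) == len)
  p <- pmin(1, error_probs * error_scale)
  u <- matrix(runif(n * len), nrow = n)
  hit <- which(u < p)                      # column-major flat indices
  rows <- (hit - 1L) %% n + 1L
  cols <- (hit - 1L) %/% n + 1L

  out <- seqs
  if (length(hit) > 0) {
    ord <- order(rows, cols)
    rows <- rows[ord]; cols <- cols[ord]
    old <- substring(out[rows], cols, cols)
    # uniformly one of the three bases differing from the original
    alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                  nrow = 3,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    pick <- sample.int(3L, length(hit), replace = TRUE)
    new <- alt[cbind(pick, match(old, colnames(alt)))]
    # N (no entry in alt) stays N: drop those events
    keep <- !is.na(new)
    rows <- rows[keep]; cols <- cols[keep]; new <- new[keep]
    for (k in seq_along(rows)) {
      substr(out[rows[k]], cols[k], cols[k]) <- new[k]
    }
  }
  positions <- unname(split(cols, factor(rows, levels = seq_len(n))))
  list(sequences = out, positions = positions,
       n_mutations = lengths(positions))
}

#' Simulate read pairs with ground truth
#'
#' Generates `length(contaminated)` pairs against a reference. A
#' contaminated pair is built from one reference window of the true insert
#' length `read_length - A` (A drawn per [sample_adapter_length()]): mate 1
#' is the window followed by the first A bases of the forward adapter, mate
#' 2 is the window's reverse complement followed by the first A bases of
#' the reverse adapter. A clean pair uses two independent read-length
#' windows, or, in overlap mode, the two ends of a single
#' `clean_fragment_length` window. Qualities are sampled from the quality
#' model and substitution errors applied per base with probability
#' `min(1, 10^(-Q/10) * error_scale)`.
#'
#' @param params A [simulation_params()] object.
#' @param contaminated Logical vector: which pairs carry adapter.
#' @param reference Reference string (defaults to the one named in
#'   `params`, generated on the fly if `NULL`).
#' @param first_id Integer identifier of the first pair; pairs are numbered
#'   sequentially.
#' @return A list of two tibbles: `pairs` (`pair_id`, `id1`, `seq1`,
#'   `qual1`, `id2`, `seq2`, `qual2`) and `truth` (`pair_id`,
#'   `contaminated`, `insert_length`, `mut_dna_r1`, `mut_adapter_r1`,
#'   `mut_dna_r2`, `mut_adapter_r2`). For a contaminated pair
#'   `insert_length` is the true trimming site; for clean pairs it is the
#'   fragment length (`read_length` for independent windows, the overlap
#'   fragment length in overlap mode).
#' @export
simulate_pairs <- function(params, contaminated, reference = NULL,
                           first_id = 1L) {
  n <- length(contaminated)
  R <- params$read_length
  if (is.null(reference)) reference <- resolve_reference(params)
  ref_len <- nchar(reference)
  stopifnot(ref_len >= max(2L * R, params$clean_fragment_length))

  ids <- as.character(seq.int(first_id, length.out = n))
  seq1 <- character(n); seq2 <- character(n)
  insert <- integer(n)
  A <- integer(n)

  idx_c <- which(contaminated)
  idx_f <- which(!contaminated)
  adapter_cap <- min(nchar(params$adapters$forward),
                     nchar(params$adapters$reverse))

  if (length(idx_c) > 0) {
    A[idx_c] <- sample_adapter_length(length(idx_c), params$adapter_mu,
                                      params$adapter_sigma, R, adapter_cap)
    t <- R - A[idx_c]
    frag <- draw_windows(reference, t)
    seq1[idx_c] <- paste0(frag,
                          substr(rep(params$adapters$forward, length(idx_c)),
                                 1L, A[idx_c]))
    seq2[idx_c] <- paste0(reverse_complement(frag),
                          substr(rep(params$adapters$reverse, length(idx_c)),
                                 1L, A[idx_c]))
    insert[idx_c] <- t
  }
  if (length(idx_f) > 0) {
    if (params$overlap_mode) {
      Fl <- params$clean_fragment_length
      frag <- draw_windows(reference, rep(Fl, length(idx_f)))
      seq1[idx_f] <- substr(frag, 1L, R)
      seq2[idx_f] <- reverse_complement(substr(frag, Fl - R + 1L, Fl))
      insert[idx_f] <- Fl
    } else {
      w1 <- draw_windows(reference, rep(R, length(idx_f)))
      w2 <- draw_windows(reference, rep(R, length(idx_f)))
      seq1[idx_f] <- w1
      seq2[idx_f] <- reverse_complement(w2)
      insert[idx_f] <- R
    }
  }

  q1 <- sample_quality_matrix(params$quality_model, n)
  q2 <- sample_quality_matrix(params$quality_model, n)
  m1 <- mutate_sequences(seq1, 10^(-q1 / 10), params$error_scale)
  m2 <- mutate_sequences(seq2, 10^(-q2 / 10), params$error_scale)

  # split mutation counts at the true junction (whole read is DNA for
  # clean pairs: insert >= R there)
  dna_end <- pmin(insert, R)
  count_split <- function(positions, end) {
    in_dna <- mapply(function(p, e) sum(p <= e), positions, end)
    list(dna = as.integer(in_dna),
         adapter = lengths(positions) - as.integer(in_dna))
  }
  s1 <- count_split(m1$positions, dna_end)
  s2 <- count_split(m2$positions, dna_end)

  pairs <- tibble(
    pair_id = ids,
    id1 = paste0(ids, "/1"), seq1 = m1$sequences,
    qual1 = raw_to_strings(as.raw(t(q1) + 33L), R, n),
    id2 = paste0(ids, "/2"), seq2 = m2$sequences,
    qual2 = raw_to_strings(as.raw(t(q2) + 33L), R, n))
  truth <- tibble(
    pair_id = ids, contaminated = contaminated,
    insert_length = insert,
    mut_dna_r1 = s1$dna, mut_adapter_r1 = s1$adapter,
    mut_dna_r2 = s2$dna, mut_adapter_r2 = s2$adapter)
  list(pairs = pairs, truth = truth)
}

resolve_reference <- function(params) {
  ref <- params$reference
  if (is.null(ref)) {
    generate_reference(params$reference_length)
  } else if (file.exists(ref)) {
    generate_reference(fasta = ref)
  } else {
    toupper(ref)
  }
}

# Sample one window of each requested length; windows containing N (contig
# separators in FASTA-derived references) are redrawn.
draw_windows <- function(reference, lens, max_tries = 50L) {
  ref_len <- nchar(reference)
  starts <- 1L + floor(runif(length(lens)) * (ref_len - lens + 1L))
  out <- substring(reference, starts, starts + lens - 1L)
  bad <- grepl("N", out, fixed = TRUE)
  tries <- 0L
  while (any(bad)) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort("reference has no N-free window of the required size")
    }
    k <- which(bad)
    starts <- 1L + floor(runif(length(k)) * (ref_len - lens[k] + 1L))
    out[k] <- substring(reference, starts, starts + lens[k] - 1L)
    bad[k] <- grepl("N", out[k], fixed = TRUE)
  }
  out
}

#' Generate a benchmark dataset on disk
#'
#' Writes paired FASTQ files and a tab-separated truth table for
#' `params$n_pairs` pairs, exactly
#' `round(n_pairs * contaminated_fraction)` of them adapter-appended, in
#' shuffled order with sequential numeric identifiers. Fully reproducible
#' from `params$seed`. Generation is chunked so memory stays bounded.
#'
#' @param params A [simulation_params()] object.
#' @param out_r1,out_r2 Output FASTQ paths (gzip when ending in `.gz`).
#' @param out_truth Output truth TSV path.
#' @param chunk_size Pairs generated per chunk.
#' @return A one-row summary tibble: `n_pairs`, `n_contaminated`,
#'   `n_clean`, `mean_adapter_length`, `total_mutations`.
#' @export
simulate_dataset <- function(params, out_r1, out_r2, out_truth,
                             chunk_size = 10000L) {
  if (!is.null(params$seed)) set.seed(params$seed)
  reference <- resolve_reference(params)
  n <- params$n_pairs
  n_cont <- as.integer(round(n * params$contaminated_fraction))
  status <- sample(c(rep(TRUE, n_cont), rep(FALSE, n - n_cont)))

  con1 <- if (grepl("\\.gz$", out_r1)) gzfile(out_r1, "wt")
          else file(out_r1, "wt")
  con2 <- if (grepl("\\.gz$", out_r2)) gzfile(out_r2, "wt")
          else file(out_r2, "wt")
  on.exit({ close(con1); close(con2) }, add = TRUE)

  truth_chunks <- list()
  done <- 0L
  while (done < n || (n == 0L && done == 0L)) {
    take <- min(chunk_size, n - done)
    if (take > 0L) {
      res <- simulate_pairs(params, status[done + seq_len(take)],
                            reference, first_id = done + 1L)
      writeLines(as.vector(rbind(paste0("@", res$pairs$id1),
                                 res$pairs$seq1, "+", res$pairs$qual1)),
                 con1)
      writeLines(as.vector(rbind(paste0("@", res$pairs$id2),
                                 res$pairs$seq2, "+", res$pairs$qual2)),
                 con2)
      truth_chunks[[length(truth_chunks) + 1L]] <- res$truth
    }
    done <- done + take
    if (n == 0L) break
  }
  truth <- if (length(truth_chunks) > 0) dplyr::bind_rows(truth_chunks)
           else tibble(pair_id = character(), contaminated = logical(),
                       insert_length = integer(), mut_dna_r1 = integer(),
                       mut_adapter_r1 = integer(), mut_dna_r2 = integer(),
                       mut_adapter_r2 = integer())
  write_truth(truth, out_truth)

  adapters <- params$read_length - truth$insert_length[truth$contaminated]
  tibble(n_pairs = n, n_contaminated = n_cont, n_clean = n - n_cont,
         mean_adapter_length = if (n_cont > 0) mean(adapters) else NA_real_,
         total_mutations = sum(truth$mut_dna_r1 + truth$mut_adapter_r1 +
                               truth$mut_dna_r2 + truth$mut_adapter_r2))
}

write_truth <- function(truth, path) {
  out <- truth
  out$contaminated <- as.integer(out$contaminated)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth table written by [simulate_dataset()]
#'
#' @param path Path to the truth TSV.
#' @return A tibble with `contaminated` as logical.
#' @export
read_truth <- function(path) {
  tbl <- read.delim(path, sep = "\t",
                    colClasses = c(pair_id = "character"))
  tbl$contaminated <- tbl$contaminated == 1L
  as_tibble(tbl)
}
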