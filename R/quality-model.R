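#' Per-position Phred quality model
#'
#' A quality model assigns each read position a discrete distribution over
#' Phred scores, from which simulated quality strings (and hence per-base
#' error probabilities) are drawn. Two constructors exist:
#' [quality_model_parametric()] builds an idealized Illumina-like profile
#' whose mean quality declines from the 5' to the 3' end;
#' [learn_quality_model()] tabulates the empirical per-position distribution
#' of a real FASTQ file.
#'
#' @name quality_model
#' @keywords internal
NULL

new_quality_model <- function(probs, q_values, source) {
  stopifnot(ncol(probs) == length(q_values),
            all(abs(rowSums(probs) - 1) < 1e-8))
  structure(list(probs = probs, q_values = as.integer(q_values),
                 read_length = nrow(probs), source = source),
            class = "quality_model")
}

#' @export
print.quality_model <- function(x, ...) {
  mq <- as.vector(x$probs %*% x$q_values)
  cat(sprintf(
    "<quality_model> %s, %d positions, mean Q %.1f (5') -> %.1f (3')\n",
    x$source, x$read_length, mq[1], mq[x$read_length]))
  invisible(x)
}

#' Parametric Illumina-like quality profile
#'
#' Mean Phred score declines linearly from `q_start` at the first position
#' to `q_end` at the last — the usual 3'-ward degradation of Illumina base
#' calls — with Gaussian dispersion `q_sd` around the mean, discretized to
#' integer scores and truncated to `[q_min, q_max]`.
#'
#' @param read_length Number of positions the model covers.
#' @param q_start,q_end Mean Phred score at the first and last position
#'   (defaults 38 and 20, i.e. error rates 1.6e-4 to 1e-2).
#' @param q_sd Per-position standard deviation of the score (default 3).
#' @param q_min,q_max Score truncation bounds (defaults 2 and 40).
#' @return A `quality_model`.
#' @export
quality_model_parametric <- function(read_length = 101L, q_start = 38,
                                     q_end = 20, q_sd = 3,
                                     q_min = 2L, q_max = 40L) {
  stopifnot(read_length >= 1, q_sd > 0, q_min <= q_max)
  means <- seq(q_start, q_end, length.out = read_length)
  q_values <- q_min:q_max
  # P(Q = q) for integer q: mass of N(mean, sd) on [q - .5, q + .5],
  # renormalized over the truncated support.
  probs <- t(vapply(means, function(m) {
    p <- stats::pnorm(q_values + 0.5, m, q_sd) -
         stats::pnorm(q_values - 0.5, m, q_sd)
    p / sum(p)
  }, numeric(length(q_values))))
  new_quality_model(probs, q_values, "parametric")
}

#' Learn an empirical quality model from a FASTQ file
#'
#' Tabulates the per-position distribution of observed Phred scores. All
#' reads must share one length; variable-length input is a fatal error
#' (consider the parametric model instead).
#'
#' @param fastq_path Path to a FASTQ file (plain or gzip).
#' @param offset Phred encoding offset (default 33).
#' @return A `quality_model`.
#' @export
learn_quality_model <- function(fastq_path, offset = 33L) {
  con <- open_fastq_connection(fastq_path, "r")
  on.exit(close(con), add = TRUE)
  counts <- NULL
  read_length <- NULL
  offset_rec <- 0L
  repeat {
    block <- read_fastq_block(con, fastq_path, offset_rec, 10000L)
    n <- length(block$qual)
    if (n == 0L) break
    offset_rec <- offset_rec + n
    lens <- nchar(block$qual)
    if (is.null(read_length)) read_length <- lens[1]
    if (any(lens != read_length)) {
      abort(paste0(
        "reads in '", fastq_path, "' have variable lengths; ",
        "an empirical per-position model needs a constant read length ",
        "(use quality_model_parametric() instead)"))
    }
    q <- matrix(utf8ToInt(paste0(block$qual, collapse = "")) -
                  as.integer(offset),
                nrow = read_length)           # positions x reads
    if (is.null(counts)) counts <- matrix(0, read_length, 94L)
    for (pos in seq_len(read_length)) {
      tab <- tabulate(q[pos, ] + 1L, nbins = 94L)
      counts[pos, ] <- counts[pos, ] + tab
    }
  }
  if (is.null(counts)) abort(sprintf("no records in '%s'", fastq_path))
  used <- which(colSums(counts) > 0)
  probs <- counts[, used, drop = FALSE] / rowSums(counts)
  new_quality_model(probs, used - 1L, "empirical")
}

#' Sample quality strings from a model
#'
#' Each position of each string is drawn independently from the model's
#' distribution for that position.
#'
#' @param model A `quality_model`.
#' @param n Number of strings to draw.
#' @param offset Phred encoding offset for the returned characters.
#' @return Character vector of `n` quality strings of length
#'   `model$read_length`.
#' @export
sample_quality_strings <- function(model, n, offset = 33L) {
  q <- sample_quality_matrix(model, n)
  raw_to_strings(as.raw(t(q) + as.integer(offset)), model$read_length, n)
}

# Integer matrix of Phred scores, n rows x read_length columns.
sample_quality_matrix <- function(model, n) {
  rl <- model$read_length
  q <- matrix(0L, nrow = n, ncol = rl)
  if (n == 0L) return(q)
  qv <- model$q_values
  for (pos in seq_len(rl)) {
    # sample() would treat a length-1 qv as 1:qv
    q[, pos] <- qv[sample.int(length(qv), n, replace = TRUE,
                              prob = model$probs[pos, ])]
  }
  q
}

# Split a raw vector laid out read-major into n strings of length len.
raw_to_strings <- function(bytes, len, n) {
  if (n == 0L) return(character())
  big <- rawToChar(bytes)
  starts <- seq.int(1L, by = len, length.out = n)
  substring(big, starts, starts + len - 1L)
}
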