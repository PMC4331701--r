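#' Read a pair of FASTQ files into a tibble of read pairs
#'
#' Reads two synchronized FASTQ files (plain or gzip; compression is detected
#' from the file content) and pairs records positionally: record i of the
#' first file with record i of the second. Identifiers are checked for pair
#' identity (equal after stripping a trailing `/1`, `/2` or mate-number
#' token); a mismatch only warns, because positional pairing is the
#' convention for synchronized paired FASTQ.
#'
#' Sequences are upper-cased on read and must use the alphabet
#' `{A,C,G,T,N}`; any other character, a missing `@`/`+` line, or a quality
#' line whose length differs from its sequence line is a fatal parse error
#' naming the file and record index. Unequal record counts between the two
#' files are fatal.
#'
#' @param path_r1,path_r2 Paths to the forward- and reverse-mate FASTQ files.
#' @param check_ids Warn when mate identifiers do not share a pair identity.
#' @return A tibble with one row per pair: `pair_id`, `id1`, `seq1`, `qual1`,
#'   `id2`, `seq2`, `qual2`.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@p1/1", "ACGT", "+", "IIII"), fq)
#' read_paired_fastq(fq, fq)
#' @export
read_paired_fastq <- function(path_r1, path_r2, check_ids = TRUE) {
  chunks <- list()
  fastq_pair_chunks(path_r1, path_r2, function(tbl, idx) {
    chunks[[idx]] <<- tbl
  }, chunk_size = 100000L, check_ids = check_ids)
  if (length(chunks) == 0) {
    return(tibble(pair_id = character(), id1 = character(),
                  seq1 = character(), qual1 = character(),
                  id2 = character(), seq2 = character(),
                  qual2 = character()))
  }
  dplyr::bind_rows(chunks)
}

#' Stream a pair of FASTQ files in bounded-memory chunks
#'
#' Applies `f` to successive chunks of read pairs, holding at most
#' `chunk_size` pairs in memory at a time. This is the streaming primitive
#' behind [read_paired_fastq()]; use it directly to process files larger
#' than memory (for example a record-count-only pass).
#'
#' @inheritParams read_paired_fastq
#' @param f Function of `(pairs_tibble, chunk_index)` called per chunk.
#' @param chunk_size Maximum pairs per chunk.
#' @return (Invisibly) the total number of pairs processed.
#' @export
fastq_pair_chunks <- function(path_r1, path_r2, f, chunk_size = 10000L,
                              check_ids = TRUE) {
  con1 <- open_fastq_connection(path_r1, "r")
  con2 <- open_fastq_connection(path_r2, "r")
  on.exit({ close(con1); close(con2) }, add = TRUE)
  total <- 0L
  idx <- 0L
  id_warned <- FALSE
  repeat {
    b1 <- read_fastq_block(con1, path_r1, total, chunk_size)
    b2 <- read_fastq_block(con2, path_r2, total, chunk_size)
    n1 <- length(b1$id); n2 <- length(b2$id)
    if (n1 != n2) {
      short <- if (n1 < n2) path_r1 else path_r2
      abort(sprintf(
        "paired FASTQ files have unequal record counts: '%s' ended after record %d",
        short, total + min(n1, n2)))
    }
    if (n1 == 0L) break
    pid1 <- pair_identity(b1$id)
    if (check_ids && !id_warned) {
      bad <- which(pid1 != pair_identity(b2$id))
      if (length(bad) > 0) {
        warn(sprintf(
          "mate identifiers disagree at record %d ('%s' vs '%s'); pairing positionally",
          total + bad[1], b1$id[bad[1]], b2$id[bad[1]]))
        id_warned <- TRUE
      }
    }
    idx <- idx + 1L
    f(tibble(pair_id = pid1,
             id1 = b1$id, seq1 = b1$seq, qual1 = b1$qual,
             id2 = b2$id, seq2 = b2$seq, qual2 = b2$qual),
      idx)
    total <- total + n1
    if (n1 < chunk_size) break
  }
  invisible(total)
}

# gzfile() reads both gzip-compressed and plain text, keying on the magic
# bytes, which is exactly the transparent behaviour wanted here.
open_fastq_connection <- function(path, mode) {
  if (mode == "r" && !file.exists(path)) {
    abort(sprintf("FASTQ file not found: '%s'", path))
  }
  gzfile(path, open = if (mode == "r") "rt" else "wt")
}

# Read up to `n_max` 4-line records from an open connection, validating each.
# `offset` is the number of records already consumed (for error messages).
read_fastq_block <- function(con, path, offset, n_max) {
  lines <- readLines(con, n = 4L * n_max)
  n_lines <- length(lines)
  if (n_lines == 0L) return(list(id = character(), seq = character(),
                                 qual = character()))
  if (n_lines %% 4L != 0L) {
    abort(sprintf("truncated FASTQ record %d in '%s' (%d trailing lines)",
                  offset + n_lines %/% 4L + 1L, path, n_lines %% 4L))
  }
  n <- n_lines %/% 4L
  hdr <- lines[seq(1L, n_lines, by = 4L)]
  seq <- toupper(lines[seq(2L, n_lines, by = 4L)])
  plus <- lines[seq(3L, n_lines, by = 4L)]
  qual <- lines[seq(4L, n_lines, by = 4L)]

  bad <- which(substr(hdr, 1L, 1L) != "@" | substr(plus, 1L, 1L) != "+")
  if (length(bad) > 0) {
    abort(sprintf("malformed FASTQ record %d in '%s': missing '@' or '+' line",
                  offset + bad[1], path))
  }
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed FASTQ record %d in '%s': sequence length %d != quality length %d",
      offset + bad[1], path, nchar(seq[bad[1]]), nchar(qual[bad[1]])))
  }
  bad <- which(grepl("[^ACGTN]", seq))
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed FASTQ record %d in '%s': sequence contains characters outside {A,C,G,T,N}",
      offset + bad[1], path))
  }
  list(id = sub("^@", "", hdr), seq = seq, qual = qual)
}

# Shared pair identity: the token before the first whitespace, with a
# trailing /1, /2, .1, .2, _1 or _2 mate marker stripped.
pair_identity <- function(ids) {
  ids <- sub("\\s.*$", "", ids)
  sub("[/._][12]$", "", ids)
}

#' Write a tibble of read pairs as two FASTQ files
#'
#' Writes standard 4-line FASTQ records in row order; output is
#' gzip-compressed when a path ends in `.gz`. Reading a file written by this
#' function reproduces the input pairs exactly.
#'
#' @param pairs A tibble with columns `id1`, `seq1`, `qual1`, `id2`, `seq2`,
#'   `qual2` (as produced by [read_paired_fastq()] or [trim_pairs()]).
#' @param path_r1,path_r2 Output paths for the forward and reverse mates.
#' @return (Invisibly) the number of pairs written.
#' @export
write_paired_fastq <- function(pairs, path_r1, path_r2) {
  write_one_fastq(pairs$id1, pairs$seq1, pairs$qual1, path_r1)
  write_one_fastq(pairs$id2, pairs$seq2, pairs$qual2, path_r2)
  invisible(nrow(pairs))
}

write_one_fastq <- function(ids, seqs, quals, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  if (length(ids) > 0) {
    rec <- rbind(paste0("@", ids), seqs, "+", quals)
    writeLines(as.vector(rec), con)
  }
  invisible(length(ids))
}

#' Convert Phred quality characters to error probabilities
#'
#' A Phred score Q encodes a base-call error probability of `10^(-Q/10)`;
#' in FASTQ the score is stored as the character with ordinal `Q + offset`
#' (offset 33 for modern Illumina data).
#'
#' @param q_char Character vector of single quality characters.
#' @param offset Encoding offset (default 33).
#' @return Numeric vector of error probabilities in \[0, 1\].
#' @examples
#' phred_to_error_prob(c("!", "+", "I")) # Q0, Q10, Q40
#' @export
phred_to_error_prob <- function(q_char, offset = 33L) {
  q <- decode_quality(paste0(q_char, collapse = ""), offset)
  10^(-q / 10)
}

#' Decode a quality string to integer Phred scores
#'
#' @param qual A quality string (one character per base).
#' @inheritParams phred_to_error_prob
#' @return Integer vector of Phred scores.
#' @export
decode_quality <- function(qual, offset = 33L) {
  ord <- utf8ToInt(qual)
  if (any(ord < offset)) {
    abort(sprintf(
      "quality character '%s' is below the Phred+%d offset; wrong encoding?",
      intToUtf8(min(ord)), offset))
  }
  ord - as.integer(offset)
}

encode_quality <- function(q, offset = 33L) {
  intToUtf8(q + offset)
}

#' Write a per-pair trimming report
#'
#' Emits a tab-separated file with one row per pair and columns `pair_id`,
#' `trimmed` (0/1), `insert_length` (empty when untrimmed),
#' `n_candidates_stage1` (size of the stage-1 intersection) and
#' `n_candidates_validated` (stage-2 validations performed).
#'
#' @param decisions A tibble from [trim_pairs()].
#' @param path Output path.
#' @return (Invisibly) `path`.
#' @export
write_trim_report <- function(decisions, path) {
  out <- data.frame(
    pair_id = decisions$pair_id,
    trimmed = as.integer(decisions$trimmed),
    insert_length = ifelse(decisions$trimmed,
                           as.character(decisions$insert_length), ""),
    n_candidates_stage1 = decisions$n_candidates,
    n_candidates_validated = decisions$n_validated)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trimming report written by [write_trim_report()]
#'
#' @param path Path to the TSV report.
#' @return A tibble with `trimmed` as logical and `insert_length` as integer
#'   (`NA` when untrimmed).
#' @export
read_trim_report <- function(path) {
  tbl <- read.delim(path, sep = "\t", colClasses = c(
    pair_id = "character", trimmed = "integer", insert_length = "integer",
    n_candidates_stage1 = "integer", n_candidates_validated = "integer"))
  tbl$trimmed <- tbl$trimmed == 1L
  as_tibble(tbl)
}
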