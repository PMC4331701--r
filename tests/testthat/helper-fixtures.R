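# Shared fixture builders: everything is generated in code at test time.

random_seq <- function(len, n = 1L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# A pairs tibble from raw sequences; qualities default to uniform Q40.
pair_tbl <- function(seq1, seq2, qual1 = NULL, qual2 = NULL,
                     pair_id = paste0("p", seq_along(seq1))) {
  q40 <- function(s) strrep("I", nchar(s))
  tibble::tibble(
    pair_id = pair_id,
    id1 = paste0(pair_id, "/1"), seq1 = seq1,
    qual1 = if (is.null(qual1)) q40(seq1) else qual1,
    id2 = paste0(pair_id, "/2"), seq2 = seq2,
    qual2 = if (is.null(qual2)) q40(seq2) else qual2)
}

# Error-free adapter-appended pair built from first principles: mates share
# a reverse-complementary insert and carry adapter prefixes. Adapters are
# tiled when the requested length exceeds the adapter sequence, so any
# insert length down to 0 can be constructed.
contaminated_pair <- function(insert_len, adapter_len,
                              adapters = adapter_set("illumina")) {
  tile <- function(a) substr(strrep(a, ceiling(adapter_len / nchar(a))),
                             1, adapter_len)
  frag <- random_seq(insert_len)
  seq1 <- paste0(frag, tile(adapters$forward))
  seq2 <- paste0(reverse_complement(frag), tile(adapters$reverse))
  pair_tbl(seq1, seq2)
}

write_fastq_file <- function(ids, seqs, quals, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con)
  path
}

# Small simulated dataset returned in memory with its truth table.
sim_in_memory <- function(params) {
  set.seed(params$seed)
  ref <- generate_reference(params$reference_length)
  n_cont <- round(params$n_pairs * params$contaminated_fraction)
  status <- sample(c(rep(TRUE, n_cont),
                     rep(FALSE, params$n_pairs - n_cont)))
  simulate_pairs(params, status, ref)
}
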