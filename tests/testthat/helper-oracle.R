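# Independent pure-R brute-force read placer used as the alignment oracle.
# Enumerates every admissible (mature, offset5, tail length) decomposition
# directly on character vectors and picks the minimum of
# (n_subst, tail_len, |offset5| + |offset3|), ties by |offset5|, mature id,
# offset5, offset3 — deliberately a separate code path from the package's
# aligner.
oracle_align <- function(read, ref, params = align_params()) {
  rd <- strsplit(read, "")[[1]]
  L <- length(rd)
  cand <- list()
  mt <- ref$matures
  for (i in seq_len(nrow(mt))) {
    m <- mt[i, ]
    hp <- strsplit(ref$hairpins[[m$hairpin_id]], "")[[1]]
    for (off5 in -params$max_shift5:params$max_shift5) {
      p0 <- m$start + off5
      if (p0 < 0) next
      for (t in 0:min(params$max_tail, L - 1L)) {
        Tlen <- L - t
        if (p0 + Tlen > length(hp)) next
        off3 <- p0 + Tlen - m$end
        if (abs(off3) > params$max_shift3) next
        mm <- sum(rd[seq_len(Tlen)] != hp[p0 + seq_len(Tlen)])
        if (mm > params$max_mismatch) next
        cand[[length(cand) + 1L]] <- data.frame(
          mature_id = m$mature_id, offset5 = off5, offset3 = off3,
          n_subst = mm, tail_len = t,
          nta_tail = if (t > 0) paste(rd[(Tlen + 1L):L], collapse = "")
                     else "",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) return(NULL)
  cand <- do.call(rbind, cand)
  o <- with(cand, order(n_subst, tail_len, abs(offset5) + abs(offset3),
                        abs(offset5), mature_id, offset5, offset3))
  cand[o[1L], , drop = FALSE]
}

# Small fixed reference used across tests: two hairpins, two matures.
toy_reference <- function() {
  hp1 <- paste0("GGCCTAGCCT", "CC", "TGAGGTAGTAGGTTGTATAGTT",
                "GTTTGGAACCAGGAGG")
  hp2 <- paste0("TTGACCGTGA", "CC", "TACCCTGTAGATCCGAATTTGT",
                "ACCTTGGATCCTGAC")
  mirna_reference(
    hairpins = c("toy-mir-1" = hp1, "toy-mir-2" = hp2),
    matures = data.frame(
      mature_id = c("toy-miR-1", "toy-miR-2"),
      hairpin_id = c("toy-mir-1", "toy-mir-2"),
      start = c(12L, 12L), end = c(34L, 34L),
      arm = c("5p", "5p")))
}

# Write a batch of sequences as an uncompressed FASTQ for clean_reads().
write_test_fastq <- function(seqs, path) {
  writeLines(paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), path)
  path
}

# Wrap raw sequences as an already-clean batch (bypassing file I/O).
as_batch <- function(seqs, mult = NULL, sample_id = "test") {
  if (is.null(mult)) {
    tab <- table(seqs)
    df <- data.frame(sequence = names(tab), multiplicity = as.integer(tab),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(sequence = seqs, multiplicity = as.integer(mult),
                     stringsAsFactors = FALSE)
  }
  df <- df[order(df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(sample_id = sample_id, reads = df,
                 n_raw = sum(df$multiplicity), n_len_filtered = 0L,
                 n_contaminant = 0L),
            class = "clean_reads")
}

table2_path <- function() {
  system.file("extdata", "ccc_grade_means_cpm.tsv", package = "isomiRseq")
}
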