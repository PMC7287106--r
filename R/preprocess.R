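#' Read cleaning: adapter trimming, length filter, collapsing
#'
#' Parses FASTQ or FASTA (gzip ok), optionally removes a 3' adapter by
#' exact-prefix search (a match of at least 8 nt of the adapter prefix at
#' the read 3' end, earliest occurrence wins), applies the insert length
#' window and collapses identical sequences with multiplicities. Qualities
#' are ignored throughout.
#'
#' @param path FASTQ/FASTA file.
#' @param min_len,max_len retained insert length window (nt). The lower
#'   bound sits below the library's 20-40 nt insert window so 3'-trimmed
#'   isomiRs of short miRNAs survive.
#' @param adapter optional 3' adapter sequence.
#' @param format `"fastq"` (default) or `"fasta"`; guessed from the file
#'   extension when `NULL`.
#' @return A `clean_reads` object: list with `sample_id`, `reads`
#'   (data.frame `sequence`, `multiplicity`), `n_raw`, `n_len_filtered`,
#'   `n_contaminant` (0 until [filter_contaminants()]).
#' @export
clean_reads <- function(path, min_len = 15L, max_len = 40L, adapter = NULL,
                        format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fa|fasta)(\\.gz)?$", path, ignore.case = TRUE))
      "fasta" else "fastq"
  }
  ss <- Biostrings::readDNAStringSet(path, format = format,
                                     with.qualities = FALSE)
  seqs <- normalize_seq(as.character(ss))
  n_raw <- length(seqs)
  if (!is.null(adapter) && n_raw > 0L) {
    adapter <- normalize_seq(adapter)
    probe <- substr(adapter, 1L, max(8L, min(12L, nchar(adapter))))
    if (nchar(probe) < 8L)
      stop("adapter must be at least 8 nt for exact-prefix search")
    pos <- regexpr(probe, seqs, fixed = TRUE)
    has <- pos > 0L
    seqs[has] <- substr(seqs[has], 1L, pos[has] - 1L)
  }
  len <- nchar(seqs)
  keep <- len >= min_len & len <= max_len
  n_len_filtered <- sum(!keep)
  tab <- table(seqs[keep])
  reads <- data.frame(sequence = names(tab),
                      multiplicity = as.integer(tab),
                      stringsAsFactors = FALSE)
  reads <- reads[order(reads$sequence), , drop = FALSE]
  rownames(reads) <- NULL
  if (nrow(reads) == 0L)
    warning("no reads retained from ", path)
  structure(list(sample_id = sub("\\.(fastq|fq|fa|fasta)(\\.gz)?$", "",
                                 basename(path), ignore.case = TRUE),
                 reads = reads, n_raw = n_raw,
                 n_len_filtered = n_len_filtered, n_contaminant = 0L),
            class = "clean_reads")
}

#' @export
print.clean_reads <- function(x, ...) {
  cat("clean_reads [", x$sample_id, "]: ", sum(x$reads$multiplicity),
      " reads (", nrow(x$reads), " distinct); raw ", x$n_raw,
      ", length-filtered ", x$n_len_filtered,
      ", contaminant ", x$n_contaminant, "\n", sep = "")
  invisible(x)
}

#' Remove non-miRNA small RNA contaminants by decoy matching
#'
#' Reads occurring as a substring of any decoy sequence with at most
#' `max_mismatch` substitutions (no indels) are removed and tallied in
#' `n_contaminant`. This preserves the role of the genome-wide contaminant
#' exclusion step (rRNA/tRNA/snoRNA/piRNA/repeat fragments) without a
#' genome index.
#'
#' @param batch a [clean_reads()] object.
#' @param decoy_fasta decoy FASTA path, or a named character vector of
#'   decoy sequences.
#' @param max_mismatch maximum substitutions for a decoy match.
#' @return The batch with matching reads removed and tallies updated.
#' @export
filter_contaminants <- function(batch, decoy_fasta, max_mismatch = 1L) {
  stopifnot(inherits(batch, "clean_reads"))
  decoys <- if (is.character(decoy_fasta) && length(decoy_fasta) == 1L &&
                file.exists(decoy_fasta)) {
    as.character(Biostrings::readDNAStringSet(decoy_fasta))
  } else as.character(decoy_fasta)
  decoys <- normalize_seq(decoys)
  if (length(decoys) == 0L || nrow(batch$reads) == 0L) return(batch)
  hit <- .match_decoys_cpp(batch$reads$sequence, decoys,
                           as.integer(max_mismatch))
  batch$n_contaminant <- batch$n_contaminant +
    sum(batch$reads$multiplicity[hit])
  batch$reads <- batch$reads[!hit, , drop = FALSE]
  rownames(batch$reads) <- NULL
  batch
}

#' Alignment parameter bounds
#'
#' @param max_shift5 maximum |5' offset| from the mature start (nt).
#' @param max_shift3 maximum |3' offset| of the templated body end from the
#'   mature end (nt).
#' @param max_tail maximum non-templated 3' tail length (nt).
#' @param max_mismatch maximum internal substitutions in the templated body.
#' @return Named list of validated integer bounds.
#' @export
align_params <- function(max_shift5 = 4L, max_shift3 = 5L, max_tail = 3L,
                         max_mismatch = 2L) {
  p <- list(max_shift5 = as.integer(max_shift5),
            max_shift3 = as.integer(max_shift3),
            max_tail = as.integer(max_tail),
            max_mismatch = as.integer(max_mismatch))
  stopifnot(all(vapply(p, function(x) length(x) == 1L && x >= 0L,
                       logical(1))))
  p
}

#' Place collapsed reads on hairpin precursors
#'
#' Every candidate placement of each read is enumerated: for each mature
#' arm and each 5' offset in `[-max_shift5, max_shift5]` the read is
#' compared with the templated hairpin from `mature_start + offset5`;
#' trailing bases beyond the templated match are tested as a non-templated
#' 3' tail. The placement minimizing
#' `(n_subst, tail_len, |offset5| + |offset3|)` is reported; ties break by
#' smaller |offset5|, then lexicographically smallest mature id. Reads with
#' no admissible placement are tallied unaligned. A 3' base that matches
#' the hairpin template is always read as templated extension, never tail.
#'
#' @param batch a [clean_reads()] object (post contaminant filtering).
#' @param ref a [mirna_reference].
#' @param params bounds from [align_params()].
#' @return List with `alignments` (data.frame: `sequence`, `multiplicity`,
#'   `mature_id`, `hairpin_id`, `offset5`, `offset3`, `n_subst`,
#'   `nta_tail`, `substitutions` as `"pos:ref>alt"` comma strings with
#'   0-based mature-relative positions), `n_unaligned` (read units) and
#'   `sample_id`.
#' @export
align_to_hairpins <- function(batch, ref, params = align_params()) {
  stopifnot(inherits(batch, "clean_reads"), inherits(ref, "mirna_reference"))
  mt <- ref$matures[order(ref$matures$mature_id), , drop = FALSE]
  if (nrow(batch$reads) == 0L) {
    return(list(alignments = empty_alignments(), n_unaligned = 0L,
                sample_id = batch$sample_id))
  }
  res <- .align_reads_cpp(batch$reads$sequence,
                          unname(ref$hairpins[mt$hairpin_id]),
                          mt$start, mt$end,
                          params$max_shift5, params$max_shift3,
                          params$max_tail, params$max_mismatch)
  ok <- res$aligned
  aln <- data.frame(
    sequence = batch$reads$sequence[ok],
    multiplicity = batch$reads$multiplicity[ok],
    mature_id = mt$mature_id[res$mature_idx[ok]],
    hairpin_id = mt$hairpin_id[res$mature_idx[ok]],
    offset5 = res$offset5[ok], offset3 = res$offset3[ok],
    n_subst = res$n_subst[ok], nta_tail = res$nta_tail[ok],
    substitutions = res$substitutions[ok],
    stringsAsFactors = FALSE)
  rownames(aln) <- NULL
  list(alignments = aln,
       n_unaligned = sum(batch$reads$multiplicity[!ok]),
       sample_id = batch$sample_id)
}

empty_alignments <- function() {
  data.frame(sequence = character(), multiplicity = integer(),
             mature_id = character(), hairpin_id = character(),
             offset5 = integer(), offset3 = integer(), n_subst = integer(),
             nta_tail = character(), substitutions = character(),
             stringsAsFactors = FALSE)
}

#' Verify the reconstruction invariant of an alignment table
#'
#' Removing the non-templated tail from each read and reverting its
#' substitutions must reconstruct the hairpin slice
#' `[mature_start + offset5, mature_end + offset3)` exactly.
#'
#' @param aln alignment data.frame from [align_to_hairpins()].
#' @param ref the [mirna_reference] aligned against.
#' @return Logical vector, one entry per alignment row.
#' @export
check_reconstruction <- function(aln, ref) {
  mt <- ref$matures
  rownames(mt) <- mt$mature_id
  vapply(seq_len(nrow(aln)), function(i) {
    a <- aln[i, ]
    m <- mt[a$mature_id, ]
    body_len <- nchar(a$sequence) - nchar(a$nta_tail)
    body <- substr(a$sequence, 1L, body_len)
    if (nzchar(a$substitutions)) {
      for (s in strsplit(a$substitutions, ",", fixed = TRUE)[[1]]) {
        p <- as.integer(sub(":.*", "", s))
        ref_base <- sub(".*:(.)>.*", "\\1", s)
        pos_in_read <- p - a$offset5 + 1L
        substr(body, pos_in_read, pos_in_read) <- ref_base
      }
    }
    slice <- substr(ref$hairpins[[m$hairpin_id]],
                    m$start + a$offset5 + 1L, m$end + a$offset3)
    identical(body, slice)
  }, logical(1))
}
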