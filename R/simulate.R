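#' Configuration for the synthetic small RNA cohort generator
#'
#' The generator emulates the statistical and sequence structure the
#' analysis assumes: two sample groups of negative-binomial counts over a
#' modest set of miRNA loci, a dominant locus holding a large share of all
#' counts, a subset of loci with strong injected effects (|log2FC| > 2),
#' per-locus isomiR structure (3' trims, templated 3' extensions,
#' non-templated 3' tails, 5' shifts of 1-2 nt realized as C
#' insertion/deletion, internal substitutions), uniform sequencing error and
#' a contaminant read fraction.
#'
#' @param n_group_A,n_group_B samples per group (>= 2).
#' @param n_mirnas number of miRNA loci.
#' @param library_size_mean,library_size_cv mean and coefficient of
#'   variation of per-sample library sizes (reads).
#' @param dispersion negative-binomial dispersion phi >= 0
#'   (variance = mu + phi * mu^2); 0 gives Poisson counts.
#' @param abundance_skew fraction of counts assigned to locus 1 (0-0.6).
#' @param de_fraction fraction of loci (excluding the dominant locus) with
#'   an injected group effect.
#' @param de_log2fc_range length-2 numeric, |log2FC| magnitude range for
#'   injected effects; the lower bound must exceed 2 so injected loci are
#'   "strong" by the pipeline's definition.
#' @param isomir_profile named numeric summing to 1 over classes
#'   `canonical`, `trim3`, `ext3`, `nta3`, `shift5`, `subst`.
#' @param shift5_indel_base base inserted/deleted at the 5' end by shift5
#'   isomiRs (default "C"; [simulate_reference()] templates this base
#'   upstream of every mature so 5' extensions are C insertions).
#' @param seq_error_rate per-base sequencing error probability.
#' @param contaminant_fraction fraction of reads drawn from decoy
#'   (non-miRNA small RNA) sequences.
#' @param seed integer seed driving every random choice.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_group_A = 2L, n_group_B = 7L, n_mirnas = 50L,
                       library_size_mean = 1e6, library_size_cv = 0.2,
                       dispersion = 0.2, abundance_skew = 0.3,
                       de_fraction = 0.2, de_log2fc_range = c(2.5, 4),
                       isomir_profile = c(canonical = 0.25, trim3 = 0.30,
                                          ext3 = 0.15, nta3 = 0.10,
                                          shift5 = 0.05, subst = 0.15),
                       shift5_indel_base = "C",
                       seq_error_rate = 0.001,
                       contaminant_fraction = 0.05,
                       seed = 1L) {
  cfg <- list(n_group_A = as.integer(n_group_A),
              n_group_B = as.integer(n_group_B),
              n_mirnas = as.integer(n_mirnas),
              library_size_mean = library_size_mean,
              library_size_cv = library_size_cv,
              dispersion = dispersion,
              abundance_skew = abundance_skew,
              de_fraction = de_fraction,
              de_log2fc_range = de_log2fc_range,
              isomir_profile = isomir_profile,
              shift5_indel_base = shift5_indel_base,
              seq_error_rate = seq_error_rate,
              contaminant_fraction = contaminant_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_group_A >= 2L, cfg$n_group_B >= 2L, cfg$n_mirnas >= 1L,
            cfg$library_size_mean > 0, cfg$library_size_cv >= 0,
            cfg$dispersion >= 0,
            cfg$abundance_skew >= 0, cfg$abundance_skew <= 0.6,
            cfg$de_fraction >= 0, cfg$de_fraction <= 1,
            length(cfg$de_log2fc_range) == 2L,
            cfg$de_log2fc_range[1] > 2,
            cfg$de_log2fc_range[2] >= cfg$de_log2fc_range[1],
            cfg$seq_error_rate >= 0, cfg$seq_error_rate <= 1,
            cfg$contaminant_fraction >= 0, cfg$contaminant_fraction <= 1)
  classes <- c("canonical", "trim3", "ext3", "nta3", "shift5", "subst")
  p <- cfg$isomir_profile
  if (!all(classes %in% names(p)) || length(p) != 6L)
    stop("isomir_profile must name exactly: ",
         paste(classes, collapse = ", "))
  if (abs(sum(p) - 1) > 1e-9) stop("isomir_profile must sum to 1")
  if (any(p < 0)) stop("isomir_profile probabilities must be >= 0")
  if (!cfg$shift5_indel_base %in% c("A", "C", "G", "T"))
    stop("shift5_indel_base must be one of A/C/G/T")
  invisible(cfg)
}

rand_bases <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

#' Simulate a hairpin/mature reference
#'
#' Random hairpins of 60-90 nt, each carrying one mature arm of 20-23 nt
#' placed at least 10 nt from either hairpin end, so every mature has ample
#' templated flank for 5' shifts and 3' extensions. The two bases
#' immediately 5' of each mature are set to `shift5_indel_base` (default
#' "C"), so 5'-extended isomiRs carry inserted C's.
#'
#' @param n_mirnas number of loci (>= 1).
#' @param seed integer seed; identical seeds give identical references.
#' @param shift5_indel_base base templated immediately upstream of each
#'   mature (default "C").
#' @return A [mirna_reference] with hairpins `sim-mir-1` ... and matures
#'   `sim-miR-1` ....
#' @export
simulate_reference <- function(n_mirnas, seed = 1L, shift5_indel_base = "C") {
  stopifnot(n_mirnas >= 1L)
  set.seed(seed)
  hp <- character(n_mirnas)
  rows <- vector("list", n_mirnas)
  for (i in seq_len(n_mirnas)) {
    len <- sample(60:90, 1L)
    s <- rand_bases(len)
    mlen <- sample(20:23, 1L)
    start <- sample(10:(len - mlen - 10L), 1L)  # 0-based
    s[(start - 1L):start] <- shift5_indel_base  # 2 nt upstream of mature
    hp[i] <- paste(s, collapse = "")
    rows[[i]] <- data.frame(
      mature_id = sprintf("sim-miR-%d", i),
      hairpin_id = sprintf("sim-mir-%d", i),
      start = start, end = start + mlen,
      arm = if (start + mlen / 2 < len / 2) "5p" else "3p")
  }
  names(hp) <- sprintf("sim-mir-%d", seq_len(n_mirnas))
  mirna_reference(hp, do.call(rbind, rows))
}

#' Simulate decoy (contaminant) sequences
#'
#' A small pool of random sequences standing in for the non-miRNA small RNA
#' compartment (rRNA/tRNA/snoRNA/piRNA fragments). Labelled synthetic; not
#' derived from any real annotation.
#'
#' @param n_decoys number of decoy sequences.
#' @param seed integer seed.
#' @return Named character vector of decoy sequences (80-120 nt).
#' @export
simulate_decoys <- function(n_decoys = 5L, seed = 1L) {
  set.seed(seed + 7L)
  setNames(
    vapply(seq_len(n_decoys),
           function(i) paste(rand_bases(sample(80:120, 1L)), collapse = ""),
           character(1)),
    sprintf("sim-decoy-%d", seq_len(n_decoys)))
}

#' Simulate per-sample per-locus counts under the negative-binomial model
#'
#' Baseline relative abundances give locus 1 `abundance_skew` of the total;
#' the remainder is log-normally distributed over the other loci. A
#' `de_fraction` of non-dominant loci receive an injected effect: group B
#' means scaled by `2^log2fc` with |log2FC| drawn from `de_log2fc_range`
#' and random sign. Counts are NB with variance `mu + phi * mu^2`
#' (Poisson when `phi = 0`).
#'
#' @param cfg a [sim_config].
#' @param ref a [mirna_reference] with at least `cfg$n_mirnas` matures;
#'   defaults to [simulate_reference()] on the same seed.
#' @return List with `counts` (locus x sample integer matrix),
#'   `groups` (named group factor), `truth` (per-locus data.frame:
#'   `mature_id`, `baseline`, `true_log2fc`, `is_de`) and
#'   `library_sizes` (the drawn target sizes; realized column sums differ
#'   by NB noise).
#' @export
simulate_counts <- function(cfg, ref = NULL) {
  validate_sim_config(cfg)
  if (is.null(ref)) ref <- simulate_reference(cfg$n_mirnas, cfg$seed,
                                              cfg$shift5_indel_base)
  stopifnot(nrow(ref$matures) >= cfg$n_mirnas)
  ids <- ref$matures$mature_id[seq_len(cfg$n_mirnas)]
  set.seed(cfg$seed + 1L)
  n <- cfg$n_mirnas
  base <- if (n == 1L) 1 else {
    rest <- stats::rlnorm(n - 1L, meanlog = 0, sdlog = 1.5)
    c(cfg$abundance_skew, (1 - cfg$abundance_skew) * rest / sum(rest))
  }
  lfc <- numeric(n)
  n_de <- round(cfg$de_fraction * n)
  if (n_de > 0 && n > 1L) {
    de_idx <- sample(2:n, min(n_de, n - 1L))
    mag <- runif(length(de_idx), cfg$de_log2fc_range[1], cfg$de_log2fc_range[2])
    sgn <- sample(c(-1, 1), length(de_idx), replace = TRUE)
    lfc[de_idx] <- mag * sgn
  }
  n_samp <- cfg$n_group_A + cfg$n_group_B
  groups <- factor(rep(c("A", "B"), c(cfg$n_group_A, cfg$n_group_B)))
  sample_ids <- sprintf("%s%d", groups,
                        c(seq_len(cfg$n_group_A), seq_len(cfg$n_group_B)))
  libs <- pmax(100, round(rnorm(n_samp, cfg$library_size_mean,
                                cfg$library_size_cv * cfg$library_size_mean)))
  counts <- matrix(0L, n, n_samp, dimnames = list(ids, sample_ids))
  for (s in seq_len(n_samp)) {
    mu <- libs[s] * base * (if (groups[s] == "B") 2^lfc else rep(1, n))
    counts[, s] <- as.integer(
      if (cfg$dispersion == 0) rpois(n, mu)
      else rnbinom(n, mu = mu, size = 1 / cfg$dispersion))
  }
  list(counts = counts,
       groups = setNames(groups, sample_ids),
       truth = data.frame(mature_id = ids, baseline = base,
                          true_log2fc = lfc, is_de = lfc != 0),
       library_sizes = setNames(libs, sample_ids))
}

# Build one isomiR read of the given class from its mature context.
# Returns list(seq, offset5, offset3, tail, subst_pos) where subst_pos is
# the 0-based mature-relative substitution position (NA if none).
# Generator-side constraints keeping the minimal-score decomposition equal
# to the generating one: substitutions avoid the first base and the last
# max_tail + 1 bases; the first tail base differs from the templated
# hairpin base at that position.
make_isomir_read <- function(class, hairpin, start, end, max_tail = 3L) {
  mat <- substr(hairpin, start + 1L, end)
  L <- nchar(mat)
  switch(class,
    canonical = list(seq = mat, offset5 = 0L, offset3 = 0L, tail = "",
                     subst_pos = NA_integer_),
    trim3 = {
      k <- sample(1:3, 1L)
      list(seq = substr(mat, 1L, L - k), offset5 = 0L, offset3 = -k,
           tail = "", subst_pos = NA_integer_)
    },
    ext3 = {
      k <- sample(1:3, 1L)
      list(seq = substr(hairpin, start + 1L, end + k), offset5 = 0L,
           offset3 = k, tail = "", subst_pos = NA_integer_)
    },
    nta3 = {
      k <- sample(1:3, 1L)
      tmpl <- strsplit(substr(hairpin, end + 1L, end + k), "")[[1]]
      tail <- character(k)
      for (i in seq_len(k)) {
        pool <- c("A", "T")
        if (i == 1L) pool <- setdiff(pool, tmpl[i])  # force non-templated
        tail[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
      }
      tail <- paste(tail, collapse = "")
      list(seq = paste0(mat, tail), offset5 = 0L, offset3 = 0L,
           tail = tail, subst_pos = NA_integer_)
    },
    shift5 = {
      d <- sample(1:2, 1L) * sample(c(-1L, 1L), 1L)  # -d: 5' extension
      list(seq = substr(hairpin, start + d + 1L, end), offset5 = d,
           offset3 = 0L, tail = "", subst_pos = NA_integer_)
    },
    subst = {
      p <- sample(2:(L - max_tail - 1L), 1L)  # 1-based read position
      b <- substr(mat, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      s <- mat
      substr(s, p, p) <- alt
      list(seq = s, offset5 = 0L, offset3 = 0L, tail = "",
           subst_pos = p - 1L)
    },
    stop("unknown isomiR class: ", class))
}

apply_seq_errors <- function(seqs, rate) {
  if (rate <= 0) return(list(seqs = seqs, n_err = integer(length(seqs))))
  n_err <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    hit <- which(runif(L) < rate)
    if (length(hit)) {
      s <- strsplit(seqs[i], "")[[1]]
      for (p in hit) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
      seqs[i] <- paste(s, collapse = "")
      n_err[i] <- length(hit)
    }
  }
  list(seqs = seqs, n_err = n_err)
}

#' Emit per-sample FASTQ reads plus a per-read ground-truth table
#'
#' Each count unit from [simulate_counts()] becomes one read whose isomiR
#' class is drawn from `cfg$isomir_profile`; sequencing errors are applied
#' at `cfg$seq_error_rate` and a `cfg$contaminant_fraction` of extra reads
#' is drawn as substrings of the decoy pool. Qualities are constant "I".
#'
#' @param sim result of [simulate_counts()].
#' @param ref the [mirna_reference] used for `sim`.
#' @param cfg the [sim_config].
#' @param out_dir directory for `<sample>.fastq.gz`, `truth.tsv`,
#'   `decoys.fa` and `config.yaml`.
#' @param decoys named character vector of decoy sequences; defaults to
#'   [simulate_decoys()] on the config seed.
#' @return List with `fastq` (named paths), `truth` (data.frame: one row
#'   per emitted read), `decoy_fasta` and `truth_tsv` paths.
#' @export
emit_reads <- function(sim, ref, cfg, out_dir, decoys = NULL) {
  validate_sim_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(decoys)) decoys <- simulate_decoys(seed = cfg$seed)
  set.seed(cfg$seed + 2L)
  classes <- names(cfg$isomir_profile)
  mt <- ref$matures
  rownames(mt) <- mt$mature_id
  truth <- vector("list", ncol(sim$counts))
  fastqs <- character(0)
  for (s in seq_len(ncol(sim$counts))) {
    sample_id <- colnames(sim$counts)[s]
    recs <- vector("list", nrow(sim$counts) + 1L)
    for (f in seq_len(nrow(sim$counts))) {
      n <- sim$counts[f, s]
      if (n == 0L) next
      id <- rownames(sim$counts)[f]
      m <- mt[id, ]
      hp <- ref$hairpins[[m$hairpin_id]]
      cls <- sample(classes, n, replace = TRUE, prob = cfg$isomir_profile)
      parts <- lapply(cls, make_isomir_read, hairpin = hp,
                      start = m$start, end = m$end)
      recs[[f]] <- data.frame(
        sample_id = sample_id, mature_id = id, class = cls,
        offset5 = vapply(parts, `[[`, integer(1), "offset5"),
        offset3 = vapply(parts, `[[`, integer(1), "offset3"),
        nta_tail = vapply(parts, `[[`, character(1), "tail"),
        subst_pos = vapply(parts, `[[`, integer(1), "subst_pos"),
        sequence = vapply(parts, `[[`, character(1), "seq"),
        is_contaminant = FALSE)
    }
    n_mirna <- sum(sim$counts[, s])
    n_cont <- if (cfg$contaminant_fraction > 0)
      rbinom(1L, n_mirna, cfg$contaminant_fraction /
               max(1e-12, 1 - cfg$contaminant_fraction)) else 0L
    if (n_cont > 0L) {
      dseq <- vapply(seq_len(n_cont), function(i) {
        d <- decoys[[sample(length(decoys), 1L)]]
        len <- sample(20:30, 1L)
        p <- sample(nchar(d) - len + 1L, 1L)
        substr(d, p, p + len - 1L)
      }, character(1))
      recs[[nrow(sim$counts) + 1L]] <- data.frame(
        sample_id = sample_id, mature_id = NA_character_,
        class = "contaminant", offset5 = NA_integer_, offset3 = NA_integer_,
        nta_tail = NA_character_, subst_pos = NA_integer_,
        sequence = dseq, is_contaminant = TRUE)
    }
    tab <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
    if (is.null(tab)) {
      tab <- data.frame(sample_id = character(), mature_id = character(),
                        class = character(), offset5 = integer(),
                        offset3 = integer(), nta_tail = character(),
                        subst_pos = integer(), sequence = character(),
                        is_contaminant = logical(), n_seq_errors = integer(),
                        read_id = character())
    } else {
      err <- apply_seq_errors(tab$sequence, cfg$seq_error_rate)
      tab$sequence <- err$seqs
      tab$n_seq_errors <- err$n_err
      tab$read_id <- sprintf("%s_read%06d", sample_id, seq_len(nrow(tab)))
    }
    fq <- file.path(out_dir, paste0(sample_id, ".fastq.gz"))
    write_fastq(tab$read_id, tab$sequence, fq)
    fastqs[sample_id] <- fq
    truth[[s]] <- tab
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  truth_tsv <- file.path(out_dir, "truth.tsv")
  write.table(truth, truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  decoy_fasta <- file.path(out_dir, "decoys.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(decoys), decoy_fasta)
  cfg_plain <- unclass(cfg)
  cfg_plain$isomir_profile <- as.list(cfg_plain$isomir_profile)
  yaml::write_yaml(cfg_plain, file.path(out_dir, "config.yaml"))
  list(fastq = fastqs, truth = truth, decoy_fasta = decoy_fasta,
       truth_tsv = truth_tsv)
}

write_fastq <- function(ids, seqs, path) {
  con <- gzfile(path, "wt")
  on.exit(close(con))
  if (length(seqs))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                      strrep("I", nchar(seqs))), con)
  else writeLines(character(0), con)
  invisible(path)
}
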