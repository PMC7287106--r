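test_that("clean_reads trims adapters, filters lengths, collapses", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  insert <- strrep("ACGT", 6)                      # 24 nt
  fq <- write_test_fastq(
    c(paste0(insert, adapter), paste0(insert, adapter),
      "ACGTACGTAC",                                # 10 nt -> filtered
      "TGCATGCATGCATGCATGCA"),
    tempfile(fileext = ".fastq"))
  b <- clean_reads(fq, adapter = adapter)
  expect_identical(b$n_raw, 4L)
  expect_identical(b$n_len_filtered, 1L)
  expect_identical(sum(b$reads$multiplicity), 3L)
  expect_identical(b$reads$multiplicity[b$reads$sequence == insert], 2L)
})

test_that("contaminant filtering matches decoy substrings within mismatch budget", {
  decoy <- paste0("GGGTTTCCCAAAGGGTTTCCCAAA", "TGCATGCATGCATGCATGCATG",
                  "ACACACAC")
  sub22 <- substr(decoy, 25, 46)
  mm1 <- sub22; substr(mm1, 5, 5) <- "A"   # 1 mismatch (T->A)
  mm2 <- mm1;  substr(mm2, 9, 9) <- "C"    # 2 mismatches
  keepme <- "TGAGGTAGTAGGTTGTATAGTT"
  b <- as_batch(c(sub22, mm1, mm2, keepme))
  f <- filter_contaminants(b, c(d1 = decoy), max_mismatch = 1)
  expect_identical(f$n_contaminant, 2L)
  expect_setequal(f$reads$sequence, c(mm2, keepme))
  # empty decoy set leaves the batch unchanged
  f0 <- filter_contaminants(b, character(0))
  expect_identical(f0$reads, b$reads)
})

test_that("alignment recovers canonical, trimmed, and tailed reads", {
  ref <- toy_reference()
  mat <- mature_sequence(ref, "toy-miR-1")
  b <- as_batch(c(mat,
                  substr(mat, 1, nchar(mat) - 2),   # 3' trim by 2
                  paste0(mat, "AA")))               # hairpin continues GT
  res <- align_to_hairpins(b, ref)
  aln <- res$alignments
  expect_identical(res$n_unaligned, 0L)
  rownames(aln) <- aln$sequence
  expect_identical(unname(unlist(
    aln[mat, c("offset5", "offset3", "n_subst", "nta_tail")])),
    c("0", "0", "0", ""))
  expect_identical(aln[substr(mat, 1, 20), "offset3"], -2L)
  expect_identical(aln[substr(mat, 1, 20), "n_subst"], 0L)
  expect_identical(aln[paste0(mat, "AA"), "offset3"], 0L)
  expect_identical(aln[paste0(mat, "AA"), "nta_tail"], "AA")
  expect_true(all(check_reconstruction(aln, ref)))
})

test_that("a 3' base matching the template is read as extension, not tail", {
  ref <- toy_reference()
  mat <- mature_sequence(ref, "toy-miR-1")
  # hairpin continues "GT": appending "G" must become offset3 = +1
  res <- align_to_hairpins(as_batch(paste0(mat, "G")), ref)
  expect_identical(res$alignments$offset3, 1L)
  expect_identical(res$alignments$nta_tail, "")
})

test_that("unplaceable reads are tallied unaligned", {
  ref <- toy_reference()
  res <- align_to_hairpins(as_batch(strrep("AG", 11)), ref)
  expect_identical(nrow(res$alignments), 0L)
  expect_identical(res$n_unaligned, 1L)
})

test_that("aligner agrees with the brute-force oracle on random reads", {
  set.seed(301)
  ref <- simulate_reference(5, seed = 301)
  params <- align_params()
  mats <- vapply(ref$matures$mature_id,
                 function(id) mature_sequence(ref, id), character(1))
  n_checked <- 0L
  for (rep in 1:250) {
    base <- sample(mats, 1)
    # random perturbation: trims, extensions, tails, shifts, substitutions
    s <- strsplit(base, "")[[1]]
    if (runif(1) < 0.5) s <- s[seq_len(length(s) - sample(0:3, 1))]
    if (runif(1) < 0.3) s <- c(s, sample(c("A", "C", "G", "T"),
                                         sample(1:3, 1), replace = TRUE))
    nmut <- sample(0:2, 1)
    for (k in seq_len(nmut)) {
      p <- sample(length(s), 1)
      s[p] <- sample(c("A", "C", "G", "T"), 1)
    }
    read <- paste(s, collapse = "")
    if (nchar(read) < 15) next
    n_checked <- n_checked + 1L
    got <- align_to_hairpins(as_batch(read), ref, params)
    want <- oracle_align(read, ref, params)
    if (is.null(want)) {
      expect_identical(got$n_unaligned, 1L)
    } else {
      expect_identical(nrow(got$alignments), 1L)
      a <- got$alignments
      expect_identical(
        unname(c(a$mature_id, a$offset5, a$offset3, a$n_subst, a$nta_tail)),
        unname(c(want$mature_id, want$offset5, want$offset3, want$n_subst,
                 want$nta_tail)))
    }
  }
  expect_gt(n_checked, 200L)
})
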