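mk_aln <- function(offset5 = 0L, offset3 = 0L, n_subst = 0L,
                   nta_tail = "", substitutions = "", parent = "toy-miR-1",
                   sequence = "X", multiplicity = 1L) {
  data.frame(sequence = sequence, multiplicity = multiplicity,
             mature_id = parent, hairpin_id = "toy-mir-1",
             offset5 = offset5, offset3 = offset3, n_subst = n_subst,
             nta_tail = nta_tail, substitutions = substitutions,
             stringsAsFactors = FALSE)
}

test_that("classification partitions calls into the class taxonomy", {
  cases <- rbind(
    cbind(mk_aln(), want = "canonical", seed = FALSE),
    cbind(mk_aln(offset3 = -2L), want = "3", seed = FALSE),
    cbind(mk_aln(nta_tail = "AA"), want = "3", seed = FALSE),
    cbind(mk_aln(offset5 = 2L), want = "5", seed = TRUE),
    cbind(mk_aln(offset5 = -1L, offset3 = 1L), want = "53", seed = TRUE),
    cbind(mk_aln(n_subst = 1L, substitutions = "3:A>G"), want = "0",
          seed = TRUE),
    cbind(mk_aln(n_subst = 1L, substitutions = "12:A>G"), want = "0",
          seed = FALSE))
  got <- classify_alignments(cases[, 1:9])
  expect_identical(got$class_code, cases$want)
  expect_identical(got$seed_altered, cases$seed)
  expect_identical(got$canonical, cases$want == "canonical")
  # partition property: every non-canonical call has exactly one class
  expect_true(all(got$class_code[!got$canonical] %in%
                    c("0", "3", "5", "53")))
})

test_that("names follow the dotted grammar with deterministic serials", {
  calls <- classify_alignments(rbind(
    mk_aln(sequence = "CANON", multiplicity = 10L),
    mk_aln(offset3 = -1L, sequence = "TRIMA", multiplicity = 5L),
    mk_aln(offset3 = -2L, sequence = "TRIMB", multiplicity = 9L),
    mk_aln(offset5 = 1L, sequence = "SHIFT", multiplicity = 2L,
           parent = "toy-miR-2")))
  cat1 <- assign_names(calls)
  cat2 <- assign_names(calls[sample(nrow(calls)), ])
  expect_identical(cat1[order(cat1$name), ], cat2[order(cat2$name), ])
  # abundance order: TRIMB (9) takes serial 1, TRIMA (5) serial 2
  expect_identical(cat1$name[cat1$sequence == "TRIMB"],
                   "toy-miR-1.3.P0.S.1")
  expect_identical(cat1$name[cat1$sequence == "TRIMA"],
                   "toy-miR-1.3.P0.S.2")
  expect_identical(cat1$name[cat1$sequence == "SHIFT"],
                   "toy-miR-2.5.P0.S.1")
  expect_identical(cat1$name[cat1$sequence == "CANON"], "toy-miR-1")
  # grammar round trip
  parsed <- parse_isomir_name(cat1$name)
  expect_identical(parsed$parent, cat1$parent)
  iso <- !cat1$canonical
  expect_identical(parsed$class_code[iso], cat1$class_code[iso])
  expect_identical(parsed$n_subst[iso], cat1$n_subst[iso])
  expect_identical(parsed$serial[iso], cat1$serial[iso])
  expect_identical(parsed$class_code[!iso], rep("canonical", sum(!iso)))
})

test_that("catalog summaries report class fractions", {
  calls <- classify_alignments(rbind(
    mk_aln(offset3 = -1L, sequence = "A1"),
    mk_aln(offset3 = -2L, sequence = "A2"),
    mk_aln(offset5 = 1L, sequence = "A3"),
    mk_aln(offset5 = 1L, offset3 = 1L, sequence = "A4")))
  s <- catalog_summary(assign_names(calls))
  expect_identical(setNames(s$by_class$fraction, s$by_class$stratum),
                   c("3" = 0.5, "5" = 0.25, "53" = 0.25))
  empty <- catalog_summary(assign_names(calls[0, ]))
  expect_identical(nrow(empty$by_class), 0L)
})

test_that("recovered class frequencies match the generating profile", {
  profile <- c(canonical = 0.25, trim3 = 0.30, ext3 = 0.15, nta3 = 0.10,
               shift5 = 0.05, subst = 0.15)
  ref <- simulate_reference(10, seed = 77)
  cfg <- sim_config(n_group_A = 2, n_group_B = 2, n_mirnas = 10,
                    library_size_mean = 4000, dispersion = 0.05,
                    isomir_profile = profile, seq_error_rate = 0,
                    contaminant_fraction = 0, seed = 77)
  sim <- simulate_counts(cfg, ref)
  em <- emit_reads(sim, ref, cfg, tempfile("cls"))
  pr <- lapply(em$fastq, process_sample, ref = ref)
  calls <- do.call(rbind, lapply(pr, `[[`, "calls"))
  n <- sum(calls$multiplicity)
  got <- c(canonical = sum(calls$multiplicity[calls$canonical]) / n,
           trim3 = sum(calls$multiplicity[calls$class_code == "3" &
                                            calls$offset3 < 0]) / n,
           ext3 = sum(calls$multiplicity[calls$class_code == "3" &
                                           calls$offset3 > 0]) / n,
           nta3 = sum(calls$multiplicity[calls$class_code == "3" &
                                           calls$offset3 == 0]) / n,
           shift5 = sum(calls$multiplicity[calls$class_code == "5"]) / n,
           subst = sum(calls$multiplicity[calls$class_code == "0"]) / n)
  # binomial tolerance at n ~ 16k draws: 4 sd of the largest class
  expect_true(all(abs(got - profile) < 4 * sqrt(0.3 * 0.7 / n) + 1e-9))
})
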