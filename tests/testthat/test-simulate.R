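test_that("simulated references are deterministic with guaranteed flanks", {
  r1 <- simulate_reference(20, seed = 1)
  r2 <- simulate_reference(20, seed = 1)
  expect_identical(r1, r2)
  expect_identical(nrow(r1$matures), 20L)
  hplen <- nchar(r1$hairpins)[r1$matures$hairpin_id]
  expect_true(all(r1$matures$start >= 10))
  expect_true(all(hplen - r1$matures$end >= 10))
  # upstream dinucleotide is templated C so 5' extensions insert C
  up <- substr(r1$hairpins[r1$matures$hairpin_id],
               r1$matures$start - 1, r1$matures$start)
  expect_true(all(up == "CC"))
  expect_identical(nrow(simulate_reference(1, 2)$matures), 1L)
})

test_that("count simulation is seeded, skewed, and Poisson in the phi=0 limit", {
  cfg <- sim_config(n_mirnas = 30, dispersion = 0, de_fraction = 0,
                    library_size_mean = 5e6, library_size_cv = 0, seed = 4)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  # locus 1 holds approximately abundance_skew of all counts
  expect_equal(sum(s1$counts[1, ]) / sum(s1$counts), cfg$abundance_skew,
               tolerance = 0.02)
  # law of large numbers: proportions approach baseline abundances
  prop <- rowSums(s1$counts) / sum(s1$counts)
  expect_equal(unname(prop), s1$truth$baseline, tolerance = 0.02)
})

test_that("injected fold-changes are recovered from group-mean CPM", {
  set.seed(21)
  err <- replicate(20, {
    cfg <- sim_config(n_group_A = 50, n_group_B = 50, n_mirnas = 30,
                      library_size_mean = 1e6, dispersion = 0.2,
                      de_fraction = 1 / 30, de_log2fc_range = c(3, 3),
                      seed = sample.int(1e6, 1))
    s <- simulate_counts(cfg)
    lf <- group_log2fc(mir_counts(s$counts), s$groups)
    de_id <- s$truth$mature_id[s$truth$is_de]
    sgn <- sign(s$truth$true_log2fc[s$truth$is_de])
    lf$log2fc[lf$feature_id == de_id] * sgn - 3
  })
  # Monte-Carlo mean recovery; individual replicates carry compositional
  # CPM deflation plus sampling noise
  expect_lt(abs(mean(err)), 0.3)
})

test_that("read emission conserves counts and honors degenerate profiles", {
  ref <- simulate_reference(8, seed = 6)
  cfg <- sim_config(n_group_A = 2, n_group_B = 2, n_mirnas = 8,
                    library_size_mean = 800, dispersion = 0.1,
                    isomir_profile = c(canonical = 1, trim3 = 0, ext3 = 0,
                                       nta3 = 0, shift5 = 0, subst = 0),
                    seq_error_rate = 0, contaminant_fraction = 0, seed = 6)
  sim <- simulate_counts(cfg, ref)
  em <- emit_reads(sim, ref, cfg, tempfile("emit"))
  expect_identical(nrow(em$truth), sum(sim$counts))
  # canonical-only profile, no errors: every read equals its mature
  mats <- vapply(em$truth$mature_id, function(id) mature_sequence(ref, id),
                 character(1))
  expect_true(all(em$truth$sequence == mats))

  cfg_trim <- sim_config(n_group_A = 2, n_group_B = 2, n_mirnas = 8,
                         library_size_mean = 400, dispersion = 0,
                         isomir_profile = c(canonical = 0, trim3 = 1,
                                            ext3 = 0, nta3 = 0,
                                            shift5 = 0, subst = 0),
                         seq_error_rate = 0, contaminant_fraction = 0,
                         seed = 8)
  sim2 <- simulate_counts(cfg_trim, ref)
  em2 <- emit_reads(sim2, ref, cfg_trim, tempfile("emit"))
  mats2 <- vapply(em2$truth$mature_id, function(id) mature_sequence(ref, id),
                  character(1))
  expect_true(all(startsWith(mats2, em2$truth$sequence)))
  dlen <- nchar(mats2) - nchar(em2$truth$sequence)
  expect_true(all(dlen >= 1 & dlen <= 3))
})

test_that("contaminant reads are emitted, labelled, and tallied", {
  ref <- simulate_reference(5, seed = 9)
  cfg <- sim_config(n_group_A = 2, n_group_B = 2, n_mirnas = 5,
                    library_size_mean = 1000, dispersion = 0,
                    seq_error_rate = 0, contaminant_fraction = 0.2,
                    seed = 9)
  sim <- simulate_counts(cfg, ref)
  em <- emit_reads(sim, ref, cfg, tempfile("emit"))
  frac <- mean(em$truth$is_contaminant)
  expect_gt(frac, 0.1)
  expect_lt(frac, 0.3)
  expect_identical(sum(!em$truth$is_contaminant), sum(sim$counts))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(de_log2fc_range = c(1.5, 3)))
  expect_error(sim_config(isomir_profile = c(canonical = 0.5, trim3 = 0.4,
                                             ext3 = 0, nta3 = 0,
                                             shift5 = 0, subst = 0)),
               "sum to 1")
  expect_error(sim_config(n_group_A = 1))
  expect_error(sim_config(abundance_skew = 0.9))
})
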