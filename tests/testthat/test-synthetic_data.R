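small_params <- function(...) {
  defaults <- list(n_proteins = 60L, n_enriched = 4L, n_generic = 2L,
                   base_abundance = 2, seed = 5L)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

test_that("simulation parameters are validated", {
  expect_s3_class(sim_params(), "sim_params")
  expect_error(sim_params(n_enriched = 600),
               class = "nucenrich_validation_error")
  expect_error(sim_params(shared_peptide_fraction = 1),
               class = "nucenrich_validation_error")
  expect_error(sim_params(comparator_fold = 20, enrichment_fold = 10),
               class = "nucenrich_validation_error")
})

test_that("the planted truth is reproducible and satisfies its rate invariants", {
  p <- small_params()
  t1 <- simulate_truth(p)
  t2 <- simulate_truth(p)
  expect_equal(t1, t2)
  enriched <- t1[t1$enriched_vs_control & t1$enriched_vs_comparator, ]
  expect_equal(nrow(enriched), 4L)
  expect_true(all(enriched$rate_bait >=
                    p$enrichment_fold * enriched$rate_control))
  expect_true(all(enriched$rate_bait >=
                    p$comparator_fold * enriched$rate_comparator))
  background <- t1[!t1$enriched_vs_control, ]
  expect_true(all(background$rate_bait == background$rate_control &
                    background$rate_bait == background$rate_comparator))
  # no planted proteins when n_enriched = 0
  t0 <- simulate_truth(small_params(n_enriched = 0L, n_generic = 0L))
  expect_false(any(t0$enriched_vs_control))
})

test_that("simulated PSM tables are parseable, labelled, and byte-reproducible", {
  p <- small_params()
  tr <- simulate_truth(p)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_psm_tables(tr, p, out_dir = d1)
  s2 <- simulate_psm_tables(tr, p, out_dir = d2)
  expect_equal(nrow(s1$design), 9L)
  for (f in basename(s1$files)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  back <- read_psm_table(file.path(d1, "psm_H2AZ_rep1.tsv"))
  in_mem <- s1$psms[s1$psms$run_id == "H2AZ_rep1", ]
  expect_equal(nrow(back), nrow(in_mem))
  expect_equal(back$peptide, in_mem$peptide)
  design_back <- read_design(file.path(d1, "design.tsv"))
  expect_equal(design_back$condition, s1$design$condition)
  db_back <- read_protein_db(file.path(d1, "proteins.fasta"))
  expect_equal(sum(db_back$is_decoy), p$n_proteins)  # length-matched decoys
  expect_equal(unname(nchar(db_back$sequences[1:5])),
               unname(nchar(db_back$sequences[p$n_proteins + 1:5])))
})

test_that("a zero-abundance screen yields empty PSM tables", {
  p <- small_params(base_abundance = 0, n_enriched = 0L, n_generic = 0L,
                    incorrect_psm_rate = 0)
  s <- simulate_psm_tables(simulate_truth(p), p)
  expect_equal(nrow(s$psms), 0L)
})

test_that("with no incorrect PSMs the FDR filter keeps essentially all targets", {
  p <- small_params(incorrect_psm_rate = 0)
  s <- simulate_psm_tables(simulate_truth(p), p)
  expect_equal(sum(s$psms$is_decoy), 0L)
  sel <- select_threshold(s$psms, nominal_fdr = 0.01)
  expect_equal(sel$n_target_accepted, nrow(s$psms))
})

test_that("recovery metrics match their definitions on explicit cases", {
  p <- small_params()
  tr <- simulate_truth(p)
  s <- simulate_psm_tables(tr, p)
  run <- suppressMessages(
    run_pipeline(pipeline_config(), psms = s$psms, design = s$design))
  rec <- evaluate_recovery(run$result, tr)
  expect_gte(rec$sensitivity, 0)
  expect_lte(rec$sensitivity, 1)
  expect_equal(rec$n_enriched, 4L)

  # empty survivor set: sensitivity 0
  empty <- run$result
  empty$stage2_survivors <- integer(0)
  expect_equal(evaluate_recovery(empty, tr)$sensitivity, 0)

  # survivors exactly the planted set: sensitivity 1, no false positives
  enriched <- tr$accession[tr$enriched_vs_control & tr$enriched_vs_comparator]
  ids <- run$result$groups$group_id[
    vapply(run$result$groups$members, function(m) any(m %in% enriched), TRUE)]
  exact <- run$result
  exact$stage2_survivors <- ids
  rec2 <- evaluate_recovery(exact, tr)
  expect_equal(rec2$sensitivity, 1)
  expect_equal(rec2$n_false_positive_groups, 0L)

  # unknown accession in the result is a validation error
  bad <- run$result
  bad$groups$members[[match(bad$stage2_survivors[1], bad$groups$group_id)]] <-
    "NOT_IN_TRUTH"
  expect_error(evaluate_recovery(bad, tr),
               class = "nucenrich_validation_error")
})
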