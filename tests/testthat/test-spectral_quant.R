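triplicate_design <- function() {
  experiment_design(
    run_id = c("Z1", "Z2", "Z3", "A1", "A2", "A3", "G1", "G2", "G3"),
    condition = rep(c("H2A.Z", "H2A", "GFP"), each = 3),
    replicate = rep(1:3, 3))
}

test_that("razor assignment follows unique-evidence strength with lexicographic ties", {
  # PA: 3 unique peptides; PB: 1 unique; PEPE shared between both groups
  m <- list(PEPA = "PA", PEPC = "PA", PEPD = "PA", PEPE = c("PA", "PB"),
            PEPF = "PB", PEPG = "PB")
  g <- group_proteins(m)
  psms <- pepmap_psms(m, run_id = "Z1")
  a <- assign_razor(g, psms)
  id_of <- function(rep) g$group_id[g$representative == rep]
  expect_equal(a[psms$peptide == "PEPA"], id_of("PA"))
  expect_equal(a[psms$peptide == "PEPF"], id_of("PB"))
  # shared peptide goes to the group with more unique peptides
  expect_equal(a[psms$peptide == "PEPE"], id_of("PA"))

  # tie on unique count: lexicographically smaller representative wins
  m2 <- list(PEPA = "PA", PEPC = "PA", PEPD = "PB", PEPE = "PB",
             PEPF = c("PA", "PB"))
  g2 <- group_proteins(m2)
  psms2 <- pepmap_psms(m2, run_id = "Z1")
  a2 <- assign_razor(g2, psms2)
  expect_equal(a2[psms2$peptide == "PEPF"],
               g2$group_id[g2$representative == "PA"])
})

test_that("PSMs of peptides outside all surviving groups stay unassigned", {
  m <- list(PEPA = "PA", PEPC = "PA", PEPD = "PB")
  g <- apply_two_peptide_rule(group_proteins(m))  # PB's group dropped
  psms <- pepmap_psms(m, run_id = "Z1")
  a <- assign_razor(g, psms)
  expect_true(is.na(a[psms$peptide == "PEPD"]))
  expect_equal(sum(!is.na(a)), 2L)
})

test_that("the count matrix conserves assigned spectra over full design columns", {
  design <- triplicate_design()
  m <- list(PEPA = "PA", PEPC = "PA")
  g <- group_proteins(m)
  psms <- psm_table(
    run_id = rep("Z1", 3), spectrum_id = c("s1", "s2", "s3"),
    peptide = c("PEPA", "PEPA", "PEPC"), charge = rep(2L, 3),
    score = rep(1e-6, 3), proteins = rep(list("PA"), 3))
  a <- assign_razor(g, psms)
  sc <- count_matrix(g, a, psms, design)
  expect_equal(dim(sc$counts), c(1L, 9L))
  expect_equal(unname(sc$counts["1", ]), c(3L, rep(0L, 8)))
  expect_equal(sum(sc$counts), sum(!is.na(a)))

  # empty assignment keeps the full column set
  sc0 <- count_matrix(g, integer(0), psms[0, ], design)
  expect_equal(dim(sc0$counts), c(1L, 9L))
  expect_true(all(sc0$counts == 0L))

  # run absent from the design is a validation error
  stray <- psm_table("elsewhere", "s9", "PEPA", 2L, 1e-6, list("PA"))
  expect_error(count_matrix(g, 1L, stray, design),
               "elsewhere", class = "nucenrich_validation_error")
})

test_that("detection thresholds at a single spectrum", {
  design <- triplicate_design()
  counts <- matrix(c(5L, 7L, 0L, rep(0L, 6)), nrow = 1,
                   dimnames = list(NULL, design$run_id))
  sc <- spectral_counts(counts, design, representative = "PA")
  d <- detection_matrix(sc)
  expect_equal(unname(d[1, 1:3]), c(TRUE, TRUE, FALSE))
  # scaling counts never changes detection
  sc5 <- spectral_counts(counts * 5L, design, representative = "PA")
  expect_equal(detection_matrix(sc5), d)
})

test_that("permuting replicate labels within a condition leaves verdicts unchanged", {
  for (seed in c(2, 9)) {
    sc <- random_counts(n_groups = 30, seed = seed, lambda = 4)
    res <- run_cascade(sc, fold1 = 1.5, fold2 = 1.2, min_runs = 2)
    perm_design <- sc$design
    # swap replicates 1 and 3 inside the bait condition
    bait <- which(perm_design$condition == "BAIT")
    perm <- seq_len(nrow(perm_design))
    perm[bait] <- bait[c(3, 2, 1)]
    sc2 <- spectral_counts(sc$counts[, perm, drop = FALSE],
                           experiment_design(perm_design$run_id[perm],
                                             perm_design$label[perm],
                                             perm_design$replicate),
                           representative = sc$groups$representative)
    res2 <- run_cascade(sc2, fold1 = 1.5, fold2 = 1.2, min_runs = 2)
    expect_equal(res$stage1_survivors, res2$stage1_survivors)
    expect_equal(res$stage2_survivors, res2$stage2_survivors)
  }
})
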