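test_that("fold enrichment is a ratio of amalgamated sums with Inf/undefined edges", {
  m <- fixture_counts()
  fold_ctrl <- fold_enrichment(m, cond_b = "CONTROL")
  expect_equal(unname(fold_ctrl["1"]), 60 / 3)
  expect_equal(unname(fold_ctrl["2"]), Inf)   # 27 / 0
  fold_cmp <- fold_enrichment(m, cond_b = "COMPARATOR")
  expect_equal(unname(fold_cmp["1"]), 2.0)
  expect_equal(unname(fold_cmp["3"]), 93 / 165)
  # group absent from bait and comparator would be 0/positive = 0
  expect_equal(unname(fold_cmp["6"]), 0)
  expect_error(fold_enrichment(m, cond_b = "MOCK"),
               class = "nucenrich_validation_error")

  # 0/0 fold is undefined and fails every threshold
  design <- experiment_design(c("Z1", "A1", "G1"),
                              c("BAIT", "COMPARATOR", "CONTROL"),
                              c(1, 1, 1))
  counts <- matrix(c(0L, 0L, 4L), 1, dimnames = list(NULL, design$run_id))
  m0 <- spectral_counts(counts, design, representative = "PA")
  expect_true(is.nan(fold_enrichment(m0, cond_b = "COMPARATOR")[[1]]))
  expect_equal(length(stage_filter(m0, "BAIT", "COMPARATOR",
                                   fold_min = 0.001, min_runs = 1)), 0L)
})

test_that("a stage filter combines the fold rule with bait-run presence", {
  design <- experiment_design(
    run_id = c("Z1", "Z2", "Z3", "G1", "G2", "G3"),
    condition = rep(c("BAIT", "CONTROL"), each = 3), replicate = rep(1:3, 2))
  counts <- rbind(c(5, 7, 0, 0, 0, 0),    # Inf fold, 2/3 runs -> pass
                  c(12, 0, 0, 0, 0, 0),   # Inf fold, 1/3 runs -> fail
                  c(4, 4, 4, 2, 1, 2))    # fold 12/5 = 2.4 -> fail at 10
  colnames(counts) <- design$run_id
  m <- spectral_counts(counts, design, representative = c("PA", "PB", "PC"))
  surv <- stage_filter(m, "BAIT", "CONTROL", fold_min = 10, min_runs = 2)
  expect_equal(surv, 1L)
  # at a permissive fold the presence rule still bites
  expect_equal(stage_filter(m, "BAIT", "CONTROL", fold_min = 2, min_runs = 2),
               c(1L, 3L))
  expect_error(stage_filter(m, "BAIT", "CONTROL", 10, min_runs = 4),
               class = "nucenrich_validation_error")
})

test_that("the packaged six-group fixture reproduces its hand-derived verdicts", {
  m <- fixture_counts()
  res <- run_cascade(m)  # defaults: fold1 10, fold2 2, min_runs 2
  expect_equal(res$stage1_survivors, c(1L, 2L, 3L))
  expect_equal(res$stage2_survivors, c(1L, 2L))
  expect_equal(unname(res$funnel), c(6L, 3L, 2L))
  fv <- res$fold_values
  expect_equal(unname(fv["1", ]), c(20, 2))
  expect_equal(unname(fv["2", ]), c(Inf, Inf))
  expect_equal(unname(fv["3", ]), c(15.5, 93 / 165))
  expect_equal(unname(fv["5", ]), c(2.5, Inf))
  expect_equal(unname(res$overlap_counts),
               c(2L, 0L, 0L, 0L, 1L, 1L, 2L))
})

test_that("an all-zero matrix yields an empty funnel", {
  design <- fixture_counts()$design
  counts <- matrix(0L, nrow = 0, ncol = 9,
                   dimnames = list(NULL, design$run_id))
  m <- spectral_counts(counts, design, representative = character(0))
  res <- run_cascade(m)
  expect_equal(unname(res$funnel), c(0L, 0L, 0L))
})

test_that("a cascade without all three conditions is refused", {
  design <- experiment_design(c("Z1", "G1"), c("BAIT", "CONTROL"), c(1, 1))
  counts <- matrix(1L, 1, 2, dimnames = list(NULL, design$run_id))
  m <- spectral_counts(counts, design, representative = "PA")
  expect_error(run_cascade(m, min_runs = 1),
               "COMPARATOR", class = "nucenrich_validation_error")
})

test_that("Venn regions partition the union of detected sets", {
  ov <- overlap_sets(list(BAIT = c("A", "B"), COMPARATOR = "B",
                          CONTROL = character(0)))
  expect_equal(unname(ov["BAIT_only"]), 1L)
  expect_equal(unname(ov["BAIT_COMPARATOR"]), 1L)
  expect_equal(sum(ov), 2L)
  same <- overlap_sets(list(BAIT = c("A", "B"), COMPARATOR = c("A", "B"),
                            CONTROL = c("B", "A")))
  expect_equal(unname(same["ALL_THREE"]), 2L)
  expect_equal(sum(same), 2L)
  set.seed(5)
  for (i in 1:20) {
    sets <- lapply(1:3, function(j) sample(LETTERS, sample(0:10, 1)))
    names(sets) <- c("BAIT", "COMPARATOR", "CONTROL")
    expect_equal(sum(overlap_sets(sets)),
                 length(unique(unlist(sets))))
  }
})

test_that("funnel and threshold monotonicity hold on random matrices", {
  for (seed in 1:60) {
    sc <- random_counts(n_groups = sample(5:25, 1), seed = 300 + seed,
                        lambda = sample(1:5, 1))
    f1 <- runif(1, 1, 5); f2 <- runif(1, 1, 3)
    mr <- sample(1:3, 1)
    res <- run_cascade(sc, fold1 = f1, fold2 = f2, min_runs = mr)
    expect_true(all(res$stage2_survivors %in% res$stage1_survivors))
    expect_lte(res$funnel["n_stage2"], res$funnel["n_stage1"])
    expect_lte(res$funnel["n_stage1"], res$funnel["n_input"])
    # raising thresholds never enlarges survivor sets
    harder <- run_cascade(sc, fold1 = f1 * 2, fold2 = f2 * 1.5,
                          min_runs = min(mr + 1L, 3L))
    expect_true(all(harder$stage1_survivors %in% res$stage1_survivors))
    expect_true(all(harder$stage2_survivors %in% res$stage2_survivors))
    # scaling every count by a positive integer changes no verdict
    scaled <- spectral_counts(sc$counts * 3L, sc$design,
                              representative = sc$groups$representative)
    res_s <- run_cascade(scaled, fold1 = f1, fold2 = f2, min_runs = mr)
    expect_equal(res_s$stage1_survivors, res$stage1_survivors)
    expect_equal(res_s$stage2_survivors, res$stage2_survivors)
  }
})
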