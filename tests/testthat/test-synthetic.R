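test_that("cohort generation is bit-reproducible under a fixed seed", {
  cfg <- cohort_config(seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # a different seed changes the draw
  expect_false(identical(generate_cohort(cfg),
                         generate_cohort(cohort_config(seed = 100))))
})

test_that("default cohort has the 6/8/12 layout with consistent groups", {
  cohort <- generate_cohort(cohort_config(seed = 3))
  expect_equal(nrow(cohort), 26L)
  expect_equal(as.vector(table(cohort$group)), c(6L, 8L, 12L))
  expect_equal(response_group(cohort$bv_pre, cohort$dsuv_max), cohort$group)
  # SUV change column is exactly the pre/post percent change
  expect_equal(percent_change(cohort$suv_pre, cohort$suv_post),
               cohort$dsuv_max)
  # group-1 blood volume above threshold, others below, with the buffer gap
  expect_true(all(cohort$bv_pre[cohort$group == 1] >= 9.3 + 0.93))
  expect_true(all(cohort$bv_pre[cohort$group != 1] <= 9.3 - 0.93))
  # perfusion truth respects the central volume principle
  expect_equal(cohort$bf_pre, cohort$bv_pre * 60 / cohort$mtt_pre)
})

test_that("large cohorts realise the configured group pCR rates", {
  cfg <- cohort_config(n_patients = 1000, seed = 17)
  cohort <- generate_cohort(cfg)
  for (g in 1:3) {
    sel <- cohort$group == g
    n <- sum(sel)
    p <- cfg$pcr_probs[g]
    se <- sqrt(max(p * (1 - p), 1e-12) / n)
    expect_lt(abs(mean(cohort$pcr[sel]) - p), max(3 * se, 1e-9))
  }
})

test_that("infeasible truncation bounds are flagged", {
  cfg <- cohort_config(bv_high = c(mean = 0.1, sd = 0.01), seed = 1)
  expect_error(generate_cohort(cfg), "infeasible")
})

test_that("zero noise reproduces the forward curves exactly", {
  kin <- kinetic_params(0.15, 0.4, 0.06, 0.01, vb = 0.05, Tc = 6)
  per <- perfusion_params(50, 6, 0.2, 0.01)
  cur <- generate_patient_curves(kin, per, pet_noise_coef = 0,
                                 ctp_noise_sd = 0, seed = 1)
  expect_identical(cur$pet$values, cur$pet_true$values)
  expect_identical(cur$ctp$values, cur$ctp_true$values)
})

test_that("PET frame noise scales down with frame duration", {
  sd5 <- sabresponse:::pet_noise_sd(10, 5, coef = 2)
  sd300 <- sabresponse:::pet_noise_sd(10, 300, coef = 2)
  expect_gt(sd5, sd300)
  expect_equal(sd5 / sd300, sqrt(300 / 5))
  # and with the configured coefficient, replicate curves differ per frame
  kin <- kinetic_params(0.15, 0.4, 0.06, 0.01, vb = 0.05, Tc = 6)
  per <- perfusion_params(50, 6, 0.2, 0.01)
  a <- generate_patient_curves(kin, per, seed = 5)
  b <- generate_patient_curves(kin, per, seed = 6)
  expect_false(identical(a$pet$values, b$pet$values))
  expect_identical(a$pet_true$values, b$pet_true$values)
})

test_that("the reference cohort is the unique table matching printed margins", {
  ref <- reference_cohort()
  expect_equal(nrow(ref), 26L)
  expect_equal(sum(ref$pcr), 13L)
  expect_equal(as.vector(table(ref$group)), c(6L, 8L, 12L))
  counts <- tapply(ref$pcr, ref$group, sum)
  expect_equal(as.vector(counts), c(0L, 2L, 11L))
  # exhaustive search: the only non-negative integer cell counts compatible
  # with group sizes 6/8/12, rounded rates 0/25/92% and 13 events in total
  feasible <- list()
  for (a in 0:6) for (b in 0:8) for (c in 0:12) {
    if (a + b + c != 13) next
    if (round(100 * a / 6) != 0) next
    if (round(100 * b / 8) != 25) next
    if (round(100 * c / 12) != 92) next
    feasible[[length(feasible) + 1]] <- c(a, b, c)
  }
  expect_equal(feasible, list(c(0, 2, 11)))
  # PERCIST responder column realises the published 85% / 31% operating point
  cm <- confusion_metrics(ref$percist_responder, ref$pcr)
  expect_equal(cm$tp, 11L)
  expect_equal(cm$tn, 4L)
})
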