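test_that("cohort generation is seeded and reproducible with the study group sizes", {
  spec <- default_cohort_spec(seed = 4L)
  a <- make_cohort(spec)
  b <- make_cohort(spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 38)  # 8 controls + 30 PH
  expect_equal(as.vector(table(a$group)[c("control", "idiopathic",
                                          "hereditary", "other_PH")]),
               c(8, 9, 12, 9))
})

test_that("cohort spec validation rejects malformed inputs", {
  m <- list(a = list(dist = "norm", mean = 0, sd = 1),
            b = list(dist = "norm", mean = 0, sd = 1),
            c = list(dist = "norm", mean = 0, sd = 1))
  expect_error(cohort_spec(list(g1 = list(n = 1, measures = m),
                                g2 = list(n = 5, measures = m))),
               ">= 2")
  m2 <- m; names(m2) <- c("a", "b", "d")
  expect_error(cohort_spec(list(g1 = list(n = 5, measures = m),
                                g2 = list(n = 5, measures = m2))),
               "same measures")
  ## a correlation triangle that cannot exist
  rc <- diag(3); dimnames(rc) <- list(names(m), names(m))
  rc["a", "b"] <- rc["b", "a"] <- 0.9
  rc["b", "c"] <- rc["c", "b"] <- 0.9
  rc["a", "c"] <- rc["c", "a"] <- -0.9
  expect_error(cohort_spec(list(g1 = list(n = 5, measures = m),
                                g2 = list(n = 5, measures = m)),
                           rank_cor = rc),
               "positive semidefinite")
})

test_that("marginals converge to their configured parameters", {
  spec <- default_cohort_spec(n_control = 4000, n_idiopathic = 4000,
                              n_hereditary = 4, n_other = 4, seed = 12L)
  co <- make_cohort(spec)
  ph <- co[co$group == "idiopathic", ]
  ct <- co[co$group == "control", ]
  expect_lt(abs(mean(ph$lung_suvm) - 0.50), 0.01)
  expect_lt(abs(sd(ph$lung_suvm) - 0.15), 0.01)
  expect_lt(abs(mean(ct$lung_suvm) - 0.37), 0.01)
  expect_lt(abs(mean(ph$lung_suvt) - 2.13), 0.04)
  expect_lt(abs(mean(ph$rv_lv_ratio) - 1.20), 0.04)
  ## log-normal NT-proBNP: positive and heavy-tailed
  expect_true(all(co$ntprobnp > 0))
  expect_gt(mean(ph$ntprobnp), median(ph$ntprobnp))
})

test_that("independent measures show near-zero sample rank correlation", {
  m <- default_cohort_spec()$groups$control$measures
  spec <- cohort_spec(list(control = list(n = 4000, measures = m),
                           ph = list(n = 4, measures = m)),
                      rank_cor = NULL, seed = 5L)
  co <- make_cohort(spec)
  ct <- co[co$group == "control", ]
  expect_lt(abs(cor(ct$lung_suvm, ct$ntprobnp, method = "spearman")), 0.05)
  expect_lt(abs(cor(ct$rv_lv_ratio, ct$camphor, method = "spearman")), 0.05)
})

test_that("requested rank correlations are realized by the copula", {
  m <- default_cohort_spec()$groups$control$measures
  rc <- diag(length(m)); dimnames(rc) <- list(names(m), names(m))
  rc["rv_lv_ratio", "ntprobnp"] <- rc["ntprobnp", "rv_lv_ratio"] <- 0.8
  spec <- cohort_spec(list(control = list(n = 10000, measures = m),
                           ph = list(n = 4, measures = m)),
                      rank_cor = rc, seed = 6L)
  co <- make_cohort(spec)
  ct <- co[co$group == "control", ]
  expect_lt(abs(cor(ct$rv_lv_ratio, ct$ntprobnp, method = "spearman") - 0.8),
            0.05)
})

test_that("derived subject fields respect their physiological identities", {
  co <- make_cohort(default_cohort_spec(seed = 13L))
  expect_true(all(co$rvesv <= co$rvedv))
  expect_true(all(co$rvesv >= 0))
  expect_equal(co$rv_sv, co$rvedv - co$rvesv)
  expect_true(all(co$rvsp >= co$rap))
  expect_true(all(co$rvot_tvi > 0))
  expect_true(all(co$rves_area <= co$rved_area))
  expect_true(all(co$hr_1min_recovery > 0))
  ## explicit missingness: exactly two PH strain values are NA
  expect_equal(sum(is.na(co$strain)), 2)
  expect_true(all(co$group[is.na(co$strain)] != "control"))
})
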