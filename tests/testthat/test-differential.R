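test_that("signed fold changes follow the negative-reciprocal convention", {
  expect_equal(patient_fold_change(200, 100), 2)
  expect_equal(patient_fold_change(100, 200), -2)
  expect_equal(patient_fold_change(100, 100), 1)  # ratio 1 maps to +1
  expect_error(patient_fold_change(0, 10), "positive")
  expect_error(patient_fold_change(10, -1), "positive")

  set.seed(3)
  a <- stats::runif(50, 1, 1000)
  b <- stats::runif(50, 1, 1000)
  fab <- patient_fold_change(a, b)
  fba <- patient_fold_change(b, a)
  expect_true(all(abs(fab) >= 1))
  ne <- a != b
  expect_equal(abs(fab[ne]), abs(fba[ne]))
  expect_true(all(sign(fab[ne]) == -sign(fba[ne])))
})

test_that("log fold change is antisymmetric around zero", {
  expect_equal(ln_fold(2), log(2))
  expect_equal(ln_fold(-2), -log(2))
  expect_equal(ln_fold(1), 0)
  expect_error(ln_fold(0), "nonzero")
})

test_that("call filtering excludes Absent/Absent pairs and re-includes
           all-absent rows", {
  # five pairs absent in both tissues, four with data
  tc <- c("A", "A", "A", "P", "A", "A", "P", "A", "P")
  nc <- c("A", "A", "A", "A", "A", "A", "P", "M", "P")
  cf <- call_filter(tc, nc)
  expect_equal(sum(cf$included), 4L)
  expect_false(cf$all_absent)

  # three A/A pairs among nine
  tc2 <- c("P", "A", "A", "P", "P", "P", "A", "P", "P")
  nc2 <- c("P", "A", "A", "P", "P", "P", "A", "P", "P")
  cf2 <- call_filter(tc2, nc2)
  expect_equal(sum(cf2$included), 6L)

  # every pair absent: everyone is re-included, flagged
  cf3 <- call_filter(rep("A", 9), rep("A", 9))
  expect_equal(sum(cf3$included), 9L)
  expect_true(cf3$all_absent)

  # strict mode drops any pair with a single Absent call
  cfs <- call_filter(c("P", "A", "P"), c("P", "P", "A"), strict = TRUE)
  expect_equal(cfs$included, c(TRUE, FALSE, FALSE))

  # no calls at all: everyone included
  expect_true(all(call_filter(NULL, NULL)$included %in% TRUE))
})

test_that("sign-aware averaging reproduces published golden rows", {
  eno2 <- c(52.71, 80.66, 10.03, 7.57, 22.03, 46.03, 9.81, 25.29, 50.01)
  expect_equal(aggregate_fold_change(eno2), 33.79, tolerance = 0.0005)
  pfkfb2 <- c(-3.96, -5.78, -4.27, -8.35, -7.19, -8.58, -2.78, -3.39, -4.27)
  expect_equal(aggregate_fold_change(pfkfb2), -5.02, tolerance = 0.0005)
  pklr <- c(-10.99, -12.13, -4.63)
  expect_equal(aggregate_fold_change(pklr), -8.51, tolerance = 0.005)
})

test_that("averaging is idempotent, permutation invariant and antisymmetric", {
  expect_equal(aggregate_fold_change(rep(3.7, 5)), 3.7)    # arithmetic branch
  expect_equal(aggregate_fold_change(rep(-3.7, 5)), -3.7)  # geometric branch
  expect_error(aggregate_fold_change(numeric()), "empty")

  set.seed(21)
  for (i in 1:200) {
    n <- sample(2:9, 1)
    fcs <- sample(c(-1, 1), n, TRUE) * stats::runif(n, 1, 50)
    a <- aggregate_fold_change(fcs)
    expect_equal(aggregate_fold_change(sample(fcs)), a)
    if (any(fcs < 0) && any(fcs > 0)) {
      # both branches stay geometric, so flipping every sign negates the result
      expect_equal(aggregate_fold_change(-fcs), -a)
    }
  }
})

test_that("an all-negative row equals minus the geometric mean of magnitudes", {
  set.seed(5)
  for (i in 1:100) {
    mags <- stats::runif(sample(2:9, 1), 1, 100)
    expect_equal(aggregate_fold_change(-mags), -exp(mean(log(mags))))
  }
})

test_that("adding a patient at the current mean leaves the average unchanged", {
  set.seed(9)
  for (i in 1:50) {
    fcs <- stats::runif(sample(2:8, 1), 1, 20)
    m <- aggregate_fold_change(fcs)
    expect_equal(aggregate_fold_change(c(fcs, m)), m)
  }
})

test_that("scaling all tumor signals up never decreases the average", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(3:9, 1)
    tum <- stats::runif(n, 10, 1000)
    nor <- stats::runif(n, 10, 1000)
    k <- stats::runif(1, 1, 10)
    a0 <- aggregate_fold_change(patient_fold_change(tum, nor))
    a1 <- aggregate_fold_change(patient_fold_change(k * tum, nor))
    expect_gte(a1, a0 - 1e-9)
  }
})

test_that("the t-test on log fold changes matches the published example and
           an incomplete-beta reference", {
  pfkp <- c(13.30, 5.84, 4.69, 6.85, 8.86, 8.85, 6.74, 9.76, 7.11)
  res <- t_test_ln_fc(pfkp)
  expect_equal(res$p_value, 4.23e-08, tolerance = 0.002)
  expect_equal(res$df, 8)

  # symmetric pair: t = 0, p = 1
  expect_equal(t_test_ln_fc(c(2, -2))$p_value, 1)

  # degenerate inputs are flagged, not errors and never p = 0
  expect_equal(t_test_ln_fc(3.2)$flag, "n_too_small")
  expect_true(is.na(t_test_ln_fc(3.2)$p_value))
  zv <- t_test_ln_fc(rep(2.5, 6))
  expect_equal(zv$flag, "zero_variance")
  expect_true(is.na(zv$p_value))

  # reference: two-tailed p via the regularized incomplete beta function
  set.seed(31)
  for (i in 1:200) {
    fcs <- sample(c(-1, 1), 6, TRUE) * stats::runif(6, 1, 30)
    res <- t_test_ln_fc(fcs)
    lf <- sign(fcs) * log(abs(fcs))
    tt <- mean(lf) / (stats::sd(lf) / sqrt(6))
    p_ref <- stats::pbeta(5 / (5 + tt^2), 5 / 2, 1 / 2)
    expect_equal(res$p_value, p_ref, tolerance = 1e-9)
    expect_gt(res$p_value, 0)
    expect_lte(res$p_value, 1)
  }
})

test_that("gene summaries classify by the strict two-fold rule", {
  s <- summarize_gene("SLC2A1",
                      c(2.15, 1.49, 1.64, 1.29, 1.80, 3.99, 1.17, 3.72, 3.38))
  expect_equal(s$avg_fc, 2.29, tolerance = 0.005)
  expect_equal(s$de_class, "over")
  expect_true(s$significant)

  s2 <- summarize_gene("LDHB",
                       c(-2.27, -1.35, -1.84, -2.05, -3.05, -1.92, -1.74,
                         -1.98, -1.18))
  expect_equal(s2$de_class, "unchanged")  # -1.87: inside the band
  expect_true(s2$significant)             # yet statistically significant

  expect_equal(summarize_gene("x", rep(2, 4))$de_class, "unchanged")  # strict >
  expect_equal(summarize_gene("x", rep(-2, 4))$de_class, "unchanged")
  expect_false(summarize_gene("x", c(1, -1, 1, -1), all_absent = TRUE)$reliable)
})

test_that("the model fit reproduces its building blocks and its methods are
           coherent", {
  set.seed(77)
  pt <- planted_gene_table(n_patients = 5, n_genes = 12, effect = 1.5)
  fit <- warburg_de(pt$table, pt$pairing)
  expect_s3_class(fit, "warburg_de")
  g <- pt$table$probe_ids[1]
  direct <- aggregate_fold_change(
    patient_fold_change(pt$table$signal[g, pt$pairing$tumor],
                        pt$table$signal[g, pt$pairing$normal]))
  expect_equal(unname(coef(fit)[g]), direct)

  sm <- summary(fit)
  expect_s3_class(sm, "summary.warburg_de")
  expect_equal(abs(sm$avg_fc[1]), max(abs(fit$summary$avg_fc)))
  expect_true(all(diff(abs(sm$avg_fc)) <= 1e-12))

  r <- residuals(fit)
  expect_equal(dim(r), dim(fit$fc))
  expect_equal(unname(rowMeans(r, na.rm = TRUE)), rep(0, nrow(r)))

  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(fit$fc))
  expect_true(all(abs(sims[[1]][!is.na(sims[[1]])]) >= 1))

  expect_output(print(fit), "differential expression")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_de_table(fit, f)
  expect_true(file.exists(f))
})

test_that("fitting from a fold-change matrix honors sentinels and footnotes", {
  fc <- rbind(PKLR = c(-10.99, NA, -12.13, NA, NA, NA, NA, -4.63, NA),
              PCK1 = c(-11.87, -10.50, -15.28, -2.88, -13.13, -5.94, -4.52,
                       -21.55, -1086.66))
  colnames(fc) <- paste0("p", c(2, 3, 4, 5, 6, 9, 10, 11, 12))
  fit <- warburg_de_fc(fc, exclude = list(PCK1 = "p12"))
  sm <- fit$summary
  expect_equal(sm$avg_fc[sm$gene == "PKLR"], -8.51, tolerance = 0.005)
  expect_equal(sm$n_used[sm$gene == "PKLR"], 3L)
  expect_equal(sm$avg_fc[sm$gene == "PCK1"], -8.96, tolerance = 0.005)
  expect_equal(sm$n_used[sm$gene == "PCK1"], 8L)
})
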