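make_feature_fixture <- function(seed = 1, n = 40, n_pi = 64, n_dca = 40) {
  withr::with_seed(seed, {
    clin <- as_clinical_table(tibble::tibble(
      patient_id = sprintf("P%02d", seq_len(n)),
      gender = sample(c("M", "F"), n, TRUE),
      age = rnorm(n, 65, 10),
      morphological_grade = sample(1:4, n, TRUE),
      tnm_stage = sample(1:3, n, TRUE),
      albumin = rnorm(n, 40, 4), alkaline_phosphatase = abs(rnorm(n, 2, 1)),
      calcium = rnorm(n, 2.3, 0.1), creatinine = rnorm(n, 80, 15),
      ggt = abs(rnorm(n, 1, 1)), hemoglobin = rnorm(n, 135, 15),
      thrombocyte_count = rnorm(n, 260, 70), tumor_diameter = abs(rnorm(n, 60, 30))
    ))
    pi_ids <- sprintf("cg%05d", seq_len(n_pi))
    pim <- matrix(runif(n_pi * n), n_pi, n,
                  dimnames = list(pi_ids, clin$patient_id))
    pi_betas <- dplyr::bind_cols(tibble::tibble(probe_id = pi_ids),
                                 tibble::as_tibble(pim))
    cons <- dplyr::bind_cols(
      tibble::tibble(sample_id = clin$patient_id),
      tibble::as_tibble(matrix(runif(n * n_dca), n, n_dca,
                               dimnames = list(NULL, sprintf("DCA_%02d", seq_len(n_dca)))))
    )
    list(clin = clin, pi_betas = pi_betas, pi_ids = pi_ids, cons = cons)
  })
}

test_that("the six feature sets have the documented shapes", {
  fx <- make_feature_fixture()
  tri <- assemble_features(fx$clin, fx$pi_betas, fx$cons, "triple", fx$pi_ids)
  expect_identical(ncol(tri) - 1L, 12L + 64L + 40L)   # 116 columns
  expect_identical(ncol(assemble_features(fx$clin, set_name = "clinical")) - 1L, 12L)
  expect_identical(ncol(assemble_features(fx$clin, consensus = fx$cons,
                                          set_name = "dca")) - 1L, 40L)
  expect_identical(ncol(assemble_features(fx$clin, fx$pi_betas, set_name = "pi",
                                          pi_cpg_ids = fx$pi_ids)) - 1L, 64L)
  expect_identical(ncol(assemble_features(fx$clin, fx$pi_betas,
                                          set_name = "clinical+pi")) - 1L, 76L)
  expect_identical(ncol(assemble_features(fx$clin, consensus = fx$cons,
                                          set_name = "clinical+dca")) - 1L, 52L)
  # idempotence, alias, and validation
  expect_identical(assemble_features(fx$clin, fx$pi_betas, fx$cons, "triple", fx$pi_ids), tri)
  expect_identical(assemble_features(fx$clin, fx$pi_betas, fx$cons,
                                     "clinical+PI-CpGs+DCA", fx$pi_ids), tri)
  expect_error(assemble_features(fx$clin, set_name = "kitchen-sink"), "Unknown feature set")
  expect_error(assemble_features(fx$clin, fx$pi_betas, set_name = "pi",
                                 pi_cpg_ids = c(fx$pi_ids, "cg99999")), "cg99999")
  kinds <- attr(tri, "kinds")
  expect_identical(unname(kinds[c("gender", "morphological_grade", "tnm_stage")]),
                   rep("ordinal", 3))
  expect_identical(unname(kinds["age"]), "continuous")
})

test_that("PCA standardizes continuous and only centers ordinal columns", {
  fx <- make_feature_fixture()
  f <- assemble_features(fx$clin, set_name = "clinical")
  pca <- fit_pca(f, n_components = 5)
  expect_equal(unname(pca$scale["morphological_grade"]), 1)
  expect_equal(unname(pca$scale["tnm_stage"]), 1)
  expect_equal(unname(pca$scale["age"]), sd(f$age))
  expect_equal(unname(pca$center["age"]), mean(f$age))
  # variance is conserved by the rotation
  x <- as.matrix(f[-1])
  xs <- sweep(sweep(x, 2, pca$center), 2, pca$scale, "/")
  expect_equal(sum(pca$sdev^2), sum(apply(xs, 2, var)))
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(pca$rotation))) {
    expect_gt(pca$rotation[which.max(abs(pca$rotation[, j])), j], 0)
  }
})

test_that("rank-1 input loads fully on the first component", {
  withr::local_seed(5)
  a <- rnorm(30)
  f <- tibble::tibble(patient_id = as.character(1:30),
                      x1 = a, x2 = 2 * a + 3, x3 = rnorm(30),
                      x4 = rnorm(30), x5 = rnorm(30))
  # x1 and x2 perfectly correlated: in the 2-column sub-case PC1 carries all
  sub <- f[c("patient_id", "x1", "x2")]
  pca <- fit_pca(sub, n_components = 2)
  expect_equal(pca$sdev[1]^2 / sum(pca$sdev^2), 1, tolerance = 1e-10)
  # zero-variance continuous column is an error naming it
  f$flat <- 1
  expect_error(fit_pca(f, n_components = 5), "flat")
})

test_that("spectral oracle: orthonormal columns give a rotation-faithful score", {
  withr::local_seed(8)
  q <- qr.Q(qr(matrix(rnorm(100), 20, 5)))
  f <- dplyr::bind_cols(tibble::tibble(patient_id = as.character(1:20)),
                        tibble::as_tibble(q, .name_repair = ~ paste0("v", 1:5)))
  kinds <- setNames(rep("ordinal", 5), paste0("v", 1:5))  # center only
  pca <- fit_pca(f, n_components = 5, kinds = kinds)
  xc <- sweep(q, 2, colMeans(q))
  # scores reproduce the centered input up to the orthogonal rotation
  expect_equal(pca$scores %*% t(pca$rotation), xc, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(pca$sdev^2), sum(apply(xc, 2, var)), tolerance = 1e-10)
})

test_that("logistic coefficients match an independent IRLS oracle", {
  withr::local_seed(33)
  x <- tibble::tibble(patient_id = as.character(1:20),
                      f1 = rnorm(20), f2 = rnorm(20), f3 = rnorm(20),
                      f4 = rnorm(20), f5 = rnorm(20))
  y <- rep(c(TRUE, FALSE), 10)  # interleaved, non-separable
  m <- fit_risk_model(x, y)
  expect_false(m$metadata$ridge_fallback)
  pca <- fit_pca(x, n_components = 5)
  oracle <- oracle_irls(pca$scores, as.numeric(y))
  expect_equal(unname(c(m$intercept, m$coefficients)), oracle, tolerance = 1e-6)
})

test_that("separable toys fall back to ridge with monotone posteriors", {
  x <- tibble::tibble(patient_id = as.character(1:8),
                      a = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5),
                      b = c(0, 1, 0, 1, 0, 1, 0, 1) * 0.01,
                      c = 0:7 * 0.01, d = c(1, 0, 1, 0, 1, 0, 1, 0) * 0.01,
                      e = c(0, 0, 1, 1, 0, 0, 1, 1) * 0.01)
  y <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  m <- fit_risk_model(x, y)
  expect_true(m$metadata$ridge_fallback)
  expect_true(all(diff(m$training$posterior[order(x$a)]) > -1e-8))
})

test_that("refitting with permuted patients gives identical coefficients", {
  withr::local_seed(44)
  x <- tibble::tibble(patient_id = as.character(1:30),
                      f1 = rnorm(30), f2 = rnorm(30), f3 = rnorm(30),
                      f4 = rnorm(30), f5 = rnorm(30))
  y <- rep(c(TRUE, FALSE), 15)
  m1 <- fit_risk_model(x, y)
  perm <- sample(30)
  m2 <- fit_risk_model(x[perm, ], y[perm])
  expect_equal(m2$coefficients, m1$coefficients, tolerance = 1e-10)
  expect_equal(m2$intercept, m1$intercept, tolerance = 1e-10)
})

test_that("the cutoff lands on the k-th largest positive posterior", {
  # 20 positives at 85% target: 17 called high risk
  withr::local_seed(2)
  post <- runif(78)
  labels <- rep(c(TRUE, FALSE), c(20, 58))
  cc <- choose_cutoff(post, labels, 0.85)
  expect_identical(cc$n_tp, 17L)
  # enumerated example
  ex <- choose_cutoff(c(0.9, 0.8, 0.7, 0.2, 0.75, 0.5, 0.1),
                      c(1, 1, 1, 1, 0, 0, 0), 0.75)
  expect_equal(ex$cutoff, 0.7)
  expect_equal(ex$sensitivity, 0.75)
  expect_equal(ex$specificity, 2 / 3)
  # perfectly separated scores give specificity 1 at any target
  sep <- choose_cutoff(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE), 1)
  expect_equal(sep$specificity, 1)
  expect_error(choose_cutoff(post, labels, 1.2), "0, 1")
  expect_error(choose_cutoff(post, rep(TRUE, 78)), "Both classes")
})

test_that("chosen cutoffs are optimal against the exhaustive threshold scan", {
  withr::local_seed(61)
  for (rep in 1:200) {
    n_pos <- sample(2:15, 1); n_neg <- sample(2:20, 1)
    scores <- round(runif(n_pos + n_neg), 2)  # rounding induces ties
    labels <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
    target <- sample(c(0.5, 0.75, 0.85, 1), 1)
    cc <- choose_cutoff(scores, labels, target)
    expect_gte(cc$sensitivity, target)
    expect_equal(cc$specificity, oracle_cutoff_scan(scores, labels, target))
  }
})

test_that("sensitivity falls and specificity rises as the cutoff increases", {
  withr::local_seed(62)
  scores <- runif(60); labels <- rep(c(TRUE, FALSE), 30)
  pos <- scores[labels]; neg <- scores[!labels]
  cuts <- sort(unique(scores))
  sens <- vapply(cuts, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(cuts, function(t) mean(neg < t), numeric(1))
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("prediction reproduces training posteriors and imputes by stored means", {
  fx <- make_feature_fixture(seed = 6)
  f <- assemble_features(fx$clin, set_name = "clinical")
  y <- rep(c(TRUE, FALSE), c(12, 28))
  m <- fit_risk_model(f, y)
  p <- predict(m, f)
  expect_equal(p$posterior, m$training$posterior)
  expect_identical(p$call, m$training$call)
  # a duplicated patient row receives the same posterior
  p1 <- predict(m, f[c(3, 3), ])
  expect_equal(p1$posterior[1], p1$posterior[2])
  # missing value imputed with the stored training mean
  f2 <- f; f2$age[1] <- NA
  f3 <- f; f3$age[1] <- m$feature_means["age"]
  expect_equal(predict(m, f2)$posterior[1], predict(m, f3)$posterior[1])
  expect_error(predict(m, dplyr::mutate(f, rogue = 1)), "rogue")
  expect_error(predict(m, f[, 1:5]), "Missing feature")
})
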