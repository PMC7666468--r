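make_filter_fixture <- function() {
  probes <- sprintf("cg%02d", 1:8)
  betas <- dplyr::bind_cols(
    tibble::tibble(probe_id = probes),
    tibble::as_tibble(matrix(0.5, 8, 3, dimnames = list(NULL, c("S1", "S2", "S3"))))
  )
  ann <- tibble::tibble(
    probe_id = probes,
    chromosome = c("X", "1", "2", "3", "4", "5", "6", "7"),
    region_label = c(rep("TSS200", 6), "Body", "TSS1500"),
    flag_multi_loci = c(FALSE, TRUE, rep(FALSE, 6)),
    flag_snp_within_3bp = c(FALSE, FALSE, TRUE, rep(FALSE, 5)),
    flag_absent_on_epic = c(rep(FALSE, 3), TRUE, rep(FALSE, 4)),
    flag_mqtl = FALSE
  )
  detp <- betas; detp[-1] <- 0.01
  detp[detp$probe_id == "cg05", "S2"] <- 0.06
  beads <- betas; beads[-1] <- 10
  beads[beads$probe_id == "cg06", "S3"] <- 2
  list(betas = betas, ann = ann, detp = detp, beads = beads)
}

test_that("each probe exclusion rule fires and retained probes pass all", {
  fx <- make_filter_fixture()
  res <- filter_probes(fx$betas, fx$ann, detection_p = fx$detp, nbeads = fx$beads,
                       mqtl_ids = "cg08")
  # cg01 X chromosome, cg02 multi-loci, cg03 SNP, cg04 EPIC-absent,
  # cg05 detection p 0.06, cg06 nbeads 2, cg07 non-promoter, cg08 mQTL:
  # nothing survives in this fixture
  expect_identical(nrow(res$betas), 0L)
  counts <- setNames(res$report$n, res$report$rule)
  expect_identical(unname(counts[c("sex_chromosome", "multi_loci", "snp_within_3bp",
                                   "absent_on_epic", "detection_p", "low_bead_count",
                                   "non_promoter", "mqtl", "retained")]),
                   c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L))
  expect_identical(sum(res$report$n), nrow(fx$betas))
})

test_that("an all-pass promoter probe is retained and filtering is idempotent", {
  fx <- make_filter_fixture()
  fx$ann$chromosome[1] <- "1"; fx$ann$flag_multi_loci[2] <- FALSE
  fx$ann$flag_snp_within_3bp[3] <- FALSE; fx$ann$flag_absent_on_epic[4] <- FALSE
  fx$detp[fx$detp$probe_id == "cg05", "S2"] <- 0.05  # boundary: p = 0.05 passes
  fx$beads[fx$beads$probe_id == "cg06", "S3"] <- 3   # boundary: exactly 3 beads passes
  res <- filter_probes(fx$betas, fx$ann, detection_p = fx$detp, nbeads = fx$beads)
  expect_setequal(res$betas$probe_id, c("cg01", "cg02", "cg03", "cg04", "cg05", "cg06", "cg08"))
  res2 <- filter_probes(res$betas, fx$ann,
                        detection_p = fx$detp[fx$detp$probe_id %in% res$betas$probe_id, ],
                        nbeads = fx$beads[fx$beads$probe_id %in% res$betas$probe_id, ])
  expect_identical(res2$betas, res$betas)
})

test_that("adding an exclusion flag never grows the retained set", {
  fx <- make_filter_fixture()
  base <- filter_probes(fx$betas, fx$ann, detection_p = fx$detp, nbeads = fx$beads)
  for (fl in c("flag_multi_loci", "flag_snp_within_3bp", "flag_absent_on_epic", "flag_mqtl")) {
    ann2 <- fx$ann
    ann2[[fl]] <- TRUE
    res <- filter_probes(fx$betas, ann2, detection_p = fx$detp, nbeads = fx$beads)
    expect_true(all(res$betas$probe_id %in% base$betas$probe_id))
  }
})

test_that("promoter restriction is toggleable and unannotated probes error", {
  fx <- make_filter_fixture()
  res <- filter_probes(fx$betas, fx$ann, detection_p = fx$detp, nbeads = fx$beads,
                       cfg = pipeline_config(restrict_promoter = FALSE))
  expect_identical(res$report$n[res$report$rule == "non_promoter"], 0L)
  expect_error(filter_probes(fx$betas, fx$ann[-1, ], detection_p = fx$detp,
                             nbeads = fx$beads), "cg01")
})

test_that("delta-beta and DM flags follow the inclusive 0.2 threshold", {
  tf <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                       TF1 = c(0.30, 0.50, 0.60), TF2 = c(0.30, 0.50, 0.60))
  tum <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                        T1 = c(0.75, 0.50, 0.40), T2 = c(0.30, 0.69, 0.41))
  dm <- call_dm_cpgs(tum, tf, threshold = 0.20)
  d <- as.matrix(dm$delta[-1])
  expect_equal(d["p1" == dm$delta$probe_id, "T1"][[1]], 0.45)
  fl <- as.matrix(dm$flags[-1])
  expect_identical(fl[1, ], c(T1 = "hyper", T2 = "none"))   # 0.45 / 0.00
  expect_identical(unname(fl[3, 1]), "hypo")                # exactly -0.20 inclusive
  expect_identical(fl[2, ], c(T1 = "none", T2 = "none"))    # 0.00 / 0.19
})

test_that("extreme thresholds flag everything nonzero or nothing", {
  withr::local_seed(3)
  tf <- tibble::tibble(probe_id = sprintf("p%d", 1:10), TF1 = runif(10, 0.3, 0.7))
  tum <- tibble::tibble(probe_id = tf$probe_id,
                        T1 = runif(10, 0.05, 0.95), T2 = tf$TF1)
  dm0 <- call_dm_cpgs(tum, tf, threshold = 0)
  fl0 <- as.matrix(dm0$flags[-1])
  d <- as.matrix(dm0$delta[-1])
  expect_identical(unname(fl0 == "none"), unname(d == 0))
  dm1 <- call_dm_cpgs(tum, tf, threshold = 1)
  expect_true(all(as.matrix(dm1$flags[-1]) == "none"))
  expect_error(call_dm_cpgs(tum[-1, ], tf), "identical probe sets")
})

test_that("hypomethylation outliers are flagged by the median + 3 IQR rule", {
  # 11 ordinary samples with hypo counts 10..20, one inflated sample
  n_probes <- 60
  probes <- sprintf("p%02d", seq_len(n_probes))
  tf <- tibble::tibble(probe_id = probes, TF1 = rep(0.6, n_probes))
  counts <- c(10:20, 55)
  cols <- lapply(counts, function(k) c(rep(0.1, k), rep(0.6, n_probes - k)))
  tum <- dplyr::bind_cols(tibble::tibble(probe_id = probes),
                          tibble::as_tibble(setNames(cols, sprintf("S%02d", seq_along(counts)))))
  dm <- call_dm_cpgs(tum, tf)
  out <- flag_hypomethylation_outliers(dm)
  expect_identical(out$n_hypo, as.integer(counts))
  expect_identical(out$sample_id[out$outlier], "S12")
  expect_true(counts[12] > median(counts) + 3 * IQR(counts))
  # identical counts: nobody flagged
  tum2 <- tum; tum2[-1] <- 0.1
  out2 <- flag_hypomethylation_outliers(call_dm_cpgs(tum2, tf))
  expect_false(any(out2$outlier))
  # sample order invariance
  perm <- c("probe_id", sample(sprintf("S%02d", seq_along(counts))))
  out3 <- flag_hypomethylation_outliers(call_dm_cpgs(tum[perm], tf))
  expect_equal(dplyr::arrange(out3, sample_id), dplyr::arrange(out, sample_id))
})

test_that("the absolute outlier rule applies a fixed count", {
  fx <- tibble::tibble(probe_id = c("p1", "p2"), TF1 = c(0.6, 0.6))
  tum <- tibble::tibble(probe_id = c("p1", "p2"),
                        S1 = c(0.1, 0.1), S2 = c(0.1, 0.6), S3 = c(0.6, 0.6))
  dm <- call_dm_cpgs(tum, fx)
  out <- flag_hypomethylation_outliers(
    dm, pipeline_config(outlier_rule = "absolute", outlier_count = 1))
  expect_identical(out$sample_id[out$outlier], "S1")
})

test_that("clinical mean imputation fills gaps and records them", {
  tbl <- as_clinical_table(tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    albumin = c(2, 4, NA), hemoglobin = c(130, NA, 140)
  ))
  out <- impute_clinical_means(tbl)
  expect_equal(out$albumin, c(2, 4, 3))
  expect_equal(out$hemoglobin, c(130, 135, 140))
  expect_setequal(attr(out, "imputed")$patient_id, c("P3", "P2"))

  clean <- as_clinical_table(tibble::tibble(patient_id = "P1", albumin = 3))
  expect_equal(impute_clinical_means(clean)$albumin, 3)
  expect_identical(nrow(attr(impute_clinical_means(clean), "imputed")), 0L)

  ref <- impute_clinical_means(tbl, reference_means = c(albumin = 40))
  expect_equal(ref$albumin, c(2, 4, 40))

  all_na <- as_clinical_table(tibble::tibble(patient_id = c("P1", "P2"),
                                             calcium = c(NA_real_, NA_real_)))
  expect_error(impute_clinical_means(all_na), "calcium")
  expect_equal(impute_clinical_means(all_na, reference_means = c(calcium = 2.3))$calcium,
               c(2.3, 2.3))
})
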