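# build a synthetic CSM table with controllable features/labels
fake_csms <- function(n_tt, n_td, n_dd = 0, sep = 3, seed = 1) {
  set.seed(seed)
  n <- n_tt + n_td + n_dd
  cls <- c(rep("TT", n_tt), rep("TD", n_td), rep("DD", n_dd))
  good <- cls == "TT"
  df <- data.frame(
    spectrum_id = sprintf("S%04d", seq_len(n)),
    alpha_proteins = "P1", beta_proteins = "P2",
    alpha_starts = "1", beta_starts = "1",
    alpha_site = 3L, beta_site = 4L,
    matched_alpha = rpois(n, ifelse(good, 8 + sep, 8)),
    matched_beta = rpois(n, ifelse(good, 6 + sep, 6)),
    coverage_alpha = pmin(1, rbeta(n, ifelse(good, 6, 2), 3)),
    coverage_beta = pmin(1, rbeta(n, ifelse(good, 6, 2), 3)),
    explained_intensity = runif(n),
    doublet_support = 1 + rpois(n, 1),
    complementary = rbinom(n, 1, 0.5),
    abs_ppm_error = runif(n, 0, 5),
    longest_run_alpha = rpois(n, 3), longest_run_beta = rpois(n, 3),
    length_alpha = 12L, length_beta = 10L, charge = 4L,
    decoy_class = cls,
    link_class = sample(c("inter", "intra"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  df
}

test_that("feature matrix has the fixed order and valid ranges", {
  csms <- fake_csms(20, 20)
  X <- csm_features(csms)
  expect_identical(colnames(X),
                   c("matched_alpha", "matched_beta", "coverage_alpha",
                     "coverage_beta", "explained_intensity",
                     "doublet_support", "complementary", "abs_ppm_error",
                     "longest_run_alpha", "longest_run_beta",
                     "length_alpha", "length_beta", "charge"))
  expect_true(all(X[, "coverage_alpha"] >= 0 & X[, "coverage_alpha"] <= 1))
})

test_that("the discriminant separates targets from decoys and beats chance", {
  csms <- fake_csms(150, 100, sep = 6, seed = 2)
  disc <- train_discriminant(csms, seed = 1)
  expect_gt(disc$train_auc, 0.9)
  # perfectly separable features give AUC 1
  csms2 <- fake_csms(80, 80, sep = 40, seed = 3)
  expect_equal(train_discriminant(csms2, seed = 1)$train_auc, 1)
})

test_that("shuffled labels give chance-level AUC", {
  aucs <- vapply(1:5, function(sd) {
    csms <- fake_csms(1000, 1000, sep = 5, seed = sd)
    set.seed(sd + 50)
    csms$decoy_class <- sample(csms$decoy_class)
    suppressWarnings(train_discriminant(csms, seed = sd)$train_auc)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("too few decoys triggers the fixed-weight fallback", {
  csms <- fake_csms(60, 5)
  expect_warning(disc <- train_discriminant(csms, min_decoys = 50),
                 "fixed-weight")
  expect_true(disc$fallback)
  expect_equal(disc$kind, "fixed")
  expect_length(predict(disc, csms), nrow(csms))
})

test_that("the FDR estimator reproduces (TD - DD)/TT with running-min q", {
  # 99 TT then one TD at the bottom: q at the bottom = 1/99
  rec <- data.frame(score = c(seq(100, 2), 1),
                    decoy_class = c(rep("TT", 99), "TD"),
                    link_class = "inter")
  q <- estimate_fdr(rec)
  expect_equal(q$q_value[100], 1 / 99, tolerance = 1e-12)
  expect_true(all(q$q_value[1:99] == 0))
  # all targets: q = 0 everywhere
  rec2 <- data.frame(score = 10:1, decoy_class = "TT", link_class = "intra")
  expect_true(all(estimate_fdr(rec2)$q_value == 0))
  # TD = DD at every threshold: numerator floors at 0
  rec3 <- data.frame(score = 8:1,
                     decoy_class = rep(c("TD", "DD"), 4),
                     link_class = "inter")
  expect_true(all(estimate_fdr(rec3)$q_value %in% c(0, 1)))
  rec3b <- data.frame(score = 8:1,
                      decoy_class = c("TT", "TT", "TD", "DD", "TT", "TT",
                                      "TD", "DD"),
                      link_class = "inter")
  expect_true(all(estimate_fdr(rec3b)$q_value == 0))
})

test_that("q-values are monotone non-increasing in score within link class", {
  set.seed(9)
  rec <- data.frame(score = rnorm(400),
                    decoy_class = sample(c("TT", "TD", "DD"), 400, TRUE,
                                         prob = c(0.7, 0.2, 0.1)),
                    link_class = sample(c("inter", "intra"), 400, TRUE))
  q <- estimate_fdr(rec)
  for (cl in c("inter", "intra")) {
    sub <- q[q$link_class == cl, ]
    ord <- order(-sub$score)
    expect_true(all(diff(sub$q_value[ord]) >= -1e-12))
  }
  # tied scores share one q-value
  rec$score <- round(rec$score, 1)
  q2 <- estimate_fdr(rec)
  for (cl in c("inter", "intra")) {
    sub <- q2[q2$link_class == cl, ]
    expect_true(all(tapply(sub$q_value, sub$score, function(v)
      length(unique(v)) == 1)))
  }
})

test_that("ResPair aggregation keeps the best member score and worst class", {
  csms <- fake_csms(3, 0)
  csms$score <- c(2, 5, 3)
  rp <- aggregate_respairs(csms)
  expect_equal(nrow(rp), 1)
  expect_equal(rp$score, 5)
  expect_equal(rp$n_csms, 3)
  # distinct residue pairs stay distinct
  csms2 <- fake_csms(2, 0)
  csms2$score <- c(1, 2)
  csms2$beta_site <- c(4L, 7L)
  expect_equal(nrow(aggregate_respairs(csms2)), 2)
  # a TD member taints the group
  csms3 <- fake_csms(2, 1)
  csms3$score <- c(1, 2, 3)
  expect_equal(aggregate_respairs(csms3)$decoy_class, "TD")
})

test_that("shared peptides produce ambiguous mappings counted once", {
  csms <- fake_csms(1, 0)
  csms$alpha_proteins <- "P1;P9"
  csms$alpha_starts <- "1;11"
  csms$score <- 1
  rp <- aggregate_respairs(csms)
  expect_equal(nrow(rp), 2)
  expect_true(all(rp$ambiguous))
  expect_equal(sum(rp$counted), 1)
})

test_that("PPIs are built from inter ResPairs only, with member counts", {
  csms <- fake_csms(4, 0)
  csms$score <- 1:4
  csms$link_class <- c("inter", "inter", "intra", "intra")
  csms$beta_site <- c(4L, 9L, 4L, 9L)
  csms$alpha_proteins <- c("P1", "P1", "P3", "P3")
  csms$beta_proteins <- c("P2", "P2", "P3", "P3")
  rp <- aggregate_respairs(csms)
  ppi <- aggregate_ppis(rp)
  expect_equal(nrow(ppi), 1)
  expect_equal(ppi$n_interlink_respairs, 2)
  expect_equal(ppi$protein_a, "P1")
  # intra-only input: empty PPI table
  expect_equal(nrow(aggregate_ppis(rp[rp$link_class == "intra", ])), 0)
})

test_that("tier thresholds act monotonically on downstream counts", {
  csms <- fake_csms(300, 60, 10, sep = 6, seed = 4)
  r_loose <- suppressWarnings(filter_pipeline(csms, 1, 1, 1, seed = 1))
  r_tight <- suppressWarnings(filter_pipeline(csms, 0.05, 0.05, 0.05,
                                              seed = 1))
  expect_lte(nrow(r_tight$csms), nrow(r_loose$csms))
  expect_lte(nrow(r_tight$respairs), nrow(r_loose$respairs))
  expect_lte(nrow(r_tight$ppis), nrow(r_loose$ppis))
  # thresholds of 1 reduce filtering to aggregation
  expect_equal(nrow(r_loose$csms),
               sum(csms$decoy_class == "TT"))
})

test_that("every reported ResPair is supported by a reported CSM and every
           PPI by an inter ResPair", {
  csms <- fake_csms(200, 50, 5, sep = 5, seed = 6)
  csms$beta_site <- sample(c(4L, 9L, 13L), nrow(csms), TRUE)
  csms$alpha_proteins <- sample(c("P1", "P5"), nrow(csms), TRUE)
  res <- suppressWarnings(filter_pipeline(csms, 0.2, 0.2, 0.2, seed = 1))
  csm_keys <- unique(unlist(strsplit(res$respairs$csm_ids, ";")))
  expect_true(all(csm_keys %in% csms$spectrum_id))
  if (nrow(res$ppis) > 0) {
    pk <- paste(res$ppis$protein_a, res$ppis$protein_b)
    rk <- with(res$respairs[res$respairs$link_class == "inter", ],
               paste(pmin(protein_a, protein_b), pmax(protein_a, protein_b)))
    expect_true(all(pk %in% rk))
  }
})

test_that("the optional MLP discriminant trains reproducibly", {
  skip_if_not_installed("nnet")
  csms <- fake_csms(150, 150, sep = 6, seed = 12)
  d1 <- train_discriminant(csms, kind = "mlp", seed = 3)
  d2 <- train_discriminant(csms, kind = "mlp", seed = 3)
  expect_gt(d1$train_auc, 0.9)
  expect_identical(predict(d1, csms), predict(d2, csms))
})
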