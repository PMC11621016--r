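scheme_32x8 <- function() {
  n <- 32 * 8
  mixing_scheme(sprintf("P%03d", 1:n), rep(1:32, each = 8),
                batch_id = rep(1:4, each = 64))
}

test_that("allowed-pair enumeration matches the pairwise-mixing design", {
  sc <- scheme_32x8()
  expect_equal(nrow(enumerate_allowed_ppis(sc)), 896)     # 32 * C(8,2)
  one <- mixing_scheme(sprintf("Q%d", 1:8), rep(1, 8))
  expect_equal(nrow(enumerate_allowed_ppis(one)), 28)
  expect_equal(nrow(enumerate_allowed_ppis(sc, batches = c(3, 4))), 448)
  # random geometries: sum of per-group C(n_g, 2)
  set.seed(3)
  for (i in 1:5) {
    sizes <- sample(2:9, 6, TRUE)
    acc <- sprintf("R%03d", seq_len(sum(sizes)))
    sc2 <- mixing_scheme(acc, rep(seq_along(sizes), sizes))
    expect_equal(nrow(enumerate_allowed_ppis(sc2)),
                 sum(choose(sizes, 2)))
  }
})

test_that("identifications are classified against the scheme", {
  sc <- scheme_32x8()
  expect_equal(classify_identification("P001", "P002", sc), "allowed_inter")
  # different groups: P017 is group 3, P049 group 7
  expect_equal(classify_identification("P017", "P049", sc),
               "prohibited_inter")
  expect_equal(classify_identification("P005", "P005", sc), "allowed_intra")
  expect_equal(classify_identification("ENT01", "ENT01", sc),
               "prohibited_intra_absent")
  expect_equal(classify_identification("P001", "ENT01", sc),
               "prohibited_inter")
  # shared peptides: allowed if ANY mapping is allowed
  expect_equal(classify_identification("P017;P001", "P002", sc),
               "allowed_inter")
})

test_that("sites outside the recombinant construct are false positives", {
  sc <- mixing_scheme(c("A", "B"), c(1, 1), construct_start = c(10, 1),
                      construct_end = c(50, 100))
  expect_equal(classify_identification("A", "B", sc, pos_a = 20, pos_b = 5),
               "allowed_inter")
  expect_equal(classify_identification("A", "B", sc, pos_a = 60, pos_b = 5),
               "out_of_construct")
  expect_equal(classify_identification("A", "A", sc, pos_a = 5, pos_b = 20),
               "out_of_construct")
})

test_that("empirical FDR is the mean violation indicator", {
  sc <- scheme_32x8()
  rec <- data.frame(protein_a = c(rep("P001", 99), "P017"),
                    protein_b = c(rep("P002", 99), "P049"))
  ev <- empirical_fdr(rec, sc)
  expect_equal(ev$fdr, 0.01)
  expect_equal(ev$n_false, 1)
  all_ok <- empirical_fdr(rec[1:50, ], sc)
  expect_equal(all_ok$fdr, 0)
  none <- empirical_fdr(rec[0, ], sc)
  expect_true(is.na(none$fdr))
  # label permutation invariance of the totals
  perm <- sc
  perm$group_id <- ((perm$group_id + 4) %% 32) + 1
  expect_equal(empirical_fdr(rec, perm)$n, ev$n)
})

test_that("coverage of the theoretical PPI maximum is a simple percentage", {
  sc <- scheme_32x8()
  expect_equal(ppi_coverage(195, sc, batches = c(3, 4)), 100 * 195 / 448)
  expect_equal(round(ppi_coverage(195, sc, batches = c(3, 4)), 1), 43.5)
})

test_that("global identity and entrapment filtering behave as specified", {
  expect_equal(sequence_identity("AAAA", "AAAA"), 1)
  # half-identical constructed pair: 4 of 8 aligned positions match
  id <- sequence_identity("AAAAWWWW", "AAAAYYYY")
  expect_equal(id, 0.5)
  std <- c(S1 = "AAAAWWWWGGGG")
  pool <- c(E1 = "AAAAWWWWGGGG",        # identical: always excluded
            E2 = "AAAAYYYYHHHH",        # ~1/3 identity: usable
            E3 = "MNPQRSTVLIEF")        # unrelated: usable
  db <- build_entrapment_db(std, pool, n_total = 3,
                            identity_threshold = 0.85, seed = 1)
  expect_length(db, 3)
  expect_false("E1" %in% names(db))
  expect_setequal(names(db), c("S1", "E2", "E3"))
  expect_identical(build_entrapment_db(std, pool, n_total = 1), std)
  expect_error(build_entrapment_db(std, pool["E1"], n_total = 2),
               "exhausted")
})

test_that("mixing scheme TSV round-trips", {
  sc <- mixing_scheme(c("A", "B", "C"), c(1, 1, 2), c(1, 1, 1),
                      construct_start = c(1, 5, NA),
                      construct_end = c(100, 80, NA))
  path <- tempfile(fileext = ".tsv")
  write_mixing_scheme(sc, path)
  back <- read_mixing_scheme(path)
  expect_equal(as.data.frame(back), as.data.frame(sc))
})
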