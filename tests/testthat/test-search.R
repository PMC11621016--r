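test_that("stub variants attach exactly to link-spanning fragments", {
  th <- theoretical_fragments("AKAR", site = 2, xl = DSSO, max_charge = 1)
  plain <- th$ion_type %in% c("b", "y")
  # b1 (A), y1 (R), y2 (AR) do not span position 2; b2, b3, y3 do
  expect_setequal(paste(th$ion_type[plain], th$ordinal[plain]),
                  c("b 1", "y 1", "y 2"))
  stubbed <- th[!plain, ]
  expect_setequal(unique(paste0(substr(stubbed$ion_type, 1, 1),
                                stubbed$ordinal)),
                  c("b2", "b3", "y3"))
  # light/heavy variants differ by the doublet delta
  b2 <- stubbed[stubbed$ordinal == 2 & startsWith(stubbed$ion_type, "b"), ]
  expect_equal(diff(sort(b2$mz)), DSSO$doublet_delta, tolerance = 1e-6)
})

test_that("site 1 puts stubs on every b ion", {
  th <- theoretical_fragments("AKAR", site = 1, xl = DSSO, max_charge = 1)
  expect_false(any(th$ion_type == "b"))
  expect_error(theoretical_fragments("AKAR", site = 9), "out of range")
})

test_that("b/y mass additivity holds for non-spanning complements", {
  # for a plain linear ladder (no stubs): m(b_i) + m(y_{n-i}) singly
  # protonated = peptide mass + 2 protons
  seq <- "SAMPLER"
  m <- peptide_mass(seq)
  th <- theoretical_fragments(seq, site = 1, xl = DSSO, max_charge = 1)
  # use the light-stub b series and plain y series: b_i(+stubL) + y_{n-i}
  # = mass + stubL + 2 protons
  for (i in 1:6) {
    b <- th$mz[th$ordinal == i & th$ion_type == "b+stubL"]
    y <- th$mz[th$ordinal == (7 - i) & th$ion_type == "y"]
    expect_equal(b + y, m + DSSO$stub_light_mass + 2 * 1.00727646,
                 tolerance = 1e-5)
  }
})

test_that("candidate enumeration equals brute force over the index", {
  idx <- toy_index(c("AAKGGLRK", "VVKEEFKK", "TTKWSARK", "GGKMMNPKR",
                     "HHKLLTYK"), plain_params(mc = 2, min_len = 4))
  tab <- idx$table
  hyp <- data.frame(alpha_mass = tab$mass[10], beta_mass = tab$mass[3],
                    support = 1L, complementary = FALSE, intensity = 1)
  got <- candidates_for_hypothesis(hyp, idx, ms1_tol_ppm = 10)
  brute_a <- which(abs(tab$mass - hyp$alpha_mass) <= hyp$alpha_mass * 1e-5 &
                     nzchar(tab$link_sites))
  brute_b <- which(abs(tab$mass - hyp$beta_mass) <= hyp$beta_mass * 1e-5 &
                     nzchar(tab$link_sites))
  expect_setequal(paste(got$alpha_row, got$beta_row),
                  paste(rep(brute_a, times = length(brute_b)),
                        rep(brute_b, each = length(brute_a))))
  # empty window: no candidates
  hyp0 <- data.frame(alpha_mass = 1e6, beta_mass = tab$mass[1],
                     support = 1L, complementary = FALSE, intensity = 1)
  expect_equal(nrow(candidates_for_hypothesis(hyp0, idx)), 0)
})

test_that("fragment matching equals a brute-force all-pairs matcher", {
  set.seed(5)
  theo <- sort(runif(40, 100, 1500))
  mzv <- sort(runif(60, 100, 1500))
  hit <- xlms:::match_peaks(theo, mzv, tol_ppm = 50)
  for (i in seq_along(theo)) {
    d <- abs(mzv - theo[i])
    j <- which.min(d)
    if (d[j] <= theo[i] * 50e-6) expect_equal(hit[i], j)
    else expect_true(is.na(hit[i]))
  }
})

test_that("the planted pair ranks first on clean spectra", {
  seqs <- c(A = "AAKGGLRSSK", B = "VVKEEFMNRK", C = "TTKWSADEKR",
            D = "LLKNPQYHKK")
  params <- plain_params(mc = 2, min_len = 4)
  db <- digest_database(seqs, params, DSSO, decoys = TRUE, seed = 1)
  idx <- build_peptide_index(db)
  sp <- search_params(top_k = 1)
  s <- clean_xl_spectrum("AAKGGLRSSK", "VVKEEFMNRK", 3, 3, charge = 5)
  csm <- search_spectrum(s, idx, DSSO, sp, fixed_mods = list())
  expect_equal(nrow(csm), 1)
  expect_setequal(c(csm$alpha_sequence, csm$beta_sequence),
                  c("AAKGGLRSSK", "VVKEEFMNRK"))
  expect_equal(csm$decoy_class, "TT")
  expect_equal(csm$link_class, "inter")
  expect_true(csm$alpha_site == 3 && csm$beta_site == 3)
})

test_that("search output is deterministic", {
  seqs <- c(A = "AAKGGLRSSK", B = "VVKEEFMNRK")
  params <- plain_params(mc = 2, min_len = 4)
  idx <- build_peptide_index(digest_database(seqs, params, DSSO, seed = 1))
  s <- clean_xl_spectrum("AAKGGLRSSK", "VVKEEFMNRK", 3, 3, charge = 4)
  c1 <- search_spectrum(s, idx, DSSO, search_params(), fixed_mods = list())
  c2 <- search_spectrum(s, idx, DSSO, search_params(), fixed_mods = list())
  expect_identical(c1, c2)
})

test_that("intra links are recognized via shared accessions", {
  seqs <- c(A = "AAKGGLRSSKDDFKR")
  params <- plain_params(mc = 1, min_len = 4)
  idx <- build_peptide_index(digest_database(seqs, params, DSSO, seed = 1))
  s <- clean_xl_spectrum("AAKGGLR", "SSKDDFK", 3, 3, charge = 4)
  csm <- search_spectrum(s, idx, DSSO, search_params(), fixed_mods = list())
  expect_equal(nrow(csm), 1)
  expect_equal(csm$link_class, "intra")
})
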