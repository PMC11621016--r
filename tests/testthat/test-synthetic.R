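test_that("protein-set generation follows the scheme geometry", {
  cfg <- synth_config(n_groups = 32, group_size = 8, n_entrapment = 284,
                      seed = 2)
  ps <- generate_protein_set(cfg)
  expect_length(ps$proteins, 540)
  expect_equal(nrow(ps$scheme), 256)
  expect_equal(nrow(enumerate_allowed_ppis(ps$scheme)), 896)
  # every standard protein carries at least 3 lysines
  nk <- vapply(ps$proteins[ps$standard_accessions], function(s)
    nchar(gsub("[^K]", "", s)), numeric(1))
  expect_true(all(nk >= 3))
  # entrapment proteins are not in the scheme
  expect_false(any(grepl("^ENT", ps$scheme$accession)))
  tiny <- generate_protein_set(synth_config(n_groups = 1, group_size = 2,
                                            n_entrapment = 0, seed = 2))
  expect_equal(nrow(enumerate_allowed_ppis(tiny$scheme)), 1)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- synth_config(n_groups = 2, group_size = 3, n_entrapment = 2,
                      n_crosslink_spectra = 10,
                      n_linear_background_spectra = 5, seed = 9)
  a <- generate_benchmark_dataset(cfg)
  b <- generate_benchmark_dataset(cfg)
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$truth, b$truth)
  expect_identical(a$spectra[[3]]$mz, b$spectra[[3]]$mz)
  # and writes identical FASTA bytes
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(a$proteins, f1); write_fasta(b$proteins, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted spectra satisfy the precursor mass identity", {
  cfg <- synth_config(noise_peaks = 0, jitter_ppm = 0, missing_prob = 0)
  s <- generate_crosslinked_spectrum("t", "AAKGGLR", "VVKEEFK", 3, 3, 4,
                                     DSSO, cfg, fixed_mods = list())
  M <- precursor_neutral_mass(s)
  expect_equal(M, peptide_mass("AAKGGLR") + peptide_mass("VVKEEFK") +
                 DSSO$intact_bridge_mass, tolerance = 1e-4)
  expect_error(generate_crosslinked_spectrum("t", "AAKGGLR", "VVKEEFK",
                                             99, 3, 4, DSSO, cfg),
               "invalid link site")
})

test_that("clean planted spectra yield both chain masses via doublets", {
  s <- clean_xl_spectrum("AAKGGLR", "VVKEEFMK", 3, 3, charge = 4)
  h <- infer_mass_hypotheses(find_doublets(s, DSSO, 20),
                             precursor_neutral_mass(s), DSSO)
  m <- sort(c(peptide_mass("AAKGGLR"), peptide_mass("VVKEEFMK")))
  expect_true(any(abs(h$alpha_mass - m[2]) < 0.02 &
                    abs(h$beta_mass - m[1]) < 0.02))
})

test_that("benchmark datasets honor the configured composition", {
  cfg <- synth_config(n_groups = 4, group_size = 4, n_entrapment = 6,
                      n_crosslink_spectra = 120,
                      n_linear_background_spectra = 40,
                      intra_to_inter_ratio = 10, seed = 5)
  bm <- generate_benchmark_dataset(cfg)
  expect_equal(nrow(bm$truth), 120)
  expect_length(bm$spectra, 160)
  counts <- table(bm$truth$link_class)
  # binomial check: intra fraction near 10/11
  p_hat <- counts[["intra"]] / 120
  expect_lt(abs(p_hat - 10 / 11), 3 * sqrt((10 / 11) * (1 / 11) / 120))
  # cross-link spectra use only scheme-allowed pairs: truth itself has
  # empirical FDR zero by construction
  ev <- empirical_fdr(data.frame(protein_a = bm$truth$protein_a,
                                 protein_b = bm$truth$protein_b),
                      bm$scheme)
  expect_equal(ev$fdr, 0)
  # entrapment proteins never generate spectra
  expect_false(any(grepl("^ENT", c(bm$truth$protein_a, bm$truth$protein_b))))
  # charges lie in the configured 4..8 range
  expect_true(all(bm$truth$charge %in% 4:8))
})

test_that("written MGF re-read reproduces the generated peak lists", {
  cfg <- synth_config(n_groups = 2, group_size = 2, n_entrapment = 0,
                      n_crosslink_spectra = 5,
                      n_linear_background_spectra = 2, seed = 13)
  dir <- tempfile()
  bm <- generate_benchmark_dataset(cfg, out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c("spectra.mgf",
                                               "database.fasta",
                                               "scheme.tsv", "truth.tsv")))))
  back <- read_mgf(file.path(dir, "spectra.mgf"))
  expect_length(back, 7)
  expect_equal(back[[1]]$mz, bm$spectra[[1]]$mz, tolerance = 1e-4)
  tr <- utils::read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(tr), 5)
})
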