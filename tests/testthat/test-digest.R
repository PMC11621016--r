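test_that("tryptic digestion enumerates missed-cleavage peptides exactly", {
  d <- digest_protein("MKAREK", plain_params(mc = 1))
  expect_setequal(d$sequence, c("MK", "AR", "EK", "MKAR", "AREK"))
  # proline blocks cleavage after K/R
  d2 <- digest_protein("AKPGGR", plain_params(mc = 0))
  expect_setequal(d2$sequence, c("AKPGGR"))
  # no cleavage sites at all
  expect_equal(digest_protein("AAAA", plain_params(mc = 3))$sequence, "AAAA")
  expect_error(digest_protein("", plain_params()), "empty")
})

test_that("fully cleaved peptides reconstruct the protein; counts follow the
           missed-cleavage formula", {
  for (seed in 1:5) {
    s <- random_sequence(60, seed)
    d0 <- digest_protein(s, plain_params(mc = 0))
    expect_identical(paste(d0$sequence[order(d0$start)], collapse = ""), s)
    # with c internal sites and m allowed missed cleavages (before
    # filters): sum_{k=0..min(m,c)} (c+1-k) peptides
    chars <- strsplit(s, "")[[1]]
    c_sites <- sum(chars[-length(chars)] %in% c("K", "R") &
                     chars[-1] != "P")
    for (m in 0:3) {
      dm <- digest_protein(s, plain_params(mc = m))
      expected <- sum((c_sites + 1) - 0:min(m, c_sites))
      expect_equal(nrow(dm), expected)
    }
  }
})

test_that("digestion drops peptides with non-standard residues, with warning", {
  expect_warning(d <- digest_protein("AAAKXXXK", plain_params(mc = 0)),
                 "non-standard")
  expect_setequal(d$sequence, "AAAK")
})

test_that("peptide masses are monoisotopic with water and mods", {
  expect_equal(peptide_mass("GG"), 132.0535, tolerance = 1e-3 / 132)
  expect_equal(peptide_mass("C", list(mod_carbamidomethyl())), 178.0412,
               tolerance = 1e-3 / 178)
  expect_error(peptide_mass(""), "non-empty")
  # mass equals residue sum + water within 1e-4 for random peptides
  for (seed in 1:5) {
    s <- random_sequence(12, seed + 100)
    res <- mass_table()$residue_masses[strsplit(s, "")[[1]]]
    expect_equal(peptide_mass(s), sum(res) + mass_table()$water_mass,
                 tolerance = 1e-4 / 1000)
  }
})

test_that("variable-mod enumeration covers all placements once", {
  f <- enumerate_variable_mods("MM", list(mod_oxidation_m()), 2)
  expect_equal(nrow(f), 4)                    # none, M1, M2, both
  expect_equal(sum(f$n_mods == 0), 1)
  expect_equal(sum(f$n_mods == 1), 2)
  expect_equal(sum(f$n_mods == 2), 1)
  expect_false(any(duplicated(f$mod_sites)))
  expect_equal(nrow(enumerate_variable_mods("AAA", list(mod_oxidation_m()), 3)), 1)
  expect_equal(nrow(enumerate_variable_mods("M", list(mod_oxidation_m()), 0)), 1)
  # brute-force subset count for 4 targets, max 2: 1 + 4 + 6
  f4 <- enumerate_variable_mods("MMMM", list(mod_oxidation_m()), 2)
  expect_equal(nrow(f4), 11)
})

test_that("decoys preserve composition and C-terminus; palindromes fall back", {
  d <- generate_decoys("PEPTIDEK")
  expect_equal(d$decoy, "EDITPEPK")
  # multiset of residue masses identical => identical mass
  seqs <- vapply(1:10, function(i) random_sequence(10, i), character(1))
  d <- generate_decoys(seqs)
  for (i in seq_along(seqs)) {
    expect_equal(peptide_mass(d$decoy[i]), peptide_mass(seqs[i]),
                 tolerance = 1e-9)
    expect_equal(substr(d$decoy[i], 10, 10), substr(seqs[i], 10, 10))
  }
  kk <- generate_decoys("KK")
  expect_true(kk$collision)    # nothing to permute
  expect_equal(kk$decoy, "KK")
  # AAK is a reversal palindrome but shuffling cannot fix it either
  aak <- generate_decoys("AAK")
  expect_true(aak$collision)
})

test_that("mass index queries equal a linear scan", {
  set.seed(42)
  seqs <- unique(vapply(1:300, function(i)
    random_sequence(sample(6:14, 1), i + 1000), character(1)))
  db <- data.frame(sequence = seqs,
                   mass = vapply(seqs, peptide_mass, numeric(1)),
                   link_sites = "1")
  idx <- build_peptide_index(db)
  for (q in 1:100) {
    target <- runif(1, min(db$mass), max(db$mass))
    hits <- query_peptide_index(idx, target, tol_ppm = 10)
    brute <- which(abs(idx$table$mass - target) <= target * 10e-6)
    expect_identical(hits, brute)
  }
  # exact-mass query at tol 0 returns exactly that peptide
  hit <- query_peptide_index(idx, idx$table$mass[5], tol_da = 0)
  expect_true(5 %in% hit)
  expect_length(query_peptide_index(idx, 1e6, tol_ppm = 10), 0)
  expect_error(build_peptide_index(db[0, ]), "empty")
})

test_that("digest_database aggregates shared peptides across proteins", {
  prots <- c(A = "GGGKAAAR", B = "CCCKAAAR")
  db <- digest_database(prots, plain_params(mc = 0, min_len = 4),
                        decoys = FALSE)
  shared <- db[db$sequence == "AAAR", ]
  expect_equal(nrow(shared), 1)
  expect_setequal(strsplit(shared$proteins, ";")[[1]], c("A", "B"))
  db2 <- digest_database(prots, plain_params(mc = 0, min_len = 4),
                         decoys = TRUE)
  expect_equal(sum(db2$is_decoy), sum(!db2$is_decoy))
  expect_true(all(grepl("^DEC_", db2$proteins[db2$is_decoy])))
})

test_that("link sites are reactive residues plus protein N-terminus", {
  prots <- c(A = "MAKGGKR")
  db <- digest_database(prots, plain_params(mc = 3, min_len = 3),
                        decoys = FALSE)
  full <- db[db$sequence == "MAKGGKR", ]
  # K3, K6 plus position 1 (protein N-terminus, DSSO reactive)
  expect_equal(full$link_sites, "1,3,6")
})
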