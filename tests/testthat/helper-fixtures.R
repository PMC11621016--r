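# Shared fixtures: tiny peptide databases and noise-free spectra built in
# code at test time.

DSSO <- crosslinker_dsso()

# digest params without modifications, wide filters: convenient for
# hand-checkable combinatorics
plain_params <- function(mc = 1L, min_len = 1L, range = c(1, 1e5)) {
  digest_params(max_missed_cleavages = mc, min_length = min_len,
                mass_range = range, fixed_mods = list(),
                variable_mods = list(), max_variable_mods = 0L)
}

# a random protein-like sequence over the 20 standard residues
random_sequence <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(names(mass_table()$residue_masses), n, replace = TRUE),
        collapse = "")
}

# noise-free cross-linked spectrum for a known peptide pair
clean_xl_spectrum <- function(seq_a, seq_b, site_a, site_b, charge = 4L,
                              id = "clean") {
  cfg <- synth_config(noise_peaks = 0L, jitter_ppm = 0, missing_prob = 0)
  s <- generate_crosslinked_spectrum(id, seq_a, seq_b, site_a, site_b,
                                     charge, DSSO, cfg, fixed_mods = list())
  s$searchable <- TRUE
  s
}

# tiny target+decoy index over a handful of peptides
toy_index <- function(seqs, params = plain_params()) {
  prots <- stats::setNames(seqs, paste0("P", seq_along(seqs)))
  db <- digest_database(prots, params, DSSO, decoys = TRUE, seed = 1)
  build_peptide_index(db)
}
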