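#' Synthetic ground-truth benchmark generation
#'
#' Generates protein databases with a pairwise mixing scheme, entrapment
#' entries, and MS2 spectra of cross-linked and linear peptides with
#' planted answers, emulating the structure of the recombinant-standard
#' datasets: cross-linked precursors at charge 4--8 carrying
#' cleavable-stub signature doublets, a large linear-peptide background
#' and an intralink:interlink excess of about an order of magnitude.
#'
#' @name synthetic_data
NULL

#' Synthetic benchmark configuration
#'
#' @param n_groups,group_size Mixing-scheme geometry (default 32 x 8).
#' @param n_entrapment Entrapment proteins appended to the FASTA but
#'   never used in spectrum generation (default pads 256 to 540).
#' @param protein_length Length range of the random proteins.
#' @param k_weight Sampling weight multiplier for lysine (guarantees
#'   cross-linkable sites).
#' @param n_crosslink_spectra,n_linear_background_spectra Spectrum counts.
#' @param intra_to_inter_ratio Expected intralink:interlink spectrum
#'   ratio (about 10 in real cleavable-linker data).
#' @param noise_peaks Uniform-m/z noise peaks per spectrum.
#' @param jitter_ppm Peak m/z jitter, ppm (uniform in +/- jitter).
#' @param missing_prob Probability that any one fragment ion is absent.
#' @param charge_probs Precursor charge distribution over 4..8.
#' @param seed Integer seed.
#' @return List of class `xl_synth_config`.
#' @export
synth_config <- function(n_groups = 32L, group_size = 8L,
                         n_entrapment = 284L,
                         protein_length = c(120L, 220L),
                         k_weight = 2,
                         n_crosslink_spectra = 500L,
                         n_linear_background_spectra = 2000L,
                         intra_to_inter_ratio = 10,
                         noise_peaks = 30L,
                         jitter_ppm = 5,
                         missing_prob = 0.1,
                         charge_probs = c(`4` = 0.35, `5` = 0.30,
                                          `6` = 0.20, `7` = 0.10,
                                          `8` = 0.05),
                         seed = 1L) {
  stopifnot(intra_to_inter_ratio > 0, jitter_ppm >= 0, missing_prob < 1)
  structure(list(n_groups = as.integer(n_groups),
                 group_size = as.integer(group_size),
                 n_entrapment = as.integer(n_entrapment),
                 protein_length = as.integer(protein_length),
                 k_weight = k_weight,
                 n_crosslink_spectra = as.integer(n_crosslink_spectra),
                 n_linear_background_spectra =
                   as.integer(n_linear_background_spectra),
                 intra_to_inter_ratio = intra_to_inter_ratio,
                 noise_peaks = as.integer(noise_peaks),
                 jitter_ppm = jitter_ppm,
                 missing_prob = missing_prob,
                 charge_probs = charge_probs,
                 seed = as.integer(seed)),
            class = "xl_synth_config")
}

# Residue sampling weights: uniform over the 20 residues with K upweighted.
residue_weights <- function(k_weight) {
  w <- stats::setNames(rep(1, 20), names(.RESIDUE_MASSES))
  w["K"] <- k_weight
  w / sum(w)
}

random_protein <- function(len, rng, k_weight) {
  w <- residue_weights(k_weight)
  repeat {
    s <- paste(names(w)[rng$sample(20L, len, replace = TRUE, prob = w)],
               collapse = "")
    if (nchar(gsub("[^K]", "", s)) >= 3L) return(s)
  }
}

#' Generate a protein set with its mixing scheme
#'
#' Random protein sequences (each with at least 3 lysines) allocated to
#' interaction groups, plus entrapment proteins appended to the database
#' but absent from the scheme.
#'
#' @param cfg A [synth_config()].
#' @return List: `proteins` (named vector, standard then entrapment),
#'   `scheme` (`xl_mixing_scheme` over the standard proteins only),
#'   `standard_accessions`.
#' @export
generate_protein_set <- function(cfg = synth_config()) {
  rng <- local_rng(cfg$seed)
  n_std <- cfg$n_groups * cfg$group_size
  lens <- cfg$protein_length[1] +
    rng$sample(cfg$protein_length[2] - cfg$protein_length[1] + 1L,
               n_std + cfg$n_entrapment, replace = TRUE) - 1L
  seqs <- vapply(lens, random_protein, character(1), rng = rng,
                 k_weight = cfg$k_weight)
  acc <- c(sprintf("STD%03d", seq_len(n_std)),
           if (cfg$n_entrapment > 0L)
             sprintf("ENT%03d", seq_len(cfg$n_entrapment)))
  names(seqs) <- acc
  group <- rep(seq_len(cfg$n_groups), each = cfg$group_size)
  batch <- ((group - 1L) %/% 8L) + 1L
  scheme <- mixing_scheme(acc[seq_len(n_std)], group, batch,
                          construct_start = 1L,
                          construct_end = lens[seq_len(n_std)])
  list(proteins = seqs, scheme = scheme,
       standard_accessions = acc[seq_len(n_std)])
}

# log-normal ladder intensities; doublets scaled to the ladder median.
.LADDER_MEANLOG <- log(1000)
.LADDER_SDLOG <- 0.6

jitter_mz <- function(mz, rng, ppm) {
  if (ppm <= 0) return(mz)
  mz * (1 + rng$runif(length(mz), -ppm, ppm) * 1e-6)
}

#' Generate one cross-linked MS2 spectrum
#'
#' Plants b/y ladders of both chains (link-spanning ions in both stub
#' variants), each ion present with probability `1 - missing_prob`;
#' intact-chain stub doublet peak pairs for both chains at fragment
#' charges 1 and 2; uniform noise peaks; all m/z jittered.  The
#' precursor m/z is `(m_a + m_b + bridge + z * proton) / z`.
#'
#' @param id Spectrum identifier.
#' @param seq_a,seq_b Peptide sequences.
#' @param site_a,site_b 1-based link positions.
#' @param charge Precursor charge.
#' @param xl A [crosslinker()].
#' @param cfg A [synth_config()].
#' @param rng Internal RNG (from `local_rng`); a fresh one is created
#'   from `cfg$seed` when omitted.
#' @param fixed_mods Fixed modifications applied to residue masses.
#' @return An `xl_spectrum`.
#' @export
generate_crosslinked_spectrum <- function(id, seq_a, seq_b, site_a, site_b,
                                          charge, xl = crosslinker_dsso(),
                                          cfg = synth_config(), rng = NULL,
                                          fixed_mods = list(mod_carbamidomethyl())) {
  if (is.null(rng)) rng <- local_rng(cfg$seed)
  if (site_a < 1 || site_a > nchar(seq_a) ||
      site_b < 1 || site_b > nchar(seq_b)) stop("invalid link site")
  m_a <- peptide_mass(seq_a, fixed_mods)
  m_b <- peptide_mass(seq_b, fixed_mods)
  frag <- rbind(theoretical_fragments(seq_a, site_a, xl, 1L, fixed_mods),
                theoretical_fragments(seq_b, site_b, xl, 1L, fixed_mods))
  keep <- rng$runif(nrow(frag)) >= cfg$missing_prob
  mz <- frag$mz[keep]
  inten <- rng$rlnorm(sum(keep), .LADDER_MEANLOG, .LADDER_SDLOG)
  med <- if (length(inten)) stats::median(inten) else exp(.LADDER_MEANLOG)
  # signature doublets: intact chains carrying light / heavy stubs
  for (m_pep in c(m_a, m_b)) for (zd in 1:2) {
    mz <- c(mz, (m_pep + xl$stub_light_mass + zd * .PROTON_MASS) / zd,
            (m_pep + xl$stub_heavy_mass + zd * .PROTON_MASS) / zd)
    inten <- c(inten, 2 * med, 2 * med)
  }
  if (cfg$noise_peaks > 0L) {
    mz <- c(mz, rng$runif(cfg$noise_peaks, 200, 1600))
    inten <- c(inten, rng$rlnorm(cfg$noise_peaks, .LADDER_MEANLOG - log(10),
                                 .LADDER_SDLOG))
  }
  mz <- jitter_mz(mz, rng, cfg$jitter_ppm)
  pre <- (m_a + m_b + xl$intact_bridge_mass + charge * .PROTON_MASS) / charge
  pre <- jitter_mz(pre, rng, min(cfg$jitter_ppm, 2))
  spectrum(id, pre, charge, mz, inten)
}

# Linear-peptide background spectrum: plain b/y ladder, no doublets.
generate_linear_spectrum <- function(id, seq, charge, cfg, rng,
                                     fixed_mods = list(mod_carbamidomethyl())) {
  m <- residue_masses_of(seq, fixed_mods)
  n <- length(m)
  pre_sum <- cumsum(m)[-n]
  suf_sum <- rev(cumsum(rev(m)))[-1L]
  mz <- c(pre_sum + .PROTON_MASS, suf_sum + .WATER_MASS + .PROTON_MASS)
  keep <- rng$runif(length(mz)) >= cfg$missing_prob
  mz <- mz[keep]
  inten <- rng$rlnorm(length(mz), .LADDER_MEANLOG, .LADDER_SDLOG)
  if (cfg$noise_peaks > 0L) {
    mz <- c(mz, rng$runif(cfg$noise_peaks, 200, 1600))
    inten <- c(inten, rng$rlnorm(cfg$noise_peaks, .LADDER_MEANLOG - log(10),
                                 .LADDER_SDLOG))
  }
  mz <- jitter_mz(mz, rng, cfg$jitter_ppm)
  pep_mass <- peptide_mass(seq, fixed_mods)
  pre <- (pep_mass + charge * .PROTON_MASS) / charge
  spectrum(id, pre, charge, mz, inten)
}

#' Generate the full synthetic benchmark dataset
#'
#' Cross-linked spectra are drawn only from scheme-allowed pairs (intra
#' on present proteins, inter within one group, at the configured
#' intra:inter ratio); linear background spectra come from the present
#' proteins; entrapment proteins are in the FASTA but never generate
#' spectra.  The planted-truth table has one row per cross-link
#' spectrum.
#'
#' @param cfg A [synth_config()].
#' @param xl A [crosslinker()].
#' @param digest [digest_params()] used to draw realistic tryptic
#'   peptides (variable mods are not planted).
#' @param out_dir Optional directory; when given, writes `spectra.mgf`,
#'   `database.fasta`, `scheme.tsv` and `truth.tsv`.
#' @return List of class `xl_synth_benchmark`: `proteins`, `scheme`,
#'   `spectra` (list of `xl_spectrum`), `truth` (data frame).
#' @export
generate_benchmark_dataset <- function(cfg = synth_config(),
                                       xl = crosslinker_dsso(),
                                       digest = digest_params(),
                                       out_dir = NULL) {
  rng <- local_rng(cfg$seed + 1L)
  pset <- generate_protein_set(cfg)
  std <- pset$standard_accessions
  fixed_mods <- digest$fixed_mods

  # linkable tryptic peptides per standard protein
  pep_cache <- lapply(std, function(acc) {
    d <- digest_protein(pset$proteins[[acc]], digest)
    if (nrow(d) == 0L) return(d)
    sites <- gregexpr("K", d$sequence, fixed = TRUE)
    has_k <- vapply(sites, function(p) p[1] != -1L, logical(1))
    d <- d[has_k, , drop = FALSE]
    d[!duplicated(d$sequence), , drop = FALSE]
  })
  names(pep_cache) <- std
  usable <- std[vapply(pep_cache, nrow, 1L) >= 2L]

  allowed <- enumerate_allowed_ppis(pset$scheme)
  allowed <- allowed[allowed$protein_a %in% usable &
                       allowed$protein_b %in% usable, , drop = FALSE]
  p_intra <- cfg$intra_to_inter_ratio / (cfg$intra_to_inter_ratio + 1)
  charges <- as.integer(names(cfg$charge_probs))

  draw_peptide <- function(acc, exclude = NULL) {
    d <- pep_cache[[acc]]
    if (!is.null(exclude)) d <- d[d$sequence != exclude, , drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    row <- d[rng$sample(nrow(d), 1L), ]
    ks <- as.integer(gregexpr("K", row$sequence, fixed = TRUE)[[1]])
    row$site <- ks[rng$sample(length(ks), 1L)]
    row
  }

  spectra <- vector("list", cfg$n_crosslink_spectra +
                      cfg$n_linear_background_spectra)
  truth <- vector("list", cfg$n_crosslink_spectra)
  for (i in seq_len(cfg$n_crosslink_spectra)) {
    repeat {
      if (rng$runif(1) < p_intra) {
        acc_a <- usable[rng$sample(length(usable), 1L)]
        acc_b <- acc_a
        pa <- draw_peptide(acc_a)
        pb <- draw_peptide(acc_b, exclude = pa$sequence)
      } else {
        pr <- allowed[rng$sample(nrow(allowed), 1L), ]
        acc_a <- pr$protein_a; acc_b <- pr$protein_b
        pa <- draw_peptide(acc_a)
        pb <- draw_peptide(acc_b)
      }
      if (!is.null(pa) && !is.null(pb)) break
    }
    z <- charges[rng$sample(length(charges), 1L, prob = cfg$charge_probs)]
    id <- sprintf("XL%05d", i)
    spectra[[i]] <- generate_crosslinked_spectrum(
      id, pa$sequence, pb$sequence, pa$site, pb$site, z, xl, cfg, rng,
      fixed_mods)
    truth[[i]] <- data.frame(
      spectrum_id = id,
      protein_a = acc_a, peptide_a = pa$sequence,
      site_a = pa$site, pos_a = pa$start + pa$site - 1L,
      protein_b = acc_b, peptide_b = pb$sequence,
      site_b = pb$site, pos_b = pb$start + pb$site - 1L,
      charge = z,
      link_class = if (acc_a == acc_b) "intra" else "inter",
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(cfg$n_linear_background_spectra)) {
    repeat {
      acc <- usable[rng$sample(length(usable), 1L)]
      d <- pep_cache[[acc]]
      row <- d[rng$sample(nrow(d), 1L), ]
      if (nchar(row$sequence) >= digest$min_length) break
    }
    z <- 2L + rng$sample(3L, 1L)  # charges 3..5
    spectra[[cfg$n_crosslink_spectra + j]] <-
      generate_linear_spectrum(sprintf("LIN%05d", j), row$sequence, z,
                               cfg, rng, fixed_mods)
  }
  truth <- do.call(rbind, truth)
  out <- structure(list(proteins = pset$proteins, scheme = pset$scheme,
                        spectra = spectra, truth = truth, config = cfg),
                   class = "xl_synth_benchmark")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mgf(spectra, file.path(out_dir, "spectra.mgf"))
    write_fasta(pset$proteins, file.path(out_dir, "database.fasta"))
    write_mixing_scheme(pset$scheme, file.path(out_dir, "scheme.tsv"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.xl_synth_benchmark <- function(x, ...) {
  cat(sprintf(paste0("xl_synth_benchmark: %d proteins (%d in scheme), ",
                     "%d cross-link + %d linear spectra\n"),
              length(x$proteins), nrow(x$scheme),
              nrow(x$truth), length(x$spectra) - nrow(x$truth)))
  invisible(x)
}
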