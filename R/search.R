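#' Candidate resolution and CSM scoring
#'
#' Resolves alpha/beta mass hypotheses into peptide-pair candidates via
#' the mass index, evaluates every link-site combination by fragment
#' matching and emits cross-link spectrum matches (CSMs) with quality
#' features.
#'
#' @name csm_search
NULL

#' Search parameters
#'
#' Defaults mirror standard cleavable-cross-linker practice: 10 ppm MS1,
#' 20 ppm MS2, fragment charges up to 2, at most 8 mass hypotheses and
#' 5,000 candidate pairs per hypothesis, one reported CSM per spectrum.
#'
#' @param ms1_tol_ppm,ms2_tol_ppm Mass tolerances in ppm.
#' @param max_fragment_charge Fragment ion charges 1..max considered.
#' @param max_hypotheses Mass-hypothesis cap per spectrum.
#' @param max_pairs_per_hypothesis Candidate-pair cap (logged when hit).
#' @param top_k CSMs reported per spectrum.
#' @param min_fragments_per_chain Minimum matched fragment ions required
#'   on EACH chain for a CSM to be reported; suppresses one-sided garbage
#'   matches that carry no real cross-link evidence.
#' @param doublet_tol_ppm Fragment tolerance for doublet detection.
#' @param fdr_csm,fdr_respair,fdr_ppi Tier FDR thresholds in (0, 1].
#' @param exhaustive_fallback Search spectra without doublets by
#'   exhaustive mass partitioning over the index (slow; default off --
#'   the doublet search is the gate).
#' @return List of class `xl_search_params`.
#' @export
search_params <- function(ms1_tol_ppm = 10, ms2_tol_ppm = 20,
                          max_fragment_charge = 2L, max_hypotheses = 8L,
                          max_pairs_per_hypothesis = 5000L, top_k = 1L,
                          min_fragments_per_chain = 3L,
                          doublet_tol_ppm = 20,
                          fdr_csm = 0.01, fdr_respair = 0.01, fdr_ppi = 0.01,
                          exhaustive_fallback = FALSE) {
  structure(list(ms1_tol_ppm = ms1_tol_ppm, ms2_tol_ppm = ms2_tol_ppm,
                 max_fragment_charge = as.integer(max_fragment_charge),
                 max_hypotheses = as.integer(max_hypotheses),
                 max_pairs_per_hypothesis = as.integer(max_pairs_per_hypothesis),
                 top_k = as.integer(top_k),
                 min_fragments_per_chain = as.integer(min_fragments_per_chain),
                 doublet_tol_ppm = doublet_tol_ppm,
                 fdr_csm = fdr_csm, fdr_respair = fdr_respair,
                 fdr_ppi = fdr_ppi,
                 exhaustive_fallback = isTRUE(exhaustive_fallback)),
            class = "xl_search_params")
}

#' Candidate peptide pairs for one mass hypothesis
#'
#' All pairs (alpha from the alpha-mass window, beta from the beta-mass
#' window) where both peptides carry at least one cross-linkable site.
#' Equivalent to a brute-force double loop with mass filters; the pair
#' count is capped with a warning.
#'
#' @param hypothesis One row of [infer_mass_hypotheses()] output.
#' @param index An [build_peptide_index()] object.
#' @param ms1_tol_ppm MS1 tolerance (ppm).
#' @param max_pairs Cap on returned pairs.
#' @return Data frame with `alpha_row`, `beta_row` (indices into
#'   `index$table`).
#' @export
candidates_for_hypothesis <- function(hypothesis, index, ms1_tol_ppm = 10,
                                      max_pairs = 5000L) {
  ia <- query_peptide_index(index, hypothesis$alpha_mass, ms1_tol_ppm)
  ib <- query_peptide_index(index, hypothesis$beta_mass, ms1_tol_ppm)
  ia <- ia[nzchar(index$table$link_sites[ia])]
  ib <- ib[nzchar(index$table$link_sites[ib])]
  if (length(ia) == 0L || length(ib) == 0L)
    return(data.frame(alpha_row = integer(0), beta_row = integer(0)))
  pairs <- expand.grid(alpha_row = ia, beta_row = ib,
                       KEEP.OUT.ATTRS = FALSE)
  if (nrow(pairs) > max_pairs) {
    warning("candidate pair cap hit (", nrow(pairs), " > ", max_pairs,
            "); truncating")
    pairs <- pairs[seq_len(max_pairs), , drop = FALSE]
  }
  pairs
}

# Feature vector column order (versioned: v1).
.FEATURE_NAMES <- c("matched_alpha", "matched_beta", "coverage_alpha",
                    "coverage_beta", "explained_intensity",
                    "doublet_support", "complementary", "abs_ppm_error",
                    "longest_run_alpha", "longest_run_beta",
                    "length_alpha", "length_beta", "charge")

#' Match and score candidate pairs against a spectrum
#'
#' Every candidate pair is evaluated over all link-site combinations;
#' because each chain's fragments depend only on its own site, the best
#' site is chosen per chain (most matched fragments, ties to the
#' N-terminal-most site).  Pairs are normalized so the alpha chain is the
#' longer peptide (ties lexicographic), scored by a raw evidence score,
#' and at most `top_k` CSMs are kept per spectrum.  Ties break
#' deterministically on (score, matched-peak count, alpha sequence, beta
#' sequence).
#'
#' @param s A preprocessed `xl_spectrum`.
#' @param pairs Data frame from [candidates_for_hypothesis()].
#' @param index Peptide index the row indices refer to.
#' @param hypothesis The generating hypothesis row (for doublet features).
#' @param xl A [crosslinker()].
#' @param params [search_params()].
#' @param fixed_mods Fixed modifications used at digest time.
#' @return Data frame of CSMs (possibly empty): identities, link sites,
#'   the feature columns and `raw_score`.
#' @export
match_and_score_candidates <- function(s, pairs, index, hypothesis,
                                       xl = crosslinker_dsso(),
                                       params = search_params(),
                                       fixed_mods = list(mod_carbamidomethyl())) {
  if (nrow(pairs) == 0L) return(empty_csm_table())
  tab <- index$table
  M <- precursor_neutral_mass(s)
  total_intensity <- sum(s$intensity)
  # cache chain evidence by (row, site): the same peptide form appears in
  # many pairs
  cache <- new.env(hash = TRUE)
  best_chain <- function(row) {
    key <- as.character(row)
    if (!is.null(cache[[key]])) return(cache[[key]])
    sites <- as.integer(strsplit(tab$link_sites[row], ",", fixed = TRUE)[[1]])
    best <- NULL
    for (site in sites) {
      ev <- chain_evidence(tab$sequence[row], site, s, xl,
                           params$ms2_tol_ppm, params$max_fragment_charge,
                           fixed_mods, tab$mod_sites[row])
      if (is.null(best) || ev$n_matched > best$n_matched) {
        best <- ev; best$site <- site
      }
    }
    cache[[key]] <- best
    best
  }
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ra <- pairs$alpha_row[k]; rb <- pairs$beta_row[k]
    ev_a <- best_chain(ra); ev_b <- best_chain(rb)
    if (ev_a$n_matched < params$min_fragments_per_chain ||
        ev_b$n_matched < params$min_fragments_per_chain) next
    expl <- if (total_intensity > 0)
      sum(s$intensity[unique(c(ev_a$peak_idx, ev_b$peak_idx))]) / total_intensity
      else 0
    ppm_err <- abs(tab$mass[ra] + tab$mass[rb] + xl$intact_bridge_mass - M) /
      M * 1e6
    # normalize: alpha = longer peptide, ties lexicographic
    swap <- (nchar(tab$sequence[rb]) > nchar(tab$sequence[ra])) ||
      (nchar(tab$sequence[rb]) == nchar(tab$sequence[ra]) &&
         tab$sequence[rb] < tab$sequence[ra])
    if (swap) { tmp <- ra; ra <- rb; rb <- tmp
                tmpe <- ev_a; ev_a <- ev_b; ev_b <- tmpe }
    rows[[k]] <- data.frame(
      spectrum_id = s$spectrum_id,
      alpha_row = ra, beta_row = rb,
      alpha_sequence = tab$sequence[ra], beta_sequence = tab$sequence[rb],
      alpha_site = ev_a$site, beta_site = ev_b$site,
      alpha_proteins = tab$proteins[ra], beta_proteins = tab$proteins[rb],
      alpha_starts = tab$starts[ra], beta_starts = tab$starts[rb],
      alpha_decoy = tab$is_decoy[ra], beta_decoy = tab$is_decoy[rb],
      matched_alpha = ev_a$n_matched, matched_beta = ev_b$n_matched,
      coverage_alpha = ev_a$coverage, coverage_beta = ev_b$coverage,
      explained_intensity = expl,
      doublet_support = hypothesis$support,
      complementary = as.numeric(hypothesis$complementary),
      abs_ppm_error = ppm_err,
      longest_run_alpha = ev_a$longest_run, longest_run_beta = ev_b$longest_run,
      length_alpha = nchar(tab$sequence[ra]), length_beta = nchar(tab$sequence[rb]),
      charge = s$charge,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) return(empty_csm_table())
  out$raw_score <- raw_csm_score(out)
  ord <- order(-out$raw_score, -(out$matched_alpha + out$matched_beta),
               out$alpha_sequence, out$beta_sequence)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Raw evidence score used to rank candidates within a spectrum before the
# discriminant exists: matched fragments weighted by ladder coverage and
# explained intensity.
raw_csm_score <- function(f) {
  (f$matched_alpha + f$matched_beta) *
    (1 + f$coverage_alpha + f$coverage_beta) +
    4 * f$explained_intensity
}

empty_csm_table <- function(full = FALSE) {
  cols <- c("spectrum_id", "alpha_row", "beta_row", "alpha_sequence",
            "beta_sequence", "alpha_site", "beta_site", "alpha_proteins",
            "beta_proteins", "alpha_starts", "beta_starts", "alpha_decoy",
            "beta_decoy", .FEATURE_NAMES, "raw_score",
            if (full) c("decoy_class", "link_class"))
  as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols))
}

#' Search one spectrum
#'
#' Doublet detection, hypothesis inference, candidate lookup, fragment
#' matching; returns the `top_k` best CSMs for the spectrum with decoy
#' class and link class annotated.
#'
#' @param s A preprocessed `xl_spectrum`.
#' @param index Peptide index over targets and decoys.
#' @param xl A [crosslinker()].
#' @param params [search_params()].
#' @param fixed_mods Fixed modifications used at digest time.
#' @return CSM data frame (0 or more rows).
#' @export
search_spectrum <- function(s, index, xl = crosslinker_dsso(),
                            params = search_params(),
                            fixed_mods = list(mod_carbamidomethyl())) {
  if (!isTRUE(s$searchable)) return(empty_csm_table(full = TRUE))
  M <- precursor_neutral_mass(s)
  if (is.na(M)) return(empty_csm_table(full = TRUE))
  d <- find_doublets(s, xl, params$doublet_tol_ppm)
  hyp <- infer_mass_hypotheses(d, M, xl, params$ms1_tol_ppm,
                               params$max_hypotheses)
  if (nrow(hyp) == 0L && params$exhaustive_fallback)
    hyp <- exhaustive_hypotheses(M, index, xl, params)
  if (nrow(hyp) == 0L) return(empty_csm_table(full = TRUE))
  all_csms <- list()
  for (i in seq_len(nrow(hyp))) {
    pairs <- candidates_for_hypothesis(hyp[i, ], index, params$ms1_tol_ppm,
                                       params$max_pairs_per_hypothesis)
    if (nrow(pairs) == 0L) next
    csm_i <- match_and_score_candidates(s, pairs, index, hyp[i, ], xl,
                                        params, fixed_mods)
    if (nrow(csm_i) > 0L) all_csms[[length(all_csms) + 1L]] <- csm_i
  }
  out <- do.call(rbind, all_csms)
  if (is.null(out) || nrow(out) == 0L) return(empty_csm_table(full = TRUE))
  # one candidate may arise under several hypotheses; keep its best record
  key <- paste(out$alpha_row, out$beta_row, out$alpha_site, out$beta_site)
  ord <- order(-out$raw_score, -(out$matched_alpha + out$matched_beta),
               out$alpha_sequence, out$beta_sequence)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(key[ord]), , drop = FALSE]
  out <- utils::head(out, params$top_k)
  out$decoy_class <- ifelse(out$alpha_decoy & out$beta_decoy, "DD",
                            ifelse(out$alpha_decoy | out$beta_decoy,
                                   "TD", "TT"))
  out$link_class <- ifelse(mapply(shares_protein, out$alpha_proteins,
                                  out$beta_proteins),
                           "intra", "inter")
  rownames(out) <- NULL
  out
}

# Intra iff the two chains share a protein accession (decoy prefixes are
# stripped so decoy CSMs partition like their targets).
shares_protein <- function(pa, pb) {
  a <- sub("^DEC_", "", strsplit(pa, ";", fixed = TRUE)[[1]])
  b <- sub("^DEC_", "", strsplit(pb, ";", fixed = TRUE)[[1]])
  length(intersect(a, b)) > 0L
}

# Fallback when no doublets are found: enumerate alpha windows from the
# index against the precursor mass partition (config-gated; slow).
exhaustive_hypotheses <- function(M, index, xl, params) {
  rest <- M - xl$intact_bridge_mass
  masses <- index$masses
  ok <- which(masses < rest & (rest - masses) >= min(masses) - 1)
  if (length(ok) == 0L)
    return(data.frame(alpha_mass = numeric(0), beta_mass = numeric(0),
                      support = integer(0), complementary = logical(0),
                      intensity = numeric(0)))
  a <- masses[ok]; b <- rest - a
  keep <- a >= b
  data.frame(alpha_mass = a[keep], beta_mass = b[keep], support = 0L,
             complementary = FALSE, intensity = 0)
}

#' Search a collection of spectra
#'
#' @param spectra List of `xl_spectrum` (preprocessed or raw; raw spectra
#'   are preprocessed with `prep`).
#' @param index Peptide index over targets and decoys.
#' @param xl A [crosslinker()].
#' @param params [search_params()].
#' @param prep [preprocess_params()] applied when a spectrum has not been
#'   preprocessed yet.
#' @param fixed_mods Fixed modifications used at digest time.
#' @return CSM data frame over all spectra.
#' @export
search_spectra <- function(spectra, index, xl = crosslinker_dsso(),
                           params = search_params(),
                           prep = preprocess_params(),
                           fixed_mods = list(mod_carbamidomethyl())) {
  res <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    if (is.na(s$searchable)) s <- preprocess_spectrum(s, prep)
    res[[i]] <- search_spectrum(s, index, xl, params, fixed_mods)
  }
  res <- res[vapply(res, nrow, 1L) > 0L]
  out <- do.call(rbind, res)
  if (is.null(out)) out <- empty_csm_table(full = TRUE)
  rownames(out) <- NULL
  out
}
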