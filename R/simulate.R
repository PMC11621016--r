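#' Simulation of false residue-to-residue links
#'
#' Models a false cross-link as a true alpha-site on one of the standard
#' proteins paired with a false beta-site anywhere in the database.
#' Alpha-site placement probabilities follow a Zipfian curve fitted to
#' the ranked target cross-link counts per protein; beta-site
#' probabilities follow a Poisson model fitted to the decoy counts.
#' Co-occurrence of alpha and beta on one protein is a false intralink;
#' within one mixing-scheme group, a false within-group interlink.
#' Beta-beta co-occurrence (decoy-decoy links) is not considered.
#'
#' @name false_link_simulator
NULL

#' Fit a Zipfian exponent to ranked counts
#'
#' Least squares on `log(count) ~ log(rank)`; the exponent is the
#' negated slope.
#'
#' @param ranked_counts Positive counts in descending order.
#' @return List with `exponent`, `intercept` (log scale) and `r_squared`.
#' @export
fit_zipf <- function(ranked_counts) {
  if (length(ranked_counts) < 3L) stop("need at least 3 ranks")
  stopifnot(all(ranked_counts > 0),
            all(diff(ranked_counts) <= 0))
  r <- seq_along(ranked_counts)
  fit <- stats::lm(log(ranked_counts) ~ log(r))
  y <- log(ranked_counts)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot
        else NA_real_
  list(exponent = -unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Fit a Poisson rate to counts
#'
#' Maximum-likelihood rate = mean count.
#'
#' @param counts Non-negative counts per protein.
#' @return List with `rate` and `degenerate` (all-zero input).
#' @export
fit_poisson <- function(counts) {
  if (length(counts) == 0L) stop("empty counts")
  stopifnot(all(counts >= 0))
  list(rate = mean(counts), degenerate = all(counts == 0))
}

# Placement probabilities over n proteins from a Zipfian exponent: the
# normalized fitted curve evaluated at ranks 1..n.
zipf_probs <- function(exponent, n) {
  p <- seq_len(n)^(-exponent)
  p / sum(p)
}

# Placement probabilities over n proteins from a Poisson rate: expected
# ranked counts approximated by Poisson quantiles at plotting positions,
# normalized (near-uniform for moderate rates, as decoy hits are).
poisson_probs <- function(rate, n) {
  if (rate <= 0) return(rep(1 / n, n))
  q <- stats::qpois((n - seq_len(n) + 0.5) / n, rate)
  if (sum(q) == 0) return(rep(1 / n, n))
  (q + 0.5) / sum(q + 0.5)
}

#' Site-placement model for the false-link simulation
#'
#' @param zipf_exponent Alpha-site (target) Zipfian exponent.
#' @param poisson_rate Beta-site (decoy) Poisson rate.
#' @param n_standard_proteins Proteins eligible for alpha sites.
#' @param n_database_proteins Total database entries for beta sites.
#' @param scheme Optional `xl_mixing_scheme` over the standard proteins;
#'   defaults to 32 groups of 8 when `n_standard_proteins` is 256.
#' @return List of class `xl_site_model`.
#' @export
site_placement_model <- function(zipf_exponent, poisson_rate,
                                 n_standard_proteins = 256L,
                                 n_database_proteins = 540L,
                                 scheme = NULL) {
  stopifnot(zipf_exponent > 0, poisson_rate > 0,
            n_standard_proteins <= n_database_proteins)
  if (is.null(scheme)) {
    gsize <- if (n_standard_proteins %% 32L == 0L)
      n_standard_proteins %/% 32L else n_standard_proteins
    scheme <- mixing_scheme(paste0("P", seq_len(n_standard_proteins)),
                            ((seq_len(n_standard_proteins) - 1L) %/% gsize) + 1L)
  }
  structure(list(zipf_exponent = zipf_exponent,
                 poisson_rate = poisson_rate,
                 n_standard = as.integer(n_standard_proteins),
                 n_database = as.integer(n_database_proteins),
                 scheme = scheme), class = "xl_site_model")
}

#' Simulate false links and summarize their placement
#'
#' Places `n_links` alpha-sites on the standard proteins (Zipf-derived
#' probabilities, rank-to-protein assignment randomized per replicate)
#' and `n_links` beta-sites on all database entries (Poisson-derived
#' probabilities), then counts alpha/beta co-occurrence on the same
#' protein (false intralink) and within one group (false within-group
#' interlink).
#'
#' @param model A [site_placement_model()].
#' @param n_links Number of simulated false links (the decoy cross-link
#'   count of a real search output).
#' @param seed Integer seed.
#' @param total_intra,total_within_group Denominators for the reported
#'   fractions (overall intralink / within-group link counts of the
#'   search output); default `n_links`.
#' @return List of class `xl_false_link_summary`.
#' @export
simulate_false_links <- function(model, n_links, seed = 1L,
                                 total_intra = n_links,
                                 total_within_group = n_links) {
  stopifnot(n_links > 0)
  rng <- local_rng(seed)
  p_alpha_rank <- zipf_probs(model$zipf_exponent, model$n_standard)
  p_beta_rank <- poisson_probs(model$poisson_rate, model$n_database)
  # randomize which protein occupies which rank
  alpha_assign <- rng$sample(model$n_standard)
  beta_assign <- rng$sample(model$n_database)
  p_alpha <- numeric(model$n_standard); p_alpha[alpha_assign] <- p_alpha_rank
  p_beta <- numeric(model$n_database); p_beta[beta_assign] <- p_beta_rank
  a <- rng$sample(model$n_standard, n_links, replace = TRUE, prob = p_alpha)
  b <- rng$sample(model$n_database, n_links, replace = TRUE, prob = p_beta)
  # database layout: proteins 1..n_standard are the standard entries
  same_protein <- a == b
  grp <- model$scheme$group_id
  beta_grp <- ifelse(b <= model$n_standard, grp[b], NA_integer_)
  same_group <- !is.na(beta_grp) & grp[a] == beta_grp
  structure(list(n_simulated = as.integer(n_links),
                 n_false_intra = sum(same_protein),
                 n_false_within_group = sum(same_group & !same_protein),
                 false_intra_fraction = sum(same_protein) / total_intra,
                 false_within_group_inter_fraction =
                   sum(same_group & !same_protein) / total_within_group,
                 seed = as.integer(seed)),
            class = "xl_false_link_summary")
}

#' @export
print.xl_false_link_summary <- function(x, ...) {
  cat(sprintf(paste0("xl_false_link_summary: %d links; false intra %.4f%%;",
                     " false within-group inter %.4f%%\n"),
              x$n_simulated, 100 * x$false_intra_fraction,
              100 * x$false_within_group_inter_fraction))
  invisible(x)
}
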