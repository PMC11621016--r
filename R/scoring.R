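#' Discriminant scoring and multi-tier FDR
#'
#' Feature extraction from CSM tables, a trainable target/decoy
#' discriminant, the (TD - DD)/TT cross-link FDR estimator with q-values,
#' and aggregation of CSMs to unique residue pairs (ResPairs) and unique
#' protein pairs (PPIs) with separate FDR control at every tier.
#'
#' @name scoring_fdr
NULL

#' Feature matrix of a CSM table
#'
#' The fixed, versioned feature order used by the discriminant:
#' matched fragment counts and ladder coverages per chain, explained
#' intensity fraction, doublet support, complementarity flag, absolute
#' precursor error (ppm), longest consecutive ladder runs, peptide
#' lengths and precursor charge.
#'
#' @param csms CSM data frame from [search_spectra()].
#' @return Numeric matrix, one row per CSM.
#' @export
csm_features <- function(csms) {
  as.matrix(csms[, .FEATURE_NAMES, drop = FALSE])
}

#' Train a target/decoy discriminant
#'
#' Fits a monotone score separating target-target CSMs (label 1) from
#' decoy-containing CSMs (label 0) on z-score-normalized features.
#' `kind = "logistic"` uses logistic regression; `kind = "mlp"` a single
#' hidden layer of 16 units (via nnet, seeded).  With fewer than
#' `min_decoys` decoy records (or no targets) a fixed linear combination
#' of the normalized features is used instead and flagged.
#'
#' @param csms CSM data frame with `decoy_class`.
#' @param tier Label recorded in the model metadata.
#' @param seed Integer seed.
#' @param kind `"logistic"` or `"mlp"`.
#' @param min_decoys Minimum decoy records for trained weights.
#' @return An object of class `xl_discriminant`.
#' @export
train_discriminant <- function(csms, tier = "csm", seed = 1L,
                               kind = c("logistic", "mlp"),
                               min_decoys = 50L) {
  kind <- match.arg(kind)
  X <- csm_features(csms)
  y <- as.numeric(csms$decoy_class == "TT")
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-9] <- 1
  fallback <- sum(y == 0) < min_decoys || sum(y == 1) == 0L
  obj <- list(kind = kind, tier = tier, seed = as.integer(seed),
              mu = mu, sd = sd, fallback = fallback,
              feature_names = .FEATURE_NAMES)
  if (fallback) {
    warning("too few decoys (", sum(y == 0), " < ", min_decoys,
            "); using fixed-weight discriminant")
    obj$kind <- "fixed"
    obj$weights <- fixed_feature_weights()
  } else {
    Z <- scale(X, center = mu, scale = sd)
    if (kind == "logistic") {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, Z), y,
                       family = stats::binomial(),
                       control = list(maxit = 50)))
      obj$weights <- fit$coefficients
      obj$weights[!is.finite(obj$weights)] <- 0
    } else {
      if (!requireNamespace("nnet", quietly = TRUE))
        stop("kind = 'mlp' requires the nnet package")
      rng <- local_rng(seed)
      # draw reproducible initial weights independent of the caller's RNG
      nw <- (ncol(Z) + 1L) * 16L + 17L
      wts <- rng$runif(nw, -0.5, 0.5)
      fit <- nnet::nnet(Z, y, size = 16L, decay = 1e-3, maxit = 200,
                        trace = FALSE, Wts = wts)
      obj$net <- fit
    }
  }
  class(obj) <- "xl_discriminant"
  obj$train_auc <- auc_score(predict(obj, csms), y)
  obj
}

# Fixed weights on normalized features for the low-decoy fallback: reward
# matched evidence and coverage, penalize precursor error.
fixed_feature_weights <- function() {
  stats::setNames(
    c(0, 1, 1, 2, 2, 2, 0.5, 0.25, -1, 0.5, 0.5, 0, 0, 0),
    c("(Intercept)", .FEATURE_NAMES))
}

#' @export
predict.xl_discriminant <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else csm_features(newdata)
  Z <- scale(X, center = object$mu, scale = object$sd)
  if (!is.null(object$net)) as.numeric(predict(object$net, Z))
  else as.numeric(cbind(1, Z) %*% object$weights)
}

#' @export
print.xl_discriminant <- function(x, ...) {
  cat(sprintf("xl_discriminant (%s, tier %s%s): training AUC %.3f\n",
              x$kind, x$tier, if (x$fallback) ", fallback" else "",
              x$train_auc))
  invisible(x)
}

# Area under the ROC curve via the rank statistic.
auc_score <- function(score, label) {
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Target-decoy FDR with q-values
#'
#' Within each link class (inter/intra filtered separately), records are
#' sorted by descending score and the FDR at a score threshold t is
#' `max(TD - DD, 0) / TT` over records scoring at least t -- the standard
#' cross-link target-decoy estimator.  The q-value is the running minimum
#' of the FDR from the bottom of the list, hence monotone non-increasing
#' in score.  Tied scores share one q-value.
#'
#' @param records Data frame with `score`, `decoy_class` and (unless
#'   `by_link_class = FALSE`) `link_class` columns.
#' @param by_link_class Partition by `link_class` before estimating.
#' @return The records with a `q_value` column (original order).
#' @export
estimate_fdr <- function(records, by_link_class = TRUE) {
  if (nrow(records) == 0L) {
    records$q_value <- numeric(0)
    return(records)
  }
  part <- if (by_link_class) records$link_class else rep("all", nrow(records))
  q <- rep(NA_real_, nrow(records))
  for (cl in unique(part)) {
    ii <- which(part == cl)
    ord <- ii[order(-records$score[ii])]
    tt <- cumsum(records$decoy_class[ord] == "TT")
    td <- cumsum(records$decoy_class[ord] == "TD")
    dd <- cumsum(records$decoy_class[ord] == "DD")
    fdr <- pmax(td - dd, 0) / pmax(tt, 1)
    fdr[tt == 0] <- 1
    qv <- rev(cummin(rev(fdr)))
    # tied scores share the q of the group's last member
    sc <- records$score[ord]
    last_of_tie <- stats::ave(seq_along(sc), match(sc, unique(sc)),
                              FUN = max)
    q[ord] <- qv[last_of_tie]
  }
  records$q_value <- q
  records
}

#' Aggregate CSMs to unique residue pairs
#'
#' CSMs are mapped to protein-coordinate residue pairs
#' (`position = peptide start + in-peptide site - 1`).  Shared peptides
#' yield one ResPair per consistent protein mapping, flagged ambiguous;
#' only the first mapping (by accession order) carries `counted = TRUE`
#' and enters FDR denominators.  Keys are normalized so
#' `(protein_a, pos_a) <= (protein_b, pos_b)`; the ResPair score is the
#' highest member CSM score and a decoy member taints the group's decoy
#' class pessimistically.
#'
#' @param csms Scored CSM data frame (needs a `score` column).
#' @return ResPair data frame.
#' @export
aggregate_respairs <- function(csms) {
  if (nrow(csms) == 0L)
    return(data.frame(protein_a = character(0), pos_a = integer(0),
                      protein_b = character(0), pos_b = integer(0),
                      link_class = character(0), decoy_class = character(0),
                      score = numeric(0), n_csms = integer(0),
                      ambiguous = logical(0), counted = logical(0),
                      csm_ids = character(0)))
  maps <- vector("list", nrow(csms))
  for (i in seq_len(nrow(csms))) {
    pa <- strsplit(csms$alpha_proteins[i], ";", fixed = TRUE)[[1]]
    sa <- as.integer(strsplit(csms$alpha_starts[i], ";", fixed = TRUE)[[1]])
    pb <- strsplit(csms$beta_proteins[i], ";", fixed = TRUE)[[1]]
    sb <- as.integer(strsplit(csms$beta_starts[i], ";", fixed = TRUE)[[1]])
    oa <- order(pa); ob <- order(pb)
    g <- expand.grid(a = oa, b = ob, KEEP.OUT.ATTRS = FALSE)
    prot_a <- pa[g$a]; pos_a <- sa[g$a] + csms$alpha_site[i] - 1L
    prot_b <- pb[g$b]; pos_b <- sb[g$b] + csms$beta_site[i] - 1L
    flip <- prot_b < prot_a | (prot_b == prot_a & pos_b < pos_a)
    ka <- ifelse(flip, prot_b, prot_a); va <- ifelse(flip, pos_b, pos_a)
    kb <- ifelse(flip, prot_a, prot_b); vb <- ifelse(flip, pos_a, pos_b)
    maps[[i]] <- data.frame(
      protein_a = ka, pos_a = va, protein_b = kb, pos_b = vb,
      link_class = csms$link_class[i], decoy_class = csms$decoy_class[i],
      score = csms$score[i], spectrum_id = csms$spectrum_id[i],
      ambiguous = nrow(g) > 1L,
      counted = seq_len(nrow(g)) == 1L,
      stringsAsFactors = FALSE)
  }
  m <- do.call(rbind, maps)
  key <- paste(m$protein_a, m$pos_a, m$protein_b, m$pos_b, sep = "|")
  agg <- lapply(split(seq_len(nrow(m)), key), function(ii) {
    cls <- m$decoy_class[ii]
    worst <- if (any(cls == "DD")) "DD" else if (any(cls == "TD")) "TD" else "TT"
    data.frame(protein_a = m$protein_a[ii[1]], pos_a = m$pos_a[ii[1]],
               protein_b = m$protein_b[ii[1]], pos_b = m$pos_b[ii[1]],
               link_class = m$link_class[ii[1]],
               decoy_class = worst,
               score = max(m$score[ii]),
               n_csms = length(unique(m$spectrum_id[ii])),
               ambiguous = any(m$ambiguous[ii]),
               counted = any(m$counted[ii]),
               csm_ids = paste(unique(m$spectrum_id[ii]), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(-out$score, out$protein_a, out$pos_a, out$protein_b, out$pos_b),
      , drop = FALSE]
}

#' Aggregate inter-link ResPairs to protein pairs
#'
#' Built from inter-protein ResPairs only; `protein_a <= protein_b`,
#' score is the highest member score, decoy classes aggregate
#' pessimistically.
#'
#' @param respairs ResPair data frame (FDR-filtered at the ResPair tier).
#' @return PPI data frame with `n_interlink_respairs`.
#' @export
aggregate_ppis <- function(respairs) {
  rp <- respairs[respairs$link_class == "inter", , drop = FALSE]
  if (nrow(rp) == 0L)
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      n_interlink_respairs = integer(0),
                      decoy_class = character(0), score = numeric(0),
                      respair_ids = character(0)))
  a <- pmin(rp$protein_a, rp$protein_b)
  b <- pmax(rp$protein_a, rp$protein_b)
  key <- paste(a, b, sep = "|")
  agg <- lapply(split(seq_len(nrow(rp)), key), function(ii) {
    cls <- rp$decoy_class[ii]
    worst <- if (any(cls == "DD")) "DD" else if (any(cls == "TD")) "TD" else "TT"
    data.frame(protein_a = a[ii[1]], protein_b = b[ii[1]],
               n_interlink_respairs = length(ii),
               decoy_class = worst,
               score = max(rp$score[ii]),
               respair_ids = paste(paste0(rp$protein_a[ii], ":", rp$pos_a[ii],
                                          "-", rp$protein_b[ii], ":",
                                          rp$pos_b[ii]), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(-out$score, out$protein_a, out$protein_b), , drop = FALSE]
}

#' Sequential three-tier FDR filtering
#'
#' Scores CSMs with a discriminant (trained here unless supplied),
#' filters at the CSM tier (inter and intra separately), aggregates to
#' ResPairs, filters, aggregates inter-ResPairs to PPIs and filters at
#' the PPI tier.  Each returned table carries its tier q-values; decoy
#' rows are retained so downstream empirical checks can drop or keep
#' them (`report_decoys`).
#'
#' @param csms CSM table from [search_spectra()].
#' @param fdr_csm,fdr_respair,fdr_ppi Tier thresholds in (0, 1].
#' @param discriminant Optional pre-trained [train_discriminant()] model.
#' @param seed Seed for discriminant training.
#' @param report_decoys Keep decoy rows in the returned tables.
#' @return List of class `xl_results`: `csms`, `respairs`, `ppis`,
#'   `discriminant`.
#' @export
filter_pipeline <- function(csms, fdr_csm = 0.01, fdr_respair = 0.01,
                            fdr_ppi = 0.01, discriminant = NULL,
                            seed = 1L, report_decoys = FALSE) {
  stopifnot(fdr_csm > 0, fdr_csm <= 1, fdr_respair > 0, fdr_respair <= 1,
            fdr_ppi > 0, fdr_ppi <= 1)
  if (nrow(csms) == 0L)
    return(structure(list(csms = csms, respairs = aggregate_respairs(csms),
                          ppis = aggregate_ppis(aggregate_respairs(csms)),
                          discriminant = NULL), class = "xl_results"))
  if (is.null(discriminant))
    discriminant <- suppressWarnings(
      train_discriminant(csms, tier = "csm", seed = seed))
  csms$score <- predict(discriminant, csms)
  csms <- estimate_fdr(csms)
  csms_pass <- csms[csms$q_value <= fdr_csm, , drop = FALSE]

  respairs <- aggregate_respairs(csms_pass)
  rp_counted <- estimate_fdr(respairs[respairs$counted, , drop = FALSE])
  # ambiguous extra mappings inherit the q of their counted twin's key
  respairs <- rp_counted
  respairs_pass <- respairs[respairs$q_value <= fdr_respair, , drop = FALSE]

  ppis <- aggregate_ppis(respairs_pass)
  if (nrow(ppis) > 0L) {
    ppis$link_class <- "inter"
    ppis <- estimate_fdr(ppis)
    ppis_pass <- ppis[ppis$q_value <= fdr_ppi, , drop = FALSE]
  } else {
    ppis$q_value <- numeric(0)
    ppis_pass <- ppis
  }
  if (!report_decoys) {
    csms_pass <- csms_pass[csms_pass$decoy_class == "TT", , drop = FALSE]
    respairs_pass <- respairs_pass[respairs_pass$decoy_class == "TT", ,
                                   drop = FALSE]
    ppis_pass <- ppis_pass[ppis_pass$decoy_class == "TT", , drop = FALSE]
  }
  structure(list(csms = csms_pass, respairs = respairs_pass,
                 ppis = ppis_pass, discriminant = discriminant),
            class = "xl_results")
}

#' @export
print.xl_results <- function(x, ...) {
  cat("xl_results:\n")
  cat(sprintf("  CSMs:     %5d (%d inter / %d intra)\n", nrow(x$csms),
              sum(x$csms$link_class == "inter"),
              sum(x$csms$link_class == "intra")))
  cat(sprintf("  ResPairs: %5d (%d inter / %d intra)\n", nrow(x$respairs),
              sum(x$respairs$link_class == "inter"),
              sum(x$respairs$link_class == "intra")))
  cat(sprintf("  PPIs:     %5d\n", nrow(x$ppis)))
  invisible(x)
}
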