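#' Signature doublet detection and mass hypothesis inference
#'
#' The gate of the cleavable-cross-linker search: peak pairs separated by
#' the stub mass difference (at some fragment charge) reveal one linked
#' peptide's mass; pairing doublets against the precursor mass yields
#' alpha/beta peptide mass hypotheses for candidate lookup.
#'
#' @name doublets
NULL

#' Find signature doublets in a spectrum
#'
#' For every fragment charge z in 1..(precursor charge - 1), reports every
#' peak pair whose m/z spacing times z matches the cross-linker's doublet
#' delta within tolerance.  The light peak is interpreted as the linked
#' peptide carrying the light stub, so the peptide mass is inferred as
#' `light_mz * z - z * proton - stub_light`.
#'
#' @param s A preprocessed `xl_spectrum`.
#' @param xl A [crosslinker()].
#' @param tol_ppm Fragment m/z tolerance in ppm.
#' @param max_charge Highest fragment charge considered; defaults to
#'   precursor charge - 1 (at least 1).
#' @return Data frame: `light_mz`, `heavy_mz`, `charge`,
#'   `light_intensity`, `heavy_intensity`, `inferred_peptide_mass`.
#' @export
find_doublets <- function(s, xl = crosslinker_dsso(), tol_ppm = 20,
                          max_charge = NULL) {
  stopifnot(tol_ppm > 0)
  empty <- data.frame(light_mz = numeric(0), heavy_mz = numeric(0),
                      charge = integer(0), light_intensity = numeric(0),
                      heavy_intensity = numeric(0),
                      inferred_peptide_mass = numeric(0))
  if (length(s$mz) < 2L) return(empty)
  if (is.null(max_charge))
    max_charge <- max(1L, (if (is.na(s$charge)) 2L else s$charge) - 1L)
  # deduplicate peaks by m/z within 1e-4 (keep most intense)
  mz <- s$mz; inten <- s$intensity
  grp <- cumsum(c(TRUE, diff(mz) > 1e-4))
  keep <- unlist(lapply(split(seq_along(mz), grp), function(ii)
    ii[which.max(inten[ii])]), use.names = FALSE)
  mz <- mz[keep]; inten <- inten[keep]

  rows <- list()
  for (z in seq_len(max_charge)) {
    target <- mz + xl$doublet_delta / z
    tol <- target * tol_ppm * 1e-6
    lo <- findInterval(target - tol, mz, left.open = TRUE) + 1L
    hi <- findInterval(target + tol, mz)
    has <- hi >= lo
    if (!any(has)) next
    i_idx <- rep.int(which(has), (hi - lo + 1L)[has])
    j_idx <- unlist(mapply(seq, lo[has], hi[has], SIMPLIFY = FALSE),
                    use.names = FALSE)
    pepmass <- mz[i_idx] * z - z * .PROTON_MASS - xl$stub_light_mass
    ok <- pepmass > 0
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      light_mz = mz[i_idx][ok], heavy_mz = mz[j_idx][ok], charge = z,
      light_intensity = inten[i_idx][ok], heavy_intensity = inten[j_idx][ok],
      inferred_peptide_mass = pepmass[ok])
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Infer alpha/beta peptide-mass hypotheses from doublets
#'
#' Hypotheses are formed (a) from complementary doublet pairs whose
#' inferred masses plus the intact bridge mass reconstruct the precursor
#' neutral mass within the MS1 tolerance, and (b) from single doublets
#' with the partner mass defined by difference.  Hypotheses are
#' deduplicated within the MS1 tolerance, ranked complementary-first,
#' then by doublet support, then by summed doublet intensity, and capped.
#'
#' @param doublets Output of [find_doublets()].
#' @param precursor_neutral_mass Neutral precursor mass M, Da.
#' @param xl A [crosslinker()].
#' @param ms1_tol_ppm MS1 tolerance in ppm of M.
#' @param max_hypotheses Cap on returned hypotheses (bounds search cost).
#' @return Data frame: `alpha_mass >= beta_mass`, `support`,
#'   `complementary`, `intensity`.
#' @export
infer_mass_hypotheses <- function(doublets, precursor_neutral_mass,
                                  xl = crosslinker_dsso(), ms1_tol_ppm = 10,
                                  max_hypotheses = 8L) {
  stopifnot(precursor_neutral_mass > 0)
  empty <- data.frame(alpha_mass = numeric(0), beta_mass = numeric(0),
                      support = integer(0), complementary = logical(0),
                      intensity = numeric(0))
  if (is.null(doublets) || nrow(doublets) == 0L) return(empty)
  M <- precursor_neutral_mass
  tol <- M * ms1_tol_ppm * 1e-6
  m <- doublets$inferred_peptide_mass
  w <- doublets$light_intensity + doublets$heavy_intensity
  partner <- M - xl$intact_bridge_mass - m

  hyps <- list()
  # (a) complementary doublet pairs
  if (nrow(doublets) >= 2L) {
    cmb <- which(outer(m, m, function(a, b)
      abs(a + b + xl$intact_bridge_mass - M)) <= tol, arr.ind = TRUE)
    cmb <- cmb[cmb[, 1] < cmb[, 2], , drop = FALSE]
    if (nrow(cmb)) {
      a <- pmax(m[cmb[, 1]], m[cmb[, 2]])
      b <- pmin(m[cmb[, 1]], m[cmb[, 2]])
      hyps[[1L]] <- data.frame(alpha_mass = a, beta_mass = b, support = 2L,
                               complementary = TRUE,
                               intensity = w[cmb[, 1]] + w[cmb[, 2]])
    }
  }
  # (b) single doublets
  ok <- partner > 0
  if (any(ok))
    hyps[[length(hyps) + 1L]] <- data.frame(
      alpha_mass = pmax(m[ok], partner[ok]),
      beta_mass = pmin(m[ok], partner[ok]),
      support = 1L, complementary = FALSE, intensity = w[ok])
  if (length(hyps) == 0L) return(empty)
  h <- do.call(rbind, hyps)

  # deduplicate within MS1 tolerance on the alpha mass (beta follows from
  # complementarity); merge support and intensity, keep any complementary
  h <- h[order(h$alpha_mass), , drop = FALSE]
  grp <- cumsum(c(TRUE, diff(h$alpha_mass) > tol))
  merged <- do.call(rbind, lapply(split(seq_len(nrow(h)), grp), function(ii) {
    data.frame(alpha_mass = h$alpha_mass[ii][which.max(h$intensity[ii])],
               beta_mass = h$beta_mass[ii][which.max(h$intensity[ii])],
               support = sum(h$support[ii]),
               complementary = any(h$complementary[ii]),
               intensity = sum(h$intensity[ii]))
  }))
  ord <- order(-merged$complementary, -merged$support, -merged$intensity)
  merged <- merged[ord, , drop = FALSE]
  rownames(merged) <- NULL
  utils::head(merged, max_hypotheses)
}
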