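#' Theoretical fragment ions for cleavable cross-linked peptides
#'
#' b/y ladders where every ion spanning the cross-link site carries the
#' light- or heavy-stub mass variant; ions not spanning the site are
#' plain linear fragments (the MS-cleavable bridge is cleaved in MS2, so
#' intact two-chain fragments are not modeled).
#'
#' @name fragments
NULL

# Per-residue mass vector including fixed mods and variable mods placed
# at positions encoded in a "pos:name,..." string.
residue_masses_of <- function(sequence, fixed_mods = list(), mod_sites = "",
                              variable_mods = list(mod_oxidation_m()),
                              table = mass_table()) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- table$residue_masses[chars]
  if (anyNA(m)) stop("undefined residue mass in ", sequence)
  for (fm in fixed_mods) m[chars == fm$target] <- m[chars == fm$target] + fm$delta_mass
  if (nzchar(mod_sites)) {
    by_name <- stats::setNames(
      vapply(variable_mods, `[[`, numeric(1), "delta_mass"),
      vapply(variable_mods, `[[`, character(1), "name"))
    for (tok in strsplit(mod_sites, ",", fixed = TRUE)[[1]]) {
      kv <- strsplit(tok, ":", fixed = TRUE)[[1]]
      m[as.integer(kv[1])] <- m[as.integer(kv[1])] + by_name[[kv[2]]]
    }
  }
  unname(m)
}

#' Theoretical fragments of one chain of a cross-linked pair
#'
#' @param sequence Peptide sequence.
#' @param site 1-based cross-link position within the peptide.
#' @param xl A [crosslinker()].
#' @param max_charge Fragment charges 1..max_charge.
#' @param fixed_mods,mod_sites,variable_mods Modification bookkeeping as
#'   in the digest tables.
#' @return Data frame: `ion_type` (`b`, `y`, `b+stubL`, `b+stubH`,
#'   `y+stubL`, `y+stubH`), `ordinal`, `charge`, `mz`.
#' @export
theoretical_fragments <- function(sequence, site, xl = crosslinker_dsso(),
                                  max_charge = 2L, fixed_mods = list(),
                                  mod_sites = "",
                                  variable_mods = list(mod_oxidation_m())) {
  n <- nchar(sequence)
  if (site < 1L || site > n) stop("link site out of range: ", site)
  m <- residue_masses_of(sequence, fixed_mods, mod_sites, variable_mods)
  pre <- cumsum(m)                    # b_i neutral residue sums
  suf <- rev(cumsum(rev(m)))          # y_j neutral residue sums at j = n-i
  bi <- seq_len(n - 1L)
  b_neutral <- pre[bi]
  y_neutral <- suf[bi + 1L] + .WATER_MASS   # y_{n-i}
  yj <- n - bi                              # y ordinal
  b_spans <- bi >= site
  y_spans <- yj >= (n - site + 1L)

  rows <- list()
  add <- function(neutral, ordinal, type) {
    if (length(neutral) == 0L) return(invisible())
    for (z in seq_len(max_charge)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        ion_type = type, ordinal = ordinal, charge = z,
        mz = (neutral + z * .PROTON_MASS) / z)
    }
  }
  add(b_neutral[!b_spans], bi[!b_spans], "b")
  add(b_neutral[b_spans] + xl$stub_light_mass, bi[b_spans], "b+stubL")
  add(b_neutral[b_spans] + xl$stub_heavy_mass, bi[b_spans], "b+stubH")
  add(y_neutral[!y_spans], yj[!y_spans], "y")
  add(y_neutral[y_spans] + xl$stub_light_mass, yj[y_spans], "y+stubL")
  add(y_neutral[y_spans] + xl$stub_heavy_mass, yj[y_spans], "y+stubH")
  out <- do.call(rbind, rows)
  out <- out[out$ordinal >= 1L & nchar(out$ion_type) > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Match theoretical m/z values against a spectrum.  Each theoretical ion
# consumes at most one peak (the nearest within tolerance); a peak may
# serve several theoretical ions.  Returns the peak index per theoretical
# m/z (NA when unmatched).
match_peaks <- function(theo_mz, mz, tol_ppm) {
  if (length(mz) == 0L || length(theo_mz) == 0L)
    return(rep(NA_integer_, length(theo_mz)))
  idx <- findInterval(theo_mz, mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(mz))
  d_lo <- abs(theo_mz - mz[lo])
  d_hi <- abs(theo_mz - mz[hi])
  best <- ifelse(d_hi < d_lo, hi, lo)
  d <- pmin(d_lo, d_hi)
  tol <- theo_mz * tol_ppm * 1e-6
  out <- ifelse(d <= tol, best, NA_integer_)
  as.integer(out)
}

# Chain-level evidence for one peptide at one candidate link site.
chain_evidence <- function(sequence, site, s, xl, ms2_tol_ppm,
                           max_charge = 2L, fixed_mods = list(),
                           mod_sites = "") {
  theo <- theoretical_fragments(sequence, site, xl, max_charge,
                                fixed_mods, mod_sites)
  hit <- match_peaks(theo$mz, s$mz, ms2_tol_ppm)
  matched <- !is.na(hit)
  n <- nchar(sequence)
  covered <- rep(FALSE, n - 1L)
  if (any(matched)) {
    pos <- ifelse(startsWith(theo$ion_type, "b"), theo$ordinal,
                  n - theo$ordinal)       # cleavage position index 1..n-1
    covered[unique(pos[matched])] <- TRUE
  }
  runs <- rle(covered)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(n_matched = sum(matched),
       coverage = mean(covered),
       longest_run = as.integer(longest),
       peak_idx = unique(hit[matched]))
}
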