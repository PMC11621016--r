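#' In-silico digestion and the peptide mass index
#'
#' Tryptic digestion with missed cleavages, variable-modification
#' enumeration, decoy generation and a sorted mass index supporting
#' ppm-window queries.  Peptide tables are plain data frames; one row per
#' unique (sequence, modification placement) form.
#'
#' @name digest
NULL

#' Digestion parameters
#'
#' Defaults reproduce a standard cleavable-cross-linker search: trypsin
#' (cleave C-terminal of K/R, not before P), up to 3 missed cleavages,
#' minimum length 6, peptide mass 500--6,000 Da, carbamidomethyl-C fixed
#' and oxidation-M variable (at most 2 per peptide).
#'
#' @param max_missed_cleavages Maximum internal missed cleavage sites.
#' @param min_length Minimum peptide length in residues.
#' @param mass_range Numeric length-2, allowed peptide mass window in Da.
#' @param fixed_mods,variable_mods Lists of [modification()] objects.
#' @param max_variable_mods Cap on variable modifications per peptide.
#' @param allow_cterm_link_site Whether a reactive residue at the peptide
#'   C-terminus of a fully tryptic peptide counts as a cross-link site.
#'   A cross-linked lysine resists cleavage, but missed-cleavage forms
#'   cover it either way; allowing it maximizes recall.
#' @return A list of class `xl_digest_params`.
#' @export
digest_params <- function(max_missed_cleavages = 3L,
                          min_length = 6L,
                          mass_range = c(500, 6000),
                          fixed_mods = list(mod_carbamidomethyl()),
                          variable_mods = list(mod_oxidation_m()),
                          max_variable_mods = 2L,
                          allow_cterm_link_site = TRUE) {
  stopifnot(max_missed_cleavages >= 0, mass_range[1] < mass_range[2])
  structure(list(
    max_missed_cleavages = as.integer(max_missed_cleavages),
    min_length = as.integer(min_length),
    mass_range = as.numeric(mass_range),
    fixed_mods = fixed_mods,
    variable_mods = variable_mods,
    max_variable_mods = as.integer(max_variable_mods),
    allow_cterm_link_site = isTRUE(allow_cterm_link_site)
  ), class = "xl_digest_params")
}

# Sum of residue masses for a character vector of sequences; NA when a
# sequence contains a residue outside the 20-letter alphabet.
residue_mass_sum <- function(sequences, table = mass_table()) {
  chars <- strsplit(sequences, "", fixed = TRUE)
  lens <- lengths(chars)
  m <- table$residue_masses[unlist(chars, use.names = FALSE)]
  grp <- rep.int(seq_along(sequences), lens)
  out <- rep(NA_real_, length(sequences))
  sums <- vapply(split(m, factor(grp, levels = seq_along(sequences))),
                 sum, numeric(1))
  out[] <- sums
  out
}

#' Monoisotopic peptide mass
#'
#' Residue masses plus one water plus fixed-modification deltas (applied
#' per occurrence of the target residue) plus any extra variable-mod
#' delta.
#'
#' @param sequence Peptide sequence (single string, standard residues).
#' @param fixed_mods List of fixed [modification()]s.
#' @param extra_delta Additional mass delta (e.g. from variable mods), Da.
#' @param table A [mass_table()].
#' @return Mass in Da.
#' @examples
#' peptide_mass("GG")   # 132.0535
#' @export
peptide_mass <- function(sequence, fixed_mods = list(), extra_delta = 0,
                         table = mass_table()) {
  if (length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  base <- residue_mass_sum(sequence, table)
  if (is.na(base))
    stop("sequence contains residues with undefined mass: ", sequence)
  fx <- fixed_mod_delta(sequence, fixed_mods)
  base + table$water_mass + fx + extra_delta
}

# Total fixed-mod delta for sequences (vectorized).
fixed_mod_delta <- function(sequences, fixed_mods) {
  if (length(fixed_mods) == 0L) return(numeric(length(sequences)))
  delta <- numeric(length(sequences))
  for (m in fixed_mods) {
    n <- nchar(sequences) - nchar(gsub(m$target, "", sequences, fixed = TRUE))
    delta <- delta + n * m$delta_mass
  }
  delta
}

# Trypsin cleavage sites: after K/R not before P.  Returns 0-based cut
# positions (between site and site+1), excluding the ends.
tryptic_sites <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  idx <- which(chars[-n] %in% c("K", "R") & chars[-1] != "P")
  idx
}

#' Digest one protein sequence
#'
#' Enumerates tryptic peptides with 0..`max_missed_cleavages` internal
#' missed cleavages, then applies the length and mass filters.  Peptides
#' containing residues outside the standard 20-letter alphabet (B, J, O,
#' U, X, Z) are dropped with a warning: their masses are undefined and
#' would poison the index.
#'
#' @param sequence Protein sequence.
#' @param params An [xl_digest_params][digest_params()] object.
#' @return A data frame with columns `sequence`, `start` (1-based position
#'   in the protein), `missed` and `mass` (Da, including fixed mods).
#' @examples
#' digest_protein("MKAREK", digest_params(max_missed_cleavages = 1,
#'                                        min_length = 1,
#'                                        mass_range = c(1, 10000),
#'                                        fixed_mods = list()))
#' @export
digest_protein <- function(sequence, params = digest_params()) {
  if (length(sequence) != 1L || !nzchar(sequence)) stop("empty sequence")
  sites <- tryptic_sites(sequence)
  bounds <- c(0L, sites, nchar(sequence))  # piece boundaries
  npiece <- length(bounds) - 1L
  out_seq <- character(0); out_start <- integer(0); out_miss <- integer(0)
  for (i in seq_len(npiece)) {
    jmax <- min(npiece, i + params$max_missed_cleavages)
    for (j in i:jmax) {
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      out_seq <- c(out_seq, substr(sequence, s, e))
      out_start <- c(out_start, s)
      out_miss <- c(out_miss, j - i)
    }
  }
  keep_len <- nchar(out_seq) >= params$min_length
  out_seq <- out_seq[keep_len]; out_start <- out_start[keep_len]
  out_miss <- out_miss[keep_len]
  if (length(out_seq) == 0L)
    return(data.frame(sequence = character(0), start = integer(0),
                      missed = integer(0), mass = numeric(0)))
  base <- residue_mass_sum(out_seq)
  bad <- is.na(base)
  if (any(bad)) {
    warning("dropping ", sum(bad),
            " peptide(s) containing non-standard residues")
    out_seq <- out_seq[!bad]; out_start <- out_start[!bad]
    out_miss <- out_miss[!bad]; base <- base[!bad]
  }
  mass <- base + .WATER_MASS + fixed_mod_delta(out_seq, params$fixed_mods)
  keep <- mass >= params$mass_range[1] & mass <= params$mass_range[2]
  data.frame(sequence = out_seq[keep], start = out_start[keep],
             missed = out_miss[keep], mass = mass[keep])
}

#' Enumerate variable-modification placements
#'
#' All placements of at most `max_mods` variable modifications on a
#' sequence, including the unmodified form; no duplicate placements.
#'
#' @param sequence Peptide sequence.
#' @param mods List of variable [modification()]s.
#' @param max_mods Maximum number of variable mods per peptide.
#' @return Data frame with `sequence`, `mod_delta` (total Da), `mod_sites`
#'   (comma-separated `pos:name` labels, `""` for unmodified) and `n_mods`.
#' @examples
#' enumerate_variable_mods("MM", list(mod_oxidation_m()), 2)  # 4 forms
#' @export
enumerate_variable_mods <- function(sequence, mods, max_mods) {
  stopifnot(max_mods >= 0)
  targets <- list()
  for (m in mods) {
    pos <- gregexpr(m$target, sequence, fixed = TRUE)[[1]]
    if (pos[1] != -1L)
      for (p in pos) targets[[length(targets) + 1L]] <-
        list(pos = p, delta = m$delta_mass, name = m$name)
  }
  base <- data.frame(sequence = sequence, mod_delta = 0,
                     mod_sites = "", n_mods = 0L)
  k <- length(targets)
  if (k == 0L || max_mods == 0L) return(base)
  rows <- list(base)
  for (sz in seq_len(min(max_mods, k))) {
    combos <- utils::combn(k, sz, simplify = FALSE)
    for (cc in combos) {
      sel <- targets[cc]
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = sequence,
        mod_delta = sum(vapply(sel, `[[`, numeric(1), "delta")),
        mod_sites = paste(vapply(sel, function(s)
          paste0(s$pos, ":", s$name), character(1)), collapse = ","),
        n_mods = sz)
    }
  }
  do.call(rbind, rows)
}

#' Generate decoy peptides
#'
#' One decoy per target.  `reverse_keep_cterm` reverses all but the
#' C-terminal residue, preserving the tryptic terminus and the exact
#' composition (and hence the mass).  `shuffle_keep_cterm` shuffles
#' instead (seeded).  A decoy colliding with its target sequence
#' (palindromes) falls back to seeded shuffling with up to 10 retries,
#' then is kept and flagged.
#'
#' @param sequences Character vector of target sequences.
#' @param strategy `"reverse_keep_cterm"` or `"shuffle_keep_cterm"`.
#' @param seed Integer seed for the shuffle paths.
#' @return Data frame with `target`, `decoy` and `collision` (decoy equals
#'   target after retries).
#' @export
generate_decoys <- function(sequences,
                            strategy = c("reverse_keep_cterm",
                                         "shuffle_keep_cterm"),
                            seed = 1L) {
  strategy <- match.arg(strategy)
  rng <- local_rng(seed)
  perm1 <- function(s) {
    n <- nchar(s)
    if (n <= 2L) return(s)
    head <- strsplit(substr(s, 1L, n - 1L), "", fixed = TRUE)[[1]]
    if (strategy == "reverse_keep_cterm") head <- rev(head)
    else head <- head[rng$sample(length(head))]
    paste0(paste(head, collapse = ""), substr(s, n, n))
  }
  dec <- vapply(sequences, perm1, character(1), USE.NAMES = FALSE)
  coll <- dec == sequences
  for (i in which(coll)) {
    n <- nchar(sequences[i])
    for (try in 1:10) {
      head <- strsplit(substr(sequences[i], 1L, n - 1L), "", fixed = TRUE)[[1]]
      cand <- paste0(paste(head[rng$sample(length(head))], collapse = ""),
                     substr(sequences[i], n, n))
      if (cand != sequences[i]) { dec[i] <- cand; coll[i] <- FALSE; break }
    }
  }
  data.frame(target = sequences, decoy = dec, collision = coll)
}

# Private RNG that does not disturb the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    st
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f()
  }
  list(
    sample = function(n, size = n, replace = FALSE, prob = NULL)
      with_state(function() sample.int(n, size, replace, prob)),
    runif = function(n, min = 0, max = 1)
      with_state(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1)
      with_state(function() stats::rnorm(n, mean, sd)),
    rlnorm = function(n, meanlog = 0, sdlog = 1)
      with_state(function() stats::rlnorm(n, meanlog, sdlog)),
    rpois = function(n, lambda)
      with_state(function() stats::rpois(n, lambda)),
    rbinom = function(n, size, prob)
      with_state(function() stats::rbinom(n, size, prob))
  )
}
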