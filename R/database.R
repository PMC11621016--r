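#' Search database construction
#'
#' Reading FASTA, digesting whole databases into unique peptide forms,
#' appending decoys and building the mass-sorted peptide index used for
#' candidate lookup.
#'
#' @name database
NULL

#' Read a protein FASTA file
#'
#' The accession is the first whitespace-delimited token after `>`.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (names = accessions).
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Write a protein FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Digest a protein database into unique peptide forms
#'
#' Digests every protein, enumerates variable-modification forms,
#' aggregates identical sequences across proteins (a peptide maps to ALL
#' proteins containing it) and optionally appends reversed decoys with
#' matched masses.  Decoy accessions are the target accessions prefixed
#' `DEC_`.
#'
#' @param proteins Named character vector (accession -> sequence) or a
#'   FASTA path.
#' @param params [digest_params()].
#' @param xl An [crosslinker()]; used to annotate cross-linkable sites.
#' @param decoys Append decoy peptides?
#' @param seed Seed for decoy shuffling fallbacks.
#' @return Data frame with one row per unique peptide form: `sequence`,
#'   `mass`, `mod_delta`, `mod_sites`, `proteins` and `starts`
#'   (`;`-collapsed, parallel), `missed`, `is_decoy`, `link_sites`
#'   (comma-collapsed 1-based in-peptide positions; `""` if none).
#' @export
digest_database <- function(proteins, params = digest_params(),
                            xl = crosslinker_dsso(), decoys = TRUE,
                            seed = 1L) {
  if (is.character(proteins) && length(proteins) == 1L && is.null(names(proteins)))
    proteins <- read_fasta(proteins)
  stopifnot(length(proteins) > 0, !is.null(names(proteins)))

  per_prot <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    d <- digest_protein(proteins[[i]], params)
    if (nrow(d) > 0L) d$protein <- names(proteins)[i]
    per_prot[[i]] <- d
  }
  all_pep <- do.call(rbind, per_prot[lengths(per_prot) > 0 &
                                       vapply(per_prot, nrow, 1L) > 0])
  if (is.null(all_pep) || nrow(all_pep) == 0L)
    stop("digestion produced no peptides")

  # aggregate provenance per unique sequence
  key <- all_pep$sequence
  agg_prot <- vapply(split(all_pep$protein, key), paste, character(1),
                     collapse = ";")
  agg_start <- vapply(split(as.character(all_pep$start), key), paste,
                      character(1), collapse = ";")
  agg_miss <- vapply(split(all_pep$missed, key), min, numeric(1))
  useq <- names(agg_prot)
  base_mass <- residue_mass_sum(useq) + .WATER_MASS +
    fixed_mod_delta(useq, params$fixed_mods)

  targets <- expand_mod_forms(useq, base_mass, agg_prot[useq],
                              agg_start[useq], as.integer(agg_miss[useq]),
                              params)
  targets$is_decoy <- FALSE

  out <- targets
  if (decoys) {
    dec <- generate_decoys(useq, "reverse_keep_cterm", seed = seed)
    dseq <- dec$decoy
    dmass <- residue_mass_sum(dseq) + .WATER_MASS +
      fixed_mod_delta(dseq, params$fixed_mods)
    dprot <- vapply(strsplit(agg_prot[useq], ";", fixed = TRUE),
                    function(p) paste0("DEC_", p, collapse = ";"),
                    character(1))
    dtab <- expand_mod_forms(dseq, dmass, dprot, agg_start[useq],
                             as.integer(agg_miss[useq]), params)
    dtab$is_decoy <- TRUE
    out <- rbind(targets, dtab)
  }
  out$link_sites <- link_site_string(out$sequence, out$starts, xl, params)
  rownames(out) <- NULL
  out
}

# Expand unique sequences into variable-mod forms (vector-friendly: only
# sequences containing a target residue branch).
expand_mod_forms <- function(seqs, base_mass, prots, starts, missed, params) {
  vm <- params$variable_mods
  n <- length(seqs)
  base <- data.frame(sequence = seqs, mass = base_mass, mod_delta = 0,
                     mod_sites = "", proteins = prots, starts = starts,
                     missed = missed, stringsAsFactors = FALSE)
  if (length(vm) == 0L || params$max_variable_mods == 0L) return(base)
  pat <- paste0("[", paste(vapply(vm, `[[`, character(1), "target"),
                           collapse = ""), "]")
  has <- grepl(pat, seqs)
  extra <- list()
  for (i in which(has)) {
    forms <- enumerate_variable_mods(seqs[i], vm, params$max_variable_mods)
    forms <- forms[forms$n_mods > 0L, , drop = FALSE]
    if (nrow(forms) == 0L) next
    extra[[length(extra) + 1L]] <- data.frame(
      sequence = seqs[i], mass = base_mass[i] + forms$mod_delta,
      mod_delta = forms$mod_delta, mod_sites = forms$mod_sites,
      proteins = prots[i], starts = starts[i], missed = missed[i],
      stringsAsFactors = FALSE)
  }
  if (length(extra) == 0L) return(base)
  out <- rbind(base, do.call(rbind, extra))
  keep <- out$mass >= params$mass_range[1] & out$mass <= params$mass_range[2]
  out[keep, , drop = FALSE]
}

# Comma-collapsed cross-linkable in-peptide positions.
link_site_string <- function(seqs, starts, xl, params) {
  pat <- paste0("[", paste(xl$reactive_sites, collapse = ""), "]")
  m <- gregexpr(pat, seqs)
  nterm_ok <- xl$protein_n_terminus_reactive &
    vapply(strsplit(starts, ";", fixed = TRUE),
           function(s) any(s == "1"), logical(1))
  lens <- nchar(seqs)
  vapply(seq_along(seqs), function(i) {
    pos <- m[[i]]
    pos <- if (pos[1] == -1L) integer(0) else as.integer(pos)
    if (!params$allow_cterm_link_site)
      pos <- pos[pos != lens[i]]
    if (nterm_ok[i]) pos <- sort(unique(c(1L, pos)))
    paste(pos, collapse = ",")
  }, character(1))
}

#' Build a mass-sorted peptide index
#'
#' @param peptides Peptide table from [digest_database()] (any data frame
#'   with a numeric `mass` column).
#' @return An `xl_peptide_index`: the table sorted by mass plus the sorted
#'   mass vector for binary search.
#' @export
build_peptide_index <- function(peptides) {
  if (is.null(peptides) || nrow(peptides) == 0L)
    stop("cannot index an empty peptide list")
  ord <- order(peptides$mass)
  tab <- peptides[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, masses = tab$mass), class = "xl_peptide_index")
}

#' Query the peptide index by mass window
#'
#' Returns the row indices (into `index$table`) of all peptides whose mass
#' is within the tolerance of `mass`; equivalent to a linear scan.
#'
#' @param index An [build_peptide_index()] object.
#' @param mass Query mass, Da.
#' @param tol_ppm Tolerance in ppm (used when `tol_da` is `NULL`).
#' @param tol_da Absolute tolerance in Da, overrides `tol_ppm`.
#' @return Integer vector of row indices.
#' @export
query_peptide_index <- function(index, mass, tol_ppm = 10, tol_da = NULL) {
  tol <- if (is.null(tol_da)) mass * tol_ppm * 1e-6 else tol_da
  lo <- findInterval(mass - tol, index$masses, left.open = TRUE) + 1L
  hi <- findInterval(mass + tol, index$masses)
  if (hi < lo) integer(0) else lo:hi
}

#' @export
print.xl_peptide_index <- function(x, ...) {
  cat("xl_peptide_index:", nrow(x$table), "peptide forms,",
      sum(x$table$is_decoy %||% FALSE), "decoy forms; mass range",
      sprintf("%.2f-%.2f Da\n", min(x$masses), max(x$masses)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count unique tryptic peptides in a database
#'
#' Digests every protein (no variable-modification expansion, fixed mods
#' included in the mass filter) and counts unique peptide sequences, plus
#' how many sequences are shared between exactly two and exactly three
#' proteins.
#'
#' @param proteins Named character vector or FASTA path.
#' @param params [digest_params()].
#' @return List with `n_unique`, `n_shared_by_2`, `n_shared_by_3`.
#' @export
count_unique_peptides <- function(proteins, params = digest_params()) {
  if (is.character(proteins) && length(proteins) == 1L && is.null(names(proteins)))
    proteins <- read_fasta(proteins)
  seqs <- new.env(hash = TRUE)
  for (i in seq_along(proteins)) {
    d <- digest_protein(proteins[[i]], params)
    for (s in unique(d$sequence)) {
      cur <- if (is.null(seqs[[s]])) character(0) else seqs[[s]]
      seqs[[s]] <- union(cur, names(proteins)[i])
    }
  }
  counts <- vapply(ls(seqs), function(s) length(seqs[[s]]), integer(1))
  list(n_unique = length(counts),
       n_shared_by_2 = sum(counts == 2L),
       n_shared_by_3 = sum(counts == 3L))
}
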