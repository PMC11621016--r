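#' Mixing-scheme ground truth and empirical FDR
#'
#' The benchmark standard mixes recombinant proteins pairwise within
#' interaction groups (default 32 groups of 8, i.e. 28 allowed
#' protein pairs per group and 896 in total); groups are assigned to
#' acquisition batches.  Within-group interlinks and intralinks on
#' present proteins are allowed; between-group interlinks, intralinks on
#' absent proteins and sites outside the recombinant construct ranges
#' are false.  The fraction of such violations among the reported
#' identifications is the empirical FDR.
#'
#' @name benchmark
NULL

#' Construct a mixing scheme
#'
#' @param accessions Character vector of protein accessions.
#' @param group_id Integer group per protein (disjoint groups).
#' @param batch_id Integer batch per protein (constant within group).
#' @param construct_start,construct_end Optional 1-based residue range of
#'   the recombinant construct per protein (NA = full length).
#' @return Data frame of class `xl_mixing_scheme`.
#' @export
mixing_scheme <- function(accessions, group_id, batch_id = NULL,
                          construct_start = NA_integer_,
                          construct_end = NA_integer_) {
  stopifnot(length(accessions) == length(group_id),
            !anyDuplicated(accessions))
  if (is.null(batch_id)) batch_id <- rep(NA_integer_, length(accessions))
  structure(data.frame(accession = as.character(accessions),
                       group_id = as.integer(group_id),
                       batch_id = as.integer(batch_id),
                       construct_start = as.integer(construct_start),
                       construct_end = as.integer(construct_end),
                       stringsAsFactors = FALSE),
            class = c("xl_mixing_scheme", "data.frame"))
}

#' Read / write a mixing-scheme TSV
#'
#' Columns: accession, group_id, batch_id, construct_start, construct_end.
#'
#' @param path TSV path.
#' @return An `xl_mixing_scheme`.
#' @export
read_mixing_scheme <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  mixing_scheme(d$accession, d$group_id, d$batch_id,
                d$construct_start, d$construct_end)
}

#' @rdname read_mixing_scheme
#' @param scheme An `xl_mixing_scheme`.
#' @export
write_mixing_scheme <- function(scheme, path) {
  utils::write.table(as.data.frame(scheme), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enumerate the allowed protein pairs of a scheme
#'
#' The union over groups of all within-group unordered pairs; with g
#' groups of size n each, `g * choose(n, 2)` pairs.
#'
#' @param scheme An `xl_mixing_scheme`.
#' @param batches Optional batch ids to restrict to.
#' @return Data frame `protein_a < protein_b`, one row per allowed pair.
#' @export
enumerate_allowed_ppis <- function(scheme, batches = NULL) {
  s <- scheme
  if (!is.null(batches)) s <- s[s$batch_id %in% batches, , drop = FALSE]
  pairs <- lapply(split(s$accession, s$group_id), function(acc) {
    if (length(acc) < 2L) return(NULL)
    cmb <- utils::combn(sort(acc), 2L)
    data.frame(protein_a = cmb[1, ], protein_b = cmb[2, ],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(protein_a = character(0), protein_b = character(0))
  rownames(out) <- NULL
  out
}

#' Classify one identification against the scheme
#'
#' @param protein_a,protein_b Accessions (equal for an intralink); either
#'   may be a `;`-separated list of candidate mappings for shared
#'   peptides -- the record is labeled allowed if ANY consistent mapping
#'   is allowed.
#' @param scheme An `xl_mixing_scheme`; entrapment proteins are exactly
#'   those absent from it.
#' @param pos_a,pos_b Optional residue coordinates, checked against the
#'   construct ranges.
#' @return One of `"allowed_inter"`, `"allowed_intra"`,
#'   `"prohibited_inter"`, `"prohibited_intra_absent"`,
#'   `"out_of_construct"`.
#' @export
classify_identification <- function(protein_a, protein_b, scheme,
                                    pos_a = NA_integer_,
                                    pos_b = NA_integer_) {
  pa <- strsplit(protein_a, ";", fixed = TRUE)[[1]]
  pb <- strsplit(protein_b, ";", fixed = TRUE)[[1]]
  best <- NULL
  rank <- c(allowed_intra = 1, allowed_inter = 1, out_of_construct = 2,
            prohibited_intra_absent = 3, prohibited_inter = 3)
  for (a in pa) for (b in pb) {
    lab <- classify_one(a, b, scheme, pos_a, pos_b)
    if (is.null(best) || rank[[lab]] < rank[[best]]) best <- lab
  }
  best
}

classify_one <- function(a, b, scheme, pos_a, pos_b) {
  ga <- scheme$group_id[match(a, scheme$accession)]
  gb <- scheme$group_id[match(b, scheme$accession)]
  if (a == b) {
    if (is.na(ga)) return("prohibited_intra_absent")
    if (out_of_construct(a, c(pos_a, pos_b), scheme))
      return("out_of_construct")
    return("allowed_intra")
  }
  if (is.na(ga) || is.na(gb) || ga != gb) return("prohibited_inter")
  if (out_of_construct(a, pos_a, scheme) ||
      out_of_construct(b, pos_b, scheme)) return("out_of_construct")
  "allowed_inter"
}

out_of_construct <- function(acc, pos, scheme) {
  i <- match(acc, scheme$accession)
  if (is.na(i)) return(FALSE)
  lo <- scheme$construct_start[i]; hi <- scheme$construct_end[i]
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0L) return(FALSE)
  (!is.na(lo) && any(pos < lo)) || (!is.na(hi) && any(pos > hi))
}

#' Empirical FDR of identifications against the scheme
#'
#' `(#prohibited + #out-of-construct) / #total`, i.e. the mean of the
#' violation indicator.
#'
#' @param records Data frame with `protein_a`, `protein_b` and optional
#'   `pos_a`, `pos_b` columns (target records only).
#' @param scheme An `xl_mixing_scheme`.
#' @return List with `n`, `n_false`, `fdr` (NA when `n` is 0) and the
#'   per-record `labels`.
#' @export
empirical_fdr <- function(records, scheme) {
  if (nrow(records) == 0L)
    return(list(n = 0L, n_false = 0L, fdr = NA_real_,
                labels = character(0)))
  pos_a <- if ("pos_a" %in% names(records)) records$pos_a else NA_integer_
  pos_b <- if ("pos_b" %in% names(records)) records$pos_b else NA_integer_
  labels <- vapply(seq_len(nrow(records)), function(i)
    classify_identification(records$protein_a[i], records$protein_b[i],
                            scheme,
                            if (length(pos_a) > 1L) pos_a[i] else pos_a,
                            if (length(pos_b) > 1L) pos_b[i] else pos_b),
    character(1))
  false <- labels %in% c("prohibited_inter", "prohibited_intra_absent",
                         "out_of_construct")
  list(n = nrow(records), n_false = sum(false),
       fdr = mean(false), labels = labels)
}

#' PPI coverage of the theoretical maximum
#'
#' @param n_identified Number of allowed PPIs identified.
#' @param scheme An `xl_mixing_scheme`.
#' @param batches Optional batch restriction.
#' @return Percentage of the scheme's allowed pairs.
#' @export
ppi_coverage <- function(n_identified, scheme, batches = NULL) {
  100 * n_identified / nrow(enumerate_allowed_ppis(scheme, batches))
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment with match 1, mismatch 0, gap -1
#' (no affine opening cost); identity = matches / alignment length.
#'
#' @param a,b Protein sequences.
#' @return Identity in `[0, 1]`.
#' @export
sequence_identity <- function(a, b) {
  letters <- unique(c(Biostrings::AA_STANDARD,
                      strsplit(paste0(a, b), "")[[1]]))
  mat <- matrix(0, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 1)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' Build an entrapment database
#'
#' Appends randomly sampled pool proteins whose best global identity to
#' any standard protein is below the threshold, until `n_total` entries.
#'
#' @param standard Named character vector of standard protein sequences.
#' @param pool Named character vector of candidate entrapment sequences.
#' @param n_total Total database size (standard + entrapment).
#' @param identity_threshold Exclude pool entries with identity >= this
#'   to any standard protein.
#' @param seed Sampling seed.
#' @return Named character vector of `n_total` sequences.
#' @export
build_entrapment_db <- function(standard, pool, n_total,
                                identity_threshold = 0.85, seed = 1L) {
  stopifnot(identity_threshold > 0, identity_threshold < 1,
            n_total >= length(standard))
  n_need <- n_total - length(standard)
  if (n_need == 0L) return(standard)
  rng <- local_rng(seed)
  ord <- rng$sample(length(pool))
  chosen <- character(0)
  out <- standard
  for (i in ord) {
    if (length(chosen) == n_need) break
    ident <- vapply(standard, function(s)
      sequence_identity(pool[[i]], s), numeric(1))
    if (all(ident < identity_threshold)) {
      chosen <- c(chosen, names(pool)[i])
      out <- c(out, pool[i])
    }
  }
  if (length(chosen) < n_need)
    stop("entrapment pool exhausted: needed ", n_need, ", found ",
         length(chosen), " below identity ", identity_threshold)
  out
}
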