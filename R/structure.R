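#' Mapping residue pairs onto predicted structures
#'
#' Utilities for evaluating identified cross-links against predicted
#' protein models: the combined model confidence score, Calpha--Calpha
#' distances, and pLDDT-based filtering of disordered regions.
#'
#' @name structure_eval
NULL

#' Combined model confidence score
#'
#' `0.8 * ipTM + 0.2 * pTM`, the standard ranking score of multimeric
#' structure predictions.
#'
#' @param iptm,ptm Interface and global predicted-TM scores in `[0, 1]`.
#' @return Confidence in `[0, 1]`.
#' @export
model_confidence <- function(iptm, ptm) {
  if (any(iptm < 0 | iptm > 1 | ptm < 0 | ptm > 1))
    stop("ipTM and pTM must lie in [0, 1]")
  0.8 * iptm + 0.2 * ptm
}

#' Build a structure model table
#'
#' @param chain Chain identifiers per residue.
#' @param resno 1-based residue numbers.
#' @param x,y,z Calpha coordinates in Angstrom.
#' @param plddt Per-residue pLDDT in `[0, 100]`.
#' @return Data frame of class `xl_structure_model`.
#' @export
structure_model <- function(chain, resno, x, y, z, plddt = NA_real_) {
  stopifnot(all(is.finite(x)), all(is.finite(y)), all(is.finite(z)),
            all(is.na(plddt) | (plddt >= 0 & plddt <= 100)))
  structure(data.frame(chain = as.character(chain),
                       resno = as.integer(resno),
                       x = x, y = y, z = z, plddt = plddt,
                       stringsAsFactors = FALSE),
            class = c("xl_structure_model", "data.frame"))
}

#' Read Calpha records from a PDB file
#'
#' Uses bio3d; pLDDT is taken from the B-factor column (the convention
#' of predicted-structure outputs).
#'
#' @param path PDB file.
#' @return An [structure_model()] table.
#' @export
read_structure_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("PDB reading requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  ca <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
  structure_model(ca$chain, ca$resno, ca$x, ca$y, ca$z, ca$b)
}

#' Calpha--Calpha distance between two residues
#'
#' @param model An [structure_model()].
#' @param res_a,res_b `(chain, resno)` pairs, e.g. `list("A", 12)`.
#' @return Euclidean distance in Angstrom.
#' @export
ca_distance <- function(model, res_a, res_b) {
  find <- function(r) {
    i <- which(model$chain == r[[1]] & model$resno == as.integer(r[[2]]))
    if (length(i) == 0L)
      stop("residue not found in model: chain ", r[[1]], " resno ", r[[2]])
    i[1]
  }
  i <- find(res_a); j <- find(res_b)
  sqrt((model$x[i] - model$x[j])^2 + (model$y[i] - model$y[j])^2 +
         (model$z[i] - model$z[j])^2)
}

#' Filter residue pairs to ordered regions
#'
#' Keeps pairs where BOTH residues have pLDDT strictly above the
#' threshold, excluding cross-links located in disordered regions.
#'
#' @param respairs Data frame with `chain_a`, `resno_a`, `chain_b`,
#'   `resno_b` columns.
#' @param model An [structure_model()].
#' @param plddt_min Threshold in `[0, 100]` (strict inequality).
#' @return The kept subset.
#' @export
filter_ordered_links <- function(respairs, model, plddt_min = 50) {
  stopifnot(plddt_min >= 0, plddt_min <= 100)
  if (nrow(respairs) == 0L) return(respairs)
  plddt_of <- function(chain, resno) {
    i <- match(paste(chain, resno), paste(model$chain, model$resno))
    model$plddt[i]
  }
  pa <- plddt_of(respairs$chain_a, respairs$resno_a)
  pb <- plddt_of(respairs$chain_b, respairs$resno_b)
  keep <- !is.na(pa) & !is.na(pb) & pa > plddt_min & pb > plddt_min
  respairs[keep, , drop = FALSE]
}

#' Cross-link satisfaction of a model
#'
#' Fraction of residue pairs whose Calpha--Calpha distance is within the
#' cutoff (default 35 Angstrom, appropriate for DSSO-class linkers);
#' used to pick the best of several ranked models per protein pair.
#'
#' @param model An [structure_model()].
#' @param respairs Data frame with `chain_a`, `resno_a`, `chain_b`,
#'   `resno_b`.
#' @param cutoff Distance cutoff in Angstrom.
#' @return Fraction in `[0, 1]` (NA for no mappable pairs).
#' @export
crosslink_satisfaction <- function(model, respairs, cutoff = 35) {
  if (nrow(respairs) == 0L) return(NA_real_)
  d <- vapply(seq_len(nrow(respairs)), function(i) {
    tryCatch(ca_distance(model,
                         list(respairs$chain_a[i], respairs$resno_a[i]),
                         list(respairs$chain_b[i], respairs$resno_b[i])),
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(d))) return(NA_real_)
  mean(d[!is.na(d)] <= cutoff)
}
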