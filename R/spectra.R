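#' MS2 spectrum input and preprocessing
#'
#' Spectra are lists with `spectrum_id`, `scan`, `precursor_mz`, `charge`,
#' `mz` and `intensity` (parallel numeric vectors, m/z ascending), plus a
#' `searchable` flag set by [preprocess_spectrum()].  Collections are
#' plain lists of such spectra.
#'
#' @name spectra
NULL

#' Construct a spectrum
#'
#' @param spectrum_id Identifier (e.g. MGF TITLE).
#' @param precursor_mz Precursor m/z.
#' @param charge Precursor charge (0 when unknown).
#' @param mz,intensity Peak list; re-sorted ascending by m/z.
#' @param scan Scan number (optional).
#' @return A list of class `xl_spectrum`.
#' @export
spectrum <- function(spectrum_id, precursor_mz, charge, mz, intensity,
                     scan = NA_integer_) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  ord <- order(mz)
  structure(list(spectrum_id = as.character(spectrum_id),
                 scan = as.integer(scan),
                 precursor_mz = as.numeric(precursor_mz),
                 charge = as.integer(charge),
                 mz = as.numeric(mz[ord]),
                 intensity = as.numeric(intensity[ord]),
                 searchable = NA),
            class = "xl_spectrum")
}

#' Neutral precursor mass of a spectrum
#'
#' `M = precursor_mz * z - z * proton`.
#'
#' @param s An `xl_spectrum`.
#' @return Neutral mass in Da (NA for unknown charge).
#' @export
precursor_neutral_mass <- function(s) {
  if (is.na(s$charge) || s$charge < 1L) return(NA_real_)
  s$precursor_mz * s$charge - s$charge * .PROTON_MASS
}

#' Read an MGF file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, `CHARGE`,
#' `TITLE` and optional `SCANS`.  Blocks without a charge are kept with
#' charge 0 (excluded from search later: the cross-link search needs the
#' neutral precursor mass).  Malformed blocks are skipped with a warning.
#'
#' @param path MGF file.
#' @return List of `xl_spectrum`.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends))
    stop("malformed MGF: unbalanced BEGIN/END IONS in ", path)
  out <- vector("list", length(begins))
  n_bad <- 0L
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    is_hdr <- grepl("=", block, fixed = TRUE)
    hdr <- block[is_hdr]
    keyval <- regmatches(hdr, regexpr("=", hdr), invert = TRUE)
    keys <- toupper(vapply(keyval, `[`, character(1), 1L))
    vals <- vapply(keyval, `[`, character(1), 2L)
    getv <- function(key) if (key %in% keys) vals[match(key, keys)] else NA_character_
    pepmass <- suppressWarnings(
      as.numeric(strsplit(getv("PEPMASS"), "\\s+")[[1]][1]))
    if (is.na(pepmass)) { n_bad <- n_bad + 1L; next }
    chs <- getv("CHARGE")
    charge <- if (is.na(chs)) 0L else
      suppressWarnings(as.integer(gsub("[^0-9]", "", chs)))
    if (is.na(charge)) charge <- 0L
    title <- getv("TITLE")
    if (is.na(title)) title <- paste0(basename(path), ".", k)
    scan <- suppressWarnings(as.integer(getv("SCANS")))
    pk <- block[!is_hdr]
    pk <- pk[nzchar(pk)]
    if (length(pk)) {
      m <- do.call(rbind, lapply(strsplit(pk, "[\t ]+"), function(x)
        suppressWarnings(as.numeric(x[1:2]))))
      ok <- stats::complete.cases(m)
      mz <- m[ok, 1]; inten <- m[ok, 2]
    } else { mz <- numeric(0); inten <- numeric(0) }
    out[[k]] <- spectrum(title, pepmass, charge, mz, inten, scan)
  }
  if (n_bad > 0L) warning("skipped ", n_bad, " malformed MGF block(s)")
  out[!vapply(out, is.null, logical(1))]
}

#' Write spectra to an MGF file
#'
#' @param spectra List of `xl_spectrum`.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$spectrum_id),
                 paste0("PEPMASS=", sprintf("%.6f", s$precursor_mz)),
                 if (!is.na(s$charge) && s$charge > 0L)
                   paste0("CHARGE=", s$charge, "+"),
                 if (!is.na(s$scan)) paste0("SCANS=", s$scan),
                 sprintf("%.5f %.2f", s$mz, s$intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Read an mzML file (optional)
#'
#' MS2 spectra via the mzR package, returned under the same spectrum
#' contract as [read_mgf()].  Requires mzR to be installed.
#'
#' @param path mzML file.
#' @return List of `xl_spectrum`.
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("mzML support requires the mzR package")
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hd <- mzR::header(h)
  ms2 <- which(hd$msLevel == 2L)
  lapply(ms2, function(i) {
    pk <- mzR::peaks(h, i)
    spectrum(spectrum_id = paste0(basename(path), ".scan", hd$acquisitionNum[i]),
             precursor_mz = hd$precursorMZ[i],
             charge = ifelse(is.na(hd$precursorCharge[i]), 0L,
                             hd$precursorCharge[i]),
             mz = pk[, 1], intensity = pk[, 2],
             scan = hd$acquisitionNum[i])
  })
}

#' Preprocessing parameters
#'
#' @param top_n_per_window Peaks kept per m/z window (most intense).
#' @param window_width Window width in Da.
#' @param min_peak_count Minimum surviving peaks for a searchable spectrum.
#' @param charge_range Searchable precursor charge range (inclusive).
#' @return List of class `xl_preprocess_params`.
#' @export
preprocess_params <- function(top_n_per_window = 12L, window_width = 100,
                              min_peak_count = 15L, charge_range = c(3L, 8L)) {
  stopifnot(top_n_per_window >= 1L, window_width > 0)
  structure(list(top_n_per_window = as.integer(top_n_per_window),
                 window_width = as.numeric(window_width),
                 min_peak_count = as.integer(min_peak_count),
                 charge_range = as.integer(charge_range)),
            class = "xl_preprocess_params")
}

#' Preprocess a spectrum for search
#'
#' Keeps the `top_n_per_window` most intense peaks per `window_width` Da
#' window and flags the spectrum not-searchable when too few peaks remain
#' or the precursor charge lies outside the searchable range (the
#' acquisition selects +4..+8 cross-linked precursors; the default search
#' range 3--8 is widened by one to protect against mis-assigned charges).
#' Idempotent.
#'
#' @param s An `xl_spectrum`.
#' @param p [preprocess_params()].
#' @return The filtered spectrum with `searchable` set.
#' @export
preprocess_spectrum <- function(s, p = preprocess_params()) {
  if (length(s$mz)) {
    win <- floor(s$mz / p$window_width)
    keep <- unlist(lapply(split(seq_along(s$mz), win), function(ii) {
      if (length(ii) <= p$top_n_per_window) ii
      else ii[order(s$intensity[ii], decreasing = TRUE)[seq_len(p$top_n_per_window)]]
    }), use.names = FALSE)
    keep <- sort(keep)
    s$mz <- s$mz[keep]; s$intensity <- s$intensity[keep]
  }
  s$searchable <- length(s$mz) >= p$min_peak_count &&
    !is.na(s$charge) && s$charge >= p$charge_range[1] &&
    s$charge <= p$charge_range[2]
  s
}

#' @export
print.xl_spectrum <- function(x, ...) {
  cat(sprintf("xl_spectrum '%s': precursor %.4f m/z (%+d), %d peaks%s\n",
              x$spectrum_id, x$precursor_mz, x$charge, length(x$mz),
              if (isTRUE(x$searchable)) ", searchable"
              else if (isFALSE(x$searchable)) ", not searchable" else ""))
  invisible(x)
}
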