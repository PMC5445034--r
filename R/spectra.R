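#' Construct an MS/MS spectrum record
#'
#' The uniform spectrum container used by the similarity scorer and the
#' MGF/MSP readers.  Peaks are stored raw (no normalization) and sorted by
#' ascending m/z; intensity scaling happens only inside [dot_product()].
#'
#' @param spectrum_id text identifier.
#' @param precursor_mz precursor m/z in Da (> 0).
#' @param peaks two-column matrix or data.frame of `mz` (Da) and
#'   `intensity` (arbitrary units, >= 0); at least one peak.
#' @param ion_mode `"positive"` or `"negative"`.
#' @param annotation_key_block for library spectra: the InChIKey first block
#'   of the annotated structure (`NA` for unannotated/query spectra).
#' @return an object of class `"spectrum"`.
#' @export
spectrum <- function(spectrum_id, precursor_mz, peaks,
                     ion_mode = c("positive", "negative"),
                     annotation_key_block = NA_character_) {
  ion_mode <- match.arg(ion_mode)
  pk <- as.matrix(peaks)
  if (ncol(pk) != 2L) stop("peaks must have two columns (mz, intensity)", call. = FALSE)
  storage.mode(pk) <- "double"
  colnames(pk) <- c("mz", "intensity")
  if (nrow(pk) < 1L) stop("spectrum ", spectrum_id, ": at least one peak required",
                          call. = FALSE)
  if (any(!is.finite(pk))) stop("spectrum ", spectrum_id, ": non-finite peak values",
                                call. = FALSE)
  if (any(pk[, "intensity"] < 0)) stop("spectrum ", spectrum_id,
                                       ": negative intensities", call. = FALSE)
  if (!is.finite(precursor_mz) || precursor_mz <= 0) {
    stop("spectrum ", spectrum_id, ": precursor_mz must be > 0", call. = FALSE)
  }
  pk <- pk[order(pk[, "mz"]), , drop = FALSE]
  rownames(pk) <- NULL
  structure(
    list(spectrum_id = as.character(spectrum_id),
         precursor_mz = as.numeric(precursor_mz),
         ion_mode = ion_mode,
         peaks = pk,
         annotation_key_block = annotation_key_block),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> ", x$spectrum_id, ": ", nrow(x$peaks), " peaks, precursor ",
      format(x$precursor_mz), " m/z (", x$ion_mode, ")",
      if (!is.na(x$annotation_key_block)) paste0(" [", x$annotation_key_block, "]"),
      "\n", sep = "")
  invisible(x)
}

#' Read query spectra from a Mascot generic format (MGF) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, optional `CHARGE`
#' and `TITLE` headers and `mz intensity` peak lines.  The ion mode is
#' inferred from the sign of `CHARGE` when present, else taken from
#' `default_ion_mode`.  `TITLE` is used as the spectrum id when present,
#' otherwise the file stem plus the 1-based block index.  Blocks without
#' peaks are dropped with a [message()]; a block without `PEPMASS` is an
#' error.  Stepped-collision-energy acquisitions are treated as the single
#' merged peak list they are delivered as.
#'
#' @param path path to an MGF file.
#' @param default_ion_mode ion mode assumed when a block carries no CHARGE.
#' @return list of [spectrum()] records.
#' @export
read_mgf <- function(path, default_ion_mode = c("positive", "negative")) {
  default_ion_mode <- match.arg(default_ion_mode)
  if (!file.exists(path)) config_error("MGF file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("unbalanced BEGIN IONS/END IONS in ", path, call. = FALSE)
  }
  stem <- sub("\\.[^.]*$", "", basename(path))
  out <- vector("list", length(starts))
  dropped <- 0L
  for (i in seq_along(starts)) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    block <- block[nzchar(block)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else
      paste0(stem, "_", i)
    if (!"PEPMASS" %in% keys) {
      stop("MGF block ", sQuote(title), " in ", basename(path),
           " has no PEPMASS", call. = FALSE)
    }
    pep <- as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]), "[ \t]+")[[1L]][1L])
    mode <- default_ion_mode
    if ("CHARGE" %in% keys) {
      mode <- if (grepl("-", vals[match("CHARGE", keys)], fixed = TRUE))
        "negative" else "positive"
    }
    peak_lines <- block[!is_kv]
    peak_lines <- peak_lines[grepl("^[0-9.+-]", peak_lines)]
    if (length(peak_lines) == 0L) {
      dropped <- dropped + 1L
      next
    }
    fields <- strsplit(peak_lines, "[ \t]+")
    pk <- cbind(mz = as.numeric(vapply(fields, `[`, "", 1L)),
                intensity = as.numeric(vapply(fields, `[`, "", 2L)))
    out[[i]] <- spectrum(title, pep, pk, ion_mode = mode)
  }
  if (dropped > 0L) {
    message("read_mgf: dropped ", dropped, " block(s) without peaks from ",
            basename(path))
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Read or write spectra in NIST MSP library format
#'
#' MSP records carry `Name:`, `PrecursorMZ:`, optional `Ion_mode:` and
#' `InChIKey:` headers, a `Num Peaks:` count, and one `mz intensity` pair
#' per line.  The InChIKey field may hold a full key (the first block is
#' extracted) or a bare 14-character block.  A record whose declared peak
#' count does not match its peak lines is an error naming the record.
#' `write_msp()` followed by `read_msp()` is the identity on well-formed
#' libraries (field-for-field, peak-for-peak within text precision).
#'
#' @param path path to an MSP file.
#' @param default_ion_mode ion mode assumed for records without an
#'   `Ion_mode` header.
#' @return `read_msp()`: list of [spectrum()] records (empty list for an
#'   empty file).  `write_msp()`: `path`, invisibly.
#' @export
read_msp <- function(path, default_ion_mode = c("positive", "negative")) {
  default_ion_mode <- match.arg(default_ion_mode)
  if (!file.exists(path)) config_error("MSP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^[Nn][Aa][Mm][Ee]:", lines)
  if (length(starts) == 0L) return(list())
  bounds <- c(starts, length(lines) + 1L)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    block <- trimws(block)
    block <- block[nzchar(block)]
    is_hdr <- grepl("^[A-Za-z][A-Za-z_ /]*:", block)
    hdr <- block[is_hdr]
    keys <- toupper(gsub("[ _]", "", sub(":.*$", "", hdr)))
    vals <- trimws(sub("^[^:]*:", "", hdr))
    name <- vals[match("NAME", keys)]
    get_val <- function(key) {
      j <- match(key, keys)
      if (is.na(j)) NA_character_ else vals[j]
    }
    pmz <- get_val("PRECURSORMZ")
    if (is.na(pmz)) {
      stop("MSP record ", sQuote(name), ": no PrecursorMZ header", call. = FALSE)
    }
    npk <- get_val("NUMPEAKS")
    if (is.na(npk)) {
      stop("MSP record ", sQuote(name), ": no 'Num Peaks' header", call. = FALSE)
    }
    npk <- as.integer(npk)
    mode <- get_val("IONMODE")
    mode <- if (is.na(mode)) default_ion_mode
      else if (toupper(substr(mode, 1, 1)) == "N") "negative" else "positive"
    ik <- get_val("INCHIKEY")
    ann <- if (is.na(ik) || !nzchar(ik)) NA_character_
      else if (grepl("-", ik, fixed = TRUE)) first_block(ik)
      else if (nchar(ik) == 14L) ik
      else stop("MSP record ", sQuote(name), ": unparseable InChIKey ",
                sQuote(ik), call. = FALSE)
    peak_lines <- block[!is_hdr]
    if (length(peak_lines) != npk) {
      stop("MSP record ", sQuote(name), ": 'Num Peaks: ", npk, "' but ",
           length(peak_lines), " peak line(s)", call. = FALSE)
    }
    fields <- strsplit(peak_lines, "[ \t;]+")
    pk <- cbind(mz = as.numeric(vapply(fields, `[`, "", 1L)),
                intensity = as.numeric(vapply(fields, `[`, "", 2L)))
    out[[i]] <- spectrum(name, as.numeric(pmz), pk, ion_mode = mode,
                         annotation_key_block = ann)
  }
  out
}

#' @param spectra list of [spectrum()] records to write.
#' @rdname read_msp
#' @export
write_msp <- function(spectra, path) {
  stopifnot(all(vapply(spectra, inherits, logical(1), "spectrum")))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      paste0("Name: ", sp$spectrum_id),
      paste0("PrecursorMZ: ", fmt_num(sp$precursor_mz)),
      paste0("Ion_mode: ", sp$ion_mode),
      if (!is.na(sp$annotation_key_block))
        paste0("InChIKey: ", sp$annotation_key_block),
      paste0("Num Peaks: ", nrow(sp$peaks)),
      paste(fmt_num(sp$peaks[, "mz"]), fmt_num(sp$peaks[, "intensity"])),
      ""
    ), con)
  }
  invisible(path)
}

#' Write query spectra to an MGF file
#'
#' @param spectra list of [spectrum()] records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  stopifnot(all(vapply(spectra, inherits, logical(1), "spectrum")))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", sp$spectrum_id),
      paste0("PEPMASS=", fmt_num(sp$precursor_mz)),
      paste0("CHARGE=1", if (sp$ion_mode == "positive") "+" else "-"),
      paste(fmt_num(sp$peaks[, "mz"]), fmt_num(sp$peaks[, "intensity"])),
      "END IONS",
      ""
    ), con)
  }
  invisible(path)
}
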