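# File dialects: XFI spectrum files, scan directories, ICP-MS batch tables,
# IMC TXT pixel tables, and format validation. All package-owned dialects
# carry a versioned "# format:" header; readers refuse unknown versions.

#' Write / read an XFI spectrum file
#'
#' Delimited text, two columns (`energy_kev`, `counts`), with `#`-prefixed
#' header lines carrying the format version, the dwell time and the pixel
#' coordinates.
#'
#' @param spectrum An [xfi_spectrum()].
#' @param path File path.
#' @param pixel Optional `c(row, col)` 0-based pixel coordinate.
#' @return `write_spectrum` returns `path` invisibly; `read_spectrum` returns
#'   an `xfi_spectrum` with attribute `pixel`.
#' @export
write_spectrum <- function(spectrum, path, pixel = NULL) {
  stopifnot(inherits(spectrum, "xfi_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# format: pdnptrace-spectrum v1", con)
  writeLines(sprintf("# dwell_s: %.10g", spectrum$dwell_s), con)
  if (!is.null(pixel))
    writeLines(sprintf("# pixel: %d %d", pixel[1], pixel[2]), con)
  utils::write.table(
    data.frame(energy_kev = spectrum$energy_kev, counts = spectrum$counts),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (!any(grepl("^# format: pdnptrace-spectrum v1$", hdr)))
    stop("not a pdnptrace-spectrum v1 file: ", path)
  dwell_line <- grep("^# dwell_s:", hdr, value = TRUE)
  dwell <- if (length(dwell_line)) as.numeric(sub("^# dwell_s:", "", dwell_line[1])) else 1
  pix_line <- grep("^# pixel:", hdr, value = TRUE)
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t")
  sp <- xfi_spectrum(tab$energy_kev, tab$counts, dwell)
  if (length(pix_line))
    attr(sp, "pixel") <- as.integer(strsplit(trimws(
      sub("^# pixel:", "", pix_line[1])), "\\s+")[[1]])
  sp
}

#' Write / read an XFI scan directory
#'
#' A scan is a directory of per-pixel spectrum files plus an `index.tsv`
#' listing pixel coordinates, file names and dwell times; reference-target
#' spectra are indexed with their known mass in the beam.
#'
#' @param scan An `xfi_scan`.
#' @param dir Directory (created if needed).
#' @return `write_xfi_scan` returns `dir` invisibly; `read_xfi_scan` returns
#'   an `xfi_scan` (the generating truth map is not stored on disk).
#' @export
write_xfi_scan <- function(scan, dir) {
  stopifnot(inherits(scan, "xfi_scan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- NULL
  for (i in seq_along(scan$spectra)) for (j in seq_along(scan$spectra[[i]])) {
    fn <- sprintf("pixel_%03d_%03d.tsv", i - 1, j - 1)
    write_spectrum(scan$spectra[[i]][[j]], file.path(dir, fn),
                   pixel = c(i - 1, j - 1))
    idx <- rbind(idx, data.frame(kind = "pixel", row = i - 1, col = j - 1,
                                 file = fn, dwell_s = scan$dwell_s,
                                 mass_in_beam_ug = NA_real_))
  }
  refs <- scan$references$table
  for (k in seq_along(scan$references$spectra)) {
    fn <- sprintf("reference_%02d.tsv", k)
    write_spectrum(scan$references$spectra[[k]], file.path(dir, fn))
    idx <- rbind(idx, data.frame(kind = "reference", row = NA, col = NA,
                                 file = fn, dwell_s = refs$dwell_s[k],
                                 mass_in_beam_ug = refs$mass_in_beam_ug[k]))
  }
  con <- file(file.path(dir, "index.tsv"), "w")
  writeLines("# format: pdnptrace-scan-index v1", con)
  writeLines(sprintf("# beam: flux_ph_s=%.10g energy_kev=%g area_mm2=%g",
                     scan$beam$flux_ph_s, scan$beam$energy_kev,
                     scan$beam$area_mm2), con)
  utils::write.table(idx, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(dir)
}

#' @rdname write_xfi_scan
#' @param detector Detector configuration to attach on read (geometry is not
#'   serialized).
#' @export
read_xfi_scan <- function(dir, detector = xfi_detector()) {
  idx_path <- file.path(dir, "index.tsv")
  lines <- readLines(idx_path)
  if (!any(grepl("^# format: pdnptrace-scan-index v1$", lines)))
    stop("not a pdnptrace-scan-index v1 directory: ", dir)
  beam_line <- grep("^# beam:", lines, value = TRUE)[1]
  kv <- strsplit(strsplit(sub("^# beam:\\s*", "", beam_line), "\\s+")[[1]], "=")
  bv <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]), 0),
                        vapply(kv, `[`, "", 1))
  beam <- xfi_beam(bv[["flux_ph_s"]], bv[["energy_kev"]], bv[["area_mm2"]])
  idx <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t")
  pix <- idx[idx$kind == "pixel", ]
  nr <- max(pix$row) + 1L; nc <- max(pix$col) + 1L
  spectra <- rep(list(vector("list", nc)), nr)
  for (k in seq_len(nrow(pix)))
    spectra[[pix$row[k] + 1]][[pix$col[k] + 1]] <-
      read_spectrum(file.path(dir, pix$file[k]))
  refs <- idx[idx$kind == "reference", ]
  ref_spectra <- lapply(refs$file, function(f) read_spectrum(file.path(dir, f)))
  energy <- spectra[[1]][[1]]$energy_kev
  structure(list(spectra = spectra, energy_kev = energy,
                 dwell_s = pix$dwell_s[1], beam = beam, detector = detector,
                 background_rate = NA_real_,
                 truth_map = matrix(NA_real_, nr, nc),
                 references = list(
                   table = data.frame(mass_in_beam_ug = refs$mass_in_beam_ug,
                                      dwell_s = refs$dwell_s),
                   spectra = ref_spectra),
                 seed = NA_integer_),
            class = "xfi_scan")
}

#' Write / read a mass-map grid
#'
#' Delimited-text grid of ug Pd per pixel with a versioned header.
#'
#' @param map An `xfi_mass_map`.
#' @param path File path.
#' @return `write_mass_map` returns `path` invisibly; `read_mass_map` the
#'   numeric matrix.
#' @export
write_mass_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# format: pdnptrace-massmap v1", con)
  utils::write.table(map$mass_ug, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_mass_map
#' @export
read_mass_map <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# format: pdnptrace-massmap v1", lines[1]))
    stop("not a pdnptrace-massmap v1 file: ", path)
  as.matrix(utils::read.table(text = lines[-1], sep = "\t"))
}

#' Write / read an ICP-MS batch table
#'
#' Delimited text with the columns `record_type`, `id`, `nominal_conc`,
#' `intensity_106`, `intensity_IS`, `dilution_factor`, `digest_volume_mL`,
#' `order`, under a versioned header.
#'
#' @param batch An `icpms_batch`.
#' @param path File path.
#' @return `write_icpms_batch` returns `path` invisibly; `read_icpms_batch`
#'   an `icpms_batch` (without generator parameters).
#' @export
write_icpms_batch <- function(batch, path) {
  stopifnot(inherits(batch, "icpms_batch"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# format: pdnptrace-icpms v1", con)
  utils::write.table(batch$records, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_icpms_batch
#' @export
read_icpms_batch <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# format: pdnptrace-icpms v1", lines[1]))
    stop("not a pdnptrace-icpms v1 file: ", path)
  rec <- utils::read.table(text = lines[-1], header = TRUE, sep = "\t")
  structure(list(records = rec, params = NULL, true_concs = NULL,
                 seed = NA_integer_),
            class = "icpms_batch")
}

#' Write / read an IMC TXT pixel table
#'
#' The IMC TXT dialect: delimited text, one row per pixel, columns `X`, `Y`
#' (0-based) followed by channel columns named like `Pd108`. Extra columns
#' are tolerated on read. MCD binary files are not supported.
#'
#' @param roi An `imc_roi`.
#' @param path File path.
#' @return `write_imc_txt` returns `path` invisibly; `read_imc_txt` an
#'   `imc_roi`.
#' @export
write_imc_txt <- function(roi, path) {
  stopifnot(inherits(roi, "imc_roi"))
  grid <- expand.grid(X = seq_len(roi$width) - 1L,
                      Y = seq_len(roi$height) - 1L)
  for (ch in names(roi$channels))
    grid[[ch]] <- roi$channels[[ch]][cbind(grid$Y + 1, grid$X + 1)]
  utils::write.table(grid, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_imc_txt
#' @param roi_id,tissue Labels for the ROI read back.
#' @export
read_imc_txt <- function(path, roi_id = basename(path), tissue = "unknown") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (!all(c("X", "Y") %in% names(tab)))
    stop("IMC TXT file must have X and Y columns: ", path)
  ch_names <- grep("^Pd[0-9]+$", names(tab), value = TRUE)
  if (length(ch_names) == 0) stop("no Pd channel columns found in ", path)
  width <- max(tab$X) + 1L; height <- max(tab$Y) + 1L
  channels <- lapply(ch_names, function(ch) {
    m <- matrix(0, nrow = height, ncol = width)
    m[cbind(tab$Y + 1, tab$X + 1)] <- tab[[ch]]
    m
  })
  names(channels) <- ch_names
  structure(list(channels = channels, width = width, height = height,
                 roi_id = roi_id, tissue = tissue, truth = NULL,
                 seed = NA_integer_),
            class = "imc_roi")
}

#' Validate supported file formats
#'
#' Schema checks for every supported dialect; problems are reported as
#' line-numbered diagnostics, never as errors.
#'
#' @param paths Character vector of files to check.
#' @return Data frame with columns `file`, `line`, `message`; zero rows when
#'   everything validates.
#' @export
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines("not a known format", f)
#' validate_formats(f)
validate_formats <- function(paths) {
  diags <- list()
  note <- function(file, line, message)
    diags[[length(diags) + 1]] <<- data.frame(file = file, line = line,
                                              message = message)
  for (path in paths) {
    if (!file.exists(path)) {
      note(path, NA_integer_, "file does not exist")
      next
    }
    lines <- readLines(path, warn = FALSE)
    if (length(lines) == 0) {
      note(path, NA_integer_, "empty file")
      next
    }
    first <- lines[1]
    if (grepl("^# format: pdnptrace-spectrum v1", first)) {
      tab <- tryCatch(utils::read.table(text = lines[!startsWith(lines, "#")],
                                        header = TRUE, sep = "\t"),
                      error = function(e) NULL)
      if (is.null(tab) || !all(c("energy_kev", "counts") %in% names(tab)))
        note(path, 1L, "spectrum file lacks energy_kev/counts columns")
      else {
        if (is.unsorted(tab$energy_kev, strictly = TRUE))
          note(path, NA_integer_, "energy bins not strictly increasing")
        bad <- which(tab$counts < 0)
        if (length(bad))
          note(path, bad[1], "negative counts")
      }
    } else if (grepl("^# format: pdnptrace-icpms v1", first)) {
      tab <- tryCatch(utils::read.table(text = lines[-1], header = TRUE,
                                        sep = "\t"), error = function(e) NULL)
      need <- c("record_type", "id", "nominal_conc", "intensity_106",
                "intensity_IS", "dilution_factor", "digest_volume_mL",
                "order")
      if (is.null(tab)) note(path, 2L, "unparseable ICP-MS table")
      else {
        missing <- setdiff(need, names(tab))
        if (length(missing))
          note(path, 2L, paste("missing column(s):",
                               paste(missing, collapse = ", ")))
        else if (!all(tab$record_type %in% c("standard", "blank", "sample")))
          note(path, NA_integer_, "record_type outside {standard, blank, sample}")
      }
    } else if (grepl("^# format: pdnptrace-truth v1", first)) {
      tab <- tryCatch(utils::read.table(text = lines, header = TRUE,
                                        sep = "\t", comment.char = "#"),
                      error = function(e) NULL)
      if (is.null(tab) ||
          !all(c("compartment", "time_h", "pd_mass_ug") %in% names(tab)))
        note(path, 2L, "truth table lacks compartment/time_h/pd_mass_ug")
    } else if (grepl("^# format: pdnptrace-", first)) {
      # a package dialect of an unknown version
      note(path, 1L, paste("unknown dialect/version:", first))
    } else if (grepl("\tY\t|^X\t", first) || grepl("^X[\t ]", first)) {
      tab <- tryCatch(utils::read.table(path, header = TRUE, sep = "\t",
                                        check.names = FALSE),
                      error = function(e) NULL)
      if (is.null(tab)) note(path, 1L, "unparseable IMC TXT table")
      else {
        if (!all(c("X", "Y") %in% names(tab)))
          note(path, 1L, "IMC TXT lacks X/Y columns")
        if (!any(grepl("^Pd[0-9]+$", names(tab))))
          note(path, 1L, "IMC TXT lacks Pd channel columns (e.g. Pd108)")
      }
    } else {
      note(path, 1L, "unrecognized format")
    }
  }
  if (length(diags) == 0)
    data.frame(file = character(), line = integer(), message = character())
  else do.call(rbind, diags)
}
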