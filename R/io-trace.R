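#' Construct a fluorescence kinetic trace
#'
#' Container for a time-resolved fluorescence signal together with its
#' calibration anchors: `F0` (baseline before protein addition), `Fmax`
#' (full-transfer or fully-bound reference), `Fmin` (buffer-only
#' reference), and injection times.
#'
#' @param time numeric vector of times, seconds, strictly increasing.
#' @param intensity numeric vector of fluorescence intensities (a.u.).
#' @param F0,Fmax,Fmin optional calibration intensities (a.u.).
#' @param t_inject optional named or unnamed numeric vector of injection
#'   times (s); by convention the protein injection is named `"protein"`.
#' @return an object of class `lip_trace`: a data.frame with columns
#'   `time` and `F` plus a `calibration` attribute.
#' @export
kinetic_trace <- function(time, intensity, F0 = NA_real_, Fmax = NA_real_,
                          Fmin = NA_real_, t_inject = numeric(0)) {
  if (length(time) != length(intensity)) {
    stop("time and intensity must have equal length")
  }
  if (length(time) > 1L && any(diff(time) <= 0)) {
    stop("time must be strictly increasing")
  }
  tr <- data.frame(time = as.numeric(time), F = as.numeric(intensity))
  attr(tr, "calibration") <- list(F0 = F0, Fmax = Fmax, Fmin = Fmin,
                                  t_inject = t_inject)
  class(tr) <- c("lip_trace", "data.frame")
  tr
}

#' Calibration anchors of a kinetic trace
#' @param trace a [kinetic_trace()].
#' @return list with `F0`, `Fmax`, `Fmin`, `t_inject`.
#' @export
trace_calibration <- function(trace) {
  attr(trace, "calibration")
}

#' Read a fluorescence trace from CSV
#'
#' The file holds two numeric columns (`time` in seconds, `intensity` in
#' a.u.), optionally preceded by metadata header lines of the form
#' `# key=value` carrying the calibration anchors, e.g. `# F0=100`,
#' `# Fmax=480`, `# Fmin=20`, `# t_protein=240`. Any `t_*` key is parsed
#' as an injection time (name = suffix after `t_`).
#'
#' @param path path to the CSV file.
#' @return a [kinetic_trace()].
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_idx <- grep("^\\s*#", lines)
  meta <- list()
  for (ln in lines[meta_idx]) {
    body <- sub("^\\s*#\\s*", "", ln)
    kv <- strsplit(body, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
  }
  dat <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines), meta_idx)],
                                      collapse = "\n"),
                         header = TRUE)
  if (ncol(dat) < 2L) stop("trace CSV needs two columns (time, intensity)")
  tvals <- as.numeric(dat[[1]])
  if (anyNA(tvals) || anyNA(as.numeric(dat[[2]]))) {
    stop("non-numeric values in trace CSV")
  }
  inj_keys <- grep("^t_", names(meta), value = TRUE)
  inj <- stats::setNames(as.numeric(unlist(meta[inj_keys])),
                         sub("^t_", "", inj_keys))
  kinetic_trace(
    tvals, as.numeric(dat[[2]]),
    F0 = if (!is.null(meta$F0)) meta$F0 else NA_real_,
    Fmax = if (!is.null(meta$Fmax)) meta$Fmax else NA_real_,
    Fmin = if (!is.null(meta$Fmin)) meta$Fmin else NA_real_,
    t_inject = inj
  )
}

#' Write a kinetic trace to CSV (with calibration header)
#' @param trace a [kinetic_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  cal <- trace_calibration(trace)
  hdr <- character(0)
  for (k in c("F0", "Fmax", "Fmin")) {
    if (!is.na(cal[[k]])) hdr <- c(hdr, sprintf("# %s=%.10g", k, cal[[k]]))
  }
  if (length(cal$t_inject) > 0L) {
    nm <- names(cal$t_inject)
    if (is.null(nm)) nm <- paste0("inject", seq_along(cal$t_inject))
    hdr <- c(hdr, sprintf("# t_%s=%.10g", nm, cal$t_inject))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "time,intensity"), con)
  utils::write.table(data.frame(trace$time, trace$F), con, sep = ",",
                     col.names = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read amino-acid sequences from FASTA
#' @param path FASTA file path.
#' @return data.frame with columns `id` and `sequence`.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  data.frame(id = sub("\\s.*$", "", names(ss)),
             sequence = as.character(ss),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write amino-acid sequences to FASTA
#' @param records data.frame with columns `id` and `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(records, path) {
  ss <- Biostrings::AAStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
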