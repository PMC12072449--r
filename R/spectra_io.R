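# Centroided peak-list containers and extracted-ion chromatograms.
#
# A Run is stored long-format: one row per centroided peak, with per-scan
# metadata repeated (scan_time_min, cone_voltage_V, polarity). This maps
# directly onto the tabular CSV dialect and onto per-scan peak lists.

.run_cols <- c("scan_time_min", "cone_voltage_V", "polarity", "mz", "intensity")

#' Construct an LC-MS run from long-format peaks
#'
#' @param peaks Data frame with columns `scan_time_min`, `cone_voltage_V`,
#'   `polarity` (`"+"` or `"-"`), `mz`, `intensity`.
#' @param metadata Optional named list of instrument settings.
#' @return An `ms_run` tibble (rows ordered by scan time then m/z).
#' @export
ms_run <- function(peaks, metadata = list()) {
  peaks <- tibble::as_tibble(peaks)
  missing_cols <- setdiff(.run_cols, names(peaks))
  if (length(missing_cols) > 0L) {
    stop("run is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  num <- c("scan_time_min", "cone_voltage_V", "mz", "intensity")
  bad <- which(!stats::complete.cases(peaks[num]) |
                 !apply(is.finite(as.matrix(peaks[num])), 1L, all))
  if (length(bad) > 0L) {
    stop("non-finite values in run row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  neg <- which(peaks$intensity < 0)
  if (length(neg) > 0L) {
    stop("negative intensity in run row(s): ",
         paste(utils::head(neg, 5L), collapse = ", "))
  }
  if (!all(peaks$polarity %in% c("+", "-"))) {
    stop("polarity must be '+' or '-'")
  }
  peaks <- peaks[order(peaks$scan_time_min, peaks$mz), .run_cols]
  structure(peaks, class = c("ms_run", class(peaks)), metadata = metadata)
}

#' Read a run from disk
#'
#' The tabular dialect is a long-format CSV with columns `scan_time_min`,
#' `cone_voltage_V`, `polarity`, `mz`, `intensity`. The `mzml` dialect reads
#' centroided spectra through the `mzR` package (cone voltage and polarity
#' must then be supplied via `...` if absent from the file header).
#'
#' @param path File path.
#' @param dialect `"tabular"` (default) or `"mzml"`.
#' @param cone_voltage_V,polarity Metadata to attach when the mzML header does
#'   not carry them.
#' @return An `ms_run`.
#' @export
read_run <- function(path, dialect = c("tabular", "mzml"),
                     cone_voltage_V = NA_real_, polarity = "+") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("run file not found: ", path)
  if (dialect == "tabular") {
    df <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE),
      error = function(e) stop("failed to parse ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    if (nrow(df) == 0L) stop("empty run file: ", path)
    tryCatch(ms_run(df), error = function(e) {
      stop("invalid run in ", path, ": ", conditionMessage(e), call. = FALSE)
    })
  } else {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("the mzml dialect requires the mzR package")
    }
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    hdr <- mzR::header(h)
    pk <- mzR::peaks(h)
    if (is.matrix(pk)) pk <- list(pk)
    rows <- lapply(seq_along(pk), function(i) {
      if (nrow(pk[[i]]) == 0L) return(NULL)
      pol <- if ("polarity" %in% names(hdr) && !is.na(hdr$polarity[i])) {
        if (hdr$polarity[i] >= 0) "+" else "-"
      } else polarity
      data.frame(scan_time_min = hdr$retentionTime[i] / 60,
                 cone_voltage_V = cone_voltage_V, polarity = pol,
                 mz = pk[[i]][, 1], intensity = pk[[i]][, 2])
    })
    ms_run(do.call(rbind, rows))
  }
}

#' Write a run to the tabular CSV dialect
#'
#' @param run An `ms_run`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  df <- as.data.frame(run)[.run_cols]
  # full double precision so write -> read round-trips within 1e-9
  for (cc in c("scan_time_min", "mz", "intensity")) {
    df[[cc]] <- formatC(df[[cc]], digits = 17, format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summed intensity at a target m/z in one peak list
#'
#' Sums intensities of all peaks with `|mz - target_mz| <= tol`; 0 if none.
#'
#' @param pl Data frame with `mz` and `intensity` columns (one scan's peaks,
#'   or any peak subset).
#' @param target_mz Target m/z in Da.
#' @param tol Tolerance in Da (> 0); default 0.5, unit resolution.
#' @return Summed intensity (counts).
#' @export
extract_intensity <- function(pl, target_mz, tol = 0.5) {
  if (tol <= 0) stop("tol must be > 0")
  hit <- abs(pl$mz - target_mz) <= tol
  if (!any(hit)) 0 else sum(pl$intensity[hit])
}

#' Extracted-ion chromatogram
#'
#' Per-scan summed intensity at `target_mz` (within `tol`), aligned to scan
#' times. Scans with no matching peak contribute zero.
#'
#' @param run An `ms_run`.
#' @param target_mz Target m/z in Da.
#' @param tol Tolerance in Da; default 0.5.
#' @return A `chromatogram` tibble with columns `time_min`, `intensity` and
#'   attributes `target_mz`, `tolerance`.
#' @export
xic <- function(run, target_mz, tol = 0.5) {
  stopifnot(inherits(run, "ms_run"))
  if (nrow(run) == 0L) stop("run is empty")
  times <- sort(unique(run$scan_time_min))
  hit <- abs(run$mz - target_mz) <= tol
  sums <- vapply(split(run$intensity[hit], factor(run$scan_time_min[hit],
                                                  levels = times)),
                 sum, numeric(1))
  out <- tibble::tibble(time_min = times, intensity = unname(sums))
  out$intensity[is.na(out$intensity)] <- 0
  structure(out, class = c("chromatogram", class(out)),
            target_mz = target_mz, tolerance = tol)
}

#' Integrate a chromatogram over a retention-time window
#'
#' Trapezoidal integral of intensity over scans falling in
#' `[rt_min, rt_max]`; 0 if fewer than two scans lie in the window. Areas (not
#' apex heights) are the default abundance measure throughout the package.
#'
#' @param chrom A `chromatogram` from [xic()] (any tibble with `time_min`,
#'   `intensity` works).
#' @param rt_min,rt_max Window bounds in minutes, `rt_min < rt_max`.
#' @return Integrated area (counts x min).
#' @export
integrate_window <- function(chrom, rt_min, rt_max) {
  if (rt_min >= rt_max) stop("rt_min must be < rt_max")
  keep <- chrom$time_min >= rt_min & chrom$time_min <= rt_max
  if (sum(keep) < 2L) return(0)
  pracma::trapz(chrom$time_min[keep], chrom$intensity[keep])
}

#' Apex intensity within a retention-time window
#'
#' Alternative to [integrate_window()] for the `apex` ratio mode.
#'
#' @inheritParams integrate_window
#' @return Maximum intensity in the window (0 if no scans).
#' @export
apex_intensity <- function(chrom, rt_min, rt_max) {
  if (rt_min >= rt_max) stop("rt_min must be < rt_max")
  keep <- chrom$time_min >= rt_min & chrom$time_min <= rt_max
  if (!any(keep)) return(0)
  max(chrom$intensity[keep])
}
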