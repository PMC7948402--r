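#' Signal tracks: per-base coverage with sample metadata
#'
#' A `signal_track` holds sorted, non-overlapping `(start, end, value)`
#' intervals per chromosome (0-based half-open) together with sample
#' metadata: `sample_id`, `library_size` (total mapped reads),
#' `spike_in_reads` (reads aligned to the exogenous spike-in genome, `NA` if
#' no spike-in was used) and a one-way `normalized` flag. Regions not covered
#' by any interval are implicit zeros. "Reads in region" is implemented as
#' coverage area (sum of value times overlap length), which is proportional
#' to read count at fixed read length; the constant cancels in every ratio
#' the pipeline computes.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `value`.
#' @param sample_id sample identifier.
#' @param library_size total mapped reads (positive).
#' @param spike_in_reads spike-in read count (`NA` if absent).
#' @param normalized `"none"`, `"library_size"` or `"spike_in"`.
#' @param drop_zero drop zero-value intervals (implicit elsewhere).
#' @return A `signal_track` object.
#' @export
signal_track <- function(intervals, sample_id = "sample", library_size = 1e6,
                         spike_in_reads = NA_real_, normalized = "none",
                         drop_zero = TRUE) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(intervals)))
  iv <- intervals[, c("chrom", "start", "end", "value")]
  iv$chrom <- as.character(iv$chrom)
  if (nrow(iv) > 0) {
    if (any(!is.finite(iv$value))) .stopf("non-finite signal value")
    if (identical(normalized, "none") && any(iv$value < 0)) {
      .stopf("negative signal value at %s:%d-%d",
             iv$chrom[iv$value < 0][1], iv$start[iv$value < 0][1],
             iv$end[iv$value < 0][1])
    }
    if (any(iv$start >= iv$end)) .stopf("interval with start >= end")
    if (drop_zero) iv <- iv[iv$value != 0, , drop = FALSE]
    iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
    same <- iv$chrom[-1] == iv$chrom[-nrow(iv)]
    bad <- which(same & iv$start[-1] < iv$end[-nrow(iv)])
    if (nrow(iv) > 1 && length(bad) > 0) {
      b <- bad[1]
      .stopf("overlapping intervals: %s:%d-%d and %s:%d-%d",
             iv$chrom[b], iv$start[b], iv$end[b],
             iv$chrom[b + 1], iv$start[b + 1], iv$end[b + 1])
    }
  }
  rownames(iv) <- NULL
  if (!is.numeric(library_size) || library_size <= 0) {
    .stopf("library_size must be positive")
  }
  structure(
    list(intervals = iv, sample_id = sample_id, library_size = library_size,
         spike_in_reads = spike_in_reads, normalized = normalized),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf(
    "signal_track '%s': %d intervals on %d chromosome(s); library_size=%g, spike_in=%s, normalized=%s\n",
    x$sample_id, nrow(x$intervals), length(unique(x$intervals$chrom)),
    x$library_size,
    if (is.na(x$spike_in_reads)) "NA" else format(x$spike_in_reads),
    x$normalized
  ))
  invisible(x)
}

#' Read a 4-column bedGraph file into a signal track
#'
#' @param path bedGraph path (4 tab-separated columns, 0-based half-open).
#' @param sample_id,library_size,spike_in_reads sample metadata.
#' @return A `signal_track` (intervals sorted; zero-value rows dropped).
#' @export
read_bedgraph <- function(path, sample_id = basename(path), library_size = 1e6,
                          spike_in_reads = NA_real_) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(signal_track(data.frame(chrom = character(), start = integer(),
                                   end = integer(), value = numeric()),
                        sample_id, library_size, spike_in_reads))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad) > 0) {
    .stopf("malformed bedGraph line %d: fewer than 4 fields", lineno[bad[1]])
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  value <- suppressWarnings(as.numeric(get(4)))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad) > 0) {
    .stopf("malformed bedGraph line %d: non-numeric field", lineno[bad[1]])
  }
  signal_track(data.frame(chrom = get(1), start = start, end = end,
                          value = value, stringsAsFactors = FALSE),
               sample_id, library_size, spike_in_reads)
}

#' Write a signal track as bedGraph
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces them exactly.
#'
#' @param track a `signal_track`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  iv <- track$intervals
  writeLines(sprintf("%s\t%d\t%d\t%.17g", iv$chrom, iv$start, iv$end, iv$value),
             path)
  invisible(path)
}

#' Signal in a genomic region
#'
#' Returns the coverage area: sum of `value * overlap_length` over all track
#' intervals intersecting the region. Chromosomes absent from the track
#' count as zero.
#'
#' @param track a `signal_track`.
#' @param chrom,start,end region (0-based half-open).
#' @return Numeric scalar.
#' @export
count_region <- function(track, chrom, start, end) {
  count_regions(track, data.frame(chrom = chrom, start = start, end = end))
}

#' Signal in many regions at once
#'
#' @param track a `signal_track`.
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @return Numeric vector, one sum per region.
#' @export
count_regions <- function(track, regions) {
  stopifnot(inherits(track, "signal_track"))
  .interval_sums(track$intervals, regions$chrom, regions$start, regions$end)
}

#' FPKM for a region count
#'
#' Fragments (here: coverage area) per kilobase of region per million mapped
#' reads: `count / (region_length/1000) / (library_size/1e6)`.
#'
#' @param count signal in the region.
#' @param region_length region length in bases (positive).
#' @param library_size total mapped reads (positive).
#' @return Numeric FPKM.
#' @export
fpkm <- function(count, region_length, library_size) {
  if (any(region_length <= 0)) .stopf("region_length must be positive")
  if (any(library_size <= 0)) .stopf("library_size must be positive")
  count / (region_length / 1000) / (library_size / 1e6)
}

#' Spike-in scaling factor for a sample
#'
#' The number of reads aligned to the exogenous spike-in genome is used as a
#' scaling factor: multiplying a track by `reference_spike /
#' track$spike_in_reads` expresses it on the reference sample's spike-in
#' scale, cancelling sequencing-depth differences.
#'
#' @param track a `signal_track` with `spike_in_reads` set.
#' @param reference_spike spike-in read count of the reference sample.
#' @return Numeric scaling factor.
#' @export
spike_in_factor <- function(track, reference_spike) {
  stopifnot(inherits(track, "signal_track"))
  if (is.na(track$spike_in_reads) || track$spike_in_reads <= 0) {
    .stopf("sample '%s' has no usable spike-in read count; spike-in normalization impossible",
           track$sample_id)
  }
  if (!is.numeric(reference_spike) || reference_spike <= 0) {
    .stopf("reference_spike must be positive")
  }
  reference_spike / track$spike_in_reads
}

#' Normalize a signal track
#'
#' `library_size` mode multiplies every value by `1e6 / library_size`
#' (counts-per-million scaling); `spike_in` mode multiplies by the spike-in
#' factor against `reference_spike`. Normalization is one-way: a track can
#' only be normalized once, and the applied mode is recorded.
#'
#' @param track a `signal_track` with `normalized == "none"`.
#' @param mode `"library_size"` or `"spike_in"`.
#' @param reference_spike reference spike-in count (spike_in mode only).
#' @return A new, normalized `signal_track`.
#' @export
normalize_track <- function(track, mode = c("library_size", "spike_in"),
                            reference_spike = NULL) {
  stopifnot(inherits(track, "signal_track"))
  mode <- match.arg(mode)
  if (!identical(track$normalized, "none")) {
    .stopf("track '%s' is already normalized (%s); re-normalization is not allowed",
           track$sample_id, track$normalized)
  }
  factor <- switch(mode,
    library_size = 1e6 / track$library_size,
    spike_in = {
      if (is.null(reference_spike)) .stopf("spike_in mode requires reference_spike")
      spike_in_factor(track, reference_spike)
    }
  )
  out <- track
  out$intervals$value <- out$intervals$value * factor
  out$normalized <- mode
  out
}
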