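#' DRB/4sU clearance kinetics and elongation-velocity estimation
#'
#' DRB blocks the release of paused polymerase into productive elongation
#' while polymerases already in gene bodies run on. A short 4sU pulse
#' (default 10 min) immediately before harvest labels only RNA synthesised
#' in that window, so after `t` minutes of DRB a zone of the gene body
#' proximal to the TSS is cleared of labelled signal. Plotting per-bin log2
#' fold change of each time point against the 0-min (no DRB) sample shows a
#' clearance wavefront whose distance from the TSS grows as
#' `velocity * (t - label_duration)`: during the final `label_duration`
#' minutes no polymerase released before DRB can still occupy positions
#' closer than `v * (t - label_duration)`, so the cleared zone scales with
#' effective time, not raw time. Regressing wavefront position on effective
#' time therefore yields the elongation velocity.
#'
#' @name clearance
NULL

# Pick the sense-strand track for a gene strand. A sample is either a bare
# signal_track (unstranded) or list(plus = track, minus = track).
.sense_track <- function(sample, strand) {
  if (inherits(sample, "signal_track")) return(sample)
  if (strand == "+") sample$plus else sample$minus
}

.sample_tracks <- function(sample) {
  if (inherits(sample, "signal_track")) list(sample)
  else sample[c("plus", "minus")]
}

#' Assemble a DRB time course
#'
#' @param samples named list mapping time in minutes (as names, e.g. `"0"`,
#'   `"15"`) to a sample: either a single `signal_track` or
#'   `list(plus =, minus =)` stranded tracks. All tracks must be spike-in
#'   normalized against a common reference; time 0 (no DRB) must be present.
#' @param condition label for the condition (e.g. `"control"`).
#' @param label_min length of the 4sU pulse in minutes (default 10).
#' @return A `time_course` object.
#' @export
time_course <- function(samples, condition = "control", label_min = 10) {
  times <- suppressWarnings(as.numeric(names(samples)))
  if (any(is.na(times))) .stopf("sample names must be numeric times in minutes")
  if (!0 %in% times) .stopf("time course must contain time 0 (no DRB)")
  for (s in samples) {
    for (tr in .sample_tracks(s)) {
      if (!inherits(tr, "signal_track")) .stopf("samples must be signal_track(s)")
      if (!identical(tr$normalized, "spike_in")) {
        .stopf("track '%s' is not spike-in normalized; normalize all time points against a common reference first",
               tr$sample_id)
      }
    }
  }
  samples <- samples[order(times)]
  structure(list(samples = samples, times = sort(times),
                 condition = condition, label_min = label_min),
            class = "time_course")
}

#' Spike-in normalize a set of raw time-point samples
#'
#' Convenience wrapper: applies [normalize_track()] in `spike_in` mode to
#' every track of every sample against one common `reference_spike`.
#'
#' @param samples named list of raw samples as in [time_course()].
#' @param reference_spike common reference spike-in read count; defaults to
#'   the spike count of the time-0 sample.
#' @return Named list of normalized samples.
#' @export
normalize_timecourse <- function(samples, reference_spike = NULL) {
  if (is.null(reference_spike)) {
    s0 <- samples[[which(as.numeric(names(samples)) == 0)[1]]]
    reference_spike <- .sample_tracks(s0)[[1]]$spike_in_reads
  }
  lapply(samples, function(s) {
    if (inherits(s, "signal_track")) {
      normalize_track(s, "spike_in", reference_spike)
    } else {
      list(plus = normalize_track(s$plus, "spike_in", reference_spike),
           minus = normalize_track(s$minus, "spike_in", reference_spike))
    }
  })
}

#' Per-time clearance profiles relative to time 0
#'
#' For every gene, sense-strand signal is averaged in `bin`-sized bins from
#' the TSS into the gene body (strand-aware, up to `extent` or the gene end,
#' whichever comes first); per bin the log2 fold change
#' `log2((signal_t + pc) / (signal_0 + pc))` is computed and averaged across
#' genes. Genes shorter than `extent` contribute only their covered bins.
#'
#' @param tc a `time_course`.
#' @param genes a `gene_set` (pre-filtered for expression/overlap).
#' @param bin bin size in bases (default 100).
#' @param extent maximum distance from the TSS in bases (default 1e5).
#' @param pseudocount positive stabilizer for the log ratio (default 1).
#' @param drop_first_bin exclude the first (promoter-proximal) bin, where
#'   paused polymerases keep synthesising the first ~50-100 nt and labelled
#'   signal never clears.
#' @return A `clearance_profile`: list with `times`, `bin`, `extent`,
#'   `profiles` (times x bins matrix of mean log2 fold change; the time-0
#'   row is identically 0), `n_genes`, `per_gene` (list of genes x bins
#'   matrices, rows ranked by gene length short to long, `NA` beyond a
#'   gene's covered bins) and `gene_lengths`.
#' @export
clearance_profiles <- function(tc, genes, bin = 100, extent = 1e5,
                               pseudocount = 1, drop_first_bin = FALSE) {
  stopifnot(inherits(tc, "time_course"), inherits(genes, "gene_set"))
  if (pseudocount <= 0) .stopf("pseudocount must be positive")
  n <- nrow(genes)
  if (n == 0) .stopf("empty gene set")
  len <- genes$end - genes$start
  nb_g <- pmin(len, extent) %/% bin
  if (all(nb_g == 0)) .stopf("no gene covers a single bin")
  nb_max <- max(nb_g)
  gene_idx <- rep(seq_len(n), times = nb_g)
  bin_idx <- unlist(lapply(nb_g, seq_len), use.names = FALSE)
  plus <- genes$strand[gene_idx] == "+"
  q_start <- ifelse(plus,
                    genes$start[gene_idx] + (bin_idx - 1L) * bin,
                    genes$end[gene_idx] - bin_idx * bin)
  q_chrom <- genes$chrom[gene_idx]

  bin_signal <- function(sample) {
    out <- numeric(length(q_start))
    for (str in c("+", "-")) {
      sel <- genes$strand[gene_idx] == str
      if (!any(sel)) next
      tr <- .sense_track(sample, str)
      out[sel] <- .interval_sums(tr$intervals, q_chrom[sel], q_start[sel],
                                 q_start[sel] + bin)
    }
    out / bin
  }

  i0 <- which(tc$times == 0)
  sig0 <- bin_signal(tc$samples[[i0]])
  first_bin_ok <- if (drop_first_bin) bin_idx > 1L else rep(TRUE, length(bin_idx))

  nt <- length(tc$times)
  profiles <- matrix(NA_real_, nt, nb_max,
                     dimnames = list(as.character(tc$times), NULL))
  per_gene <- vector("list", nt)
  names(per_gene) <- as.character(tc$times)
  len_rank <- base::order(len, genes$gene_id)
  for (ti in seq_len(nt)) {
    sig_t <- if (ti == i0) sig0 else bin_signal(tc$samples[[ti]])
    lfc <- log2((sig_t + pseudocount) / (sig0 + pseudocount))
    m <- matrix(NA_real_, n, nb_max,
                dimnames = list(genes$gene_id, NULL))
    m[cbind(gene_idx, bin_idx)] <- lfc
    if (drop_first_bin) m[, 1] <- NA_real_
    use <- first_bin_ok
    sums <- rowsum(lfc[use], bin_idx[use])
    cnts <- rowsum(rep(1, sum(use)), bin_idx[use])
    prof <- rep(NA_real_, nb_max)
    prof[as.integer(rownames(sums))] <- sums[, 1] / cnts[, 1]
    profiles[ti, ] <- prof
    per_gene[[ti]] <- m[len_rank, , drop = FALSE]
  }
  structure(list(times = tc$times, bin = bin, extent = extent,
                 pseudocount = pseudocount, profiles = profiles,
                 n_genes = n, per_gene = per_gene,
                 gene_lengths = stats::setNames(len, genes$gene_id)[len_rank],
                 condition = tc$condition, label_min = tc$label_min),
            class = "clearance_profile")
}

#' Locate the clearance wavefront in a profile vector
#'
#' The per-bin profile is smoothed with a centred running mean of width
#' `smooth_bins` (edges use the available shorter windows); the wavefront is
#' the distance from the TSS of the first bin, scanning outward, at which
#' the smoothed profile rises above `threshold` and stays above it for
#' `smooth_bins` consecutive bins (clipped at the profile end). If the
#' profile starts above the threshold the wavefront is 0; if it never rises
#' above it, `NA` is returned with a warning.
#'
#' @param profile numeric vector of per-bin mean log2 fold change, bin 1 at
#'   the TSS.
#' @param threshold negative log2 threshold (default -0.5, half clearance).
#' @param smooth_bins odd window width >= 1 (default 5).
#' @param bin_size bin size in bases used to convert bins to distance.
#' @return Wavefront distance from the TSS in bases.
#' @export
wavefront <- function(profile, threshold = -0.5, smooth_bins = 5,
                      bin_size = 100) {
  if (threshold >= 0) .stopf("threshold must be negative")
  if (smooth_bins < 1 || smooth_bins %% 2 != 1) {
    .stopf("smooth_bins must be odd and >= 1")
  }
  profile <- profile[!is.na(profile)]
  nbin <- length(profile)
  if (nbin < smooth_bins) .stopf("profile shorter than smooth_bins")
  half <- (smooth_bins - 1L) / 2L
  smoothed <- vapply(seq_len(nbin), function(i) {
    mean(profile[max(1L, i - half):min(nbin, i + half)])
  }, numeric(1))
  above <- smoothed > threshold
  if (above[1]) return(0)
  for (i in seq_len(nbin)) {
    run <- i:min(nbin, i + smooth_bins - 1L)
    if (all(above[run])) return((i - 1) * bin_size)
  }
  .warnf("profile never rises above threshold %g; wavefront undetermined",
         threshold)
  NA_real_
}

#' Wavefront positions for every time point of a clearance profile
#'
#' @param cp a `clearance_profile`.
#' @param threshold,smooth_bins as in [wavefront()].
#' @return Named numeric vector, time (min) -> wavefront (bp). A warning is
#'   issued if wavefronts are not non-decreasing in time.
#' @export
clearance_wavefronts <- function(cp, threshold = -0.5, smooth_bins = 5) {
  stopifnot(inherits(cp, "clearance_profile"))
  fronts <- vapply(seq_along(cp$times), function(ti) {
    wavefront(cp$profiles[ti, ], threshold, smooth_bins, cp$bin)
  }, numeric(1))
  names(fronts) <- as.character(cp$times)
  ok <- !is.na(fronts)
  if (any(diff(fronts[ok]) < 0)) {
    .warnf("wavefront positions are not non-decreasing in time")
  }
  fronts
}

#' Elongation velocity from wavefront positions
#'
#' Ordinary least squares of wavefront position (bp) against effective time
#' `time - label_duration` (min), using only time points strictly greater
#' than the label duration (earlier points carry no cleared zone).
#'
#' @param fronts named numeric vector, time (min) -> wavefront (bp); `NA`
#'   fronts are dropped.
#' @param label_duration_min 4sU pulse length in minutes (default 10).
#' @return A `wavefront_fit`: `velocity_kb_per_min`, `intercept_bp`,
#'   `residuals_bp`, `times_used`, `fronts_used`.
#' @export
estimate_velocity <- function(fronts, label_duration_min = 10) {
  times <- as.numeric(names(fronts))
  if (any(is.na(times))) .stopf("fronts must be named by time in minutes")
  use <- times > label_duration_min & !is.na(fronts)
  if (sum(use) < 2) {
    .stopf("need >= 2 usable time points beyond the %g-min label duration, got %d",
           label_duration_min, sum(use))
  }
  eff <- times[use] - label_duration_min
  y <- unname(fronts[use])
  fit <- stats::lm(y ~ eff)
  structure(list(
    velocity_kb_per_min = unname(stats::coef(fit)[2]) / 1000,
    intercept_bp = unname(stats::coef(fit)[1]),
    residuals_bp = unname(stats::residuals(fit)),
    times_used = times[use],
    fronts_used = y,
    label_duration_min = label_duration_min
  ), class = "wavefront_fit")
}

#' @export
print.wavefront_fit <- function(x, ...) {
  cat(sprintf("wavefront_fit: velocity %.3f kb/min (intercept %.0f bp) from %d time points (%s min)\n",
              x$velocity_kb_per_min, x$intercept_bp, length(x$times_used),
              paste(x$times_used, collapse = ", ")))
  invisible(x)
}

#' Compare two clearance profiles
#'
#' @param a,b `clearance_profile` objects on matching bin grids and time
#'   points.
#' @param threshold,smooth_bins as in [wavefront()].
#' @return List with `wavefront_diff` (data.frame: time, front_a, front_b,
#'   diff_bp = front_a - front_b) and `profile_diff` (times x bins matrix of
#'   per-bin differences a - b).
#' @export
compare_clearance <- function(a, b, threshold = -0.5, smooth_bins = 5) {
  stopifnot(inherits(a, "clearance_profile"), inherits(b, "clearance_profile"))
  if (a$bin != b$bin || ncol(a$profiles) != ncol(b$profiles) ||
      !identical(a$times, b$times)) {
    .stopf("clearance profiles have mismatched bin grids or time points")
  }
  fa <- clearance_wavefronts(a, threshold, smooth_bins)
  fb <- clearance_wavefronts(b, threshold, smooth_bins)
  list(
    wavefront_diff = data.frame(time_min = a$times, front_a = unname(fa),
                                front_b = unname(fb),
                                diff_bp = unname(fa - fb)),
    profile_diff = a$profiles - b$profiles
  )
}
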