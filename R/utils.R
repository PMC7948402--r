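# Internal helpers shared across modules. All genomic coordinates in this
# package are 0-based half-open (BED convention); IRanges is 1-based closed,
# so conversion happens only inside these helpers.

#' @importFrom IRanges IRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

# Sum of value * overlap_length for a set of query intervals against a set of
# track intervals on a single chromosome. Inputs are 0-based half-open.
.interval_sums_chrom <- function(t_start, t_end, t_value, q_start, q_end) {
  out <- numeric(length(q_start))
  if (length(t_start) == 0L || length(q_start) == 0L) return(out)
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(q_start + 1L, q_end),
    IRanges::IRanges(t_start + 1L, t_end)
  )
  if (length(hits) == 0L) return(out)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- pmin(q_end[qh], t_end[sh]) - pmax(q_start[qh], t_start[sh])
  acc <- rowsum(t_value[sh] * ov, qh)
  out[as.integer(rownames(acc))] <- acc[, 1L]
  out
}

# Vectorised coverage-area sums for arbitrary regions (possibly on several
# chromosomes) against a track intervals data.frame (chrom/start/end/value).
.interval_sums <- function(intervals, chrom, start, end) {
  out <- numeric(length(start))
  for (cn in unique(chrom)) {
    qi <- which(chrom == cn)
    ti <- intervals$chrom == cn
    out[qi] <- .interval_sums_chrom(
      intervals$start[ti], intervals$end[ti], intervals$value[ti],
      start[qi], end[qi]
    )
  }
  out
}

# Deterministic derived seed: mixes a base seed with a string tag so that
# independent simulation stages draw from decoupled streams. Result is kept
# inside the 32-bit integer range R's RNG accepts.
.child_seed <- function(seed, tag) {
  h <- 0
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 48271) %% 2147483647)
}

# Multiplicative lognormal noise with unit mean and given coefficient of
# variation; cv = 0 returns exact ones.
.lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Evaluate code under a given seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
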