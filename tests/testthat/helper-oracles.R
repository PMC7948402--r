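# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (per-base loops, all-pairs scans, full enumeration) and never call
# the code paths they check.

random_gene_set <- function(n, chroms = c("chr1", "chr2"),
                            len_range = c(400, 5000), span = 2e6) {
  start <- sample.int(span, n)
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  gene_set(data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len,
    gene_id = sprintf("g%04d", seq_len(n)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}

random_track <- function(n_intervals, chrom = "chr1", span = 2000,
                         max_value = 5) {
  bounds <- sort(sample.int(span, 2 * n_intervals))
  start <- bounds[seq(1, length(bounds), by = 2)]
  end <- bounds[seq(2, length(bounds), by = 2)]
  keep <- start < end
  signal_track(data.frame(chrom = chrom, start = start[keep], end = end[keep],
                          value = round(stats::runif(sum(keep), 0, max_value), 3),
                          stringsAsFactors = FALSE))
}

# Per-base accumulation: loop over every base of the region.
per_base_count <- function(track, chrom, start, end) {
  iv <- track$intervals[track$intervals$chrom == chrom, , drop = FALSE]
  total <- 0
  for (b in seq(start, end - 1)) {
    hit <- iv$start <= b & iv$end > b
    if (any(hit)) total <- total + sum(iv$value[hit])
  }
  total
}

# All-pairs overlap filter: gene g survives iff no other gene intersects
# [g$start - flank, g$end + flank) on the same chromosome.
all_pairs_nonoverlapping <- function(genes, flank) {
  n <- nrow(genes)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (genes$chrom[i] != genes$chrom[j]) next
      if (genes$start[i] - flank < genes$end[j] &&
          genes$end[i] + flank > genes$start[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  genes$gene_id[keep]
}

# Exact two-sided rank-sum test by full enumeration of group assignments.
exact_rank_sum <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  combs <- utils::combn(length(pooled), n1)
  w_all <- colSums(matrix(r[combs], nrow = n1))
  u_all <- w_all - n1 * (n1 + 1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(b) / 2
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  list(u = u_obs, p = p)
}

# Small deterministic time-course pipeline used by several tests: simulate,
# spike-normalize, assemble, profile.
sim_clearance_pipeline <- function(params, genes = NULL, truth = NULL,
                                   depth = params$read_depth_factor,
                                   noise = TRUE, bin = 100, extent = 1e5) {
  if (is.null(truth)) {
    sim <- simulate_genes(params)
    genes <- sim$genes
    truth <- sim$truth
  }
  samples <- lapply(stats::setNames(params$drb_times_min, params$drb_times_min),
                    function(t) simulate_nascent(params, truth, drb_min = t,
                                                 depth_factor = depth,
                                                 noise = noise))
  samples <- normalize_timecourse(samples, reference_spike = params$spike_reads)
  tc <- time_course(samples, "sim", label_min = params$label_min)
  clearance_profiles(tc, genes, bin = bin, extent = extent)
}
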