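#' Kinetic transcription simulator
#'
#' Generates ground-truthed coverage fixtures from an
#' initiation-pause-release-elongation model: polymerases initiate at a
#' gene's TSS as a Poisson process with rate `alpha` (events/min), pause
#' 50-100 nt downstream of the TSS, wait an exponential time with release
#' rate `beta` (1/min), then elongate deterministically at velocity `v`
#' until they run off the gene end. A 4sU pulse labels RNA synthesised in
#' the final `label_min` minutes before harvest; DRB added `drb_min` minutes
#' before harvest blocks all further pause release (paused polymerases stay,
#' released ones run on). The simulator emits the *expected* coverage of
#' this process (closed form under Poisson traffic) with multiplicative
#' lognormal noise, which is what coverage-consuming downstream code sees;
#' read-level sampling is deliberately not modelled.
#'
#' For `drb_min > label_min` the expected labelled coverage at distance `x`
#' beyond the pause site is 0 up to `v * (drb_min - label_min)`, rises
#' linearly to `alpha * label_min` at `v * drb_min`, and is flat beyond -
#' the rear edge of this labelled zone is the clearance wavefront.
#'
#' @name simulator
NULL

#' Simulation parameters
#'
#' @param n_genes number of genes.
#' @param length_range_bp gene length range, sampled uniformly.
#' @param strand_fraction_plus probability a gene is on the + strand.
#' @param alpha mean initiation rate (events/min/gene); per-gene rates are
#'   `alpha` times a lognormal(0, `alpha_sdlog`) draw.
#' @param alpha_sdlog lognormal spread of per-gene initiation rates.
#' @param beta mean pause-release rate (1/min), per-gene lognormal as above.
#' @param beta_sdlog lognormal spread of per-gene release rates.
#' @param pause_range_bp pause-site position relative to the TSS, sampled
#'   uniformly (default 50-100 nt, the canonical promoter-proximal window).
#' @param v_kb_per_min mean elongation velocity; per-gene velocities are
#'   lognormal with spread `v_sdlog` (0 = identical).
#' @param v_sdlog lognormal spread of per-gene velocities.
#' @param label_min 4sU pulse length in minutes (default 10).
#' @param drb_times_min DRB pre-treatment durations in minutes; 0 = no DRB.
#' @param read_depth_factor default sequencing-depth factor per sample.
#' @param spike_reads nominal spike-in read pool per sample; the observed
#'   spike count scales with the sample's depth factor.
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   coverage noise (0 = noise-free).
#' @param gene_gap spacing between consecutive genes on the synthetic
#'   chromosome (default 12 kb, clear of the 5-kb overlap flank).
#' @param chrom synthetic chromosome name.
#' @param chrom_length optional chromosome length; placement beyond it
#'   errors.
#' @param res_bp resolution at which expected coverage is discretised and
#'   noised (default 50 bp).
#' @param expr_scale FPKM per unit initiation rate in the synthetic
#'   expression table.
#' @param occ_scale overall scale of the occupancy track.
#' @param seed integer seed; identical parameters including the seed give
#'   byte-identical fixture sets.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_genes = 200, length_range_bp = c(5000, 50000),
                       strand_fraction_plus = 0.5,
                       alpha = 2, alpha_sdlog = 0.5,
                       beta = 1, beta_sdlog = 0.5,
                       pause_range_bp = c(50, 100),
                       v_kb_per_min = 2, v_sdlog = 0,
                       label_min = 10, drb_times_min = c(0, 15, 25, 35),
                       read_depth_factor = 1, spike_reads = 1e5,
                       noise_cv = 0.2, gene_gap = 12000,
                       chrom = "chrS", chrom_length = NULL, res_bp = 50,
                       expr_scale = 10, occ_scale = 20, seed = 1) {
  stopifnot(n_genes >= 0, alpha > 0, beta > 0, v_kb_per_min > 0,
            strand_fraction_plus >= 0, strand_fraction_plus <= 1,
            label_min > 0, noise_cv >= 0, res_bp >= 1, gene_gap >= 0,
            length_range_bp[1] <= length_range_bp[2], length_range_bp[1] >= 1)
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate gene models, expression and ground truth
#'
#' Places genes sequentially on a synthetic chromosome separated by
#' `gene_gap` bases and draws per-gene kinetic parameters. The expression
#' table reflects steady-state nascent output (proportional to the
#' initiation rate, since every initiated polymerase is eventually
#' released) with multiplicative noise.
#'
#' @param params a [sim_params()] object.
#' @return List with `genes` (a `gene_set`), `fpkm` (named numeric) and
#'   `truth` (data.frame of per-gene kinetic parameters).
#' @export
simulate_genes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_genes
  if (n == 0) {
    empty <- gene_set(data.frame(chrom = character(), start = integer(),
                                 end = integer(), gene_id = character(),
                                 strand = character()),
                      provenance = "simulated (0 genes)")
    return(list(genes = empty, fpkm = stats::setNames(numeric(0), character(0)),
                truth = data.frame()))
  }
  .with_seed(.child_seed(params$seed, "genes"), {
    len <- round(stats::runif(n, params$length_range_bp[1],
                              params$length_range_bp[2]))
    strand <- ifelse(stats::runif(n) < params$strand_fraction_plus, "+", "-")
    alpha <- params$alpha * stats::rlnorm(n, 0, params$alpha_sdlog)
    beta <- params$beta * stats::rlnorm(n, 0, params$beta_sdlog)
    pause <- round(stats::runif(n, params$pause_range_bp[1],
                                params$pause_range_bp[2]))
    v_bp <- 1000 * params$v_kb_per_min * stats::rlnorm(n, 0, params$v_sdlog)
    fpkm_vals <- params$expr_scale * alpha * .lognormal_noise(n, params$noise_cv)
  })
  start <- params$gene_gap + cumsum(c(0, len[-n] + params$gene_gap))
  end <- start + len
  if (!is.null(params$chrom_length) &&
      end[n] + params$gene_gap > params$chrom_length) {
    .stopf("cannot place %d genes of these lengths on a %d-bp chromosome",
           n, params$chrom_length)
  }
  ids <- sprintf("g%04d", seq_len(n))
  genes <- gene_set(
    data.frame(chrom = params$chrom, start = start, end = end, gene_id = ids,
               strand = strand, stringsAsFactors = FALSE),
    provenance = sprintf("simulated (%d genes, seed %d)", n, params$seed)
  )
  truth <- data.frame(
    gene_id = ids, chrom = params$chrom, start = start, end = end,
    strand = strand, length = len, alpha = alpha, beta = beta,
    pause_site_bp = pause, v_bp_per_min = v_bp, fpkm = fpkm_vals,
    stringsAsFactors = FALSE
  )
  list(genes = genes, fpkm = stats::setNames(fpkm_vals, ids), truth = truth)
}

# Expected labelled 4sU coverage (per base, in units of polymerase
# traversals) at offset `x` from the TSS, for one gene. Closed form for
# Poisson initiation traffic with deterministic elongation.
.nascent_expectation <- function(x, alpha, pause, v_bp, label_min, drb_min) {
  s <- (x - pause) / v_bp  # travel time from the pause site, minutes
  ifelse(x < pause,
         alpha * label_min,  # promoter-proximal traffic, unaffected by DRB
         alpha * pmax(0, pmin(label_min, label_min - drb_min + s)))
}

#' Simulate a 4sU-seq sample (per-strand coverage)
#'
#' Expected labelled coverage under the kinetic model, discretised at
#' `res_bp`, with multiplicative lognormal noise and a sequencing-depth
#' factor. The noise stream is keyed by `(seed, noise_tag)` only, so two
#' samples differing only in depth share noise draws and are exactly
#' proportional - the configuration used to validate spike-in
#' normalization. Observed spike-in reads scale with the depth factor.
#'
#' @param params a [sim_params()] object.
#' @param truth per-gene truth from [simulate_genes()].
#' @param drb_min DRB pre-treatment duration in minutes (0 = no DRB).
#' @param sample_id sample identifier.
#' @param depth_factor sequencing-depth factor (default
#'   `params$read_depth_factor`).
#' @param noise apply lognormal noise (`FALSE` gives the exact expectation).
#' @param noise_tag key of the noise stream; defaults to `drb_min` so
#'   conditions sharing a time point are depth-comparable. Pass a distinct
#'   tag for independent noise.
#' @return List with `plus` and `minus` `signal_track`s and `time_min`.
#' @export
simulate_nascent <- function(params, truth, drb_min, sample_id = "nascent",
                             depth_factor = params$read_depth_factor,
                             noise = TRUE, noise_tag = drb_min) {
  stopifnot(inherits(params, "sim_params"))
  res <- params$res_bp
  n <- nrow(truth)
  nchunk <- ceiling(truth$length / res)
  gi <- rep(seq_len(n), times = nchunk)
  off0 <- unlist(lapply(nchunk, function(k) (seq_len(k) - 1) * res),
                 use.names = FALSE)
  off1 <- pmin(off0 + res, truth$length[gi])
  mid <- (off0 + off1) / 2
  cov <- .nascent_expectation(mid, truth$alpha[gi], truth$pause_site_bp[gi],
                              truth$v_bp_per_min[gi], params$label_min, drb_min)
  noise_f <- if (noise) {
    .with_seed(.child_seed(params$seed, paste0("nascent|", noise_tag)),
               .lognormal_noise(length(cov), params$noise_cv))
  } else rep(1, length(cov))
  value <- cov * noise_f * depth_factor
  plus_g <- truth$strand[gi] == "+"
  g_start <- ifelse(plus_g, truth$start[gi] + off0, truth$end[gi] - off1)
  g_end <- ifelse(plus_g, truth$start[gi] + off1, truth$end[gi] - off0)
  lib <- round(1e6 * depth_factor)
  spike <- round(params$spike_reads * depth_factor)
  mk <- function(sel, suffix) {
    signal_track(data.frame(chrom = truth$chrom[gi][sel],
                            start = g_start[sel], end = g_end[sel],
                            value = value[sel], stringsAsFactors = FALSE),
                 sample_id = paste0(sample_id, suffix), library_size = lib,
                 spike_in_reads = spike)
  }
  list(plus = mk(plus_g, "_plus"), minus = mk(!plus_g, "_minus"),
       time_min = drb_min)
}

#' Simulate a Pol II occupancy (ChIP-like) track
#'
#' Expected steady-state polymerase density: gene-body density `alpha / v`
#' per base (polymerases in transit) plus a pause peak of mass
#' `alpha / beta` (mean number of paused polymerases) spread over a 50-bp
#' kernel centred on the pause site, all scaled by `occ_scale`, noised and
#' depth-scaled. Lower release rates give taller pause peaks at fixed body
#' density, hence higher pausing indices.
#'
#' @param params a [sim_params()] object.
#' @param truth per-gene truth from [simulate_genes()] (modify its `beta`
#'   column to emulate a release-rate perturbation between conditions).
#' @param sample_id sample identifier.
#' @param depth_factor sequencing-depth factor.
#' @param noise apply lognormal noise.
#' @param noise_tag key of the noise stream (default `sample_id`).
#' @return An unstranded `signal_track`.
#' @export
simulate_occupancy <- function(params, truth, sample_id = "occupancy",
                               depth_factor = params$read_depth_factor,
                               noise = TRUE, noise_tag = sample_id) {
  stopifnot(inherits(params, "sim_params"))
  res <- params$res_bp
  n <- nrow(truth)
  nchunk <- ceiling(truth$length / res)
  gi <- rep(seq_len(n), times = nchunk)
  off0 <- unlist(lapply(nchunk, function(k) (seq_len(k) - 1) * res),
                 use.names = FALSE)
  off1 <- pmin(off0 + res, truth$length[gi])
  width <- off1 - off0
  peak_lo <- truth$pause_site_bp[gi] - 25
  peak_hi <- truth$pause_site_bp[gi] + 25
  ovl <- pmax(0, pmin(off1, peak_hi) - pmax(off0, peak_lo))
  dens <- truth$alpha[gi] / truth$v_bp_per_min[gi] +
    (truth$alpha[gi] / truth$beta[gi] / 50) * ovl / width
  noise_f <- if (noise) {
    .with_seed(.child_seed(params$seed, paste0("occupancy|", noise_tag)),
               .lognormal_noise(length(dens), params$noise_cv))
  } else rep(1, length(dens))
  value <- params$occ_scale * dens * noise_f * depth_factor
  plus_g <- truth$strand[gi] == "+"
  g_start <- ifelse(plus_g, truth$start[gi] + off0, truth$end[gi] - off1)
  g_end <- ifelse(plus_g, truth$start[gi] + off1, truth$end[gi] - off0)
  signal_track(data.frame(chrom = truth$chrom[gi], start = g_start,
                          end = g_end, value = value, stringsAsFactors = FALSE),
               sample_id = sample_id, library_size = round(1e6 * depth_factor),
               spike_in_reads = round(params$spike_reads * depth_factor))
}

#' Write a complete simulated experiment to disk
#'
#' Emits `genes.bed`, `fpkm.tsv`, `truth.tsv`, per-time-point bedGraph pairs
#' `nascent_t<t>_{plus,minus}.bedgraph`, an `occupancy.bedgraph` and a
#' `samples.yaml` manifest (sample_id, file paths, library_size,
#' spike_in_reads, time_min, condition). With a fixed seed the output files
#' are byte-identical across runs.
#'
#' @param params a [sim_params()] object.
#' @param out_dir output directory (created if needed).
#' @param condition condition label recorded in the manifest.
#' @return Invisibly, the list from [simulate_genes()] plus `dir`.
#' @export
simulate_experiment <- function(params, out_dir, condition = "control") {
  stopifnot(inherits(params, "sim_params"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genes(params)
  write_bed6(sim$genes, file.path(out_dir, "genes.bed"))
  writeLines(c("gene_id\tfpkm",
               sprintf("%s\t%.17g", names(sim$fpkm), sim$fpkm)),
             file.path(out_dir, "fpkm.tsv"))
  tr <- sim$truth
  writeLines(c(paste(names(tr), collapse = "\t"),
               sprintf("%s\t%s\t%d\t%d\t%s\t%d\t%.17g\t%.17g\t%d\t%.17g\t%.17g",
                       tr$gene_id, tr$chrom, tr$start, tr$end, tr$strand,
                       tr$length, tr$alpha, tr$beta, tr$pause_site_bp,
                       tr$v_bp_per_min, tr$fpkm)),
             file.path(out_dir, "truth.tsv"))
  manifest <- list()
  for (t in params$drb_times_min) {
    nas <- simulate_nascent(params, sim$truth, drb_min = t,
                            sample_id = sprintf("%s_t%g", condition, t))
    fp <- sprintf("nascent_t%g_plus.bedgraph", t)
    fm <- sprintf("nascent_t%g_minus.bedgraph", t)
    write_bedgraph(nas$plus, file.path(out_dir, fp))
    write_bedgraph(nas$minus, file.path(out_dir, fm))
    manifest[[length(manifest) + 1]] <- list(
      sample_id = sprintf("%s_t%g", condition, t), bedgraph_plus = fp,
      bedgraph_minus = fm, library_size = nas$plus$library_size,
      spike_in_reads = nas$plus$spike_in_reads, time_min = t,
      condition = condition
    )
  }
  occ <- simulate_occupancy(params, sim$truth,
                            sample_id = paste0(condition, "_occupancy"))
  write_bedgraph(occ, file.path(out_dir, "occupancy.bedgraph"))
  manifest[[length(manifest) + 1]] <- list(
    sample_id = paste0(condition, "_occupancy"),
    bedgraph = "occupancy.bedgraph", library_size = occ$library_size,
    spike_in_reads = occ$spike_in_reads, time_min = NA, condition = condition
  )
  yaml::write_yaml(list(label_min = params$label_min, samples = manifest),
                   file.path(out_dir, "samples.yaml"))
  invisible(c(sim, list(dir = out_dir)))
}

#' Read a sample manifest written by [simulate_experiment()]
#'
#' @param path path to a `samples.yaml`.
#' @return The parsed manifest list (`label_min`, `samples`).
#' @export
read_sample_config <- function(path) yaml::read_yaml(path)

#' Load the 4sU time course of one condition from a manifest
#'
#' Reads the per-time bedGraph pairs, spike-in normalizes them against a
#' common reference and assembles a [time_course()].
#'
#' @param dir directory containing `samples.yaml` and the bedGraphs.
#' @param condition condition label to select.
#' @param reference_spike common reference spike count (default: the
#'   time-0 sample's).
#' @return A `time_course`.
#' @export
load_timecourse <- function(dir, condition = NULL, reference_spike = NULL) {
  cfg <- read_sample_config(file.path(dir, "samples.yaml"))
  entries <- Filter(function(s) !is.null(s$time_min) && !is.na(s$time_min) &&
                      (is.null(condition) || identical(s$condition, condition)),
                    cfg$samples)
  if (length(entries) == 0) .stopf("no time-course samples found")
  samples <- list()
  for (s in entries) {
    samples[[as.character(s$time_min)]] <- list(
      plus = read_bedgraph(file.path(dir, s$bedgraph_plus),
                           paste0(s$sample_id, "_plus"),
                           s$library_size, s$spike_in_reads),
      minus = read_bedgraph(file.path(dir, s$bedgraph_minus),
                            paste0(s$sample_id, "_minus"),
                            s$library_size, s$spike_in_reads)
    )
  }
  samples <- normalize_timecourse(samples, reference_spike)
  time_course(samples, condition = entries[[1]]$condition,
              label_min = cfg$label_min)
}
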