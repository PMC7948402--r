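test_that("gene simulation honours counts, spacing and determinism", {
  p0 <- sim_params(n_genes = 0)
  empty <- simulate_genes(p0)
  expect_equal(nrow(empty$genes), 0)
  expect_length(empty$fpkm, 0)

  p <- sim_params(n_genes = 25, seed = 90)
  a <- simulate_genes(p)
  b <- simulate_genes(p)
  expect_identical(a$truth, b$truth)
  # default spacing clears the 5-kb flank: all genes survive overlap filtering
  expect_equal(nrow(filter_nonoverlapping(a$genes, 5000)), 25)

  # spacing override 0 makes adjacent genes conflict by construction
  p0gap <- sim_params(n_genes = 5, gene_gap = 0, seed = 90)
  touching <- simulate_genes(p0gap)
  expect_equal(nrow(filter_nonoverlapping(touching$genes, 1000)), 0)

  p_inf <- sim_params(n_genes = 100, length_range_bp = c(50000, 50000),
                      chrom_length = 1e6)
  expect_error(simulate_genes(p_inf), "cannot place")
})

test_that("nascent coverage follows the closed-form labelled-zone geometry", {
  p <- sim_params(n_genes = 10, length_range_bp = c(60000, 90000),
                  v_kb_per_min = 2, label_min = 10, noise_cv = 0, seed = 91)
  sim <- simulate_genes(p)

  # no DRB: uniform alpha * label_min everywhere in the gene
  s0 <- simulate_nascent(p, sim$truth, drb_min = 0, noise = FALSE)
  g <- sim$truth[sim$truth$strand == "+", ][1, ]
  tr <- s0$plus
  mid_cov <- count_region(tr, g$chrom, g$start + 20000, g$start + 20100) / 100
  far_cov <- count_region(tr, g$chrom, g$start + 50000, g$start + 50100) / 100
  expect_equal(mid_cov, g$alpha * 10, tolerance = 1e-9)
  expect_equal(far_cov, mid_cov, tolerance = 1e-9)

  # DRB for t > label: zero on (pause, v(t-10)), positive beyond, up to v t
  s25 <- simulate_nascent(p, sim$truth, drb_min = 25, noise = FALSE)
  v <- g$v_bp_per_min
  cleared_end <- v * (25 - 10)
  expect_equal(count_region(s25$plus, g$chrom, g$start + g$pause_site_bp + 200,
                            g$start + cleared_end - 200), 0)
  expect_gt(count_region(s25$plus, g$chrom, g$start + cleared_end + 200,
                         g$start + cleared_end + 1200), 0)
  # promoter-proximal traffic keeps labelling the first ~pause_site bases
  expect_gt(count_region(s25$plus, g$chrom, g$start, g$start + g$pause_site_bp), 0)

  # first strictly-positive bin beyond the pause sits at v(t - label) +- 1 bin
  for (t in c(15, 25, 35)) {
    st <- simulate_nascent(p, sim$truth, drb_min = t, noise = FALSE)
    bins <- seq(0, 60000 - 100, by = 100)
    sig <- count_regions(st$plus, data.frame(chrom = g$chrom,
                                             start = g$start + bins,
                                             end = g$start + bins + 100))
    beyond_pause <- bins > g$pause_site_bp
    first_pos <- bins[beyond_pause][which(sig[beyond_pause] > 0)[1]]
    expect_lte(abs(first_pos - v * (t - 10)), 100)
  }
})

test_that("pause-release limits confine or free the labelled signal", {
  p <- sim_params(n_genes = 6, length_range_bp = c(20000, 30000),
                  noise_cv = 0, seed = 92)
  sim <- simulate_genes(p)
  # beta -> 0 (never released): signal confined to [TSS, pause_site].
  # In the expectation model release rate only shapes occupancy; confinement
  # under permanent DRB is the equivalent limit: drb_min much longer than
  # any run-off time.
  s_blocked <- simulate_nascent(p, sim$truth, drb_min = 1000, noise = FALSE)
  for (i in which(sim$truth$strand == "+")) {
    g <- sim$truth[i, ]
    expect_equal(count_region(s_blocked$plus, g$chrom,
                              g$start + g$pause_site_bp + 100, g$end), 0)
    expect_gt(count_region(s_blocked$plus, g$chrom, g$start,
                           g$start + g$pause_site_bp), 0)
  }
})

test_that("occupancy fixtures reproduce closed-form pausing indices and the beta effect", {
  p <- sim_params(n_genes = 120, length_range_bp = c(2000, 20000), seed = 93)
  sim <- simulate_genes(p)
  occ <- simulate_occupancy(p, sim$truth, noise = FALSE)
  genes <- filter_min_length(sim$genes, 300)
  tab <- pausing_table(genes, occ)
  t <- sim$truth[match(genes$gene_id, sim$truth$gene_id), ]
  # closed form: body density alpha/v, pause peak mass alpha/beta entirely
  # inside the TSS window (pause site 50-100, kernel half-width 25)
  tss_count <- p$occ_scale * (300 * t$alpha / t$v_bp_per_min + t$alpha / t$beta)
  body_count <- p$occ_scale * (t$length - 300) * t$alpha / t$v_bp_per_min
  lib <- occ$library_size
  want <- log2((tss_count / 0.4 / (lib / 1e6) + 1) /
               (body_count / ((t$length - 300) / 1000) / (lib / 1e6) + 1))
  expect_equal(tab$pausing_index, want, tolerance = 1e-6)

  # alpha = 0 gives an empty track
  t0 <- sim$truth
  t0$alpha <- 0
  expect_equal(nrow(simulate_occupancy(p, t0, noise = FALSE)$intervals), 0)

  # halving beta strictly increases the median pausing index
  t_half <- sim$truth
  t_half$beta <- t_half$beta / 2
  occ_half <- simulate_occupancy(p, t_half, "halved", noise_tag = "halved")
  tab_half <- pausing_table(genes, occ_half)
  expect_gt(stats::median(tab_half$pausing_index),
            stats::median(pausing_table(genes, simulate_occupancy(p, sim$truth))$pausing_index))
})

test_that("fixture sets are byte-identical under a fixed seed", {
  p <- sim_params(n_genes = 15, length_range_bp = c(3000, 10000),
                  drb_times_min = c(0, 15), seed = 94)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_experiment(p, d1)
  simulate_experiment(p, d2)
  files <- list.files(d1)
  expect_true(length(files) >= 7)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("written experiments reload into a working time course", {
  p <- sim_params(n_genes = 10, length_range_bp = c(5000, 12000),
                  drb_times_min = c(0, 15), seed = 95)
  d <- withr::local_tempdir()
  simulate_experiment(p, d, condition = "control")
  genes <- load_gene_models(file.path(d, "genes.bed"))
  expect_equal(nrow(genes), 10)
  expr <- read_fpkm_table(file.path(d, "fpkm.tsv"))
  expect_length(expr, 10)
  tc <- load_timecourse(d, condition = "control",
                        reference_spike = p$spike_reads)
  expect_equal(tc$times, c(0, 15))
  cp <- clearance_profiles(tc, genes, bin = 100, extent = 5000)
  expect_true(all(cp$profiles["0", ] == 0))
  # 15-min DRB with a 10-min label clears the first ~10 kb: early gene-body
  # bins (beyond the promoter bin) show negative log2 fold change
  expect_lt(mean(cp$profiles["15", 2:10]), -1)
})
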