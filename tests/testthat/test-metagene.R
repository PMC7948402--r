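uniform_track <- function(value = 3, span = 1e6) {
  signal_track(data.frame(chrom = "chr1", start = -span, end = span,
                          value = value))
}

test_that("anchored matrices average per bin and match a per-base oracle", {
  sch <- anchor_scheme("point_anchor", bin_size = 10, half_window_bp = 100)
  anchors <- data.frame(chrom = "chr1", pos = c(5000, 9000),
                        strand = c("+", "-"), id = c("a1", "a2"))
  pm <- anchored_matrix(uniform_track(3), anchors, sch)
  expect_equal(dim(pm$values), c(2, 20))
  expect_true(all(pm$values == 3))

  # delta of signal at the anchor: single hot centre bin per row
  delta <- signal_track(data.frame(chrom = "chr1", start = c(5000, 8999),
                                   end = c(5001, 9000), value = 1))
  pmd <- anchored_matrix(delta, anchors, sch)
  expect_equal(unname(rowSums(pmd$values > 0)), c(1, 1))
  expect_equal(unname(apply(pmd$values, 1, which.max)), c(11, 11))

  set.seed(70)
  tr <- random_track(60, span = 5000)
  anch <- data.frame(chrom = "chr1", pos = sample(200:4800, 20),
                     strand = sample(c("+", "-", "*"), 20, replace = TRUE),
                     id = sprintf("p%02d", 1:20))
  sch2 <- anchor_scheme("point_anchor", bin_size = 20, half_window_bp = 100)
  pm2 <- anchored_matrix(tr, anch, sch2)
  for (i in seq_len(20)) {
    starts <- anch$pos[i] - 100 + 20 * (0:9)
    want <- vapply(starts, function(s)
      per_base_count(tr, "chr1", s, s + 20) / 20, numeric(1))
    if (anch$strand[i] == "-") want <- rev(want)
    expect_equal(unname(pm2$values[i, ]), want)
  }
})

test_that("out-of-range bins are zero-filled and masked from column means", {
  sch <- anchor_scheme("point_anchor", bin_size = 10, half_window_bp = 100)
  anchors <- data.frame(chrom = "chr1", pos = c(50, 5000), strand = "+",
                        id = c("edge", "mid"))
  pm <- anchored_matrix(uniform_track(2), anchors, sch)
  expect_equal(unname(pm$values["edge", 1:5]), rep(0, 5))
  expect_false(any(pm$mask["edge", 1:5]))
  expect_equal(unname(mean_profile(pm)), rep(2, 20))  # masked cells excluded
})

test_that("scaled-body partitions are balanced, exhaustive and flank-aware", {
  # 1234-bp body into 100 bins: segment lengths all 12 or 13, summing to 1234
  bounds <- floor(0:100 * 1234 / 100)
  seg <- diff(bounds)
  expect_true(all(seg %in% c(12, 13)))
  expect_equal(sum(seg), 1234)

  genes <- gene_set(data.frame(chrom = "chr1", start = c(10000, 40000),
                               end = c(11234, 49999), gene_id = c("gA", "gB"),
                               strand = c("+", "-")))
  sch <- anchor_scheme("scaled_body", bin_size = 100, upstream_bp = 2000,
                       downstream_bp = 2000, n_body_bins = 100)
  pm <- scaled_matrix(uniform_track(4), genes, sch)
  expect_equal(dim(pm$values), c(2, 140))
  expect_true(all(abs(pm$values - 4) < 1e-12))  # flat profile everywhere

  # signal only inside gene bodies: flank bins 0, body bins > 0
  body_only <- signal_track(data.frame(chrom = "chr1",
                                       start = c(10000, 40000),
                                       end = c(11234, 49999), value = 2))
  pmb <- scaled_matrix(body_only, genes, sch)
  expect_true(all(pmb$values[, 1:20] == 0))
  expect_true(all(pmb$values[, 121:140] == 0))
  expect_true(all(pmb$values[, 21:120] > 0))

  expect_warning(
    scaled_matrix(uniform_track(1),
                  gene_set(data.frame(chrom = "chr1", start = 0, end = 50,
                                      gene_id = "tiny", strand = "+")),
                  sch),
    "shorter"
  )
})

test_that("strand reflection symmetry holds exactly for matrix rows", {
  set.seed(71)
  tr <- random_track(80, span = 20000)
  gene_p <- gene_set(data.frame(chrom = "chr1", start = 6000, end = 13000,
                                gene_id = "g", strand = "+"))
  # reflect track and gene about C so that coordinates stay positive
  C <- 20000
  iv <- tr$intervals
  refl <- signal_track(data.frame(chrom = "chr1", start = 2 * C - iv$end,
                                  end = 2 * C - iv$start, value = iv$value))
  gene_m <- gene_set(data.frame(chrom = "chr1", start = 2 * C - 13000,
                                end = 2 * C - 6000, gene_id = "g",
                                strand = "-"))
  sch <- anchor_scheme("scaled_body", bin_size = 50, upstream_bp = 1000,
                       downstream_bp = 1000, n_body_bins = 70)
  expect_equal(scaled_matrix(tr, gene_p, sch)$values,
               scaled_matrix(refl, gene_m, sch)$values)

  schp <- anchor_scheme("point_anchor", bin_size = 50, half_window_bp = 1000)
  a_p <- data.frame(chrom = "chr1", pos = 6000, strand = "+", id = "g")
  a_m <- data.frame(chrom = "chr1", pos = 2 * C - 6000, strand = "-", id = "g")
  expect_equal(anchored_matrix(tr, a_p, schp)$values,
               anchored_matrix(refl, a_m, schp)$values)
})

test_that("mean_profile equals a naive column loop", {
  set.seed(72)
  tr <- random_track(60, span = 8000)
  anch <- data.frame(chrom = "chr1", pos = sample(1000:7000, 15), strand = "+",
                     id = sprintf("a%02d", 1:15))
  sch <- anchor_scheme("point_anchor", bin_size = 25, half_window_bp = 500)
  pm <- anchored_matrix(tr, anch, sch)
  want <- vapply(seq_len(ncol(pm$values)), function(j) mean(pm$values[, j]),
                 numeric(1))
  expect_equal(unname(mean_profile(pm)), want)
  one <- anchored_matrix(tr, anch[1, ], sch)
  expect_equal(unname(mean_profile(one)), unname(one$values[1, ]))
})

test_that("log2 fold-change matrices follow the formula and vanish on self", {
  set.seed(73)
  tr <- random_track(50, span = 5000)
  anch <- data.frame(chrom = "chr1", pos = sample(500:4500, 10), strand = "+",
                     id = sprintf("a%02d", 1:10))
  sch <- anchor_scheme("point_anchor", bin_size = 50, half_window_bp = 500)
  a <- anchored_matrix(tr, anch, sch)
  for (pc in c(0.1, 1, 7)) {
    expect_true(all(log2fc_matrix(a, a, pc)$values == 0))
  }
  b <- a
  b$values <- a$values * 3 + 2  # arbitrary affine treatment
  fc <- log2fc_matrix(b, a, pseudocount = 1)
  expect_equal(fc$values, log2((b$values + 1) / (a$values + 1)))
  ctrl1 <- a; ctrl1$values <- a$values * 0 + 1
  tr3 <- a; tr3$values <- a$values * 0 + 3
  expect_true(all(log2fc_matrix(tr3, ctrl1, 1)$values == 1))

  short <- anchored_matrix(tr, anch[1:5, ], sch)
  expect_error(log2fc_matrix(a, short), "identical rows")
  expect_error(log2fc_matrix(a, a, pseudocount = 0), "positive")
})

test_that("row ranking is stable with lexicographic tie-breaks", {
  set.seed(74)
  tr <- random_track(40, span = 5000)
  anch <- data.frame(chrom = "chr1", pos = sample(500:4500, 12), strand = "+",
                     id = sprintf("r%02d", sample(1:12)))
  sch <- anchor_scheme("point_anchor", bin_size = 100, half_window_bp = 500)
  pm <- anchored_matrix(tr, anch, sch)

  const <- stats::setNames(rep(1, 12), anch$id)
  expect_equal(row_ids(rank_rows(pm, const)), sort(anch$id))

  key <- stats::setNames(stats::runif(12), anch$id)
  ranked <- rank_rows(pm, key, "desc", key_name = "expression")
  expect_equal(row_ids(ranked), names(sort(key, decreasing = TRUE)))
  expect_equal(ranked$values[1, ],
               pm$values[which(rownames(pm$values) == row_ids(ranked)[1]), ])
  asc <- rank_rows(pm, key, "asc")
  expect_equal(row_ids(asc), rev(row_ids(ranked)))
  expect_error(rank_rows(pm, key[1:5]), "missing")
})
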