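#' Promoter-proximal pausing analysis
#'
#' The pausing index of a gene is the log2 ratio of TSS-region signal density
#' to gene-body signal density, with +1 pseudocounts on each FPKM:
#' `log2((TSS_FPKM + 1) / (genebody_FPKM + 1))`. The TSS region defaults to
#' 100 bp upstream to 300 bp downstream of the TSS; the gene body runs from
#' 300 bp downstream of the TSS to the TES. High values indicate polymerase
#' accumulation at the promoter relative to the body.
#'
#' @name pausing
NULL

#' TSS and gene-body regions for the pausing index
#'
#' Strand-aware: for `+` genes the TSS region is
#' `[start - upstream, start + downstream)` and the body
#' `[start + downstream, end)`; for `-` genes both are mirrored about the TSS
#' at `end`. The two regions are disjoint and the body abuts the TSS region,
#' so together they tile `[TSS - upstream, TES)` in transcript orientation.
#'
#' @param genes a `gene_set` (all genes must be longer than `downstream`;
#'   apply [filter_min_length()] first).
#' @param upstream bases upstream of the TSS in the TSS region (default 100).
#' @param downstream bases downstream of the TSS in the TSS region
#'   (default 300).
#' @return List with data.frames `tss` and `body`, each with `chrom`,
#'   `start`, `end`, `gene_id`, `strand`.
#' @export
pi_regions <- function(genes, upstream = 100, downstream = 300) {
  stopifnot(inherits(genes, "gene_set"))
  len <- genes$end - genes$start
  if (any(len <= downstream)) {
    .stopf("%d gene(s) are not longer than downstream=%d bp; apply filter_min_length() first",
           sum(len <= downstream), downstream)
  }
  plus <- genes$strand == "+"
  tss_start <- ifelse(plus, genes$start - upstream, genes$end - downstream)
  tss_end <- ifelse(plus, genes$start + downstream, genes$end + upstream)
  body_start <- ifelse(plus, genes$start + downstream, genes$start)
  body_end <- ifelse(plus, genes$end, genes$end - downstream)
  list(
    tss = data.frame(chrom = genes$chrom, start = tss_start, end = tss_end,
                     gene_id = genes$gene_id, strand = genes$strand,
                     stringsAsFactors = FALSE),
    body = data.frame(chrom = genes$chrom, start = body_start, end = body_end,
                      gene_id = genes$gene_id, strand = genes$strand,
                      stringsAsFactors = FALSE)
  )
}

#' Pausing index from TSS and body FPKM
#'
#' @param tss_fpkm,body_fpkm non-negative FPKM values (vectorised).
#' @return `log2((tss_fpkm + 1) / (body_fpkm + 1))`.
#' @export
pausing_index <- function(tss_fpkm, body_fpkm) {
  if (any(tss_fpkm < 0) || any(body_fpkm < 0)) {
    .stopf("FPKM inputs to pausing_index must be non-negative")
  }
  log2((tss_fpkm + 1) / (body_fpkm + 1))
}

#' Per-gene pausing table from an occupancy track
#'
#' Combines region definition, signal counting, FPKM scaling (using the
#' track's library size) and the pausing-index formula, one record per gene.
#'
#' @param genes a `gene_set`, pre-filtered for expression, length and
#'   neighbouring transcripts (a warning is issued if genes of 300 bp or
#'   shorter are present).
#' @param track an occupancy `signal_track` (e.g. total Pol II ChIP).
#' @param upstream,downstream TSS-region extents, as in [pi_regions()].
#' @return data.frame with `gene_id`, `tss_fpkm`, `body_fpkm`,
#'   `pausing_index`.
#' @export
pausing_table <- function(genes, track, upstream = 100, downstream = 300) {
  stopifnot(inherits(genes, "gene_set"), inherits(track, "signal_track"))
  if (any(genes$end - genes$start <= downstream)) {
    .warnf("gene set contains genes <= %d bp; they will be dropped", downstream)
    genes <- filter_min_length(genes, downstream)
  }
  reg <- pi_regions(genes, upstream, downstream)
  tss_count <- count_regions(track, reg$tss)
  body_count <- count_regions(track, reg$body)
  tss_fpkm <- fpkm(tss_count, reg$tss$end - reg$tss$start, track$library_size)
  body_fpkm <- fpkm(body_count, reg$body$end - reg$body$start,
                    track$library_size)
  data.frame(
    gene_id = genes$gene_id,
    tss_fpkm = tss_fpkm,
    body_fpkm = body_fpkm,
    pausing_index = pausing_index(tss_fpkm, body_fpkm),
    stringsAsFactors = FALSE
  )
}

#' Rank genes by a value and split into quantile groups
#'
#' Stable sort by value (ties broken by `gene_id` lexicographic order), then
#' split into `k` contiguous groups whose sizes differ by at most one; group
#' 1 is always the top of the ordering.
#'
#' @param values named numeric vector (names are gene ids).
#' @param k number of groups (default 4).
#' @param order `"desc"` (group 1 = highest values) or `"asc"`.
#' @return data.frame `gene_id`, `value`, `group` in ranked order, with
#'   attributes `k` and `order`.
#' @export
rank_and_group <- function(values, k = 4, order = c("desc", "asc")) {
  order <- match.arg(order)
  if (k < 2) .stopf("k must be >= 2")
  n <- length(values)
  if (n < k) .stopf("need at least k=%d genes, got %d", k, n)
  ids <- names(values)
  if (is.null(ids)) .stopf("values must be named by gene_id")
  ord <- if (order == "desc") base::order(-values, ids) else base::order(values, ids)
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1
  out <- data.frame(gene_id = ids[ord], value = unname(values[ord]),
                    group = rep(seq_len(k), times = sizes),
                    stringsAsFactors = FALSE)
  attr(out, "k") <- k
  attr(out, "order") <- order
  out
}

#' Per-group summary of a metric
#'
#' @param grouping output of [rank_and_group()].
#' @param metric named numeric vector defined for every grouped gene.
#' @return data.frame `group`, `n`, `mean`, `median`.
#' @export
group_summary <- function(grouping, metric) {
  vals <- metric[grouping$gene_id]
  if (any(is.na(vals))) {
    .stopf("metric missing for gene(s): %s",
           paste(utils::head(grouping$gene_id[is.na(vals)], 5), collapse = ", "))
  }
  groups <- sort(unique(grouping$group))
  data.frame(
    group = groups,
    n = vapply(groups, function(g) sum(grouping$group == g), integer(1)),
    mean = vapply(groups, function(g) mean(vals[grouping$group == g]), numeric(1)),
    median = vapply(groups, function(g) stats::median(vals[grouping$group == g]),
                    numeric(1))
  )
}

#' Compare two distributions of a per-gene statistic
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test (normal approximation with
#' tie correction), chosen for distribution-freeness on skewed statistics
#' such as pausing indices. The shift is reported as `median(b) - median(a)`.
#'
#' @param a,b numeric vectors (non-empty).
#' @return List with `shift`, `u_statistic` (number of (a, b) pairs with
#'   a > b, ties counted half) and `p_two_sided`.
#' @export
compare_distributions <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) .stopf("both samples must be non-empty")
  shift <- stats::median(b) - stats::median(a)
  if (length(unique(c(a, b))) == 1L) {
    return(list(shift = 0, u_statistic = length(a) * length(b) / 2,
                p_two_sided = 1))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  )
  list(shift = shift, u_statistic = unname(wt$statistic),
       p_two_sided = wt$p.value)
}
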