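#' Metagene and anchored profile matrices
#'
#' All metaplots and heatmaps in the pipeline are built from a
#' `profile_matrix`: rows are genes (or peaks), columns are bins, values are
#' per-bin mean signal (bin averaging, not summing, so changing the bin size
#' does not rescale profiles). Two anchor schemes exist: `point_anchor`
#' (fixed window around TSS/TES/summit) and `scaled_body` (real-coordinate
#' flanks plus a gene body partitioned into a fixed number of equal-length
#' segments). Minus-strand rows are orientation-flipped so column 1 is
#' always 5'/upstream. Bins extending past the chromosome start are
#' zero-filled and masked out of column means.
#'
#' @name metagene
NULL

#' Define an anchor scheme for profile matrices
#'
#' @param kind `"point_anchor"` or `"scaled_body"`.
#' @param bin_size bin width in bases. Defaults follow common practice for
#'   the underlying assay: 10 bp suits ChIP/CUT&RUN tracks, 100 bp suits
#'   RNA-seq/4sU-seq tracks.
#' @param half_window_bp (point_anchor) half-width of the window around the
#'   anchor; `bin_size` must divide `2 * half_window_bp`.
#' @param anchor (point_anchor) `"TSS"`, `"TES"` or `"summit"` - recorded in
#'   metadata; the anchor coordinates themselves are supplied to
#'   [anchored_matrix()].
#' @param upstream_bp,downstream_bp (scaled_body) flank widths in real
#'   coordinates; `bin_size` must divide both.
#' @param n_body_bins (scaled_body) number of equal-length body segments.
#' @return An `anchor_scheme` list.
#' @export
anchor_scheme <- function(kind = c("point_anchor", "scaled_body"),
                          bin_size = 10, half_window_bp = 2000,
                          anchor = c("TSS", "TES", "summit"),
                          upstream_bp = 2000, downstream_bp = 2000,
                          n_body_bins = 100) {
  kind <- match.arg(kind)
  anchor <- match.arg(anchor)
  stopifnot(bin_size >= 1)
  if (kind == "point_anchor") {
    if ((2 * half_window_bp) %% bin_size != 0) {
      .stopf("bin_size must divide 2*half_window_bp")
    }
  } else {
    if (upstream_bp %% bin_size != 0 || downstream_bp %% bin_size != 0) {
      .stopf("bin_size must divide upstream_bp and downstream_bp")
    }
    if (n_body_bins < 1) .stopf("n_body_bins must be >= 1")
  }
  structure(list(kind = kind, bin_size = bin_size,
                 half_window_bp = half_window_bp, anchor = anchor,
                 upstream_bp = upstream_bp, downstream_bp = downstream_bp,
                 n_body_bins = n_body_bins),
            class = "anchor_scheme")
}

.profile_matrix <- function(values, mask, scheme, ranking_key = NA_character_) {
  structure(list(values = values, mask = mask, scheme = scheme,
                 ranking_key = ranking_key),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d rows x %d bins (%s, bin %d bp, ranking %s)\n",
              nrow(x$values), ncol(x$values), x$scheme$kind, x$scheme$bin_size,
              x$ranking_key))
  invisible(x)
}

#' Row identifiers of a profile matrix
#' @param pm a `profile_matrix`.
#' @return Character vector of row ids in current order.
#' @export
row_ids <- function(pm) rownames(pm$values)

#' Fixed-window matrix around anchor points
#'
#' For each anchor, mean signal per bin over
#' `[anchor - half_window, anchor + half_window)`, bins ordered 5' to 3' with
#' respect to the anchor's strand (`"*"` anchors use reference orientation).
#'
#' @param track a `signal_track`.
#' @param anchors data.frame with `chrom`, `pos` (0-based point), `strand`
#'   (`"+"`, `"-"` or `"*"`) and `id`.
#' @param scheme a `point_anchor` [anchor_scheme()].
#' @return A `profile_matrix`; out-of-range bins (before the chromosome
#'   start) are zero and masked.
#' @export
anchored_matrix <- function(track, anchors, scheme) {
  stopifnot(inherits(track, "signal_track"), inherits(scheme, "anchor_scheme"))
  if (scheme$kind != "point_anchor") .stopf("scheme must be point_anchor")
  bin <- scheme$bin_size
  nb <- as.integer(2 * scheme$half_window_bp / bin)
  n <- nrow(anchors)
  starts <- outer(anchors$pos - scheme$half_window_bp, bin * (seq_len(nb) - 1L), `+`)
  q <- data.frame(chrom = rep(anchors$chrom, times = nb),
                  start = as.vector(starts),
                  end = as.vector(starts) + bin)
  sums <- .interval_sums(track$intervals, q$chrom, q$start, q$end)
  values <- matrix(sums / bin, nrow = n, ncol = nb)
  mask <- starts >= 0
  values[!mask] <- 0
  flip <- anchors$strand == "-"
  if (any(flip)) {
    values[flip, ] <- values[flip, nb:1, drop = FALSE]
    mask[flip, ] <- mask[flip, nb:1, drop = FALSE]
  }
  rownames(values) <- rownames(mask) <- as.character(anchors$id)
  .profile_matrix(values, mask, scheme)
}

#' Scaled gene-body matrix (TSS to TES with real-coordinate flanks)
#'
#' Flanks are binned at `bin_size` in real coordinates; the gene body is
#' partitioned into `n_body_bins` equal-length (within 1 bp) segments whose
#' lengths always sum to the gene length; each bin holds mean signal.
#' Minus-strand genes are flipped into transcript orientation.
#'
#' @param track a `signal_track`.
#' @param genes a `gene_set`; genes shorter than `n_body_bins` bases are
#'   dropped with a warning.
#' @param scheme a `scaled_body` [anchor_scheme()].
#' @return A `profile_matrix` with `upstream_bp/bin + n_body_bins +
#'   downstream_bp/bin` columns.
#' @export
scaled_matrix <- function(track, genes, scheme) {
  stopifnot(inherits(track, "signal_track"), inherits(genes, "gene_set"))
  if (scheme$kind != "scaled_body") .stopf("scheme must be scaled_body")
  bin <- scheme$bin_size
  nbb <- scheme$n_body_bins
  short <- (genes$end - genes$start) < nbb
  if (any(short)) {
    .warnf("dropping %d gene(s) shorter than n_body_bins=%d bases",
           sum(short), nbb)
    genes <- gene_set(as.data.frame(genes)[!short, , drop = FALSE],
                      provenance = attr(genes, "provenance"))
  }
  n <- nrow(genes)
  nu <- as.integer(scheme$upstream_bp / bin)
  nd <- as.integer(scheme$downstream_bp / bin)
  ncol_total <- nu + nbb + nd
  values <- matrix(0, n, ncol_total)
  mask <- matrix(TRUE, n, ncol_total)
  if (n > 0) {
    len <- genes$end - genes$start
    # body segment boundaries per gene: floor(i * len / nbb), i = 0..nbb
    bounds <- floor(outer(len, 0:nbb) / nbb)
    starts <- matrix(0, n, ncol_total)
    widths <- matrix(bin, n, ncol_total)
    plus <- genes$strand == "+"
    up_off <- bin * (seq_len(nu) - 1L)
    dn_off <- bin * (seq_len(nd) - 1L)
    for (j in which(plus)) {
      starts[j, seq_len(nu)] <- genes$start[j] - scheme$upstream_bp + up_off
      starts[j, nu + seq_len(nbb)] <- genes$start[j] + bounds[j, 1:nbb]
      widths[j, nu + seq_len(nbb)] <- diff(bounds[j, ])
      starts[j, nu + nbb + seq_len(nd)] <- genes$end[j] + dn_off
    }
    for (j in which(!plus)) {
      starts[j, seq_len(nu)] <- genes$end[j] + scheme$upstream_bp - up_off - bin
      starts[j, nu + seq_len(nbb)] <- genes$end[j] - bounds[j, 2:(nbb + 1)]
      widths[j, nu + seq_len(nbb)] <- diff(bounds[j, ])
      starts[j, nu + nbb + seq_len(nd)] <- genes$start[j] - dn_off - bin
    }
    sums <- .interval_sums(track$intervals, rep(genes$chrom, times = ncol_total),
                           as.vector(starts), as.vector(starts + widths))
    values <- matrix(sums, n, ncol_total) / widths
    mask <- starts >= 0
    values[!mask] <- 0
  }
  rownames(values) <- rownames(mask) <- genes$gene_id
  .profile_matrix(values, mask, scheme)
}

#' Column-mean profile of a matrix
#'
#' Means ignore masked (out-of-range) cells; a column with no valid cell
#' yields `NaN`.
#'
#' @param pm a `profile_matrix`.
#' @return Numeric vector of per-bin means.
#' @export
mean_profile <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (nrow(pm$values) == 0) .stopf("empty profile matrix")
  colSums(pm$values * pm$mask) / colSums(pm$mask)
}

#' Cellwise log2 fold-change matrix
#'
#' `log2((treat + pseudocount) / (control + pseudocount))`; negative values
#' indicate signal loss in the treatment. Both matrices must share row ids,
#' row order, scheme kind and bin count.
#'
#' @param treat,control `profile_matrix` objects on the same rows and scheme.
#' @param pseudocount positive stabilizer (default 1, echoing the +1 in the
#'   pausing-index formula).
#' @return A `profile_matrix` of log2 ratios.
#' @export
log2fc_matrix <- function(treat, control, pseudocount = 1) {
  stopifnot(inherits(treat, "profile_matrix"), inherits(control, "profile_matrix"))
  if (pseudocount <= 0) .stopf("pseudocount must be positive")
  if (!identical(dim(treat$values), dim(control$values)) ||
      !identical(rownames(treat$values), rownames(control$values))) {
    .stopf("treat and control matrices must have identical rows and bin counts")
  }
  if (!identical(treat$scheme$kind, control$scheme$kind)) {
    .stopf("treat and control matrices use different anchor schemes")
  }
  vals <- log2((treat$values + pseudocount) / (control$values + pseudocount))
  .profile_matrix(vals, treat$mask & control$mask, treat$scheme,
                  treat$ranking_key)
}

#' Reorder matrix rows by a ranking key
#'
#' Stable sort with `gene_id` lexicographic tie-break; values untouched.
#'
#' @param pm a `profile_matrix`.
#' @param key named numeric vector defined on all row ids (e.g. expression,
#'   occupancy, gene length).
#' @param order `"desc"` (highest first) or `"asc"`.
#' @param key_name label recorded as the matrix's ranking key.
#' @return The reordered `profile_matrix`.
#' @export
rank_rows <- function(pm, key, order = c("desc", "asc"), key_name = "custom") {
  stopifnot(inherits(pm, "profile_matrix"))
  order <- match.arg(order)
  ids <- rownames(pm$values)
  vals <- key[ids]
  if (any(is.na(vals))) {
    .stopf("ranking key missing for row(s): %s",
           paste(utils::head(ids[is.na(vals)], 5), collapse = ", "))
  }
  ord <- if (order == "desc") base::order(-vals, ids) else base::order(vals, ids)
  .profile_matrix(pm$values[ord, , drop = FALSE], pm$mask[ord, , drop = FALSE],
                  pm$scheme, key_name)
}

#' Write a profile matrix and its metadata
#'
#' Emits `<prefix>.matrix.tsv` (row_id plus one column per bin) and
#' `<prefix>.meta.yaml` (scheme, bin size, ranking key).
#'
#' @param pm a `profile_matrix`.
#' @param prefix output path prefix.
#' @export
write_profile_matrix <- function(pm, prefix) {
  stopifnot(inherits(pm, "profile_matrix"))
  df <- data.frame(row_id = rownames(pm$values), pm$values,
                   check.names = FALSE)
  colnames(df) <- c("row_id", paste0("bin", seq_len(ncol(pm$values))))
  utils::write.table(df, paste0(prefix, ".matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(kind = pm$scheme$kind, bin_size = pm$scheme$bin_size,
                        n_bins = ncol(pm$values), ranking_key = pm$ranking_key),
                   paste0(prefix, ".meta.yaml"))
  invisible(prefix)
}
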