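#' Gene sets: stranded gene models and the standard selection filters
#'
#' A `gene_set` is a data.frame of stranded genomic intervals (0-based
#' half-open, BED convention) with one row per gene and columns `chrom`,
#' `start`, `end`, `gene_id`, `score`, `strand`, `name`. It carries a
#' `provenance` attribute describing the filters applied so far and a
#' `filter_log` attribute with per-filter removal counts.
#'
#' @param df data.frame with at least `chrom`, `start`, `end`, `gene_id`,
#'   `strand`; `score` and `name` are filled in if absent.
#' @param provenance character vector describing how the set was derived.
#' @param filter_log data.frame of per-filter removal counts (internal).
#' @return A `gene_set` object.
#' @export
gene_set <- function(df, provenance = character(), filter_log = NULL) {
  required <- c("chrom", "start", "end", "gene_id", "strand")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    .stopf("gene_set is missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$score)) df$score <- rep(0, nrow(df))
  if (is.null(df$name)) df$name <- df$gene_id
  df <- df[, c("chrom", "start", "end", "gene_id", "score", "strand", "name")]
  df$chrom <- as.character(df$chrom)
  df$gene_id <- as.character(df$gene_id)
  df$strand <- as.character(df$strand)
  if (nrow(df) > 0) {
    if (any(!df$strand %in% c("+", "-"))) {
      .stopf("strand must be '+' or '-'")
    }
    if (any(df$start >= df$end)) {
      bad <- which(df$start >= df$end)[1]
      .stopf("gene '%s' has start >= end", df$gene_id[bad])
    }
    dup <- df$gene_id[duplicated(df$gene_id)]
    if (length(dup) > 0) {
      .stopf("duplicate gene_id(s): %s", paste(unique(dup), collapse = ", "))
    }
  }
  rownames(df) <- NULL
  if (is.null(filter_log)) {
    filter_log <- data.frame(
      filter = character(), n_in = integer(), n_out = integer(),
      n_removed = integer(), stringsAsFactors = FALSE
    )
  }
  structure(df, provenance = provenance, filter_log = filter_log,
            class = c("gene_set", "data.frame"))
}

.log_filter <- function(genes, out_df, label) {
  log <- attr(genes, "filter_log")
  log <- rbind(log, data.frame(
    filter = label, n_in = nrow(genes), n_out = nrow(out_df),
    n_removed = nrow(genes) - nrow(out_df), stringsAsFactors = FALSE
  ))
  gene_set(out_df, provenance = c(attr(genes, "provenance"), label),
           filter_log = log)
}

#' Report the filters applied to a gene set
#'
#' @param genes a `gene_set`.
#' @return data.frame with one row per applied filter: name, genes in,
#'   genes out, genes removed.
#' @export
filter_report <- function(genes) {
  stopifnot(inherits(genes, "gene_set"))
  attr(genes, "filter_log")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set with %d genes\n", nrow(x)))
  prov <- attr(x, "provenance")
  if (length(prov) > 0) cat("provenance:", paste(prov, collapse = " -> "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Load gene models from a BED file
#'
#' Reads BED6 or BED12; BED12 records are reduced to their outer transcript
#' span (exon structure is ignored, since all downstream statistics are
#' span-based). Coordinates stay 0-based half-open.
#'
#' @param path BED file path.
#' @param format `"auto"` (detect from column count), `"BED6"` or `"BED12"`.
#' @return A `gene_set`, records in file order.
#' @export
load_gene_models <- function(path, format = c("auto", "BED6", "BED12")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(gene_set(data.frame(chrom = character(), start = integer(),
                               end = integer(), gene_id = character(),
                               strand = character()),
                    provenance = sprintf("loaded 0 genes from %s", basename(path))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  want <- switch(format, auto = NA, BED6 = 6L, BED12 = 12L)
  if (is.na(want)) want <- if (nf[1] >= 12L) 12L else 6L
  bad <- which(nf < want)
  if (length(bad) > 0) {
    .stopf("malformed BED line %d: expected >= %d fields, got %d",
           lineno[bad[1]], want, nf[bad[1]])
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    .stopf("malformed BED line %d: non-numeric coordinates", lineno[bad[1]])
  }
  strand <- get(6)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0) {
    .stopf("malformed BED line %d: strand must be '+' or '-'", lineno[bad[1]])
  }
  df <- data.frame(chrom = get(1), start = start, end = end,
                   gene_id = get(4), score = suppressWarnings(as.numeric(get(5))),
                   strand = strand, stringsAsFactors = FALSE)
  gene_set(df, provenance = sprintf("loaded %d genes from %s", nrow(df),
                                    basename(path)))
}

#' Write a gene set as BED6
#'
#' @param genes a `gene_set`.
#' @param path output path.
#' @export
write_bed6 <- function(genes, path) {
  stopifnot(inherits(genes, "gene_set"))
  df <- as.data.frame(genes)[, c("chrom", "start", "end", "gene_id", "score",
                                 "strand")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a per-gene expression table
#'
#' Expects a TSV with header `gene_id<TAB>fpkm`.
#'
#' @param path TSV path.
#' @return Named numeric vector of FPKM values.
#' @export
read_fpkm_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "fpkm") %in% names(df))) {
    .stopf("expression table must have columns 'gene_id' and 'fpkm'")
  }
  if (any(!is.finite(df$fpkm)) || any(df$fpkm < 0)) {
    .stopf("FPKM values must be finite and non-negative")
  }
  stats::setNames(df$fpkm, df$gene_id)
}

#' Keep genes expressed above an FPKM cutoff
#'
#' Retains genes with FPKM strictly greater than `min_fpkm` (the comparison
#' is strict by design). Genes absent from the expression table are dropped
#' and counted separately in the filter log.
#'
#' @param genes a `gene_set`.
#' @param expr named numeric vector, gene_id -> FPKM.
#' @param min_fpkm expression cutoff (default 5).
#' @return Filtered `gene_set`.
#' @export
filter_expressed <- function(genes, expr, min_fpkm = 5) {
  stopifnot(inherits(genes, "gene_set"), min_fpkm >= 0)
  vals <- expr[genes$gene_id]
  absent <- is.na(vals)
  keep <- !absent & vals > min_fpkm
  out <- .log_filter(genes, as.data.frame(genes)[keep, , drop = FALSE],
                     sprintf("expressed: FPKM > %g (%d absent from table dropped)",
                             min_fpkm, sum(absent)))
  out
}

#' Keep genes with no neighbouring transcript within a flank
#'
#' A gene survives iff no other gene (from `conflict_set`, by default the
#' input set itself) intersects the window `[start - flank, end + flank)` on
#' the same chromosome. The check is strand-blind and symmetric: both members
#' of a conflicting pair are removed.
#'
#' @param genes a `gene_set`.
#' @param flank flank width in bases (default 5000).
#' @param conflict_set optional `gene_set` of transcripts to test against
#'   (e.g. the full annotation rather than the expressed subset).
#' @return Filtered `gene_set`.
#' @export
filter_nonoverlapping <- function(genes, flank = 5000, conflict_set = NULL) {
  stopifnot(inherits(genes, "gene_set"), flank >= 0)
  conf <- if (is.null(conflict_set)) genes else conflict_set
  n <- nrow(genes)
  has_conflict <- logical(n)
  if (n > 0 && nrow(conf) > 0) {
    for (cn in unique(genes$chrom)) {
      gi <- which(genes$chrom == cn)
      ci <- which(conf$chrom == cn)
      if (length(ci) == 0) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(genes$start[gi] - flank + 1L, genes$end[gi] + flank),
        IRanges::IRanges(conf$start[ci] + 1L, conf$end[ci])
      )
      qh <- gi[S4Vectors::queryHits(hits)]
      sh <- ci[S4Vectors::subjectHits(hits)]
      self <- genes$gene_id[qh] == conf$gene_id[sh]
      has_conflict[unique(qh[!self])] <- TRUE
    }
  }
  label <- sprintf("nonoverlapping: flank %d bp%s", flank,
                   if (is.null(conflict_set)) "" else " (external conflict set)")
  .log_filter(genes, as.data.frame(genes)[!has_conflict, , drop = FALSE], label)
}

#' Keep genes longer than a minimum length
#'
#' Retains genes with `end - start` strictly greater than `min_len`.
#'
#' @param genes a `gene_set`.
#' @param min_len minimum length in bases (default 300).
#' @return Filtered `gene_set`.
#' @export
filter_min_length <- function(genes, min_len = 300) {
  stopifnot(inherits(genes, "gene_set"), min_len >= 0)
  keep <- (genes$end - genes$start) > min_len
  .log_filter(genes, as.data.frame(genes)[keep, , drop = FALSE],
              sprintf("min_length: > %d bp", min_len))
}
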