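#' Subtype-specific CNA association screen
#'
#' For every gene, builds the 2x2 table (event / no event) x (target /
#' comparator subtype group), computes the two-sided Fisher exact p-value,
#' and applies Benjamini-Hochberg correction over all tested genes.  A gene
#' with zero events in both groups contributes p = 1 and stays in the FDR
#' denominator.  The significance flag marks genes with `q < fdr`, event
#' frequency in the target group `>= min_freq`, and odds ratio `> 1`.
#'
#' @param cna A `gene_cna_matrix` (character states genes x samples).
#' @param labels Named subtype vector (names = sample ids) or a vector
#'   aligned with `colnames(cna)`.
#' @param target Target subtype (e.g. `"lumB"`).
#' @param comparator Character vector of comparator subtypes, or `"rest"`
#'   for all non-target tumor subtypes.
#' @param event Event definition: `"gain_or_amp"`, `"amp_only"`,
#'   `"any_loss"` or `"homo_only"`.
#' @param min_freq Minimum event frequency in the target group (default
#'   0.30).
#' @param fdr FDR threshold for the significance flag (default 0.05).
#' @return Data frame (one row per gene): `gene`, `event`, `n_target`,
#'   `n_comparator`, `freq_target`, `freq_rest`, `odds_ratio`, `p`, `q`,
#'   `significant`.
#' @examples
#' # the 2x2 arithmetic: 21/32 vs 31/156 carriers
#' fisher.test(matrix(c(21, 11, 31, 125), 2, 2))$p.value
#' @export
subtype_cna_association <- function(cna, labels, target, comparator = "rest",
                                    event = "gain_or_amp", min_freq = 0.30,
                                    fdr = 0.05) {
  labels <- align_labels(labels, colnames(cna))
  if (identical(comparator, "rest")) {
    comparator <- setdiff(unique(labels[!is.na(labels)]), target)
  }
  tgt <- which(labels == target)
  cmp <- which(labels %in% comparator)
  if (!length(tgt) || !length(cmp)) {
    cd_stop("target and comparator groups must be non-empty")
  }
  if (length(intersect(tgt, cmp))) {
    cd_stop("target and comparator groups must be disjoint")
  }
  ev <- match_event(cna, event)
  dim(ev) <- dim(cna)
  a <- rowSums(ev[, tgt, drop = FALSE])
  c_ <- rowSums(ev[, cmp, drop = FALSE])
  n_t <- length(tgt); n_c <- length(cmp)
  p <- vapply(seq_len(nrow(cna)), function(i) {
    if (a[i] + c_[i] == 0) return(1)
    stats::fisher.test(matrix(c(a[i], n_t - a[i], c_[i], n_c - c_[i]),
                              2, 2))$p.value
  }, numeric(1))
  or <- vapply(seq_len(nrow(cna)), function(i)
    sample_odds_ratio(a[i], n_t - a[i], c_[i], n_c - c_[i]), numeric(1))
  q <- p.adjust(p, method = "BH")
  res <- data.frame(gene = rownames(cna), event = event,
                    n_target = n_t, n_comparator = n_c,
                    freq_target = a / n_t, freq_rest = c_ / n_c,
                    odds_ratio = or, p = p, q = q,
                    significant = q < fdr & (a / n_t) >= min_freq & or > 1,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

align_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels))) {
    miss <- setdiff(sample_ids, names(labels))
    if (length(miss)) {
      cd_stop("samples missing from labels: ", paste(miss, collapse = ", "))
    }
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    cd_stop("labels length does not match number of samples")
  }
  unname(labels)
}

#' Merge significant genes into genomic regions
#'
#' Significant genes of the same event type are merged into one region when
#' the gap between consecutive gene intervals is at most `gap_tolerance`.
#' Region boundaries are the min start / max end of the member genes; the
#' peak q is the smallest member q.
#'
#' @param results Output of [subtype_cna_association()] (or a subset).
#' @param genes Gene annotation data frame (`gene`, `chrom`, `start`, `end`).
#' @param gap_tolerance Maximum gap in bp between member genes (default
#'   1 Mb).
#' @param only_significant Restrict to rows flagged significant (default
#'   TRUE).
#' @return Data frame: `chrom`, `start`, `end`, `event`, `n_genes`,
#'   `genes` (comma-joined), `peak_q`.
#' @export
aggregate_regions <- function(results, genes, gap_tolerance = 1e6,
                              only_significant = TRUE) {
  if (only_significant) results <- results[results$significant, , drop = FALSE]
  if (!nrow(results)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), event = character(),
                      n_genes = integer(), genes = character(),
                      peak_q = numeric(), stringsAsFactors = FALSE))
  }
  gi <- match(results$gene, genes$gene)
  if (anyNA(gi)) cd_stop("results carry genes absent from annotation")
  df <- data.frame(gene = results$gene, event = results$event,
                   chrom = genes$chrom[gi], start = genes$start[gi],
                   end = genes$end[gi], q = results$q,
                   stringsAsFactors = FALSE)
  df <- df[order(df$event, df$chrom, df$start), ]
  out <- list()
  for (key in unique(paste(df$event, df$chrom))) {
    sub <- df[paste(df$event, df$chrom) == key, , drop = FALSE]
    cur_start <- sub$start[1]; cur_end <- sub$end[1]
    members <- sub$gene[1]; qs <- sub$q[1]
    flush <- function() {
      out[[length(out) + 1L]] <<- data.frame(
        chrom = sub$chrom[1], start = cur_start, end = cur_end,
        event = sub$event[1], n_genes = length(members),
        genes = paste(members, collapse = ","), peak_q = min(qs),
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] - cur_end <= gap_tolerance) {
        cur_end <- max(cur_end, sub$end[i])
        members <- c(members, sub$gene[i]); qs <- c(qs, sub$q[i])
      } else {
        flush()
        cur_start <- sub$start[i]; cur_end <- sub$end[i]
        members <- sub$gene[i]; qs <- sub$q[i]
      }
    }
    flush()
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$event), ]
  rownames(res) <- NULL
  res
}
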