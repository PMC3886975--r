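#' Filter genes by expression level
#'
#' Keeps a gene iff its log2 expression is `>= min_level` in at least
#' `min_fraction` of samples (both comparisons inclusive).  By default the
#' level cutoff is the cohort's 25th-percentile signal and the fraction is
#' 0.25.
#'
#' @param expr Genes x samples log2 expression matrix.
#' @param min_level Minimum expression level; `NULL` uses the cohort 25th
#'   percentile.
#' @param min_fraction Minimum fraction of samples at or above `min_level`.
#' @return Character vector of retained gene ids (warns when empty).
#' @export
filter_expressed <- function(expr, min_level = NULL, min_fraction = 0.25) {
  if (min_fraction <= 0 || min_fraction > 1) {
    cd_stop("min_fraction must be in (0, 1]")
  }
  if (is.null(min_level)) min_level <- quantile(expr, 0.25, names = FALSE)
  frac <- rowMeans(expr >= min_level)
  keep <- rownames(expr)[frac >= min_fraction]
  if (!length(keep)) warning("expression filter retained no genes",
                             call. = FALSE)
  keep
}

#' Copy-number dosage association (Mann-Whitney)
#'
#' Per gene, compares log2 expression between samples carrying the CNA
#' event and samples not carrying it (pooled across the supplied sample
#' set) with a two-sided Mann-Whitney (Wilcoxon rank-sum) test.  Genes with
#' fewer than 3 samples in either group are skipped and excluded from the
#' BH denominator (the count is logged).  Exact enumeration is used when
#' both groups have at most 8 samples and no ties; otherwise the normal
#' approximation with tie correction.  Constant expression gives p = 1.
#'
#' @param expr Genes x samples log2 expression matrix.
#' @param cna `gene_cna_matrix` sharing gene and sample ids with `expr`.
#' @param samples Sample ids to pool (typically target + comparator group).
#' @param event Event definition as in [subtype_cna_association()].
#' @param genes Optional gene universe (default: rows shared by both
#'   matrices).
#' @return Data frame: `gene`, `n_event`, `n_noevent`, `statistic` (U for
#'   the event group), `direction` (`"up"`/`"down"`), `p`, `q`.  Skipped
#'   genes are absent.
#' @export
dosage_association <- function(expr, cna, samples, event = "gain_or_amp",
                               genes = NULL) {
  if (is.null(genes)) genes <- intersect(rownames(expr), rownames(cna))
  samples <- intersect(samples, intersect(colnames(expr), colnames(cna)))
  if (!length(samples)) cd_stop("no shared samples")
  rows <- vector("list", length(genes))
  n_skipped <- 0L
  for (i in seq_along(genes)) {
    g <- genes[i]
    has_ev <- match_event(cna[g, samples], event)
    x <- expr[g, samples][has_ev]    # event group
    y <- expr[g, samples][!has_ev]
    if (length(x) < 3 || length(y) < 3) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (stats::sd(c(x, y)) == 0) {
      u <- length(x) * length(y) / 2; pv <- 1
    } else {
      exact <- length(x) <= 8 && length(y) <= 8 &&
        !any(duplicated(c(x, y)))
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                                correct = !exact))
      u <- unname(wt$statistic); pv <- wt$p.value
    }
    rows[[i]] <- data.frame(
      gene = g, n_event = length(x), n_noevent = length(y),
      statistic = u,
      direction = if (median(x) >= median(y)) "up" else "down",
      p = pv, stringsAsFactors = FALSE)
  }
  if (n_skipped > 0) {
    cd_log("dosage_association: skipped ", n_skipped,
           " genes with < 3 samples in a group (excluded from FDR)")
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(gene = character(), n_event = integer(),
                      n_noevent = integer(), statistic = numeric(),
                      direction = character(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  res$q <- p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Subtype-specific expression deregulation (Welch t)
#'
#' Per gene, a two-sided Welch (unequal-variance) t-test of log2 expression
#' in the target subtype against the comparator group, with BH correction
#' over the supplied gene universe.  Two constant equal groups give p = 1.
#'
#' @param expr Genes x samples log2 expression matrix.
#' @param labels Subtype labels (named by sample or aligned to columns).
#' @param target Target subtype.
#' @param comparator Comparator subtypes, or `"rest"`.
#' @param genes Optional gene universe (default: all rows); BH runs within
#'   it, so pass the previous step's pass set for a stepwise screen.
#' @return Data frame: `gene`, `t`, `direction` (`"up"` = higher in
#'   target), `delta` (mean difference), `p`, `q`.
#' @export
subtype_deregulation <- function(expr, labels, target = "lumB",
                                 comparator = "rest", genes = NULL) {
  labels <- align_labels(labels, colnames(expr))
  if (identical(comparator, "rest")) {
    comparator <- setdiff(unique(labels[!is.na(labels)]), target)
  }
  tgt <- which(labels == target)
  cmp <- which(labels %in% comparator)
  if (length(tgt) < 3 || length(cmp) < 3) {
    cd_stop("both groups need >= 3 samples")
  }
  if (is.null(genes)) genes <- rownames(expr)
  res <- do.call(rbind, lapply(genes, function(g) {
    w <- safe_welch(expr[g, tgt], expr[g, cmp])
    data.frame(gene = g, t = w$statistic,
               direction = if (w$diff >= 0) "up" else "down",
               delta = w$diff, p = w$p.value, stringsAsFactors = FALSE)
  }))
  res$q <- p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Nominate candidate oncogenes and tumor suppressor genes
#'
#' Combines the three screens: a gene is a candidate iff it (1) passed the
#' expression filter, (2) has dosage q < `fdr` (expression tracks copy
#' number), (3) has subtype q < `fdr`, (4) carries a subtype-associated CNA
#' event, and (5) all directions are concordant: gain/amplification with
#' expression up yields an oncogene, loss with expression down a tumor
#' suppressor.  Genes failing only the concordance rule are returned in the
#' `rejected` attribute with reason code `"discordant"`.
#'
#' @param expressed Character vector from [filter_expressed()].
#' @param dosage Data frame from [dosage_association()].
#' @param subtype Data frame from [subtype_deregulation()].
#' @param cna_assoc Data frame from [subtype_cna_association()].
#' @param target Target subtype recorded on each candidate.
#' @param comparator Comparator description recorded on each candidate.
#' @param fdr FDR threshold applied to the dosage and subtype q-values.
#' @return A `candidate_set`: data frame with one row per candidate
#'   (`gene`, `class`, `subtype`, `comparator`, `event`, `freq_target`,
#'   `cna_q`, `dosage_stat`, `dosage_p`, `dosage_q`, `t`, `subtype_p`,
#'   `subtype_q`, `direction`), with rejected-but-otherwise-passing genes
#'   in `attr(, "rejected")`.
#' @export
nominate_candidates <- function(expressed, dosage, subtype, cna_assoc,
                                target = "lumB", comparator = "rest",
                                fdr = 0.05) {
  sig_cna <- cna_assoc[cna_assoc$significant, , drop = FALSE]
  pool <- Reduce(intersect, list(expressed, dosage$gene, subtype$gene,
                                 sig_cna$gene))
  rows <- list(); rej <- list()
  for (g in pool) {
    d <- dosage[dosage$gene == g, ][1, ]
    s <- subtype[subtype$gene == g, ][1, ]
    cn <- sig_cna[sig_cna$gene == g, ][1, ]
    if (d$q >= fdr || s$q >= fdr) next
    sign_ev <- event_sign(cn$event)
    dir_ok <- (sign_ev > 0 && d$direction == "up" && s$direction == "up") ||
              (sign_ev < 0 && d$direction == "down" && s$direction == "down")
    if (!dir_ok) {
      rej[[length(rej) + 1L]] <- data.frame(gene = g, reason = "discordant",
                                            stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, class = if (sign_ev > 0) "oncogene" else "TSG",
      subtype = target,
      comparator = paste(comparator, collapse = "+"),
      event = cn$event, freq_target = cn$freq_target, cna_q = cn$q,
      dosage_stat = d$statistic, dosage_p = d$p, dosage_q = d$q,
      t = s$t, subtype_p = s$p, subtype_q = s$q,
      direction = s$direction, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), class = character(), subtype = character(),
               comparator = character(), event = character(),
               freq_target = numeric(), cna_q = numeric(),
               dosage_stat = numeric(), dosage_p = numeric(),
               dosage_q = numeric(), t = numeric(), subtype_p = numeric(),
               subtype_q = numeric(), direction = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- if (length(rej)) do.call(rbind, rej) else
    data.frame(gene = character(), reason = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("candidate_set", class(out))
  out
}

#' Run the full stepwise CNA-expression integration for one comparison
#'
#' Orchestrates the three successive screens with stepwise BH denominators,
#' mirroring how such integrative analyses restrict each test to the
#' previous step's survivors: the CNA association screen runs genome-wide;
#' the dosage Mann-Whitney runs (and is BH-corrected) within the
#' CNA-associated, expressed genes; the subtype Welch t runs within the
#' dosage survivors.  Gain/amplification and loss events are screened
#' separately and pooled.
#'
#' @param cohort An `omics_cohort` with expression and annotation.
#' @param cna A `gene_cna_matrix`.
#' @param target Target subtype.
#' @param comparator Comparator subtypes or `"rest"`.
#' @param events CNA event definitions to screen (default gain_or_amp and
#'   any_loss).
#' @param min_freq,fdr Thresholds of the CNA screen and both FDR gates.
#' @param min_level,min_fraction Expression filter parameters.
#' @return A `candidate_set` (see [nominate_candidates()]).
#' @export
run_integration <- function(cohort, cna, target = "lumB",
                            comparator = "rest",
                            events = c("gain_or_amp", "any_loss"),
                            min_freq = 0.30, fdr = 0.05,
                            min_level = NULL, min_fraction = 0.25) {
  expr <- cohort$expression
  labels <- setNames(cohort$annotation$subtype, cohort$annotation$sample)
  labels <- labels[colnames(expr)]
  if (identical(comparator, "rest")) {
    comparator <- setdiff(unique(labels[!is.na(labels)]), target)
  }
  samples <- colnames(expr)[labels %in% c(target, comparator)]
  expressed <- filter_expressed(expr, min_level, min_fraction)

  parts <- lapply(events, function(ev) {
    assoc <- subtype_cna_association(cna, labels, target, comparator,
                                     event = ev, min_freq = min_freq,
                                     fdr = fdr)
    step1 <- intersect(expressed, assoc$gene[assoc$significant])
    if (!length(step1)) return(NULL)
    dos <- dosage_association(expr, cna, samples, event = ev, genes = step1)
    step2 <- dos$gene[dos$q < fdr]
    if (!length(step2)) return(NULL)
    der <- subtype_deregulation(expr, labels, target, comparator,
                                genes = step2)
    nominate_candidates(expressed, dos, der, assoc, target, comparator, fdr)
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  out <- if (length(parts)) do.call(rbind, lapply(parts, as.data.frame)) else
    nominate_candidates(character(), data.frame(gene = character()),
                        data.frame(gene = character()),
                        data.frame(gene = character(),
                                   significant = logical()),
                        target, comparator, fdr)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_set", class(out))
  out
}

#' Intersect candidate lists from two comparisons
#'
#' Returns genes present in both lists with the same class, in stable
#' gene-id order; statistics are carried from the first list.
#'
#' @param a,b `candidate_set` data frames from the same run.
#' @return A `candidate_set` restricted to the common core.
#' @export
core_candidates <- function(a, b) {
  key_a <- paste(a$gene, a$class)
  key_b <- paste(b$gene, b$class)
  out <- a[key_a %in% key_b, , drop = FALSE]
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set:", nrow(x), "candidates (",
      sum(x$class == "oncogene"), "oncogenes,",
      sum(x$class == "TSG"), "TSGs )\n")
  if (nrow(x)) print(as.data.frame(
    x[, c("gene", "class", "event", "freq_target", "dosage_q",
          "subtype_q", "direction")]), ...)
  invisible(x)
}
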