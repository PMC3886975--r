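#' Normalize promoter-array M-values (GC then quantile)
#'
#' Two-step normalization of probe-level M-values (M = log2 red - log2
#' green): (1) within each sample, the median M of each GC bin (equal-width
#' bins over the probes' GC range) is subtracted, removing GC-dependent
#' signal; bins with fewer than 10 probes are merged into their nearest
#' neighbor (logged); (2) inter-array quantile normalization: each sample's
#' sorted values are replaced by the rank-wise mean profile across samples,
#' making all per-sample distributions identical.
#'
#' @param m Probes x samples M-value matrix.
#' @param gc GC fraction per probe (aligned with rows), in `[0, 1]`.
#' @param gc_bins Number of equal-width GC bins (default 20).
#' @return Normalized matrix of the same shape.
#' @export
normalize_m <- function(m, gc, gc_bins = 20) {
  if (gc_bins < 1) cd_stop("gc_bins must be >= 1")
  if (length(gc) != nrow(m)) cd_stop("gc must have one value per probe")
  if (any(gc < 0 | gc > 1)) cd_stop("GC fractions must lie in [0, 1]")

  # equal-width bins over the observed GC range
  rng <- range(gc)
  breaks <- if (diff(rng) == 0) c(rng[1] - .5, rng[1] + .5) else
    seq(rng[1], rng[2], length.out = gc_bins + 1)
  bin <- findInterval(gc, breaks, rightmost.closed = TRUE, all.inside = TRUE)

  # merge sparse bins (< 10 probes) into their nearest occupied neighbor
  repeat {
    tab <- table(factor(bin, levels = sort(unique(bin))))
    small <- as.integer(names(tab))[tab < 10]
    if (!length(small) || length(tab) == 1) break
    b <- small[1]
    others <- setdiff(as.integer(names(tab)), b)
    nb <- others[which.min(abs(others - b))]
    cd_log("normalize_m: merging GC bin ", b, " (", tab[as.character(b)],
           " probes) into bin ", nb)
    bin[bin == b] <- nb
  }

  centered <- m
  for (b in unique(bin)) {
    ix <- bin == b
    med <- apply(m[ix, , drop = FALSE], 2, median)
    centered[ix, ] <- sweep(m[ix, , drop = FALSE], 2, med)
  }

  quantile_normalize(centered)
}

# rank-wise mean quantile normalization; ties share the mean reference
# value of their rank range
quantile_normalize <- function(m) {
  if (ncol(m) < 2) return(m)
  sorted <- apply(m, 2, sort)
  ref <- rowMeans(sorted)
  out <- apply(m, 2, function(col) ref[rank(col, ties.method = "average")])
  dimnames(out) <- dimnames(m)
  out
}

#' Promoter methylation score
#'
#' Summarizes a promoter's probe M-values into one score per sample as the
#' frequency-weighted amplitude of methylated and unmethylated probes:
#' \deqn{s = f_+ \bar{M}_+ + f_- \bar{M}_-,}
#' where `f+` (`f-`) is the fraction of the promoter's probes with M > 0
#' (M < 0) and `M̄+` (`M̄-`) their mean amplitude.  Probes with M exactly 0
#' count in neither fraction but stay in the denominator.  The score always
#' lies between the min and max probe M-value; algebraically the formula
#' reduces to the plain probe mean, and is implemented as written.  An
#' optional trimmed variant averages only the `trim_k` probes of largest
#' absolute M-value.
#'
#' @param m Probes x samples M-value matrix (typically normalized).
#' @param map Probe-to-promoter map: data frame with `probe`, `gene`.
#' @param genes Gene ids to score (default: all mapped genes).
#' @param method `"freq_amplitude"` (default) or `"trimmed"`.
#' @param trim_k Number of top-|M| probes in the trimmed variant.
#' @return Genes x samples score matrix; genes with no mapped probe are
#'   dropped (logged).
#' @export
promoter_score <- function(m, map, genes = NULL,
                           method = c("freq_amplitude", "trimmed"),
                           trim_k = 4) {
  method <- match.arg(method)
  if (is.null(genes)) genes <- unique(map$gene)
  miss <- !genes %in% map$gene
  if (any(miss)) {
    cd_log("promoter_score: ", sum(miss), " genes with no mapped probes ",
           "excluded")
    genes <- genes[!miss]
  }
  probe_rows <- split(match(map$probe, rownames(m)), map$gene)
  out <- matrix(NA_real_, length(genes), ncol(m),
                dimnames = list(genes, colnames(m)))
  for (g in genes) {
    ix <- probe_rows[[g]]
    ix <- ix[!is.na(ix)]
    if (!length(ix)) next
    sub <- m[ix, , drop = FALSE]
    if (method == "freq_amplitude") {
      n <- nrow(sub)
      f_pos <- colSums(sub > 0) / n
      f_neg <- colSums(sub < 0) / n
      mean_pos <- apply(sub, 2, function(v)
        if (any(v > 0)) mean(v[v > 0]) else 0)
      mean_neg <- apply(sub, 2, function(v)
        if (any(v < 0)) mean(v[v < 0]) else 0)
      out[g, ] <- f_pos * mean_pos + f_neg * mean_neg
    } else {
      out[g, ] <- apply(sub, 2, function(v) {
        k <- min(trim_k, length(v))
        mean(v[order(abs(v), decreasing = TRUE)[seq_len(k)]])
      })
    }
  }
  out[!apply(out, 1, anyNA), , drop = FALSE]
}

#' Select promoters with variable methylation scores
#'
#' @param scores Genes x samples score matrix.
#' @param sd_min Keep genes with across-sample standard deviation strictly
#'   greater than this (default 0.3).
#' @return Character vector of gene ids.
#' @export
select_variable_promoters <- function(scores, sd_min = 0.3) {
  if (ncol(scores) < 2) cd_stop("need >= 2 samples")
  sds <- apply(scores, 1, sd)
  rownames(scores)[sds > sd_min]
}

#' Hierarchical clustering of samples on methylation scores
#'
#' Distance = 1 - Pearson correlation between sample score vectors;
#' average-linkage agglomeration.  Deterministic for fixed input.
#'
#' @param scores Genes x samples score matrix (restricted to variable
#'   promoters upstream).
#' @param k Optional number of flat clusters to cut.
#' @return A list with `hclust` (the tree) and, when `k` is given,
#'   `clusters` (named integer vector).
#' @export
cluster_samples <- function(scores, k = NULL) {
  if (ncol(scores) < 3) cd_stop("need >= 3 samples")
  sds <- apply(scores, 2, sd)
  if (any(sds == 0)) {
    cd_stop("zero-variance sample vector(s): ",
            paste(colnames(scores)[sds == 0], collapse = ", "))
  }
  d <- as.dist(1 - cor(scores))
  hc <- hclust(d, method = "average")
  out <- list(hclust = hc)
  if (!is.null(k)) out$clusters <- cutree(hc, k = k)
  out
}

#' Supervised methylation comparison between ER groups
#'
#' Two-sided Welch t-test per gene promoter on methylation scores between
#' ER-positive and ER-negative tumors, BH-corrected.
#'
#' @param scores Genes x samples score matrix.
#' @param er ER status per sample (`"+"` / `"-"`), named or aligned.
#' @return Data frame: `gene`, `t`, `p`, `q`, `higher_in` (`"ER+"` or
#'   `"ER-"`).
#' @export
er_supervised_test <- function(scores, er) {
  er <- align_labels(er, colnames(scores))
  pos <- which(er == "+"); neg <- which(er == "-")
  if (length(pos) < 3 || length(neg) < 3) {
    cd_stop("both ER groups need >= 3 samples")
  }
  res <- do.call(rbind, lapply(rownames(scores), function(g) {
    w <- safe_welch(scores[g, pos], scores[g, neg])
    data.frame(gene = g, t = w$statistic, p = w$p.value,
               higher_in = if (w$diff >= 0) "ER+" else "ER-",
               stringsAsFactors = FALSE)
  }))
  res$q <- p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res[, c("gene", "t", "p", "q", "higher_in")]
}

#' Subtype-specific promoter methylation calls
#'
#' Three-stage screen for promoters whose methylation deviates in exactly
#' one intrinsic subtype: (1) one-way ANOVA across the five subtypes with
#' BH q < `fdr`; (2) Tukey HSD on the ANOVA survivors — a gene is specific
#' for subtype S iff all four pairwise comparisons involving S are
#' significant (adjusted p <= `tukey_alpha`) with a consistent sign, and no
#' other subtype satisfies the same rule; (3) each call is flagged against
#' normal-breast references by a Welch t-test, BH-corrected across calls
#' (skipped with a warning when no references are supplied).
#'
#' @param scores Genes x samples score matrix (tumors).
#' @param labels Subtype labels (named or aligned); all five subtypes need
#'   >= 3 samples.
#' @param normal_scores Optional genes x samples matrix of normal-breast
#'   references.
#' @param fdr ANOVA BH threshold (default 0.05).
#' @param tukey_alpha Tukey adjusted-p threshold (default 0.05).
#' @return Data frame of calls: `gene`, `subtype`, `direction`
#'   (`"hyper"`/`"hypo"` relative to the other subtypes), `anova_p`,
#'   `anova_q`, `max_pair_p`, and when references are present `vs_normal_t`,
#'   `vs_normal_p`, `vs_normal_q`, `vs_normal_significant`.
#' @export
subtype_specificity <- function(scores, labels, normal_scores = NULL,
                                fdr = 0.05, tukey_alpha = 0.05) {
  labels <- align_labels(labels, colnames(scores))
  tab <- table(labels)
  if (length(tab) < 5 || any(tab < 3)) {
    cd_stop("all five subtypes need >= 3 samples")
  }
  fac <- factor(labels)

  anova_p <- vapply(seq_len(nrow(scores)), function(i) {
    y <- scores[i, ]
    if (sd(y) == 0) return(1)
    stats::oneway.test(y ~ fac, var.equal = TRUE)$p.value
  }, numeric(1))
  anova_q <- p.adjust(anova_p, method = "BH")
  pass <- which(anova_q < fdr)

  calls <- list()
  lv <- levels(fac)
  for (i in pass) {
    y <- scores[i, ]
    tk <- TukeyHSD(aov(y ~ fac))$fac
    pairs <- rownames(tk)
    hit_subtype <- NULL; hit_dir <- NULL; hit_maxp <- NULL
    for (s in lv) {
      inv <- grepl(paste0("(^|-)", s, "(-|$)"), pairs)
      if (sum(inv) != length(lv) - 1) next
      sig <- tk[inv, "p adj"] <= tukey_alpha
      if (!all(sig)) next
      # sign of (S - other) for each pair involving S
      signs <- ifelse(startsWith(pairs[inv], paste0(s, "-")),
                      sign(tk[inv, "diff"]), -sign(tk[inv, "diff"]))
      if (length(unique(signs)) != 1) next
      if (!is.null(hit_subtype)) { hit_subtype <- "ambiguous"; break }
      hit_subtype <- s
      hit_dir <- if (signs[1] > 0) "hyper" else "hypo"
      hit_maxp <- max(tk[inv, "p adj"])
    }
    if (is.null(hit_subtype) || hit_subtype == "ambiguous") next
    calls[[length(calls) + 1L]] <- data.frame(
      gene = rownames(scores)[i], subtype = hit_subtype,
      direction = hit_dir, anova_p = anova_p[i], anova_q = anova_q[i],
      max_pair_p = hit_maxp, stringsAsFactors = FALSE)
  }
  res <- if (length(calls)) do.call(rbind, calls) else
    data.frame(gene = character(), subtype = character(),
               direction = character(), anova_p = numeric(),
               anova_q = numeric(), max_pair_p = numeric(),
               stringsAsFactors = FALSE)

  if (is.null(normal_scores)) {
    if (nrow(res)) warning("no normal references; vs-normal stage skipped",
                           call. = FALSE)
    return(res)
  }
  if (nrow(res)) {
    vs <- do.call(rbind, lapply(seq_len(nrow(res)), function(j) {
      g <- res$gene[j]
      sub_samp <- labels == res$subtype[j]
      if (!g %in% rownames(normal_scores)) {
        return(data.frame(vs_normal_t = NA_real_, vs_normal_p = NA_real_))
      }
      w <- safe_welch(scores[g, sub_samp], normal_scores[g, ])
      data.frame(vs_normal_t = w$statistic, vs_normal_p = w$p.value)
    }))
    res <- cbind(res, vs)
    res$vs_normal_q <- p.adjust(res$vs_normal_p, method = "BH")
    res$vs_normal_significant <- !is.na(res$vs_normal_q) &
      res$vs_normal_q < fdr
  }
  rownames(res) <- NULL
  res
}

#' Link promoter methylation to expression
#'
#' Per gene, the Pearson correlation between the methylation score and log2
#' expression across shared samples; genes with correlation strictly below
#' `threshold` (default -0.40) are reported.  Constant vectors are skipped
#' (logged).
#'
#' @param scores Genes x samples methylation score matrix.
#' @param expr Genes x samples log2 expression matrix.
#' @param threshold Correlation cutoff (strict `<`; default -0.40).
#' @param samples Optional sample subset (default: all shared samples).
#' @return Data frame: `gene`, `r`, `n`, `kept`.
#' @export
methylation_expression_link <- function(scores, expr, threshold = -0.40,
                                        samples = NULL) {
  shared <- intersect(colnames(scores), colnames(expr))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  if (length(shared) < 5) cd_stop("need >= 5 shared samples")
  genes <- intersect(rownames(scores), rownames(expr))
  n_skip <- 0L
  rows <- lapply(genes, function(g) {
    x <- scores[g, shared]; y <- expr[g, shared]
    if (sd(x) == 0 || sd(y) == 0) {
      n_skip <<- n_skip + 1L
      return(NULL)
    }
    r <- cor(x, y)
    data.frame(gene = g, r = r, n = length(shared), kept = r < threshold,
               stringsAsFactors = FALSE)
  })
  if (n_skip > 0) cd_log("methylation_expression_link: skipped ", n_skip,
                         " genes with constant vectors")
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(gene = character(), r = numeric(), n = integer(),
                      kept = logical(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Joint copy-number / methylation deregulation
#'
#' Reports genes whose expression change is consistent with both evidence
#' chains: gain or amplification plus hypomethylation plus expression up
#' (class `"up"`), or loss plus hypermethylation plus expression down
#' (class `"down"`).
#'
#' @param candidates A `candidate_set` from the CNA-expression integration.
#' @param meth_calls Subtype-specificity calls ([subtype_specificity()]),
#'   restricted upstream to genes with a negative expression link.
#' @param target Subtype whose methylation calls are considered.
#' @return Data frame joining both chains: `gene`, `class`, `event`,
#'   `direction`, `meth_direction`, plus the candidate statistics.
#' @export
joint_cna_methylation <- function(candidates, meth_calls, target = "lumB") {
  mc <- meth_calls[meth_calls$subtype == target, , drop = FALSE]
  shared <- intersect(candidates$gene, mc$gene)
  rows <- lapply(shared, function(g) {
    cand <- candidates[candidates$gene == g, ][1, ]
    m <- mc[mc$gene == g, ][1, ]
    up_chain <- cand$class == "oncogene" && cand$direction == "up" &&
      m$direction == "hypo"
    down_chain <- cand$class == "TSG" && cand$direction == "down" &&
      m$direction == "hyper"
    if (!up_chain && !down_chain) return(NULL)
    data.frame(gene = g, class = if (up_chain) "up" else "down",
               event = cand$event, direction = cand$direction,
               meth_direction = m$direction,
               freq_target = cand$freq_target, dosage_q = cand$dosage_q,
               subtype_q = cand$subtype_q, anova_q = m$anova_q,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(gene = character(), class = character(),
                      event = character(), direction = character(),
                      meth_direction = character(), freq_target = numeric(),
                      dosage_q = numeric(), subtype_q = numeric(),
                      anova_q = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
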