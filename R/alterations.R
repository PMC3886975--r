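#' Subtype association screen for somatic mutations
#'
#' Applies the mutation-count filters, then per (gene, subtype) tests the
#' 2x2 table (mutated / wild-type) x (in subtype / other subtypes) with a
#' two-sided Fisher exact test, BH-corrected across all tested pairs.  A
#' gene-subtype pair is flagged associated iff `q < fdr` and odds
#' ratio > 1.
#'
#' @param m Binary genes x samples mutation matrix.
#' @param labels Subtype labels (named or aligned to columns).
#' @param min_total_mutations Keep genes with strictly more total mutations
#'   than this (default 5).
#' @param min_subtype_mutations Test a (gene, subtype) pair only when the
#'   gene has strictly more mutations than this inside the subtype
#'   (default 0).
#' @param fdr FDR threshold for the associated flag (default 0.25).
#' @return Data frame: `gene`, `subtype`, `n_mut_subtype`, `n_subtype`,
#'   `freq_subtype`, `freq_rest`, `odds_ratio`, `p`, `q`, `associated`.
#' @export
mutation_subtype_association <- function(m, labels, min_total_mutations = 5,
                                         min_subtype_mutations = 0,
                                         fdr = 0.25) {
  if (min_total_mutations < 0 || min_subtype_mutations < 0) {
    cd_stop("count thresholds must be >= 0")
  }
  labels <- align_labels(labels, colnames(m))
  if (anyNA(labels)) cd_stop("labels must cover all samples")
  subtypes <- unique(labels)
  for (s in subtypes) {
    if (!sum(labels == s)) cd_stop("subtype with zero samples: ", s)
  }
  tot <- rowSums(m)
  genes <- rownames(m)[tot > min_total_mutations]
  rows <- list()
  for (g in genes) {
    for (s in subtypes) {
      ins <- labels == s
      a <- sum(m[g, ins]); b <- sum(ins) - a
      c_ <- sum(m[g, !ins]); d <- sum(!ins) - c_
      if (a <= min_subtype_mutations) next
      ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, 2))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, subtype = s, n_mut_subtype = a, n_subtype = sum(ins),
        freq_subtype = a / sum(ins), freq_rest = c_ / sum(!ins),
        odds_ratio = sample_odds_ratio(a, b, c_, d),
        p = ft$p.value, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(gene = character(), subtype = character(),
                      n_mut_subtype = integer(), n_subtype = integer(),
                      freq_subtype = numeric(), freq_rest = numeric(),
                      odds_ratio = numeric(), p = numeric(), q = numeric(),
                      associated = logical(), stringsAsFactors = FALSE))
  }
  res$q <- p.adjust(res$p, method = "BH")
  res$associated <- res$q < fdr & res$odds_ratio > 1
  rownames(res) <- NULL
  res
}

#' Mutual-exclusivity / co-occurrence tests for alteration pairs
#'
#' Tests each candidate event pair against a margin-preserving null: the
#' binary alteration matrix is randomized by repeated 2x2 checkerboard
#' swaps (which preserve every row and column sum exactly), with burn-in
#' `10 x` the number of ones and the same number of swaps as thinning
#' between draws.  For each pair, the empirical one-sided p-values are
#' \deqn{p_{excl} = (1 + \#\{null \le obs\}) / (n + 1)} and the analogue
#' with `>=` for co-occurrence (the +1 pseudocount keeps p-values valid at
#' finite permutation counts).  BH runs within each direction.  A pair is
#' labelled `mutually_exclusive` or `co_occurring` when the corresponding
#' q (or raw p, see `label_by`) passes `threshold`; otherwise `neither`.
#'
#' When the margins admit no checkerboard swap the chain cannot move; if
#' the matrix has at most 20 ones the null is then computed by exact
#' enumeration of all margin-preserving matrices, otherwise an error is
#' raised.
#'
#' @param m Binary events x samples `AlterationMatrix` (see
#'   [build_cna_events()]); plain 0/1 matrices work too.
#' @param pairs Two-column matrix or data frame of event ids (or a list of
#'   length-2 vectors); default: all pairs of rows of `m`.
#' @param n_permutations Number of null draws (>= 1000).
#' @param seed Integer seed for the chain.
#' @param threshold Significance threshold for labelling (default 0.05).
#' @param label_by `"q"` (BH within direction; used for CNA event pairs) or
#'   `"p"` (raw empirical p; used for mutation pairs).
#' @return Data frame: `event_a`, `event_b`, `observed`, `expected`
#'   (null mean), `p_excl`, `p_cooc`, `q_excl`, `q_cooc`, `label`.
#' @export
pair_event_tests <- function(m, pairs = NULL, n_permutations = 10000,
                             seed = 1, threshold = 0.05,
                             label_by = c("q", "p")) {
  label_by <- match.arg(label_by)
  if (n_permutations < 1000) cd_stop("n_permutations must be >= 1000")
  if (!all(m %in% c(0L, 1L))) cd_stop("alteration matrix must be binary")
  storage.mode(m) <- "integer"
  if (is.null(rownames(m))) rownames(m) <- paste0("e", seq_len(nrow(m)))
  if (any(rowSums(m) == 0)) {
    cd_stop("every candidate event needs >= 1 occurrence")
  }
  if (is.null(pairs)) {
    pairs <- t(utils::combn(rownames(m), 2))
  }
  if (is.list(pairs) && !is.data.frame(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  ia <- match(pairs[, 1], rownames(m))
  ib <- match(pairs[, 2], rownames(m))
  if (anyNA(ia) || anyNA(ib)) cd_stop("pair references unknown event ids")

  obs <- vapply(seq_along(ia), function(k)
    sum(m[ia[k], ] & m[ib[k], ]), integer(1))

  ones <- sum(m)
  if (!has_checkerboard(m)) {
    if (ones <= 20) {
      cd_log("degenerate margins; falling back to exact enumeration")
      null_cooc <- enumerate_null_cooc(m, ia, ib)
      return(summarize_pair_tests(pairs, obs, null_cooc$counts,
                                  null_cooc$weights, threshold, label_by))
    }
    cd_stop("margins admit no swap and matrix has > 20 ones")
  }

  draws <- with_seed(seed,
    swap_null_cooc(m, ia - 1L, ib - 1L, as.integer(n_permutations),
                   10 * ones, ones))
  summarize_pair_tests(pairs, obs, draws, NULL, threshold, label_by)
}

#' Margin-preserving swap randomization of a binary matrix
#'
#' Draws one (or several) randomizations of a binary matrix under the
#' checkerboard-swap chain used by [pair_event_tests()]; every draw has
#' exactly the row and column sums of the input.
#'
#' @param m Binary matrix.
#' @param n_swaps Number of proposals per draw (default `10 x` the number
#'   of ones).
#' @param n_draws Number of successive draws to return.
#' @param seed Integer seed.
#' @return A single matrix when `n_draws = 1`, else a list of matrices
#'   (each draw continues the chain from the previous one).
#' @export
swap_randomize_matrix <- function(m, n_swaps = NULL, n_draws = 1, seed = 1) {
  if (!all(m %in% c(0L, 1L))) cd_stop("matrix must be binary")
  storage.mode(m) <- "integer"
  if (is.null(n_swaps)) n_swaps <- 10 * sum(m)
  with_seed(seed, {
    out <- vector("list", n_draws)
    cur <- m
    for (i in seq_len(n_draws)) {
      cur <- swap_chain_step(cur, n_swaps)
      dimnames(cur) <- dimnames(m)
      out[[i]] <- cur
    }
    if (n_draws == 1) out[[1]] else out
  })
}

has_checkerboard <- function(m) {
  nr <- nrow(m)
  for (i in seq_len(nr - 1)) {
    for (j in (i + 1):nr) {
      a <- m[i, ]; b <- m[j, ]
      if (any(a == 1 & b == 0) && any(a == 0 & b == 1)) return(TRUE)
    }
  }
  FALSE
}

# exhaustive enumeration of all 0/1 matrices with the margins of m;
# returns co-occurrence counts per enumerated matrix (uniform weights)
enumerate_null_cooc <- function(m, ia, ib) {
  rs <- rowSums(m); cs <- colSums(m)
  nr <- nrow(m); nc <- ncol(m)
  results <- list()
  recurse <- function(row, remaining_cs, built) {
    if (row > nr) {
      results[[length(results) + 1L]] <<- built
      return(invisible(NULL))
    }
    cand <- utils::combn(nc, rs[row], simplify = FALSE)
    for (cols in cand) {
      if (all(remaining_cs[cols] >= 1)) {
        # feasibility: remaining ones must fit remaining rows
        new_cs <- remaining_cs
        new_cs[cols] <- new_cs[cols] - 1L
        if (sum(new_cs) == sum(rs[-seq_len(row)])) {
          rr <- rep(0L, nc); rr[cols] <- 1L
          recurse(row + 1L, new_cs, rbind(built, rr))
        }
      }
    }
  }
  recurse(1L, cs, NULL)
  counts <- vapply(results, function(mm)
    vapply(seq_along(ia), function(k)
      sum(mm[ia[k], ] & mm[ib[k], ]), integer(1)),
    integer(length(ia)))
  counts <- if (length(ia) == 1) matrix(counts, ncol = 1) else t(counts)
  list(counts = counts, weights = rep(1, length(results)))
}

summarize_pair_tests <- function(pairs, obs, null_counts, weights,
                                 threshold, label_by) {
  n <- nrow(null_counts)
  p_excl <- p_cooc <- expected <- numeric(length(obs))
  for (k in seq_along(obs)) {
    nc_k <- null_counts[, k]
    if (is.null(weights)) {
      p_excl[k] <- (1 + sum(nc_k <= obs[k])) / (n + 1)
      p_cooc[k] <- (1 + sum(nc_k >= obs[k])) / (n + 1)
      expected[k] <- mean(nc_k)
    } else {
      w <- weights / sum(weights)
      p_excl[k] <- sum(w[nc_k <= obs[k]])
      p_cooc[k] <- sum(w[nc_k >= obs[k]])
      expected[k] <- sum(w * nc_k)
    }
  }
  q_excl <- p.adjust(p_excl, method = "BH")
  q_cooc <- p.adjust(p_cooc, method = "BH")
  crit_e <- if (label_by == "q") q_excl else p_excl
  crit_c <- if (label_by == "q") q_cooc else p_cooc
  label <- ifelse(crit_e < threshold & obs <= expected, "mutually_exclusive",
           ifelse(crit_c < threshold & obs >= expected, "co_occurring",
                  "neither"))
  data.frame(event_a = pairs[, 1], event_b = pairs[, 2],
             observed = obs, expected = expected,
             p_excl = p_excl, p_cooc = p_cooc,
             q_excl = q_excl, q_cooc = q_cooc,
             label = label, stringsAsFactors = FALSE)
}

#' Build a binary alteration matrix from CNA states
#'
#' One binary row per (region, event type): a sample's bit is 1 iff the
#' region's member-gene states satisfy the event definition under the
#' chosen rule (`"majority"` by default; `"any"` and `"all"` available).
#'
#' @param cna A `gene_cna_matrix`.
#' @param regions Named list; each element is a list with `genes`
#'   (character, non-empty) and `event` (see [subtype_cna_association()]).
#' @param rule Aggregation over member genes: `"majority"`, `"any"` or
#'   `"all"`.
#' @return Integer 0/1 matrix with one row per region, class attribute
#'   `event_class = "cna"` rows named `<region>:<event>`.
#' @export
build_cna_events <- function(cna, regions, rule = c("majority", "any",
                                                    "all")) {
  rule <- match.arg(rule)
  rows <- lapply(names(regions), function(rn) {
    rg <- regions[[rn]]
    if (!length(rg$genes)) cd_stop("empty region: ", rn)
    miss <- setdiff(rg$genes, rownames(cna))
    if (length(miss)) cd_stop("region ", rn, " references unknown genes: ",
                              paste(miss, collapse = ", "))
    hit <- match_event(cna[rg$genes, , drop = FALSE], rg$event)
    dim(hit) <- c(length(rg$genes), ncol(cna))
    frac <- colMeans(hit)
    as.integer(switch(rule,
      majority = frac > 0.5,
      any = frac > 0,
      all = frac == 1))
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(paste0(names(regions), ":",
                             vapply(regions, `[[`, "", "event")),
                      colnames(cna))
  attr(m, "event_class") <- "cna"
  m
}
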