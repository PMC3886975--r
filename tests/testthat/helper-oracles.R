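# Independent oracles used across the suite.  These deliberately use
# different algorithms from the package code paths they check.

# Benjamini-Hochberg step-up, written directly from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# brute-force average-linkage agglomeration on a distance matrix:
# returns the sequence of merge heights
avg_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# exhaustive enumeration of binary matrices with fixed margins, built
# column-by-column (the package fallback builds row-by-row)
enum_margin_cooc <- function(m, a, b) {
  rs <- rowSums(m); cs <- colSums(m)
  nr <- nrow(m); nc <- ncol(m)
  counts <- integer(0)
  recurse <- function(col, rem_rs, built) {
    if (col > nc) {
      counts <<- c(counts, sum(built[a, ] & built[b, ]))
      return(invisible(NULL))
    }
    if (cs[col] == 0) {
      recurse(col + 1L, rem_rs, cbind(built, rep(0L, nr)))
      return(invisible(NULL))
    }
    for (rows in utils::combn(nr, cs[col], simplify = FALSE)) {
      if (all(rem_rs[rows] >= 1)) {
        new_rs <- rem_rs
        new_rs[rows] <- new_rs[rows] - 1L
        if (sum(new_rs) <= (nc - col) * nr) {
          v <- rep(0L, nr); v[rows] <- 1L
          recurse(col + 1L, new_rs, cbind(built, v))
        }
      }
    }
  }
  recurse(1L, rs, NULL)
  counts
}

# exact null distribution of the Mann-Whitney U statistic by enumerating
# every assignment of the pooled values into the two groups
mw_exact_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(pool)[seq_len(n1)])
  u_obs <- r_obs - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pool), n1, simplify = FALSE)
  us <- vapply(idx, function(ix) {
    sum(rank(pool)[ix]) - n1 * (n1 + 1) / 2
  }, numeric(1))
  mu <- n1 * length(y) / 2
  # two-sided: as extreme or more, measured from the null center
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# small reusable genome/cohort builders -------------------------------

tiny_model <- function(seed = 1, n_chrom = 1, genes = 30, cgh = 3, prom = 3) {
  build_genome_model(n_chrom, genes, cgh, prom, seed = seed)
}

tiny_config <- function(model, seed = 1, ...) {
  cohort_config(n_samples = c(lumA = 8, lumB = 6, basal = 6, ERBB2 = 4,
                              normal_like = 4),
                n_normal_meth = 3, seed = seed, ...)
}

# categorical truth matrix from the simulator's integer states
truth_states_cat <- function(truth) {
  m <- matrix(c("HOMO_LOSS", "HEMI_LOSS", "NEUTRAL", "GAIN",
                "AMP")[truth$true_states + 3L],
              nrow = nrow(truth$true_states),
              dimnames = dimnames(truth$true_states))
  m
}

subtype_labels <- function(cohort) {
  stats::setNames(cohort$annotation$subtype, cohort$annotation$sample)
}
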