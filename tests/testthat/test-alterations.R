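test_that("mutation-subtype association flags extreme tables and filters counts", {
  samples <- sprintf("s%03d", 1:100)
  labels <- stats::setNames(rep(c("lumB", "lumA"), c(20, 80)), samples)
  m <- matrix(0L, 3, 100, dimnames = list(c("hot", "rare", "flat"), samples))
  m["hot", 1:10] <- 1L                      # 10/20 in lumB, 0/80 elsewhere
  m["rare", 1:4] <- 1L                      # only 4 total mutations
  m["flat", seq(1, 100, by = 10)] <- 1L     # ~10% everywhere
  res <- mutation_subtype_association(m, labels, min_total_mutations = 5)
  expect_false("rare" %in% res$gene)        # excluded before testing
  hot <- res[res$gene == "hot" & res$subtype == "lumB", ]
  expect_true(hot$associated)
  expect_gt(hot$odds_ratio, 1)
  flat <- res[res$gene == "flat" & res$subtype == "lumB", ]
  expect_false(isTRUE(flat$associated))
})

test_that("null mutation rates stay near the nominal association rate", {
  set.seed(17)
  n_assoc <- 0L; n_tests <- 0L
  for (r in 1:10) {
    samples <- sprintf("s%03d", 1:100)
    labels <- stats::setNames(rep(c("lumB", "lumA", "basal"), c(20, 40, 40)),
                              samples)
    m <- matrix(rbinom(30 * 100, 1, 0.10), 30, 100,
                dimnames = list(sprintf("g%02d", 1:30), samples))
    res <- mutation_subtype_association(m, labels, min_total_mutations = 5,
                                        fdr = 0.25)
    n_assoc <- n_assoc + sum(res$associated)
    n_tests <- n_tests + nrow(res)
  }
  expect_lt(n_assoc / n_tests, 0.25)
})

test_that("CNA event matrices follow the aggregation rule", {
  cna <- matrix("NEUTRAL", 3, 5,
                dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:5)))
  cna["g1", 1:3] <- "GAIN"
  cna["g2", c(1, 2)] <- "HEMI_LOSS"
  cna["g3", 2] <- "HEMI_LOSS"
  class(cna) <- c("gene_cna_matrix", class(cna))

  single <- build_cna_events(cna, list(r1 = list(genes = "g1",
                                                 event = "gain_or_amp")))
  expect_equal(unname(single[1, ]), c(1L, 1L, 1L, 0L, 0L))

  # 2 of 3 genes lost in s2 -> majority fires; s1 has 1 of 3 -> no
  multi <- build_cna_events(cna, list(r2 = list(
    genes = c("g1", "g2", "g3"), event = "any_loss")))
  expect_equal(unname(multi[1, ]), c(0L, 1L, 0L, 0L, 0L))
  any_rule <- build_cna_events(cna, list(r2 = list(
    genes = c("g1", "g2", "g3"), event = "any_loss")), rule = "any")
  expect_equal(unname(any_rule[1, ]), c(1L, 1L, 0L, 0L, 0L))

  expect_error(build_cna_events(cna, list(bad = list(genes = character(),
                                                     event = "any_loss"))),
               "empty region")
})

test_that("swap randomization preserves all margins on every draw", {
  set.seed(23)
  m <- matrix(rbinom(15 * 40, 1, 0.3), 15, 40)
  draws <- swap_randomize_matrix(m, n_draws = 50, seed = 4)
  for (d in draws) {
    expect_identical(rowSums(d), rowSums(m))
    expect_identical(colSums(d), colSums(m))
  }
  # the chain actually moves
  expect_true(any(vapply(draws, function(d) any(d != m), logical(1))))
})

test_that("empirical p-values are valid and bounded by the pseudocount", {
  set.seed(29)
  m <- matrix(rbinom(6 * 30, 1, 0.4), 6, 30,
              dimnames = list(paste0("e", 1:6), paste0("s", 1:30)))
  m[rowSums(m) == 0, 1] <- 1L  # every event needs at least one occurrence
  res <- pair_event_tests(m, n_permutations = 1000, seed = 5)
  n <- 1000
  expect_true(all(res$p_excl >= 1 / (n + 1) & res$p_excl <= 1))
  expect_true(all(res$p_cooc >= 1 / (n + 1) & res$p_cooc <= 1))
  # both directions cannot be simultaneously extreme
  expect_true(all(res$p_excl + res$p_cooc >= 1))
})

test_that("identical-support events maximize co-occurrence significance", {
  m <- rbind(A = c(1, 1, 1, 1, rep(0, 8)),
             B = c(1, 1, 1, 1, rep(0, 8)),
             C = rep(c(1, 0), 6),
             D = rep(c(0, 1), 6))
  colnames(m) <- paste0("s", 1:12)
  res <- pair_event_tests(m, pairs = rbind(c("A", "B")),
                          n_permutations = 2000, seed = 7)
  expect_equal(res$observed, 4)
  expect_lt(res$p_cooc, 0.05)
  expect_equal(res$label, "co_occurring")
})

test_that("permutation p-values agree with exhaustive enumeration on small instances", {
  # every instance here has <= 20 total ones
  instances <- list(
    rbind(A = c(1, 1, 1, 0, 0, 0), B = c(0, 0, 0, 1, 1, 1),
          C = c(1, 0, 1, 0, 1, 0)),
    rbind(A = c(1, 1, 0, 0, 0, 0, 1), B = c(0, 0, 1, 1, 0, 0, 1),
          C = c(1, 0, 0, 1, 1, 0, 0), D = c(0, 1, 1, 0, 0, 1, 0)),
    rbind(A = c(1, 1, 1, 1, 0, 0, 0, 0), B = c(0, 0, 1, 1, 1, 1, 0, 0)))
  for (m in instances) {
    colnames(m) <- paste0("s", seq_len(ncol(m)))
    res <- pair_event_tests(m, pairs = rbind(c("A", "B")),
                            n_permutations = 10000, seed = 11)
    cooc <- enum_margin_cooc(m, 1, 2)
    p_excl_exact <- mean(cooc <= res$observed)
    p_cooc_exact <- mean(cooc >= res$observed)
    # Monte-Carlo tolerance: ~4 binomial sd at n = 10000
    tol <- 4 * sqrt(0.25 / 10000) + 2e-4
    expect_lt(abs(res$p_excl - p_excl_exact), tol + 0.01)
    expect_lt(abs(res$p_cooc - p_cooc_exact), tol + 0.01)
  }
})

test_that("an injected fully exclusive pair is detected", {
  set.seed(37)
  hits <- vapply(1:20, function(r) {
    n <- 100
    a <- rbinom(n, 1, 0.3)
    b <- ifelse(a == 1, 0L, rbinom(n, 1, 0.3 / 0.7))
    bg <- matrix(rbinom(4 * n, 1, 0.3), 4, n)
    m <- rbind(A = a, B = b, bg)
    rownames(m) <- c("A", "B", paste0("bg", 1:4))
    colnames(m) <- paste0("s", 1:n)
    res <- pair_event_tests(m, pairs = rbind(c("A", "B")),
                            n_permutations = 1000, seed = r,
                            label_by = "p")
    res$p_excl < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("degenerate margins fall back to exact enumeration", {
  # all columns full: no checkerboard exists
  m <- rbind(A = c(1, 1, 1), B = c(1, 1, 1))
  colnames(m) <- paste0("s", 1:3)
  res <- pair_event_tests(m, n_permutations = 1000, seed = 1)
  expect_equal(res$observed, 3)
  expect_equal(res$p_excl, 1)
  expect_equal(res$p_cooc, 1)
})
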