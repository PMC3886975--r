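test_that("GC median centering and quantile normalization behave as specified", {
  # one sample, one GC bin: medians removed (median of {-1,0,1} is 0)
  m <- matrix(c(-1, 0, 1), 3, 1, dimnames = list(paste0("p", 1:3), "s1"))
  out <- normalize_m(m, gc = rep(0.5, 3), gc_bins = 1)
  expect_equal(unname(out[, 1]), c(-1, 0, 1))

  # two samples with identical value multisets in different orders
  m2 <- cbind(s1 = c(3, 1, 2, 0), s2 = c(0, 2, 1, 3))
  rownames(m2) <- paste0("p", 1:4)
  out2 <- normalize_m(m2, gc = rep(0.5, 4), gc_bins = 1)
  expect_equal(sort(unname(out2[, 1])), sort(unname(out2[, 2])))

  # after quantile normalization all samples share one sorted vector
  set.seed(5)
  m3 <- matrix(rnorm(500 * 6), 500, 6,
               dimnames = list(sprintf("p%03d", 1:500), paste0("s", 1:6)))
  gc <- runif(500, 0.2, 0.8)
  out3 <- normalize_m(m3, gc, gc_bins = 10)
  sorted <- apply(out3, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
})

test_that("quantile step agrees with limma's reference implementation", {
  skip_if_not_installed("limma")
  set.seed(8)
  m <- matrix(rnorm(300 * 4), 300, 4)
  ours <- cnadriver:::quantile_normalize(m)
  theirs <- limma::normalizeQuantiles(m)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
})

test_that("sparse GC bins are merged into neighbors without changing shape", {
  set.seed(9)
  gc <- c(rep(0.3, 50), rep(0.9, 3))  # second bin is sparse
  m <- matrix(rnorm(53 * 3), 53, 3,
              dimnames = list(sprintf("p%02d", 1:53), paste0("s", 1:3)))
  expect_silent(suppressMessages(out <- normalize_m(m, gc, gc_bins = 5)))
  expect_equal(dim(out), dim(m))
})

test_that("promoter score reduces to the probe mean", {
  map4 <- data.frame(probe = paste0("p", 1:4), gene = "g1",
                     stringsAsFactors = FALSE)
  m <- matrix(0.8, 4, 2, dimnames = list(paste0("p", 1:4), c("s1", "s2")))
  expect_equal(unname(promoter_score(m, map4)["g1", ]), c(0.8, 0.8))

  m2 <- matrix(c(1, 1, -1, -1), 4, 1, dimnames = list(paste0("p", 1:4), "s"))
  expect_equal(unname(promoter_score(m2, map4)["g1", ]), 0)

  # random promoters: score == mean(M) exactly, and stays inside [min, max]
  set.seed(12)
  n_prom <- 300
  probes_per <- sample(2:6, n_prom, replace = TRUE)
  map <- data.frame(
    probe = sprintf("p%05d", seq_len(sum(probes_per))),
    gene = rep(sprintf("g%04d", seq_len(n_prom)), probes_per),
    stringsAsFactors = FALSE)
  m3 <- matrix(rnorm(sum(probes_per) * 3), ncol = 3,
               dimnames = list(map$probe, paste0("s", 1:3)))
  sc <- promoter_score(m3, map)
  oracle <- do.call(rbind, lapply(split(seq_len(nrow(m3)), map$gene),
                                  function(ix) colMeans(m3[ix, , drop = FALSE])))
  expect_equal(sc, oracle[rownames(sc), ], tolerance = 1e-12)
  for (g in sample(rownames(sc), 20)) {
    ix <- map$gene == g
    expect_true(all(sc[g, ] >= apply(m3[ix, , drop = FALSE], 2, min) - 1e-12))
    expect_true(all(sc[g, ] <= apply(m3[ix, , drop = FALSE], 2, max) + 1e-12))
  }
})

test_that("variable-promoter selection is strict and matches an SD scan", {
  scores <- rbind(constant = rep(1, 6),
                  two_vals = c(0, 0.6, 0, 0.6, 0, 0.6),
                  noisy = rnorm(6, 0, 2))
  colnames(scores) <- paste0("s", 1:6)
  keep <- select_variable_promoters(scores, sd_min = 0.3)
  expect_false("constant" %in% keep)
  expect_true("two_vals" %in% keep)  # SD ~ 0.33 > 0.3

  set.seed(4)
  m <- matrix(rnorm(50 * 8, 0, 0.4), 50, 8,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:8)))
  expect_setequal(select_variable_promoters(m, 0.3),
                  rownames(m)[apply(m, 1, sd) > 0.3])
})

test_that("sample clustering separates duplicated groups and matches the oracle", {
  set.seed(21)
  sig_a <- rnorm(40); sig_b <- rnorm(40)
  scores <- cbind(a1 = sig_a + rnorm(40, 0, .05),
                  a2 = sig_a + rnorm(40, 0, .05),
                  a3 = sig_a + rnorm(40, 0, .05),
                  b1 = sig_b + rnorm(40, 0, .05),
                  b2 = sig_b + rnorm(40, 0, .05),
                  b3 = sig_b + rnorm(40, 0, .05))
  rownames(scores) <- sprintf("g%02d", 1:40)
  cl <- cluster_samples(scores, k = 2)
  expect_equal(length(unique(cl$clusters[1:3])), 1)
  expect_equal(length(unique(cl$clusters[4:6])), 1)
  expect_false(cl$clusters[1] == cl$clusters[4])

  # merge heights match the brute-force average-linkage oracle
  d <- 1 - stats::cor(scores)
  expect_equal(sort(cl$hclust$height),
               sort(avg_linkage_heights(stats::as.dist(d))),
               tolerance = 1e-12)

  dup <- scores; dup[, 4:6] <- dup[, 1:3]; colnames(dup) <- colnames(scores)
  d2 <- 1 - stats::cor(dup)
  expect_equal(unname(d2[1, 4]), 0, tolerance = 1e-12)

  flat <- scores; flat[, 2] <- 5
  expect_error(cluster_samples(flat), "zero-variance.*a2")
})

test_that("ER-supervised testing recovers implanted differences", {
  set.seed(31)
  er <- stats::setNames(rep(c("+", "-"), each = 20),
                        sprintf("s%02d", 1:40))
  scores <- matrix(rnorm(50 * 40, 0, 0.4), 50,
                   dimnames = list(sprintf("g%02d", 1:50), names(er)))
  hyper_neg <- sprintf("g%02d", 1:10)
  scores[hyper_neg, 21:40] <- scores[hyper_neg, 21:40] + 1
  res <- er_supervised_test(scores, er)
  hit <- res$gene %in% hyper_neg & res$q < 0.05 & res$higher_in == "ER-"
  expect_gte(sum(hit) / 10, 0.9)

  # permuted labels: approximately nominal false positive rate
  perm <- stats::setNames(sample(er), names(er))
  null_p <- er_supervised_test(scores[11:50, ], perm)$p
  expect_lt(mean(null_p < 0.05), 0.2)
})

test_that("subtype specificity calls one and only one deviant subtype", {
  set.seed(41)
  labels <- stats::setNames(
    rep(c("lumA", "lumB", "basal", "ERBB2", "normal_like"),
        times = c(10, 8, 8, 5, 5)), sprintf("s%02d", 1:36))
  scores <- matrix(rnorm(30 * 36, 0, 0.4), 30,
                   dimnames = list(sprintf("g%02d", 1:30), names(labels)))
  scores["g01", labels == "lumB"] <- scores["g01", labels == "lumB"] + 1.5
  scores["g02", labels == "lumB"] <- scores["g02", labels == "lumB"] + 1.5
  scores["g02", labels == "basal"] <- scores["g02", labels == "basal"] + 1.5
  nb <- matrix(rnorm(30 * 5, 0, 0.4), 30,
               dimnames = list(rownames(scores), paste0("NB", 1:5)))
  calls <- subtype_specificity(scores, labels, normal_scores = nb)
  expect_true("g01" %in% calls$gene)
  g01 <- calls[calls$gene == "g01", ]
  expect_equal(g01$subtype, "lumB")
  expect_equal(g01$direction, "hyper")
  expect_true(g01$vs_normal_significant)
  expect_false("g02" %in% calls$gene)  # two deviant subtypes: no call
})

test_that("specificity calls ignore sample order within other subtypes", {
  set.seed(51)
  labels <- stats::setNames(
    rep(c("lumA", "lumB", "basal", "ERBB2", "normal_like"), each = 6),
    sprintf("s%02d", 1:30))
  scores <- matrix(rnorm(10 * 30, 0, 0.3), 10,
                   dimnames = list(sprintf("g%02d", 1:10), names(labels)))
  scores["g03", labels == "basal"] <- scores["g03", labels == "basal"] - 1.5
  calls1 <- suppressWarnings(subtype_specificity(scores, labels))
  perm <- c(1:12, sample(13:18), 19:30)  # permute basal columns
  calls2 <- suppressWarnings(subtype_specificity(scores[, perm],
                                                 labels[perm]))
  expect_equal(calls1[order(calls1$gene), c("gene", "subtype", "direction")],
               calls2[order(calls2$gene), c("gene", "subtype", "direction")])
})

test_that("methylation-expression linking applies the strict -0.40 cutoff", {
  samples <- sprintf("s%02d", 1:20)
  sc <- matrix(rnorm(3 * 20), 3, dimnames = list(c("anti", "boundary",
                                                   "indep"), samples))
  expr <- sc
  expr["anti", ] <- -sc["anti", ]
  # construct an exact r = -0.40 pair
  set.seed(6)
  x <- rnorm(20); y <- -0.4 * scale(x)[, 1] + sqrt(1 - 0.16) *
    scale(resid(lm(rnorm(20) ~ x)))[, 1]
  sc["boundary", ] <- x; expr["boundary", ] <- y
  expr["indep", ] <- rnorm(20)
  res <- methylation_expression_link(sc, expr)
  expect_true(res$kept[res$gene == "anti"])
  expect_equal(res$r[res$gene == "anti"], -1)
  expect_equal(res$r[res$gene == "boundary"], -0.4, tolerance = 1e-9)
  expect_false(res$kept[res$gene == "boundary"])  # strict inequality
})

test_that("joint CNA + methylation deregulation enforces both chains", {
  cands <- data.frame(
    gene = c("up_ok", "up_bad", "down_ok"),
    class = c("oncogene", "oncogene", "TSG"),
    direction = c("up", "up", "down"),
    event = c("gain_or_amp", "gain_or_amp", "any_loss"),
    freq_target = 0.5, dosage_q = 0.01, subtype_q = 0.01,
    stringsAsFactors = FALSE)
  meth <- data.frame(
    gene = c("up_ok", "up_bad", "down_ok"),
    subtype = "lumB",
    direction = c("hypo", "hyper", "hyper"),
    anova_q = 0.01, stringsAsFactors = FALSE)
  out <- joint_cna_methylation(cands, meth, "lumB")
  expect_setequal(out$gene, c("up_ok", "down_ok"))
  expect_equal(out$class[out$gene == "up_ok"], "up")
  expect_equal(out$class[out$gene == "down_ok"], "down")
})
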