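test_that("expression filter boundary is inclusive and matches a row scan", {
  expr <- rbind(at_boundary = c(5, 5, 0, 0),
                below = c(4.9, 4.9, 0, 0),
                high = c(9, 9, 9, 9))
  colnames(expr) <- paste0("s", 1:4)
  keep <- filter_expressed(expr, min_level = 5, min_fraction = 0.5)
  expect_setequal(keep, c("at_boundary", "high"))

  zeros <- matrix(0, 3, 4, dimnames = list(letters[1:3], paste0("s", 1:4)))
  expect_warning(keep0 <- filter_expressed(zeros, min_level = 1,
                                           min_fraction = 0.25), "no genes")
  expect_length(keep0, 0)

  set.seed(1)
  rmat <- matrix(rnorm(200, 6), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:10)))
  keep_pkg <- filter_expressed(rmat, min_level = 6, min_fraction = 0.3)
  keep_oracle <- rownames(rmat)[vapply(seq_len(20), function(i)
    sum(rmat[i, ] >= 6) >= 0.3 * 10, logical(1))]
  expect_setequal(keep_pkg, keep_oracle)
})

dosage_fixture <- function(event_expr, noevent_expr, gene = "g1") {
  n1 <- length(event_expr); n2 <- length(noevent_expr)
  samples <- sprintf("s%02d", seq_len(n1 + n2))
  expr <- matrix(c(event_expr, noevent_expr), 1,
                 dimnames = list(gene, samples))
  cna <- matrix(c(rep("GAIN", n1), rep("NEUTRAL", n2)), 1,
                dimnames = list(gene, samples))
  class(cna) <- c("gene_cna_matrix", class(cna))
  list(expr = expr, cna = cna, samples = samples)
}

test_that("complete separation gives maximal U and direction up", {
  fx <- dosage_fixture(c(5, 6, 7), c(1, 2, 3))
  res <- dosage_association(fx$expr, fx$cna, fx$samples)
  expect_equal(res$statistic, 9)  # 3 * 3
  expect_equal(res$direction, "up")
})

test_that("identical distributions give p near 1; constants give p = 1", {
  fx <- dosage_fixture(c(1, 4, 5, 8), c(2, 3, 6, 7))  # U at its null mean
  res <- dosage_association(fx$expr, fx$cna, fx$samples)
  expect_equal(res$p, 1)

  fx2 <- dosage_fixture(rep(2, 4), rep(2, 5))
  res2 <- dosage_association(fx2$expr, fx2$cna, fx2$samples)
  expect_equal(res2$p, 1)
})

test_that("exact 4-vs-4 Mann-Whitney p matches full enumeration of 70 splits", {
  set.seed(7)
  for (rep in 1:5) {
    x <- round(rnorm(4, 1), 3); y <- round(rnorm(4), 3)
    fx <- dosage_fixture(x, y)
    res <- dosage_association(fx$expr, fx$cna, fx$samples)
    expect_equal(res$p, mw_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("genes with tiny groups are skipped and left out of the BH family", {
  samples <- sprintf("s%02d", 1:10)
  expr <- matrix(rnorm(20), 2, dimnames = list(c("ok", "tiny"), samples))
  cna <- matrix("NEUTRAL", 2, 10, dimnames = list(c("ok", "tiny"), samples))
  cna["ok", 1:5] <- "GAIN"
  cna["tiny", 1:2] <- "GAIN"
  class(cna) <- c("gene_cna_matrix", class(cna))
  res <- dosage_association(expr, cna, samples)
  expect_equal(res$gene, "ok")
  expect_equal(res$q, res$p)  # family of size 1
})

test_that("subtype deregulation recovers implanted shifts and stays calibrated", {
  set.seed(11)
  n1 <- 32; n2 <- 64
  labels <- stats::setNames(c(rep("lumB", n1), rep("lumA", n2)),
                            sprintf("s%03d", seq_len(n1 + n2)))
  n_genes <- 60
  shifted <- sprintf("g%02d", 1:20)
  expr <- matrix(rnorm(n_genes * (n1 + n2), 0, 0.3), n_genes,
                 dimnames = list(sprintf("g%02d", 1:n_genes), names(labels)))
  expr[shifted, 1:n1] <- expr[shifted, 1:n1] + 1.0
  res <- subtype_deregulation(expr, labels, "lumB", "lumA")
  hit <- res$gene %in% shifted & res$q < 0.05 & res$direction == "up"
  expect_gte(sum(hit) / length(shifted), 0.95)

  # null genes: raw p roughly uniform
  null_p <- res$p[!res$gene %in% shifted]
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 0.12)

  const <- matrix(3, 2, n1 + n2,
                  dimnames = list(c("c1", "c2"), names(labels)))
  resc <- subtype_deregulation(const, labels, "lumB", "lumA")
  expect_equal(resc$p, c(1, 1))
})

test_that("candidate nomination applies the concordance rules", {
  mk_assoc <- function(gene, event) data.frame(
    gene = gene, event = event, freq_target = 0.5, q = 0.01,
    significant = TRUE, stringsAsFactors = FALSE)
  dosage <- data.frame(gene = c("gainup", "lossup"),
                       statistic = c(9, 9), direction = c("up", "up"),
                       p = c(0.001, 0.001), q = c(0.01, 0.01),
                       stringsAsFactors = FALSE)
  subtype <- data.frame(gene = c("gainup", "lossup"), t = c(3, 3),
                        direction = c("up", "up"), p = c(0.001, 0.001),
                        q = c(0.01, 0.01), stringsAsFactors = FALSE)
  cna <- rbind(mk_assoc("gainup", "gain_or_amp"),
               mk_assoc("lossup", "any_loss"))
  out <- nominate_candidates(c("gainup", "lossup"), dosage, subtype, cna)
  expect_equal(out$gene, "gainup")
  expect_equal(out$class, "oncogene")
  rej <- attr(out, "rejected")
  expect_equal(rej$gene, "lossup")
  expect_equal(rej$reason, "discordant")
})

test_that("lowering the FDR threshold never enlarges the candidate set", {
  gm <- tiny_model(genes = 40, cgh = 3)
  cfg <- tiny_config(gm, seed = 13, dosage_effect = 1,
    cna_events = list(list(chrom = "chr1", start = 0, end = 10e6,
                           state = 1L,
                           freq = c(lumB = 0.8, lumA = 0.1, basal = 0.1,
                                    ERBB2 = 0.1, normal_like = 0.1))))
  sim <- simulate_cohort(gm, cfg)
  cnam <- gene_cna_matrix(sim$cohort$cgh, gm$genes)
  sets <- lapply(c(0.05, 0.01, 0.001), function(f)
    run_integration(sim$cohort, cnam, fdr = f)$gene)
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("core intersection behaves as a keyed set operation", {
  a <- data.frame(gene = c("g1", "g2", "g3"),
                  class = c("oncogene", "TSG", "oncogene"),
                  stringsAsFactors = FALSE)
  b <- data.frame(gene = c("g2", "g3", "g4"),
                  class = c("TSG", "TSG", "oncogene"),
                  stringsAsFactors = FALSE)
  core <- core_candidates(a, b)
  expect_equal(core$gene, "g2")  # g3 differs in class

  expect_equal(nrow(core_candidates(a, a)), 3)
  disjoint <- core_candidates(a, data.frame(gene = "zz", class = "TSG",
                                            stringsAsFactors = FALSE))
  expect_equal(nrow(disjoint), 0)

  set.seed(3)
  g1 <- data.frame(gene = sample(letters, 10), class = "oncogene",
                   stringsAsFactors = FALSE)
  g2 <- data.frame(gene = sample(letters, 10), class = "oncogene",
                   stringsAsFactors = FALSE)
  expect_setequal(core_candidates(g1, g2)$gene, intersect(g1$gene, g2$gene))
})
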