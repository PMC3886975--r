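#' Simulate a multi-omic tumor cohort with known ground truth
#'
#' Generates aligned aCGH probe tracks, a log2 expression matrix, a promoter
#' M-value matrix (tumors plus normal-breast references), a binary somatic
#' mutation matrix and a sample annotation, together with the implanted
#' ground truth, under the generative model:
#'
#' * copy number: each configured event occurs in a sample with its
#'   (per-subtype) frequency; probe log2 ratio = segment mean of the integer
#'   copy state (-1.2, -0.45, 0, 0.45, 1.2 for states -2..2) + Gaussian
#'   noise;
#' * expression: `baseline(g) + dosage_effect * state(g, s) +
#'   coupling * meth_deviation(g, s) + noise`;
#' * methylation: probe baseline (with a GC-linked trend) + per-(gene,
#'   sample) deviation (`delta_m` in target-subtype samples, plus
#'   sample-level biological scatter for event genes) + probe noise;
#'   normal-breast references are drawn from the unshifted baseline model;
#' * mutations: Bernoulli per gene x subtype rate, with injected
#'   exclusive / co-occurring pairs enforced at the configured strength
#'   (strength 1 makes an exclusive pair never co-occur).
#'
#' The master seed is expanded into independent per-layer substreams, so the
#' same seed always reproduces the identical cohort.
#'
#' @param model A [build_genome_model()] object.
#' @param config A [cohort_config()] object; may only reference genes and
#'   regions present in `model`.
#'
#' @return A list with elements `cohort` (class `omics_cohort`: `cgh` list of
#'   `probe_track`s, `expression`, `methylation`, `normal_methylation`,
#'   `promoter_map`, `mutations`, `annotation`) and `truth` (class
#'   `ground_truth`: `candidates`, `methylation_genes`, `pairs`,
#'   `true_states` integer matrix, `segments`, `event_occurrence`).
#' @examples
#' gm <- build_genome_model(1, 30, 3, 3, seed = 1)
#' cfg <- cohort_config(n_samples = c(lumB = 6, lumA = 8), n_normal_meth = 2,
#'                      seed = 5)
#' sim <- simulate_cohort(gm, cfg)
#' dim(sim$cohort$expression)
#' @export
simulate_cohort <- function(model, config) {
  stopifnot(inherits(model, "genome_model"), inherits(config, "cohort_config"))
  validate_config_against_model(model, config)

  genes <- model$genes
  n_genes <- nrow(genes)
  gene_mid <- (genes$start + genes$end) / 2

  subtype_of <- rep(names(config$n_samples), config$n_samples)
  n_samp <- length(subtype_of)
  if (n_samp == 0) cd_stop("cohort has no tumor samples")
  samples <- sprintf("%s_%03d", subtype_of,
                     unlist(lapply(config$n_samples, seq_len)))
  ss <- substream_seeds(config$seed, 5L)

  ## --- CNA layer -------------------------------------------------------
  cna <- with_seed(ss[1], {
    occ <- matrix(FALSE, nrow = length(config$cna_events), ncol = n_samp)
    state_g <- matrix(0L, nrow = n_genes, ncol = n_samp,
                      dimnames = list(genes$gene, samples))
    probes <- model$probes_cgh
    state_p <- matrix(0L, nrow = nrow(probes), ncol = n_samp,
                      dimnames = list(probes$probe, samples))
    for (i in seq_along(config$cna_events)) {
      ev <- config$cna_events[[i]]
      f <- event_freq_by_sample(ev$freq, subtype_of)
      hit <- runif(n_samp) < f
      occ[i, ] <- hit
      gi <- which(genes$chrom == ev$chrom &
                  gene_mid >= ev$start & gene_mid < ev$end)
      pi <- which(probes$chrom == ev$chrom &
                  probes$start >= ev$start & probes$start < ev$end)
      if (any(hit)) {
        state_g[gi, hit] <- ev$state
        state_p[pi, hit] <- ev$state
      }
    }
    vals <- matrix(STATE_MEANS[as.character(state_p)], nrow = nrow(probes)) +
      rnorm(length(state_p), 0, config$sd_cgh)
    dimnames(vals) <- dimnames(state_p)
    list(occ = occ, state_g = state_g, state_p = state_p, vals = vals)
  })

  tracks <- lapply(seq_len(n_samp), function(j) {
    probe_track(sample = samples[j],
                probes = data.frame(model$probes_cgh,
                                    value = cna$vals[, j],
                                    stringsAsFactors = FALSE))
  })
  names(tracks) <- samples

  ## --- methylation layer ----------------------------------------------
  prom <- model$promoter_probes
  meth <- with_seed(ss[3], {
    base_p <- rnorm(nrow(prom), 0, 0.6) + config$gc_slope * (prom$gc - 0.5)
    dev <- matrix(0, nrow = n_genes, ncol = n_samp,
                  dimnames = list(genes$gene, samples))
    coupling <- matrix(0, nrow = n_genes, ncol = 1,
                       dimnames = list(genes$gene, NULL))
    for (me in config$methylation_events) {
      gi <- match(me$genes, genes$gene)
      cpl <- if (is.null(me$coupling)) -1 else me$coupling
      tgt <- subtype_of == me$subtype
      # biological scatter keeps within-cohort variation for event genes
      dev[gi, ] <- dev[gi, ] +
        matrix(rnorm(length(gi) * n_samp, 0, config$sd_meth),
               length(gi), n_samp)
      dev[gi, tgt] <- dev[gi, tgt] + me$delta_m
      coupling[gi, 1] <- cpl
    }
    gi_of_probe <- match(prom$gene, genes$gene)
    m <- base_p + dev[gi_of_probe, , drop = FALSE] +
      matrix(rnorm(nrow(prom) * n_samp, 0, config$sd_meth), nrow(prom), n_samp)
    dimnames(m) <- list(prom$probe, samples)
    nb <- NULL
    if (config$n_normal_meth > 0) {
      nb <- base_p + matrix(rnorm(nrow(prom) * config$n_normal_meth, 0,
                                  config$sd_meth),
                            nrow(prom), config$n_normal_meth)
      dimnames(nb) <- list(prom$probe,
                           sprintf("NB_%02d", seq_len(config$n_normal_meth)))
    }
    list(m = m, nb = nb, dev = dev, coupling = coupling)
  })

  ## --- expression layer ------------------------------------------------
  expr <- with_seed(ss[2], {
    baseline <- rnorm(n_genes, config$expression_baseline_mean,
                      config$expression_baseline_sd)
    e <- baseline + config$dosage_effect * cna$state_g +
      as.vector(meth$coupling) * meth$dev +
      matrix(rnorm(n_genes * n_samp, 0, config$sd_expr), n_genes, n_samp)
    dimnames(e) <- list(genes$gene, samples)
    e
  })

  ## --- mutation layer --------------------------------------------------
  mut <- with_seed(ss[4], {
    rate <- matrix(config$mutation_rate, n_genes, n_samp,
                   dimnames = list(genes$gene, samples))
    for (g in names(config$mutation_rates)) {
      r <- config$mutation_rates[[g]]
      if (length(r) == 1 && is.null(names(r))) {
        rate[g, ] <- r
      } else {
        for (st in names(r)) rate[g, subtype_of == st] <- r[[st]]
      }
    }
    m <- matrix(as.integer(runif(length(rate)) < rate), n_genes, n_samp,
                dimnames = dimnames(rate))
    for (pr in config$injected_pairs) {
      a <- pr$gene_a; b <- pr$gene_b
      apply_pair <- runif(n_samp) < pr$strength
      if (pr$type == "exclusive") {
        both <- m[a, ] == 1L & m[b, ] == 1L
        m[b, both & apply_pair] <- 0L
      } else {
        m[b, apply_pair] <- m[a, apply_pair]
      }
    }
    m
  })

  ## --- annotation ------------------------------------------------------
  annot <- with_seed(ss[5], {
    er <- ifelse(subtype_of %in% c("lumA", "lumB"), "+",
          ifelse(subtype_of == "basal", "-",
                 sample(c("+", "-"), n_samp, replace = TRUE)))
    pr <- ifelse(er == "+",
                 sample(c("+", "-"), n_samp, replace = TRUE, prob = c(.8, .2)),
                 sample(c("+", "-"), n_samp, replace = TRUE, prob = c(.2, .8)))
    grade <- ifelse(subtype_of %in% c("lumB", "basal", "ERBB2"),
                    sample(2:3, n_samp, replace = TRUE, prob = c(.3, .7)),
                    sample(1:2, n_samp, replace = TRUE))
    data.frame(sample = samples, subtype = subtype_of, ER = er, PR = pr,
               grade = grade, tissue = "tumor", stringsAsFactors = FALSE)
  })

  truth <- build_ground_truth(model, config, cna, meth, subtype_of, samples)

  cohort <- structure(list(
    cgh = tracks,
    expression = expr,
    methylation = meth$m,
    normal_methylation = meth$nb,
    promoter_map = prom,
    mutations = mut,
    annotation = annot,
    genes = genes), class = "omics_cohort")

  list(cohort = cohort, truth = truth)
}

# per-sample event frequency from a scalar or per-subtype named vector
event_freq_by_sample <- function(freq, subtype_of) {
  if (length(freq) == 1 && is.null(names(freq))) {
    rep(freq, length(subtype_of))
  } else {
    f <- freq[subtype_of]
    f[is.na(f)] <- 0
    unname(f)
  }
}

validate_config_against_model <- function(model, config) {
  for (ev in config$cna_events) {
    ci <- match(ev$chrom, model$chromosomes$chrom)
    if (is.na(ci)) cd_stop("cna_event references unknown chromosome: ",
                           ev$chrom)
    if (ev$start < 0 || ev$end > model$chromosomes$length[ci] ||
        ev$end <= ev$start) {
      cd_stop("cna_event region invalid on ", ev$chrom)
    }
  }
  for (me in config$methylation_events) {
    bad <- setdiff(me$genes, model$genes$gene)
    if (length(bad)) cd_stop("methylation_event references unknown genes: ",
                             paste(bad, collapse = ", "))
  }
  for (pr in config$injected_pairs) {
    bad <- setdiff(c(pr$gene_a, pr$gene_b), model$genes$gene)
    if (length(bad)) cd_stop("injected pair references unknown genes: ",
                             paste(bad, collapse = ", "))
  }
  for (g in names(config$mutation_rates)) {
    if (!g %in% model$genes$gene) {
      cd_stop("mutation_rates references unknown gene: ", g)
    }
  }
  invisible(TRUE)
}

build_ground_truth <- function(model, config, cna, meth, subtype_of, samples) {
  genes <- model$genes
  gene_mid <- (genes$start + genes$end) / 2

  cand <- list()
  for (ev in config$cna_events) {
    f <- ev$freq
    if (length(f) > 1 && diff(range(c(f, rep(0, length(SUBTYPES) -
                                               length(f)))))) {
      full <- setNames(rep(0, length(SUBTYPES)), SUBTYPES)
      full[names(f)] <- f
      tgt <- names(which.max(full))
      gi <- which(genes$chrom == ev$chrom &
                  gene_mid >= ev$start & gene_mid < ev$end)
      if (length(gi)) {
        cand[[length(cand) + 1L]] <- data.frame(
          gene = genes$gene[gi],
          class = if (ev$state > 0) "oncogene" else "TSG",
          subtype = tgt, stringsAsFactors = FALSE)
      }
    }
  }
  cand <- if (length(cand)) unique(do.call(rbind, cand)) else
    data.frame(gene = character(), class = character(),
               subtype = character(), stringsAsFactors = FALSE)

  mg <- list()
  for (me in config$methylation_events) {
    mg[[length(mg) + 1L]] <- data.frame(
      gene = me$genes, subtype = me$subtype,
      direction = if (me$delta_m > 0) "hyper" else "hypo",
      stringsAsFactors = FALSE)
  }
  mg <- if (length(mg)) do.call(rbind, mg) else
    data.frame(gene = character(), subtype = character(),
               direction = character(), stringsAsFactors = FALSE)

  prs <- if (length(config$injected_pairs)) {
    do.call(rbind, lapply(config$injected_pairs, function(p)
      data.frame(gene_a = p$gene_a, gene_b = p$gene_b, type = p$type,
                 strength = p$strength, stringsAsFactors = FALSE)))
  } else {
    data.frame(gene_a = character(), gene_b = character(),
               type = character(), strength = numeric(),
               stringsAsFactors = FALSE)
  }

  segs <- true_segment_maps(model, cna$state_p, samples)

  structure(list(candidates = cand, methylation_genes = mg, pairs = prs,
                 true_states = cna$state_g,
                 event_occurrence = cna$occ,
                 segments = segs), class = "ground_truth")
}

# run-length encode per-sample probe states into true segment maps
true_segment_maps <- function(model, state_p, samples) {
  probes <- model$probes_cgh
  out <- vector("list", length(samples))
  for (j in seq_along(samples)) {
    per_chrom <- lapply(split(seq_len(nrow(probes)), probes$chrom), function(ix) {
      st <- state_p[ix, j]
      r <- rle(st)
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1) + 1L)
      data.frame(chrom = probes$chrom[ix[1]],
                 start = probes$start[ix[starts]],
                 end = probes$end[ix[ends]],
                 state = r$values, n_probes = r$lengths,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, per_chrom)
    df$sample <- samples[j]
    out[[j]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("sample", "chrom", "start", "end", "state", "n_probes")]
}

#' Serialize simulator ground truth to JSON
#'
#' @param truth A `ground_truth` object from [simulate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- list(candidates = truth$candidates,
              methylation_genes = truth$methylation_genes,
              pairs = truth$pairs,
              true_states = list(genes = rownames(truth$true_states),
                                 samples = colnames(truth$true_states),
                                 states = unname(as.data.frame(
                                   truth$true_states))),
              segments = truth$segments)
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
print.omics_cohort <- function(x, ...) {
  cat("omics_cohort:", ncol(x$expression), "tumor samples,",
      nrow(x$expression), "genes,", nrow(x$methylation), "promoter probes,",
      if (is.null(x$normal_methylation)) 0 else ncol(x$normal_methylation),
      "normal-breast references\n")
  cat("subtypes:",
      paste(names(table(x$annotation$subtype)),
            table(x$annotation$subtype), collapse = ", ", sep = ":"), "\n")
  invisible(x)
}
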