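#' Build a synthetic genome model
#'
#' Constructs the genomic scaffold used by the cohort simulator: chromosomes,
#' a uniform gene annotation, an ordered array-CGH probe track, and
#' strand-aware promoter probes placed within 3 kb of each gene's
#' transcription start site (TSS), each carrying a GC fraction.
#'
#' Genes are laid out on a uniform grid (one 1-Mb slot per gene) so gene
#' density is constant along each chromosome; aCGH probes tile every slot so
#' multi-gene segments are supported by many probes.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param genes_per_chrom Genes per chromosome (>= 1).
#' @param cgh_probes_per_gene aCGH probes per gene slot (>= 1).
#' @param promoter_probes_per_gene Promoter probes per gene (>= 1), placed at
#'   distinct offsets in `TSS - 3000 .. TSS + 3000`.
#' @param seed Integer seed; the model is a pure function of its arguments.
#'
#' @return An object of class `genome_model`: a list with elements
#'   `chromosomes` (data frame: `chrom`, `length`), `genes` (data frame:
#'   `gene`, `chrom`, `start`, `end`, `strand`, `tss`; 0-based half-open),
#'   `probes_cgh` (data frame: `probe`, `chrom`, `start`, `end`, sorted by
#'   genome position) and `promoter_probes` (data frame: `probe`, `gene`,
#'   `chrom`, `pos`, `offset`, `gc`).
#' @examples
#' gm <- build_genome_model(2, 20, 5, 4, seed = 1)
#' nrow(gm$probes_cgh)       # 2 * 20 * 5
#' @export
build_genome_model <- function(n_chrom, genes_per_chrom, cgh_probes_per_gene,
                               promoter_probes_per_gene, seed) {
  counts <- c(n_chrom, genes_per_chrom, cgh_probes_per_gene,
              promoter_probes_per_gene)
  if (any(counts < 1) || any(counts != round(counts))) {
    cd_stop("all counts must be positive integers")
  }
  if (promoter_probes_per_gene > 6001) {
    cd_stop("at most 6001 distinct promoter probe offsets fit in TSS +/- 3 kb")
  }
  slot_bp <- 1e6
  gene_len <- 2e4
  chrom_len <- genes_per_chrom * slot_bp

  with_seed(seed, {
    chroms <- data.frame(
      chrom = paste0("chr", seq_len(n_chrom)),
      length = rep(chrom_len, n_chrom),
      stringsAsFactors = FALSE)

    genes_l <- vector("list", n_chrom)
    probes_l <- vector("list", n_chrom)
    prom_l <- vector("list", n_chrom)
    for (ci in seq_len(n_chrom)) {
      cn <- chroms$chrom[ci]
      slot0 <- (seq_len(genes_per_chrom) - 1L) * slot_bp
      start <- slot0 + 2e5
      end <- start + gene_len
      strand <- sample(c("+", "-"), genes_per_chrom, replace = TRUE)
      tss <- ifelse(strand == "+", start, end)
      gid <- sprintf("g%02d_%04d", ci, seq_len(genes_per_chrom))
      genes_l[[ci]] <- data.frame(
        gene = gid, chrom = cn, start = start, end = end,
        strand = strand, tss = tss, stringsAsFactors = FALSE)

      # evenly spaced probes across each gene slot, globally sorted
      frac <- seq(0.05, 0.95, length.out = cgh_probes_per_gene)
      pos <- as.vector(t(outer(slot0, round(frac * slot_bp), `+`)))
      probes_l[[ci]] <- data.frame(
        probe = sprintf("p%02d_%06d", ci, seq_along(pos)),
        chrom = cn, start = pos, end = pos + 60L,  # 60-mer oligo footprint
        stringsAsFactors = FALSE)

      offs <- t(vapply(seq_len(genes_per_chrom), function(i)
        sort(sample(-3000:3000, promoter_probes_per_gene)),
        integer(promoter_probes_per_gene)))
      prom_l[[ci]] <- data.frame(
        probe = sprintf("m%02d_%04d_%02d",
                        ci, rep(seq_len(genes_per_chrom),
                                each = promoter_probes_per_gene),
                        rep(seq_len(promoter_probes_per_gene),
                            genes_per_chrom)),
        gene = rep(gid, each = promoter_probes_per_gene),
        chrom = cn,
        pos = rep(tss, each = promoter_probes_per_gene) + as.vector(t(offs)),
        offset = as.vector(t(offs)),
        gc = round(runif(genes_per_chrom * promoter_probes_per_gene,
                         0.25, 0.75), 4),
        stringsAsFactors = FALSE)
    }

    model <- list(
      chromosomes = chroms,
      genes = do.call(rbind, genes_l),
      probes_cgh = do.call(rbind, probes_l),
      promoter_probes = do.call(rbind, prom_l),
      params = list(n_chrom = n_chrom, genes_per_chrom = genes_per_chrom,
                    cgh_probes_per_gene = cgh_probes_per_gene,
                    promoter_probes_per_gene = promoter_probes_per_gene,
                    slot_bp = slot_bp, seed = seed))
    rownames(model$genes) <- rownames(model$probes_cgh) <-
      rownames(model$promoter_probes) <- NULL
    class(model) <- "genome_model"
    model
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$genes), "genes,", nrow(x$probes_cgh), "aCGH probes,",
      nrow(x$promoter_probes), "promoter probes\n")
  invisible(x)
}
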