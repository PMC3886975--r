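#' Simulate a genome-complexity archetype profile
#'
#' Generates a single-sample aCGH probe track following one of the three
#' genome complexity archetypes used to describe tumor genomes:
#'
#' * `simplex`: a small number of broad, arm-scale gains and losses on an
#'   otherwise quiet genome;
#' * `sawtooth`: many alternating short gain/loss segments spread over the
#'   whole genome (a high state-transition count);
#' * `firestorm`: clusters of narrow, high-level amplifications confined to
#'   one chromosome arm, on a background of few broad changes.
#'
#' @param model A [build_genome_model()] object.
#' @param pattern One of `"simplex"`, `"sawtooth"`, `"firestorm"`.
#' @param noise_sd Gaussian probe noise sd (log2).
#' @param seed Integer seed.
#' @return A `probe_track` whose `sample` id encodes the pattern.
#' @export
simulate_archetype_profile <- function(model,
                                       pattern = c("simplex", "sawtooth",
                                                   "firestorm"),
                                       noise_sd = 0.1, seed = 1) {
  stopifnot(inherits(model, "genome_model"))
  pattern <- match.arg(pattern)
  probes <- model$probes_cgh
  n <- nrow(probes)
  chroms <- model$chromosomes$chrom

  with_seed(seed, {
    state <- rep(0L, n)
    if (pattern == "simplex") {
      # one or two whole-arm events
      for (k in seq_len(sample(1:2, 1))) {
        cn <- sample(chroms, 1)
        ix <- which(probes$chrom == cn)
        half <- if (runif(1) < 0.5) ix[seq_len(length(ix) %/% 2)] else
          ix[(length(ix) %/% 2 + 1):length(ix)]
        state[half] <- sample(c(-1L, 1L), 1)
      }
    } else if (pattern == "sawtooth") {
      # many short segments genome-wide, every boundary a state change
      seg_len <- max(3L, n %/% 70L)
      ix <- 1L
      cur <- 0L
      while (ix <= n) {
        to <- min(n, ix + seg_len - 1L)
        cur <- sample(setdiff(c(-1L, 0L, 1L), cur), 1)
        state[ix:to] <- cur
        ix <- to + 1L
      }
    } else {
      # firestorm: >= 3 focal amplicons (< 10 slots) on one arm
      cn <- sample(chroms, 1)
      ix <- which(probes$chrom == cn)
      arm <- ix[seq_len(length(ix) %/% 2)]
      n_amp <- sample(3:5, 1)
      starts <- sort(sample(seq_len(max(1, length(arm) - 4L)), n_amp))
      # keep amplicons separated by at least one non-AMP probe
      starts <- starts[c(TRUE, diff(starts) > 4L)]
      while (length(starts) < 3L) {
        starts <- sort(unique(c(starts, sample(seq_len(max(1,
          length(arm) - 4L)), 1))))
        starts <- starts[c(TRUE, diff(starts) > 4L)]
      }
      for (s0 in starts) state[arm[s0:min(length(arm), s0 + 2L)]] <- 2L
      # background broad gain elsewhere (multi-chromosome models only)
      if (length(chroms) > 1) {
        other <- which(probes$chrom == sample(setdiff(chroms, cn), 1))
        state[other[seq_len(length(other) %/% 2)]] <- 1L
      }
    }
    vals <- STATE_MEANS[as.character(state)] + rnorm(n, 0, noise_sd)
    probe_track(sample = paste0(pattern, "_", seed),
                probes = data.frame(probes, value = unname(vals),
                                    stringsAsFactors = FALSE))
  })
}
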