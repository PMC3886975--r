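#' Segment an aCGH probe track by recursive binary splitting
#'
#' Within each chromosome, the probe value vector is recursively split at
#' the position maximizing the two-sample z statistic of the flanking
#' segment means,
#' \deqn{z = |m_L - m_R| / (s \sqrt{1/n_L + 1/n_R}),}
#' where `s` is a robust probe-noise estimate for the segment being
#' considered: the median absolute deviation of adjacent-probe differences
#' divided by `sqrt(2)`, which is insensitive to the copy-number structure
#' itself.  A split is accepted iff `z >= z_threshold` and both
#' sides retain at least `min_probes` probes; accepted splits recurse.
#' Segment means are the plain means of member probe values.  A chromosome
#' shorter than `min_probes` yields a single segment.
#'
#' @param track A [probe_track()].
#' @param min_probes Minimum probes per segment (>= 2).
#' @param z_threshold Acceptance threshold for the split statistic.
#' @return A `segmented_profile`: list with `sample` and `segments`
#'   (data frame `chrom`, `start`, `end`, `n_probes`, `mean`, `state`;
#'   `state` is `NA` until [call_states()]).
#' @examples
#' gm <- build_genome_model(1, 10, 10, 2, seed = 1)
#' tr <- simulate_archetype_profile(gm, "simplex", noise_sd = 0.1, seed = 2)
#' segment_sample(tr)
#' @export
segment_sample <- function(track, min_probes = 3, z_threshold = 5) {
  stopifnot(inherits(track, "probe_track"))
  if (min_probes < 2) cd_stop("min_probes must be >= 2")
  pr <- track$probes
  segs <- lapply(split(seq_len(nrow(pr)), pr$chrom), function(ix) {
    v <- pr$value[ix]
    bounds <- binseg_recurse(v, min_probes, z_threshold)
    data.frame(chrom = pr$chrom[ix[1]],
               start = pr$start[ix[bounds$from]],
               end = pr$end[ix[bounds$to]],
               n_probes = bounds$to - bounds$from + 1L,
               mean = bounds$mean,
               state = NA_character_,
               stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs)
  rownames(segs) <- NULL
  structure(list(sample = track$sample, segments = segs),
            class = "segmented_profile")
}

# returns data.frame(from, to, mean) of probe-index segments of v
binseg_recurse <- function(v, min_probes, z_threshold) {
  n <- length(v)
  if (n < 2 * min_probes) {
    return(data.frame(from = 1L, to = n, mean = mean(v)))
  }
  split_at <- best_split(v, min_probes)
  if (is.null(split_at) || split_at$z < z_threshold) {
    return(data.frame(from = 1L, to = n, mean = mean(v)))
  }
  k <- split_at$k
  left <- binseg_recurse(v[1:k], min_probes, z_threshold)
  right <- binseg_recurse(v[(k + 1):n], min_probes, z_threshold)
  right$from <- right$from + k
  right$to <- right$to + k
  rbind(left, right)
}

# best split point k (left = 1..k) maximizing the two-sample z statistic;
# the noise scale is estimated robustly from adjacent-probe differences
# (MAD / sqrt(2)) so genuine copy-number structure does not inflate it
best_split <- function(v, min_probes) {
  n <- length(v)
  ks <- min_probes:(n - min_probes)
  if (!length(ks)) return(NULL)
  cs <- cumsum(v)
  tot <- cs[n]
  m1 <- cs[ks] / ks
  m2 <- (tot - cs[ks]) / (n - ks)
  s <- stats::mad(diff(v)) / sqrt(2)
  if (!is.finite(s) || s < 1e-12) s <- 1e-12
  z <- abs(m1 - m2) / (s * sqrt(1 / ks + 1 / (n - ks)))
  best <- which.max(z)
  list(k = ks[best], z = z[best])
}

#' @export
print.segmented_profile <- function(x, ...) {
  st <- if (all(is.na(x$segments$state))) "uncalled" else "called"
  cat("segmented_profile '", x$sample, "': ", nrow(x$segments),
      " segments (", st, ")\n", sep = "")
  invisible(x)
}

#' Call categorical copy-number states on a segmented profile
#'
#' Thresholds on the segment mean log2 ratio: `mean >= t_amp` is `AMP`,
#' `>= t_gain` is `GAIN`, `<= t_homo` is `HOMO_LOSS`, `<= t_loss` is
#' `HEMI_LOSS`, otherwise `NEUTRAL`.
#'
#' @param profile A `segmented_profile`.
#' @param thresholds Named numeric vector `c(t_gain, t_amp, t_loss, t_homo)`
#'   satisfying `t_homo < t_loss < 0 < t_gain < t_amp`.  Defaults
#'   (0.25, 0.9, -0.25, -0.9) follow conventional two-copy aCGH practice.
#' @return The profile with `state` filled in.
#' @export
call_states <- function(profile,
                        thresholds = c(t_gain = 0.25, t_amp = 0.9,
                                       t_loss = -0.25, t_homo = -0.9)) {
  stopifnot(inherits(profile, "segmented_profile"))
  th <- thresholds
  need <- c("t_gain", "t_amp", "t_loss", "t_homo")
  if (!all(need %in% names(th))) {
    cd_stop("thresholds must be named: ", paste(need, collapse = ", "))
  }
  if (!(th["t_homo"] < th["t_loss"] && th["t_loss"] < 0 &&
        0 < th["t_gain"] && th["t_gain"] < th["t_amp"])) {
    cd_stop("thresholds must satisfy t_homo < t_loss < 0 < t_gain < t_amp")
  }
  m <- profile$segments$mean
  st <- ifelse(m >= th["t_amp"], "AMP",
        ifelse(m >= th["t_gain"], "GAIN",
        ifelse(m <= th["t_homo"], "HOMO_LOSS",
        ifelse(m <= th["t_loss"], "HEMI_LOSS", "NEUTRAL"))))
  profile$segments$state <- st
  profile
}

#' Fraction of probes in altered (non-neutral) segments
#'
#' @param profile A called `segmented_profile`.
#' @return Proportion in `[0, 1]`, weighted by probe counts.
#' @export
fraction_altered <- function(profile) {
  stopifnot(inherits(profile, "segmented_profile"))
  segs <- profile$segments
  if (any(is.na(segs$state))) cd_stop("states not called; run call_states()")
  if (!nrow(segs)) return(0)
  sum(segs$n_probes[segs$state != "NEUTRAL"]) / sum(segs$n_probes)
}

#' Classify a genome profile as simplex, sawtooth or firestorm
#'
#' Heuristic genome-complexity taxonomy: a profile is `complex_firestorm`
#' iff at least one chromosome arm carries `min_focal_amps` (default 3) or
#' more `AMP` segments each shorter than `focal_max_bp` and separated by
#' non-AMP gaps; otherwise `complex_sawtooth` iff the genome-wide count of
#' state transitions between adjacent segments reaches `k_transitions`;
#' otherwise `simplex`.
#'
#' @param profile A called `segmented_profile`.
#' @param k_transitions Sawtooth transition-count threshold (default 40).
#' @param min_focal_amps Minimum focal amplifications on one arm (default 3).
#' @param focal_max_bp Maximum focal amplicon width in bp (default 10 Mb).
#' @param arm_boundaries Optional data frame (`chrom`, `boundary`) giving
#'   the centromere position per chromosome; by default the midpoint of the
#'   chromosome's segment extent is used.
#' @return One of `"simplex"`, `"complex_sawtooth"`, `"complex_firestorm"`.
#' @export
classify_genome_pattern <- function(profile, k_transitions = 40,
                                    min_focal_amps = 3, focal_max_bp = 10e6,
                                    arm_boundaries = NULL) {
  stopifnot(inherits(profile, "segmented_profile"))
  segs <- profile$segments
  if (any(is.na(segs$state))) cd_stop("states not called; run call_states()")

  # firestorm test per arm
  for (cn in unique(segs$chrom)) {
    sc <- segs[segs$chrom == cn, , drop = FALSE]
    bnd <- if (!is.null(arm_boundaries)) {
      arm_boundaries$boundary[match(cn, arm_boundaries$chrom)]
    } else {
      (min(sc$start) + max(sc$end)) / 2
    }
    mid <- (sc$start + sc$end) / 2
    for (arm in list(sc[mid < bnd, , drop = FALSE],
                     sc[mid >= bnd, , drop = FALSE])) {
      if (!nrow(arm)) next
      # contiguous AMP segments form one amplicon; runs must be separated
      # by non-AMP gaps and each narrower than focal_max_bp
      r <- rle(arm$state == "AMP")
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1) + 1L)
      amp_runs <- which(r$values)
      if (length(amp_runs)) {
        widths <- arm$end[ends[amp_runs]] - arm$start[starts[amp_runs]]
        if (sum(widths < focal_max_bp) >= min_focal_amps) {
          return("complex_firestorm")
        }
      }
    }
  }

  transitions <- sum(unlist(lapply(split(segs$state, segs$chrom), function(s)
    if (length(s) < 2) 0L else sum(s[-1] != s[-length(s)]))))
  if (transitions >= k_transitions) return("complex_sawtooth")
  "simplex"
}

#' Per-gene copy-number states for one sample
#'
#' A gene takes the state of the segment containing its midpoint; genes
#' outside probe coverage are `NEUTRAL` and flagged.
#'
#' @param profile A called `segmented_profile`.
#' @param genes Gene annotation data frame (`gene`, `chrom`, `start`, `end`).
#' @return Named character vector of states with a logical attribute
#'   `"covered"`.
#' @export
gene_cna_status <- function(profile, genes) {
  stopifnot(inherits(profile, "segmented_profile"))
  segs <- profile$segments
  if (any(is.na(segs$state))) cd_stop("states not called; run call_states()")
  states <- setNames(rep("NEUTRAL", nrow(genes)), genes$gene)
  covered <- setNames(rep(FALSE, nrow(genes)), genes$gene)
  mid <- (genes$start + genes$end) / 2
  for (cn in unique(genes$chrom)) {
    gi <- which(genes$chrom == cn)
    sc <- segs[segs$chrom == cn, , drop = FALSE]
    if (!nrow(sc)) next
    pos <- findInterval(mid[gi], sc$start)
    ok <- pos >= 1 & pos <= nrow(sc)
    ok[ok] <- mid[gi][ok] < sc$end[pos[ok]]
    states[gi[ok]] <- sc$state[pos[ok]]
    covered[gi[ok]] <- TRUE
  }
  attr(states, "covered") <- covered
  states
}

#' Build a gene-by-sample copy-number state matrix
#'
#' Applies [segment_sample()], [call_states()] and [gene_cna_status()] to a
#' list of probe tracks (or takes already-called profiles).
#'
#' @param tracks Named list of `probe_track`s or of called
#'   `segmented_profile`s.
#' @param genes Gene annotation data frame.
#' @param min_probes,z_threshold,thresholds Passed to the stages when raw
#'   tracks are given.
#' @return A `gene_cna_matrix`: character matrix genes x samples with a
#'   `"covered"` attribute.
#' @export
gene_cna_matrix <- function(tracks, genes, min_probes = 3, z_threshold = 5,
                            thresholds = c(t_gain = 0.25, t_amp = 0.9,
                                           t_loss = -0.25, t_homo = -0.9)) {
  profiles <- lapply(tracks, function(tr) {
    if (inherits(tr, "segmented_profile")) tr
    else call_states(segment_sample(tr, min_probes, z_threshold), thresholds)
  })
  cols <- lapply(profiles, gene_cna_status, genes = genes)
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(profiles, `[[`, "", "sample")
  cov <- do.call(cbind, lapply(cols, attr, "covered"))
  colnames(cov) <- colnames(m)
  structure(m, covered = cov, class = c("gene_cna_matrix", class(m)))
}
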