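#' @useDynLib cnadriver, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fisher.test wilcox.test t.test oneway.test aov TukeyHSD
#'   p.adjust cor sd mad median quantile rnorm runif rbinom hclust as.dist
#'   cutree setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

# Logging goes to stderr so result streams on stdout stay clean.
# Verbosity: getOption("cnadriver.verbose", TRUE); set FALSE to silence.
cd_log <- function(...) {
  if (isTRUE(getOption("cnadriver.verbose", TRUE))) {
    message("[cnadriver] ", ...)
  }
  invisible(NULL)
}

cd_stop <- function(...) stop(..., call. = FALSE)

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive independent substream seeds (< 2^31) from one master seed.
substream_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

SUBTYPES <- c("lumA", "lumB", "basal", "ERBB2", "normal_like")

# Copy-number state vocabulary, ordered for aggregation
CNA_STATES <- c("HOMO_LOSS", "HEMI_LOSS", "NEUTRAL", "GAIN", "AMP")

# Integer copy-state code -> categorical state
state_code_to_category <- function(code) {
  stopifnot(all(code %in% -2:2))
  c("HOMO_LOSS", "HEMI_LOSS", "NEUTRAL", "GAIN", "AMP")[code + 3L]
}

# Expected aCGH segment mean per integer copy state (two-copy genome,
# conventional array response; separable by default calling thresholds)
STATE_MEANS <- c(`-2` = -1.2, `-1` = -0.45, `0` = 0, `1` = 0.45, `2` = 1.2)

# Event definitions used by association screens
match_event <- function(states, event = c("gain_or_amp", "amp_only",
                                          "any_loss", "homo_only")) {
  event <- match.arg(event)
  switch(event,
    gain_or_amp = states %in% c("GAIN", "AMP"),
    amp_only    = states == "AMP",
    any_loss    = states %in% c("HEMI_LOSS", "HOMO_LOSS"),
    homo_only   = states == "HOMO_LOSS")
}

event_sign <- function(event) {
  if (event %in% c("gain_or_amp", "amp_only")) 1 else -1
}

# Sample odds ratio for a 2x2 table (a,b,c,d = event/target, no-event/target,
# event/comparator, no-event/comparator), Haldane 0.5 correction on zeros.
sample_odds_ratio <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

# Welch t test that tolerates constant groups (contract: both constant and
# equal -> p = 1; constant but unequal -> p = 0, complete separation).
safe_welch <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  if ((is.na(vx) || vx == 0) && (is.na(vy) || vy == 0)) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(statistic = 0, p.value = 1, diff = 0))
    }
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, p.value = 0,
                diff = mean(x) - mean(y)))
  }
  tt <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
  if (is.null(tt)) {
    return(list(statistic = NA_real_, p.value = 1, diff = mean(x) - mean(y)))
  }
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       diff = mean(x) - mean(y))
}
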