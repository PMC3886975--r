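## I/O for every external format the pipeline touches.
## Internal coordinates are 0-based half-open throughout; disk dialects are
## declared per format (aCGH probe tables and SEG files are 1-based
## inclusive on disk), so conversions happen in exactly one place.

#' Probe track constructor
#'
#' @param sample Sample identifier.
#' @param probes Data frame with columns `probe`, `chrom`, `start`, `end`,
#'   `value` (log2 ratio); coordinates 0-based half-open.  Rows are sorted
#'   by `(chrom, start)` on construction.
#' @return A `probe_track` object.
#' @export
probe_track <- function(sample, probes) {
  need <- c("probe", "chrom", "start", "end", "value")
  if (!all(need %in% names(probes))) {
    cd_stop("probe track needs columns: ", paste(need, collapse = ", "))
  }
  ord <- order(probes$chrom, probes$start)
  if (any(ord != seq_along(ord))) {
    probes <- probes[ord, , drop = FALSE]
  }
  rownames(probes) <- NULL
  structure(list(sample = sample, probes = probes[, need]),
            class = "probe_track")
}

#' @export
print.probe_track <- function(x, ...) {
  cat("probe_track '", x$sample, "': ", nrow(x$probes), " probes on ",
      length(unique(x$probes$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

to_internal <- function(start, dialect) {
  if (dialect == "1-based inclusive") start - 1L else start
}
to_disk <- function(start, dialect) {
  if (dialect == "1-based inclusive") start + 1L else start
}

#' Read a probe-level aCGH log2-ratio table
#'
#' Expects a TSV with header columns `probe`, `chrom`, `start`, `end`
#' followed by one column of log2 ratios per sample.  Rows with a missing
#' ratio are dropped per sample (the count is logged); unsorted input is
#' sorted with a warning.
#'
#' @param path Input file.
#' @param dialect Coordinate convention of the file, `"1-based inclusive"`
#'   (default) or `"0-based half-open"`.
#' @return A named list of [probe_track()] objects, one per sample column.
#' @export
read_probe_table <- function(path,
                             dialect = c("1-based inclusive",
                                         "0-based half-open")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) cd_stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probe", "chrom", "start", "end")
  if (!all(need %in% names(df))) {
    cd_stop("probe table must declare columns: ",
            paste(need, collapse = ", "))
  }
  sample_cols <- setdiff(names(df), need)
  if (!length(sample_cols)) cd_stop("probe table has no sample columns")
  for (col in c("start", "end", sample_cols)) {
    v <- df[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !(is.na(v) | v %in% c("NA", "NaN", "")))
      if (length(bad)) {
        cd_stop("malformed value in column '", col, "' at line ",
                bad[1] + 1L, " of ", path)
      }
      df[[col]] <- conv
    }
  }
  if (anyNA(df$start) || anyNA(df$end)) {
    cd_stop("missing coordinates in ", path)
  }
  df$start <- to_internal(df$start, dialect)
  ord <- order(df$chrom, df$start)
  if (any(ord != seq_along(ord))) {
    warning("probe table not sorted by genome position; sorting", call. = FALSE)
    df <- df[ord, , drop = FALSE]
  }
  out <- lapply(sample_cols, function(s) {
    keep <- is.finite(df[[s]])
    n_drop <- sum(!keep)
    if (n_drop > 0) {
      cd_log("sample ", s, ": dropped ", n_drop, " probes with missing values")
    }
    probe_track(sample = s,
                probes = data.frame(probe = df$probe[keep],
                                    chrom = df$chrom[keep],
                                    start = df$start[keep],
                                    end = df$end[keep],
                                    value = df[[s]][keep],
                                    stringsAsFactors = FALSE))
  })
  names(out) <- sample_cols
  out
}

#' Write probe tracks as a TSV probe table
#'
#' Inverse of [read_probe_table()]; all tracks must share one probe grid.
#'
#' @param tracks A `probe_track` or list of them.
#' @param path Output file.
#' @param dialect On-disk coordinate convention.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(tracks, path,
                              dialect = c("1-based inclusive",
                                          "0-based half-open")) {
  dialect <- match.arg(dialect)
  if (inherits(tracks, "probe_track")) tracks <- list(tracks)
  base <- tracks[[1]]$probes[, c("probe", "chrom", "start", "end")]
  out <- base
  out$start <- to_disk(out$start, dialect)
  for (tr in tracks) {
    stopifnot(identical(tr$probes$probe, base$probe))
    out[[tr$sample]] <- tr$probes$value
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled omics matrix from TSV
#'
#' First column = row labels (genes or probes), header = sample ids.
#' Mutation matrices are validated to be strictly binary.
#'
#' @param path Input file.
#' @param kind One of `"expression"`, `"methylation"`, `"mutation"`.
#' @return A numeric (or integer 0/1 for mutations) matrix with dimnames.
#' @export
read_matrix <- function(path, kind = c("expression", "methylation",
                                       "mutation")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) cd_stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) cd_stop("empty file: ", path)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (length(unique(nfield)) != 1) {
    cd_stop("ragged rows in ", path, " (line ",
            which(nfield != nfield[1])[1], ")")
  }
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   row.names = NULL)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    cd_stop("duplicate row ids in ", path, ": ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cols <- names(df)[-1]
  if (anyDuplicated(cols)) {
    cd_stop("duplicate column ids in ", path, ": ",
            paste(unique(cols[duplicated(cols)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  dimnames(m) <- list(ids, cols)
  if (kind == "mutation") {
    bad <- which(matrix(!(m %in% c(0, 1)), nrow(m)), arr.ind = TRUE)
    if (nrow(bad)) {
      cd_stop("non-binary mutation entry '", m[bad[1, 1], bad[1, 2]],
              "' at gene ", ids[bad[1, 1]], ", sample ", cols[bad[1, 2]])
    }
    mode(m) <- "integer"
  }
  m
}

#' Write a labelled matrix as TSV
#'
#' @param m Matrix with row and column names.
#' @param path Output file.
#' @param id_col Name of the leading label column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' TSV with columns `sample`, `subtype`, `ER`, `PR`, `grade`, `tissue`.
#' Tumor subtypes must be among lumA/lumB/basal/ERBB2/normal_like;
#' normal-breast samples carry subtype NA.  Missing values are encoded
#' `"NA"`, never the empty string.
#'
#' @param path Input file.
#' @return A data frame.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) cd_stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("sample", "subtype", "tissue")
  if (!all(need %in% names(df))) {
    cd_stop("annotation must declare columns: ", paste(need, collapse = ", "))
  }
  tum <- df$tissue == "tumor"
  bad <- !is.na(df$subtype) & !df$subtype %in% SUBTYPES
  if (any(bad)) {
    cd_stop("unknown subtype label(s): ",
            paste(unique(df$subtype[bad]), collapse = ", "))
  }
  if (any(!tum & !is.na(df$subtype))) {
    cd_stop("normal-breast samples must not carry a subtype")
  }
  if (any(tum & is.na(df$subtype))) {
    cd_stop("tumor samples must carry a subtype")
  }
  df
}

#' @rdname read_annotation
#' @param annotation Data frame as returned by [read_annotation()].
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Assemble and validate an omics cohort from its layers
#'
#' Checks that sample ids are consistent across all supplied layers (every
#' matrix column must be annotated) and that gene ids are unique.
#'
#' @param annotation Sample annotation data frame.
#' @param expression,methylation,mutations Optional matrices (columns =
#'   samples).
#' @param promoter_map Optional probe-to-promoter map (data frame with
#'   `probe`, `gene`, `gc`).
#' @param normal_methylation Optional matrix of normal-breast references.
#' @return An `omics_cohort` object.
#' @export
assemble_cohort <- function(annotation, expression = NULL,
                            methylation = NULL, mutations = NULL,
                            promoter_map = NULL, normal_methylation = NULL) {
  for (nm in c("expression", "methylation", "mutations")) {
    m <- get(nm)
    if (is.null(m)) next
    orphan <- setdiff(colnames(m), annotation$sample)
    if (length(orphan)) {
      cd_stop(nm, " columns absent from annotation: ",
              paste(orphan, collapse = ", "))
    }
  }
  if (!is.null(methylation) && is.null(promoter_map)) {
    cd_stop("methylation layer requires a promoter_map")
  }
  structure(list(cgh = NULL, expression = expression,
                 methylation = methylation,
                 normal_methylation = normal_methylation,
                 promoter_map = promoter_map, mutations = mutations,
                 annotation = annotation, genes = NULL),
            class = "omics_cohort")
}

#' Write segments in IGV SEG format
#'
#' Standard SEG columns (sample, chrom, start, end, number of probes,
#' segment mean), 1-based inclusive on disk.  An empty profile yields a
#' header-only file.
#'
#' @param profiles A `segmented_profile` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_seg <- function(profiles, path) {
  if (inherits(profiles, "segmented_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    if (!nrow(p$segments)) return(NULL)
    data.frame(Sample = p$sample,
               Chromosome = p$segments$chrom,
               Start = to_disk(p$segments$start, "1-based inclusive"),
               End = p$segments$end,
               Num_Probes = p$segments$n_probes,
               Segment_Mean = p$segments$mean,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(Sample = character(), Chromosome = character(),
                      Start = integer(), End = integer(),
                      Num_Probes = integer(), Segment_Mean = numeric())
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an IGV SEG file into segment data frames
#'
#' @param path Input SEG file (1-based inclusive on disk).
#' @return A named list (by sample) of data frames with internal 0-based
#'   half-open coordinates: `chrom`, `start`, `end`, `n_probes`, `mean`.
#' @export
read_seg <- function(path) {
  if (!file.exists(path)) cd_stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) return(list())
  out <- split(data.frame(chrom = df$Chromosome,
                          start = to_internal(df$Start, "1-based inclusive"),
                          end = df$End,
                          n_probes = df$Num_Probes,
                          mean = df$Segment_Mean,
                          stringsAsFactors = FALSE),
               df$Sample)
  lapply(out, function(x) { rownames(x) <- NULL; x })
}

#' Read a MAF-lite mutation table into a binary matrix
#'
#' MAF-lite is a TSV with columns `sample`, `gene` and optionally
#' `class`; one row per mutation call.
#'
#' @param path Input file.
#' @param samples,genes Optional universes fixing matrix dimensions (ids not
#'   observed in the file become zero rows/columns).
#' @return Integer 0/1 matrix, genes x samples.
#' @export
read_maf_lite <- function(path, samples = NULL, genes = NULL) {
  if (!file.exists(path)) cd_stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "gene") %in% names(df))) {
    cd_stop("MAF-lite must declare columns: sample, gene")
  }
  if (is.null(samples)) samples <- sort(unique(df$sample))
  if (is.null(genes)) genes <- sort(unique(df$gene))
  orphan <- setdiff(df$sample, samples)
  if (length(orphan)) {
    cd_stop("MAF-lite samples absent from sample universe: ",
            paste(orphan, collapse = ", "))
  }
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  keep <- df$gene %in% genes
  m[cbind(match(df$gene[keep], genes), match(df$sample[keep], samples))] <- 1L
  m
}

#' Write a binary mutation matrix as MAF-lite
#'
#' @param m Binary genes x samples matrix.
#' @param path Output file.
#' @param class Mutation class recorded for every call.
#' @return `path`, invisibly.
#' @export
write_maf_lite <- function(m, path, class = "somatic") {
  hit <- which(m == 1L, arr.ind = TRUE)
  df <- data.frame(sample = colnames(m)[hit[, 2]],
                   gene = rownames(m)[hit[, 1]],
                   class = class, stringsAsFactors = FALSE)
  df <- df[order(df$sample, df$gene), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a directory of plain-text files
#'
#' Emits the same formats the readers consume: probe table TSV, expression /
#' methylation matrices, MAF-lite mutations, annotation TSV, promoter map
#' TSV and ground-truth JSON (when given).
#'
#' @param cohort An `omics_cohort`.
#' @param dir Output directory (created if missing).
#' @param truth Optional `ground_truth` to serialize alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort$cgh)) {
    write_probe_table(cohort$cgh, file.path(dir, "acgh_probes.tsv"))
  }
  if (!is.null(cohort$expression)) {
    write_matrix(cohort$expression, file.path(dir, "expression.tsv"), "gene")
  }
  if (!is.null(cohort$methylation)) {
    write_matrix(cohort$methylation, file.path(dir, "methylation_m.tsv"),
                 "probe")
    write.table(cohort$promoter_map, file.path(dir, "promoter_map.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cohort$normal_methylation)) {
    write_matrix(cohort$normal_methylation,
                 file.path(dir, "methylation_m_normal.tsv"), "probe")
  }
  if (!is.null(cohort$mutations)) {
    write_maf_lite(cohort$mutations, file.path(dir, "mutations.maf.tsv"))
  }
  write_annotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  if (!is.null(truth)) write_ground_truth(truth, file.path(dir, "truth.json"))
  invisible(dir)
}
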