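#' Build a frequency dataset from a mutation table
#'
#' The central input container: one row per somatic mutation with read counts
#' and the frequency value used for fitting. Frequencies must lie in `[0, 1]`;
#' cancer cell fractions (CCF) are halved on input (see [adjust_ccf()]) so that
#' a clonal diploid-heterozygous mutation sits at 0.5, like a VAF. Records with
#' missing frequency are dropped with a message; frequencies exactly 0 or 1 are
#' excluded before fitting because the Beta and Pareto densities live on the
#' open interval.
#'
#' @param df Data frame with (some of) the columns `chrom`, `pos`, `ref`,
#'   `alt`, `depth`, `alt_reads`, `vaf`, `ccf`, `id`. If `vaf` is missing it is
#'   computed as `alt_reads / depth`. Missing ids are generated.
#' @param frequency_kind `"VAF"` or `"CCF"`. For `"CCF"` the `ccf` column is
#'   halved to give the fitted frequency (recorded as kind `"CCF_halved"`).
#' @param min_frequency Lower analysis cutoff already applied (bookkeeping
#'   only; use [filter_dataset()] to filter).
#'
#' @return An object of class `sfs_data`: a list with `data` (the validated
#'   data frame including a `frequency` column), `frequency_kind`, `n`,
#'   `min_frequency` and `n_dropped_na`.
#' @export
freq_dataset <- function(df, frequency_kind = c("VAF", "CCF"),
                         min_frequency = 0) {
  frequency_kind <- match.arg(frequency_kind)
  df <- as.data.frame(df, stringsAsFactors = FALSE)

  if (is.null(df$id))
    df$id <- if (nrow(df) == 0) character(0)
             else paste0("m", seq_len(nrow(df)))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("mutation ids must be unique", call. = FALSE)

  has_counts <- !is.null(df$depth) && !is.null(df$alt_reads)
  if (has_counts) {
    df$depth <- as.integer(df$depth)
    df$alt_reads <- as.integer(df$alt_reads)
    bad <- which(!is.na(df$depth) & !is.na(df$alt_reads) &
                   df$alt_reads > df$depth)
    if (length(bad))
      stop("alt_reads exceeds depth for record(s): ",
           paste(df$id[bad], collapse = ", "), call. = FALSE)
    if (is.null(df$vaf)) {
      df$vaf <- ifelse(!is.na(df$depth) & df$depth > 0,
                       df$alt_reads / df$depth, NA_real_)
    } else {
      df$vaf <- as.numeric(df$vaf)
      chk <- which(!is.na(df$vaf) & !is.na(df$depth) & df$depth > 0 &
                     abs(df$vaf - df$alt_reads / df$depth) > 1e-9)
      if (length(chk))
        stop("vaf does not equal alt_reads/depth for record(s): ",
             paste(df$id[chk], collapse = ", "), call. = FALSE)
    }
  }
  if (frequency_kind == "VAF") {
    if (is.null(df$vaf))
      stop("need a 'vaf' column or 'depth' + 'alt_reads' columns",
           call. = FALSE)
    df$frequency <- as.numeric(df$vaf)
    kind <- "VAF"
  } else {
    if (is.null(df$ccf))
      stop("frequency_kind = 'CCF' needs a 'ccf' column", call. = FALSE)
    df$frequency <- adjust_ccf(as.numeric(df$ccf), ids = df$id)
    kind <- "CCF_halved"
  }

  n_na <- sum(is.na(df$frequency))
  if (n_na > 0) {
    message(n_na, " record(s) with missing frequency dropped")
    df <- df[!is.na(df$frequency), , drop = FALSE]
  }
  out_of_range <- which(df$frequency < 0 | df$frequency > 1)
  if (length(out_of_range))
    stop("frequency outside [0,1] for record(s): ",
         paste(df$id[out_of_range], collapse = ", "), call. = FALSE)

  structure(
    list(data = df, frequency_kind = kind, n = nrow(df),
         min_frequency = min_frequency, n_dropped_na = n_na),
    class = "sfs_data"
  )
}

#' @export
print.sfs_data <- function(x, ...) {
  cat("<sfs_data> ", x$n, " mutations (", x$frequency_kind,
      "), min frequency cutoff ", format(x$min_frequency), "\n", sep = "")
  if (x$n > 0)
    cat("  frequency range: ",
        paste(format(range(x$data$frequency), digits = 4), collapse = " - "),
        "\n", sep = "")
  invisible(x)
}

#' Halve cancer cell fraction estimates
#'
#' CCF values of clonal mutations centre on 1 (they are present in 100% of
#' cancer cells), so they are divided by two to fit on the same `[0, 1]` scale
#' as VAFs: the halved value is the expected allele frequency of a clonal
#' diploid-heterozygous mutation in a pure sample. Raw values in `(1, 2]`
#' (multi-copy states) are legal; values above 2 are not representable and are
#' rejected.
#'
#' @param raw_ccf Numeric vector of raw CCF values, each `>= 0`.
#' @param ids Optional record ids used in error messages.
#' @return `raw_ccf / 2`.
#' @export
#'
#' @examples
#' adjust_ccf(1) # clonal -> 0.5
adjust_ccf <- function(raw_ccf, ids = NULL) {
  if (is.null(ids)) ids <- seq_along(raw_ccf)
  neg <- which(!is.na(raw_ccf) & raw_ccf < 0)
  if (length(neg))
    stop("negative CCF for record(s): ", paste(ids[neg], collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(raw_ccf) & raw_ccf / 2 > 1)
  if (length(bad))
    stop("CCF > 2 is not representable after halving; record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  raw_ccf / 2
}

default_column_map <- function() {
  list(chrom = "chr", pos = "from", ref = "ref", alt = "alt",
       depth = "DP", alt_reads = "NV", vaf = "VAF", id = "id", ccf = "CCF")
}

#' Read a delimited mutation table
#'
#' Reads a TSV or CSV of somatic mutations (the separator is sniffed from the
#' header line) and maps its columns onto the canonical fields via
#' `column_map`. Either a VAF column or depth + variant-read-count columns must
#' be mappable; missing optional columns are tolerated.
#'
#' @param path Path to the file.
#' @param column_map Named list mapping canonical names (`chrom`, `pos`,
#'   `ref`, `alt`, `depth`, `alt_reads`, `vaf`, `ccf`, `id`) to the file's
#'   column names. Defaults: `chr`, `from`, `ref`, `alt`, `DP`, `NV`, `VAF`.
#' @param frequency_kind `"VAF"` or `"CCF"`.
#' @return An [freq_dataset()] object.
#' @export
read_freq_table <- function(path, column_map = default_column_map(),
                            frequency_kind = c("VAF", "CCF")) {
  frequency_kind <- match.arg(frequency_kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  cmap <- utils::modifyList(default_column_map(), as.list(column_map))

  required <- if (frequency_kind == "CCF") "ccf"
              else if (cmap$vaf %in% names(raw)) "vaf"
              else c("depth", "alt_reads")
  for (field in required) {
    if (!cmap[[field]] %in% names(raw))
      stop("required column '", cmap[[field]], "' (", field,
           ") not found in ", path, call. = FALSE)
  }
  cols <- list()
  for (field in names(cmap)) {
    if (cmap[[field]] %in% names(raw)) cols[[field]] <- raw[[cmap[[field]]]]
  }
  if (length(cols) == 0)
    stop("no mappable columns found in ", path, call. = FALSE)
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  freq_dataset(df, frequency_kind = frequency_kind)
}

#' Write a mutation table (optionally with cluster assignments)
#'
#' Writes the dataset as TSV using the default column names, so the output
#' round-trips through [read_freq_table()]. When a fitted model is supplied, a
#' `cluster` column with hard assignments is appended.
#'
#' @param d An `sfs_data` object.
#' @param path Output path.
#' @param model Optional fitted `sfs_model` for the same dataset.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(d, path, model = NULL) {
  stopifnot(inherits(d, "sfs_data"))
  df <- d$data
  out <- data.frame(id = df$id, stringsAsFactors = FALSE)
  if (!is.null(df$chrom)) out$chr <- df$chrom
  if (!is.null(df$pos)) out$from <- df$pos
  if (!is.null(df$ref)) out$ref <- df$ref
  if (!is.null(df$alt)) out$alt <- df$alt
  if (!is.null(df$depth)) out$DP <- df$depth
  if (!is.null(df$alt_reads)) out$NV <- df$alt_reads
  out$VAF <- df$frequency
  if (!is.null(model)) {
    stopifnot(inherits(model, "sfs_model"))
    if (model$n != d$n)
      stop("model was fitted on a dataset of different size", call. = FALSE)
    out$cluster <- model$assignments
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read somatic mutations from a VCF
#'
#' Extracts per-sample depth and allelic depth from the FORMAT fields of a
#' VCF 4.x file (AD for allelic depths; DP for depth, falling back to the sum
#' of AD). One record is produced per biallelic variant row; multiallelic rows
#' are skipped (or split into one record per alternate allele) with a logged
#' count. Records with zero depth are dropped with a warning.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @param sample Sample name; defaults to the only sample if there is one.
#' @param multiallelic `"skip"` (default) or `"split"`.
#' @return An [freq_dataset()] object with `frequency_kind = "VAF"`.
#' @export
read_freq_vcf <- function(path, sample = NULL,
                          multiallelic = c("skip", "split")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  if (is.null(sample)) {
    if (length(samples) != 1)
      stop("specify one of the samples: ", paste(samples, collapse = ", "),
           call. = FALSE)
    sample <- samples
  }
  if (!sample %in% samples)
    stop("sample '", sample, "' not in VCF; available: ",
         paste(samples, collapse = ", "), call. = FALSE)

  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if (!"AD" %in% fmt_keys)
    stop("VCF FORMAT lacks the 'AD' (allelic depth) field", call. = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")[, sample]
  dp <- if ("DP" %in% fmt_keys)
    suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, sample]))
  else rep(NA_integer_, length(ad))

  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  n_multi <- sum(multi)

  rows <- list()
  for (i in seq_along(ad)) {
    alts <- strsplit(fix$ALT[i], ",")[[1]]
    counts <- suppressWarnings(as.integer(strsplit(ad[i], ",")[[1]]))
    if (length(alts) > 1 && multiallelic == "skip") next
    take <- if (length(alts) > 1) seq_along(alts) else 1L
    for (j in take) {
      altr <- counts[j + 1L]
      depth <- if (!is.na(dp[i])) dp[i] else sum(counts, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[j],
        depth = depth, alt_reads = altr, stringsAsFactors = FALSE)
    }
  }
  if (n_multi > 0 && multiallelic == "skip")
    message(n_multi, " multiallelic row(s) skipped")
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0)
    stop("no usable variant rows in ", path, call. = FALSE)
  zero <- which(is.na(df$depth) | df$depth == 0)
  if (length(zero)) {
    warning(length(zero), " record(s) with zero depth dropped", call. = FALSE)
    df <- df[-zero, , drop = FALSE]
  }
  df$id <- paste0(df$chrom, ":", df$pos, ":", df$ref, ">", df$alt)
  freq_dataset(df, frequency_kind = "VAF")
}

#' Filter a dataset on a frequency cutoff
#'
#' Retains mutations with frequency strictly above `min_vaf` and strictly
#' below 1 ("above 5%" is read as a strict inequality). Filtering is
#' idempotent.
#'
#' @param d An `sfs_data` object.
#' @param min_vaf Cutoff in `[0, 1)`; default 0.05.
#' @return The filtered `sfs_data`, with `min_frequency` updated.
#' @export
filter_dataset <- function(d, min_vaf = 0.05) {
  stopifnot(inherits(d, "sfs_data"), min_vaf >= 0, min_vaf < 1)
  keep <- d$data$frequency > min_vaf & d$data$frequency < 1
  n_drop <- sum(!keep)
  if (all(!keep))
    stop("no mutations above the cutoff ", min_vaf,
         "; lower the cutoff", call. = FALSE)
  if (n_drop > 0)
    message(n_drop, " of ", d$n, " mutation(s) removed at cutoff ", min_vaf)
  out <- d
  out$data <- d$data[keep, , drop = FALSE]
  out$n <- nrow(out$data)
  out$min_frequency <- max(d$min_frequency, min_vaf)
  out
}

# internal: dataset straight from a frequency vector (simulator, sampling)
freq_dataset_from_values <- function(freq, frequency_kind = "VAF",
                                     ids = NULL, min_frequency = 0) {
  df <- data.frame(vaf = freq, stringsAsFactors = FALSE)
  if (!is.null(ids)) df$id <- ids
  freq_dataset(df, frequency_kind = "VAF", min_frequency = min_frequency)
}
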