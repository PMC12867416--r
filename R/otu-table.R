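#' OTU count table
#'
#' The universal input of the pipeline: a samples x OTUs matrix of
#' non-negative integer read counts with unique sample and OTU identifiers,
#' optionally carrying a taxonomy lineage string per OTU.
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns. Must have
#'   unique, non-empty rownames (sample ids) and colnames (OTU ids), and only
#'   non-negative whole numbers.
#' @param taxonomy optional named character vector mapping OTU id to a
#'   lineage string; names must be a subset of the OTU ids.
#' @return an object of class `otu_table`.
#' @examples
#' m <- matrix(c(5, 0, 1, 3), 2, 2, byrow = TRUE,
#'             dimnames = list(c("S1", "S2"), c("OTU1", "OTU2")))
#' otu_table(m)
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    abort("`counts` must be a numeric matrix (samples x OTUs)")
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    abort("empty count matrix: need at least one sample and one OTU")
  sn <- rownames(counts); on <- colnames(counts)
  if (is.null(sn) || anyNA(sn) || any(sn == ""))
    abort("`counts` must have sample ids as rownames")
  if (is.null(on) || anyNA(on) || any(on == ""))
    abort("`counts` must have OTU ids as colnames")
  if (anyDuplicated(sn)) abort("duplicate sample ids: ", fmt_ids(sn[duplicated(sn)]))
  if (anyDuplicated(on)) abort("duplicate OTU ids: ", fmt_ids(on[duplicated(on)]))
  if (anyNA(counts) || any(!is.finite(counts))) abort("counts contain NA/non-finite values")
  if (any(counts < 0)) abort("counts contain negative entries")
  if (any(abs(counts - round(counts)) > 1e-8)) abort("counts must be whole numbers")
  counts <- round(counts)
  storage.mode(counts) <- "double"
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)) || !all(names(taxonomy) %in% on))
      abort("taxonomy names must be OTU ids present in the table")
    taxonomy <- taxonomy[intersect(on, names(taxonomy))]
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs\n")
  cat("  total reads:", sum(x$counts),
      "| depth range:", paste(range(rowSums(x$counts)), collapse = "-"), "\n")
  if (!is.null(x$taxonomy)) cat("  taxonomy for", length(x$taxonomy), "OTUs\n")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Accessors for `otu_table`
#' @param x an `otu_table`.
#' @return `sample_ids()`/`otu_ids()` return character vectors;
#'   `otu_counts()` the samples x OTUs count matrix.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname sample_ids
#' @export
otu_ids <- function(x) colnames(x$counts)

#' @rdname sample_ids
#' @export
otu_counts <- function(x) x$counts

subset_table <- function(x, samples = NULL, otus = NULL) {
  m <- x$counts
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  if (!is.null(otus)) m <- m[, otus, drop = FALSE]
  tax <- x$taxonomy
  if (!is.null(tax)) tax <- tax[names(tax) %in% colnames(m)]
  if (nrow(m) == 0L)
    return(structure(list(counts = m, taxonomy = tax), class = "otu_table"))
  otu_table(m, tax)
}

#' Read an OTU table from disk
#'
#' Two dialects are supported: `tsv_wide`, the common wide export with one
#' identifier column and a header of ids (orientation auto-detected when
#' sample metadata is supplied, defaulting to OTUs-as-rows), and `biom_json`
#' (BIOM format version 1.0; requires the biomformat package).
#'
#' @param path file path.
#' @param format `"tsv_wide"` or `"biom_json"`.
#' @param metadata optional data frame with a `sample_id` column, used to
#'   auto-detect orientation of a wide TSV by id overlap.
#' @param orientation `"auto"` (default), or an explicit override:
#'   `"otus_as_rows"` / `"samples_as_rows"`.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path, format = c("tsv_wide", "biom_json"),
                           metadata = NULL,
                           orientation = c("auto", "otus_as_rows", "samples_as_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort("file not found: ", path)
  if (format == "biom_json") return(read_biom_json(path))

  df <- tryCatch(read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
                 error = function(e) abort("malformed TSV '", path, "': ", conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 2L)
    abort("empty data section in '", path, "': need an id column plus counts")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    abort("duplicate ids in first column of '", path, "': ", fmt_ids(ids[duplicated(ids)]))
  num <- df[, -1L, drop = FALSE]
  bad <- names(num)[!vapply(num, is.numeric, logical(1))]
  if (length(bad) > 0)
    abort("non-numeric count column(s) in '", path, "': ", fmt_ids(bad))
  m <- as.matrix(num)
  rownames(m) <- ids

  rows_are_otus <- switch(orientation,
    otus_as_rows = TRUE,
    samples_as_rows = FALSE,
    auto = {
      if (!is.null(metadata)) {
        meta_ids <- as.character(metadata$sample_id)
        row_hits <- mean(rownames(m) %in% meta_ids)
        col_hits <- mean(colnames(m) %in% meta_ids)
        col_hits >= row_hits  # sample ids in header => OTUs are rows
      } else TRUE
    })
  if (rows_are_otus) m <- t(m)
  otu_table(m)
}

read_biom_json <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    abort("reading BIOM files requires the 'biomformat' package")
  b <- tryCatch(biomformat::read_biom(path),
                error = function(e) abort("malformed BIOM file '", path, "': ", conditionMessage(e)))
  m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
  tax <- NULL
  om <- tryCatch(suppressWarnings(biomformat::observation_metadata(b)),
                 error = function(e) NULL)
  if (!is.null(om) && length(om) > 0) {
    if (is.data.frame(om)) {
      tax <- apply(om, 1L, function(r) paste(r[!is.na(r) & r != ""], collapse = "; "))
    } else if (is.list(om)) {
      tax <- vapply(om, function(r) paste(unlist(r), collapse = "; "), character(1))
    }
    if (!is.null(tax)) names(tax) <- rownames(m)
  }
  otu_table(t(m), taxonomy = tax)
}

#' Write an OTU table as wide TSV (OTUs as rows)
#'
#' Deterministic row/column order; round-trips exactly through
#' [read_otu_table()].
#'
#' @param x an `otu_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(otu_id = otu_ids(x), t(x$counts), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a TSV with at least `sample_id` and `condition` columns
#' (`condition` must be `"case"` or `"control"`); `cohort` and `timepoint`
#' are carried through when present. Every sample id must be unique.
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("metadata missing column(s): ", fmt_ids(miss))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    abort("duplicate sample_id in metadata: ", fmt_ids(df$sample_id[duplicated(df$sample_id)]))
  bad <- setdiff(unique(df$condition), c("case", "control"))
  if (length(bad)) abort("condition must be 'case' or 'control'; found: ", fmt_ids(bad))
  df
}

#' Filtering thresholds for samples and OTUs
#'
#' Defaults follow common 16S practice for association networks: samples
#' sequenced below 10,000 reads are excluded, and OTUs present in fewer than
#' 10% of samples or with mean relative abundance below 5e-5 are removed.
#' Prevalence counts strictly positive entries and both OTU thresholds are
#' exclusive (`<`), so an OTU exactly at a threshold is kept.
#'
#' @param min_depth minimum per-sample read count (inclusive).
#' @param min_prevalence minimum fraction of samples with a positive count.
#' @param min_mean_rel_abundance minimum mean per-sample relative abundance.
#' @return a `filter_spec` object.
#' @export
filter_spec <- function(min_depth = 10000, min_prevalence = 0.10,
                        min_mean_rel_abundance = 0.00005) {
  stopifnot(min_depth >= 0, min_prevalence >= 0, min_prevalence <= 1,
            min_mean_rel_abundance >= 0)
  structure(list(min_depth = min_depth, min_prevalence = min_prevalence,
                 min_mean_rel_abundance = min_mean_rel_abundance),
            class = "filter_spec")
}

#' Remove shallowly sequenced samples
#'
#' Drops samples whose total read count is strictly below `min_depth`
#' ("sequencing depth below N excluded"): a sample exactly at the threshold
#' is kept. Sample order is preserved; the result may be empty.
#'
#' @param x an `otu_table`.
#' @param min_depth inclusive minimum row sum.
#' @return an `otu_table`.
#' @export
filter_samples_by_depth <- function(x, min_depth = 10000) {
  stopifnot(inherits(x, "otu_table"), is.numeric(min_depth), min_depth >= 0)
  keep <- rowSums(x$counts) >= min_depth
  subset_table(x, samples = which(keep))
}

#' Filter OTUs by prevalence and mean relative abundance
#'
#' An OTU is removed iff its prevalence (fraction of samples with a positive
#' count) is `< min_prevalence` OR its mean per-sample relative abundance is
#' `< min_mean_rel_abundance`. Column order is preserved. Idempotent.
#'
#' @param x an `otu_table` (all samples must have positive depth).
#' @param spec a [filter_spec()].
#' @return an `otu_table`.
#' @export
filter_otus <- function(x, spec = filter_spec()) {
  stopifnot(inherits(x, "otu_table"), inherits(spec, "filter_spec"))
  prevalence <- colMeans(x$counts > 0)
  mean_rel <- colMeans(relative_abundance(x))
  drop <- prevalence < spec$min_prevalence | mean_rel < spec$min_mean_rel_abundance
  if (all(drop)) abort("empty feature set: every OTU removed by the filter")
  subset_table(x, otus = which(!drop))
}

#' Per-sample relative abundance
#'
#' @param x an `otu_table`.
#' @return samples x OTUs matrix of fractions; each row sums to 1.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  depth <- rowSums(x$counts)
  if (any(depth == 0))
    abort("zero-depth sample(s): ", fmt_ids(sample_ids(x)[depth == 0]))
  x$counts / depth
}

#' Centered log-ratio transform
#'
#' Maps compositional counts to an unconstrained scale:
#' `clr_i = log(x_i + delta) - mean_j log(x_j + delta)` per sample. The
#' half-count pseudocount `delta = 0.5` keeps zeros finite. Each row of the
#' result sums to 0 (within numerical tolerance) and the transform is
#' invariant to rescaling a sample's composition.
#'
#' @param x an `otu_table`.
#' @param pseudocount positive offset added to every count.
#' @return samples x OTUs numeric matrix.
#' @export
clr_transform <- function(x, pseudocount = 0.5) {
  stopifnot(inherits(x, "otu_table"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    abort("`pseudocount` must be a positive number")
  lx <- log(x$counts + pseudocount)
  lx - rowMeans(lx)
}

#' Rarefy samples to a common depth
#'
#' Optional pre-processing step (off by default in the pipeline): subsamples
#' reads without replacement so every sample has exactly `depth` reads.
#' Samples below `depth` are dropped first.
#'
#' @param x an `otu_table`.
#' @param depth target depth; defaults to the minimum sample depth.
#' @param seed integer seed controlling the subsampling.
#' @return an `otu_table` with equal row sums.
#' @export
rarefy_table <- function(x, depth = NULL, seed = 1) {
  stopifnot(inherits(x, "otu_table"))
  depths <- rowSums(x$counts)
  if (is.null(depth)) depth <- min(depths)
  stopifnot(depth >= 1)
  x <- subset_table(x, samples = which(depths >= depth))
  if (nrow(x$counts) == 0L) abort("no sample reaches the rarefaction depth")
  k <- ncol(x$counts)
  with_seed(seed, {
    m <- t(apply(x$counts, 1L, function(row) {
      pool <- rep.int(seq_len(k), row)
      tabulate(sample(pool, depth), nbins = k)
    }))
  })
  dimnames(m) <- dimnames(x$counts)
  otu_table(m, x$taxonomy)
}
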