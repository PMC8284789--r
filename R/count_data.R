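#' Count tables of sequence reads
#'
#' A count table is a taxa-by-samples matrix of nonnegative integer read
#' counts with unique taxon row names and sample column names.  `count_table()`
#' validates a matrix (or coerces a data frame whose first column holds taxon
#' identifiers).
#'
#' @param x Matrix or data frame of counts.
#' @param taxa,samples Optional identifier vectors overriding dimnames.
#' @return An integer matrix with class `count_table`.
#' @export
count_table <- function(x, taxa = NULL, samples = NULL) {
  if (is.data.frame(x)) {
    if (is.null(taxa) && (is.character(x[[1]]) || is.factor(x[[1]]))) {
      taxa <- as.character(x[[1]])
      x <- x[, -1, drop = FALSE]
    }
    x <- as.matrix(x)
  }
  if (!is.null(taxa)) rownames(x) <- taxa
  if (!is.null(samples)) colnames(x) <- samples
  if (is.null(rownames(x))) rownames(x) <- paste0("taxon_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("sample_", seq_len(ncol(x)))
  if (nrow(x) < 2L) stop("a count table needs at least 2 taxa", call. = FALSE)
  if (ncol(x) < 1L) stop("a count table needs at least 1 sample", call. = FALSE)
  bad <- which(!is.finite(x) | x < 0 | x != round(x), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-integer or negative count at row %d (%s), column %d (%s)",
                 bad[1, 1], rownames(x)[bad[1, 1]],
                 bad[1, 2], colnames(x)[bad[1, 2]]), call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("duplicate taxon identifiers", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate sample identifiers", call. = FALSE)
  storage.mode(x) <- "integer"
  class(x) <- c("count_table", class(x))
  x
}

#' Read and write count tables
#'
#' Count tables are stored as delimited text with taxa in rows (first column =
#' taxon identifier) and samples in columns.  `read_counts()` also accepts
#' BIOM files when the `biomformat` package is available.  The round trip
#' through `write_counts()` is lossless for integers and identifiers.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"`, or `"biom"`.
#' @param transpose If `TRUE` the file stores samples in rows and is
#'   transposed on read.
#' @return A [count_table].
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "biom"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", biom = "biom", "tsv")
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the biomformat package", call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    tab <- count_table(m)
    return(if (transpose) count_table(t(unclass(tab))) else tab)
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric count near row %d, column %d of %s",
                 bad[1, 1], bad[1, 2] + 1L, path), call. = FALSE)
  }
  if (transpose) {
    count_table(t(m), taxa = colnames(m), samples = ids)
  } else {
    count_table(m, taxa = ids)
  }
}

#' @rdname read_counts
#' @param table A [count_table].
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- data.frame(taxon_id = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Metadata accompany a count table with one row per sample: `sample_id`,
#' `cycle` (number of PCR cycles the sample underwent), `group` (community /
#' subject label indexing intercepts), and `batch` (PCR machine label).
#'
#' @param path Delimited text file (TSV or CSV by extension).
#' @return A tibble with columns `sample_id`, `cycle`, `group`, `batch`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "cycle", "group", "batch")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$cycle <- as.integer(df$cycle)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id", call. = FALSE)
  tibble::as_tibble(df[, c(need, setdiff(names(df), need))])
}

#' @rdname read_metadata
#' @param metadata Tibble/data frame of metadata.
#' @param path File path.
#' @export
write_metadata <- function(metadata, path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::write.table(metadata, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Drop shallowly sequenced samples
#'
#' Retains exactly the samples whose total read count is strictly greater
#' than `threshold` (default 1000 reads) and reports the fraction of reads
#' retained.
#'
#' @param table A [count_table].
#' @param threshold Minimum total; samples with sums `> threshold` are kept.
#' @return Filtered [count_table] (possibly with zero samples, with a
#'   warning).
#' @export
filter_min_reads <- function(table, threshold = 1000) {
  stopifnot(inherits(table, "count_table"), threshold >= 0)
  sums <- colSums(table)
  keep <- sums > threshold
  if (!any(keep)) {
    warning("no samples exceed the read threshold; returning empty table",
            call. = FALSE)
  }
  frac <- if (sum(sums) > 0) sum(sums[keep]) / sum(sums) else NA_real_
  message(sprintf("filter_min_reads: kept %d/%d samples (%.1f%% of reads)",
                  sum(keep), length(keep), 100 * frac))
  out <- unclass(table)[, keep, drop = FALSE]
  class(out) <- c("count_table", class(out))
  out
}

#' Amalgamate rare taxa into a single category
#'
#' A taxon is kept when it is seen with at least `min_count` reads in at least
#' a fraction `prevalence` of the samples; all other taxa are summed into one
#' row labelled `label`.  Per-sample totals are conserved exactly.
#'
#' @param table A [count_table].
#' @param prevalence Required fraction of samples (inclusive), default 0.30.
#' @param min_count Count defining "seen" (inclusive), default 3.
#' @param label Name of the amalgamated row.
#' @return A [count_table]; unchanged when no taxon is rare.
#' @export
amalgamate_rare <- function(table, prevalence = 0.30, min_count = 3,
                            label = "other") {
  stopifnot(inherits(table, "count_table"),
            prevalence >= 0, prevalence <= 1)
  n <- ncol(table)
  seen_frac <- rowMeans(unclass(table) >= min_count)
  keep <- seen_frac >= prevalence
  if (!any(keep)) {
    stop("all taxa fall below the prevalence rule; nothing left to model",
         call. = FALSE)
  }
  if (all(keep)) return(table)
  m <- unclass(table)
  other <- colSums(m[!keep, , drop = FALSE])
  out <- rbind(m[keep, , drop = FALSE], other)
  rownames(out)[nrow(out)] <- label
  count_table(out)
}

#' Map sequence variants to reference sequences by edit distance
#'
#' Each query sequence is assigned to the reference with minimum Levenshtein
#' distance.  Ties are reported, never broken silently.
#'
#' @param query_seqs Named character vector of query DNA sequences
#'   (alphabet A, C, G, T, N), or a FASTA file path.
#' @param ref_seqs Named character vector of reference sequences, or a FASTA
#'   file path.
#' @return A tibble with one row per query: `query`, `reference` (comma-joined
#'   when tied), `distance`, `tie` (logical), and a list-column `matches`.
#' @export
map_variants <- function(query_seqs, ref_seqs) {
  query_seqs <- .as_seqs(query_seqs, "query")
  ref_seqs <- .as_seqs(ref_seqs, "reference")
  if (length(ref_seqs) == 0L) stop("empty reference set", call. = FALSE)
  if (length(query_seqs) == 0L) stop("empty query set", call. = FALSE)
  dmat <- utils::adist(query_seqs, ref_seqs)  # Levenshtein distances
  purrr::map_dfr(seq_along(query_seqs), function(i) {
    d <- dmat[i, ]
    best <- which(d == min(d))
    tibble::tibble(
      query = names(query_seqs)[i],
      reference = paste(names(ref_seqs)[best], collapse = ","),
      distance = min(d),
      tie = length(best) > 1L,
      matches = list(names(ref_seqs)[best])
    )
  })
}

.as_seqs <- function(x, what) {
  if (length(x) == 0L) return(character(0))
  if (length(x) == 1L && !grepl("^[ACGTNacgtn]+$", x) && file.exists(x)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA requires the Biostrings package", call. = FALSE)
    }
    ss <- Biostrings::readDNAStringSet(x)
    x <- stats::setNames(as.character(ss), names(ss))
  }
  if (is.null(names(x))) names(x) <- paste0(what, "_", seq_along(x))
  x <- toupper(x)
  if (any(!grepl("^[ACGTN]+$", x))) {
    stop(what, " sequences must be nonempty over {A,C,G,T,N}", call. = FALSE)
  }
  x
}
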