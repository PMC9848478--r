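#' Region tables
#'
#' Regions (promoters, transposable-element copies, arbitrary intervals)
#' are plain data frames with the columns `id`, `chrom`, `start`, `end`,
#' `strand` and `kind`, using 0-based half-open coordinates throughout
#' (the BED convention). Any further columns are carried along as
#' attributes (`gene_id`, `te_family`, `te_class`, `te_subfamily`, ...).
#'
#' @param id character vector of unique region identifiers.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open interval bounds; `start < end`.
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @param kind region kind, typically `"promoter"` or `"te"`.
#' @param ... further attribute columns, recycled to length.
#' @return A `data.frame` of regions.
#' @examples
#' regions(id = "AluY_1", chrom = "chr1", start = 0, end = 300, kind = "te")
#' @export
regions <- function(id, chrom, start, end, strand = ".", kind = "te", ...) {
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), kind = as.character(kind),
                   ..., stringsAsFactors = FALSE)
  validate_regions(df)
}

validate_regions <- function(df, chrom_lengths = NULL) {
  stopifnot_cols(df, c("id", "chrom", "start", "end"), "region table")
  if (any(df$start < 0)) stop("region start must be >= 0")
  if (any(df$start >= df$end)) stop("region start must be < end")
  if (anyDuplicated(df$id)) stop("region ids must be unique")
  if (!is.null(df$strand) && !all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(unique(df$chrom), names(chrom_lengths))
    if (length(unknown))
      stop("regions on undeclared chromosome(s): ",
           paste(unknown, collapse = ", "))
    if (any(df$end > chrom_lengths[df$chrom]))
      stop("region end exceeds chromosome length")
  }
  df
}

#' Promoter window specification
#'
#' Promoters are defined as fixed windows around the TSS: `upstream` bp
#' 5' of the TSS and `downstream` bp 3' of it, in gene orientation. The
#' defaults give the (-2000, +500) window commonly used for promoter
#' quantification.
#'
#' @param upstream bp upstream of the TSS (default 2000).
#' @param downstream bp downstream of the TSS (default 500).
#' @return A list with class `promoter_window_spec`.
#' @export
promoter_window_spec <- function(upstream = 2000L, downstream = 500L) {
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  if (upstream < 0 || downstream < 0) stop("window extents must be >= 0")
  if (upstream + downstream <= 0) stop("window must have positive width")
  structure(list(upstream = upstream, downstream = downstream),
            class = "promoter_window_spec")
}

#' Build a promoter region from a TSS
#'
#' Windows are strand-aware: on `+` the interval is
#' `[tss - upstream, tss + downstream)`, on `-` it is mirrored to
#' `[tss - downstream, tss + upstream)`. Intervals are clipped at 0 and,
#' when `chrom_length` is given, at the chromosome end.
#'
#' @param tss_chrom chromosome of the TSS.
#' @param tss_pos 0-based TSS position.
#' @param strand `"+"` or `"-"` (gene orientation).
#' @param spec a [promoter_window_spec()].
#' @param id region id; defaults to `"<chrom>:<tss>:<strand>"`.
#' @param gene_id optional gene identifier carried as an attribute column.
#' @param chrom_length optional chromosome length used for clipping.
#' @return One-row region `data.frame` with `tss` attribute column.
#' @examples
#' promoter_from_tss("chr1", 10000, "+")  # chr1:8000-10500
#' @export
promoter_from_tss <- function(tss_chrom, tss_pos, strand,
                              spec = promoter_window_spec(),
                              id = NULL, gene_id = NA_character_,
                              chrom_length = NULL) {
  if (!strand %in% c("+", "-"))
    stop("unknown strand symbol: ", strand)
  if (tss_pos < 0) stop("tss_pos must be >= 0")
  if (strand == "+") {
    s <- tss_pos - spec$upstream; e <- tss_pos + spec$downstream
  } else {
    s <- tss_pos - spec$downstream; e <- tss_pos + spec$upstream
  }
  s <- max(0L, as.integer(s)); e <- as.integer(e)
  if (!is.null(chrom_length)) e <- min(e, as.integer(chrom_length))
  if (s >= e) stop("promoter window collapsed to zero width after clipping")
  if (is.null(id)) id <- sprintf("%s:%d:%s", tss_chrom, as.integer(tss_pos), strand)
  data.frame(id = id, chrom = tss_chrom, start = s, end = e, strand = strand,
             kind = "promoter", gene_id = gene_id,
             tss = as.integer(tss_pos), stringsAsFactors = FALSE)
}

#' Genome annotation
#'
#' Bundles chromosome lengths with promoter and TE region tables and
#' validates that all regions lie within the declared chromosomes.
#'
#' @param chromosomes named integer vector of chromosome lengths.
#' @param promoters,tes region tables (see [regions()]).
#' @return A list with class `genome_annotation`.
#' @export
genome_annotation <- function(chromosomes, promoters, tes) {
  stopifnot(is.numeric(chromosomes), !is.null(names(chromosomes)))
  validate_regions(promoters, chromosomes)
  validate_regions(tes, chromosomes)
  structure(list(chromosomes = chromosomes, promoters = promoters, tes = tes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d chromosome(s), %d promoters, %d TEs\n",
              length(x$chromosomes), nrow(x$promoters), nrow(x$tes)))
  invisible(x)
}

# -- readers / writers -------------------------------------------------------

read_tsv_raw <- function(path, n_min_fields) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (!length(lines)) return(NULL)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < n_min_fields)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected >= %d tab-separated fields, got %d",
                 bad[1], path, n_min_fields, nf[bad[1]]))
  fields
}

#' Read interval annotations
#'
#' `format = "bed"` reads BED3+ (0-based half-open; column 4 becomes the
#' region `id`, column 6 the strand, columns beyond 6 become `attr1`,
#' `attr2`, ...). `format = "region-table"` reads a headered TSV with at
#' least the columns `id`, `chrom`, `start`, `end`; extra columns are
#' kept as attributes. Records with `start >= end` are rejected with a
#' diagnostic message; input order of the surviving records is preserved.
#'
#' @param path file path.
#' @param format `"bed"` or `"region-table"`.
#' @param kind region kind stamped on BED records (default `"te"`).
#' @return A region `data.frame` (zero rows for an empty file).
#' @export
read_regions <- function(path, format = c("bed", "region-table"), kind = "te") {
  format <- match.arg(format)
  if (format == "region-table") {
    df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                     stringsAsFactors = FALSE, comment.char = "")
    if (!nrow(df)) return(df)
    stopifnot_cols(df, c("id", "chrom", "start", "end"), path)
  } else {
    fields <- read_tsv_raw(path, 3L)
    if (is.null(fields))
      return(data.frame(id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), kind = character(),
                        stringsAsFactors = FALSE))
    starts <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
    ends <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
    if (anyNA(starts) || anyNA(ends))
      stop(sprintf("malformed line %d in %s: non-integer coordinate",
                   which(is.na(starts) | is.na(ends))[1], path))
    nf <- lengths(fields)
    get_col <- function(i, default) {
      ifelse(nf >= i, vapply(fields, function(f) f[min(i, length(f))], ""), default)
    }
    ids <- get_col(4L, NA_character_)
    ids <- ifelse(is.na(ids) | ids == ".",
                  sprintf("region_%d", seq_along(fields)), ids)
    if (anyDuplicated(ids))
      ids <- make.unique(ids, sep = "_")
    df <- data.frame(id = ids,
                     chrom = vapply(fields, `[`, "", 1L),
                     start = starts, end = ends,
                     strand = ifelse(nf >= 6L, get_col(6L, "."), "."),
                     kind = kind, stringsAsFactors = FALSE)
    if (any(nf > 6L)) {
      for (i in seq_len(max(nf) - 6L))
        df[[paste0("attr", i)]] <- get_col(6L + i, NA_character_)
    }
  }
  bad <- df$start >= df$end | df$start < 0
  if (any(bad)) {
    message(sprintf("read_regions: rejected %d record(s) with start >= end or start < 0 (lines: %s)",
                    sum(bad), paste(head(which(bad), 5), collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write interval annotations
#'
#' Writers emit tab-separated UTF-8 without quoting. `"bed"` writes
#' chrom/start/end/id/score/strand (score 0); `"region-table"` writes a
#' headered TSV with every column of the table.
#'
#' @param x region `data.frame`.
#' @param path output path.
#' @param format `"bed"` or `"region-table"`.
#' @export
write_regions <- function(x, path, format = c("bed", "region-table")) {
  format <- match.arg(format)
  if (format == "bed") {
    out <- data.frame(x$chrom, x$start, x$end, x$id, 0L,
                      if (is.null(x$strand)) "." else x$strand)
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8")
  } else {
    write.table(x, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read ENCODE peak files
#'
#' Supports the ENCODE broadPeak (9 column) and narrowPeak (10 column)
#' dialects. The `-log10` p- and q-value columns are mapped back to
#' linear probabilities; the ENCODE missing-value sentinel `-1` maps to
#' `NA` ("undefined"). For narrowPeak, the summit offset is retained in
#' a `summit` column.
#'
#' @param path file path.
#' @param format `"broadPeak"` or `"narrowPeak"`.
#' @return A peak `data.frame` with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`, `signal`, `p`, `q` (and `summit`).
#' @export
read_peaks <- function(path, format = c("broadPeak", "narrowPeak")) {
  format <- match.arg(format)
  want <- if (format == "broadPeak") 9L else 10L
  fields <- read_tsv_raw(path, want)
  if (is.null(fields)) return(empty_peaks())
  nf <- lengths(fields)
  if (any(nf != want))
    stop(sprintf("%s line %d: expected %d columns, got %d",
                 format, which(nf != want)[1], want, nf[nf != want][1]))
  m <- do.call(rbind, fields)
  delog <- function(v) {
    v <- as.numeric(v)
    ifelse(v < 0, NA_real_, 10^(-v))
  }
  df <- data.frame(chrom = m[, 1], start = as.integer(m[, 2]),
                   end = as.integer(m[, 3]), name = m[, 4],
                   score = as.numeric(m[, 5]), strand = m[, 6],
                   signal = as.numeric(m[, 7]),
                   p = delog(m[, 8]), q = delog(m[, 9]),
                   stringsAsFactors = FALSE)
  if (format == "narrowPeak") df$summit <- as.integer(m[, 10])
  if (any(df$start >= df$end)) stop("peak with start >= end in ", path)
  df
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), strand = character(),
             signal = numeric(), p = numeric(), q = numeric(),
             stringsAsFactors = FALSE)
}

#' Write peaks in broadPeak format
#'
#' @param peaks peak `data.frame` as returned by [read_peaks()].
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  tolog <- function(v) ifelse(is.na(v), -1, -log10(pmax(v, 1e-300)))
  out <- data.frame(peaks$chrom, peaks$start, peaks$end,
                    peaks$name %||% sprintf("peak_%d", seq_len(nrow(peaks))),
                    round(peaks$score %||% 0, 3), peaks$strand %||% ".",
                    signif(peaks$signal %||% 0, 6),
                    signif(tolog(peaks$p), 6), signif(tolog(peaks$q), 6))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Convert a 0-based half-open region/peak table to GRanges (1-based closed)
# for overlap work. Internal.
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = "*")
}

# >=1 bp overlap between two 0-based half-open tables; returns logical
# vector over rows of `query`.
overlaps_any0 <- function(query, subject) {
  if (!nrow(query)) return(logical(0))
  if (!nrow(subject)) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(as_granges0(query), as_granges0(subject))
}
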