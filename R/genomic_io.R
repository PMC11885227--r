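#' Genomic intervals
#'
#' Intervals are plain data frames in 0-based half-open (BED) coordinates:
#' columns `chrom` (character), `start` (integer, inclusive), `end` (integer,
#' exclusive) and optionally `strand` (`"+"`, `"-"` or `"."`). All package
#' functions use this convention internally; 1-based coordinates appear only
#' in display output.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end`.
#' @param strand optional character vector in `+`, `-`, `.`.
#' @return data.frame of validated intervals.
#' @export
gintervals <- function(chrom, start, end, strand = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  n <- max(length(chrom), length(start), length(end))
  recycle <- function(v) if (length(v) == 1L) rep_len(v, n) else v
  chrom <- recycle(chrom); start <- recycle(start); end <- recycle(end)
  if (length(start) != n || length(end) != n || length(chrom) != n)
    stop("chrom, start, end must have equal length (or length 1)")
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad))
    stop("invalid interval(s) at index ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  x <- data.frame(chrom = as.character(chrom), start = start, end = end,
                  stringsAsFactors = FALSE)
  if (!is.null(strand)) {
    if (!all(strand %in% c("+", "-", "."))) stop("strand must be one of +, -, .")
    x$strand <- strand
  }
  x
}

#' Validate intervals against a chromosome-size table
#'
#' @param x interval data.frame (see [gintervals()]).
#' @param chrom_sizes named integer vector, chromosome name -> length (bp).
#' @return `x` invisibly; errors if any interval is off-genome.
#' @export
validate_intervals <- function(x, chrom_sizes) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  unknown <- setdiff(unique(x$chrom), names(chrom_sizes))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  lim <- unname(chrom_sizes[x$chrom])
  bad <- which(x$end > lim | x$start < 0L | x$start >= x$end)
  if (length(bad))
    stop("interval(s) beyond chromosome bounds or malformed at row ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(x)
}

#' Read / write a chromosome-size table
#'
#' Two-column TSV (`chrom`, `length`), no header.
#'
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"))
  if (any(dt$length <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(dt$chrom)) stop("duplicate chromosome names")
  stats::setNames(as.integer(dt$length), dt$chrom)
}

#' @param chrom_sizes named integer vector.
#' @rdname read_chrom_sizes
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  data.table::fwrite(data.table::data.table(chrom = names(chrom_sizes),
                                            length = unname(chrom_sizes)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# read a BED-like file, skipping comment/track lines, keeping line numbers
read_bedlike <- function(path, min_cols = 3L) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  if (!any(keep))
    return(list(fields = list(), lineno = integer(0)))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < min_cols)
  if (length(bad))
    stop("malformed line ", lineno[bad[1]], " in ", path,
         ": expected at least ", min_cols, " tab-separated fields")
  list(fields = fields, lineno = lineno)
}

#' Read aligned-fragment intervals from a BED file
#'
#' BED3+ dialect; coordinates are validated against `chrom_sizes`. Parse
#' errors name the offending line.
#'
#' @param path BED file of fragments.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return interval data.frame (`chrom`, `start`, `end`, and `strand` when a
#'   6th column is present), input order preserved.
#' @export
read_fragments <- function(path, chrom_sizes) {
  raw <- read_bedlike(path, 3L)
  if (!length(raw$fields))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  chrom <- vapply(raw$fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(raw$fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(raw$fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad))
    stop("malformed interval at line ", raw$lineno[bad[1]], " in ", path,
         ": need integer 0 <= start < end")
  x <- data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
  has6 <- all(lengths(raw$fields) >= 6L)
  if (has6) x$strand <- vapply(raw$fields, `[[`, "", 6L)
  validate_intervals(x, chrom_sizes)
  x
}

#' Write intervals as BED
#'
#' Writes BED3 (or BED6 when a `strand` column is present; `name` and `score`
#' columns are used if available). An empty set produces a file holding only
#' a header comment.
#'
#' @param x interval data.frame.
#' @param path output path.
#' @export
write_fragments <- function(x, path) {
  if (nrow(x) == 0L) {
    writeLines("# chrom\tstart\tend (no intervals)", path)
    return(invisible(path))
  }
  out <- data.table::data.table(chrom = x$chrom, start = x$start, end = x$end)
  if (!is.null(x$strand)) {
    out$name <- if (is.null(x$name)) "." else x$name
    out$score <- if (is.null(x$score)) 0L else x$score
    out$strand <- x$strand
    out <- out[, c("chrom", "start", "end", "name", "score", "strand")]
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
write_regions <- write_fragments

#' @param chrom_sizes named integer vector for validation.
#' @rdname write_fragments
#' @export
read_regions <- function(path, chrom_sizes) read_fragments(path, chrom_sizes)

#' Depth track constructor
#'
#' A depth track stores one numeric per-base vector per chromosome plus the
#' total read count used for normalization.
#'
#' @param counts named list, chromosome -> per-base numeric vector.
#' @param total_reads normalizing denominator (uniquely mapped read count).
#' @param mode `"coverage"` (each read covers its full span) or
#'   `"read_start"` (5' end only).
#' @param normalized logical; `scale` records the normalization scale.
#' @param scale numeric scale used at normalization time.
#' @return object of class `depth_track`.
#' @export
depth_track <- function(counts, total_reads, mode = "coverage",
                        normalized = FALSE, scale = NA_real_) {
  stopifnot(is.list(counts), !is.null(names(counts)),
            is.na(total_reads) || total_reads >= 0)
  structure(list(counts = counts, total_reads = total_reads, mode = mode,
                 normalized = normalized, scale = scale),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat("<depth_track> mode=", x$mode,
      if (x$normalized) paste0(" normalized(scale=", format(x$scale), ")") else " raw",
      "\n  chromosomes: ", paste(names(x$counts), collapse = ", "),
      "\n  total_reads: ", format(x$total_reads),
      "  sum(depth): ", format(sum(vapply(x$counts, sum, 0))), "\n", sep = "")
  invisible(x)
}

#' Accumulate per-base depth from fragment intervals
#'
#' In `coverage` mode the total depth mass equals the summed fragment
#' lengths; in `read_start` mode it equals the number of fragments.
#' An empty fragment set yields an all-zero track.
#'
#' @param fragments interval data.frame (validated against `chrom_sizes`).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param mode see [depth_track()].
#' @param total_reads normalizing denominator; defaults to `nrow(fragments)`.
#' @return a raw [depth_track()].
#' @export
accumulate_depth <- function(fragments, chrom_sizes,
                             mode = c("coverage", "read_start"),
                             total_reads = nrow(fragments)) {
  mode <- match.arg(mode)
  if (nrow(fragments)) validate_intervals(fragments, chrom_sizes)
  counts <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    sel <- fragments$chrom == ch
    if (!any(sel)) return(numeric(L))
    s <- fragments$start[sel]
    if (mode == "read_start") return(as.numeric(tabulate(s + 1L, nbins = L)))
    e <- fragments$end[sel]
    # difference-array coverage: +1 at start, -1 at end (end == L drops off)
    cumsum(tabulate(s + 1L, nbins = L) - tabulate(e + 1L, nbins = L))
  })
  names(counts) <- names(chrom_sizes)
  depth_track(counts, total_reads = total_reads, mode = mode)
}

#' Normalize a depth track by its total read count
#'
#' `value' = value / total_reads * scale`.
#'
#' @param track a raw [depth_track()].
#' @param scale positive scale factor (e.g. `1e6` for per-million).
#' @return normalized `depth_track` with the scale recorded.
#' @export
normalize_track <- function(track, scale = 1e6) {
  stopifnot(inherits(track, "depth_track"), scale > 0)
  if (track$normalized) stop("track is already normalized")
  if (track$total_reads == 0) stop("total_reads is 0; cannot normalize")
  track$counts <- lapply(track$counts, function(v) v / track$total_reads * scale)
  track$normalized <- TRUE
  track$scale <- scale
  track
}

#' Write / read a depth track as bedGraph
#'
#' Runs of equal depth are run-length encoded; zero runs are omitted, so the
#' round trip through [read_track()] (which needs `chrom_sizes` to restore
#' the zeros) is lossless.
#'
#' @param track a [depth_track()].
#' @param path output path.
#' @export
write_track <- function(track, path) {
  out <- "track type=bedGraph"
  for (ch in names(track$counts)) {
    v <- track$counts[[ch]]
    r <- rle(v)
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    out <- c(out, sprintf("%s\t%d\t%d\t%.17g", ch, start[keep], end[keep],
                          r$values[keep]))
  }
  writeLines(out, path)
  invisible(path)
}

#' @param chrom_sizes named integer vector (restores omitted zero runs).
#' @param total_reads,mode,normalized,scale track metadata to re-attach.
#' @rdname write_track
#' @export
read_track <- function(path, chrom_sizes, total_reads = NA_real_,
                       mode = "coverage", normalized = FALSE, scale = NA_real_) {
  raw <- read_bedlike(path, 4L)
  counts <- lapply(names(chrom_sizes), function(ch) numeric(chrom_sizes[[ch]]))
  names(counts) <- names(chrom_sizes)
  if (length(raw$fields)) {
    chrom <- vapply(raw$fields, `[[`, "", 1L)
    start <- as.integer(vapply(raw$fields, `[[`, "", 2L))
    end <- as.integer(vapply(raw$fields, `[[`, "", 3L))
    val <- as.numeric(vapply(raw$fields, `[[`, "", 4L))
    unknown <- setdiff(unique(chrom), names(chrom_sizes))
    if (length(unknown)) stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    for (i in seq_along(chrom)) {
      if (end[i] > chrom_sizes[[chrom[i]]]) stop("interval beyond chromosome end")
      counts[[chrom[i]]][(start[i] + 1L):end[i]] <- val[i]
    }
  }
  depth_track(counts, total_reads = total_reads, mode = mode,
              normalized = normalized, scale = scale)
}

#' Read / write gene annotation (BED6)
#'
#' Columns: chrom, start, end, gene_id, score (ignored), strand. The TSS is
#' derived strand-aware: body start on `+`, body end − 1 on `-`.
#'
#' @param path BED6 file.
#' @param chrom_sizes named integer vector for validation.
#' @return data.frame with `gene_id`, `gene_name`, `chrom`, `start`, `end`,
#'   `strand`, `tss` (0-based position).
#' @export
read_annotation <- function(path, chrom_sizes) {
  raw <- read_bedlike(path, 6L)
  if (!length(raw$fields))
    return(data.frame(gene_id = character(0), gene_name = character(0),
                      chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), tss = integer(0)))
  x <- data.frame(
    gene_id = vapply(raw$fields, `[[`, "", 4L),
    chrom = vapply(raw$fields, `[[`, "", 1L),
    start = as.integer(vapply(raw$fields, `[[`, "", 2L)),
    end = as.integer(vapply(raw$fields, `[[`, "", 3L)),
    strand = vapply(raw$fields, `[[`, "", 6L),
    stringsAsFactors = FALSE)
  x$gene_name <- x$gene_id
  validate_intervals(x, chrom_sizes)
  if (!all(x$strand %in% c("+", "-"))) stop("annotation strand must be + or -")
  x$tss <- ifelse(x$strand == "+", x$start, x$end - 1L)
  x[, c("gene_id", "gene_name", "chrom", "start", "end", "strand", "tss")]
}

#' @param annotation annotation data.frame as returned by [read_annotation()].
#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  data.table::fwrite(
    data.table::data.table(chrom = annotation$chrom, start = annotation$start,
                           end = annotation$end, name = annotation$gene_id,
                           score = 0L, strand = annotation$strand),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' TSV with header; columns `sample_id`, `total_reads`, `fetal_sex`,
#' `ff_chrY`, `group_label`, `condition` and optionally `true_ff`
#' (synthetic cohorts only).
#'
#' @param path TSV file.
#' @return data.frame of sample metadata.
#' @export
read_sample_meta <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("sample_id", "total_reads", "fetal_sex", "ff_chrY", "group_label",
            "condition")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x)) {
    if (any(x$total_reads <= 0)) stop("total_reads must be > 0")
    for (col in intersect(c("ff_chrY", "true_ff"), names(x))) {
      v <- x[[col]]
      if (any(!is.na(v) & (v < 0 | v > 1))) stop(col, " must lie in [0, 1]")
    }
  }
  x
}

#' @param meta metadata data.frame.
#' @rdname read_sample_meta
#' @export
write_sample_meta <- function(meta, path) {
  data.table::fwrite(meta, path, sep = "\t", col.names = TRUE, na = "NA")
  invisible(path)
}
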