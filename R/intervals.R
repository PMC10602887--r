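#' Construct an interval set
#'
#' An interval set is a plain `data.frame` of genomic intervals in 0-based
#' half-open (BED) coordinates, the substrate for peaks, enhancers and gene
#' bodies throughout the package. Columns are `chrom`, `start`, `end`,
#' `name`, `score`, `strand`; a `provenance` attribute records where the set
#' came from (file path, mark, condition).
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector, 0-based inclusive starts.
#' @param end integer vector, exclusive ends; must satisfy `start < end`.
#' @param name optional labels (`NA` allowed).
#' @param score optional non-negative scores (`NA` allowed).
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @param provenance free-form tag stored as an attribute.
#' @return A `data.frame` with class `interval_set`.
#' @export
interval_set <- function(chrom, start, end, name = NA_character_,
                         score = NA_real_, strand = ".", provenance = NULL) {
  n <- length(start)
  if (length(end) != n)
    stop("start and end must have equal length")
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = as.integer(start),
    end = as.integer(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  attr(df, "provenance") <- provenance
  class(df) <- c("interval_set", "data.frame")
  df
}

validate_intervals <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    stop("interval chromosome names must be non-empty")
  if (any(is.na(df$start) | is.na(df$end)))
    stop("interval coordinates must be finite integers")
  bad <- which(!(df$start >= 0L & df$start < df$end))
  if (length(bad))
    stop("invalid interval coordinates (need 0 <= start < end) at row ",
         bad[1L])
  if (any(!df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(df)
}

#' Sort an interval set by (chrom, start, end)
#'
#' Duplicated intervals are permitted; they are flagged with a message.
#'
#' @param x an `interval_set` or compatible data.frame.
#' @return The sorted set.
#' @export
sort_intervals <- function(x) {
  o <- order(x$chrom, x$start, x$end, method = "radix")
  out <- x[o, , drop = FALSE]
  rownames(out) <- NULL
  dup <- duplicated(out[, c("chrom", "start", "end")])
  if (any(dup))
    message(sum(dup), " duplicated interval(s) in set")
  out
}

# 0-based half-open -> GRanges (1-based closed). Internal bridge used for
# overlap machinery only; all user-facing coordinates stay BED-style.
as_granges <- function(x) {
  strand <- x$strand
  if (is.null(strand)) strand <- "."
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' Read a BED3-BED6 file
#'
#' Lines beginning with `track`, `browser` or `#` are skipped. Coordinates
#' are kept 0-based half-open. Malformed lines (fewer than three fields,
#' non-integer coordinates, `start >= end`) raise an error naming the line.
#'
#' @param path path to a tab-separated BED file.
#' @return An `interval_set`; empty files yield an empty set. The source path
#'   is recorded as provenance, and the number of BED columns seen as
#'   attribute `bed_fields` (used by [write_bed()] to round-trip).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    out <- empty_interval_set()
    attr(out, "provenance") <- path
    attr(out, "bed_fields") <- 3L
    return(out)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED line ", idx[which(nf < 3L)[1L]], " has fewer than 3 fields")
  nmax <- min(max(nf), 6L)
  get <- function(k, default) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else default, "")
  }
  chrom <- get(1L, NA_character_)
  start_s <- get(2L, NA_character_)
  end_s <- get(3L, NA_character_)
  start <- suppressWarnings(as.integer(start_s))
  end <- suppressWarnings(as.integer(end_s))
  bad <- which(is.na(start) | is.na(end) | start_s != as.character(start) |
                 end_s != as.character(end))
  if (length(bad))
    stop("BED line ", idx[bad[1L]], ": non-integer coordinate")
  bad <- which(!(start >= 0L & start < end))
  if (length(bad))
    stop("BED line ", idx[bad[1L]], ": start must satisfy 0 <= start < end")
  name <- if (nmax >= 4L) get(4L, NA_character_) else NA_character_
  score_s <- if (nmax >= 5L) get(5L, NA_character_) else NA_character_
  score <- suppressWarnings(as.numeric(score_s))
  score[score_s %in% c(".", "")] <- NA_real_
  strand <- if (nmax >= 6L) get(6L, ".") else "."
  strand[!strand %in% c("+", "-")] <- "."
  out <- interval_set(chrom, start, end, name, score, strand,
                      provenance = path)
  attr(out, "bed_fields") <- nmax
  out
}

empty_interval_set <- function() {
  interval_set(character(0), integer(0), integer(0))
}

#' Write an interval set as BED
#'
#' Writes as many of the six BED columns as the set carries (attribute
#' `bed_fields`, defaulting to six when names are present). Missing names and
#' scores are written as `.` and `0` respectively, per BED convention.
#'
#' @param x an `interval_set`.
#' @param path output path.
#' @param n_fields number of columns to write (3-6); defaults to the
#'   `bed_fields` attribute, else 6.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, n_fields = NULL) {
  if (is.null(n_fields)) n_fields <- attr(x, "bed_fields")
  if (is.null(n_fields)) n_fields <- 6L
  n_fields <- max(3L, min(6L, as.integer(n_fields)))
  cols <- list(x$chrom, format_coord(x$start), format_coord(x$end))
  if (n_fields >= 4L) {
    nm <- x$name
    nm[is.na(nm)] <- "."
    cols <- c(cols, list(nm))
  }
  if (n_fields >= 5L) {
    sc <- ifelse(is.na(x$score), "0", format_num(x$score))
    cols <- c(cols, list(sc))
  }
  if (n_fields >= 6L) cols <- c(cols, list(x$strand))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_coord <- function(x) sprintf("%d", as.integer(x))
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("0")
    if (v == round(v) && abs(v) < 1e15) sprintf("%d", as.integer(v))
    else sprintf("%.17g", v)
  }, "")
  out
}

#' Overlap flags between two interval sets
#'
#' For each interval of `a`, reports whether some interval of `b` shares at
#' least `min_bp` bases with it, under half-open semantics (an interval
#' ending at position p does not overlap one starting at p).
#'
#' @param a,b `interval_set` objects on a shared chromosome namespace.
#' @param min_bp minimum shared bases (positive integer).
#' @return Logical vector, one flag per interval of `a`.
#' @export
overlaps <- function(a, b, min_bp = 1L) {
  if (!is.numeric(min_bp) || length(min_bp) != 1L || min_bp < 1)
    stop("min_bp must be a positive integer")
  if (nrow(a) == 0L) return(logical(0))
  if (nrow(b) == 0L || !any(unique(b$chrom) %in% a$chrom))
    return(rep(FALSE, nrow(a)))
  GenomicRanges::countOverlaps(
    as_granges(a), as_granges(b),
    minoverlap = as.integer(min_bp), ignore.strand = TRUE
  ) > 0L
}

#' Distance from a point to an interval
#'
#' Zero when the point lies inside `[start, end)`; otherwise the distance to
#' the nearest covered base, i.e. `min(|p - start|, |p - (end - 1)|)`.
#' Vectorized over all arguments; the caller is responsible for restricting
#' to a shared chromosome.
#'
#' @param p integer position(s), 0-based.
#' @param start,end interval bounds, 0-based half-open.
#' @return Non-negative integer distance(s) in bp.
#' @export
point_interval_distance <- function(p, start, end) {
  inside <- p >= start & p < end
  d <- pmin(abs(p - start), abs(p - (end - 1)))
  d[inside] <- 0
  as.integer(d)
}

#' Center of an interval
#'
#' Defined as `start + floor((end - start) / 2)` so even-length intervals
#' have a deterministic center.
#'
#' @param x an `interval_set` (or any data.frame with `start`/`end`).
#' @return Integer positions.
#' @export
interval_center <- function(x) {
  as.integer(x$start + (x$end - x$start) %/% 2L)
}
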