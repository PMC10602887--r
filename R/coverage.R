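#' Construct a coverage track
#'
#' A coverage track holds dense per-base signal for each chromosome of a
#' small genome, plus library-size metadata used for depth normalization.
#' Values must be finite and non-negative.
#'
#' @param values named list of numeric vectors, one per chromosome; element
#'   `i` is the signal on base `i - 1` (0-based genome coordinate).
#' @param library_size total mapped-read count or total signal; defaults to
#'   the sum of all values.
#' @param normalized logical; whether values are already depth-normalized.
#' @param label free-form tag (mark/timepoint/genotype).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, library_size = NULL, normalized = FALSE,
                           label = "") {
  if (!is.list(values) || is.null(names(values)) || any(!nzchar(names(values))))
    stop("values must be a named list of per-chromosome numeric vectors")
  for (chrom in names(values)) {
    v <- values[[chrom]]
    if (!is.numeric(v)) stop("values for ", chrom, " are not numeric")
    if (any(!is.finite(v)) || any(v < 0))
      stop("coverage on ", chrom, " must be finite and non-negative")
  }
  if (is.null(library_size))
    library_size <- sum(vapply(values, sum, 0))
  structure(
    list(values = values,
         chrom_sizes = vapply(values, length, 0L),
         library_size = as.numeric(library_size),
         normalized = isTRUE(normalized),
         label = label),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track", if (nzchar(x$label)) paste0("'", x$label, "'"), "\n")
  cat("  chromosomes:", length(x$values),
      "| genome:", sum(x$chrom_sizes), "bp\n")
  cat("  library_size:", format(x$library_size),
      "| normalized:", x$normalized, "\n")
  invisible(x)
}

#' Read a chrom.sizes table
#'
#' @param path two-column TSV (chromosome name, length in bp), no header.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "size"))
  stats::setNames(as.integer(df$size), df$chrom)
}

#' Load a coverage track from a bedGraph file
#'
#' Materializes dense per-base values over the supplied chromosome sizes;
#' bases not covered by any bedGraph interval get 0. A comment line of the
#' form `# library_size=<n>` is honoured as metadata; otherwise the library
#' size may be supplied, defaulting to the total signal.
#'
#' @param path bedGraph file (4 tab-separated columns, 0-based half-open),
#'   or a bigWig file (`.bw`/`.bigWig`, read via rtracklayer).
#' @param chrom_sizes named integer vector (see [read_chrom_sizes()]).
#' @param library_size optional override for the library size.
#' @param label track tag.
#' @return A `coverage_track` (unnormalized).
#' @export
load_track <- function(path, chrom_sizes, library_size = NULL, label = "") {
  if (!file.exists(path)) stop("track file not found: ", path)
  if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE))
    return(load_bigwig(path, chrom_sizes, library_size, label))
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#\\s*library_size=", lines, value = TRUE)
  if (is.null(library_size) && length(meta))
    library_size <- as.numeric(sub("^#\\s*library_size=", "", meta[1L]))
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  vals <- lapply(chrom_sizes, numeric)
  if (any(keep)) {
    df <- utils::read.table(
      text = lines[keep], sep = "\t", stringsAsFactors = FALSE,
      col.names = c("chrom", "start", "end", "value"),
      colClasses = c("character", "integer", "integer", "numeric")
    )
    unknown <- setdiff(unique(df$chrom), names(chrom_sizes))
    if (length(unknown))
      stop("bedGraph chromosome(s) absent from chrom_sizes: ",
           paste(unknown, collapse = ", "))
    if (any(df$start < 0L | df$start >= df$end))
      stop("bedGraph has invalid interval coordinates")
    if (any(df$end > chrom_sizes[df$chrom]))
      stop("bedGraph interval extends beyond chromosome end")
    for (chrom in unique(df$chrom)) {
      d <- df[df$chrom == chrom, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
        stop("overlapping bedGraph intervals on ", chrom)
      v <- vals[[chrom]]
      for (i in seq_len(nrow(d)))
        v[(d$start[i] + 1L):d$end[i]] <- d$value[i]
      vals[[chrom]] <- v
    }
  }
  coverage_track(vals, library_size = library_size, label = label)
}

load_bigwig <- function(path, chrom_sizes, library_size, label) {
  gr <- rtracklayer::import(path, format = "BigWig")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   value = S4Vectors::mcols(gr)$score,
                   stringsAsFactors = FALSE)
  unknown <- setdiff(unique(df$chrom), names(chrom_sizes))
  if (length(unknown))
    stop("bigWig chromosome(s) absent from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  if (any(df$end > chrom_sizes[df$chrom]))
    stop("bigWig interval extends beyond chromosome end")
  vals <- lapply(chrom_sizes, numeric)
  for (chrom in unique(df$chrom)) {
    d <- df[df$chrom == chrom, , drop = FALSE]
    v <- vals[[chrom]]
    for (i in seq_len(nrow(d)))
      v[(d$start[i] + 1L):d$end[i]] <- d$value[i]
    vals[[chrom]] <- v
  }
  coverage_track(vals, library_size = library_size, label = label)
}

#' Write a coverage track as bedGraph
#'
#' Zero runs are omitted (they are implicit on reload); the library size is
#' recorded in a `# library_size=` comment so a round trip preserves it.
#' Values are printed with full precision so reloading reproduces per-base
#' values exactly.
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# library_size=%.17g", track$library_size), con)
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%.17g", chrom, starts[keep], ends[keep],
                       r$values[keep]), con)
  }
  invisible(path)
}

#' Depth-normalize a coverage track
#'
#' Counts-per-million style scaling: every per-base value is multiplied by
#' `1e6 / library_size`. Pure rescaling, so all downstream ratios are
#' unaffected by the choice of unit.
#'
#' @param track an unnormalized `coverage_track`.
#' @param library_size positive scale; defaults to the track's own.
#' @return The normalized track (flag set; repeated normalization errors).
#' @export
normalize_depth <- function(track, library_size = track$library_size) {
  if (track$normalized)
    stop("track '", track$label, "' is already normalized")
  if (!is.numeric(library_size) || library_size <= 0)
    stop("library_size must be positive")
  f <- 1e6 / library_size
  track$values <- lapply(track$values, function(v) v * f)
  track$library_size <- library_size
  track$normalized <- TRUE
  track
}

#' Total coverage over an interval
#'
#' Sum of per-base values over `[start, end)`; the quantity summarized by
#' region boxplots and used as the super-enhancer ranking signal.
#'
#' @param track a `coverage_track`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds, within the chromosome.
#' @return Non-negative total.
#' @export
region_total <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  if (start < 0L || end > length(v) || start >= end)
    stop("interval [", start, ",", end, ") out of bounds on ", chrom)
  sum(v[(start + 1L):end])
}

#' Vectorized region totals
#'
#' @param track a `coverage_track`.
#' @param regions an `interval_set` (or data.frame with chrom/start/end).
#' @return Numeric vector of totals, one per region.
#' @export
region_totals <- function(track, regions) {
  vapply(seq_len(nrow(regions)), function(i) {
    region_total(track, regions$chrom[i], regions$start[i], regions$end[i])
  }, 0)
}

#' Extract a binned coverage matrix around anchor points
#'
#' Each anchor interval contributes one row covering the window
#' `[center - flank_bp, center + flank_bp)`, split into bins of `bin_width`
#' bp whose values are arithmetic means of the per-base signal. Bins that
#' extend past a chromosome end are masked (`NA`) rather than zero-filled,
#' so edge anchors do not bias aggregate profiles downward. Rows of
#' minus-strand anchors are reversed so column order is always 5' to 3'.
#'
#' @param track a `coverage_track`.
#' @param anchors an `interval_set`; the anchor point of each interval is its
#'   center, `start + floor(width/2)` (width-1 intervals are points).
#' @param flank_bp half-window, divisible by `bin_width`.
#' @param bin_width bin size in bp.
#' @return A `profile_matrix`: list with `values` (regions x bins matrix,
#'   masked cells `NA`), `bin_offsets` (bp offset of each bin start from the
#'   anchor), `bin_width`, `anchor_mode = "point_centered"`, `region_ids`.
#' @export
extract_matrix <- function(track, anchors, flank_bp = 2000L, bin_width = 10L) {
  flank_bp <- as.integer(flank_bp); bin_width <- as.integer(bin_width)
  if (flank_bp <= 0L || bin_width <= 0L)
    stop("flank_bp and bin_width must be positive")
  if (flank_bp %% bin_width != 0L)
    stop("flank_bp must be divisible by bin_width")
  unknown <- setdiff(unique(anchors$chrom), names(track$values))
  if (length(unknown))
    stop("anchor chromosome(s) unknown to track: ",
         paste(unknown, collapse = ", "))
  n_bins <- 2L * flank_bp %/% bin_width
  centers <- interval_center(anchors)
  n <- nrow(anchors)
  m <- matrix(NA_real_, nrow = n, ncol = n_bins)
  for (i in seq_len(n)) {
    v <- track$values[[anchors$chrom[i]]]
    L <- length(v)
    if (centers[i] < 0L || centers[i] >= L) {
      warning("anchor center outside chromosome; row ", i, " fully masked")
      next
    }
    pos <- (centers[i] - flank_bp):(centers[i] + flank_bp - 1L)
    vals <- rep(NA_real_, length(pos))
    ok <- pos >= 0L & pos < L
    vals[ok] <- v[pos[ok] + 1L]
    row <- colMeans(matrix(vals, nrow = bin_width))  # NA poisons partial bins
    if (identical(anchors$strand[i], "-")) row <- rev(row)
    m[i, ] <- row
  }
  ids <- anchors$name
  if (is.null(ids) || all(is.na(ids)))
    ids <- paste0(anchors$chrom, ":", anchors$start, "-", anchors$end)
  structure(
    list(values = m,
         bin_offsets = seq(-flank_bp, flank_bp - bin_width, by = bin_width),
         bin_width = bin_width,
         anchor_mode = "point_centered",
         region_ids = ids,
         label = track$label),
    class = "profile_matrix"
  )
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix (", x$anchor_mode, "): ",
      nrow(x$values), " regions x ", ncol(x$values), " bins\n", sep = "")
  invisible(x)
}
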