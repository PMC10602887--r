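# Independent brute-force oracles. These deliberately re-derive every
# quantity with naive loops and their own arithmetic; they must never call
# the package functions they check.

oracle_overlap <- function(a, b, min_bp = 1) {
  vapply(seq_len(nrow(a)), function(i) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      shared <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (shared >= min_bp) return(TRUE)
    }
    FALSE
  }, logical(1))
}

oracle_distance <- function(p, s, e) {
  if (p >= s && p < e) return(0L)
  as.integer(min(abs(p - s), abs(p - (e - 1))))
}

# Exhaustive nearest-enhancer scan with the module's tie-break rule
# (smaller distance, then smaller start, then smaller id).
oracle_nearest <- function(genes, enhancers, require_ar = TRUE) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    best <- NULL
    for (j in seq_len(nrow(enhancers))) {
      if (require_ar && !enhancers$ar_positive[j]) next
      if (enhancers$chrom[j] != genes$chrom[i]) next
      d <- oracle_distance(genes$tss[i], enhancers$start[j],
                           enhancers$end[j])
      cand <- list(d = d, start = enhancers$start[j],
                   id = enhancers$enhancer_id[j])
      if (is.null(best) || d < best$d ||
          (d == best$d && (cand$start < best$start ||
                           (cand$start == best$start && cand$id < best$id))))
        best <- cand
    }
    if (!is.null(best))
      out[[length(out) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i], enhancer_id = best$id,
        distance_bp = best$d, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Per-base binned-mean oracle for point-centered windows.
oracle_extract <- function(values_by_chrom, chrom, center, strand,
                           flank, bin_width) {
  v <- values_by_chrom[[chrom]]
  L <- length(v)
  n_bins <- 2 * flank / bin_width
  row <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    acc <- 0
    masked <- FALSE
    for (k in 0:(bin_width - 1)) {
      pos <- center - flank + (b - 1) * bin_width + k
      if (pos < 0 || pos >= L) { masked <- TRUE; break }
      acc <- acc + v[pos + 1]
    }
    row[b] <- if (masked) NA_real_ else acc / bin_width
  }
  if (strand == "-") row <- rev(row)
  row
}

oracle_geometric_mean <- function(col, pseudocount = 1) {
  x <- col[!is.na(col)]
  if (length(x) == 0) return(NA_real_)
  exp(sum(log(x + pseudocount)) / length(x)) - pseudocount
}

# Fractional-apportionment oracle for one gene body: per-base overlap with
# each of the B equal real-valued bins.
oracle_body_bins <- function(v, gs, ge, B) {
  L <- ge - gs
  bw <- L / B
  out <- numeric(B)
  for (b in seq_len(B)) {
    lo <- gs + (b - 1) * bw
    hi <- gs + b * bw
    acc <- 0
    for (i in floor(lo):ceiling(hi - 1e-12)) {
      ov <- min(hi, i + 1) - max(lo, i)
      if (ov > 0 && i >= 0 && i < length(v)) acc <- acc + v[i + 1] * ov
    }
    out[b] <- acc / bw
  }
  out
}

# Transitive-closure merge oracle (union-find by repeated sweeps).
oracle_stitch <- function(peaks, stitch_bp) {
  o <- order(peaks$chrom, peaks$start, peaks$end)
  p <- peaks[o, , drop = FALSE]
  regions <- list()
  cur <- NULL
  for (i in seq_len(nrow(p))) {
    if (is.null(cur)) {
      cur <- list(chrom = p$chrom[i], start = p$start[i], end = p$end[i])
    } else if (p$chrom[i] == cur$chrom &&
               p$start[i] - cur$end <= stitch_bp) {
      cur$end <- max(cur$end, p$end[i])
    } else {
      regions[[length(regions) + 1L]] <- cur
      cur <- list(chrom = p$chrom[i], start = p$start[i], end = p$end[i])
    }
  }
  if (!is.null(cur)) regions[[length(regions) + 1L]] <- cur
  do.call(rbind, lapply(regions, as.data.frame))
}

# Direct-formula paired t oracle (mean/sd/pt, no t.test).
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_stat, df = n - 1, p = 2 * pt(-abs(t_stat), df = n - 1))
}

# profile_matrix wrapper for hand-built matrices
make_pm <- function(m, bin_width = 10) {
  structure(list(values = m,
                 bin_offsets = seq(0, by = bin_width,
                                   length.out = ncol(m)),
                 bin_width = bin_width, anchor_mode = "point_centered",
                 region_ids = paste0("r", seq_len(nrow(m))), label = ""),
            class = "profile_matrix")
}

random_interval_set <- function(n, chroms = c("chr1", "chr2"),
                                chrom_len = 100000, max_width = 500) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(chrom_len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  interval_set(chrom, start, start + width,
               name = sprintf("iv_%04d", seq_len(n)),
               strand = sample(c("+", "-", "."), n, replace = TRUE))
}

random_track <- function(chrom_sizes, max_val = 10) {
  vals <- lapply(chrom_sizes, function(L)
    as.numeric(sample.int(max_val + 1, L, replace = TRUE) - 1L))
  coverage_track(vals)
}
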