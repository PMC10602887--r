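#' Simulation configuration
#'
#' Defines a miniature multi-condition dataset with the statistical
#' structure the analysis assumes: a small genome with non-overlapping
#' genes, intergenic enhancers (a planted fraction overlapped by AR peaks),
#' one clustered high-amplitude super-enhancer, per-(mark, timepoint,
#' genotype) Gaussian enrichment amplitudes over Poisson background, and
#' planted differentially expressed genes. All randomness flows from the
#' master seed via named substreams, so each output is independently
#' reproducible.
#'
#' @param seed master seed (integer).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param n_genes number of genes; bodies never overlap.
#' @param gene_length_range min/max gene length (bp), drawn uniformly.
#' @param n_enhancers number of enhancers, placed in intergenic space.
#' @param enhancer_width_range min/max enhancer width (bp).
#' @param ar_positive_fraction fraction of enhancers overlapped by a
#'   planted AR peak.
#' @param ar_peak_width_range min/max AR peak width (bp); at most the
#'   minimum enhancer width so AR peaks stay inside their enhancer.
#' @param marks marks to simulate.
#' @param timepoints induction timepoints (hours).
#' @param genotypes cell-line genotypes.
#' @param background_rate Poisson background (expected reads per bp).
#' @param enhancer_peak_sd,tss_peak_sd Gaussian peak shape widths (bp).
#' @param amplitude_plan data.frame from [default_amplitude_plan()] (or a
#'   modified copy) with columns `mark`, `timepoint`, `genotype`,
#'   `enhancer_amp`, `tss_amp`.
#' @param de_plan list: `contrasts` (named list of `list(n_up, n_down)`)
#'   and `padj_na_fraction` of null genes with missing padj.
#' @param se_plan list: `k` clustered enhancers and amplitude `multiplier`.
#' @param feature_buffer_bp minimum clearance between placed features.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    seed = 1L,
    chrom_sizes = c(chrS1 = 1000000L, chrS2 = 1000000L),
    n_genes = 80L,
    gene_length_range = c(3000L, 9000L),
    n_enhancers = 150L,
    enhancer_width_range = c(400L, 1200L),
    ar_positive_fraction = 0.4,
    ar_peak_width_range = c(200L, 400L),
    marks = c("H3.3", "H3K27Ac", "H3K4me1", "H3.3S31Ph", "AR", "BRD4",
              "ATAC"),
    timepoints = c(0, 4, 12, 24),
    genotypes = c("parental", "AR_KO", "Daxx_KO", "HIRA_KO"),
    background_rate = 0.5,
    enhancer_peak_sd = 150,
    tss_peak_sd = 100,
    amplitude_plan = default_amplitude_plan(),
    de_plan = list(contrasts = list(parental_4h = list(n_up = 40L,
                                                       n_down = 30L)),
                   padj_na_fraction = 0.05),
    se_plan = list(k = 6L, multiplier = 5),
    feature_buffer_bp = 500L) {
  # tolerate list-valued fields from YAML/JSON configs
  chrom_sizes <- unlist(chrom_sizes)
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector of chromosome lengths")
  gene_length_range <- unlist(gene_length_range)
  enhancer_width_range <- unlist(enhancer_width_range)
  ar_peak_width_range <- unlist(ar_peak_width_range)
  marks <- unlist(marks)
  timepoints <- unlist(timepoints)
  genotypes <- unlist(genotypes)
  stopifnot(length(chrom_sizes) >= 1L, all(chrom_sizes > 0),
            n_genes >= 0L, n_enhancers >= 0L,
            ar_positive_fraction >= 0, ar_positive_fraction <= 1,
            background_rate > 0, enhancer_peak_sd > 0, tss_peak_sd > 0)
  if (ar_peak_width_range[2] > enhancer_width_range[1])
    stop("ar_peak_width_range must not exceed the minimum enhancer width")
  structure(
    list(seed = as.integer(seed), chrom_sizes = chrom_sizes,
         n_genes = as.integer(n_genes),
         gene_length_range = as.integer(gene_length_range),
         n_enhancers = as.integer(n_enhancers),
         enhancer_width_range = as.integer(enhancer_width_range),
         ar_positive_fraction = ar_positive_fraction,
         ar_peak_width_range = as.integer(ar_peak_width_range),
         marks = marks, timepoints = timepoints, genotypes = genotypes,
         background_rate = background_rate,
         enhancer_peak_sd = enhancer_peak_sd, tss_peak_sd = tss_peak_sd,
         amplitude_plan = amplitude_plan, de_plan = de_plan,
         se_plan = se_plan,
         feature_buffer_bp = as.integer(feature_buffer_bp)),
    class = "simulation_config"
  )
}

#' Default per-condition enrichment amplitudes
#'
#' Encodes the qualitative chromatin dynamics the simulator emulates, per
#' mark, timepoint (0/4/12/24 h androgen induction) and genotype:
#' in parental cells AR spikes at 4 h and stays bound, H3K27Ac and
#' H3.3S31Ph rise gradually, H3.3 dips at 4 h (nucleosome displacement) and
#' is restored late; AR knockout zeroes AR and abolishes the acetylation
#' and BRD4 response; Daxx knockout transiently overshoots at 4 h; HIRA
#' knockout scales the H3.3 axis down (H3.3 amplitude ratio 0.3) and turns
#' AR/BRD4 binding into a 4 h spike followed by decay.
#'
#' @return data.frame with columns `mark`, `timepoint`, `genotype`,
#'   `enhancer_amp`, `tss_amp`.
#' @export
default_amplitude_plan <- function() {
  tp <- c(0, 4, 12, 24)
  base <- list(  # parental: list(enhancer amps, tss amps) over tp
    "H3.3"      = list(c(8, 6, 7, 9),       c(5, 5, 5, 6)),
    "H3K27Ac"   = list(c(3, 4, 5, 6),       c(2, 2, 3, 4)),
    "H3K4me1"   = list(c(6, 6, 6, 6),       c(1, 1, 1, 1)),
    "H3.3S31Ph" = list(c(1.5, 2.5, 3, 3.5), c(0.5, 0.5, 0.5, 0.5)),
    "AR"        = list(c(0.5, 8, 7.5, 7),   c(0, 0, 0, 0)),
    "BRD4"      = list(c(1, 5, 5, 5),       c(1, 1, 1, 1)),
    "ATAC"      = list(c(3, 5, 5, 4.5),     c(4, 4.5, 4.5, 4.5))
  )
  rows <- list()
  for (mark in names(base)) {
    enh <- base[[mark]][[1]]; tss <- base[[mark]][[2]]
    for (genotype in c("parental", "AR_KO", "Daxx_KO", "HIRA_KO")) {
      e <- enh; t <- tss
      if (genotype == "AR_KO") {
        switch(mark,
          "AR" = { e[] <- 0; t[] <- 0 },
          "BRD4" = { e[] <- 1; t[] <- 1 },
          "H3K27Ac" = { e[] <- 2; t[] <- 1.5 },
          "H3.3" = { e <- e * 0.6; t <- t * 0.6 },
          "H3.3S31Ph" = { e[] <- 1.5; t[] <- 0.5 },
          "ATAC" = { e[] <- 3; t[] <- 4 },
          "H3K4me1" = { e <- e * 0.7 })
      } else if (genotype == "Daxx_KO") {
        if (mark == "H3K27Ac") e[2] <- e[2] * 1.3
        if (mark == "AR") e[2] <- e[2] * 1.2
        if (mark == "H3.3") e[4] <- e[4] * 1.2
      } else if (genotype == "HIRA_KO") {
        switch(mark,
          "H3.3" = { e <- e * 0.3; t <- t * 0.3 },
          "H3.3S31Ph" = { e <- e * 0.35; t <- t * 0.35 },
          "H3K27Ac" = { e <- e * 0.4; t <- t * 0.4 },
          "H3K4me1" = { e <- e * 0.6 },
          "AR" = { e <- c(0.3, 10, 1, 0.8) },
          "BRD4" = { e <- c(1, 6, 1, 1) },
          "ATAC" = { e <- e * 0.6; t <- t * 0.6 })
      }
      rows[[length(rows) + 1L]] <- data.frame(
        mark = mark, timepoint = tp, genotype = genotype,
        enhancer_amp = e, tss_amp = t, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Deterministic substream seed below 2^31, derived from the master seed and
# a stream name so individual outputs are independently reproducible.
stream_seed <- function(master, name) {
  h <- as.numeric(master) %% 2147483563
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483563
  as.integer(h)
}

#' Simulate the genome annotation and planted truth
#'
#' Places non-overlapping gene bodies, intergenic non-overlapping
#' enhancers, AR peaks inside a planted fraction of enhancers, and one
#' cluster of `se_plan$k` enhancers within stitching range of one another
#' (the planted super-enhancer). Deterministic given the config seed.
#'
#' @param config a `simulation_config`.
#' @return A `synthetic_truth` list: `genes` (`gene_records`), `enhancers`
#'   (`interval_set` with SE constituents named `se_*`), `ar_peaks`
#'   (`interval_set`), `ar_positive_ids`, `se_enhancer_ids`, `config`.
#' @export
simulate_annotation <- function(config) {
  set.seed(stream_seed(config$seed, "annotation"))
  buf <- config$feature_buffer_bp
  chroms <- names(config$chrom_sizes)
  n_chrom <- length(chroms)
  gene_chrom <- sort(rep_len(seq_len(n_chrom), config$n_genes))
  genes <- list()
  gaps_all <- list()
  for (ci in seq_len(n_chrom)) {
    L <- config$chrom_sizes[[ci]]
    k <- sum(gene_chrom == ci)
    lens <- if (k > 0L)
      as.integer(round(stats::runif(k, config$gene_length_range[1],
                                    config$gene_length_range[2])))
    else integer(0)
    free <- L - sum(lens) - (k + 1L) * buf
    if (free < 0)
      stop("genome too small: chromosome ", chroms[ci],
           " cannot host ", k, " genes plus buffers")
    cuts <- sort(stats::runif(k, 0, free))
    gap_sizes <- as.integer(round(diff(c(0, cuts)))) + buf
    starts <- cumsum(gap_sizes) + c(0L, cumsum(lens))[seq_len(k)]
    if (k > 0L) {
      genes[[ci]] <- data.frame(
        chrom = chroms[ci], start = starts, end = starts + lens,
        strand = sample(c("+", "-"), k, replace = TRUE),
        stringsAsFactors = FALSE)
      bounds <- c(0L, as.vector(rbind(starts, starts + lens)), L)
      gs <- bounds[seq(1L, length(bounds), by = 2L)]
      ge <- bounds[seq(2L, length(bounds), by = 2L)]
    } else {
      gs <- 0L; ge <- L
    }
    gaps_all[[ci]] <- data.frame(chrom = chroms[ci], start = gs, end = ge,
                                 stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  genes <- gene_records(sprintf("gene_%03d", seq_len(nrow(genes))),
                        genes$chrom, genes$start, genes$end, genes$strand)
  gaps <- do.call(rbind, gaps_all)
  gaps$width <- gaps$end - gaps$start
  gaps <- gaps[gaps$width >= 2L * buf + config$enhancer_width_range[2], ,
               drop = FALSE]

  # Reserve the widest gap for the planted SE cluster.
  k_se <- config$se_plan$k
  se <- NULL
  if (k_se > 0L) {
    need <- k_se * (config$enhancer_width_range[2] + 2000L) + 2L * buf
    cand <- which(gaps$width >= need)
    if (length(cand) == 0L)
      stop("genome too small: no intergenic gap can host the ", k_se,
           "-enhancer SE cluster")
    gi <- cand[which.max(gaps$width[cand])]
    w <- as.integer(round(stats::runif(
      k_se, config$enhancer_width_range[1], config$enhancer_width_range[2])))
    spacing <- as.integer(round(stats::runif(k_se, 500, 2000)))
    starts <- gaps$start[gi] + buf + cumsum(spacing) +
      c(0L, cumsum(w))[seq_len(k_se)]
    se <- data.frame(chrom = gaps$chrom[gi], start = starts,
                     end = starts + w, stringsAsFactors = FALSE)
    gaps <- gaps[-gi, , drop = FALSE]
  }

  # Distribute remaining enhancers over gaps proportionally to capacity.
  n_rest <- config$n_enhancers - k_se
  rest <- NULL
  if (n_rest > 0L) {
    wmax <- config$enhancer_width_range[2]
    cap <- pmax((gaps$width - buf) %/% (wmax + buf), 0L)
    if (sum(cap) < n_rest)
      stop("genome too small: intergenic space fits only ", sum(cap),
           " of ", n_rest, " enhancers")
    alloc <- integer(nrow(gaps))
    order_by_cap <- order(-cap)
    left <- n_rest
    for (gi in order_by_cap) {
      take <- min(cap[gi], ceiling(left * cap[gi] / sum(cap)))
      take <- min(take, left)
      alloc[gi] <- take
      left <- left - take
      if (left == 0L) break
    }
    gi <- order_by_cap[1L]
    while (left > 0L) {  # top up in capacity order
      for (gi in order_by_cap) {
        if (left == 0L) break
        if (alloc[gi] < cap[gi]) { alloc[gi] <- alloc[gi] + 1L; left <- left - 1L }
      }
    }
    pieces <- list()
    for (gi in which(alloc > 0L)) {
      k <- alloc[gi]
      w <- as.integer(round(stats::runif(
        k, config$enhancer_width_range[1], config$enhancer_width_range[2])))
      free <- gaps$width[gi] - sum(w) - (k + 1L) * buf
      cuts <- sort(stats::runif(k, 0, free))
      gsz <- as.integer(round(diff(c(0, cuts)))) + buf
      starts <- gaps$start[gi] + cumsum(gsz) + c(0L, cumsum(w))[seq_len(k)]
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = gaps$chrom[gi], start = starts, end = starts + w,
        stringsAsFactors = FALSE)
    }
    rest <- do.call(rbind, pieces)
  }
  enh <- rbind(se, rest)
  if (is.null(enh) || nrow(enh) == 0L) {
    enhancers <- empty_interval_set()
    se_ids <- character(0)
  } else {
    enh <- enh[order(enh$chrom, enh$start), , drop = FALSE]
    is_se <- rep(FALSE, nrow(enh))
    if (!is.null(se))
      is_se <- enh$chrom %in% se$chrom[1] & enh$start %in% se$start
    ids <- sprintf("enh_%03d", seq_len(nrow(enh)))
    ids[is_se] <- sprintf("se_%02d", seq_len(sum(is_se)))
    enhancers <- interval_set(enh$chrom, enh$start, enh$end, name = ids,
                              provenance = "simulated enhancers")
    se_ids <- ids[is_se]
  }

  # AR peaks inside a planted fraction of enhancers (cluster included so
  # the SE is AR-associated, as in the study's FKBP5 region).
  n_pos <- round(config$ar_positive_fraction * nrow(enhancers))
  ar_ids <- character(0)
  ar_peaks <- empty_interval_set()
  if (n_pos > 0L && nrow(enhancers) > 0L) {
    pool <- setdiff(seq_len(nrow(enhancers)), which(enhancers$name %in% se_ids))
    n_from_pool <- max(n_pos - length(se_ids), 0L)
    sel <- sort(c(which(enhancers$name %in% se_ids)[seq_len(min(length(se_ids), n_pos))],
                  if (n_from_pool > 0L) sample(pool, n_from_pool)))
    w <- as.integer(round(stats::runif(length(sel),
                                       config$ar_peak_width_range[1],
                                       config$ar_peak_width_range[2])))
    centers <- interval_center(enhancers[sel, , drop = FALSE])
    ar_peaks <- interval_set(
      enhancers$chrom[sel], centers - w %/% 2L, centers - w %/% 2L + w,
      name = sprintf("ar_%03d", seq_along(sel)),
      provenance = "simulated AR peaks")
    ar_ids <- enhancers$name[sel]
  }

  structure(
    list(genes = genes, enhancers = enhancers, ar_peaks = ar_peaks,
         ar_positive_ids = ar_ids, se_enhancer_ids = se_ids,
         config = config),
    class = "synthetic_truth"
  )
}

#' Simulate a coverage track for one (mark, timepoint, genotype)
#'
#' Per-base expected rate is the Poisson background plus Gaussian bumps of
#' the planted amplitude at enhancer centers (times the SE multiplier for
#' cluster constituents) and gene TSSs; realized coverage is drawn per base
#' from a Poisson with that rate. Library size is the total realized
#' signal.
#'
#' @param truth a `synthetic_truth`.
#' @param mark,timepoint,genotype condition key; must exist in the
#'   amplitude plan.
#' @param seed optional override; defaults to the substream derived from
#'   the config seed and the condition.
#' @return An unnormalized `coverage_track` labelled
#'   `"<mark>_<timepoint>h_<genotype>"`.
#' @export
simulate_coverage <- function(truth, mark, timepoint, genotype,
                              seed = NULL) {
  config <- truth$config
  plan <- config$amplitude_plan
  row <- plan[plan$mark == mark & plan$timepoint == timepoint &
                plan$genotype == genotype, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("no amplitude entry for (", mark, ", ", timepoint, ", ",
         genotype, ")")
  label <- sprintf("%s_%sh_%s", mark, as.character(timepoint), genotype)
  if (is.null(seed)) seed <- stream_seed(config$seed,
                                         paste0("coverage:", label))
  set.seed(seed)
  vals <- list()
  for (chrom in names(config$chrom_sizes)) {
    L <- config$chrom_sizes[[chrom]]
    rate <- rep(config$background_rate, L)
    enh <- truth$enhancers[truth$enhancers$chrom == chrom, , drop = FALSE]
    if (nrow(enh) > 0L && row$enhancer_amp > 0) {
      amp <- rep(row$enhancer_amp, nrow(enh))
      amp[enh$name %in% truth$se_enhancer_ids] <-
        amp[enh$name %in% truth$se_enhancer_ids] * config$se_plan$multiplier
      rate <- add_gaussian_bumps(rate, interval_center(enh), amp,
                                 config$enhancer_peak_sd)
    }
    g <- truth$genes[truth$genes$chrom == chrom, , drop = FALSE]
    if (nrow(g) > 0L && row$tss_amp > 0)
      rate <- add_gaussian_bumps(rate, g$tss, rep(row$tss_amp, nrow(g)),
                                 config$tss_peak_sd)
    vals[[chrom]] <- stats::rpois(L, rate)
  }
  coverage_track(vals, label = label)
}

# Add A * exp(-(x - c)^2 / (2 sd^2)) bumps to a per-base rate vector,
# evaluated within +/- 5 sd of each center.
add_gaussian_bumps <- function(rate, centers, amps, sd) {
  L <- length(rate)
  half <- ceiling(5 * sd)
  for (i in seq_along(centers)) {
    lo <- max(centers[i] - half, 0L)
    hi <- min(centers[i] + half, L - 1L)
    if (lo > hi) next
    x <- lo:hi
    rate[x + 1L] <- rate[x + 1L] +
      amps[i] * exp(-(x - centers[i])^2 / (2 * sd^2))
  }
  rate
}

#' Simulate a differential-expression result table
#'
#' Planted up-regulated genes draw `log2FoldChange >= 1` with
#' `padj < 0.05`; planted down genes are symmetric; null genes draw fold
#' changes near zero and `padj` uniform on (0.05, 1], with a configurable
#' fraction getting missing `padj` (emulating upstream independent
#' filtering). Counts are exact by construction.
#'
#' @param truth a `synthetic_truth`.
#' @param contrast name of a contrast in the config's `de_plan`.
#' @param seed optional override (defaults to the contrast substream).
#' @return A data.frame with `gene_id`, `log2FoldChange`, `padj`; the
#'   planted up/down ids are attached as attributes `planted_up` /
#'   `planted_down`.
#' @export
simulate_de_table <- function(truth, contrast = NULL, seed = NULL) {
  config <- truth$config
  if (is.null(contrast)) contrast <- names(config$de_plan$contrasts)[1L]
  plan <- config$de_plan$contrasts[[contrast]]
  if (is.null(plan)) stop("unknown contrast: ", contrast)
  n <- nrow(truth$genes)
  if (plan$n_up + plan$n_down > n)
    stop("DE plan (", plan$n_up, " up + ", plan$n_down,
         " down) exceeds gene count ", n)
  if (is.null(seed)) seed <- stream_seed(config$seed, paste0("de:", contrast))
  set.seed(seed)
  ids <- truth$genes$gene_id
  pick <- sample(ids, plan$n_up + plan$n_down)
  up <- pick[seq_len(plan$n_up)]
  down <- setdiff(pick, up)
  lfc <- stats::rnorm(n, 0, 0.25)
  lfc <- pmin(pmax(lfc, -0.99), 0.99)
  padj <- stats::runif(n, 0.0500001, 1)
  na_frac <- config$de_plan$padj_na_fraction
  if (!is.null(na_frac) && na_frac > 0) {
    null_idx <- which(!ids %in% pick)
    n_na <- round(na_frac * length(null_idx))
    if (n_na > 0L) padj[sample(null_idx, n_na)] <- NA_real_
  }
  iu <- match(up, ids); id_ <- match(down, ids)
  lfc[iu] <- 1 + stats::rexp(plan$n_up, rate = 1)
  lfc[id_] <- -(1 + stats::rexp(plan$n_down, rate = 1))
  padj[iu] <- stats::runif(plan$n_up, 1e-8, 0.0499)
  padj[id_] <- stats::runif(plan$n_down, 1e-8, 0.0499)
  out <- data.frame(gene_id = ids, log2FoldChange = lfc, padj = padj,
                    stringsAsFactors = FALSE)
  attr(out, "planted_up") <- up
  attr(out, "planted_down") <- down
  out
}

#' Write a complete synthetic dataset to disk
#'
#' Emits `chrom.sizes`, `genes.tsv`, `enhancers.bed`, `ar_peaks.bed`,
#' one bedGraph per requested (mark, timepoint, genotype), one
#' `de_<contrast>.tsv` per planned contrast, and `truth.json` recording the
#' planted parameters. Deterministic given the config seed.
#'
#' @param config a `simulation_config`.
#' @param out_dir output directory (created if needed).
#' @param marks,timepoints,genotypes optional subsets of the config grid.
#' @return The `synthetic_truth`, invisibly, with attribute `files` listing
#'   every written path.
#' @export
simulate_dataset <- function(config, out_dir,
                             marks = config$marks,
                             timepoints = config$timepoints,
                             genotypes = config$genotypes) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_annotation(config)
  files <- character(0)
  p <- file.path(out_dir, "chrom.sizes")
  writeLines(sprintf("%s\t%d", names(config$chrom_sizes),
                     config$chrom_sizes), p)
  files <- c(files, p)
  p <- file.path(out_dir, "genes.tsv")
  write_gene_models(truth$genes, p); files <- c(files, p)
  p <- file.path(out_dir, "enhancers.bed")
  write_bed(truth$enhancers, p, n_fields = 4L); files <- c(files, p)
  p <- file.path(out_dir, "ar_peaks.bed")
  write_bed(truth$ar_peaks, p, n_fields = 4L); files <- c(files, p)
  for (mark in marks) for (tp in timepoints) for (g in genotypes) {
    track <- simulate_coverage(truth, mark, tp, g)
    p <- file.path(out_dir, paste0(track$label, ".bedGraph"))
    write_bedgraph(track, p)
    files <- c(files, p)
  }
  for (contrast in names(config$de_plan$contrasts)) {
    de <- simulate_de_table(truth, contrast)
    p <- file.path(out_dir, paste0("de_", contrast, ".tsv"))
    utils::write.table(de, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, p)
  }
  p <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(seed = config$seed,
         chrom_sizes = as.list(config$chrom_sizes),
         genes = truth$genes[, c("gene_id", "chrom", "start", "end",
                                 "strand")],
         enhancers = as.data.frame(truth$enhancers)[, c("name", "chrom",
                                                        "start", "end")],
         ar_positive_ids = truth$ar_positive_ids,
         se_enhancer_ids = truth$se_enhancer_ids,
         amplitude_plan = config$amplitude_plan,
         se_plan = config$se_plan,
         de_plan = lapply(config$de_plan$contrasts, function(x)
           list(n_up = x$n_up, n_down = x$n_down))),
    p, auto_unbox = TRUE, digits = NA)
  files <- c(files, p)
  attr(truth, "files") <- files
  invisible(truth)
}
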