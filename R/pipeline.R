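#' Run the full analysis pipeline
#'
#' Configuration-driven runner tying the stages together: synthetic data
#' generation (or user-supplied files), regulated-gene filtering, AR-positive
#' enhancer linking, geometric-mean profiles over AR-anchored, TSS-anchored
#' and metagene region sets for every (mark, timepoint, genotype) track,
#' super-enhancer calling, and the paired accessibility test. Each stage
#' consumes only files, so any stage can be re-run standalone; every run
#' writes a resolved-config copy, a log, and a manifest with content hashes.
#'
#' @param config a named list, or the path of a YAML/JSON file holding one.
#'   Recognized keys (all optional except one of `simulate`/`inputs`):
#'   \describe{
#'     \item{simulate}{arguments for [simulation_config()]; when present the
#'       data stage generates the dataset under `<out_dir>/data`.}
#'     \item{inputs}{paths for pre-existing data: `chrom_sizes`, `genes`,
#'       `enhancers`, `ar_peaks`, `tracks` (named list label -> bedGraph),
#'       `de_tables` (named list contrast -> TSV).}
#'     \item{params}{stage parameters: `fold_threshold` (2), `alpha` (0.05),
#'       `flank_bp` (2000), `bin_width` (10), `pseudocount` (1),
#'       `body_bins` (100), `metagene_flank_bp` (1000),
#'       `metagene_flank_bin_width` (10), `stitch_bp` (12500),
#'       `se_score_track` (label; default `H3K27Ac_4h_parental` when
#'       available), `paired_tracks` (character pair of track labels),
#'       `p_threshold` (1e-4).}
#'     \item{seed}{overrides the simulation seed.}
#'   }
#' @param out_dir output directory.
#' @return Path of the written `manifest.json`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  params <- utils::modifyList(
    list(fold_threshold = 2, alpha = 0.05, flank_bp = 2000L,
         bin_width = 10L, pseudocount = 1, body_bins = 100L,
         metagene_flank_bp = 1000L, metagene_flank_bin_width = 10L,
         stitch_bp = 12500L, se_score_track = NULL, paired_tracks = NULL,
         p_threshold = 1e-4),
    config$params %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    writeLines(msg, log_con)
    message(msg)
  }
  logmsg("enhancerdyn ",
         as.character(utils::packageVersion("enhancerdyn")),
         " pipeline start")
  artifacts <- list()
  add_artifact <- function(stage, path, extra = list()) {
    artifacts[[length(artifacts) + 1L]] <<- c(
      list(stage = stage, path = path,
           md5 = unname(tools::md5sum(path))), extra)
  }

  # --- stage: data --------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    sim_config <- do.call(simulation_config, sim_args)
    logmsg("stage data: simulating dataset (seed ", sim_config$seed, ")")
    data_dir <- file.path(out_dir, "data")
    truth <- simulate_dataset(sim_config, data_dir)
    for (p in attr(truth, "files")) add_artifact("data", p)
    inputs <- list(
      chrom_sizes = file.path(data_dir, "chrom.sizes"),
      genes = file.path(data_dir, "genes.tsv"),
      enhancers = file.path(data_dir, "enhancers.bed"),
      ar_peaks = file.path(data_dir, "ar_peaks.bed"),
      tracks = track_paths(data_dir, sim_config),
      de_tables = stats::setNames(
        file.path(data_dir, paste0("de_", names(sim_config$de_plan$contrasts),
                                   ".tsv")),
        names(sim_config$de_plan$contrasts))
    )
  } else if (!is.null(config$inputs)) {
    inputs <- config$inputs
  } else {
    stop("config needs either 'simulate' or 'inputs'")
  }
  missing <- !file.exists(unlist(c(inputs[c("chrom_sizes", "genes",
                                            "enhancers", "ar_peaks")],
                                   inputs$tracks, inputs$de_tables)))
  if (any(missing)) stop("missing input file(s)")

  chrom_sizes <- read_chrom_sizes(inputs$chrom_sizes)
  genes <- read_gene_models(inputs$genes, format = "tsv")
  enh_peaks <- read_bed(inputs$enhancers)
  ar_peaks <- read_bed(inputs$ar_peaks)

  # --- stage: regulated genes --------------------------------------------
  reg_dir <- file.path(out_dir, "regulated")
  reg_sets <- list()
  for (contrast in names(inputs$de_tables)) {
    de <- read_de_table(inputs$de_tables[[contrast]])
    sets <- filter_de(de, fold_threshold = params$fold_threshold,
                      alpha = params$alpha, contrast = contrast)
    logmsg("stage regulated [", contrast, "]: ", length(sets$up), " up, ",
           length(sets$down), " down")
    for (p in write_regulated_sets(sets, reg_dir, prefix = contrast))
      add_artifact("regulated", p, list(contrast = contrast))
    reg_sets[[contrast]] <- sets
  }

  # --- stage: enhancer linking -------------------------------------------
  link_dir <- file.path(out_dir, "linking")
  dir.create(link_dir, showWarnings = FALSE)
  enhancers <- call_enhancers(enh_peaks, ar_peaks)
  links_by <- list()
  for (contrast in names(reg_sets)) {
    for (direction in c("up", "down")) {
      ids <- reg_sets[[contrast]][[direction]]
      sub <- genes[genes$gene_id %in% ids, , drop = FALSE]
      if (nrow(sub) == 0L) {
        logmsg("stage linking [", contrast, " ", direction, "]: 0 genes")
        next
      }
      links <- withCallingHandlers(
        link_nearest(sub, enhancers),
        message = function(m) {
          writeLines(paste0("WARN ", conditionMessage(m)), log_con)
          invokeRestart("muffleMessage")
        })
      tsv <- file.path(link_dir, paste0(contrast, "_", direction,
                                        "_links.tsv"))
      json <- file.path(link_dir, paste0(contrast, "_", direction,
                                         "_summary.json"))
      if (nrow(links) > 0L) {
        write_links(links, tsv, json)
        add_artifact("linking", tsv, list(contrast = contrast,
                                          direction = direction))
        add_artifact("linking", json, list(contrast = contrast,
                                           direction = direction))
        logmsg("stage linking [", contrast, " ", direction, "]: ",
               nrow(links), " links, median ",
               link_summary(links)$median_distance_bp, " bp")
      }
      links_by[[paste(contrast, direction, sep = "_")]] <- links
    }
  }

  # --- stage: profiles ----------------------------------------------------
  prof_dir <- file.path(out_dir, "profiles")
  dir.create(prof_dir, showWarnings = FALSE)
  region_sets <- list(
    ar_anchored = ar_peaks,
    tss_anchored = tss_anchors(genes)
  )
  for (label in names(inputs$tracks)) {
    track <- load_track(inputs$tracks[[label]], chrom_sizes, label = label)
    track <- normalize_depth(track)
    for (set_name in names(region_sets)) {
      anchors <- region_sets[[set_name]]
      out_tsv <- file.path(prof_dir, paste0(label, "_", set_name, ".tsv"))
      if (nrow(anchors) == 0L) {
        utils::write.table(
          data.frame(condition = character(0), bin = integer(0),
                     bin_offset = numeric(0), gm = numeric(0),
                     n = integer(0)),
          out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
        logmsg("stage profiles [", label, " ", set_name, "]: 0 regions")
      } else {
        pm <- extract_matrix(track, anchors, flank_bp = params$flank_bp,
                             bin_width = params$bin_width)
        prof <- geometric_profile(pm, pseudocount = params$pseudocount)
        overlay_profiles(stats::setNames(list(prof), label), path = out_tsv)
      }
      add_artifact("profiles", out_tsv,
                   list(track = label, region_set = set_name,
                        n_regions = nrow(anchors)))
    }
    out_tsv <- file.path(prof_dir, paste0(label, "_metagene.tsv"))
    if (nrow(genes) == 0L) {
      utils::write.table(
        data.frame(condition = character(0), bin = integer(0),
                   bin_offset = numeric(0), gm = numeric(0),
                   n = integer(0)),
        out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      mm <- metagene_matrix(track, genes, body_bins = params$body_bins,
                            flank_bp = params$metagene_flank_bp,
                            flank_bin_width = params$metagene_flank_bin_width)
      prof <- geometric_profile(mm, pseudocount = params$pseudocount)
      overlay_profiles(stats::setNames(list(prof), label), path = out_tsv)
    }
    add_artifact("profiles", out_tsv,
                 list(track = label, region_set = "metagene",
                      n_regions = nrow(genes)))
  }

  # --- stage: super-enhancers --------------------------------------------
  se_dir <- file.path(out_dir, "superenhancer")
  dir.create(se_dir, showWarnings = FALSE)
  se_label <- params$se_score_track %||%
    (if ("H3K27Ac_4h_parental" %in% names(inputs$tracks))
      "H3K27Ac_4h_parental" else names(inputs$tracks)[1L])
  if (!is.null(se_label) && se_label %in% names(inputs$tracks) &&
      nrow(enh_peaks) > 0L) {
    track <- normalize_depth(load_track(inputs$tracks[[se_label]],
                                        chrom_sizes, label = se_label))
    stitched <- stitch_peaks(enh_peaks, stitch_bp = params$stitch_bp)
    stitched <- score_regions(stitched, track)
    ranked <- withCallingHandlers(
      rank_and_cut(stitched),
      warning = function(w) {
        writeLines(paste0("WARN ", conditionMessage(w)), log_con)
        invokeRestart("muffleWarning")
      })
    bed <- file.path(se_dir, "superenhancers.bed")
    json <- file.path(se_dir, "cutoff.json")
    write_se_calls(ranked, bed, json)
    add_artifact("superenhancer", bed, list(score_track = se_label))
    add_artifact("superenhancer", json, list(score_track = se_label))
    logmsg("stage superenhancer: ", attr(ranked, "cutoff")$n_super, " of ",
           attr(ranked, "cutoff")$n_total, " regions super (signal: ",
           se_label, ")")
  } else {
    logmsg("stage superenhancer: skipped (no signal track or no peaks)")
  }

  # --- stage: paired accessibility test ----------------------------------
  pt_dir <- file.path(out_dir, "accessibility")
  dir.create(pt_dir, showWarnings = FALSE)
  pair <- params$paired_tracks %||% intersect(
    c("ATAC_4h_parental", "ATAC_4h_HIRA_KO"), names(inputs$tracks))
  ar_pos <- enhancers[enhancers$ar_positive, , drop = FALSE]
  if (length(pair) == 2L && nrow(ar_pos) > 0L) {
    totals <- lapply(pair, function(lbl) {
      tr <- normalize_depth(load_track(inputs$tracks[[lbl]], chrom_sizes,
                                       label = lbl))
      data.frame(region_id = ar_pos$enhancer_id,
                 total = region_totals(tr, ar_pos))
    })
    tsvs <- file.path(pt_dir, paste0(pair, "_totals.tsv"))
    for (i in 1:2) {
      utils::write.table(totals[[i]], tsvs[i], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add_artifact("accessibility", tsvs[i], list(track = pair[i]))
    }
    res <- paired_t_test(totals[[1]]$total, totals[[2]]$total,
                         comparison = paste(pair, collapse = "_vs_"),
                         p_threshold = params$p_threshold)
    json <- file.path(pt_dir, "paired_test.json")
    jsonlite::write_json(unclass(res), json, auto_unbox = TRUE, digits = NA)
    add_artifact("accessibility", json)
    logmsg("stage accessibility: t = ", signif(res$t, 5), ", p = ",
           signif(res$p, 4), ", significant: ", res$significant)
  } else {
    logmsg("stage accessibility: skipped (needs a track pair and ",
           "AR-positive enhancers)")
  }

  # --- manifest and resolved config --------------------------------------
  cfg_path <- file.path(out_dir, "config.resolved.yaml")
  yaml::write_yaml(list(config = config, params = params), cfg_path)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(tool = "enhancerdyn",
         version = as.character(utils::packageVersion("enhancerdyn")),
         seed = config$seed %||% config$simulate$seed,
         artifacts = artifacts),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg("pipeline done: ", length(artifacts), " artifacts")
  invisible(manifest_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expected bedGraph paths for a simulated grid.
track_paths <- function(data_dir, sim_config) {
  grid <- expand.grid(mark = sim_config$marks,
                      timepoint = sim_config$timepoints,
                      genotype = sim_config$genotypes,
                      stringsAsFactors = FALSE)
  labels <- sprintf("%s_%sh_%s", grid$mark, as.character(grid$timepoint),
                    grid$genotype)
  stats::setNames(file.path(data_dir, paste0(labels, ".bedGraph")), labels)
}
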