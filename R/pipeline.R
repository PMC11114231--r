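# Configuration, orchestration and manifest generation for end-to-end runs on
# synthetic data.

#' Default run configuration
#'
#' All analysis thresholds at their published defaults plus synthetic-data
#' scale parameters. Every value is echoed into the run manifest.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    active_z = 1.64, rescue_z = 2.32, min_support = 5L, pseudocount = 0.001,
    importance_z = 1.96, min_zero_run = 4L, min_instances = 25L,
    n_shuffles = 100L, n_models = 10L, window = 100000L,
    top_k = 50000L, min_active = 10000L,
    n_chroms = 3L, chrom_len = 1e6, n_elements = 5000L, element_len = 300L,
    n_adult = 20L, n_fetal = 6L, n_neuron = 4L, n_glia = 4L,
    signal_shift_sd = 2.5, noise_sd = 1.0,
    n_species = 40L, n_primates = 10L,
    site_z = 3.0, importance_window = 402L, max_windows = 60L
  )
}

#' Read and validate a run configuration
#'
#' Reads a YAML file of configuration overrides, merges it onto
#' [default_config()], rejects unknown keys and validates ranges.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list applied after the file.
#' @return validated configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, user)
  if (cfg$min_support < 1) stop("min_support must be >= 1")
  if (cfg$pseudocount <= 0) stop("pseudocount must be > 0")
  if (cfg$n_shuffles < 1 || cfg$n_models < 1)
    stop("n_shuffles and n_models must be >= 1")
  cfg
}

write_tsv <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = !is.null(rownames(x)) &&
                       !identical(rownames(x), as.character(seq_len(nrow(x)))))
  path
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order (simulate, atlas, celltype,
#' conserve, enrich, ctfbs, motifs), writes per-stage outputs under `out_dir`
#' and a `manifest.json` with MD5 checksums and the configuration echo.
#' Identical config + seed produce identical checksums.
#'
#' @param config configuration list (see [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run (dependency closure is the
#'   caller's responsibility; default all).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("bccre_run_"),
                         stages = c("simulate", "atlas", "celltype", "conserve",
                                    "enrich", "ctfbs", "motifs")) {
  cfg <- read_run_config(NULL, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log_stage <- function(stage, msg)
    message(sprintf("[%s] %s", stage, msg))

  # --- simulate ---
  log_stage("simulate", "generating genome, elements and planted truth")
  world <- generate_genome_and_elements(cfg$seed, cfg$n_chroms, cfg$chrom_len,
                                        cfg$n_elements, cfg$element_len)
  acc <- simulate_accessibility_tracks(world$truth, world$elements,
                                       cfg$n_adult, cfg$n_fetal, cfg$n_neuron,
                                       cfg$n_glia, cfg$signal_shift_sd,
                                       cfg$noise_sd, seed = cfg$seed + 1L)
  aln <- simulate_alignment_fractions(world$truth, cfg$n_species,
                                      cfg$n_primates, seed = cfg$seed + 2L)
  aux <- simulate_expression_and_regions(world$truth, world$elements,
                                         seed = cfg$seed + 3L)
  if ("simulate" %in% stages) {
    write_element_bed(world$elements, file.path(out_dir, "elements.bed"))
    Biostrings::writeXStringSet(world$genome, file.path(out_dir, "genome.fa"))
    truth_df <- data.frame(id = world$truth$ids,
                           life_stage = world$truth$life_stage,
                           cell_type = world$truth$cell_type,
                           cons_group = world$truth$cons_group)
    write_tsv(truth_df, file.path(out_dir, "truth.tsv"))
    files <- c(files, "elements.bed", "genome.fa", "truth.tsv")
  }

  # --- atlas ---
  log_stage("atlas", "consensus calling of brain-active elements")
  is_af <- acc$groups$class %in% c("adult", "fetal")
  z <- zscore_matrix(acc$tracks[is_af], world$elements, cfg$pseudocount)
  activity <- z > cfg$active_z
  adult_cols <- acc$groups$class[is_af] == "adult"
  adult_set <- consensus_bccres(activity[, adult_cols], z[, adult_cols],
                                cfg$min_support, rescue_threshold = NULL)
  fetal_set <- consensus_bccres(activity[, !adult_cols], z[, !adult_cols],
                                cfg$min_support, cfg$rescue_z)
  stage_label <- classify_life_stage(adult_set, fetal_set, world$truth$ids)
  if ("atlas" %in% stages) {
    write_tsv(round(z, 4), file.path(out_dir, "zscores.tsv"))
    bccre <- world$elements[stage_label[names(world$elements)] != "non-brain"]
    S4Vectors::mcols(bccre)$label <- unname(stage_label[names(bccre)])
    write_element_bed(bccre, file.path(out_dir, "bccres.bed"))
    files <- c(files, "zscores.tsv", "bccres.bed")
  }

  # --- celltype ---
  log_stage("celltype", "aggregating neuron/glia tracks and classifying")
  zn <- lognorm_zscores(mean_signal_over_elements(
    sum_tracks(acc$tracks[acc$groups$class == "neuron"]), world$elements),
    cfg$pseudocount)
  zg <- lognorm_zscores(mean_signal_over_elements(
    sum_tracks(acc$tracks[acc$groups$class == "glia"]), world$elements),
    cfg$pseudocount)
  bccre_ids <- world$truth$ids[stage_label != "non-brain"]
  ct_label <- classify_neuron_glia(zn[bccre_ids], zg[bccre_ids], cfg$active_z,
                                   ids = bccre_ids)
  if ("celltype" %in% stages) {
    df <- data.frame(id = bccre_ids, z_neuron = round(zn[bccre_ids], 4),
                     z_glia = round(zg[bccre_ids], 4), label = ct_label)
    write_tsv(df, file.path(out_dir, "celltype.tsv"))
    files <- c(files, "celltype.tsv")
  }

  # --- conserve ---
  log_stage("conserve", "triangle coordinates, groups, slices and origins")
  coords <- triangle_coordinates(aln$fractions)
  groups <- conservation_groups(aln$fractions, aln$species)
  slices <- triangle_slices(coords$N1, coords$N2)
  origin <- evolutionary_origin(aln$fractions, aln$species)
  if ("conserve" %in% stages) {
    df <- data.frame(id = rownames(coords), N1 = coords$N1, N2 = coords$N2,
                     group = unname(groups), slice = slices,
                     origin = unname(origin))
    write_tsv(df, file.path(out_dir, "conservation.tsv"))
    files <- c(files, "conservation.tsv")
  }

  # --- enrich ---
  log_stage("enrich", "validation weighting and shuffle enrichment")
  vista_classes <- ifelse(stage_label == "non-brain", "nb-cCRE",
                          unname(stage_label))
  cls_el <- world$elements
  S4Vectors::mcols(cls_el)$label <- vista_classes[names(cls_el)]
  vw <- vista_weighted_validation(aux$regions, cls_el)
  genome_sizes <- setNames(rep(cfg$chrom_len, cfg$n_chroms),
                           paste0("chr", seq_len(cfg$n_chroms)))
  bccre_el <- world$elements[bccre_ids]
  enr <- shuffle_enrichment(bccre_el, aux$regions, genome_sizes,
                            n_shuffles = cfg$n_shuffles, seed = cfg$seed + 4L)
  traits <- select_independent_traits(aux$rg, seed = cfg$seed + 5L)
  if ("enrich" %in% stages) {
    write_tsv(as.data.frame(vw$weights), file.path(out_dir, "vista_weights.tsv"))
    jsonlite::write_json(enr, file.path(out_dir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(traits, file.path(out_dir, "independent_traits.txt"))
    files <- c(files, "vista_weights.tsv", "enrichment.json",
               "independent_traits.txt")
  }

  # --- ctfbs ---
  log_stage("ctfbs", "HMM segmentation of importance tracks")
  imp <- simulate_importance_tracks(world$truth, world$elements, aux$catalog,
                                    aux$planted_motifs,
                                    cell_types = c("neuron", "glia"),
                                    site_z = cfg$site_z,
                                    window_len = cfg$importance_window,
                                    max_windows = cfg$max_windows,
                                    genome = world$genome,
                                    seed = cfg$seed + 6L)
  ctfbs_out <- list()
  for (ct in c("neuron", "glia")) {
    zi <- importance_zscores(imp[[ct]]$importance)
    sym <- discretize_importance(zi, cfg$importance_z)
    model <- fit_importance_hmm(sym, seed = cfg$seed + 7L)
    calls <- call_ctfbs(model, sym, windows = imp[[ct]]$windows,
                        importance = imp[[ct]]$importance,
                        min_zero_run = cfg$min_zero_run)
    if (nrow(calls) > 0L) {
      seqs <- vapply(seq_len(nrow(calls)), function(i)
        as.character(Biostrings::subseq(imp$genome[[calls$chrom[i]]],
                                        calls$start[i], calls$end[i])), "")
      best <- lapply(seqs, assign_best_motif, catalog = aux$catalog)
      calls$motif <- vapply(best, `[[`, "", "motif")
      calls$similarity <- vapply(best, `[[`, 0, "similarity")
    }
    ctfbs_out[[ct]] <- calls
    if ("ctfbs" %in% stages) {
      fn <- sprintf("ctfbs_%s.bed", ct)
      df <- calls
      if (nrow(df) > 0L)
        df <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                         name = df$motif, score = round(df$similarity, 3),
                         strand = ".", direction = df$direction,
                         mean_importance = round(df$mean_importance, 4))
      write_tsv(df, file.path(out_dir, fn))
      files <- c(files, fn)
    }
  }

  # --- motifs ---
  log_stage("motifs", "random-forest motif importance")
  ids_n <- names(imp$neuron$windows)
  seqs_pos <- vapply(ids_n, function(id) {
    el <- world$elements[id]
    as.character(Biostrings::subseq(
      imp$genome[[as.character(GenomicRanges::seqnames(el))]],
      GenomicRanges::start(el), GenomicRanges::end(el)))
  }, "")
  seqs_neg <- vapply(seq_along(seqs_pos), function(i)
    dinucleotide_shuffle(seqs_pos[i], seed = cfg$seed + 100L + i), "")
  pos_feat <- pwm_max_scores(seqs_pos, aux$catalog)
  neg_feat <- pwm_max_scores(seqs_neg, aux$catalog)
  importance <- rf_motif_importance(pos_feat, neg_feat,
                                    n_models = cfg$n_models,
                                    seed = cfg$seed + 8L)
  if ("motifs" %in% stages) {
    write_tsv(data.frame(motif = names(importance),
                         importance = unname(importance)),
              file.path(out_dir, "motif_importance.tsv"))
    files <- c(files, "motif_importance.tsv")
  }

  manifest <- list(
    config = cfg,
    stages = stages,
    files = lapply(setNames(files, files), function(f)
      list(path = f, md5 = unname(tools::md5sum(file.path(out_dir, f)))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
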