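## Pipeline orchestration: a single configuration object with every
## threshold at its standard default, stage drivers, and the
## reference-strategy comparison harness.

#' Default pipeline configuration
#'
#' All thresholds of the pipeline with their standard defaults: the ddRAD
#' digest window, demultiplex/trim/quality settings, alignment budget,
#' cluster depth window, genotype-calling and marker filters, and mapping
#' thresholds. The configuration round-trips unchanged through YAML.
#'
#' @param ... named overrides of any default.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # simulation
    scaffold_lengths = rep(600000L, 4), repeat_fraction = 0.4,
    gene_density = 0.05, het_rate_maternal = 3e-4, het_rate_paternal = 3.7e-3,
    conv_frac = 0.5, cm_per_mb = 0.9, n_progeny = 51L,
    mean_depth = 30, dispersion = 10, error_rate = 0.001, read_len = 100L,
    parent_depth_mult = 2,
    # digest
    enzyme1_site = "ATGCAT", cut_after1 = 5L, enzyme2_site = "TTAA",
    cut_after2 = 1L, min_len = 200L, max_len = 500L,
    # read processing
    tag_len = 92L, min_q = 20L, max_low_q = 4L,
    # alignment + clustering
    max_mm = 2L, max_indel = 2L, seed_len = 23L,
    cluster_min_depth = 4L, cluster_max_depth = 200L,
    # genotyping + filters
    het_min_frac = 0.25, call_min_depth = 3L, min_cover = 0.90,
    max_missing = 0.10,
    # mapping
    lod_min = 5.0, rf_max = 0.25, ripple_window = 3L,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop_radmap("unknown config keys: %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Simulate a study-structured dataset
#'
#' Generates the genome, parents, progeny and reads of one synthetic
#' experiment under a configuration.
#'
#' @param cfg a [pipeline_config()].
#' @return List with `genome`, `parents`, `progeny`, `sim` (reads and
#'   samples).
#' @export
simulate_dataset <- function(cfg = pipeline_config()) {
  genome <- simulate_genome(cfg$scaffold_lengths,
                            repeat_fraction = cfg$repeat_fraction,
                            gene_density = cfg$gene_density, seed = cfg$seed)
  parents <- simulate_parents(genome, cfg$het_rate_maternal,
                              cfg$het_rate_paternal, conv_frac = cfg$conv_frac,
                              seed = cfg$seed)
  progeny <- simulate_f1(genome, parents, cm_per_mb = cfg$cm_per_mb,
                         n_progeny = cfg$n_progeny, seed = cfg$seed)
  sim <- sim_radseq_experiment(genome, parents, progeny,
                               mean_depth = cfg$mean_depth,
                               dispersion = cfg$dispersion,
                               error_rate = cfg$error_rate,
                               read_len = cfg$read_len,
                               parent_depth_mult = cfg$parent_depth_mult,
                               seed = cfg$seed,
                               enzyme1_site = cfg$enzyme1_site,
                               cut_after1 = cfg$cut_after1,
                               enzyme2_site = cfg$enzyme2_site,
                               cut_after2 = cfg$cut_after2,
                               min_len = cfg$min_len, max_len = cfg$max_len)
  list(genome = genome, parents = parents, progeny = progeny, sim = sim)
}

#' Run marker discovery and mapping against one reference mode
#'
#' @param tags processed tag table from [process_reads()].
#' @param genome an `annotated_genome`.
#' @param samples sample table (`sample_id`, `role`).
#' @param mode reference mode (`"unmasked"`, `"masked"`, `"genemodels"`).
#' @param cfg a [pipeline_config()].
#' @return List with `index`, `alignments`, `clusters`, `markers`
#'   (`cp_geno`), `bins`, `map` (paternal `genetic_map`), and `summary`
#'   (scored/mapped counts, percent anchored, mean concordance purity).
#' @export
run_reference_mode <- function(tags, genome, samples, mode, cfg = pipeline_config()) {
  index <- build_reference_index(genome, mode, seed_len = cfg$seed_len)
  utags <- unique(tags$tag)
  aln0 <- align_tags(index, utags, max_mm = cfg$max_mm,
                     max_indel = cfg$max_indel, tag_len = cfg$tag_len)
  aln0[, tag := utags]
  aln <- merge(tags[, .(sample_id, tag)], aln0, by = "tag",
               allow.cartesian = TRUE)
  parents <- samples$sample_id[samples$role %in% c("mother", "father")]
  cl <- build_clusters(aln, parents, min_depth = cfg$cluster_min_depth,
                       max_depth = cfg$cluster_max_depth)
  mother <- samples$sample_id[samples$role == "mother"]
  father <- samples$sample_id[samples$role == "father"]
  prog <- samples$sample_id[samples$role == "progeny"]
  mk <- call_markers(cl$clusters, mother, father, prog,
                     min_frac = cfg$het_min_frac,
                     min_depth = cfg$call_min_depth,
                     min_cover = cfg$min_cover, max_missing = cfg$max_missing)
  out <- list(index = index, alignments = aln, clusters = cl, markers = mk$geno,
              filter_log = mk$log)
  if (is.null(mk$geno) ||
      sum(mk$geno$info$seg_type %in% c("nnxnp", "hkxhk")) < 4) {
    out$summary <- data.table(mode = mode, scored = 0L, mapped = 0L,
                              percent_anchored = NA_real_,
                              mean_purity = NA_real_)
    return(out)
  }
  bins <- collapse_bins(mk$geno)
  map <- tryCatch(
    build_genetic_map(bins$geno, "paternal", lod_min = cfg$lod_min,
                      rf_max = cfg$rf_max, ripple_window = cfg$ripple_window),
    error = function(e) NULL)
  out$bins <- bins
  out$map <- map
  scored <- sum(mk$geno$info$seg_type %in% c("nnxnp", "hkxhk"))
  if (is.null(map) || length(map$lgs) == 0) {
    out$summary <- data.table(mode = mode, scored = scored, mapped = 0L,
                              percent_anchored = 0,
                              mean_purity = NA_real_)
    return(out)
  }
  placed_bins <- map_table(map)$marker
  mapped <- sum(bins$bins$representative %in% placed_bins &
                  bins$bins$marker %in%
                  mk$geno$info$marker[mk$geno$info$seg_type %in% c("nnxnp", "hkxhk")])
  conc <- build_concordance(map, mk$geno$info, genome$lengths,
                            top_n = length(genome$lengths))
  out$concordance <- conc
  out$summary <- data.table(mode = mode, scored = scored, mapped = mapped,
                            percent_anchored = percent_anchored(mapped, scored),
                            mean_purity = mean(conc$purity, na.rm = TRUE))
  out
}

#' Reference-strategy comparison on one simulated dataset
#'
#' Runs the same processed reads against the unmasked, repeat-masked and
#' gene-model references and collects the per-mode summaries used to
#' choose a marker-scoring strategy.
#'
#' @param cfg a [pipeline_config()].
#' @param modes reference modes to run.
#' @return List with `dataset`, `tags`, per-mode results, and `summary`
#'   (one row per mode).
#' @export
compare_references <- function(cfg = pipeline_config(),
                               modes = c("unmasked", "masked", "genemodels")) {
  ds <- simulate_dataset(cfg)
  pr <- process_reads(ds$sim$reads, ds$sim$samples[, .(sample_id, barcode)],
                      tag_len = cfg$tag_len, min_q = cfg$min_q,
                      max_low_q = cfg$max_low_q)
  runs <- lapply(modes, function(m)
    run_reference_mode(pr$tags, ds$genome, ds$sim$samples, m, cfg))
  names(runs) <- modes
  list(dataset = ds, tags = pr, runs = runs,
       summary = rbindlist(lapply(runs, `[[`, "summary")))
}

#' Run the full pipeline end to end
#'
#' Simulation, read processing, alignment against the configured reference
#' mode, marker discovery, binning, paternal map construction, scaffold
#' anchoring and megascaffold statistics on one configuration.
#'
#' @param cfg a [pipeline_config()].
#' @param mode reference mode (default `"masked"`, the optimal strategy).
#' @param out_dir optional directory to write report TSVs, the AGP and the
#'   genotype matrix into.
#' @return List with all stage outputs (`dataset`, `tags`, `run`,
#'   `anchors`, `megascaffolds`, `stats`).
#' @export
run_pipeline <- function(cfg = pipeline_config(), mode = "masked",
                         out_dir = NULL) {
  ds <- simulate_dataset(cfg)
  pr <- process_reads(ds$sim$reads, ds$sim$samples[, .(sample_id, barcode)],
                      tag_len = cfg$tag_len, min_q = cfg$min_q,
                      max_low_q = cfg$max_low_q)
  run <- run_reference_mode(pr$tags, ds$genome, ds$sim$samples, mode, cfg)
  out <- list(dataset = ds, tags = pr, run = run)
  if (!is.null(run$map) && length(run$map$lgs) > 0) {
    asg <- assign_scaffolds(run$map, run$markers$info)
    meg <- order_orient(asg, run$map, run$markers$info, ds$genome$lengths)
    tab <- map_table(run$map)
    lg_cm <- tab[, .(cm = max(cm), markers = .N), by = lg]
    phys <- meg$scaffolds[, .(mb = sum(len) / 1e6, n_scf = .N), by = lg]
    st <- merge(lg_cm, phys, by = "lg", all.x = TRUE)
    out$anchors <- asg
    out$megascaffolds <- meg
    out$stats <- map_stats(st$lg, st$cm, st$markers,
                           fifelse(is.na(st$mb), 0, st$mb),
                           scaffolds = fifelse(is.na(st$n_scf), 0L, st$n_scf))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fwrite_tsv <- function(x, f)
      utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    fwrite_tsv(run$summary, "summary.tsv")
    if (!is.null(run$markers))
      fwrite_tsv(cbind(run$markers$info,
                       as.data.table(run$markers$calls)), "genotypes.tsv")
    if (!is.null(out$stats)) fwrite_tsv(out$stats, "map_stats.tsv")
    if (!is.null(out$megascaffolds))
      write_agp(out$megascaffolds, file.path(out_dir, "megascaffolds.agp"))
    if (!is.null(run$map)) fwrite_tsv(map_table(run$map), "map.tsv")
    if (!is.null(run$bins)) fwrite_tsv(run$bins$bins, "bins.tsv")
    if (!is.null(run$concordance))
      write_concordance(run$concordance,
                        file.path(out_dir, "concordance_counts.tsv"),
                        file.path(out_dir, "concordance_fractions.tsv"))
  }
  out
}
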