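# allowed keys per config section; unknown keys are an error
config_schema <- list(
  top = c("output_dir", "stages", "simulate", "target", "ewce", "network",
          "preservation", "ldsc"),
  stages = c("ewce", "network", "preservation", "heritability"),
  simulate = c("seed", "cell_profiles", "tissues", "ld", "sumstats"),
  cell_profiles = c("n_genes", "cell_types", "n_markers_per_type",
                    "fold_change", "dispersion"),
  tissues = c("n_genes", "names", "n_samples", "noise_sd", "blocks"),
  ld = c("n_snps", "n_individuals", "block_size", "within_block_rho",
         "chrom_length", "maf_min", "maf_max"),
  sumstats = c("seed", "n_gwas_sample", "gwas"),
  target = c("n_genes"),
  ewce = c("reps", "seed", "n_quantiles", "alpha"),
  network = c("beta", "cut_height", "min_size", "kmeans_iters"),
  preservation = c("n_permutations", "seed"),
  ldsc = c("window_bp", "n_blocks", "maf_min", "flank_bp", "kme_min",
           "seed", "alpha", "n_baseline_random")
)

check_keys <- function(x, section) {
  unknown <- setdiff(names(x), config_schema[[section]])
  if (length(unknown))
    dn_stop("unknown config key(s) in '", section, "': ",
            paste(unknown, collapse = ", "))
  x
}

fill <- function(x, defaults) {
  for (k in names(defaults)) if (is.null(x[[k]])) x[[k]] <- defaults[[k]]
  x
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent nested list), checks
#' every section against the known key set, fills defaults, and enforces
#' that every stochastic stage carries an explicit seed. The normalized
#' configuration is echoed to the log and returned; validation is
#' idempotent, so re-validating a serialized validated config is a no-op.
#'
#' @param config Path to a YAML file, or a nested list.
#' @return The normalized configuration list (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) dn_stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- check_keys(config, "top")
  cfg$stages <- fill(check_keys(cfg$stages %||% list(), "stages"),
                     list(ewce = TRUE, network = TRUE, preservation = TRUE,
                          heritability = TRUE))
  sim <- check_keys(cfg$simulate %||% list(), "simulate")
  if (is.null(sim$seed)) dn_stop("missing seed: simulate.seed")
  sim$cell_profiles <- fill(check_keys(sim$cell_profiles %||% list(),
                                       "cell_profiles"),
                            list(n_genes = 2000,
                                 cell_types = list(neuron = 250, astro = 250,
                                                   oligo = 250, micro = 250),
                                 n_markers_per_type = 50, fold_change = 8,
                                 dispersion = 0.5))
  sim$tissues <- fill(check_keys(sim$tissues %||% list(), "tissues"),
                      list(n_genes = 1000,
                           names = c("putamen", "cortex", "cerebellum"),
                           n_samples = 150, noise_sd = 1,
                           blocks = list(
                             list(size = 60, strength = 0.8,
                                  tissue = "putamen"),
                             list(size = 50, strength = 0.8, tissue = "all"),
                             list(size = 40, strength = 0.7, tissue = "all"))))
  sim$ld <- fill(check_keys(sim$ld %||% list(), "ld"),
                 list(n_snps = 4000, n_individuals = 400, block_size = 20,
                      within_block_rho = 0.6, chrom_length = 4e7,
                      maf_min = 0.05, maf_max = 0.5))
  sim$sumstats <- fill(check_keys(sim$sumstats %||% list(), "sumstats"),
                       list(n_gwas_sample = 10000,
                            gwas = list(trait_linked = list(tau_module = 5e-5),
                                        trait_null = list(tau_module = 0))))
  if (is.null(sim$sumstats$seed)) dn_stop("missing seed: simulate.sumstats.seed")
  cfg$simulate <- sim
  cfg$target <- fill(check_keys(cfg$target %||% list(), "target"),
                     list(n_genes = 30))
  cfg$ewce <- check_keys(cfg$ewce %||% list(), "ewce")
  if (isTRUE(cfg$stages$ewce) && is.null(cfg$ewce$seed))
    dn_stop("missing seed: ewce.seed")
  cfg$ewce <- fill(cfg$ewce, list(reps = 2000, n_quantiles = 10,
                                  alpha = 0.05, seed = NA))
  cfg$network <- fill(check_keys(cfg$network %||% list(), "network"),
                      list(beta = 6, cut_height = 0.92, min_size = 30,
                           kmeans_iters = 30))
  cfg$preservation <- check_keys(cfg$preservation %||% list(), "preservation")
  if (isTRUE(cfg$stages$preservation) && is.null(cfg$preservation$seed))
    dn_stop("missing seed: preservation.seed")
  cfg$preservation <- fill(cfg$preservation,
                           list(n_permutations = 50, seed = NA))
  cfg$ldsc <- check_keys(cfg$ldsc %||% list(), "ldsc")
  if (isTRUE(cfg$stages$heritability) && is.null(cfg$ldsc$seed))
    dn_stop("missing seed: ldsc.seed")
  cfg$ldsc <- fill(cfg$ldsc, list(window_bp = 1e6, n_blocks = 100,
                                  maf_min = 0.05, flank_bp = 1e5,
                                  kme_min = 0.5, alpha = 0.05,
                                  n_baseline_random = 2, seed = NA))
  cfg$output_dir <- cfg$output_dir %||% NULL
  dn_log("config", "validated: stages ",
         paste(names(Filter(isTRUE, cfg$stages)), collapse = ", "))
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Serialize a validated configuration to YAML text
#' @param config A `pipeline_config`.
#' @return A YAML string.
#' @export
serialize_config <- function(config) {
  yaml::as.yaml(unclass(config))
}

#' Run the full pipeline on synthetic data with planted signal
#'
#' Executes the stages in dependency order: data simulation; specificity +
#' expression-weighted cell-type enrichment of the target list; per-tissue
#' signed co-expression networks and module over-representation of the
#' target list; module preservation of the first tissue's modules across
#' the remaining tissues; stratified LD-score heritability of the enriched
#' modules' kME-filtered annotations. The target list is the leading block
#' of gene symbols, which the generators plant both as markers of the first
#' cell type and as members of the first (tissue-specific) co-expression
#' block, so every stage has a recoverable planted conclusion. Any stage
#' failure aborts with a stage-tagged error.
#'
#' @param config A `pipeline_config` from [validate_config()] (or a path /
#'   raw list, validated on entry).
#' @return A `run_report` list with one element per executed stage plus
#'   `params`. When `config$output_dir` is set, stage tables are written as
#'   TSV and the report as JSON under that directory.
#' @export
run_all <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  report <- list(params = list(seed = cfg$simulate$seed,
                               stages = cfg$stages))
  stage <- function(name, expr) {
    dn_log(name, "running")
    tryCatch(expr, error = function(e)
      dn_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
  }
  out_dir <- cfg$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  save_tsv <- function(df, file) {
    if (!is.null(out_dir))
      utils::write.table(df, file.path(out_dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }

  any_stage <- any(unlist(cfg$stages))
  if (!any_stage) {
    report$note <- "all stages disabled"
    if (!is.null(out_dir))
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = 10, pretty = TRUE)
    return(structure(report, class = c("run_report", "list")))
  }

  ## --- simulate ---------------------------------------------------------
  sim <- cfg$simulate
  cells <- stage("simulate", simulate_cell_profiles(
    n_genes = sim$cell_profiles$n_genes,
    cell_types = unlist(sim$cell_profiles$cell_types),
    n_markers_per_type = sim$cell_profiles$n_markers_per_type,
    fold_change = sim$cell_profiles$fold_change,
    dispersion = sim$cell_profiles$dispersion,
    seed = sim$seed))
  tiss <- stage("simulate", simulate_tissue_expression(
    n_genes = sim$tissues$n_genes, tissues = sim$tissues$names,
    n_samples = sim$tissues$n_samples, blocks = sim$tissues$blocks,
    noise_sd = sim$tissues$noise_sd, seed = sim$seed + 1L))
  target <- gene_list("target",
                      sprintf("G%05d", seq_len(cfg$target$n_genes)))
  report$simulate <- list(
    n_genes_cells = sim$cell_profiles$n_genes,
    n_genes_tissue = sim$tissues$n_genes,
    tissues = sim$tissues$names,
    target_size = length(target$genes))

  ## --- EWCE -------------------------------------------------------------
  if (isTRUE(cfg$stages$ewce)) {
    spec <- stage("ewce", compute_specificity(cells$counts, cells$cell_meta))
    bins <- stage("ewce", match_covariate_bins(cells$gene_annot,
                                               rownames(spec),
                                               cfg$ewce$n_quantiles))
    ew <- stage("ewce", bootstrap_enrichment(spec, target,
                                             reps = cfg$ewce$reps,
                                             bins = bins,
                                             seed = cfg$ewce$seed))
    save_tsv(ew, "ewce_results.tsv")
    report$ewce <- list(significant = flag_significant(ew, cfg$ewce$alpha),
                        table = ew)
  }

  ## --- networks + module enrichment ------------------------------------
  if (isTRUE(cfg$stages$network)) {
    nets <- stage("network", lapply(tiss$expr, function(x)
      build_network(x, beta = cfg$network$beta,
                    cut_height = cfg$network$cut_height,
                    min_size = cfg$network$min_size,
                    kmeans_iters = cfg$network$kmeans_iters)))
    enr <- stage("enrich", module_list_enrichment(nets, target))
    save_tsv(enr, "module_enrichment.tsv")
    hits <- enr[enr$q < 0.05, , drop = FALSE]
    report$network <- list(
      modules_per_tissue = lapply(nets, function(n)
        as.list(table(n$labels[n$labels != "grey"]))),
      n_modules_tested = nrow(enr),
      enriched = hits[, c("network", "module", "overlap", "q")],
      overlap_genes = hits$overlap_genes)
  }

  ## --- preservation -----------------------------------------------------
  if (isTRUE(cfg$stages$preservation)) {
    if (!isTRUE(cfg$stages$network))
      dn_stop("stage 'preservation' failed: requires stage 'network'")
    home <- sim$tissues$names[[1]]
    others <- setdiff(sim$tissues$names, home)
    pres <- stage("preserve", do.call(rbind, lapply(others, function(ts) {
      df <- preservation_statistics(tiss$expr[[home]], tiss$expr[[ts]],
                                    nets[[home]]$labels,
                                    beta = cfg$network$beta,
                                    n_permutations =
                                      cfg$preservation$n_permutations,
                                    seed = cfg$preservation$seed)
      df$test_tissue <- ts
      df
    })))
    summ <- stage("preserve", summarize_preservation(pres))
    # flag the module carrying the planted target genes
    home_labels <- nets[[home]]$labels
    tg_mod <- names(sort(table(home_labels[intersect(target$genes,
                                                     names(home_labels))]),
                         decreasing = TRUE))[1]
    summ$carries_target <- summ$module == tg_mod
    save_tsv(pres, "preservation_detail.tsv")
    save_tsv(summ, "preservation_summary.tsv")
    report$preservation <- list(reference_tissue = home, summary = summ)
  }

  ## --- heritability -----------------------------------------------------
  if (isTRUE(cfg$stages$heritability)) {
    if (!isTRUE(cfg$stages$network))
      dn_stop("stage 'heritability' failed: requires stage 'network'")
    ld <- stage("ldsc", simulate_ld_reference(
      n_snps = sim$ld$n_snps, n_individuals = sim$ld$n_individuals,
      block_size = sim$ld$block_size,
      within_block_rho = sim$ld$within_block_rho,
      maf_range = c(sim$ld$maf_min, sim$ld$maf_max),
      chrom_length = sim$ld$chrom_length, seed = sim$seed + 2L))
    coords <- stage("ldsc", simulate_gene_coordinates(
      sim$tissues$n_genes, chrom_length = sim$ld$chrom_length,
      seed = sim$seed + 3L))
    # true annotation: the planted tissue-specific block, full membership
    block1 <- names(tiss$truth$block)[tiss$truth$block == 1L]
    truth_annot <- build_gene_annotation(
      block1, stats::setNames(rep(1, length(block1)), block1), coords,
      ld$map, kme_threshold = cfg$ldsc$kme_min,
      flank_bp = cfg$ldsc$flank_bp, maf_min = cfg$ldsc$maf_min)
    set.seed(cfg$ldsc$seed)
    n_rand <- cfg$ldsc$n_baseline_random
    baseline <- cbind(base = rep(1L, nrow(ld$map)),
                      matrix(stats::rbinom(nrow(ld$map) * n_rand, 1, 0.3),
                             ncol = n_rand,
                             dimnames = list(NULL,
                                             paste0("rand", seq_len(n_rand)))))
    rownames(baseline) <- ld$map$snp
    base_scores <- stage("ldsc", compute_ld_scores(ld, baseline,
                                                   cfg$ldsc$window_bp))
    truth_scores <- stage("ldsc", compute_ld_scores(
      ld, matrix(truth_annot, ncol = 1,
                 dimnames = list(ld$map$snp, "module")), cfg$ldsc$window_bp))
    gwas <- list()
    for (gw in names(sim$sumstats$gwas)) {
      tau <- c(base = 0, module = sim$sumstats$gwas[[gw]]$tau_module)
      ss <- stage("ldsc", simulate_sumstats(
        ld, cbind(baseline, module = truth_annot), tau,
        N = sim$sumstats$n_gwas_sample,
        seed = sim$sumstats$seed + match(gw, names(sim$sumstats$gwas)),
        ld_scores = cbind(base_scores, truth_scores)))
      gwas[[gw]] <- ss$sumstats
    }
    # module annotations from detected, target-enriched modules
    hits <- enr[enr$q < 0.05, , drop = FALSE]
    if (nrow(hits) == 0L)
      dn_stop("stage 'heritability' failed: no enriched modules to test")
    hits <- utils::head(hits, 6L)
    modules <- list()
    for (i in seq_len(nrow(hits))) {
      net <- nets[[hits$network[i]]]
      members <- names(net$labels)[net$labels == hits$module[i]]
      modules[[paste(hits$network[i], hits$module[i], sep = ".")]] <-
        build_gene_annotation(members, net$kme[members, hits$module[i]],
                              coords, ld$map,
                              kme_threshold = cfg$ldsc$kme_min,
                              flank_bp = cfg$ldsc$flank_bp,
                              maf_min = cfg$ldsc$maf_min)
    }
    bat <- stage("ldsc", run_heritability_battery(
      modules, gwas, ld, baseline, window_bp = cfg$ldsc$window_bp,
      n_blocks = cfg$ldsc$n_blocks, alpha = cfg$ldsc$alpha,
      baseline_scores = base_scores))
    save_tsv(bat, "heritability.tsv")
    report$heritability <- list(threshold = attr(bat, "threshold"),
                                table = bat)
  }

  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  structure(report, class = c("run_report", "list"))
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (!is.null(x$ewce))
    cat("  EWCE significant cell types:",
        paste(x$ewce$significant, collapse = ", "), "\n")
  if (!is.null(x$network))
    cat("  enriched modules:",
        paste(paste0(x$network$enriched$network, ".",
                     x$network$enriched$module), collapse = ", "), "\n")
  if (!is.null(x$preservation)) {
    s <- x$preservation$summary
    cat("  preservation (median Z):",
        paste(sprintf("%s=%.1f(%s)", s$module, s$median_z, s$category),
              collapse = ", "), "\n")
  }
  if (!is.null(x$heritability)) {
    h <- x$heritability$table
    sig <- h[h$bonferroni_significant, ]
    cat("  Bonferroni-significant heritability:",
        paste(paste0(sig$module, " x ", sig$gwas), collapse = ", "), "\n")
  }
  invisible(x)
}
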