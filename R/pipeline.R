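#' Scan one analysis trait and summarize its significant effects
#'
#' Permutation threshold plus single-QTL genome scan (optionally
#' refined by multiple interval mapping) for one trait vector, returning
#' the tagged effect rows the classifier consumes.
#'
#' @param probs a [genotype_probabilities()] object
#' @param y named line values of the analysis trait
#' @param trait analysis trait name (e.g. `"dGY"`)
#' @param set set tag: `obs`, `df`, `d` or `ddf`
#' @param base_trait observed trait the value derives from
#' @param env environment tag (`WW`, `WL`, or `both`)
#' @param n_perm,alpha,seed permutation-threshold parameters
#' @param mim apply [mim_refine()] when more than one chromosome carries
#'   an effect (default TRUE)
#' @param cap LOD ceiling
#' @return data.frame of effect rows (possibly empty), with `threshold`
#' @export
scan_trait <- function(probs, y, trait, set, base_trait, env,
                       n_perm = 1000L, alpha = 0.05, seed = 1L,
                       mim = TRUE, cap = 50) {
  if (stats::sd(y, na.rm = TRUE) == 0 || sum(!is.na(y)) < 10L)
    return(empty_effects())
  thr <- permutation_threshold(probs, y, n_perm, alpha, seed, cap)
  prof <- scan_single(probs, y, cap)
  eff <- effect_summary(prof, thr)
  if (nrow(eff) == 0L) return(empty_effects())
  if (mim && nrow(eff) > 1L) {
    eff <- mim_refine(eff, probs, y, cap = cap)
  } else {
    eff$lod_mim <- eff$lod; eff$a_mim <- eff$a; eff$pev_mim <- eff$pev
  }
  data.frame(trait = trait, base_trait = base_trait, set = set, env = env,
             eff, threshold = thr$threshold, stringsAsFactors = FALSE)
}

empty_effects <- function() {
  data.frame(trait = character(), base_trait = character(), set = character(),
             env = character(), chrom = character(), pos_cM = numeric(),
             lod = numeric(), a = numeric(), pev = numeric(),
             itv = character(), ci_lo = numeric(), ci_hi = numeric(),
             n = integer(), lod_mim = numeric(), a_mim = numeric(),
             pev_mim = numeric(), threshold = numeric(),
             stringsAsFactors = FALSE)
}

#' Scan every observed and derivative trait
#'
#' The full multi-set scan sweep: observed traits per environment,
#' phenology-adjusted (`df`) traits per environment, drought plasticity
#' I (`d`) and II (`ddf`) traits.  Per-trait permutation thresholds (no
#' cross-trait multiplicity correction); the per-trait seed is derived
#' deterministically from `seed`.
#'
#' @param probs a [genotype_probabilities()] object
#' @param means line means from [aggregate_means()]
#' @param derivs derivative traits from [derivative_traits()]
#' @param n_perm,alpha,seed scan parameters
#' @param mim apply MIM refinement
#' @return combined effects data.frame (see [scan_trait()])
#' @export
scan_all_traits <- function(probs, means, derivs, n_perm = 1000L,
                            alpha = 0.05, seed = 1L, mim = TRUE) {
  jobs <- list()
  for (tr in unique(means$trait)) for (e in c("WW", "WL")) {
    v <- line_mean_vector(means, tr, e)
    jobs[[length(jobs) + 1L]] <- list(y = v, trait = paste0(tr, "_", e),
                                      set = "obs", base = tr, env = e)
  }
  for (dt in unique(derivs$trait)) {
    sub <- derivs[derivs$trait == dt, , drop = FALSE]
    v <- stats::setNames(sub$value, sub$line)
    jobs[[length(jobs) + 1L]] <- list(y = v, trait = dt, set = sub$set[1],
                                      base = sub$base_trait[1], env = sub$env[1])
  }
  out <- vector("list", length(jobs))
  for (k in seq_along(jobs)) {
    j <- jobs[[k]]
    out[[k]] <- scan_trait(probs, j$y, j$trait, j$set, j$base, j$env,
                           n_perm = n_perm, alpha = alpha,
                           seed = seed + k, mim = mim)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pipeline configuration
#'
#' Either simulated mode (a [sim_config()] plus architecture) or
#' real-data mode (paths to genotype, phenotype and optional anchor /
#' GFF3 files), with all stage parameters in one place.
#'
#' @param mode `"simulate"` or `"files"`
#' @param sim a [sim_config()] (simulate mode)
#' @param arch a [trait_architecture()] (simulate mode)
#' @param genotypes_tsv,phenotypes_tsv input paths (files mode)
#' @param anchors_tsv,gff3 optional physical-anchoring inputs
#' @param rf_threshold,max_missing,max_chi2,target_groups map stage
#' @param step_cM,n_perm,alpha,seed scan stage
#' @param run_genes run the candidate-gene stage (needs anchors + gff3)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(mode = c("simulate", "files"),
                            sim = sim_config(), arch = default_trait_architecture(),
                            genotypes_tsv = NULL, phenotypes_tsv = NULL,
                            anchors_tsv = NULL, gff3 = NULL,
                            rf_threshold = 0.2, max_missing = 0.10,
                            max_chi2 = 35, target_groups = 14L,
                            step_cM = 1, n_perm = 1000L, alpha = 0.05,
                            seed = 1L, run_genes = !is.null(gff3)) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, sim = sim, arch = arch,
              genotypes_tsv = genotypes_tsv, phenotypes_tsv = phenotypes_tsv,
              anchors_tsv = anchors_tsv, gff3 = gff3,
              rf_threshold = rf_threshold, max_missing = max_missing,
              max_chi2 = max_chi2, target_groups = target_groups,
              step_cM = step_cM, n_perm = n_perm, alpha = alpha,
              seed = as.integer(seed), run_genes = run_genes)
  if (mode == "files") {
    for (f in c("genotypes_tsv", "phenotypes_tsv"))
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
        stop("files mode requires an existing ", f)
  }
  if (cfg$run_genes && (is.null(cfg$anchors_tsv) || is.null(cfg$gff3)))
    stop("candidate-gene stage enabled but anchors_tsv / gff3 missing")
  if (cfg$run_genes && !is.null(cfg$anchors_tsv) && !file.exists(cfg$anchors_tsv))
    stop("anchor table not found: ", cfg$anchors_tsv)
  if (cfg$run_genes && !is.null(cfg$gff3) && !file.exists(cfg$gff3))
    stop("GFF3 not found: ", cfg$gff3)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Scalar fields map one-to-one onto [pipeline_config()] arguments;
#' `sim:` is passed to [sim_config()].
#'
#' @param path YAML or JSON file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  sim <- do.call(sim_config, raw$sim %||% list())
  args <- raw[setdiff(names(raw), "sim")]
  do.call(pipeline_config, c(list(sim = sim), args))
}

#' Run the whole analysis pipeline
#'
#' simulate/load -> trait derivation and statistics -> map construction
#' and diagnostics -> multi-set QTL scans -> locus classification ->
#' (optional) candidate genes.  Every output file is checksummed into a
#' machine-readable JSON report together with parameters, seeds and
#' versions; re-running the same configuration reproduces identical
#' checksums.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory
#' @return invisibly, the run report (also written to `report.json`)
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warn_log <- list()
  note <- function(stage, w) warn_log[[stage]] <<- c(warn_log[[stage]], w)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- character(0)

  # stage: data
  if (config$mode == "simulate") {
    study <- simulate_study(config$sim, config$arch)
    geno <- study$geno; phenotypes <- study$phenotypes
    files <- c(files, unname(write_simulated_study(
      list(map = study$map, geno = geno, phenotypes = phenotypes,
           truth = study$truth), out_dir)))
  } else {
    geno <- read_genotypes_tsv(config$genotypes_tsv)
    phenotypes <- read_phenotypes_tsv(config$phenotypes_tsv)
  }

  # stage: traits
  agg <- aggregate_means(phenotypes)
  derivs <- withCallingHandlers(
    derivative_traits(agg$means),
    warning = function(w) { note("traits", conditionMessage(w)); invokeRestart("muffleWarning") })
  h2 <- do.call(rbind, lapply(unique(phenotypes$trait), function(tr) {
    v <- variance_components_heritability(phenotypes, tr)
    data.frame(trait = tr, MS_gen = v$MS_gen, MS_gxe = v$MS_gxe,
               sigma2_g = v$sigma2_g, sigma2_gxe = v$sigma2_gxe, h2 = v$h2,
               truncated = v$truncated, stringsAsFactors = FALSE)
  }))
  obs_mat <- trait_matrix(agg$means[agg$means$env == "WL", ], "mean")
  cors <- correlation_analysis(obs_mat, "pearson")
  files <- c(files, tsv(agg$means, "line_means.tsv"),
             tsv(derivs, "derivative_traits.tsv"),
             tsv(h2, "heritability.tsv"),
             tsv(cors$edges, "correlation_edges_WL.tsv"))

  # stage: map
  gmap <- withCallingHandlers(
    build_genetic_map(geno, config$max_missing, config$max_chi2,
                      config$rf_threshold, config$target_groups),
    warning = function(w) { note("map", conditionMessage(w)); invokeRestart("muffleWarning") })
  diag <- map_diagnostics(geno, gmap$map, alpha = 0.05)
  files <- c(files, tsv(gmap$map, "genetic_map.tsv"),
             tsv(gmap$groups, "linkage_groups.tsv"),
             tsv(diag$marker_distortion, "marker_distortion.tsv"))
  if (!is.null(config$anchors_tsv)) {
    anchors <- read_anchors_tsv(config$anchors_tsv)
    conc <- withCallingHandlers(
      physical_concordance(gmap$map, anchors),
      warning = function(w) { note("map", conditionMessage(w)); invokeRestart("muffleWarning") })
    if (!is.null(conc)) files <- c(files, tsv(conc, "physical_concordance.tsv"))
  }

  # stage: scan
  probs <- genotype_probabilities(gmap$map, geno, config$step_cM)
  effects <- scan_all_traits(probs, agg$means, derivs,
                             n_perm = config$n_perm, alpha = config$alpha,
                             seed = config$seed)
  files <- c(files, tsv(effects, "qtl_effects.tsv"))

  # stage: classify
  loci <- group_colocalized_effects(effects)
  classified <- classify_loci(loci)
  itv <- itv_accounting(loci)
  arch_summary <- summarize_architecture(loci, classified)
  files <- c(files,
             tsv(classified %||% empty_classified(), "loci_classified.tsv"),
             tsv(itv, "itv_accounting.tsv"),
             tsv(arch_summary, "architecture_summary.tsv"))

  # stage: genes
  gene_tables <- NULL
  if (config$run_genes) {
    anchors <- read_anchors_tsv(config$anchors_tsv)
    genes <- read_gene_models_gff3(config$gff3)
    rows <- list()
    for (lc in loci) {
      pi <- tryCatch(qtl_physical_interval(lc, gmap$map, anchors),
                     error = function(e) { note("genes", conditionMessage(e)); NULL })
      if (is.null(pi)) next
      gl <- genes_in_interval(pi, genes)
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = pi$locus_id, chrom = pi$chrom, start_bp = pi$start_bp,
        end_bp = pi$end_bp, n_genes = gl$n_genes,
        excluded_from_cg = gl$excluded_from_cg, stringsAsFactors = FALSE)
    }
    gene_tables <- do.call(rbind, rows)
    if (!is.null(gene_tables))
      files <- c(files, tsv(gene_tables, "qtl_physical_intervals.tsv"))
  }

  report <- list(
    parameters = config[setdiff(names(config), c("arch"))],
    versions = list(R = as.character(getRversion()),
                    plastiqtl = as.character(utils::packageVersion("plastiqtl"))),
    n_effects = nrow(effects), n_loci = length(loci),
    warnings = warn_log,
    checksums = as.list(tools::md5sum(sort(unique(files)))))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

empty_classified <- function() {
  data.frame(locus_id = character(), chrom = character(), ci_lo = numeric(),
             ci_hi = numeric(), n_effects = integer(), n_traits = integer(),
             multi_trait = logical(), phenology = character(),
             drought = character(), strategies = character(),
             op_resistance_allele = character(), stringsAsFactors = FALSE)
}
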