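#' Simulation configuration for a biparental RIL study
#'
#' Defines the dimensions and nuisance processes of a simulated
#' recombinant-inbred-line (RIL) experiment: a two-parent cross advanced
#' to near-complete homozygosity, genotyped on a skeleton marker grid and
#' phenotyped with replicates under two irrigation regimes (well-watered
#' `WW` and water-limited `WL`).
#'
#' The defaults reproduce the dimensions of the wheat study the package
#' is built around: 150 lines, 14 chromosomes totalling about 1750 cM
#' with ~1.3 cM marker spacing (about 1360 skeleton loci), and three
#' replicates per environment.
#'
#' @param n_lines number of RILs (>= 2)
#' @param n_chromosomes number of chromosomes / linkage groups
#' @param chrom_lengths_cM numeric vector of map lengths (recycled to
#'   `n_chromosomes`); default spans 85-165 cM as in tetraploid wheat
#' @param marker_spacing_cM inter-marker distance on the skeleton grid
#' @param missing_rate fraction of genotype calls set to missing in
#'   [`corrupt_genotypes()`], in `[0, 1)`
#' @param distortion per-chromosome segregation-distortion shift of the
#'   favoured-allele frequency away from 0.5, in `(-0.5, 0.5)`; positive
#'   values favour the wild parent (`B`), negative the cultivated parent
#'   (`A`); recycled to `n_chromosomes`
#' @param replicates_per_env replicates per line and environment
#' @param seed integer RNG seed; fixing it makes all outputs reproducible
#' @return an object of class `sim_config` (a validated list)
#' @export
sim_config <- function(n_lines = 150L,
                       n_chromosomes = 14L,
                       chrom_lengths_cM = NULL,
                       marker_spacing_cM = 1.3,
                       missing_rate = 0,
                       distortion = 0,
                       replicates_per_env = 3L,
                       seed = 1L) {
  if (is.null(chrom_lengths_cM))
    chrom_lengths_cM <- round(seq(85, 165, length.out = n_chromosomes))
  chrom_lengths_cM <- rep_len(chrom_lengths_cM, n_chromosomes)
  distortion <- rep_len(distortion, n_chromosomes)
  if (n_lines < 2L) stop("n_lines must be >= 2")
  if (n_chromosomes < 1L) stop("need at least one chromosome")
  if (any(chrom_lengths_cM <= 0)) stop("all chromosome lengths must be > 0")
  if (marker_spacing_cM <= 0) stop("marker_spacing_cM must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (any(abs(distortion) >= 0.5)) stop("distortion shifts must be in (-0.5, 0.5)")
  if (replicates_per_env < 1L) stop("replicates_per_env must be >= 1")
  structure(list(
    n_lines = as.integer(n_lines),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_lengths_cM = as.numeric(chrom_lengths_cM),
    marker_spacing_cM = marker_spacing_cM,
    missing_rate = missing_rate,
    distortion = as.numeric(distortion),
    replicates_per_env = as.integer(replicates_per_env),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Chromosome names "1A".."7B" for 14 chromosomes, else "chr1", "chr2", ...
chromosome_names <- function(n) {
  if (n == 14L) paste0(rep(1:7, each = 2), rep(c("A", "B"), 7))
  else paste0("chr", seq_len(n))
}

#' Simulate a skeleton genetic map and RIL genotypes
#'
#' Places markers on each chromosome at regular `marker_spacing_cM`
#' intervals and simulates each RIL chromosome as a Markov crossover
#' process on the observed (selfed-RIL) scale: adjacent markers recombine
#' with probability `R = 2r/(1+2r)` where the meiotic `r` comes from the
#' Kosambi inverse of the inter-marker distance.  Genotypes are fully
#' homozygous two-state codes, `A` for the cultivated parent (P1) and
#' `B` for the wild parent (P2).
#'
#' @param config a [sim_config()]
#' @return a list with `map` (data.frame: `marker`, `chrom`, `pos_cM`)
#'   and `geno` (character matrix lines x markers with codes `A`/`B`)
#' @export
simulate_map_and_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- chromosome_names(config$n_chromosomes)
  map_list <- vector("list", config$n_chromosomes)
  geno_list <- vector("list", config$n_chromosomes)
  for (c_i in seq_len(config$n_chromosomes)) {
    len <- config$chrom_lengths_cM[c_i]
    pos <- seq(0, len, by = config$marker_spacing_cM)
    m <- length(pos)
    ids <- sprintf("%s_m%03d", chroms[c_i], seq_len(m))
    map_list[[c_i]] <- data.frame(marker = ids, chrom = chroms[c_i],
                                  pos_cM = pos, stringsAsFactors = FALSE)
    R_adj <- ril_cM_to_R(diff(pos))
    # state in {-1,+1}; a recombination between adjacent markers flips it
    start <- sample(c(-1, 1), config$n_lines, replace = TRUE)
    if (m > 1L) {
      flips <- matrix(stats::runif(config$n_lines * (m - 1L)) <
                        rep(R_adj, each = config$n_lines),
                      config$n_lines, m - 1L)
      signs <- cbind(rep(1, config$n_lines), ifelse(flips, -1, 1))
      dos <- start * t(apply(signs, 1L, cumprod))
    } else {
      dos <- matrix(start, ncol = 1L)
    }
    colnames(dos) <- ids
    geno_list[[c_i]] <- dos
  }
  map <- do.call(rbind, map_list)
  dos <- do.call(cbind, geno_list)
  rownames(dos) <- sprintf("RIL%03d", seq_len(config$n_lines))
  list(map = map, geno = dosage_to_geno(dos))
}

#' Inject missing calls and segregation distortion
#'
#' Applies the configured nuisance processes to a clean genotype matrix:
#' calls are set to missing uniformly at random at `missing_rate`, and on
#' chromosomes with a nonzero `distortion` shift `s`, whole line x
#' chromosome genotype vectors are replaced by the favoured parent's with
#' probability `2|s|`, so the favoured-allele frequency is `0.5 + |s|`
#' in expectation while within-chromosome co-segregation is preserved
#' (whole-chromosome transmission bias also inflates the non-recombinant
#' chromosome count, as observed in wide wheat crosses).
#'
#' @param geno character genotype matrix from [simulate_map_and_genotypes()]
#' @param map its marker map (needed to locate chromosomes)
#' @param config a [sim_config()]
#' @return the corrupted genotype matrix
#' @export
corrupt_genotypes <- function(geno, map, config) {
  stopifnot(inherits(config, "sim_config"))
  assert_genotype_matrix(geno)
  stopifnot(identical(colnames(geno), map$marker))
  set.seed(config$seed + 1L)
  chroms <- chromosome_names(config$n_chromosomes)
  for (c_i in seq_len(config$n_chromosomes)) {
    s <- config$distortion[c_i]
    if (s == 0) next
    fav <- if (s > 0) "B" else "A"
    cols <- which(map$chrom == chroms[c_i])
    hit <- stats::runif(nrow(geno)) < 2 * abs(s)
    geno[hit, cols] <- fav
  }
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(geno)) < config$missing_rate,
                   nrow(geno), ncol(geno))
    geno[drop] <- NA_character_
  }
  geno
}

#' Trait architecture for the phenotype simulator
#'
#' Encodes the causal structure of the simulated phenotypes.  A phenology
#' trait (`DP-H`, days from planting to heading) is simulated first from
#' its own QTLs; every other trait is then built as
#' `intercept + sum(QTL effects at the line's genotype dosage, per
#' environment) + phenology_coupling * DP-H + replicate noise`, so that
#' part of a downstream trait's genetic signal can be mediated by
#' phenology (the drought-escape pathway).
#'
#' @param traits data.frame with columns `name`, `group`
#'   (yield/biomass/morphology/DAT/phenology), `intercept`, `noise_sd_ww`,
#'   `noise_sd_wl` (replicate noise per environment)
#' @param qtls data.frame with columns `trait`, `chrom`, `pos_cM`,
#'   `a_ww`, `a_wl` (additive effects per environment, sign toward the
#'   wild parent `B`)
#' @param phenology_coupling named numeric: per-trait slope on the line's
#'   simulated DP-H value (0 when absent)
#' @param dph_line_sd line-level environmental spread of DP-H (days),
#'   propagated to coupled traits
#' @return an object of class `trait_architecture`
#' @export
trait_architecture <- function(traits, qtls, phenology_coupling = NULL,
                               dph_line_sd = 1.5) {
  stopifnot(all(c("name", "group", "intercept", "noise_sd_ww", "noise_sd_wl")
                %in% names(traits)))
  stopifnot(all(c("trait", "chrom", "pos_cM", "a_ww", "a_wl") %in% names(qtls)))
  if (!all(qtls$trait %in% traits$name))
    stop("QTL refers to unknown trait: ",
         paste(setdiff(qtls$trait, traits$name), collapse = ", "))
  pc <- stats::setNames(rep(0, nrow(traits)), traits$name)
  if (!is.null(phenology_coupling)) {
    stopifnot(!is.null(names(phenology_coupling)))
    pc[names(phenology_coupling)] <- phenology_coupling
  }
  if (any(pc != 0) && !("DP-H" %in% traits$name))
    stop("phenology_coupling requires a trait named 'DP-H'")
  if (any(pc[names(pc) == "DP-H"] != 0))
    stop("DP-H cannot be coupled to itself")
  structure(list(traits = traits, qtls = qtls, phenology_coupling = pc,
                 dph_line_sd = dph_line_sd),
            class = "trait_architecture")
}

#' Default trait architecture of the simulated drought study
#'
#' Seventeen traits in the five field groups (yield, biomass, morphology,
#' drought-adaptive physiology, phenology) with a QTL architecture that
#' exercises every downstream classification archetype: a major phenology
#' QTL with a stronger water-limited effect whose influence on yield
#' traits is entirely mediated by heading date (drought escape), a
#' WL-specific carbon-isotope QTL (avoidance), an osmotic-potential QTL
#' (tolerance), equal-effect QTLs (non-plastic), and a phenology QTL
#' whose downstream effects vanish after heading adjustment (associated).
#'
#' @return a [trait_architecture()]
#' @export
default_trait_architecture <- function() {
  tr <- function(name, group, intercept, sd_ww, sd_wl = sd_ww)
    data.frame(name = name, group = group, intercept = intercept,
               noise_sd_ww = sd_ww, noise_sd_wl = sd_wl,
               stringsAsFactors = FALSE)
  traits <- rbind(
    tr("GY", "yield", 200, 18), tr("TKW", "yield", 40, 2.5),
    tr("KNSP", "yield", 35, 3), tr("HI", "yield", 0.35, 0.03),
    tr("SpDM", "biomass", 90, 8), tr("VegDM", "biomass", 300, 25),
    tr("TotDM", "biomass", 390, 30),
    tr("CL", "morphology", 80, 6), tr("SpL", "morphology", 7, 0.5),
    tr("FLL", "morphology", 20, 1.8), tr("FLW", "morphology", 14, 1.2),
    tr("delta13C", "DAT", -27, 0.4), tr("OP", "DAT", -1.6, 0.15),
    tr("Chl", "DAT", 45, 3), tr("LR", "DAT", 2.5, 0.5),
    tr("DP-H", "phenology", 60, 1.5), tr("DH-M", "phenology", 38, 2)
  )
  q <- function(trait, chrom, pos, a_ww, a_wl)
    data.frame(trait = trait, chrom = chrom, pos_cM = pos,
               a_ww = a_ww, a_wl = a_wl, stringsAsFactors = FALSE)
  qtls <- rbind(
    # major heading QTL, stronger under water limitation (escape driver);
    # wild-parent allele heads earlier
    q("DP-H", "7B", 30, -1.5, -3.5),
    q("DP-H", "5A", 90, 1.2, 1.2),
    # equal-effect (non-plastic) yield/morphology QTLs
    q("TKW", "6A", 40, 1.6, 1.6),
    q("CL", "4B", 25, 3.5, 3.5),
    # WL-specific direct effects (drought plasticity)
    q("delta13C", "4A", 70, 0, 0.45),
    q("OP", "4B", 60, 0, -0.12),
    q("HI", "2B", 55, 0, 0.025),
    # WW-stronger effect on biomass
    q("VegDM", "3A", 45, 18, 6),
    # maturity-window QTL, both environments
    q("DH-M", "2B", 80, -1.4, -2.0)
  )
  coupling <- c(
    "GY" = -3.0, "KNSP" = -0.45, "HI" = -0.004, "SpDM" = -1.2,
    "TotDM" = -3.0, "DH-M" = -0.55, "SpL" = -0.05, "Chl" = -0.35
  )
  trait_architecture(traits, qtls, coupling, dph_line_sd = 1.5)
}

#' Simulate replicate-level phenotypes with a known QTL architecture
#'
#' DP-H is generated first from its QTLs plus a line-level environmental
#' deviation; each downstream trait then receives its direct QTL effects,
#' its phenology-mediated component, and Gaussian replicate noise.
#' Returns both the long-format trait table and a truth registry holding
#' the per-environment direct, mediated and total additive effect of
#' every (QTL, trait) pair, from which expected classification labels can
#' be derived with the same rules the classifier uses
#' (see [truth_expected_labels()]).
#'
#' @param map,geno output of [simulate_map_and_genotypes()]
#' @param arch a [trait_architecture()]
#' @param config the [sim_config()] used for the genotypes
#' @return list with `phenotypes` (data.frame: `line`, `env`, `rep`,
#'   `trait`, `value`) and `truth` (class `truth_registry`)
#' @export
simulate_phenotypes <- function(map, geno, arch, config) {
  stopifnot(inherits(arch, "trait_architecture"),
            inherits(config, "sim_config"))
  assert_genotype_matrix(geno)
  stopifnot(identical(colnames(geno), map$marker))
  bad <- setdiff(arch$qtls$chrom, unique(map$chrom))
  if (length(bad))
    stop("QTL on chromosome absent from the map: ", paste(bad, collapse = ", "))
  set.seed(config$seed + 2L)
  dos <- geno_to_dosage(geno)
  n <- nrow(dos)
  lines <- rownames(dos)
  envs <- c("WW", "WL")

  # dosage at each QTL = dosage of the nearest mapped marker
  qtl_dos <- vapply(seq_len(nrow(arch$qtls)), function(k) {
    on_chr <- map$chrom == arch$qtls$chrom[k]
    idx <- which(on_chr)[which.min(abs(map$pos_cM[on_chr] - arch$qtls$pos_cM[k]))]
    d <- dos[, idx]
    d[is.na(d)] <- 0  # uninformative call contributes no effect
    d
  }, numeric(n))

  tr <- arch$traits
  genetic_value <- function(trait, env) {
    rows <- which(arch$qtls$trait == trait)
    a <- if (env == "WW") arch$qtls$a_ww else arch$qtls$a_wl
    base <- tr$intercept[tr$name == trait]
    if (length(rows)) base + as.vector(qtl_dos[, rows, drop = FALSE] %*% a[rows])
    else rep(base, n)
  }

  # line-level DP-H per environment: QTLs + line environmental deviation
  dph_line <- lapply(stats::setNames(envs, envs), function(e) {
    if ("DP-H" %in% tr$name)
      genetic_value("DP-H", e) + stats::rnorm(n, 0, arch$dph_line_sd)
    else rep(0, n)
  })
  dph_center <- if ("DP-H" %in% tr$name) tr$intercept[tr$name == "DP-H"] else 0

  recs <- vector("list", nrow(tr) * 2L)
  k <- 0L
  for (t_i in seq_len(nrow(tr))) {
    trait <- tr$name[t_i]
    for (e in envs) {
      gv <- if (trait == "DP-H") dph_line[[e]]
      else genetic_value(trait, e) +
        arch$phenology_coupling[[trait]] * (dph_line[[e]] - dph_center)
      sd_e <- if (e == "WW") tr$noise_sd_ww[t_i] else tr$noise_sd_wl[t_i]
      nrep <- config$replicates_per_env
      vals <- rep(gv, nrep) + stats::rnorm(n * nrep, 0, sd_e)
      k <- k + 1L
      recs[[k]] <- data.frame(
        line = rep(lines, nrep), env = e,
        rep = rep(seq_len(nrep), each = n),
        trait = trait, value = vals, stringsAsFactors = FALSE)
    }
  }
  phenotypes <- do.call(rbind, recs[seq_len(k)])

  truth <- truth_registry(arch)
  list(phenotypes = phenotypes, truth = truth)
}

#' Ground-truth QTL effect registry of a simulated architecture
#'
#' Expands the architecture into per-(QTL, trait) expected additive
#' effects: the direct effect per environment, the component mediated by
#' DP-H (coupling x the locus's DP-H effect), and their total.  From
#' these, the expected presence of an effect in each analysis set follows
#' the same logic the downstream scans estimate:
#' observed-trait effect when the total is nonzero; phenology-adjusted
#' (df) effect when the direct part is nonzero; drought plasticity I (d)
#' effect when WL and WW totals differ; drought plasticity II (ddf)
#' effect when WL and WW *direct* parts differ (the mediated part is
#' removed by the heading adjustment).
#'
#' @param arch a [trait_architecture()]
#' @return object of class `truth_registry`: data.frame `effects` with
#'   one row per expected (locus, trait, set) effect
#' @export
truth_registry <- function(arch) {
  q <- arch$qtls
  loci <- unique(q[, c("chrom", "pos_cM")])
  eff <- list(); k <- 0L
  for (l_i in seq_len(nrow(loci))) {
    at <- q$chrom == loci$chrom[l_i] & q$pos_cM == loci$pos_cM[l_i]
    dph_ww <- sum(q$a_ww[at & q$trait == "DP-H"])
    dph_wl <- sum(q$a_wl[at & q$trait == "DP-H"])
    # traits with a direct QTL here, plus coupled traits if DP-H is here
    direct_traits <- unique(q$trait[at])
    coupled <- if (dph_ww != 0 || dph_wl != 0)
      names(arch$phenology_coupling)[arch$phenology_coupling != 0] else character()
    for (trait in union(direct_traits, coupled)) {
      d_ww <- sum(q$a_ww[at & q$trait == trait])
      d_wl <- sum(q$a_wl[at & q$trait == trait])
      cp <- if (trait == "DP-H") 0 else arch$phenology_coupling[[trait]]
      m_ww <- cp * dph_ww; m_wl <- cp * dph_wl
      k <- k + 1L
      eff[[k]] <- data.frame(
        chrom = loci$chrom[l_i], pos_cM = loci$pos_cM[l_i], trait = trait,
        direct_ww = d_ww, direct_wl = d_wl,
        mediated_ww = m_ww, mediated_wl = m_wl,
        total_ww = d_ww + m_ww, total_wl = d_wl + m_wl,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(effects = do.call(rbind, eff), arch = arch),
            class = "truth_registry")
}

#' Write simulated study files
#'
#' Serializes a simulated study to the plain-text layout the rest of the
#' pipeline reads: genotypes TSV (lines x markers, `A`/`B`/`NA`), map
#' TSV, long-format phenotypes TSV, and truth JSON.
#'
#' @param sim list with `map`, `geno`, `phenotypes`, `truth`
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of written paths
#' @export
write_simulated_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             map = file.path(dir, "map.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.json"))
  write_genotypes_tsv(sim$geno, paths[["genotypes"]])
  utils::write.table(sim$map, paths[["map"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$phenotypes, paths[["phenotypes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(effects = sim$truth$effects),
                       paths[["truth"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Simulate a complete study in one call
#'
#' Convenience wrapper: genotypes, corruption (missingness/distortion)
#' and phenotypes under one configuration and architecture.
#'
#' @param config a [sim_config()]
#' @param arch a [trait_architecture()]; default
#'   [default_trait_architecture()]
#' @return list with `map`, `geno` (corrupted), `geno_clean`,
#'   `phenotypes`, `truth`
#' @export
simulate_study <- function(config = sim_config(),
                           arch = default_trait_architecture()) {
  mg <- simulate_map_and_genotypes(config)
  geno <- corrupt_genotypes(mg$geno, mg$map, config)
  ph <- simulate_phenotypes(mg$map, mg$geno, arch, config)
  list(map = mg$map, geno = geno, geno_clean = mg$geno,
       phenotypes = ph$phenotypes, truth = ph$truth)
}
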