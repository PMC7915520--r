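#' Group co-localized trait-level QTL effects into loci
#'
#' Single-linkage grouping of significant effects on the same chromosome
#' with support-interval overlap as the link relation (a chain of
#' pairwise-overlapping intervals forms one locus).  Locus ids are
#' assigned by chromosome and cM order of the merged interval, e.g.
#' `"7B.1"`; a locus is multi-trait when its members cover two or more
#' distinct base traits.
#'
#' @param effects data.frame of trait-level effects: `trait` (analysis
#'   trait name), `base_trait` (the observed trait it derives from),
#'   `set` (`obs`/`df`/`d`/`ddf`), `env`, `chrom`, `pos_cM`, `lod`, `a`,
#'   `pev`, `itv`, `ci_lo`, `ci_hi`
#' @return list of `qtl_locus` objects: each a list with `locus_id`,
#'   `chrom`, `interval` (merged), `effects` (member rows)
#' @export
group_colocalized_effects <- function(effects) {
  req <- c("trait", "base_trait", "set", "chrom", "pos_cM", "lod", "a",
           "pev", "itv", "ci_lo", "ci_hi")
  stopifnot(all(req %in% names(effects)))
  if (nrow(effects) == 0L) return(list())
  loci <- list()
  for (g in unique(effects$chrom)) {
    sub <- effects[effects$chrom == g, , drop = FALSE]
    sub <- sub[order(sub$ci_lo, sub$ci_hi, sub$trait), , drop = FALSE]
    edges_i <- integer(0); edges_j <- integer(0)
    if (nrow(sub) > 1L) {
      for (i in 1:(nrow(sub) - 1L)) for (j in (i + 1L):nrow(sub)) {
        if (sub$ci_lo[j] <= sub$ci_hi[i] && sub$ci_hi[j] >= sub$ci_lo[i]) {
          edges_i <- c(edges_i, i); edges_j <- c(edges_j, j)
        }
      }
    }
    comp <- connected_components(nrow(sub), edges_i, edges_j)
    starts <- tapply(sub$ci_lo, comp, min)
    ord <- order(starts)
    for (k in seq_along(ord)) {
      members <- sub[comp == as.integer(names(starts))[ord[k]], , drop = FALSE]
      loci[[length(loci) + 1L]] <- structure(list(
        locus_id = paste0(g, ".", k), chrom = g,
        interval = c(min(members$ci_lo), max(members$ci_hi)),
        effects = members), class = "qtl_locus")
    }
  }
  loci
}

# Effects of one set within a locus, optionally for one base trait.
set_members <- function(locus, set, base_trait = NULL) {
  e <- locus$effects
  sel <- e$set == set
  if (!is.null(base_trait)) sel <- sel & e$base_trait == base_trait
  e[sel, , drop = FALSE]
}

#' Phenology-plasticity classification of a locus
#'
#' Applies the presence/absence rules over observed and
#' phenology-adjusted (`df`) member effects:
#' *associated* when a member's trait is the phenology trait itself, or
#' when some observed effect is fully suppressed after heading
#' adjustment (no significant `df` counterpart);
#' *plastic* when a `df` effect has no observed counterpart (the effect
#' appears only after adjustment);
#' *non-plastic* when every affected trait shows both effects and they
#' are similar: same ITV parent and a standardized-effect ratio (taken
#' as `sqrt(PEV_df / PEV_obs)`) within `similarity_ratio`.
#' Precedence across member traits: associated > plastic > non-plastic.
#' A locus with only `d`/`ddf` members is not classifiable here and
#' returns `NA`.
#'
#' @param locus a `qtl_locus`
#' @param phenology_trait name of the phenology trait (default `"DP-H"`)
#' @param similarity_ratio allowed standardized-effect ratio band
#'   (default `c(0.5, 2)`)
#' @return `"associated"`, `"plastic"`, `"non-plastic"`, or `NA`
#' @export
classify_phenology <- function(locus, phenology_trait = "DP-H",
                               similarity_ratio = c(0.5, 2)) {
  e <- locus$effects
  if (!any(e$set %in% c("obs", "df"))) return(NA_character_)
  if (any(e$base_trait == phenology_trait & e$set %in% c("obs", "df")))
    return("associated")
  traits <- unique(e$base_trait[e$set %in% c("obs", "df")])
  verdicts <- character(0)
  for (tr in traits) {
    obs <- set_members(locus, "obs", tr)
    dfm <- set_members(locus, "df", tr)
    if (nrow(obs) > 0L && nrow(dfm) == 0L) {
      verdicts <- c(verdicts, "associated")        # full suppression
    } else if (nrow(obs) == 0L && nrow(dfm) > 0L) {
      verdicts <- c(verdicts, "plastic")           # df-only effect
    } else if (nrow(obs) > 0L && nrow(dfm) > 0L) {
      bo <- obs[which.max(obs$lod), ]; bd <- dfm[which.max(dfm$lod), ]
      ratio <- sqrt(bd$pev / bo$pev)
      similar <- bo$itv == bd$itv &&
        ratio >= similarity_ratio[1] && ratio <= similarity_ratio[2]
      verdicts <- c(verdicts, if (similar) "non-plastic" else "plastic")
    }
  }
  if ("associated" %in% verdicts) "associated"
  else if ("plastic" %in% verdicts) "plastic"
  else "non-plastic"
}

#' Drought-plasticity classification of a locus
#'
#' *plastic* when any member is a drought plasticity effect (`d` or
#' `ddf`), alone or co-located with observed effects; *non-plastic* when
#' only observed/`df` members are present.
#'
#' @param locus a `qtl_locus`
#' @return `"plastic"` or `"non-plastic"`
#' @export
classify_drought_plasticity <- function(locus) {
  if (any(locus$effects$set %in% c("d", "ddf"))) "plastic" else "non-plastic"
}

#' Drought-resistance strategies of a locus
#'
#' *tolerance* when any member trait is osmotic potential (`OP`) or
#' chlorophyll content (`Chl`); *avoidance* for carbon-isotope ratio
#' (`delta13C`) or leaf rolling (`LR`); *escape* when for some trait a
#' drought plasticity I (`d`) effect exists with no plasticity II
#' (`ddf`) counterpart for the same trait - the signature of a response
#' mediated entirely by heading date.  For OP the resistance-conferring
#' allele is the value-decreasing one (lower osmotic potential = more
#' tolerant), reported in `op_resistance_allele`.
#'
#' @param locus a `qtl_locus`
#' @param tolerance_traits,avoidance_traits trait name sets
#' @return list: `strategies` (character subset of escape / avoidance /
#'   tolerance, or `"none"`), `op_resistance_allele` (`P1`/`P2`/`NA`)
#' @export
assign_strategy <- function(locus,
                            tolerance_traits = c("OP", "Chl"),
                            avoidance_traits = c("delta13C", "LR")) {
  e <- locus$effects
  strategies <- character(0)
  if (any(e$base_trait %in% tolerance_traits)) strategies <- c(strategies, "tolerance")
  if (any(e$base_trait %in% avoidance_traits)) strategies <- c(strategies, "avoidance")
  for (tr in unique(e$base_trait[e$set == "d"])) {
    if (nrow(set_members(locus, "ddf", tr)) == 0L) {
      strategies <- c(strategies, "escape")
      break
    }
  }
  op <- e[e$base_trait == "OP", , drop = FALSE]
  op_allele <- if (nrow(op)) {
    # ITV is the value-increasing parent; resistance goes with the other
    best <- op[which.max(op$lod), ]
    if (best$itv == "P1") "P2" else "P1"
  } else NA_character_
  if (!length(strategies)) strategies <- "none"
  list(strategies = unique(strategies), op_resistance_allele = op_allele)
}

#' Classify a list of loci
#'
#' Runs the phenology, drought-plasticity and strategy rules over every
#' locus and returns a tidy per-locus table.
#'
#' @param loci list of `qtl_locus` from [group_colocalized_effects()]
#' @param phenology_trait name of the phenology trait
#' @param similarity_ratio see [classify_phenology()]
#' @return data.frame: `locus_id`, `chrom`, `ci_lo`, `ci_hi`,
#'   `n_effects`, `n_traits`, `multi_trait`, `phenology`, `drought`,
#'   `strategies` (comma-joined), `op_resistance_allele`
#' @export
classify_loci <- function(loci, phenology_trait = "DP-H",
                          similarity_ratio = c(0.5, 2)) {
  rows <- lapply(loci, function(lc) {
    strat <- assign_strategy(lc)
    data.frame(
      locus_id = lc$locus_id, chrom = lc$chrom,
      ci_lo = lc$interval[1], ci_hi = lc$interval[2],
      n_effects = nrow(lc$effects),
      n_traits = length(unique(lc$effects$base_trait)),
      multi_trait = length(unique(lc$effects$base_trait)) >= 2L,
      phenology = classify_phenology(lc, phenology_trait, similarity_ratio),
      drought = classify_drought_plasticity(lc),
      strategies = paste(strat$strategies, collapse = ","),
      op_resistance_allele = strat$op_resistance_allele,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' ITV-origin accounting for drought-plasticity effects
#'
#' Per base trait and parent: the count and summed PEV of plasticity
#' (`d`/`ddf`) effects.  When `d` and `ddf` effects for the same trait
#' co-locate within one locus, only the higher-PEV member contributes.
#'
#' @param loci list of `qtl_locus`
#' @return data.frame: `base_trait`, `itv`, `n`, `total_pev`
#' @export
itv_accounting <- function(loci) {
  contrib <- list()
  for (lc in loci) {
    pl <- lc$effects[lc$effects$set %in% c("d", "ddf"), , drop = FALSE]
    for (tr in unique(pl$base_trait)) {
      sub <- pl[pl$base_trait == tr, , drop = FALSE]
      best <- sub[which.max(sub$pev), , drop = FALSE]
      contrib[[length(contrib) + 1L]] <-
        data.frame(base_trait = tr, itv = best$itv, pev = best$pev,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(contrib))
    return(data.frame(base_trait = character(), itv = character(),
                      n = integer(), total_pev = numeric(),
                      stringsAsFactors = FALSE))
  all_c <- do.call(rbind, contrib)
  agg <- stats::aggregate(pev ~ base_trait + itv, all_c,
                          function(v) c(n = length(v), s = sum(v)))
  data.frame(base_trait = agg$base_trait, itv = agg$itv,
             n = as.integer(agg$pev[, "n"]), total_pev = agg$pev[, "s"],
             stringsAsFactors = FALSE)
}

#' Architecture summary table
#'
#' Per base trait: total / multi-trait / single-trait locus counts, the
#' LOD range of its effects, ITV-parent counts, environment-specificity
#' counts, and phenology / drought category counts, in the layout of a
#' per-trait QTL summary table.
#'
#' @param loci list of `qtl_locus`
#' @param classified output of [classify_loci()] for the same loci
#' @return data.frame with one row per base trait plus an `All` row
#' @export
summarize_architecture <- function(loci, classified) {
  if (!length(loci))
    return(data.frame(trait = character(), n_loci = integer(),
                      n_multi = integer(), n_single = integer(),
                      lod_min = numeric(), lod_max = numeric(),
                      itv_P1 = integer(), itv_P2 = integer(),
                      assoc = integer(), pheno_np = integer(),
                      pheno_p = integer(), drought_np = integer(),
                      drought_p = integer(), stringsAsFactors = FALSE))
  traits <- sort(unique(unlist(lapply(loci, function(lc) lc$effects$base_trait))))
  per_locus_traits <- lapply(loci, function(lc) unique(lc$effects$base_trait))
  rows <- lapply(traits, function(tr) {
    hit <- vapply(per_locus_traits, function(s) tr %in% s, logical(1))
    cls <- classified[hit, , drop = FALSE]
    effs <- do.call(rbind, lapply(loci[hit], function(lc)
      lc$effects[lc$effects$base_trait == tr, , drop = FALSE]))
    data.frame(
      trait = tr, n_loci = sum(hit),
      n_multi = sum(cls$multi_trait), n_single = sum(!cls$multi_trait),
      lod_min = min(effs$lod), lod_max = max(effs$lod),
      itv_P1 = sum(effs$itv == "P1"), itv_P2 = sum(effs$itv == "P2"),
      assoc = sum(cls$phenology == "associated", na.rm = TRUE),
      pheno_np = sum(cls$phenology == "non-plastic", na.rm = TRUE),
      pheno_p = sum(cls$phenology == "plastic", na.rm = TRUE),
      drought_np = sum(cls$drought == "non-plastic"),
      drought_p = sum(cls$drought == "plastic"),
      stringsAsFactors = FALSE)
  })
  per_trait <- do.call(rbind, rows)
  all_row <- data.frame(
    trait = "All", n_loci = length(loci),
    n_multi = sum(classified$multi_trait),
    n_single = sum(!classified$multi_trait),
    lod_min = min(per_trait$lod_min), lod_max = max(per_trait$lod_max),
    itv_P1 = sum(per_trait$itv_P1), itv_P2 = sum(per_trait$itv_P2),
    assoc = sum(classified$phenology == "associated", na.rm = TRUE),
    pheno_np = sum(classified$phenology == "non-plastic", na.rm = TRUE),
    pheno_p = sum(classified$phenology == "plastic", na.rm = TRUE),
    drought_np = sum(classified$drought == "non-plastic"),
    drought_p = sum(classified$drought == "plastic"),
    stringsAsFactors = FALSE)
  rbind(per_trait, all_row)
}

#' Expected classification labels from a simulation truth registry
#'
#' Converts the registry's expected per-set effects into the same
#' effects-table shape the scans produce (pseudo LOD/PEV proportional to
#' squared effect size, a fixed-width pseudo support interval), groups
#' them, and runs the *same* classification rules - so simulator truth
#' and classifier output are comparable label-for-label.
#'
#' @param truth a `truth_registry`
#' @param tol effects smaller than this (absolute) count as absent
#' @return data.frame from [classify_loci()] on the expected effects
#' @export
truth_expected_labels <- function(truth, tol = 1e-9) {
  te <- truth$effects
  rows <- list()
  add <- function(chrom, pos, trait, set, env, a) {
    if (abs(a) < tol) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      trait = trait, base_trait = trait, set = set, env = env,
      chrom = chrom, pos_cM = pos, lod = 3 + a^2, a = a, pev = min(a^2, 1),
      itv = if (a > 0) "P2" else "P1",
      ci_lo = pos - 5, ci_hi = pos + 5, stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(te))) {
    with(te[r, ], {
      add(chrom, pos_cM, trait, "obs", "WW", total_ww)
      add(chrom, pos_cM, trait, "obs", "WL", total_wl)
      add(chrom, pos_cM, trait, "df", "WW", direct_ww)
      add(chrom, pos_cM, trait, "df", "WL", direct_wl)
      add(chrom, pos_cM, trait, "d", "WL", total_wl - total_ww)
      add(chrom, pos_cM, trait, "ddf", "WL", direct_wl - direct_ww)
    })
  }
  effects <- do.call(rbind, rows)
  loci <- group_colocalized_effects(effects)
  classify_loci(loci)
}
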