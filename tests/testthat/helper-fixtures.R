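# Shared fixtures, built in code and cached per test run.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) assign(name, builder(), envir = fixture_env)
  get(name, envir = fixture_env)
}

# Architecture on generic chromosome names for small simulated studies.
small_arch <- function() {
  traits <- data.frame(
    name = c("DP-H", "GY", "TKW", "OP", "delta13C"),
    group = c("phenology", "yield", "yield", "DAT", "DAT"),
    intercept = c(60, 200, 40, -1.6, -27),
    noise_sd_ww = c(1.5, 10, 2, 0.15, 0.4),
    noise_sd_wl = c(1.5, 10, 2, 0.15, 0.4))
  qtls <- data.frame(trait = c("DP-H", "TKW", "OP", "GY"),
                     chrom = c("chr1", "chr2", "chr3", "chr4"),
                     pos_cM = c(30, 40, 30, 20),
                     a_ww = c(-2, 1.6, 0, 5), a_wl = c(-3, 1.6, -0.12, 8))
  trait_architecture(traits, qtls, phenology_coupling = c(GY = -3),
                     dph_line_sd = 1.5)
}

# Small clean study: 150 lines, 4 chromosomes, 5 cM spacing, no corruption.
small_study <- function() cached("small_study", function() {
  cfg <- sim_config(n_lines = 150, n_chromosomes = 4,
                    chrom_lengths_cM = c(100, 90, 80, 70),
                    marker_spacing_cM = 5, missing_rate = 0,
                    distortion = 0, seed = 42)
  st <- simulate_study(cfg, small_arch())
  st$config <- cfg
  st
})

small_map_probs <- function(step_cM = 1) cached("small_probs", function() {
  st <- small_study()
  genotype_probabilities(st$map, st$geno, step_cM = step_cM)
})

# Genotype matrix from explicit dosage rows (lines x markers).
geno_from_dosage <- function(dos, lines = NULL, markers = NULL) {
  dos <- as.matrix(dos)
  rownames(dos) <- lines %||% sprintf("L%02d", seq_len(nrow(dos)))
  colnames(dos) <- markers %||% sprintf("m%02d", seq_len(ncol(dos)))
  g <- matrix(NA_character_, nrow(dos), ncol(dos), dimnames = dimnames(dos))
  g[dos == -1] <- "A"
  g[dos == 1] <- "B"
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent OLS oracle: solve the normal equations directly.
ols_oracle <- function(y, X) {
  keep <- stats::complete.cases(cbind(y, X))
  Xc <- cbind(1, as.matrix(X)[keep, , drop = FALSE])
  beta <- solve(t(Xc) %*% Xc, t(Xc) %*% y[keep])
  list(beta = as.vector(beta),
       residuals = as.vector(y[keep] - Xc %*% beta))
}

# Effect-table row constructor for classifier tests.
eff_row <- function(trait, set, chrom, pos, lod = 5, a = 1, pev = 0.1,
                    env = "WL", ci = c(pos - 5, pos + 5),
                    base_trait = trait) {
  data.frame(trait = trait, base_trait = base_trait, set = set, env = env,
             chrom = chrom, pos_cM = pos, lod = lod, a = a, pev = pev,
             itv = if (a > 0) "P2" else "P1", ci_lo = ci[1], ci_hi = ci[2],
             stringsAsFactors = FALSE)
}
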