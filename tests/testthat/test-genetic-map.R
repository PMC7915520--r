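test_that("marker QC removes high-missingness and strongly distorted markers", {
  set.seed(1)
  n <- 100
  base <- sample(c(-1, 1), n, replace = TRUE)
  g <- geno_from_dosage(cbind(base, base, base, base),
                        markers = c("ok", "gap", "skew", "perfect"))
  g[1:11, "gap"] <- NA                      # 11% missing at the 10% rule
  g[, "skew"] <- "A"; g[1:20, "skew"] <- "B" # 80:20 -> chi2 = 36 > 35
  g[, "perfect"] <- rep(c("A", "B"), 50)     # exact 1:1, chi2 = 0
  out <- qc_filter_markers(g, max_missing = 0.10, max_distortion_chi2 = 35)
  expect_setequal(colnames(out), c("ok", "perfect"))
  rep <- attr(out, "qc_report")
  expect_equal(rep$removed[rep$marker == "gap"], "missing")
  expect_equal(rep$removed[rep$marker == "skew"], "distortion")
})

test_that("the distortion chi-square matches the hand-computed 120:30 case", {
  g <- geno_from_dosage(matrix(c(rep(1, 120), rep(-1, 30),
                                 rep(c(1, -1), 75)), ncol = 2),
                        markers = c("skewed", "fair"))
  expect_error(qc_filter_markers(g[, c("skewed", "skewed"), drop = FALSE]),
               "every marker")
  out <- qc_filter_markers(g)
  expect_equal(colnames(out), "fair")
  expect_equal(attr(out, "qc_report")$chi2[1], 54)  # (120-75)^2/75 + (30-75)^2/75
})

test_that("RF estimation counts recombinants over informative lines", {
  set.seed(2)
  a <- sample(c(-1, 1), 150, replace = TRUE)
  b <- a; b[1:15] <- -b[1:15]          # 15 recombinants out of 150
  g <- geno_from_dosage(cbind(a, a, -a, b),
                        markers = c("m1", "m2", "comp", "rec"))
  rf <- estimate_rf_matrix(g)
  expect_equal(rf$rf["m1", "m2"], 0)
  expect_equal(rf$rf["m1", "comp"], 0.5)       # truncated
  expect_equal(rf$rf_raw["m1", "comp"], 1.0)   # raw kept
  expect_equal(rf$rf["m1", "rec"], 0.10)
  expect_true(isSymmetric(rf$rf))
  expect_equal(unname(diag(rf$rf)), rep(0, 4))
})

test_that("a pair with no informative lines gets NA, not zero", {
  g <- geno_from_dosage(cbind(c(1, 1, NA, NA), c(NA, NA, 1, -1)))
  rf <- estimate_rf_matrix(g)
  expect_true(is.na(rf$rf[1, 2]))
  expect_equal(rf$n_inf[1, 2], 0L)
})

test_that("co-segregation binning keeps one skeleton per distinct column", {
  set.seed(3)
  a <- sample(c(-1, 1), 60, replace = TRUE)
  b <- a; b[1:10] <- -b[1:10]
  g <- geno_from_dosage(cbind(a, a, a, b, b),
                        markers = c("a1", "a2", "a3", "b1", "b2"))
  rf <- estimate_rf_matrix(g)
  bn <- bin_skeleton_markers(g, rf)
  expect_equal(ncol(bn$skeleton_geno), 2L)  # distinct-column count
  expect_equal(sum(bn$bins$marker == bn$bins$skeleton), 2L)
  # least-missing / lexicographic skeleton choice
  expect_equal(sort(unique(bn$bins$skeleton)), c("a1", "b1"))
})

test_that("markers identical up to a missing call are binned together", {
  a <- c(rep(1, 20), rep(-1, 20))
  b <- a; b[5] <- NA
  g <- geno_from_dosage(cbind(a, b), markers = c("full", "gappy"))
  g[5, "gappy"] <- NA
  rf <- estimate_rf_matrix(g)
  bn <- bin_skeleton_markers(g, rf)
  expect_equal(unique(bn$bins$skeleton), "full")  # fewer missing wins
})

test_that("linkage-group clustering separates unlinked chromosomes at RF 0.2", {
  cfg <- sim_config(n_lines = 200, n_chromosomes = 2,
                    chrom_lengths_cM = c(60, 60), marker_spacing_cM = 5,
                    seed = 17)
  mg <- simulate_map_and_genotypes(cfg)
  rf <- estimate_rf_matrix(mg$geno)
  lg <- cluster_linkage_groups(mg$geno, rf, rf_threshold = 0.2)
  expect_equal(length(unique(lg)), 2L)
  # groups coincide with true chromosomes
  split_by_lg <- split(mg$map$chrom, lg[mg$map$marker])
  expect_true(all(vapply(split_by_lg, function(x) length(unique(x)) == 1L,
                         logical(1))))
})

test_that("a sparse within-chromosome gap merges back via the end-to-end rule", {
  set.seed(4)
  n <- 400
  left <- sample(c(-1, 1), n, replace = TRUE)
  l2 <- left * ifelse(runif(n) < 0.05, -1, 1)
  gap <- l2 * ifelse(runif(n) < 0.3, -1, 1)    # RF ~0.3 > threshold
  r2 <- gap * ifelse(runif(n) < 0.05, -1, 1)
  g <- geno_from_dosage(cbind(left, l2, gap, r2),
                        markers = c("p1", "p2", "q1", "q2"))
  rf <- estimate_rf_matrix(g)
  natural <- cluster_linkage_groups(g, rf, rf_threshold = 0.2)
  expect_equal(length(unique(natural)), 2L)
  merged <- cluster_linkage_groups(g, rf, rf_threshold = 0.2,
                                   target_groups = 1L)
  expect_equal(length(unique(merged)), 1L)
  expect_warning(cluster_linkage_groups(g, rf, 0.2, target_groups = 4L),
                 "fewer than target")
})

test_that("three-marker ordering matches the exhaustive optimum", {
  # RF(AB)=0.05, RF(BC)=0.05, RF(AC)=0.10: only A-B-C (or reverse) is optimal
  rfm <- matrix(c(0, .05, .10, .05, 0, .05, .10, .05, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  rf <- structure(list(rf = rfm, rf_raw = rfm,
                       n_inf = matrix(100, 3, 3, dimnames = dimnames(rfm))),
                  class = "rf_matrix")
  o <- order_and_space_markers(c("A", "B", "C"), rf)
  expect_equal(o$marker[2], "B")
  expect_equal(o$marker[1], "A")  # deterministic orientation
  expect_equal(o$pos_cM[1], 0)
  expect_true(all(diff(o$pos_cM) > 0))
})

test_that("single markers map to a zero-length group", {
  rf <- structure(list(rf = matrix(0, 1, 1, dimnames = list("A", "A")),
                       rf_raw = matrix(0, 1, 1), n_inf = matrix(0L, 1, 1)),
                  class = "rf_matrix")
  o <- order_and_space_markers("A", rf)
  expect_equal(o$pos_cM, 0)
})

test_that("order recovery on a simulated chromosome is near-perfect", {
  cfg <- sim_config(n_lines = 1000, n_chromosomes = 1, chrom_lengths_cM = 90,
                    marker_spacing_cM = 10, seed = 23)
  mg <- simulate_map_and_genotypes(cfg)
  rf <- estimate_rf_matrix(mg$geno)
  o <- order_and_space_markers(mg$map$marker, rf)
  truth_idx <- match(o$marker, mg$map$marker)
  expect_gte(abs(cor(truth_idx, seq_along(truth_idx), method = "spearman")), 0.99)
})

test_that("map diagnostics flag non-recombinant units and distorted markers", {
  dos <- rbind(c(1, -1, 1, -1, 1, -1),   # recombinant on both groups
               c(1, 1, 1, 1, 1, 1),      # non-recombinant everywhere
               c(-1, -1, -1, 1, -1, -1)) # non-recombinant on g1 only
  g <- geno_from_dosage(dos)
  map <- data.frame(marker = colnames(g),
                    chrom = rep(c("g1", "g2"), each = 3),
                    pos_cM = rep(c(0, 10, 20), 2))
  d <- map_diagnostics(g, map)
  expect_equal(d$n_units_total, 6L)
  nr <- d$nonrecombinant
  expect_true(nr$nonrecombinant[nr$line == "L02" & nr$chrom == "g1"])
  expect_true(nr$nonrecombinant[nr$line == "L03" & nr$chrom == "g1"])
  expect_false(nr$nonrecombinant[nr$line == "L01" & nr$chrom == "g1"])
  expect_equal(d$prop_nonrecombinant, 3 / 6)
})

test_that("units with fewer than two calls leave the denominator", {
  g <- geno_from_dosage(rbind(c(1, 1), c(1, -1), c(1, 1)))
  g[3, 2] <- NA
  map <- data.frame(marker = colnames(g), chrom = "g1", pos_cM = c(0, 10))
  d <- map_diagnostics(g, map)
  expect_equal(d$n_units_evaluated, 2L)
  expect_equal(d$n_units_total, 3L)
})

test_that("the 90:60 marker is distorted at p about 0.0143, favouring P1", {
  dos <- c(rep(-1, 90), rep(1, 60))
  g <- geno_from_dosage(cbind(dos, dos * c(rep(1, 75), rep(-1, 75))))
  map <- data.frame(marker = colnames(g), chrom = "g1", pos_cM = c(0, 10))
  d <- map_diagnostics(g, map)
  row1 <- d$marker_distortion[1, ]
  expect_equal(row1$chi2, 6)
  expect_equal(row1$p, stats::pchisq(6, 1, lower.tail = FALSE))
  expect_lt(abs(row1$p - 0.0143), 5e-4)
  expect_true(row1$distorted)
  expect_equal(row1$favoured, "P1")
})

test_that("physical concordance folds orientation and matches the rank formula", {
  map <- data.frame(marker = sprintf("m%02d", 1:10), chrom = "g1",
                    order = 1:10, pos_cM = seq(0, 90, 10))
  collinear <- data.frame(marker = map$marker, chrom = "g1",
                          bp = seq(1e6, 10e6, 1e6))
  expect_equal(physical_concordance(map, collinear)$rank_cor, 1.0)
  reversed <- collinear; reversed$bp <- rev(reversed$bp)
  expect_equal(physical_concordance(map, reversed)$rank_cor, 1.0)
  swapped <- collinear; swapped$bp[4:5] <- swapped$bp[5:4]
  # Spearman 1 - 6*sum(d^2)/(n(n^2-1)) with two displaced ranks
  expect_equal(physical_concordance(map, swapped)$rank_cor,
               1 - 6 * 2 / (10 * 99))
  expect_warning(physical_concordance(map, collinear[1:2, ]), "fewer than 3")
})

test_that("the full map builder reconstructs simulated chromosomes", {
  st <- small_study()
  gm <- build_genetic_map(st$geno, target_groups = 4L)
  expect_equal(nrow(gm$groups), 4L)
  expect_true(all(tapply(gm$map$pos_cM, gm$map$chrom,
                         function(p) !is.unsorted(p))))
  expect_equal(sum(gm$groups$length_cM),
               sum(tapply(gm$map$pos_cM, gm$map$chrom, max)))
  expect_setequal(gm$map$marker, unique(gm$bins$skeleton))
})
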