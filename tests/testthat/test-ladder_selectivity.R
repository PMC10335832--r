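make_ladder <- function(kd_by_len = c(`20` = 50, `30` = 50, `40` = 50, `50` = 50),
                        conc = c(0, 37, 75, 150, 300, 450, 600, 760),
                        n_rep = 1L, cv = 0, seed = 1L,
                        include_10bp = TRUE, construct = "wt") {
  lens <- as.integer(names(kd_by_len))
  k_assoc <- setNames(1 / kd_by_len, names(kd_by_len))
  fp <- setNames(lens, names(kd_by_len))  # one site per fragment
  lens_all <- if (include_10bp) c(10L, lens) else lens
  if (include_10bp) {
    k_assoc <- c(`10` = unname(k_assoc[1]), k_assoc)
    fp <- c(`10` = 20L, fp)  # 10 bp cannot hold a 20 bp footprint
  }
  render_emsa_ladder(fragment_lengths_bp = lens_all, conc_grid_nM = conc,
                     K_assoc_per_nM = k_assoc, footprint_bp = fp, omega = 1,
                     n_replicates = n_rep, noise = noise_model(cv = cv, seed = seed),
                     construct = construct)
}

test_that("free-DNA normalization anchors at the zero-protein lane", {
  lad <- data.frame(protein_conc_nM = rep(c(0, 100), each = 2),
                    fragment_bp = rep(c(20, 40), 2),
                    free_intensity = c(120, 80, 30, 80))
  norm <- normalize_free_dna(lad)
  expect_equal(norm$normalized_free[norm$protein_conc_nM == 0], c(1, 1))
  expect_equal(norm$normalized_free[norm$protein_conc_nM == 100 &
                                      norm$fragment_bp == 20], 0.25)
  # flat titration stays at 1
  expect_equal(norm$normalized_free[norm$fragment_bp == 40], c(1, 1))
  bad <- lad; bad$free_intensity[1] <- 0
  expect_error(normalize_free_dna(bad), "fragment 20")
})

test_that("kdapp recovers single-site depletion and censors inert fragments", {
  lad <- make_ladder(cv = 0)
  res <- analyze_ladder(lad)
  fits <- res$fits
  expect_true(fits$censored[fits$fragment_bp == 10])
  expect_equal(fits$censor_bound_nM[fits$fragment_bp == 10], 760)
  for (len in c(20, 30, 40, 50))
    expect_equal(fits$kdapp_nM[fits$fragment_bp == len], 50, tolerance = 1e-4)
  # c50 = kdapp when h = 1 and Bmax = 1
  expect_equal(fits$c50_nM[!fits$censored], fits$kdapp_nM[!fits$censored],
               tolerance = 1e-4)
})

test_that("kdapp ordering matches the generator's partition-function ordering", {
  # length-coupled cooperativity: longer fragments bind effectively tighter
  conc <- c(0, exp(seq(log(10), log(2000), length.out = 9)))
  lad <- render_emsa_ladder(fragment_lengths_bp = c(20, 30, 40, 50),
                            conc_grid_nM = conc, K_assoc_per_nM = 0.004,
                            footprint_bp = 20L, omega = 40, n_replicates = 1,
                            noise = noise_model(cv = 0))
  fits <- kdapp_per_fragment(normalize_free_dna(lad))
  kd <- fits$kdapp_nM[order(fits$fragment_bp)]
  # oracle: concentration at which the exact partition function reaches 50%
  # free-DNA depletion, by brute-force enumeration
  c50_enum <- vapply(c(20, 30, 40, 50), function(L) {
    f <- function(x) enumerate_occupancy(L, 20, 0.004, 40, x)[1] - 0.5
    uniroot(f, c(1e-3, 1e6))$root
  }, numeric(1))
  expect_equal(order(kd), order(c50_enum))
  expect_true(all(diff(kd) <= 1e-6))  # monotone tighter with length here
})

test_that("c50 inversion matches the closed form and censors correctly", {
  fit1 <- list(kd_nM = 100, hill_h = 1, bmax = 1)
  expect_equal(sahdna:::c50_from_fit(fit1), 100)
  fit2 <- list(kd_nM = 100, hill_h = 2, bmax = 0.8)
  expect_equal(sahdna:::c50_from_fit(fit2), 100 * sqrt(0.5 / 0.3))
  fit3 <- list(kd_nM = 100, hill_h = 1, bmax = 0.45)
  expect_true(is.na(sahdna:::c50_from_fit(fit3)))
  # raw interpolation fallback
  curves <- normalize_free_dna(data.frame(
    protein_conc_nM = c(0, 50, 100, 200), fragment_bp = 40,
    free_intensity = c(100, 80, 60, 20)))
  c50_raw <- c50(curves = curves, method = "interpolate")
  expect_equal(c50_raw$c50_nM, 125)  # linear crossing between 0.6 and 0.2
})

test_that("selectivity slope arithmetic, censoring flags and replicate stats", {
  fits <- data.frame(construct = "wt", replicate = rep(1:3, each = 2),
                     fragment_bp = rep(c(40, 50), 3),
                     kdapp_nM = c(200, 150, 210, 170, 190, 130),
                     censored = FALSE)
  sl <- selectivity_slope(fits)
  expect_equal(sl$slopes$slope_nM_per_bp, c(-5, -4, -6))
  expect_equal(sl$summary$mean_slope, -5)
  expect_equal(sl$summary$sd_slope, 1)
  # equal kdapp: the threshold-effect null
  fits0 <- fits; fits0$kdapp_nM <- 100
  expect_equal(selectivity_slope(fits0)$summary$mean_slope, 0)
  # censored 50 bp leaves the slope undefined
  fits$censored[fits$fragment_bp == 50 & fits$replicate == 1] <- TRUE
  sl2 <- selectivity_slope(fits)
  expect_true(is.na(sl2$slopes$slope_nM_per_bp[1]))
  expect_true(sl2$slopes$censored[1])
})

test_that("construct comparison reproduces the closed-form ANOVA table", {
  slopes <- data.frame(construct = rep(c("wt", "mut"), each = 3),
                       slope_nM_per_bp = c(1, 2, 3, 4, 5, 6))
  res <- compare_constructs(slopes, reference = "wt")
  # hand computation: SSB = 13.5 (df 1), SSW = 4 (df 4)
  expect_equal(res$F, 13.5)
  expect_equal(res$p, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(res$contrasts$estimate, 3)
  # identical groups: F = 0, p = 1
  same <- data.frame(construct = rep(c("a", "b"), each = 3),
                     slope_nM_per_bp = rep(c(1, 2, 3), 2))
  res0 <- compare_constructs(same)
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  expect_error(compare_constructs(
    data.frame(construct = c("a", "a", "b"), slope_nM_per_bp = 1:3)),
    "single replicate")
})

test_that("p-value falls monotonically as one group's shift grows", {
  base <- c(-5.2, -4.8, -5.0, -5.1)
  ps <- vapply(c(0.5, 1.5, 3), function(shift) {
    slopes <- data.frame(
      construct = rep(c("wt", "edgsl", "kerhker"), each = 4),
      slope_nM_per_bp = c(base, base + shift, base + 0.1))
    compare_constructs(slopes, reference = "wt")$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})
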