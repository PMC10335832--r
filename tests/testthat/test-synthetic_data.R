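test_that("lattice configuration counts match combinatorics", {
  cc <- sahdna:::lattice_counts(50, 20)
  expect_equal(sum(cc["1", ]), 31)         # L - m + 1 single placements
  expect_equal(sum(cc["2", ]), choose(12, 2))  # 66 two-ligand placements
  # too-short lattice: only the empty configuration
  p <- lattice_partition(lattice_config(19, 20), 500)
  expect_equal(p$k_max, 0L)
  expect_equal(unname(p$p), 1)
})

test_that("transfer recursion equals brute-force enumeration with cooperativity", {
  cases <- list(c(50, 20), c(60, 25), c(60, 20), c(30, 10), c(24, 8),
                c(19, 20), c(12, 5))
  for (cs in cases) {
    L <- cs[1]; m <- cs[2]
    tab <- enumerate_lattice(L, m)
    cc <- sahdna:::lattice_counts(L, m)
    for (k in 0:(L %/% m)) for (a in seq_len(ncol(cc)) - 1L) {
      expected <- sum(tab$count[tab$k == k & tab$a == a])
      expect_equal(unname(cc[as.character(k), as.character(a)]), expected)
    }
    for (omega in c(0.1, 1, 10)) {
      cfg <- lattice_config(L, m, K_assoc_per_nM = 0.02, omega = omega)
      for (conc in c(0, 20, 150, 900)) {
        got <- lattice_partition(cfg, conc)$p
        want <- enumerate_occupancy(L, m, 0.02, omega, conc)
        expect_equal(unname(got), want, tolerance = 1e-10)
        expect_lt(abs(sum(got) - 1), 1e-12)
      }
    }
  }
})

test_that("single-site lattice reduces to the Hill curve with h = 1", {
  kd <- 50
  cfg <- lattice_config(20, 20, K_assoc_per_nM = 1 / kd,
                        conc_grid_nM = c(0, 5, 25, 50, 150, 400))
  tit <- simulate_titration(cfg)
  expect_equal(unname(tit$p[, "1"]),
               hill_fraction(cfg$conc_grid_nM, kd, 1, 1), tolerance = 1e-12)
})

test_that("mean occupancy is monotone and depletion mode matches trace limit", {
  cfg <- lattice_config(60, 20, K_assoc_per_nM = 0.05, omega = 5,
                        conc_grid_nM = c(0, 2, 9, 30, 90, 300, 900))
  tit <- simulate_titration(cfg)
  expect_true(all(diff(tit$mean_occupancy) >= -1e-12))
  expect_true(all(abs(rowSums(tit$p) - 1) < 1e-12))
  # 1 nM DNA: ligand depletion fades as protein excess grows
  dep <- simulate_titration(cfg, dna_conc_nM = 1)
  expect_lt(max(abs(dep$p[cfg$conc_grid_nM >= 9, ] -
                      tit$p[cfg$conc_grid_nM >= 9, ])), 0.05)
  expect_lt(max(abs(dep$p[cfg$conc_grid_nM >= 90, ] -
                      tit$p[cfg$conc_grid_nM >= 90, ])), 0.01)
  expect_true(all(dep$free_nM <= cfg$conc_grid_nM + 1e-9))
  # zero ligand leaves all DNA free
  expect_equal(unname(dep$p[1, "0"]), 1)
})

test_that("strong cooperativity on a two-site lattice steepens the Hill fit", {
  conc <- exp(seq(log(1), log(3000), length.out = 12))
  mk <- function(omega) {
    cfg <- lattice_config(40, 20, K_assoc_per_nM = 0.005, omega = omega,
                          conc_grid_nM = c(0, conc))
    tit <- simulate_titration(cfg)
    frac <- 1 - tit$p[, "0"]
    fit_hill(titration_series(c(0, conc), frac))
  }
  h_noncoop <- mk(1)$hill_h
  h_coop <- mk(1000)$hill_h
  expect_gt(h_coop, 1.3)
  expect_gt(h_coop, h_noncoop + 0.2)
})

test_that("rendered EMSA lanes are proportional to occupancy and band count scales with length", {
  cfg80 <- lattice_config(80, 20, K_assoc_per_nM = 1, conc_grid_nM = c(0, 5000))
  lanes80 <- render_emsa(simulate_titration(cfg80), noise_model(cv = 0))
  expect_equal(sum(grepl("^complex", names(lanes80))), 4L)  # floor(80/20)
  cfg40 <- lattice_config(40, 20, K_assoc_per_nM = 1, conc_grid_nM = c(0, 5000))
  lanes40 <- render_emsa(simulate_titration(cfg40), noise_model(cv = 0))
  expect_equal(sum(grepl("^complex", names(lanes40))), 2L)
  # at saturating ligand nearly all signal sits in the top band
  expect_gt(lanes40$complex2[2] / sum(lanes40[2, c("free", "complex1", "complex2")]),
            0.95)
  # zero noise: intensities exactly proportional to probabilities
  tit <- simulate_titration(lattice_config(40, 20, K_assoc_per_nM = 0.02,
                                           conc_grid_nM = c(0, 50, 200)))
  lanes <- render_emsa(tit, noise_model(cv = 0), scale = 1000)
  expect_equal(unname(as.matrix(lanes[, c("free", "complex1", "complex2")])),
               unname(tit$p * 1000), tolerance = 1e-12)
  # determinism under a fixed seed
  l1 <- render_emsa(tit, noise_model(cv = 0.1, seed = 9))
  l2 <- render_emsa(tit, noise_model(cv = 0.1, seed = 9))
  expect_identical(l1, l2)
})

test_that("render-fit round trip recovers the effective K_D within 10%", {
  kd <- 50
  conc <- c(0, exp(seq(log(5), log(1000), length.out = 11)))
  cfg <- lattice_config(20, 20, K_assoc_per_nM = 1 / kd, conc_grid_nM = conc)
  tit <- simulate_titration(cfg)
  kds <- vapply(1:60, function(s) {
    lanes <- render_emsa(tit, noise_model(cv = 0.05, seed = s))
    fit_hill(fraction_bound(lanes))$kd_nM
  }, numeric(1))
  expect_lt(abs(median(kds) / kd - 1), 0.10)
})

test_that("CD and melt simulators round-trip through the analysis", {
  for (hf in c(0, 0.37, 1)) {
    s <- simulate_cd(hf)
    expect_equal(fractional_helicity(mre222(s)), hf, tolerance = 1e-6)
  }
  m <- simulate_melt(tm_C = 45, dH_kJ = 150)
  fit <- fit_melt(m)
  expect_equal(fit$tm_C, 45, tolerance = 0.1)
  expect_equal(fit$model_class, "two_state")
})

test_that("helix generator is deterministic, writable and re-readable", {
  h <- generate_helix(30)
  expect_equal(sqrt(sum((h$xyz[30, ] - h$xyz[1, ])[3]^2)), 29 * 1.5)
  # curvature_radius = Inf equals the straight generator
  hc <- generate_helix(30, curvature_radius = Inf)
  expect_equal(h$xyz, hc$xyz)
  tf <- tempfile(fileext = ".pdb")
  write_helix_pdb(h, tf)
  back <- read_structure(tf)
  expect_equal(back$A$xyz, h$xyz, tolerance = 1e-3)  # PDB stores 3 decimals
  expect_equal(back$A$resno, h$resno)
})

test_that("SAH sequence generator obeys density, bias and seed contracts", {
  s1 <- generate_sah_sequence(64, seed = 3)
  s2 <- generate_sah_sequence(64, seed = 3)
  expect_identical(unclass(s1), unclass(s2))
  # full density: every residue participates in at least one predicted pair
  dense <- generate_sah_sequence(64, ion_pair_density = 1, seed = 5)
  net <- predict_ion_pairs(dense)
  expect_true(all(attr(net, "participates")))
  # zero density / zero bias: uncharged, near-zero face bias
  flat <- generate_sah_sequence(64, ion_pair_density = 0,
                                basic_stripe_bias = 0, seed = 5)
  fb <- helical_face_bias(flat)
  expect_equal(fb$total_charge, 0)
  expect_lt(abs(fb$bias_index), 1e-9)
  # strong stripe bias concentrates positive charge on one face
  striped <- generate_sah_sequence(64, ion_pair_density = 0,
                                   basic_stripe_bias = 1, seed = 5)
  fbs <- helical_face_bias(striped, sector_width_deg = 120)
  expect_gt(fbs$max_basic_sector$net_charge, 10)
})
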