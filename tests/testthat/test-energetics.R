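pair_atoms <- function(d, element = "C") {
  data.frame(chain = c("A", "B"), resno = 1, ins = "", resid = "ALA",
             elety = "CB", element = element, x = c(0, d), y = 0, z = 0,
             o = 1, b = 0, stringsAsFactors = FALSE)
}

test_that("the potential has the documented shape", {
  cfg <- scan_config()
  at_min <- score_assembly(pair_atoms(3.4), cfg)     # C-C contact distance
  expect_lt(at_min$terms[["attractive"]], 0)
  expect_equal(at_min$terms[["repulsive"]], 0)
  expect_equal(at_min$terms[["attractive"]], -0.14, tolerance = 1e-9)

  clash <- score_assembly(pair_atoms(2.5), cfg)
  expect_gt(clash$terms[["repulsive"]], 0)
  expect_equal(clash$terms[["attractive"]], -0.14, tolerance = 1e-9)

  far <- score_assembly(pair_atoms(100), cfg)
  expect_equal(far$terms[["attractive"]], 0)
  expect_equal(far$terms[["repulsive"]], 0)
  iso <- 4 * pi * (1.7 + 1.4)^2 * 0.005      # asp(C) * isolated area
  expect_equal(far$total, 2 * iso, tolerance = 0.01 * 2 * iso)
})

test_that("a hand-built three-atom case matches manual evaluation", {
  at <- data.frame(chain = c("A", "B", "C"), resno = 1, ins = "",
                   resid = "ALA", elety = "CB", element = "C",
                   x = c(0, 4.0, 100), y = 0, z = 0, o = 1, b = 0,
                   stringsAsFactors = FALSE)
  cfg <- scan_config()
  got <- score_assembly(at, cfg)
  # manual: one LJ pair at r = 4.0 (rm = 3.4, eps = 0.14), no switch
  s6 <- (3.4 / 4.0)^6
  lj <- 0.14 * (s6^2 - 2 * s6)
  expect_equal(got$terms[["attractive"]], lj, tolerance = 1e-9)
  expect_equal(got$terms[["repulsive"]], 0)
  # solvation: asp * per-atom areas from the sasa module
  area <- attr(residue_sasa(at, n_points = cfg$solv_n_points), "atom_area")
  expect_equal(got$terms[["solvation"]], 0.005 * sum(area), tolerance = 1e-9)
  expect_equal(got$total, lj + 0.005 * sum(area), tolerance = 1e-9)
})

test_that("per-residue attribution sums exactly to the total", {
  fib <- small_fibril("SAKLVT", n_layers = 3)
  sb <- score_assembly(fib, scan_config())
  expect_equal(sum(sb$per_residue$energy), sb$total, tolerance = 1e-9)
  expect_equal(sum(sb$per_chain), sb$total, tolerance = 1e-9)
  expect_equal(unname(sum(sb$terms)), sb$total, tolerance = 1e-9)
})

test_that("mutation truncates to CB and relabels every layer", {
  fib <- small_fibril("SALKV", n_layers = 3)
  mut <- mutate_to_alanine(fib, 3)       # leucine
  for (ch in mut$chain_order) {
    res <- mut$atoms[mut$atoms$chain == ch & mut$atoms$resno == 3, ]
    expect_setequal(res$elety, c("N", "CA", "C", "O", "CB"))
    expect_true(all(res$resid == "ALA"))
  }
  # untouched positions keep their side chains
  expect_true("CD" %in% mut$atoms$elety[mut$atoms$resno == 4])
  expect_error(mutate_to_alanine(fib, 99), "absent")
})

test_that("glycine positions are excluded with a structured reason", {
  fib <- small_fibril("SAGLV", n_layers = 3)
  err <- tryCatch(mutate_to_alanine(fib, 3), error = identity)
  expect_s3_class(err, "fibrilscan_glycine_exclusion")

  over <- mutate_to_alanine(fib, 3, override_glycine = TRUE)
  expect_true("CB" %in% over$atoms$elety[over$atoms$resno == 3])
  expect_true(all(over$atoms$resid[over$atoms$resno == 3] == "ALA"))

  cfg <- scan_config(n_replicates = 1, rng_seed = 1, compute_ddg = FALSE)
  scan <- run_alanine_scan(fib, cfg, minimize_input = FALSE)
  expect_equal(scan$excluded$position, 3)
  expect_equal(scan$excluded$reason, "glycine")
  expect_false(3 %in% scan$replicates$position)
})

test_that("relaxation descends and never moves the backbone", {
  fib <- two_sided_fibril()
  cfg <- test_scan_config()
  set.seed(5)
  out <- relax_assembly(fib, cfg, site = 313, perturb = TRUE)
  d <- attr(out, "relax")
  expect_lte(d$objective_end, d$objective_start + 1e-9)
  bb <- fib$atoms$elety %in% c("N", "CA", "C", "O", "CB")
  expect_equal(as.matrix(out$atoms[bb, c("x", "y", "z")]),
               as.matrix(fib$atoms[bb, c("x", "y", "z")]))

  # an already-minimal sparse structure with zero jitter is unchanged
  iso <- small_fibril("LL", n_layers = 1)
  at <- iso$atoms
  at[at$resno == 2, c("x", "y", "z")] <- at[at$resno == 2, c("x", "y", "z")] + 100
  iso$atoms <- at
  cfg0 <- scan_config(n_replicates = 1, perturb_sigma_chi = 0)
  still <- relax_assembly(iso, cfg0, site = 1, perturb = TRUE)
  expect_equal(still$atoms, iso$atoms)
})

test_that("alanine self-mutation yields exactly zero at every replicate", {
  fib <- small_fibril("SATAL", n_layers = 5)
  cfg <- scan_config(n_replicates = 3, rng_seed = 9)
  out <- delta_reu_assembly(fib, 4, cfg)    # position 4 is alanine
  expect_identical(out$replicates$delta_reu, rep(0, 3))
  expect_identical(out$replicates$ddg_interface, rep(0, 3))
  expect_true(all(out$per_chain_delta == 0))
  expect_identical(out$replicates$d_attractive, rep(0, 3))
})

test_that("disjoint layers scale additively and have zero interface ddG", {
  # layers 100 A apart: no inter-layer interactions at all
  seqs <- "SLKT"
  path <- cbind(seq(0, by = 3.8, length.out = 4), 0)
  far5 <- generate_fibril(fibril_spec(seqs, path, rise = 100, twist = 0,
                                      n_layers = 5))
  cfg <- scan_config(n_replicates = 1, perturb_sigma_chi = 0, rng_seed = 2)
  out5 <- delta_reu_assembly(far5, 2, cfg)
  expect_equal(out5$replicates$ddg_interface, 0, tolerance = 1e-9)
  expect_equal(out5$replicates$dg_mut, 0, tolerance = 1e-9)

  far1 <- generate_fibril(fibril_spec(seqs, path, rise = 100, twist = 0,
                                      n_layers = 1))
  cfg1 <- scan_config(n_replicates = 1, perturb_sigma_chi = 0, rng_seed = 2,
                      compute_ddg = FALSE)
  out1 <- delta_reu_assembly(far1, 2, cfg1)
  expect_equal(out5$replicates$delta_reu, 5 * out1$replicates$delta_reu,
               tolerance = 1e-6)
  # per-layer attribution equals the isolated-layer value
  expect_equal(unname(out5$per_chain_delta[1, ]),
               rep(out1$replicates$delta_reu, 5), tolerance = 1e-6)
})

test_that("interface ddG equals the identity of its stored components", {
  scan <- two_sided_scan()
  df <- scan$replicates
  expect_equal(df$ddg_interface, df$dg_mut - df$dg_wt, tolerance = 1e-12)
  expect_equal(df$delta_reu, df$bound_mut - df$bound_wt, tolerance = 1e-12)
  expect_error(ddg_interface(small_fibril(n_layers = 3), 1), ">= 5")
})

test_that("edge + internal decomposition is exact for every replicate", {
  scan <- two_sided_scan()
  dec <- layer_decomposition(scan)
  expect_lt(max(abs(dec$delta_edge + dec$delta_internal -
                      scan$replicates$delta_reu)), 1e-9)
  means <- attr(dec, "means")
  expect_equal(nrow(means), length(unique(scan$replicates$position)))
})

test_that("scans are deterministic under a fixed seed", {
  fib <- small_fibril("SLKVT", n_layers = 3)
  cfg <- scan_config(n_replicates = 2, rng_seed = 31, compute_ddg = FALSE)
  s1 <- run_alanine_scan(fib, cfg, "a")
  s2 <- run_alanine_scan(fib, cfg, "a")
  expect_identical(s1$replicates, s2$replicates)
  cfg2 <- scan_config(n_replicates = 2, rng_seed = 32, compute_ddg = FALSE)
  s3 <- run_alanine_scan(fib, cfg2, "a")
  expect_false(identical(s1$replicates$delta_reu, s3$replicates$delta_reu))
  # reduced replicate count is honoured
  expect_equal(max(s1$replicates$replicate), 2)
})

test_that("external score tables are ingested and round-tripped", {
  toy <- data.frame(structure_id = "toy", residue = 7, replicate = 1:3,
                    bound_mut = c(-99, -98, -97), bound_wt = -100)
  sc <- ingest_external_scores(toy)
  expect_s3_class(sc, "scan_result")
  expect_equal(summary(sc)$mean_delta_reu, 2)

  scan <- two_sided_scan()
  f <- tempfile(fileext = ".tsv")
  write_scan_result(scan, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- ingest_external_scores(f)
  expect_equal(back$replicates$delta_reu, scan$replicates$delta_reu,
               tolerance = 1e-9)
  expect_equal(back$replicates$position, scan$replicates$position)

  dup <- rbind(toy, toy[1, ])
  expect_error(ingest_external_scores(dup), "duplicate.*row 4")
  expect_error(ingest_external_scores(toy[, -4]), "missing column")
  bad <- toy
  bad$bound_mut <- as.character(bad$bound_mut)
  bad$bound_mut[2] <- "oops"
  expect_error(ingest_external_scores(bad), "non-numeric.*row 2")
})

test_that("planted buried hotspots dominate the scan", {
  scan <- two_sided_scan()
  s <- summary(scan)
  top3 <- s$position[order(-s$mean_delta_reu)][1:3]
  expect_setequal(top3, planted_hotspots())
  hs <- identify_hotspots(normalize_profile(scan))
  expect_true(all(planted_hotspots() %in% hs$top))
})

test_that("mean scan energetics track nonpolar burial", {
  scan <- two_sided_scan()
  s <- summary(scan)
  np <- memo("ts_burial", nonpolar_burial(two_sided_fibril(), n_points = 384))
  m <- merge(s, np, by.x = "position", by.y = "resno")
  rho <- cor(m$mean_delta_reu, m$buried_nonpolar, method = "spearman")
  expect_gte(rho, 0.8)
})
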