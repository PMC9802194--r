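test_that("generators are pure functions of (config, seed)", {
  cfg <- scenario_config(seed = 21)
  expect_identical(generate_geochem(cfg), generate_geochem(cfg))
  expect_identical(generate_pigments_grainsize(cfg),
                   generate_pigments_grainsize(cfg))
  com1 <- generate_community(community_scenario(), cfg)
  com2 <- generate_community(community_scenario(), cfg)
  expect_identical(com1$tables$bac16S$counts, com2$tables$bac16S$counts)
  expect_identical(ape::write.tree(com1$trees$euk18S),
                   ape::write.tree(com2$trees$euk18S))
  expect_identical(com1$genes, com2$genes)
  # a different seed changes the draw
  com3 <- generate_community(community_scenario(), scenario_config(seed = 22))
  expect_false(identical(com1$tables$bac16S$counts, com3$tables$bac16S$counts))
})

test_that("zero noise reproduces the forward model exactly", {
  cfg <- scenario_config(
    seed = 5,
    solutes = list(DIC = list(d0 = 0.8, c_ow = 2.1, c_init = 7,
                              noise_sdlog = 0)))
  geo <- generate_geochem(cfg)
  truth <- geo$truth$noiseless
  expect_equal(geo$observations$value, truth$value)
})

test_that("planted sand bump yields a feeding-intensity peak in the window", {
  cfg <- scenario_config(seed = 31)
  pg <- generate_pigments_grainsize(cfg)
  sb <- pg$sand[pg$sand$treatment == "bioturbated" &
                  pg$sand$time_point == "T2", ]
  sc <- pg$sand[pg$sand$treatment == "nonbioturbated" &
                  pg$sand$time_point == "T2", ]
  fb <- feeding_intensity(sb[c("depth_cm", "fraction")],
                          sc[c("depth_cm", "fraction")])
  peak <- fb$depth_cm[which.max(fb$F_B)]
  expect_gte(peak, 15); expect_lte(peak, 25)
  # peak height ~ planted 0.2 within noise (sd 0.02 each arm)
  expect_lt(abs(max(fb$F_B) - 0.2), 3 * sqrt(2) * 0.02 + 0.02)
  # no bump: F_B fluctuates around zero
  cfg0 <- scenario_config(seed = 32,
                          sand = list(base = 0.65, bump = 0, window = c(15, 25),
                                      ramp = 2, noise_sd = 0.02))
  pg0 <- generate_pigments_grainsize(cfg0)
  sb0 <- pg0$sand[pg0$sand$treatment == "bioturbated" &
                    pg0$sand$time_point == "T2", ]
  sc0 <- pg0$sand[pg0$sand$treatment == "nonbioturbated" &
                    pg0$sand$time_point == "T2", ]
  fb0 <- feeding_intensity(sb0[c("depth_cm", "fraction")],
                           sc0[c("depth_cm", "fraction")])
  se <- sqrt(2) * 0.02 / sqrt(nrow(fb0))
  expect_lt(abs(mean(fb0$F_B)), 3 * se)
})

test_that("freshness declines with depth in the noiseless control profile", {
  cfg <- scenario_config(
    seed = 1,
    pigments = list(k_chl = 0.02, k_pheo = 0.002, yield = 1, flux = 1.5,
                    noise_sdlog = 0))
  pg <- generate_pigments_grainsize(cfg)
  prof <- pg$truth$profiles$nonbioturbated
  fresh <- freshness_index(prof$chl_a, prof$pheopigment)
  expect_true(all(diff(fresh) < 1e-10))
})

test_that("community tables satisfy the consuming-module invariants", {
  cfg <- scenario_config(seed = 41)
  com <- generate_community(community_scenario(), cfg)
  for (dom in names(com$tables)) {
    tab <- com$tables[[dom]]
    expect_s3_class(tab, "zotu_table")
    expect_true(all(tab$counts >= 0))
    expect_true(all(rowSums(tab$counts) > 0))
    expect_true(all(colnames(tab$counts) %in% com$trees[[dom]]$tip.label))
    expect_true(all(com$trees[[dom]]$edge.length >= 0))
  }
  # BL of the bioturbated arm is depleted in the qPCR profile
  genes <- com$genes
  bl_bio <- genes$zone == "BL"
  bl_ctrl <- genes$treatment == "nonbioturbated" &
    genes$depth_cm >= 12.5 & genes$depth_cm < 25
  w <- welch_t(log10(genes$bac16S[bl_bio]), log10(genes$bac16S[bl_ctrl]))
  expect_lt(w$p, 0.05)
  expect_lt(mean(log10(genes$bac16S[bl_bio])),
            mean(log10(genes$bac16S[bl_ctrl])))
})

test_that("the BL depletion dial moves the measured effect monotonically", {
  effects <- vapply(c(1, 10, 100), function(fold) {
    sc <- community_scenario(bl_fold_abundance = c(prok = fold, euk = fold))
    com <- generate_community(sc, scenario_config(seed = 51))
    genes <- com$genes
    bl_bio <- genes$zone == "BL"
    bl_ctrl <- genes$treatment == "nonbioturbated" &
      genes$depth_cm >= 12.5 & genes$depth_cm < 25
    mean(log10(genes$bac16S[bl_ctrl])) - mean(log10(genes$bac16S[bl_bio]))
  }, numeric(1))
  expect_true(all(diff(effects) > 0))
  expect_lt(abs(effects[1]), 0.2)       # no planted effect at fold = 1
  expect_gt(effects[3], 1.5)            # ~2 orders at fold = 100
})

test_that("null community scenario leaves treatments exchangeable", {
  sc0 <- community_scenario(bl_fold_abundance = c(prok = 1, euk = 1),
                            bl_richness_loss = 0)
  com <- generate_community(sc0, scenario_config(seed = 61))
  tab <- com$tables$bac16S
  md <- tab$metadata
  bl <- md$depth_cm >= 12.5 & md$depth_cm < 25
  r <- rarefy(tab, depth = 5000, seed = 1)
  rich <- richness(r)
  md_r <- r$metadata
  in_bl <- md_r$depth_cm >= 12.5 & md_r$depth_cm < 25
  w <- welch_t(rich[in_bl & md_r$treatment == "bioturbated"],
               rich[in_bl & md_r$treatment == "nonbioturbated"])
  expect_gt(w$p, 0.01)   # no planted effect to detect
})
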