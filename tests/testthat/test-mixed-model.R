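test_that("Henderson MME match a hand-built system for two founders", {
  ped <- as_pedigree(data.frame(animal = c("a1", "a2"), sire = NA, dam = NA))
  A <- build_A(ped)
  dat <- data.frame(animal_id = c("a1", "a2"), pond = "P1", y = c(1.5, 2.5))
  m <- build_mme(dat, "y", A, sigmaA2 = 1, sigmaE2 = 1)
  # X = [1,1]', Z = I2, A^-1 = I2, lambda = 1:
  C_hand <- rbind(c(2, 1, 1), c(1, 2, 0), c(1, 0, 2))
  expect_equal(unname(as.matrix(m$C)), C_hand)
  expect_equal(unname(m$rhs), c(4, 1.5, 2.5))
  expect_equal(unname(m$solution), unname(solve(C_hand, c(4, 1.5, 2.5))))
})

test_that("MME without the random effect reduce to normal equations for pond means", {
  set.seed(1)
  dat <- data.frame(animal_id = sprintf("a%d", 1:40),
                    pond = rep(c("P1", "P2"), each = 20),
                    y = rnorm(40, rep(c(5, 7), each = 20)))
  ped <- as_pedigree(data.frame(animal = dat$animal_id, sire = NA, dam = NA))
  m <- build_mme(dat, "y", build_A(ped), random = FALSE)
  ols <- coef(lm(y ~ factor(pond), dat))
  expect_equal(unname(m$solution), unname(ols), tolerance = 1e-10)
})

test_that("MME solutions are invariant to animal ordering", {
  set.seed(2)
  ped <- random_pedigree(30, n_founder = 8, seed = 3)
  A <- build_A(ped)
  dat <- data.frame(animal_id = ped$animal[11:30],
                    pond = rep(c("P1", "P2"), each = 10),
                    y = rnorm(20, 5))
  m1 <- build_mme(dat, "y", A, sigmaA2 = 0.4, sigmaE2 = 0.6)
  perm <- sample.int(nrow(dat))
  m2 <- build_mme(dat[perm, ], "y", A, sigmaA2 = 0.4, sigmaE2 = 0.6)
  expect_equal(m2$solution[names(m1$solution)], m1$solution, tolerance = 1e-8)
})

test_that("REML matches the balanced half-sib ANOVA estimator", {
  set.seed(42)
  ns <- 80; k <- 15
  ped <- halfsib_pedigree(ns, k)
  A <- build_A(ped)
  sires <- ped$animal[ped$founder]
  off <- ped$animal[!ped$founder]
  sA <- 0.32; sE <- 0.68
  u_s <- rnorm(ns, 0, sqrt(sA))
  bv <- 0.5 * rep(u_s, each = k) + rnorm(ns * k, 0, sqrt(0.75 * sA))
  y <- 10 + bv + rnorm(ns * k, 0, sqrt(sE))
  dat <- data.frame(animal_id = off, pond = "P1", y = y)
  fit <- reml_fit(dat, "y", A)
  expect_true(fit$converged)

  ms <- anova(lm(y ~ factor(rep(sires, each = k))))
  sigmaA_anova <- 4 * (ms$`Mean Sq`[1] - ms$`Mean Sq`[2]) / k
  expect_lt(abs(fit$sigmaA2 - sigmaA_anova), 2 * fit$se[1])
  expect_lt(abs(fit$h2 - 0.32), 3 * fit$h2_se)
})

test_that("a constant response drives both components to the lower bound", {
  ped <- halfsib_pedigree(10, 5)
  dat <- data.frame(animal_id = ped$animal[!ped$founder], pond = "P1", y = 7)
  fit <- reml_fit(dat, "y", ped |> build_A())
  expect_true(fit$boundary)
  expect_equal(fit$sigmaA2, 0)
  expect_equal(fit$sigmaE2, 0)
})

test_that("EM and AI REML agree and EM is monotone in the log-likelihood", {
  set.seed(5)
  ped <- halfsib_pedigree(30, 10)
  A <- build_A(ped)
  off <- ped$animal[!ped$founder]
  bv <- 0.5 * rep(rnorm(30, 0, sqrt(0.3)), each = 10) + rnorm(300, 0, sqrt(0.225))
  dat <- data.frame(animal_id = off,
                    pond = rep(c("P1", "P2", "P3"), length.out = 300),
                    y = 5 + bv + rnorm(300, 0, sqrt(0.7)))
  ai <- reml_fit(dat, "y", A, algorithm = "ai")
  em <- reml_fit(dat, "y", A, algorithm = "em", sp = ai$sp, keep_trace = TRUE)
  expect_true(ai$converged && em$converged)
  expect_lt(abs(ai$loglik - em$loglik), 1e-4)
  expect_lt(abs(ai$sigmaA2 - em$sigmaA2) / max(ai$sigmaA2, 1e-8), 1e-3)
  expect_lt(abs(ai$sigmaE2 - em$sigmaE2) / ai$sigmaE2, 1e-3)
  # monotone non-decreasing REML log-likelihood at every EM iteration
  expect_true(all(diff(em$loglik_trace) >= -1e-8))
})

test_that("bivariate fit recovers a known genetic correlation and its null", {
  for (case in list(list(rg = 0.8, seed = 7), list(rg = 0, seed = 8))) {
    g12 <- case$rg * 0.3
    cfg <- sim_config(n_sires = 40, n_dams = 32, n_offspring = 1400,
                      n_families = 50, n_ponds = 4, traits = c("T1", "T2"),
                      trueG = matrix(c(0.3, g12, g12, 0.3), 2),
                      trueR = matrix(c(0.7, 0.1, 0.1, 0.7), 2),
                      trait_means = c(0, 0), seed = case$seed)
    des <- simulate_pedigree(cfg)
    pond <- allocate_to_ponds(des$offspring, cfg)
    ds <- simulate_traits(cfg, des$pedigree, pond)
    A <- build_A(des$pedigree)
    fit <- reml_bivariate(ds$phenotypes, c("T1", "T2"), A)
    expect_true(fit$converged)
    rg <- fit$correlations$rg
    expect_true(rg$estimable)
    expect_lt(abs(rg$r - case$rg), 2 * rg$se)
  }
})

test_that("a duplicated trait pushes rg to the unit boundary and is flagged", {
  set.seed(9)
  ped <- halfsib_pedigree(25, 10)
  A <- build_A(ped)
  off <- ped$animal[!ped$founder]
  bv <- 0.5 * rep(rnorm(25, 0, sqrt(0.4)), each = 10) + rnorm(250, 0, sqrt(0.3))
  y <- 3 + bv + rnorm(250, 0, sqrt(0.6))
  dat <- data.frame(animal_id = off, pond = "P1", T1 = y, T2 = y)
  fit <- reml_bivariate(dat, c("T1", "T2"), A, max_iter = 60)
  rg <- fit$correlations$rg$r
  expect_true(rg > 0.98 || isTRUE(fit$clipped))

  dat$T2 <- 5  # constant second trait
  expect_error(reml_bivariate(dat, c("T1", "T2"), A), "constant")
})

test_that("a univariate fit is recovered from a bivariate fit with independent noise", {
  set.seed(10)
  cfg <- sim_config(n_sires = 25, n_dams = 20, n_offspring = 700,
                    n_families = 30, n_ponds = 2, traits = c("T1", "T2"),
                    trueG = diag(c(0.35, 1e-4)), trueR = diag(c(0.65, 1)),
                    trait_means = c(0, 0), seed = 10)
  des <- simulate_pedigree(cfg)
  pond <- allocate_to_ponds(des$offspring, cfg)
  ds <- simulate_traits(cfg, des$pedigree, pond)
  A <- build_A(des$pedigree)
  uni <- reml_fit(ds$phenotypes, "T1", A)
  biv <- reml_bivariate(ds$phenotypes, c("T1", "T2"), A, sp = uni$sp)
  expect_lt(abs(biv$G[1, 1] - uni$sigmaA2) / uni$sigmaA2, 1e-2)
})

test_that("EBVs satisfy the mid-parent property and shrink to zero without heritability", {
  set.seed(11)
  ns <- 15; k <- 20
  sires <- sprintf("s%02d", 1:ns); dams <- sprintf("d%02d", 1:ns)
  off <- sprintf("o%03d", 1:(ns * k))
  base <- data.frame(animal = c(sires, dams, off),
                     sire = c(rep(NA, 2 * ns), rep(sires, each = k)),
                     dam = c(rep(NA, 2 * ns), rep(dams, each = k)))
  ped <- as_pedigree(rbind(base,
                           data.frame(animal = "probe", sire = "o001", dam = "o009")))
  A <- build_A(ped)
  bv <- 0.5 * (rep(rnorm(ns, 0, 0.6), each = k) + rep(rnorm(ns, 0, 0.6), each = k)) +
    rnorm(ns * k, 0, sqrt(0.18))
  dat <- data.frame(animal_id = off, pond = rep(c("P1", "P2"), length.out = ns * k),
                    y = 4 + bv + rnorm(ns * k, 0, 0.8))
  fit <- reml_fit(dat, "y", A)
  e <- blup_ebv(fit, A, ids = c("probe", "o001", "o009"))
  expect_equal(e$ebv[1], mean(e$ebv[2:3]), tolerance = 1e-10)
  expect_true(all(e$pev >= 0))
  expect_true(all(e$pev <= fit$sigmaA2 * diag(A)[e$animal_id] + 1e-10))
  expect_error(blup_ebv(fit, A, ids = "ghost"), "absent")

  # pure-noise phenotype: estimated genetic variance ~ 0, EBVs shrink to ~ 0
  set.seed(12)
  dat0 <- dat; dat0$y <- rnorm(nrow(dat), 4, 1)
  fit0 <- reml_fit(dat0, "y", A)
  expect_lt(fit0$sigmaA2, 0.35 * fit$sigmaA2)
  e0 <- blup_ebv(fit0, A, ids = off, pev = FALSE)
  expect_lt(max(abs(e0$ebv)), 0.3 * sd(dat0$y))
})

test_that("EBV accuracy matches the reliability it reports", {
  cfg <- sim_config(n_sires = 40, n_dams = 35, n_offspring = 1500,
                    n_families = 55, n_ponds = 4, traits = "y",
                    trueG = matrix(0.32), trueR = matrix(0.68),
                    trait_means = 0, seed = 13)
  des <- simulate_pedigree(cfg)
  pond <- allocate_to_ponds(des$offspring, cfg)
  ds <- simulate_traits(cfg, des$pedigree, pond)
  A <- build_A(des$pedigree)
  fit <- reml_fit(ds$phenotypes, "y", A)
  off <- ds$phenotypes$animal_id
  e <- blup_ebv(fit, A, ids = off)
  acc <- cor(e$ebv, ds$bv[off, "y"])
  expect_lt(abs(acc - sqrt(mean(e$reliability))), 0.05)
})
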