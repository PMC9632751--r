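test_that("heritability reproduces published worked examples from components", {
  expect_equal(round(heritability(0.35, 0.61)$h2, 2), 0.36)   # body length
  expect_equal(round(heritability(0.15, 1.48)$h2, 2), 0.09)   # abdominal pct
  expect_equal(round(heritability(0.25, 0.56)$h2, 2), 0.31)   # head size
  expect_equal(heritability(0, 1)$h2, 0)
  expect_error(heritability(0, 0), "undefined")
  se <- heritability(0.35, 0.61, cov = diag(c(0.07, 0.03))^2)$se
  expect_gt(se, 0); expect_lt(se, 0.2)
})

test_that("genetic correlation handles boundaries and non-estimable input", {
  expect_equal(genetic_correlation(0, 1, 2)$r, 0)
  b <- genetic_correlation(sqrt(0.3 * 0.5), 0.3, 0.5)
  expect_equal(b$r, 1, tolerance = 1e-12)
  expect_false(b$clipped)
  over <- genetic_correlation(1.2 * sqrt(0.3 * 0.5), 0.3, 0.5)
  expect_true(over$clipped)
  expect_equal(over$r, 1)
  ne <- genetic_correlation(0.1, 0, 0.5)
  expect_false(ne$estimable)
  expect_true(is.na(ne$r))
})

test_that("correlated response and %IS reproduce verified published cells", {
  # one-SD selection on body weight / body length, standardised responses
  expect_equal(round(correlated_response(0.36, 0.32, 0.09), 2), 0.06)  # BW -> AP
  expect_equal(round(correlated_response(0.96, 0.32, 0.28), 2), 0.29)  # BW -> TT
  expect_equal(round(correlated_response(0.99, 0.32, 0.31), 2), 0.31)  # BW -> HS
  expect_equal(round(relative_efficiency(-0.48, 0.32, 0.08)), -96)     # BW -> FBR
  expect_equal(round(relative_efficiency(0.36, 0.36, 0.09)), 72)       # BL -> AP
  expect_equal(round(relative_efficiency(0.99, 0.32, 0.31)), 101)      # BW -> HS
  expect_equal(round(relative_efficiency(-0.69, 0.36, 0.06)), -169)    # BL -> CF

  expect_equal(correlated_response(0, 0.3, 0.3), 0)
  expect_error(correlated_response(1.2, 0.3, 0.3), "rg")
  expect_error(relative_efficiency(0.5, 0.3, 0), "h2y")
  # sd_y option converts to trait units
  expect_equal(correlated_response(0.5, 0.25, 0.25, sd_y = 4),
               0.5 * 0.5 * 0.5 * 4)
})

test_that("%IS reduces to 100*rg at equal heritability and CR symmetry holds", {
  set.seed(3)
  for (i in 1:20) {
    rg <- runif(1, -1, 1); h2 <- runif(1, 0.05, 0.9)
    expect_equal(relative_efficiency(rg, h2, h2), 100 * rg, tolerance = 1e-12)
    h2y <- runif(1, 0.05, 0.9)
    expect_equal(correlated_response(rg, h2, h2y),
                 correlated_response(rg, h2y, h2), tolerance = 1e-12)
  }
})

test_that("descriptives reproduce published CVs and handle edge cases", {
  # two-point vectors with exact published mean and SD
  mk <- function(m, s) c(m - s / sqrt(2), m + s / sqrt(2))
  d <- descriptives(data.frame(BW = mk(14.52, 3.92), BL = mk(10.82, 1.01),
                               AP = mk(63.87, 1.48), CFL = mk(11.30, 0.52)))
  expect_equal(round(d$cv[d$trait == "BW"], 1), 27.0)
  expect_equal(round(d$cv[d$trait == "BL"], 1), 9.3)
  expect_equal(round(d$cv[d$trait == "AP"], 1), 2.3)
  expect_equal(round(d$cv[d$trait == "CFL"], 1), 4.6)

  cst <- descriptives(data.frame(x = rep(3, 5)))
  expect_equal(cst$sd, 0); expect_equal(cst$cv, 0)
  zero <- descriptives(data.frame(x = c(-1, 1)))
  expect_true(is.na(zero$cv))
  expect_error(descriptives(data.frame(x = 1)), "n >= 2")
})

test_that("GxE table recovers a shared genetic effect and flags non-overlap", {
  cfg <- sim_config(n_sires = 16, n_dams = 14, n_offspring = 700,
                    n_families = 20, n_ponds = 2, traits = "BL",
                    trueG = matrix(0.35), trueR = matrix(0.65),
                    trait_means = 10, allocation_concentration = 50, seed = 77)
  des <- simulate_pedigree(cfg)
  pond <- allocate_to_ponds(des$offspring, cfg)
  ds <- simulate_traits(cfg, des$pedigree, pond)
  A <- build_A(des$pedigree)
  g <- gxe_matrix(ds$phenotypes, "BL", A, des$pedigree)
  expect_equal(nrow(g$table), 1)
  expect_true(g$table$estimable)
  # one shared genetic effect -> cross-pond rg within 2 SE of 1
  expect_gt(g$table$rg + 2 * g$table$se, 1 - 1e-8)
  expect_gt(g$table$rg, 0.6)

  # ponds split along sire lines share no families -> non-estimable, missing
  off <- des$offspring
  sires <- sort(unique(off$sire))
  pond2 <- setNames(
    ifelse(off$sire %in% sires[seq_len(length(sires) %/% 2)], "P1", "P2"),
    off$animal)
  ds2 <- simulate_traits(cfg, des$pedigree, pond2)
  g2 <- gxe_matrix(ds2$phenotypes, "BL", A, des$pedigree)
  expect_false(g2$table$estimable)
  expect_true(is.na(g2$table$rg))
  expect_error(gxe_matrix(ds$phenotypes[ds$phenotypes$pond == "P1", ],
                          "BL", A, des$pedigree), "two ponds")
})
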