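test_that("map expansion for sib-mated RI lines is exact and monotone", {
  expect_equal(expand_rf(0), 0)
  expect_equal(expand_rf(0.5), 0.5)
  expect_equal(expand_rf(0.1), 0.25)
  expect_error(expand_rf(-0.01), "\\[0, 0.5\\]")
  expect_error(expand_rf(0.51), "\\[0, 0.5\\]")
  r <- seq(0.001, 0.499, length.out = 200)
  R <- expand_rf(r)
  expect_true(all(diff(R) > 0))
  expect_true(all(R <= 0.5 & R > r))  # expansion inflates but stays bounded
})

test_that("simulated RI genotypes follow the expanded two-state chain", {
  # markers 0 cM apart are identical in every line
  map0 <- tiny_map(c(0, 0, 15))
  G0 <- simulate_ri_genotypes(map0, 50, seed = 4)
  expect_identical(G0[, 1], G0[, 2])

  # allele frequency: binomial 99% interval at n = 10,000 is 0.5 +/- 0.013
  map1 <- tiny_map(0)
  G1 <- simulate_ri_genotypes(map1, 10000, seed = 9)
  expect_lt(abs(mean(G1) - 0.5), 0.02)

  # inter-marker discordance matches expand_rf(haldane(d)) for several gaps
  for (d in c(1, 5, 10, 25)) {
    m <- tiny_map(c(0, d))
    G <- simulate_ri_genotypes(m, 10000, seed = 100 + d)
    expected <- expand_rf(haldane_rf(d))
    expect_lt(abs(mean(G[, 1] != G[, 2]) - expected), 0.015)
  }
  expect_equal(expand_rf(haldane_rf(10)), 0.23484, tolerance = 1e-4)

  # determinism and no heterozygotes
  map <- default_map()
  expect_identical(simulate_ri_genotypes(map, 20, seed = 3),
                   simulate_ri_genotypes(map, 20, seed = 3))
  expect_true(all(simulate_ri_genotypes(map, 20, seed = 3) %in% 0:1))
})

test_that("family simulation injects planted effects additively", {
  map <- tiny_map(c(0, 20, 40))
  mk <- map$marker[2]
  base <- list(n_lines = 24, replicates_per_line = 2, dropout_prob = 0,
               days = 6, line_env_sd = 0,
               covariate_effects = list(batch = c(0, 0, 0, 0)))

  # noiseless direct effect: line means differ by exactly the effect size
  scen <- do.call(sim_scenario, c(base, list(
    qtl_effects = data.frame(marker = mk, role = "BXD_offspring",
                             trait = "sucking", day = 6,
                             effect_class = "direct", effect = 1.0),
    noise_sd_within_family = 0, seed = 21)))
  G <- simulate_ri_genotypes(map, 24, seed = 21)
  tbl <- simulate_families(G, map, scen)
  sub <- tbl[tbl$role == "BXD_offspring" & tbl$trait == "sucking", ]
  lm_ <- tapply(sub$value, sub$line_id, mean)
  g <- G[names(lm_), mk]
  expect_equal(unname(mean(lm_[g == 1]) - mean(lm_[g == 0])), 1.0)

  # noiseless indirect effect on the mother: genotype of the fostered
  # half-litter separates maternal line means perfectly (R2 = 1)
  scen_i <- do.call(sim_scenario, c(base, list(
    qtl_effects = data.frame(marker = mk, role = "mother",
                             trait = "suckling", day = 6,
                             effect_class = "indirect", effect = 1.0),
    noise_sd_within_family = 0, seed = 22)))
  tbl_i <- simulate_families(G, map, scen_i)
  sub_i <- tbl_i[tbl_i$role == "mother" & tbl_i$trait == "suckling", ]
  ym <- tapply(sub_i$value, sub_i$line_id, mean)
  pr <- peak_r2(ym, G[, mk])
  expect_equal(pr$R2, 1.0)
  expect_equal(pr$allele_increasing, "D2")
})

test_that("with no planted effects line means are uncorrelated with genotype", {
  map <- tiny_map(c(0, 30))
  n_seeds <- 200
  within <- logical(n_seeds)
  for (k in seq_len(n_seeds)) {
    scen <- sim_scenario(n_lines = 32, replicates_per_line = 3,
                         dropout_prob = 0, days = 6,
                         qtl_effects = data.frame(),
                         line_env_sd = 0, seed = 400 + k)
    G <- simulate_ri_genotypes(map, 32, seed = 800 + k)
    tbl <- simulate_families(G, map, scen)
    sub <- tbl[tbl$role == "BXD_offspring" & tbl$trait == "sucking", ]
    lm_ <- tapply(sub$value, sub$line_id, mean)
    g <- G[names(lm_), 1]
    within[k] <- length(unique(g)) > 1 && abs(cor(lm_, g)) < 0.3
  }
  # null r has t-transform distribution with df = 30; compute P(|r| < 0.3)
  tcrit <- 0.3 * sqrt(30) / sqrt(1 - 0.3^2)
  p_in <- 1 - 2 * pt(tcrit, df = 30, lower.tail = FALSE)
  expect_lt(abs(mean(within) - p_in), 0.06)
})

test_that("scenario validation rejects impossible effect targets", {
  expect_error(sim_scenario(qtl_effects = data.frame(
    marker = "m1_000", role = "mother", trait = "suckling", day = 6,
    effect_class = "direct", effect = 1)), "direct effects")
  expect_error(sim_scenario(qtl_effects = data.frame(
    marker = "m1_000", role = "BXD_offspring", trait = "sucking", day = 6,
    effect_class = "indirect", effect = 1)), "indirect effects")
  expect_error(sim_scenario(line_env_sd = -1), "non-negative")
  scen <- sim_scenario(qtl_effects = data.frame(
    marker = "nope", role = "BXD_offspring", trait = "sucking", day = 6,
    effect_class = "direct", effect = 1))
  expect_error(igemap:::validate_scenario(scen, default_map()),
               "absent from the map")
})

test_that("fixtures round-trip and are byte-identical across runs", {
  map <- tiny_map(c(0, 10, 25))
  qtl <- data.frame(marker = map$marker[2], role = "BXD_offspring",
                    trait = "sucking", day = 6, effect_class = "direct",
                    effect = 1)
  scen <- sim_scenario(n_lines = 10, replicates_per_line = 2, days = 6,
                       qtl_effects = qtl, seed = 31)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- generate_fixture(scen, d1, map)
  p2 <- generate_fixture(scen, d2, map)

  rt <- read_geno(p1$geno)
  expect_identical(rt$geno, simulate_ri_genotypes(map, 10, seed = 31))
  expect_equal(as.data.frame(rt$map), as.data.frame(map))
  tbl <- read_pheno(p1$pheno)
  expect_equal(tbl, simulate_families(rt$geno, map, scen), ignore_attr = TRUE)

  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))

  truth <- jsonlite::read_json(p1$truth, simplifyVector = TRUE)
  expect_equal(nrow(truth), nrow(scen$qtl_effects))

  scen0 <- sim_scenario(n_lines = 10, days = 6, qtl_effects = data.frame(),
                        seed = 31)
  p0 <- generate_fixture(scen0, withr::local_tempdir(), map)
  expect_length(jsonlite::read_json(p0$truth), 0)
})
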