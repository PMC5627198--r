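test_that("LRS to LOD conversion uses the GeneNetwork divisor", {
  expect_equal(lrs_to_lod(0), 0)
  expect_equal(round(lrs_to_lod(19.517), 3), 4.234)
  expect_equal(round(lrs_to_lod(23.847), 3), 5.173)
  expect_equal(lrs_to_lod(4.61, divisor = "exact"), 4.61 / (2 * log(10)))
  expect_error(lrs_to_lod(-1), "non-negative")
})

test_that("conditional genotype probabilities match the chain enumeration", {
  map <- tiny_map(c(0, 10, 20))
  G <- matrix(c(1L, 0L, 1L), 1, 3, dimnames = list("L1", map$marker))

  # at a typed marker the call itself is returned
  expect_equal(genotype_prob(G, map, "L1", "1", 0), 1)
  expect_equal(genotype_prob(G, map, "L1", "1", 10), 0)

  # midpoint between discordant flanks: symmetry gives 1/2
  expect_equal(genotype_prob(G, map, "L1", "1", 5), 0.5)
  expect_equal(genotype_prob(G, map, "L1", "1", 15), 0.5)

  # concordant flanks at 5 cM each side vs exhaustive enumeration
  Gbb <- matrix(c(0L, 0L), 1, 2,
                dimnames = list("L1", tiny_map(c(0, 10))$marker))
  got <- genotype_prob(Gbb, tiny_map(c(0, 10)), "L1", "1", 5)
  expect_equal(got, genotype_prob_oracle(0, 0, 5, 5), tolerance = 1e-12)

  # asymmetric distances and mixed flanks, against the same oracle
  for (gl in 0:1) for (gr in 0:1) {
    Gx <- matrix(c(gl, gr), 1, 2,
                 dimnames = list("L1", tiny_map(c(0, 25))$marker))
    expect_equal(genotype_prob(Gx, tiny_map(c(0, 25)), "L1", "1", 7),
                 genotype_prob_oracle(gl, gr, 7, 18), tolerance = 1e-12)
  }

  # one informative flank only
  Gna <- matrix(c(1L, NA), 1, 2,
                dimnames = list("L1", tiny_map(c(0, 10))$marker))
  R <- expand_rf(haldane_rf(8))
  expect_equal(genotype_prob(Gna, tiny_map(c(0, 10)), "L1", "1", 8), 1 - R)

  # fully untyped chromosome: missing
  Gua <- matrix(NA_integer_, 1, 2,
                dimnames = list("L1", tiny_map(c(0, 10))$marker))
  expect_true(is.na(genotype_prob(Gua, tiny_map(c(0, 10)), "L1", "1", 5)))
})

test_that("marker LRS equals the independent regression oracle", {
  map <- default_map()
  for (k in 1:20) {
    G <- simulate_ri_genotypes(map, 32, seed = 40 + k)
    y <- withr::with_seed(90 + k, setNames(rnorm(32), rownames(G)))
    sr <- qtl_scan(y, G, map)
    idx <- withr::with_seed(k, sample(nrow(map), 10))
    for (j in idx) {
      x <- G[names(y), map$marker[j]]
      if (length(unique(x)) < 2) next
      expect_equal(sr$grid$lrs[match(map$marker[j], sr$grid$marker)],
                   lrs_oracle(y, x), tolerance = 1e-8)
    }
  }
})

test_that("the LRS profile is invariant to affine transforms and relabeling", {
  map <- default_map()
  G <- simulate_ri_genotypes(map, 32, seed = 77)
  y <- withr::with_seed(78, setNames(rnorm(32), rownames(G)))
  s1 <- qtl_scan(y, G, map)
  s2 <- qtl_scan(5 * y + 2, G, map)
  expect_equal(s1$grid$lrs, s2$grid$lrs, tolerance = 1e-10)

  relab <- withr::with_seed(79, sample(rownames(G)))
  y3 <- setNames(y[relab], paste0("Z", seq_along(relab)))
  G3 <- G[relab, ]; rownames(G3) <- paste0("Z", seq_along(relab))
  s3 <- qtl_scan(y3, G3, map)
  expect_equal(s1$grid$lrs, s3$grid$lrs, tolerance = 1e-10)

  expect_warning(s0 <- qtl_scan(setNames(rep(1, 32), rownames(G)), G, map),
                 "zero phenotypic variance")
  expect_true(all(s0$grid$lrs == 0))
})

test_that("permutation nulls are seeded, monotone, and handle extremes", {
  map <- tiny_map(c(0, 20, 40, 60))
  G <- simulate_ri_genotypes(map, 20, seed = 5)
  y <- withr::with_seed(6, setNames(rnorm(20), rownames(G)))
  p1 <- permutation_null(y, G, map, n_perm = 150, seed = 42)
  p2 <- permutation_null(y, G, map, n_perm = 150, seed = 42)
  expect_identical(p1$null_max, p2$null_max)
  expect_length(p1$null_max, 150)
  expect_equal(p1$threshold, unname(quantile(p1$null_max, 0.95)))

  # observed below every permutation maximum: add-one p at its ceiling
  expect_equal(genomewide_p(p1, -1), 1)
  expect_equal(genomewide_p(p1, -1, method = "raw"), 1)
  big <- max(p1$null_max) + 1
  expect_equal(genomewide_p(p1, big), 1 / 151)
  expect_equal(genomewide_p(p1, big, method = "raw"), 0)
  # p is non-increasing in the observed statistic
  obs <- seq(0, big, length.out = 50)
  ps <- vapply(obs, function(o) genomewide_p(p1, o), numeric(1))
  expect_true(all(diff(ps) <= 0))

  expect_warning(permutation_null(y, G, map, n_perm = 50, seed = 1),
                 "fewer than 100")

  # missing genotypes route through the per-position loop; still seeded
  Gna <- G; Gna[1, 2] <- NA
  pn_a <- permutation_null(y, Gna, map, n_perm = 120, seed = 9)
  pn_b <- permutation_null(y, Gna, map, n_perm = 120, seed = 9)
  expect_identical(pn_a$null_max, pn_b$null_max)
  # with one cell masked the null maxima stay close to the complete-data path
  pn_fast <- permutation_null(y, G, map, n_perm = 120, seed = 9)
  expect_equal(median(pn_a$null_max), median(pn_fast$null_max),
               tolerance = 0.25)
})

test_that("LOD-drop support intervals walk out to the last point within drop", {
  mk_sr <- function(lod, Mb = seq_along(lod)) {
    grid <- data.frame(chr = "1", cM = Mb, Mb = Mb, lod = lod)
    pk <- which.max(lod)
    list(grid = grid, peak_chr = "1", peak_cM = grid$cM[pk],
         max_lod = max(lod))
  }
  expect_equal(lod_drop_interval(mk_sr(c(1, 3.6, 5, 3.6, 1))), c(2, 4))
  expect_equal(lod_drop_interval(mk_sr(c(1, 3.4, 5, 3.4, 1))), c(3, 3))
  # flat profile spans the chromosome
  expect_equal(lod_drop_interval(mk_sr(rep(2, 6))), c(1, 6))
  # monotone decline from the first point: CI starts at the chromosome end
  expect_equal(lod_drop_interval(mk_sr(c(5, 4, 3.4, 1, 0.5))), c(1, 2))
})

test_that("point-wise marker tests match the F-distribution oracle", {
  # equal group means with identical values: F = 0, p = 1
  y <- setNames(c(1, 1, 2, 2), paste0("L", 1:4))
  calls <- setNames(c(0, 1, 0, 1), names(y))
  res <- pointwise_p(y, calls)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  # perfect separation at n = 30 is overwhelming evidence
  y2 <- setNames(c(rep(0, 15), rep(1, 15)), paste0("L", 1:30))
  calls2 <- setNames(c(rep(0, 15), rep(1, 15)), names(y2))
  expect_lt(pointwise_p(y2, calls2)$p, 1e-6)

  # 100 random instances against anova on lm
  for (k in 1:100) {
    n <- withr::with_seed(k, sample(10:40, 1))
    yk <- withr::with_seed(200 + k, setNames(rnorm(n), paste0("L", 1:n)))
    ck <- withr::with_seed(300 + k,
                           setNames(rbinom(n, 1, 0.5), names(yk)))
    if (length(unique(ck)) < 2) next
    res <- pointwise_p(yk, ck)
    oracle <- anova(lm(yk ~ ck))
    expect_equal(res$p, oracle[["Pr(>F)"]][1], tolerance = 1e-10)
    expect_lt(abs(res$F - oracle[["F value"]][1]) / (1 + oracle[["F value"]][1]),
              1e-10)
  }

  expect_warning(res0 <- pointwise_p(y, setNames(rep(1, 4), names(y))),
                 "monomorphic")
  expect_true(is.na(res0$p))
})
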