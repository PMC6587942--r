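test_that("window_pi matches hand values and the all-pairs oracle", {
  ## two haplotypes differing at exactly one SNP, 100 bp window
  m <- mk_geno(matrix(c(0L, 1L), 1, 2), pos = 50L)
  expect_equal(window_pi(m, c("s01", "s02"), "chr1", 1, 100), 0.01)
  ## identical haplotypes
  m2 <- mk_geno(matrix(c(1L, 1L), 1, 2), pos = 50L)
  expect_equal(window_pi(m2, c("s01", "s02"), "chr1", 1, 100), 0)
  ## arbitrary 4-haplotype, 3-SNP window vs brute force
  set.seed(99)
  for (rep in 1:20) {
    al <- matrix(sample(c(0L, 1L, -1L), 12, replace = TRUE,
                        prob = c(0.4, 0.4, 0.2)), 3, 4)
    m3 <- mk_geno(al, pos = c(10L, 20L, 30L))
    expect_equal(window_pi(m3, colnames(al) <- sprintf("s%02d", 1:4),
                           "chr1", 1, 50),
                 oracle_window_pi(al, 50), tolerance = 1e-12)
  }
})

test_that("fst follows its defining identity", {
  expect_equal(fst(0.2, 0.1), 0.5)
  expect_equal(fst(0.3, 0.3), 0)
  expect_true(is.na(fst(0, 0)))
  ## two oppositely fixed groups: within = 0, fst = 1 (brute force)
  alR <- matrix(0L, 5, 4); alS <- matrix(1L, 5, 4)
  m <- mk_geno(cbind(alR, alS), pos = (1:5) * 10L)
  piR <- window_pi(m, sprintf("s%02d", 1:4), "chr1", 1, 100)
  piS <- window_pi(m, sprintf("s%02d", 5:8), "chr1", 1, 100)
  g <- group_spec("t", sprintf("s%02d", 1:4), sprintf("s%02d", 5:8))
  st <- sweep_scan(m, g, win_size = 100, step = 100)
  expect_equal(piR, 0); expect_equal(piS, 0)
  expect_equal(st$fst[1], 1)
})

test_that("ln_ratio handles degenerate diversities as flags", {
  expect_equal(ln_ratio(0.02, 0.02), 0)
  expect_equal(ln_ratio(0.01, 0.02), log(0.5))
  expect_true(is.na(ln_ratio(0.01, 0)))
  expect_true(is.na(ln_ratio(0, 0.01)))
})

test_that("windows tile chromosomes at the configured step", {
  al <- matrix(rep(c(0L, 1L), 10), 2, 10, byrow = TRUE)
  m <- mk_geno(al, pos = c(5000L, 995000L))
  g <- group_spec("t", sprintf("s%02d", 1:5), sprintf("s%02d", 6:10))
  st <- sweep_scan(m, g, win_size = 1e5, step = 1e4,
                   chrom_len = c(chr1 = 1e6))
  expect_equal(nrow(st), 91)
  expect_equal(st$win_start, seq(1, 900001, by = 1e4))
  expect_equal(st$win_end, st$win_start + 1e5 - 1)
})

test_that("identical group alleles never show positive differentiation", {
  ## with the unbiased within-group estimator (pairs of distinct
  ## haplotypes), duplicating one group gives fst = 1 - n/(n-1) exactly
  set.seed(12)
  half <- matrix(sample(0:1, 40, replace = TRUE), 4, 10)
  m <- mk_geno(cbind(half, half), pos = (1:4) * 1000L,
               ids = sprintf("s%02d", 1:20))
  g <- group_spec("t", sprintf("s%02d", 1:10), sprintf("s%02d", 11:20))
  st <- sweep_scan(m, g, win_size = 2000, step = 1000)
  f <- st$fst[!is.na(st$fst)]
  expect_true(all(abs(f - (1 - 10 / 9)) < 1e-12))
})

test_that("scan is invariant to sample order within groups", {
  sim <- simulate_panel(sim_config(seed = 41, n_chrom = 1))
  g <- sim$groups$tolerance
  g_shuf <- group_spec(g$trait, rev(g$tolerant), sample(g$sensitive))
  st1 <- sweep_scan(sim$geno, g)
  st2 <- sweep_scan(sim$geno, g_shuf)
  expect_equal(st1$fst, st2$fst)
  expect_equal(st1$ln_ratio, st2$ln_ratio)
})

test_that("group-label permutation gives mean fst near zero", {
  sim <- simulate_panel(sim_config(seed = 43, n_chrom = 1,
                                   sweep_region = NULL))
  ids <- c(sim$groups$tolerance$tolerant, sim$groups$tolerance$sensitive)
  set.seed(200)
  means <- replicate(200, {
    perm <- sample(ids)
    g <- group_spec("t", perm[1:6], perm[7:12])
    st <- sweep_scan(sim$geno, g, win_size = 1e5, step = 1e5)
    mean(st$fst, na.rm = TRUE)
  })
  expect_lt(abs(mean(means)), 0.02)
})

test_that("select_candidates keeps joint-tail windows with tie and monotone rules", {
  set.seed(7)
  n <- 1000
  st <- data.frame(chrom = "c1", win_start = seq(1, by = 1000, length.out = n),
                   win_end = seq(1000, by = 1000, length.out = n),
                   n_snps = 5, pi_r = 1, pi_s = 1, pi_between = 1,
                   fst = sample(seq(0, 0.999, length.out = n)),
                   ln_ratio = sample(seq(-3, 3, length.out = n)))
  sel <- select_candidates(st, tail = 0.01)
  n_sel <- sum(vapply(strsplit(sel$window_ids, ";"), length, 0L))
  expect_lte(n_sel, 10)
  for (w in as.integer(unlist(strsplit(sel$window_ids, ";")))) {
    expect_gte(st$fst[w], sort(st$fst, decreasing = TRUE)[10])
    expect_lte(st$ln_ratio[w], sort(st$ln_ratio)[10])
  }
  ## all-identical stats tie at the cutoff -> all selected
  st2 <- st; st2$fst <- 0.5; st2$ln_ratio <- -1
  sel2 <- select_candidates(st2, tail = 0.01)
  expect_equal(sum(vapply(strsplit(sel2$window_ids, ";"), length, 0L)), n)
  ## raising the tail never drops selected windows
  w1 <- unlist(strsplit(select_candidates(st, 0.01)$window_ids, ";"))
  w2 <- unlist(strsplit(select_candidates(st, 0.05)$window_ids, ";"))
  expect_true(all(w1 %in% w2))
})

test_that("select_candidates merges overlapping windows into regions", {
  st <- data.frame(chrom = "c1",
                   win_start = c(1, 101, 201, 901, 2001),
                   win_end = c(200, 300, 400, 1100, 2200),
                   n_snps = 5, pi_r = 1, pi_s = 1, pi_between = 1,
                   fst = c(0.9, 0.95, 0.92, 0.91, 0.1),
                   ln_ratio = c(-2, -2.5, -2.2, -2.1, 1))
  sel <- select_candidates(st, tail = 0.8)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$start, c(1, 901))
  expect_equal(sel$end, c(400, 1100))
  expect_equal(sel$n_windows, c(3L, 1L))
  expect_equal(sel$peak_fst[1], 0.95)
})
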