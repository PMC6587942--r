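ped8 <- pedigree_spec("P1", "P2", "F",
                      c("C1", "C2", "C3", "C4", "C5"))

haps8 <- function(p1, p2, f, prog) {
  setNames(c(p1, p2, f, rep(prog, length.out = 5)),
           c("P1", "P2", "F", paste0("C", 1:5)))
}

test_that("block_haplotype_equal compares strings with the missing-data rule", {
  b <- mk_block(haps8("0110", "1001", "0110", "0110"))
  expect_true(block_haplotype_equal(b, "P1", "F"))
  expect_false(block_haplotype_equal(b, "P1", "P2"))
  b2 <- mk_block(c(haps8("0110", "0111", "0110", "0110")))
  expect_false(block_haplotype_equal(b2, "P1", "P2"))
  b3 <- mk_block(replace(haps8("0110", "1001", "0110", "0110"), "P1",
                         NA_character_))
  expect_false(block_haplotype_equal(b3, "P1", "F"))
  expect_error(block_haplotype_equal(b, "nope", "F"), class = "hb_invalid")
})

test_that("classification follows the priority rules on constructed blocks", {
  blocks <- structure(list(
    mk_block(haps8("010", "010", "010", "010"), "fs"),
    mk_block(haps8("0110", "1001", "0110", "0110"), "pa"),
    mk_block(haps8("1001", "0110", "0110", "0110"), "pb"),
    mk_block(haps8("0000", "1111", "0011", "0011"), "rec"),
    mk_block(haps8("0110", "1001", "0110", "1001"), "oth_prog"),
    mk_block(replace(haps8("0110", "1001", "0110", "0110"), "C3",
                     NA_character_), "oth_na")),
    class = "haplotype_blocks")
  cl <- classify_blocks(blocks, ped8)
  expect_equal(cl$category,
               c("family_shared", "parentA_inherited", "parentB_inherited",
                 "recombined", "other", "other"))
  expect_equal(cl$breakpoints[4], "2")
  expect_match(cl$reason[5], "progeny")
  expect_match(cl$reason[6], "missing")
})

test_that("recombined blocks report minimal, leftmost breakpoints", {
  ## f = A on [1..2], B on [3..6]; also splittable at 1 but 2 is the
  ## maximal-first-segment minimal solution; both have 1 breakpoint, and
  ## the leftmost valid split is after SNP 1
  b <- mk_block(haps8("110111", "000111", "110111", "110111"))
  ## focal equals parent A outright -> inherited, not recombined
  expect_equal(classify_blocks(structure(list(b),
                                         class = "haplotype_blocks"),
                               ped8)$category, "parentA_inherited")
  b2 <- mk_block(haps8("111000", "000111", "111111", "111111"))
  cl <- classify_blocks(structure(list(b2), class = "haplotype_blocks"),
                        ped8)
  expect_equal(cl$category, "recombined")
  expect_equal(cl$breakpoints, "3")
  ## two breakpoints needed: A-B-A mosaic
  b3 <- mk_block(haps8("000000", "111111", "001100", "001100"))
  cl3 <- classify_blocks(structure(list(b3), class = "haplotype_blocks"),
                         ped8)
  expect_equal(cl3$category, "recombined")
  expect_equal(cl3$breakpoints, "2;4")
})

test_that("classification agrees with the exhaustive oracle on random strings", {
  set.seed(77)
  for (rep in 1:200) {
    L <- sample(2:6, 1)
    rand <- function() paste(sample(0:1, L, replace = TRUE), collapse = "")
    h <- haps8(rand(), rand(),
               f <- rand(),
               if (stats::runif(1) < 0.8) f else rand())
    b <- structure(list(mk_block(h)), class = "haplotype_blocks")
    expect_equal(classify_blocks(b, ped8)$category,
                 oracle_classify(h, ped8),
                 info = paste(h, collapse = " "))
  }
})

test_that("classification is invariant to progeny order", {
  sim <- simulate_panel(sim_config(seed = 51, n_chrom = 1))
  blocks <- blocks_from_intervals(sim$geno, sim$truth$blocks)
  cl1 <- classify_blocks(blocks, sim$pedigree)
  ped_rev <- pedigree_spec(sim$pedigree$parentA, sim$pedigree$parentB,
                           sim$pedigree$focal, rev(sim$pedigree$progeny))
  cl2 <- classify_blocks(blocks, ped_rev)
  expect_equal(cl1$category, cl2$category)
})

test_that("family_report reproduces printed-accounting arithmetic and flags", {
  r <- family_report(c(family_shared = 23752), total_blocks = 58116)
  expect_equal(r$pct[["family_shared"]], 40.87)
  r2 <- family_report(c(family_shared = 23752, parentA_inherited = 1003,
                        parentB_inherited = 3420))
  expect_equal(r2$pct[["parentA_inherited"]], 4.22)
  expect_equal(r2$pct[["parentB_inherited"]], 14.40)
  r3 <- family_report(c(other = 0), total_blocks = 0)
  expect_true(all(is.na(r3$pct)))
  ## percentages recompute exactly from integer counts
  set.seed(5)
  for (rep in 1:20) {
    cnt <- setNames(sample(0:500, 5, replace = TRUE),
                    c("family_shared", "parentA_inherited",
                      "parentB_inherited", "recombined", "other"))
    r <- family_report(cnt)
    expect_equal(r$pct[["family_shared"]],
                 round_half_up(100 * cnt[["family_shared"]] / sum(cnt), 2))
    if (cnt[["family_shared"]] > 0)
      expect_equal(r$pct[["parentA_inherited"]],
                   round_half_up(100 * cnt[["parentA_inherited"]] /
                                 cnt[["family_shared"]], 2))
  }
})

test_that("subgenome_tally splits counts by the At/Dt convention", {
  df <- data.frame(chrom = rep("A03", 10), start = 1:10, end = 2:11,
                   block_id = letters[1:10])
  t1 <- subgenome_tally(df)
  expect_equal(t1$pct, c(100, 0))
  df2 <- data.frame(chrom = c(rep("A01", 3), rep("D05", 7)))
  t2 <- subgenome_tally(df2)
  expect_equal(t2$n_blocks, c(3L, 7L))
  expect_equal(t2$pct[t2$subgenome == "Dt"], 70.00)
  expect_error(subgenome_tally(data.frame(chrom = "chrX")),
               class = "hb_invalid")
})

test_that("categories are mutually exclusive and exhaustive on simulations", {
  sim <- simulate_panel(sim_config(seed = 52))
  blocks <- blocks_from_intervals(sim$geno, sim$truth$blocks)
  cl <- classify_blocks(blocks, sim$pedigree)
  expect_equal(nrow(cl), length(blocks))
  r <- family_report(cl)
  expect_equal(sum(r$counts), length(blocks))
})
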