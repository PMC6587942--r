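test_that("read_vcf transcribes biallelic homozygous genotypes directly", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    "A01\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t1/1\t0/0\t1/1",
    "A01\t200\t.\tC\tG\t.\tPASS\t.\tGT\t1/1\t1/1\t0/0\t0/0",
    "A01\t300\t.\tG\tA\t.\tPASS\t.\tGT\t./.\t0/0\t1/1\t1/1",
    "A01\t400\t.\tT\tC\t.\tPASS\t.\tGT\t0/1\t0/0\t1/1\t1/1",
    "A01\t500\t.\tT\tG\t.\tPASS\t.\tGT\t0/0\t0/0\t1/1\t1/1"),
    vcf)
  m <- read_vcf(vcf, maf_min = 0, max_missing = 1)
  expect_equal(n_sites(m), 5)
  expect_equal(m$sample_ids, c("s1", "s2", "s3", "s4"))
  expect_equal(unname(m$alleles[1, ]), c(0L, 1L, 0L, 1L))
  expect_equal(unname(m$alleles[3, ]), c(-1L, 0L, 1L, 1L))  # ./. missing
  expect_equal(unname(m$alleles[4, ]), c(-1L, 0L, 1L, 1L))  # het -> missing
  expect_equal(m$pos, c(100L, 200L, 300L, 400L, 500L))
})

test_that("MAF and missingness filters drop the right sites", {
  ## one rare site: alt frequency 1/20 = 0.05 passes maf_min = 0.05,
  ## 0/20 and a 0.02-style rare site (0 alt of 20 after rounding) do not
  al <- matrix(0L, 3, 20)
  al[1, 1:10] <- 1L          # maf 0.5
  al[2, 1] <- 1L             # maf 0.05 (boundary, kept)
  ## site 3 stays monomorphic: maf 0 (dropped)
  m <- mk_geno(al)
  kept <- filter_sites(m, maf_min = 0.05, max_missing = 0.2)
  expect_equal(n_sites(kept), 2)
  ## alt frequency 0.02 in a 50-sample panel is below maf_min = 0.05
  al2 <- rbind(matrix(rep(c(rep(1L, 25), rep(0L, 25)), 2), nrow = 2,
                      byrow = TRUE),
               c(1L, rep(0L, 49)))
  m2 <- mk_geno(al2)
  kept2 <- filter_sites(m2, maf_min = 0.05, max_missing = 0.2)
  expect_equal(n_sites(kept2), 2)
  ## filtering is monotone in maf_min
  sim <- simulate_panel(sim_config(seed = 11, n_chrom = 1))
  counts <- vapply(c(0, 0.05, 0.1, 0.2, 0.3),
                   function(f) n_sites(filter_sites(sim$geno, maf_min = f,
                                                    max_missing = 1)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("write_vcf/read_vcf round-trips a simulated panel exactly", {
  sim <- simulate_panel(sim_config(seed = 7, n_chrom = 2))
  p <- tempfile(fileext = ".vcf")
  write_vcf(sim$geno, p)
  back <- read_vcf(p, maf_min = 0, max_missing = 1)
  expect_true(isTRUE(all.equal(sim$geno, back)))
})

test_that("write_vcf handles empty and minimal matrices and rejects unsorted", {
  empty <- structure(list(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          alleles = matrix(integer(0), 0, 2,
                                           dimnames = list(NULL, c("a", "b"))),
                          sample_ids = c("a", "b")),
                     class = "genotype_matrix")
  p <- tempfile(fileext = ".vcf")
  write_vcf(empty, p)
  lines <- readLines(p)
  expect_true(all(startsWith(lines[1:3], "##")))
  expect_equal(sum(!startsWith(lines, "#")), 0)

  one <- mk_geno(matrix(c(0L, 1L), 1, 2), pos = 42L)
  write_vcf(one, p)
  body <- readLines(p)
  body <- body[!startsWith(body, "#")]
  expect_length(body, 1)
  expect_equal(strsplit(body, "\t")[[1]][10:11], c("0/0", "1/1"))

  bad <- structure(list(chrom = c("c1", "c1"), pos = c(200L, 100L),
                        ref = c("A", "A"), alt = c("T", "T"),
                        alleles = matrix(0L, 2, 2,
                                         dimnames = list(NULL, c("a", "b"))),
                        sample_ids = c("a", "b")),
                   class = "genotype_matrix")
  expect_error(write_vcf(bad, p), class = "hb_unsorted")
})

test_that("genotype_matrix validates invariants", {
  expect_error(mk_geno(matrix(2L, 1, 2)), class = "hb_invalid_matrix")
  expect_error(genotype_matrix("c1", 1L, "A", "T", matrix(0L, 1, 2),
                               c("s1", "s1")), class = "hb_invalid_matrix")
  expect_error(mk_geno(matrix(0L, 2, 2), pos = c(5L, 5L)),
               class = "hb_unsorted")
})

test_that("read_gff extracts gene features and round-trips", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "A01\tsrc\tgene\t100\t500\t.\t+\t.\tID=g1",
               "A01\tsrc\tmRNA\t100\t500\t.\t+\t.\tID=g1.t1;Parent=g1",
               "A01\tsrc\tgene\t900\t1200\t.\t-\t.\tID=g2",
               "D01\tsrc\tgene\t10\t20\t.\t+\t.\tID=g3"), gff)
  g <- read_gff(gff)
  expect_equal(g$gene_id, c("g1", "g2", "g3"))
  expect_equal(g$start, c(100L, 900L, 10L))
  expect_equal(g$end, c(500L, 1200L, 20L))

  writeLines(c("##gff-version 3",
               "A01\tsrc\tmRNA\t100\t500\t.\t+\t.\tID=t1",
               "A01\tsrc\texon\t100\t200\t.\t+\t.\tID=e1"), gff)
  expect_warning(g0 <- read_gff(gff), "no gene features")
  expect_equal(nrow(g0), 0)

  sim <- simulate_panel(sim_config(seed = 3, n_chrom = 1))
  p <- tempfile(fileext = ".gff3")
  write_gff(sim$genes, p)
  back <- read_gff(p)
  expect_equal(back$gene_id, sim$genes$gene_id)
  expect_equal(back$start, sim$genes$start)
  expect_equal(back$end, sim$genes$end)
})

test_that("metadata round-trips pedigree roles and trait groups", {
  sim <- simulate_panel(sim_config(seed = 5, n_chrom = 1))
  p <- tempfile(fileext = ".tsv")
  write_metadata(sim$pedigree, sim$groups, sim$geno$sample_ids, p)
  md <- read_metadata(p)
  expect_equal(md$pedigree$parentA, sim$pedigree$parentA)
  expect_equal(md$pedigree$progeny, sim$pedigree$progeny)
  expect_equal(sort(md$groups$tolerance$tolerant),
               sort(sim$groups$tolerance$tolerant))
  expect_equal(sort(md$groups$tolerance$sensitive),
               sort(sim$groups$tolerance$sensitive))
})
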