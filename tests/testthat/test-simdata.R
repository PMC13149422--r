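test_that("reference generation packs genes, is deterministic, and errors when infeasible", {
  ref <- generate_reference(1, 100000, 10, 2000, seed = 1)
  expect_equal(nchar(ref$contigs[[1]]$sequence), 100000)
  expect_equal(nrow(ref$genes), 10)
  g <- ref$genes[order(ref$genes$start), ]
  expect_true(all(g$start <= g$end))
  expect_true(all(g$end <= 100000))
  expect_true(all(g$start[-1] > g$end[-nrow(g)])) # non-overlapping
  # byte-identical outputs for the same seed
  d1 <- tempfile(); d2 <- tempfile()
  write_reference(ref, paste0(d1, ".fa"), paste0(d1, ".gff3"))
  write_reference(generate_reference(1, 100000, 10, 2000, seed = 1),
                  paste0(d2, ".fa"), paste0(d2, ".gff3"))
  expect_identical(readLines(paste0(d1, ".fa")), readLines(paste0(d2, ".fa")))
  expect_identical(readLines(paste0(d1, ".gff3")),
                   readLines(paste0(d2, ".gff3")))
  # 2 x 600 bp of genes cannot fit in 1000 bp
  expect_error(generate_reference(1, 1000, 2, 600, seed = 1), "infeasible")
})

test_that("population carriage follows the planted frequencies", {
  ref <- generate_reference(1, 5000, 2, 500, seed = 2)
  locus <- function(freq) data.frame(contig = "contig01", pos = 2500L,
                                     ins_len = 31L, freq = freq, beta = 1)
  # degenerate frequency ~ 1: all accessions carry
  pop <- simulate_population(ref, 25, locus(1 - 1e-12), n_neutral = 0,
                             snp_rate = 0, seed = 3)
  expect_true(all(pop$truth == 1L))
  # frequency 0.5 at n = 200: count inside the binomial 99.9% interval
  pop2 <- simulate_population(ref, 200, locus(0.5), n_neutral = 0,
                              snp_rate = 0, seed = 4)
  ci <- qbinom(c(5e-4, 1 - 5e-4), 200, 0.5)
  expect_gte(sum(pop2$truth), ci[1])
  expect_lte(sum(pop2$truth), ci[2])
  # no variation sources -> identical to the reference
  pop3 <- simulate_population(ref, 3,
                              locus(0.5)[0, , drop = FALSE], n_neutral = 0,
                              snp_rate = 0, seed = 5)
  for (h in pop3$haplotypes)
    expect_identical(h[[1]][["contig01"]], ref$contigs[[1]]$sequence)
  # overlapping insertions at one position are rejected
  two <- rbind(locus(0.5), locus(0.5))
  expect_error(simulate_population(ref, 3, two, n_neutral = 0,
                                   snp_rate = 0, seed = 6), "overlapping")
})

test_that("GBS reads have the right count, content, and error rate", {
  ref <- generate_reference(1, 100000, 2, 500, seed = 7)
  hap <- c(contig01 = ref$contigs[[1]]$sequence)
  reads <- simulate_gbs_reads(hap, read_length = 100, coverage = 30,
                              error = 0, seed = 8)
  # count formula: coverage x L / read_length
  expect_equal(length(reads), 30000)
  # zero error: every read is an exact substring, forward or reverse
  some <- reads[seq(1, 30000, by = 1000)]
  found <- vapply(some, function(r)
    grepl(r, hap, fixed = TRUE) || grepl(revcomp(r), hap, fixed = TRUE),
    logical(1))
  expect_true(all(found))
  # determinism
  expect_identical(reads,
                   simulate_gbs_reads(hap, 100, 30, 0, seed = 8))
  # error rate recovers within binomial tolerance (reads at error 0 as truth)
  r0 <- simulate_gbs_reads(hap, 100, 2, 0, seed = 9)
  r1 <- simulate_gbs_reads(hap, 100, 2, 0.01, seed = 9)
  mism <- sum(mapply(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), r0, r1))
  total <- sum(nchar(r0))
  ci <- qbinom(c(5e-4, 1 - 5e-4), total, 0.01)
  expect_gte(mism, ci[1])
  expect_lte(mism, ci[2])
  expect_error(simulate_gbs_reads(hap, nchar(hap) + 1, 1, 0, seed = 1),
               "read_length")
})

test_that("FASTQ output is deterministic and well-formed", {
  reads <- c("ACGTACGTAC", "TTTTGGGGCC")
  p1 <- tempfile(fileext = ".fastq"); p2 <- tempfile(fileext = ".fastq")
  write_fastq(reads, p1); write_fastq(reads, p2)
  l <- readLines(p1)
  expect_identical(l, readLines(p2))
  expect_equal(length(l), 8)
  expect_identical(l[2], reads[1])
  expect_identical(l[3], "+")
  expect_identical(l[4], strrep("I", 10))
  expect_identical(l[6], reads[2])
})

test_that("phenotype simulation mirrors the association model", {
  truth <- matrix(rbinom(400, 1, 0.4), ncol = 1,
                  dimnames = list(sprintf("a%03d", 1:400), "locus001"))
  # noise-free: carrier / non-carrier difference is exactly beta
  ph <- simulate_phenotypes(truth, betas = 2, sigma_g2 = 0, sigma_e2 = 0,
                            treatment_effect = 0, n_replicates = 1, seed = 1)
  m <- as.vector(tapply(ph$value, ph$accession_id, mean))
  expect_equal(m[truth[, 1] == 1] - mean(m[truth[, 1] == 0]),
               rep(2, sum(truth)), tolerance = 1e-12)
  # variance decomposition of accession means at sigma_g2 = 1, sigma_e2 = 1
  ph2 <- simulate_phenotypes(truth, betas = 0, K = diag(400), sigma_g2 = 1,
                             sigma_e2 = 1, treatment_effect = 0,
                             n_replicates = 3, seed = 2)
  hp <- ph2[ph2$treatment == "HP", ]
  v <- var(tapply(hp$value, hp$accession_id, mean))
  expect_equal(v, 1 + 1 / 3, tolerance = 0.2)
  # treatment effect shows up as the LP - HP mean difference
  ph3 <- simulate_phenotypes(truth, betas = 0, sigma_g2 = 0, sigma_e2 = 0.5,
                             treatment_effect = -1, n_replicates = 3,
                             seed = 3)
  expect_equal(mean(ph3$value[ph3$treatment == "LP"]) -
                 mean(ph3$value[ph3$treatment == "HP"]), -1,
               tolerance = 0.05)
  # non-PSD kinship is rejected
  bad <- diag(400); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(simulate_phenotypes(truth, 0, K = bad, sigma_g2 = 1,
                                   seed = 1), "positive semi-definite")
})

test_that("rendered masks carry analytic truth", {
  # one vertical segment spanning 600 px at 600 dpi is exactly 25.4 mm
  seg <- data.frame(x0 = 50, y0 = 20, x1 = 50, y1 = 620, width = 5)
  rm1 <- render_root_mask(seg, 100, 680, dpi = 600)
  expect_equal(rm1$truth$length_mm, 25.4)
  # foreground pixel count within 2% of the analytic capsule area
  area_px <- rm1$truth$area_mm2 / px_to_mm(600)^2
  expect_lt(abs(sum(rm1$mask) - area_px) / area_px, 0.02)
  # collinear touching segments: truth length is additive
  seg2 <- data.frame(x0 = c(50, 50), y0 = c(20, 320), x1 = c(50, 50),
                     y1 = c(320, 620), width = 5)
  rm2 <- render_root_mask(seg2, 100, 680, dpi = 600)
  expect_equal(rm2$truth$length_mm, rm1$truth$length_mm)
  # L-shape: hull truth equals the right-triangle closed form plus the
  # stroke offset (capsule Minkowski terms)
  w <- 6
  segL <- data.frame(x0 = c(20, 20), y0 = c(20, 20), x1 = c(320, 20),
                     y1 = c(20, 320), width = w)
  rmL <- render_root_mask(segL, 400, 400, dpi = 600)
  tri <- 300 * 300 / 2
  r <- w / 2
  per <- 300 + 300 + sqrt(2) * 300
  closed <- (tri + per * r + pi * r^2) * px_to_mm(600)^2
  expect_equal(rmL$truth$hull_area_mm2, closed, tolerance = 0.005)
  expect_error(render_root_mask(data.frame(x0 = 1, y0 = 1, x1 = 2, y1 = 2,
                                           width = 0), 10, 10), "zero-width")
})

test_that("pot-experiment tables are reproducible and well-formed", {
  t1 <- simulate_pot_experiment(n_accessions = 20, seed = 5)
  t2 <- simulate_pot_experiment(n_accessions = 20, seed = 5)
  expect_identical(t1, t2)
  expect_setequal(unique(t1$treatment), c("HP", "LP"))
  expect_true(all(t1$value > 0))
  key <- with(t1, paste(accession_id, treatment, replicate, trait))
  expect_false(anyDuplicated(key) > 0)
})
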