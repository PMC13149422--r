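test_that("canonicalization is idempotent and strand-invariant", {
  set.seed(42)
  kmers <- vapply(1:2000, function(i)
    paste(sample(c("A", "C", "G", "T"), 31, replace = TRUE), collapse = ""),
    character(1))
  canon <- canonicalize(kmers)
  expect_identical(canonicalize(revcomp(kmers)), canon)
  expect_identical(canonicalize(canon), canon)
  expect_true(all(canon <= kmers))
})

test_that("canonicalization matches a pairwise-min oracle over all 5-mers", {
  bases <- c("A", "C", "G", "T")
  all5 <- do.call(paste0, expand.grid(bases, bases, bases, bases, bases))
  expect_identical(canonicalize(all5, k = 5),
                   pmin(all5, oracle_revcomp(all5)))
})

test_that("ambiguous bases are an error in canonicalize", {
  expect_error(canonicalize("ACGTN", k = 5), "ambiguous")
  expect_error(canonicalize("ACGT", k = 5), "length")
})

test_that("per-sample count floor is applied at the canonical total", {
  read <- "ACGTACGTACGTACGTACGTACGTACGTACG" # exactly 31 bp
  five <- count_sample_kmers(rep(read, 5), k = 31, min_count = 5)
  expect_equal(nrow(five), 1)
  expect_equal(five$count, 5)
  expect_identical(five$kmer, canonicalize(read))
  four <- count_sample_kmers(rep(read, 4), k = 31, min_count = 5)
  expect_equal(nrow(four), 0)
  # empty input is an empty map, not an error
  expect_equal(nrow(count_sample_kmers(character(0))), 0)
  # reads shorter than k are skipped
  expect_equal(nrow(count_sample_kmers("ACGT", k = 31, min_count = 1)), 0)
})

test_that("counts and orientation tallies match a naive dictionary oracle", {
  set.seed(9)
  src <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
  starts <- sample.int(150, 40, replace = TRUE)
  reads <- substring(src, starts, starts + sample(30:50, 40, replace = TRUE))
  flip <- runif(40) < 0.5
  reads[flip] <- revcomp(reads[flip])
  for (mc in c(1, 3, 5)) {
    got <- count_sample_kmers(reads, k = 31, min_count = mc)
    want <- oracle_count_kmers(reads, k = 31, min_count = mc)
    expect_equal(got$kmer, want$kmer)
    expect_equal(got$count, want$count)
    expect_equal(got$fwd, want$fwd)
    expect_equal(got$rev, want$rev)
  }
})

test_that("N-containing windows are skipped with a tally", {
  reads <- c(strrep("A", 40), paste0(strrep("A", 20), "N", strrep("A", 20)))
  got <- count_sample_kmers(reads, k = 31, min_count = 1)
  expect_equal(got$kmer, strrep("A", 31))
  # every window of the second read spans the N, so only the first counts
  expect_equal(got$count, 10)
  expect_gt(attr(got, "n_skipped_n"), 0)
})

test_that("strand assignment follows the aggregate majority with canonical tie-break", {
  km <- "ACGTACGTACGTACGTACGTACGTACGTACG"
  canon <- canonicalize(km)
  rc <- revcomp(canon)
  tally <- function(fwd, rev)
    data.frame(kmer = canon, count = fwd + rev, fwd = fwd, rev = rev)
  # observed only in reverse orientation across samples -> reported as revcomp
  res <- assign_strand(list(tally(0, 3), tally(1, 2)))
  expect_identical(res$oriented, rc)
  # exact tie -> canonical form
  res <- assign_strand(list(tally(2, 1), tally(1, 2)))
  expect_identical(res$oriented, canon)
  # three-sample hand-summed oracle
  a <- count_sample_kmers(rep(canon, 5), min_count = 1)
  b <- count_sample_kmers(rep(rc, 5), min_count = 1)
  c3 <- count_sample_kmers(rep(rc, 6), min_count = 1)
  res <- assign_strand(list(a, b, c3))
  expect_identical(res$oriented, rc) # 5 fwd vs 11 rev
})

test_that("presence/absence matrix construction is a deterministic union", {
  set.seed(3)
  mk <- function(n) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 31, replace = TRUE), collapse = ""),
    character(1))
  s1 <- mk(3); s2 <- mk(3)
  km <- build_pa_matrix(list(A = s1, B = s2))
  expect_equal(dim(km), c(2L, 6L))
  expect_equal(unname(rowSums(km$presence)), c(3, 3))
  # identical sets give an all-ones matrix
  km2 <- build_pa_matrix(list(A = s1, B = s1))
  expect_true(all(km2$presence == 1L))
  # column frequency is the column mean
  km3 <- build_pa_matrix(list(A = s1, B = s2, C = c(s1[1], s2[1])))
  expect_equal(km3$freq, colMeans(km3$presence))
  # row-permutation invariance up to sample order
  km4 <- build_pa_matrix(list(C = c(s1[1], s2[1]), B = s2, A = s1))
  expect_identical(km4$canonical, km3$canonical)
  expect_equal(km4$presence[c("A", "B", "C"), ], km3$presence[c("A", "B", "C"), ])
  expect_error(build_pa_matrix(list(A = s1, A = s2)), "duplicate")
})

test_that("MAF filtering drops rare and monomorphic columns and is idempotent", {
  set.seed(8)
  n <- 200
  presence <- cbind(
    single = c(1L, rep(0L, n - 1)),      # MAF 0.005 at n = 200
    all = rep(1L, n),                     # monomorphic
    none = rep(0L, n),
    common = rep(c(0L, 1L), n / 2))
  rownames(presence) <- sprintf("a%03d", seq_len(n))
  km <- phosgwas:::new_kmer_matrix(presence, colnames(presence),
                                   colnames(presence), colMeans(presence))
  f1 <- filter_maf(km, 0.01)
  expect_identical(f1$kmers, "common")
  # idempotence
  f2 <- filter_maf(f1, 0.01)
  expect_identical(f2$presence, f1$presence)
  # maf_min = 0 still drops monomorphic columns
  f0 <- filter_maf(km, 0)
  expect_identical(f0$kmers, c("single", "common"))
})

test_that("streamed matrix equals the modular path on a fixture", {
  set.seed(21)
  src <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
  mk_reads <- function(seed) {
    set.seed(seed)
    starts <- sample.int(400, 300, replace = TRUE)
    r <- substring(src, starts, starts + 99)
    flip <- runif(300) < 0.5
    r[flip] <- revcomp(r[flip])
    r
  }
  reads <- list(a = mk_reads(1), b = mk_reads(2), c = mk_reads(3))
  tallies <- lapply(reads, count_sample_kmers, k = 31, min_count = 5)
  oriented <- assign_strand(tallies)
  modular <- filter_maf(build_pa_matrix(lapply(tallies, `[[`, "kmer"),
                                        oriented = oriented), 0.01)
  fused <- kmer_matrix_stream(reads, k = 31, min_count = 5, maf_min = 0.01)
  expect_identical(fused$canonical, modular$canonical)
  expect_identical(fused$kmers, modular$kmers)
  expect_equal(unname(fused$presence), unname(modular$presence))
  expect_equal(fused$freq, unname(modular$freq))
})

test_that("diagnostic k-mers of a planted insertion recover the truth column", {
  st <- make_small_study()
  dk <- diagnostic_kmers(st$ref, st$causal$contig, st$causal$pos,
                         st$pop$loci$ins_seq[1])
  present <- intersect(dk$carrier, st$km$canonical)
  expect_gt(length(present), 50)
  for (kmv in present)
    expect_equal(unname(st$km$presence[, kmv]), unname(st$pop$truth[, 1]))
  # reference junction k-mers are carried by exactly the non-carriers
  absent <- intersect(dk$noncarrier, st$km$canonical)
  expect_gt(length(absent), 20)
  for (kmv in absent)
    expect_equal(unname(st$km$presence[, kmv]), 1L - unname(st$pop$truth[, 1]))
})

test_that("k-mer matrix round-trips through TSV", {
  st <- make_small_study(seed = 12, n_acc = 5, contig_length = 3000,
                         n_neutral = 3)
  path <- tempfile(fileext = ".tsv")
  write_kmer_matrix(st$km, path)
  back <- read_kmer_matrix(path)
  expect_identical(back$kmers, st$km$kmers)
  expect_equal(unname(back$presence), unname(st$km$presence))
})
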