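# Independent oracles used across the suite. Each is deliberately naive
# (dictionaries, all-pairs loops, closed forms) and shares no code with the
# implementation it checks.

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(s)
    paste(rev(s), collapse = ""), character(1)))
}

# naive dictionary k-mer counter with orientation tallies
oracle_count_kmers <- function(reads, k, min_count) {
  tab <- new.env(parent = emptyenv())
  for (r in reads) {
    n <- nchar(r)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      km <- substr(r, i, i + k - 1)
      if (grepl("[^ACGT]", km)) next
      rc <- oracle_revcomp(km)
      canon <- min(km, rc)
      e <- get0(canon, tab, ifnotfound = c(fwd = 0, rev = 0))
      if (km <= rc) e["fwd"] <- e["fwd"] + 1 else e["rev"] <- e["rev"] + 1
      assign(canon, e, tab)
    }
  }
  kmers <- sort(ls(tab))
  out <- do.call(rbind, lapply(kmers, function(km) {
    e <- get(km, tab)
    data.frame(kmer = km, count = e[["fwd"]] + e[["rev"]],
               fwd = e[["fwd"]], rev = e[["rev"]], stringsAsFactors = FALSE)
  }))
  out[out$count >= min_count, , drop = FALSE]
}

# all-pairs greedy overlap assembly: repeatedly merge any two sequences with
# an exact (k-1) suffix/prefix overlap (either orientation) until no merge is
# possible; returns the sorted set of orientation-normalised sequences.
oracle_assemble <- function(kmers, k) {
  norm <- function(s) pmin(s, oracle_revcomp(s))
  seqs <- unique(norm(kmers))
  repeat {
    merged <- FALSE
    for (i in seq_along(seqs)) {
      for (j in seq_along(seqs)) {
        if (i == j) next
        for (a in c(seqs[i], oracle_revcomp(seqs[i]))) {
          for (b in c(seqs[j], oracle_revcomp(seqs[j]))) {
            if (substr(a, nchar(a) - k + 2, nchar(a)) == substr(b, 1, k - 1)) {
              cand <- paste0(a, substr(b, k, nchar(b)))
              seqs <- c(seqs[-c(i, j)], norm(cand))
              merged <- TRUE
              break
            }
          }
          if (merged) break
        }
        if (merged) break
      }
      if (merged) break
    }
    if (!merged) break
  }
  sort(seqs)
}

# two-model ordinary ML fit: LRT of adding one regressor to intercept-only
oracle_ols_lrt <- function(y, x) {
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(stats::resid(stats::lm(y ~ x))^2)
  lrt <- n * log(rss0 / rss1)
  stats::pchisq(lrt, df = 1, lower.tail = FALSE)
}

# brute-force complete-linkage agglomeration; returns merge heights and the
# partition at k clusters
oracle_complete_linkage <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
  lab
}

# quadratic-loop p-distance dedup following the stated rule directly
oracle_pdist_dedup <- function(M, thr, rounds) {
  keep <- rownames(M)
  for (r in seq_len(rounds)) {
    X <- M[keep, , drop = FALSE]
    n <- nrow(X)
    if (n < 2) break
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ok <- !is.na(X[i, ]) & !is.na(X[j, ])
        if (!any(ok)) next
        sim <- 1 - mean(X[i, ok] != X[j, ok])
        if (sim >= thr) adj[i, j] <- adj[j, i] <- TRUE
      }
    }
    if (!any(adj)) break
    comp <- seq_len(n)
    repeat {
      nc <- comp
      for (i in seq_len(n)) {
        nb <- which(adj[i, ])
        if (length(nb)) nc[i] <- min(comp[c(i, nb)])
      }
      if (identical(nc, comp)) break
      comp <- nc
    }
    ids <- rownames(X)
    miss <- rowSums(is.na(X))
    ret <- unlist(lapply(split(seq_len(n), comp), function(mem) {
      ids[mem][order(miss[mem], ids[mem])][1]
    }))
    nk <- keep[keep %in% ret]
    if (identical(nk, keep)) break
    keep <- nk
  }
  keep
}

# one-locus population + reads + matrix at small scale, shared by several
# round-trip tests
make_small_study <- function(seed = 7, n_acc = 30, contig_length = 20000,
                             freq = 0.5, beta = 2, coverage = 25,
                             n_neutral = 10, snp_rate = 0) {
  gene_len <- min(1000L, contig_length %/% 8L)
  ref <- generate_reference(1, contig_length, 4, gene_len, seed = seed)
  causal <- data.frame(contig = "contig01", pos = as.integer(contig_length / 2),
                       ins_len = 31L, freq = freq, beta = beta,
                       stringsAsFactors = FALSE)
  pop <- simulate_population(ref, n_acc, causal, n_neutral = n_neutral,
                             snp_rate = snp_rate, seed = seed + 1)
  reads <- lapply(pop$haplotypes, function(h)
    simulate_gbs_reads(h[[1]], 100, coverage, 0, seed = seed + 2))
  km <- kmer_matrix_stream(reads, k = 31, min_count = 5, maf_min = 0.01)
  list(ref = ref, causal = causal, pop = pop, reads = reads, km = km)
}
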