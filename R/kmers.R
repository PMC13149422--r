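#' Reverse complement of DNA strings
#'
#' @param x character vector of A/C/G/T sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  revcomp_cpp(x)
}

#' Canonical form of a k-mer
#'
#' The canonical form of a k-mer is the lexicographically smaller of the k-mer
#' and its reverse complement, so that both strands of a locus count as one
#' marker. Only odd `k` is allowed (no self-reverse-complement palindromes).
#'
#' @param kmers character vector of k-mers over A/C/G/T, all of length `k`.
#' @param k k-mer length (odd; default 31).
#' @return character vector of canonical k-mers.
#' @examples
#' canonicalize(c("TTTTT", "ACGTA"), k = 5)
#' @export
canonicalize <- function(kmers, k = 31L) {
  stopifnot(is.character(kmers))
  canonicalize_cpp(kmers, as.integer(k))
}

#' Count canonical k-mers in one sample's reads
#'
#' Slides a window of length `k` over each read, skipping windows containing
#' ambiguous bases and reads shorter than `k`. Counts are tallied per
#' canonical k-mer together with orientation information: `fwd` counts
#' observations in the canonical orientation, `rev` observations as its
#' reverse complement. Only k-mers whose canonical total reaches the
#' per-sample floor `min_count` are retained.
#'
#' @param reads character vector of reads (FASTQ sequences).
#' @param k k-mer length (odd, <= 31).
#' @param min_count per-sample minimum canonical count (default 5).
#' @return data.frame with columns `kmer` (canonical), `count`, `fwd`, `rev`,
#'   sorted by `kmer`; attribute `n_skipped_n` tallies windows skipped for
#'   ambiguous bases.
#' @export
count_sample_kmers <- function(reads, k = 31L, min_count = 5L) {
  stopifnot(is.character(reads))
  count_kmers_cpp(reads, as.integer(k), as.integer(min_count))
}

#' Resolve k-mer strand by majority orientation across samples
#'
#' For each canonical k-mer, sums the forward (canonical-orientation) and
#' reverse observation counts across all samples and reports the orientation
#' with the larger aggregate; ties resolve to the canonical form.
#'
#' @param tallies list of per-sample tally data.frames from
#'   [count_sample_kmers()].
#' @return data.frame with columns `canonical` and `oriented`.
#' @export
assign_strand <- function(tallies) {
  stopifnot(is.list(tallies), length(tallies) >= 1)
  all <- do.call(rbind, lapply(tallies, function(t)
    data.frame(kmer = t$kmer, fwd = t$fwd, rev = t$rev,
               stringsAsFactors = FALSE)))
  fwd <- tapply(all$fwd, all$kmer, sum)
  rev <- tapply(all$rev, all$kmer, sum)
  canonical <- sort(names(fwd))
  fwd <- fwd[canonical]; rev <- rev[canonical]
  oriented <- ifelse(rev > fwd, revcomp(canonical), canonical)
  data.frame(canonical = canonical, oriented = unname(oriented),
             stringsAsFactors = FALSE)
}

new_kmer_matrix <- function(presence, kmers, canonical, freq) {
  structure(list(presence = presence, kmers = kmers, canonical = canonical,
                 samples = rownames(presence), freq = freq),
            class = "kmer_matrix")
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat(sprintf("kmer_matrix: %d samples x %d k-mers (k = %d)\n",
              nrow(x$presence), ncol(x$presence),
              if (length(x$canonical)) nchar(x$canonical[1]) else NA_integer_))
  invisible(x)
}

#' @export
dim.kmer_matrix <- function(x) dim(x$presence)

#' Build a presence/absence k-mer matrix across samples
#'
#' Takes each sample's retained k-mer set, canonicalizes, and forms the
#' samples-by-k-mers binary matrix over the union of all sets, with columns in
#' lexicographic order of the canonical k-mer (deterministic regardless of
#' sample input order). Column labels use the strand-resolved orientation when
#' `oriented` (from [assign_strand()]) is supplied, otherwise the canonical
#' form.
#'
#' @param sets named list (sample id -> character vector of k-mers).
#' @param k k-mer length.
#' @param oriented optional data.frame from [assign_strand()].
#' @return a `kmer_matrix`: list with `presence` (binary integer matrix,
#'   samples x k-mers), `kmers` (column labels), `canonical`, `samples`,
#'   `freq` (per-column presence frequency).
#' @export
build_pa_matrix <- function(sets, k = 31L, oriented = NULL) {
  stopifnot(is.list(sets), length(sets) >= 2)
  ids <- names(sets)
  if (is.null(ids) || any(!nzchar(ids))) stop("sets must be a named list")
  if (anyDuplicated(ids)) stop("duplicate sample id")
  sets <- lapply(sets, function(s) unique(canonicalize(s, k)))
  all_kmers <- sort(unique(unlist(sets, use.names = FALSE)))
  presence <- matrix(0L, nrow = length(ids), ncol = length(all_kmers),
                     dimnames = list(ids, all_kmers))
  for (i in seq_along(sets))
    presence[i, match(sets[[i]], all_kmers)] <- 1L
  labels <- all_kmers
  if (!is.null(oriented)) {
    idx <- match(all_kmers, oriented$canonical)
    hit <- !is.na(idx)
    labels[hit] <- oriented$oriented[idx[hit]]
  }
  new_kmer_matrix(presence, labels, all_kmers, colMeans(presence))
}

#' Filter a k-mer matrix by minor allele frequency
#'
#' Retains columns with `min(freq, 1 - freq) >= maf_min`. Monomorphic columns
#' (presence frequency 0 or 1) are always dropped, because a constant
#' predictor is untestable, even at `maf_min = 0`.
#'
#' @param km a `kmer_matrix`.
#' @param maf_min MAF floor in `[0, 0.5]` (default 0.01).
#' @return the filtered `kmer_matrix`, column order preserved.
#' @export
filter_maf <- function(km, maf_min = 0.01) {
  stopifnot(inherits(km, "kmer_matrix"), maf_min >= 0, maf_min <= 0.5)
  f <- km$freq
  keep <- f > 0 & f < 1 & pmin(f, 1 - f) >= maf_min
  new_kmer_matrix(km$presence[, keep, drop = FALSE], km$kmers[keep],
                  km$canonical[keep], f[keep])
}

#' Streamed k-mer matrix construction (fused fast path)
#'
#' Counts, strand-resolves, unions and MAF-filters in one pass over samples,
#' holding only one sample's reads in memory at a time. Equivalent to
#' [count_sample_kmers()] + [assign_strand()] + [build_pa_matrix()] +
#' [filter_maf()]; the dense matrix is only materialised for columns that
#' survive the MAF / monomorphism filter, which is what makes panel-scale runs
#' feasible.
#'
#' @param read_source either a named list (sample id -> character vector of
#'   reads) or a function `function(sample_id)` returning the reads; in the
#'   latter case `sample_ids` must be given.
#' @param sample_ids sample ids (required when `read_source` is a function).
#' @param k,min_count,maf_min as in the modular operations.
#' @return a `kmer_matrix`.
#' @export
kmer_matrix_stream <- function(read_source, sample_ids = NULL, k = 31L,
                               min_count = 5L, maf_min = 0.01) {
  if (is.list(read_source)) {
    sample_ids <- names(read_source)
    getter <- function(id) read_source[[id]]
  } else if (is.function(read_source)) {
    if (is.null(sample_ids)) stop("sample_ids required with a reader function")
    getter <- read_source
  } else stop("read_source must be a named list or a function")
  acc <- kacc_new(as.integer(k), as.integer(min_count))
  for (id in sample_ids) kacc_add_sample(acc, id, getter(id))
  fin <- kacc_finalize(acc, maf_min)
  presence <- fin$presence
  dimnames(presence) <- list(fin$samples, fin$canonical)
  km <- new_kmer_matrix(presence, fin$kmers, fin$canonical, fin$freq)
  attr(km, "n_total_kmers") <- fin$n_total_kmers
  attr(km, "n_skipped_n") <- fin$n_skipped_n
  km
}

#' Write / read a k-mer matrix as TSV
#'
#' The interchange format is a TSV with sample ids in the first column and
#' one column per k-mer (strand-resolved label in the header).
#'
#' @param km a `kmer_matrix`.
#' @param path output file.
#' @export
write_kmer_matrix <- function(km, path) {
  df <- data.frame(sample = km$samples, km$presence, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("sample", km$kmers)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kmer_matrix
#' @export
read_kmer_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  kmers <- names(df)[-1]
  presence <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(presence) <- "integer"
  rownames(presence) <- df$sample
  canonical <- canonicalize(kmers, k = nchar(kmers[1]))
  colnames(presence) <- canonical
  new_kmer_matrix(presence, kmers, canonical, colMeans(presence))
}
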