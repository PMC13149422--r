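#' Extend significant k-mers into fragments by exact overlap
#'
#' Significant k-mers frequently originate from the same reads and overlap in
#' sequence; merging them recovers the underlying fragment. A k-mer and its
#' reverse complement are one node; directed edges connect oriented k-mers
#' whose (k-1)-suffix equals the other's (k-1)-prefix; maximal unambiguous
#' paths (every internal junction has out-degree 1 into a node with in-degree
#' 1 — the unitig rule) are merged into fragment sequences. Ambiguous or
#' isolated k-mers become singleton fragments. Each fragment is reported in
#' its lexicographically smaller orientation and the output is sorted by
#' sequence, so the result does not depend on input order.
#'
#' @param kmers character vector of equal-length k-mers.
#' @return list of fragments, each a list with `sequence` and `member_kmers`
#'   (canonical forms, in path order) and an empty `hits` placeholder.
#' @export
extend_fragments <- function(kmers) {
  stopifnot(is.character(kmers), length(kmers) >= 1)
  k <- unique(nchar(kmers))
  if (length(k) != 1) stop("mixed k-mer lengths")
  canon <- unique(canonicalize(kmers, k))
  n <- length(canon)
  rc <- revcomp(canon)
  # oriented k-mers: index i in 1..n forward (canonical), n+i reverse
  oriented <- c(canon, rc)
  node_of <- rep(seq_len(n), 2)
  pref <- substr(oriented, 1L, k - 1L)
  suff <- substr(oriented, 2L, k)
  # out-edges: oriented i -> oriented j iff suff[i] == pref[j], different node
  by_pref <- split(seq_along(oriented), pref)
  succs <- lapply(seq_along(oriented), function(i) {
    js <- by_pref[[suff[i]]]
    if (is.null(js)) integer(0) else js[node_of[js] != node_of[i]]
  })
  indeg <- integer(2 * n)
  for (i in seq_along(succs)) indeg[succs[[i]]] <- indeg[succs[[i]]] + 1L
  # edge i -> j is "simple" iff it is i's only successor and j's only way in
  simple_succ <- vapply(seq_along(succs), function(i) {
    js <- succs[[i]]
    if (length(js) == 1 && indeg[js] == 1L) js else NA_integer_
  }, integer(1))
  simple_pred <- rep(NA_integer_, 2 * n)
  ok <- !is.na(simple_succ)
  simple_pred[simple_succ[ok]] <- which(ok)

  mirror <- function(o) if (o > n) o - n else o + n
  visited <- rep(FALSE, n)
  frags <- list()
  for (v in seq_len(n)) {
    if (visited[v]) next
    path <- v  # oriented indices, start at the forward orientation
    # extend right
    cur <- v
    repeat {
      nxt <- simple_succ[cur]
      if (is.na(nxt) || visited[node_of[nxt]] || node_of[nxt] == v) break
      path <- c(path, nxt)
      visited[node_of[nxt]] <- TRUE
      cur <- nxt
    }
    # extend left
    cur <- v
    repeat {
      prv <- simple_pred[cur]
      if (is.na(prv) || visited[node_of[prv]] || node_of[prv] == v) break
      path <- c(prv, path)
      visited[node_of[prv]] <- TRUE
      cur <- prv
    }
    visited[v] <- TRUE
    seqs <- oriented[path]
    sequence <- paste0(seqs[1],
                       paste(substr(seqs[-1], k, k), collapse = ""))
    rcseq <- revcomp(sequence)
    if (rcseq < sequence) {
      sequence <- rcseq
      path <- rev(vapply(path, mirror, integer(1)))
    }
    frags[[length(frags) + 1]] <-
      list(sequence = sequence, member_kmers = canon[node_of[path]],
           hits = NULL)
  }
  frags[order(vapply(frags, `[[`, character(1), "sequence"))]
}

.as_contig_strings <- function(ref) {
  if (inherits(ref, "DNAStringSet")) {
    out <- as.character(ref)
  } else if (is.list(ref) && !is.null(ref$contigs)) {
    out <- vapply(ref$contigs, `[[`, character(1), "sequence")
    names(out) <- vapply(ref$contigs, `[[`, character(1), "name")
  } else if (is.character(ref)) {
    out <- ref
  } else stop("unsupported reference type")
  if (is.null(names(out))) stop("reference contigs must be named")
  out
}

#' Map fragments to a reference genome by exact match
#'
#' Exact substring search of each fragment and its reverse complement against
#' every contig; all hits are reported (1-based inclusive coordinates, strand
#' `+` for the fragment as given, `-` for its reverse complement). Fragments
#' with no hit are retained with an empty hit table.
#'
#' @param fragments list from [extend_fragments()] (or character vector of
#'   sequences).
#' @param ref named character vector of contig sequences, a `DNAStringSet`,
#'   or a `ReferenceGenome` from [generate_reference()].
#' @return the fragment list with a `hits` data.frame per fragment
#'   (`contig`, `start`, `end`, `strand`).
#' @export
map_fragments <- function(fragments, ref) {
  contigs <- .as_contig_strings(ref)
  subject <- Biostrings::DNAStringSet(contigs)
  if (is.character(fragments))
    fragments <- lapply(fragments, function(s)
      list(sequence = s, member_kmers = s, hits = NULL))
  for (i in seq_along(fragments)) {
    fr <- fragments[[i]]$sequence
    hits <- list()
    for (pat in unique(c(fr, revcomp(fr)))) {
      strand <- if (pat == fr) "+" else "-"
      m <- Biostrings::vmatchPattern(pat, subject)
      for (ci in seq_along(m)) {
        r <- m[[ci]]
        if (length(r)) {
          hits[[length(hits) + 1]] <- data.frame(
            contig = names(contigs)[ci],
            start = BiocGenerics::start(r), end = BiocGenerics::end(r),
            strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
    hits <- if (length(hits)) do.call(rbind, hits) else
      data.frame(contig = character(0), start = integer(0), end = integer(0),
                 strand = character(0), stringsAsFactors = FALSE)
    hits <- unique(hits)
    fragments[[i]]$hits <- hits[order(hits$contig, hits$start), , drop = FALSE]
  }
  fragments
}

#' Linkage-disequilibrium window around a fragment hit
#'
#' The LD block of a mapped fragment is taken as the fragment interval
#' extended by `half_width` (default 50 kb) on each side, clipped to the
#' contig bounds when contig lengths are known.
#'
#' @param contig contig name.
#' @param start,end fragment hit interval (1-based inclusive).
#' @param half_width extension in bp on each side.
#' @param contig_lengths optional named vector of contig lengths for clipping;
#'   unknown contigs are an error when supplied.
#' @return list with `contig`, `start`, `end`.
#' @export
ld_window <- function(contig, start, end, half_width = 50000L,
                      contig_lengths = NULL) {
  stopifnot(start >= 1, end >= start)
  w_start <- max(1, start - half_width)
  w_end <- end + half_width
  if (!is.null(contig_lengths)) {
    if (!contig %in% names(contig_lengths))
      stop(sprintf("unknown contig: %s", contig))
    w_end <- min(w_end, contig_lengths[[contig]])
  }
  list(contig = contig, start = as.integer(w_start), end = as.integer(w_end))
}

.as_gene_table <- function(annotation) {
  if (is.data.frame(annotation)) {
    stopifnot(all(c("gene_id", "contig", "start", "end") %in%
                    names(annotation)))
    return(annotation)
  }
  if (inherits(annotation, "GRanges")) {
    gr <- annotation
    if ("type" %in% names(S4Vectors::mcols(gr)))
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    ids <- S4Vectors::mcols(gr)$ID
    if (is.null(ids)) ids <- S4Vectors::mcols(gr)$gene_id
    return(data.frame(gene_id = as.character(ids),
                      contig = as.character(GenomicRanges::seqnames(gr)),
                      start = BiocGenerics::start(gr),
                      end = BiocGenerics::end(gr), stringsAsFactors = FALSE))
  }
  if (is.character(annotation) && length(annotation) == 1)
    return(.as_gene_table(rtracklayer::import(annotation)))
  stop("unsupported annotation type")
}

#' Candidate genes intersecting an LD window
#'
#' Reports every annotated gene whose interval overlaps the window by at
#' least 1 bp (strand-agnostic), sorted by gene start.
#'
#' @param window list from [ld_window()].
#' @param annotation a GFF3 path, a `GRanges`, or a data.frame with columns
#'   `gene_id`, `contig`, `start`, `end` (1-based inclusive).
#' @return data.frame (`gene_id`, `contig`, `start`, `end`, `overlap_bp`).
#' @export
candidate_genes <- function(window, annotation) {
  genes <- .as_gene_table(annotation)
  sel <- genes$contig == window$contig &
    genes$start <= window$end & genes$end >= window$start
  out <- genes[sel, c("gene_id", "contig", "start", "end"), drop = FALSE]
  out$overlap_bp <- pmin(out$end, window$end) - pmax(out$start, window$start) + 1L
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fragment/window/gene annotation for a selected k-mer set
#'
#' Convenience chain: [extend_fragments()] on the selected k-mers,
#' [map_fragments()] against the reference, an [ld_window()] per hit, and
#' [candidate_genes()] per window.
#'
#' @param selected data.frame from [select_significant()] (needs a `kmer`
#'   column), or a character vector of k-mers.
#' @param ref reference genome (see [map_fragments()]).
#' @param annotation gene annotation (see [candidate_genes()]).
#' @param half_width window half width in bp.
#' @param unique_only drop fragments with more than one genomic hit.
#' @return list with `fragments` (data.frame: fragment_id, sequence, n_kmers,
#'   contig, start, end, strand, multi_hit) and `candidates` (data.frame:
#'   fragment_id, gene_id, gene_start, gene_end, overlap_bp).
#' @export
annotate_fragments <- function(selected, ref, annotation,
                               half_width = 50000L, unique_only = FALSE) {
  kmers <- if (is.data.frame(selected)) selected$kmer else selected
  frags <- extend_fragments(kmers)
  frags <- map_fragments(frags, ref)
  contigs <- .as_contig_strings(ref)
  clens <- setNames(nchar(contigs), names(contigs))
  frows <- list(); crows <- list()
  for (i in seq_along(frags)) {
    f <- frags[[i]]
    fid <- sprintf("frag_%03d", i)
    multi <- nrow(f$hits) > 1
    if (nrow(f$hits) == 0) {
      frows[[length(frows) + 1]] <- data.frame(
        fragment_id = fid, sequence = f$sequence,
        n_kmers = length(f$member_kmers), contig = NA_character_,
        start = NA_integer_, end = NA_integer_, strand = NA_character_,
        multi_hit = FALSE, stringsAsFactors = FALSE)
      next
    }
    if (unique_only && multi) next
    for (h in seq_len(nrow(f$hits))) {
      hit <- f$hits[h, ]
      frows[[length(frows) + 1]] <- data.frame(
        fragment_id = fid, sequence = f$sequence,
        n_kmers = length(f$member_kmers), contig = hit$contig,
        start = hit$start, end = hit$end, strand = hit$strand,
        multi_hit = multi, stringsAsFactors = FALSE)
      win <- ld_window(hit$contig, hit$start, hit$end, half_width, clens)
      cg <- candidate_genes(win, annotation)
      if (nrow(cg))
        crows[[length(crows) + 1]] <- data.frame(
          fragment_id = fid, gene_id = cg$gene_id, contig = cg$contig,
          gene_start = cg$start, gene_end = cg$end,
          overlap_bp = cg$overlap_bp, stringsAsFactors = FALSE)
    }
  }
  list(fragments = if (length(frows)) do.call(rbind, frows) else NULL,
       candidates = if (length(crows)) do.call(rbind, crows) else NULL)
}
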