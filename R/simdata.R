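#' Generate a toy reference genome with gene annotation
#'
#' Uniform-random contig sequences with non-overlapping gene intervals packed
#' by a random composition of the free space between genes (so any feasible
#' request succeeds). Deterministic for a fixed seed.
#'
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig (bp).
#' @param n_genes total number of genes, distributed round-robin over contigs.
#' @param gene_length length of each gene (bp).
#' @param seed integer seed.
#' @return a `ReferenceGenome`: list with `contigs` (list of
#'   `list(name, sequence)`) and `genes` (data.frame `gene_id`, `contig`,
#'   `start`, `end`, `strand`; 1-based inclusive).
#' @export
generate_reference <- function(n_contigs = 1L, contig_length = 100000L,
                               n_genes = 10L, gene_length = 2000L, seed = 1L) {
  stopifnot(n_contigs >= 1, contig_length >= 1, n_genes >= 0, gene_length >= 1)
  per_contig <- table(factor(rep(seq_len(n_contigs), length.out = n_genes),
                             levels = seq_len(n_contigs)))
  if (any(per_contig * gene_length > contig_length))
    stop("infeasible gene packing: genes do not fit in contigs")
  set.seed(seed)
  contigs <- vector("list", n_contigs)
  genes <- list()
  gid <- 0L
  for (ci in seq_len(n_contigs)) {
    seq <- paste(sample(c("A", "C", "G", "T"), contig_length, replace = TRUE),
                 collapse = "")
    name <- sprintf("contig%02d", ci)
    contigs[[ci]] <- list(name = name, sequence = seq)
    ng <- per_contig[[ci]]
    if (ng > 0) {
      free <- contig_length - ng * gene_length
      # random composition of free space into ng + 1 gaps
      cuts <- sort(sample.int(free + ng, ng))
      gaps <- diff(c(0L, cuts, free + ng + 1L)) - 1L
      start <- cumsum(gaps[seq_len(ng)]) + (seq_len(ng) - 1L) * gene_length + 1L
      for (g in seq_len(ng)) {
        gid <- gid + 1L
        genes[[gid]] <- data.frame(
          gene_id = sprintf("gene%04d", gid), contig = name,
          start = start[g], end = start[g] + gene_length - 1L,
          strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      }
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(0), contig = character(0),
               start = integer(0), end = integer(0), strand = character(0))
  structure(list(contigs = contigs, genes = genes), class = "ReferenceGenome")
}

#' Write a reference genome as FASTA + GFF3
#'
#' @param ref a `ReferenceGenome`.
#' @param fasta_path,gff_path output paths.
#' @export
write_reference <- function(ref, fasta_path, gff_path) {
  seqs <- Biostrings::DNAStringSet(.as_contig_strings(ref))
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (nrow(ref$genes)) {
    gr <- GenomicRanges::GRanges(
      seqnames = ref$genes$contig,
      ranges = IRanges::IRanges(ref$genes$start, ref$genes$end),
      strand = ref$genes$strand, type = "gene", ID = ref$genes$gene_id)
    rtracklayer::export(gr, gff_path, format = "gff3")
  } else {
    writeLines("##gff-version 3", gff_path)
  }
  invisible(c(fasta_path, gff_path))
}

#' Simulate a population of accession haplotypes
#'
#' Each accession's haplotype is the reference with (i) its Bernoulli-assigned
#' causal and neutral insertion alleles and (ii) private SNPs applied.
#' Insertions (rather than SNPs) are used as the planted variants because an
#' insertion of length >= k creates unambiguous diagnostic k-mers. Accessions
#' are single haplotypes by default; `pool = TRUE` mixes two haplotypes per
#' accession (equal read contribution downstream) to emulate the fact that
#' genebank accessions are populations of genotypes.
#'
#' @param ref a `ReferenceGenome`.
#' @param n_accessions number of accessions.
#' @param causal_loci data.frame with columns `contig`, `pos` (insertion
#'   after this 1-based position), `ins_len` (>= k), `freq` in (0,1), `beta`
#'   (phenotype effect per trait unit); one row per planted locus.
#' @param n_neutral number of additional non-causal insertion loci (uniform
#'   random positions and frequencies in (0.05, 0.95)); these give the
#'   k-mer matrix genuine background polymorphism so kinship is meaningful.
#' @param snp_rate per-base probability of a private SNP per accession.
#' @param seed integer seed.
#' @param pool simulate two haplotypes per accession (pooled GBS sampling).
#' @return a `Population`: list with `haplotypes` (per accession, list of
#'   named contig character vectors; two per accession when pooled), `truth`
#'   (accessions x causal loci 0/1 carriage matrix), `loci` (all insertion
#'   loci with `causal` flag and generated `ins_seq`), `snps` (per-accession
#'   private SNP positions).
#' @export
simulate_population <- function(ref, n_accessions, causal_loci,
                                n_neutral = 40L, snp_rate = 1e-4,
                                seed = 1L, pool = FALSE) {
  stopifnot(inherits(ref, "ReferenceGenome"), n_accessions >= 1)
  contigs <- .as_contig_strings(ref)
  set.seed(seed)
  k <- 31L
  if (nrow(causal_loci)) {
    stopifnot(all(causal_loci$freq > 0 & causal_loci$freq < 1),
              all(causal_loci$ins_len >= k),
              all(causal_loci$contig %in% names(contigs)))
    if (any(causal_loci$pos < 1 |
            causal_loci$pos > nchar(contigs[causal_loci$contig])))
      stop("causal positions outside contig")
  }
  loci <- causal_loci
  loci$causal <- rep(TRUE, nrow(loci))
  if (n_neutral > 0) {
    nl <- data.frame(
      contig = sample(names(contigs), n_neutral, replace = TRUE),
      pos = NA_integer_, ins_len = k, freq = runif(n_neutral, 0.05, 0.95),
      beta = 0, causal = FALSE, stringsAsFactors = FALSE)
    nl$pos <- vapply(nl$contig, function(cn)
      sample.int(nchar(contigs[[cn]]) - 200L, 1) + 100L, integer(1))
    loci <- rbind(loci, nl)
  }
  key <- paste(loci$contig, loci$pos)
  if (anyDuplicated(key)) stop("overlapping causal insertions")
  loci$locus_id <- sprintf("locus%03d", seq_len(nrow(loci)))
  loci$ins_seq <- vapply(loci$ins_len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  carriage <- matrix(0L, nrow = n_accessions, ncol = nrow(loci),
                     dimnames = list(sprintf("acc%03d", seq_len(n_accessions)),
                                     loci$locus_id))
  for (j in seq_len(nrow(loci)))
    carriage[, j] <- rbinom(n_accessions, 1L, loci$freq[j])

  n_hap <- if (pool) 2L else 1L
  build_hap <- function(carry) {
    hap <- contigs
    snp_pos <- list()
    for (cn in names(hap)) {
      L <- nchar(hap[[cn]])
      # private SNPs first (reference coordinates), then insertions right-to-left
      if (snp_rate > 0) {
        n_snp <- rbinom(1, L, snp_rate)
        if (n_snp > 0) {
          pos <- sort(sample.int(L, n_snp))
          s <- strsplit(hap[[cn]], "")[[1]]
          for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
          hap[[cn]] <- paste(s, collapse = "")
          snp_pos[[cn]] <- pos
        }
      }
      here <- which(loci$contig == cn & carry == 1L)
      if (length(here)) {
        for (j in here[order(loci$pos[here], decreasing = TRUE)]) {
          p <- loci$pos[j]
          hap[[cn]] <- paste0(substr(hap[[cn]], 1L, p), loci$ins_seq[j],
                              substr(hap[[cn]], p + 1L, nchar(hap[[cn]])))
        }
      }
    }
    list(seq = hap, snps = snp_pos)
  }
  haplotypes <- vector("list", n_accessions)
  snps <- vector("list", n_accessions)
  for (i in seq_len(n_accessions)) {
    hs <- lapply(seq_len(n_hap), function(h) build_hap(carriage[i, ]))
    haplotypes[[i]] <- lapply(hs, `[[`, "seq")
    snps[[i]] <- lapply(hs, `[[`, "snps")
  }
  names(haplotypes) <- rownames(carriage)
  names(snps) <- rownames(carriage)
  structure(list(haplotypes = haplotypes,
                 truth = carriage[, loci$causal, drop = FALSE],
                 carriage = carriage, loci = loci, snps = snps),
            class = "Population")
}

#' Diagnostic k-mers of a planted insertion
#'
#' Canonical k-mers that distinguish carriers from non-carriers: every k-mer
#' window overlapping the inserted bases (present only in carriers) and every
#' reference k-mer spanning the insertion junction (present only in
#' non-carriers).
#'
#' @param ref a `ReferenceGenome`.
#' @param contig,pos insertion site (insertion after `pos`).
#' @param ins_seq inserted sequence.
#' @param k k-mer length.
#' @return list with `carrier` and `noncarrier` canonical k-mer sets.
#' @export
diagnostic_kmers <- function(ref, contig, pos, ins_seq, k = 31L) {
  contigs <- .as_contig_strings(ref)
  s <- contigs[[contig]]
  left <- substr(s, max(1L, pos - k + 2L), pos)
  right <- substr(s, pos + 1L, min(nchar(s), pos + k - 1L))
  all_kmers <- function(x) {
    n <- nchar(x)
    if (n < k) return(character(0))
    starts <- seq_len(n - k + 1L)
    canonicalize(substring(x, starts, starts + k - 1L), k)
  }
  carrier <- all_kmers(paste0(left, ins_seq, right))
  junction <- all_kmers(paste0(left, right))
  ref_only <- setdiff(junction, carrier)
  list(carrier = unique(carrier), noncarrier = unique(ref_only))
}

#' Simulate single-end GBS-like reads from a haplotype
#'
#' Uniform start positions, random strand, i.i.d. substitution errors at the
#' stated per-base rate, constant base quality. The read count is
#' `round(coverage * genome_length / read_length)`.
#'
#' @param haplotype named character vector of contig sequences (one
#'   accession), or a list of such vectors (pooled accession; reads drawn
#'   equally from each).
#' @param read_length read length in bp (>= k).
#' @param coverage mean sequencing depth.
#' @param error per-base substitution probability in `[0, 0.1]`.
#' @param seed integer seed.
#' @return character vector of reads.
#' @export
simulate_gbs_reads <- function(haplotype, read_length = 100L, coverage = 30,
                               error = 0, seed = 1L) {
  stopifnot(coverage > 0, error >= 0, error <= 0.1, read_length >= 31)
  if (is.list(haplotype) && !is.character(haplotype)) {
    set.seed(seed)
    seeds <- sample.int(.Machine$integer.max, length(haplotype))
    return(unlist(lapply(seq_along(haplotype), function(h)
      simulate_gbs_reads(haplotype[[h]], read_length,
                         coverage / length(haplotype), error, seeds[h])),
      use.names = FALSE))
  }
  set.seed(seed)
  reads <- list()
  for (cn in names(haplotype)) {
    s <- haplotype[[cn]]
    L <- nchar(s)
    if (read_length > L) stop("read_length exceeds haplotype length")
    n_reads <- round(coverage * L / read_length)
    starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
    r <- substring(s, starts, starts + read_length - 1L)
    flip <- runif(n_reads) < 0.5
    r[flip] <- revcomp(r[flip])
    if (error > 0) {
      n_err <- rbinom(1, n_reads * read_length, error)
      if (n_err > 0) {
        at <- sample.int(n_reads * read_length, n_err)
        ri <- (at - 1L) %/% read_length + 1L
        pos <- (at - 1L) %% read_length + 1L
        for (e in seq_len(n_err)) {
          old <- substr(r[ri[e]], pos[e], pos[e])
          substr(r[ri[e]], pos[e], pos[e]) <-
            sample(setdiff(c("A", "C", "G", "T"), old), 1)
        }
      }
    }
    reads[[cn]] <- r
  }
  unlist(reads, use.names = FALSE)
}

#' Write reads as FASTQ with constant quality
#'
#' @param reads character vector of reads.
#' @param path output file.
#' @param id_prefix read-name prefix.
#' @export
write_fastq <- function(reads, path, id_prefix = "read") {
  q <- strrep("I", nchar(reads))
  lines <- as.vector(rbind(sprintf("@%s_%d", id_prefix, seq_along(reads)),
                           reads, "+", q))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate phenotypes under the mixed-model generative twin
#'
#' `y_ij = mu + sum_l beta_l * carriage_il + g_i + treatment_j + eps_ij`,
#' with polygenic effect `g ~ MVN(0, sigma_g2 * K)` and i.i.d. replicate
#' noise. This is the generative counterpart of the association model: the
#' tested k-mer enters as a fixed effect, kinship as the random-effect
#' covariance.
#'
#' @param truth accessions x loci 0/1 carriage matrix.
#' @param betas effect per locus (recycled).
#' @param K kinship covariance (symmetric PSD), accessions in `truth` order.
#' @param mu grand intercept.
#' @param sigma_g2 polygenic variance.
#' @param sigma_e2 residual (replicate) variance.
#' @param treatment_effect additive effect of the LP treatment.
#' @param n_replicates replicates per accession x treatment.
#' @param trait trait name in the output table.
#' @param seed integer seed.
#' @return a `PhenoTable` data.frame: `accession_id`, `treatment` (HP/LP),
#'   `replicate`, `trait`, `value`.
#' @export
simulate_phenotypes <- function(truth, betas, K = NULL, mu = 10,
                                sigma_g2 = 0.25, sigma_e2 = 0.75,
                                treatment_effect = -1, n_replicates = 3L,
                                trait = "SDM", seed = 1L) {
  stopifnot(is.matrix(truth), sigma_g2 >= 0, sigma_e2 >= 0, n_replicates >= 1)
  n <- nrow(truth)
  betas <- rep_len(betas, ncol(truth))
  set.seed(seed)
  g <- rep(0, n)
  if (sigma_g2 > 0) {
    if (is.null(K)) K <- diag(n)
    if (is.list(K) && !is.matrix(K)) K <- K$K
    eig <- eigen(K, symmetric = TRUE)
    if (min(eig$values) < -1e-8 * max(abs(eig$values), 1))
      stop("kinship matrix is not positive semi-definite")
    d <- pmax(eig$values, 0)
    g <- drop(eig$vectors %*% (sqrt(sigma_g2 * d) * rnorm(n)))
  }
  base <- mu + drop(truth %*% betas) + g
  rows <- expand.grid(replicate = seq_len(n_replicates),
                      treatment = c("HP", "LP"),
                      accession_id = rownames(truth),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$trait <- trait
  rows$value <- base[rows$accession_id] +
    ifelse(rows$treatment == "LP", treatment_effect, 0) +
    rnorm(nrow(rows), 0, sqrt(sigma_e2))
  rows[, c("accession_id", "treatment", "replicate", "trait", "value")]
}

#' Simulate a pot-experiment trait table
#'
#' Multi-trait long table emulating a two-treatment pot screen: per-accession
#' random effects (loaded on a shared "vigor" factor, so biomass traits are
#' positively correlated across accessions, as they are in real panels),
#' additive LP treatment effects per trait, and replicate noise. Trait means
#' and treatment effects default to values consistent with a phosphorus
#' deficiency screen: shoot and root dry matter drop by roughly a quarter
#' under LP, and shoot P concentration drops enough that utilisation
#' efficiency (the reciprocal of concentration at the accession mean) rises
#' by roughly a third.
#'
#' @param n_accessions number of accessions.
#' @param traits named list per trait:
#'   `list(mu, sd_accession, lp_effect, sd_noise)`.
#' @param vigor_loading correlation loading of accession effects on the
#'   shared vigor factor, in `[0, 1]`.
#' @param n_replicates replicates per accession x treatment.
#' @param seed integer seed.
#' @return a `PhenoTable` data.frame (values truncated at a small positive
#'   floor, as dry-matter measurements are).
#' @export
simulate_pot_experiment <- function(
    n_accessions = 200L,
    traits = list(
      SDM = list(mu = 4.82, sd_accession = 1.6, lp_effect = -1.14,
                 sd_noise = 0.6),
      RDM = list(mu = 1.43, sd_accession = 0.55, lp_effect = -0.33,
                 sd_noise = 0.25),
      shoot_P_conc = list(mu = 3.45, sd_accession = 0.4, lp_effect = -0.95,
                          sd_noise = 0.25)),
    vigor_loading = 0.7, n_replicates = 3L, seed = 1L) {
  set.seed(seed)
  acc <- sprintf("acc%03d", seq_len(n_accessions))
  vigor <- rnorm(n_accessions)
  out <- list()
  for (tn in names(traits)) {
    p <- traits[[tn]]
    load <- if (tn %in% c("SDM", "RDM", "SFM")) vigor_loading else 0
    a_eff <- p$sd_accession *
      (load * vigor + sqrt(1 - load^2) * rnorm(n_accessions))
    rows <- expand.grid(replicate = seq_len(n_replicates),
                        treatment = c("HP", "LP"), accession_id = acc,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows$trait <- tn
    rows$value <- p$mu + a_eff[match(rows$accession_id, acc)] +
      ifelse(rows$treatment == "LP", p$lp_effect, 0) +
      rnorm(nrow(rows), 0, p$sd_noise)
    rows$value <- pmax(rows$value, 0.01)
    out[[tn]] <- rows
  }
  do.call(rbind, out)[, c("accession_id", "treatment", "replicate", "trait",
                          "value")]
}

#' Render a root mask from stroked segments with analytic truth
#'
#' Rasterises line segments with round caps (a pixel is foreground when its
#' centre lies within `width/2` of a segment; odd widths centred on pixel
#' centres rasterise exactly) and returns the geometric truth
#' computed from the segment coordinates: total centre-line length, bounding
#' extents, foreground area (sum of capsule areas; segments are assumed not
#' to overlap except at shared endpoints) and convex hull area of the stroked
#' shape (hull of the capsule outlines).
#'
#' @param segments data.frame with `x0`, `y0`, `x1`, `y1` (pixel coordinates,
#'   x = column, y = row) and `width` (stroke width in px, > 0).
#' @param width_px,height_px canvas size.
#' @param dpi scan resolution (dots per inch).
#' @return a `RootMask`: list with `mask` (0/1 integer matrix, rows = y),
#'   `dpi`, and `truth` (list: `length_mm`, `area_mm2`, `width_mm`,
#'   `depth_mm`, `hull_area_mm2`).
#' @export
render_root_mask <- function(segments, width_px, height_px, dpi = 600) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1)
  if (any(segments$width <= 0)) stop("zero-width segment")
  r <- segments$width / 2
  if (any(segments$x0 - r < 1 | segments$x1 + r > width_px |
          segments$y0 - r < 1 | segments$y1 + r > height_px |
          segments$x0 + r > width_px | segments$x1 - r < 1 |
          segments$y0 + r > height_px | segments$y1 - r < 1))
    stop("segments (with stroke) must lie inside the canvas")
  mask <- matrix(0L, nrow = height_px, ncol = width_px)
  scale <- px_to_mm(dpi)
  seg_len <- sqrt((segments$x1 - segments$x0)^2 + (segments$y1 - segments$y0)^2)
  hull_pts <- list()
  for (i in seq_len(nrow(segments))) {
    x0 <- segments$x0[i]; y0 <- segments$y0[i]
    x1 <- segments$x1[i]; y1 <- segments$y1[i]
    w2 <- segments$width[i] / 2
    xmin <- max(1L, floor(min(x0, x1) - w2)); xmax <- min(width_px, ceiling(max(x0, x1) + w2))
    ymin <- max(1L, floor(min(y0, y1) - w2)); ymax <- min(height_px, ceiling(max(y0, y1) + w2))
    xs <- xmin:xmax; ys <- ymin:ymax
    px <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    py <- matrix(ys, nrow = length(ys), ncol = length(xs))
    dx <- x1 - x0; dy <- y1 - y0
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) matrix(0, nrow(px), ncol(px)) else
      pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / L2))
    d2 <- (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
    sub <- mask[ys, xs, drop = FALSE]
    sub[d2 <= w2 * w2] <- 1L
    mask[ys, xs] <- sub
    # capsule outline points for the hull truth
    ang <- seq(0, 2 * pi, length.out = 64)
    hull_pts[[i]] <- rbind(cbind(x0 + w2 * cos(ang), y0 + w2 * sin(ang)),
                           cbind(x1 + w2 * cos(ang), y1 + w2 * sin(ang)))
  }
  pts <- do.call(rbind, hull_pts)
  h <- chull(pts)
  hp <- pts[h, , drop = FALSE]
  hull_area_px2 <- abs(sum(hp[, 1] * hp[c(2:nrow(hp), 1), 2] -
                             hp[c(2:nrow(hp), 1), 1] * hp[, 2])) / 2
  truth <- list(
    length_mm = sum(seg_len) * scale,
    area_mm2 = sum(seg_len * segments$width +
                     pi * (segments$width / 2)^2) * scale^2,
    width_mm = (max(pts[, 1]) - min(pts[, 1])) * scale,
    depth_mm = (max(pts[, 2]) - min(pts[, 2])) * scale,
    hull_area_mm2 = hull_area_px2 * scale^2)
  structure(list(mask = mask, dpi = dpi, truth = truth), class = "RootMask")
}

#' Write / read a binary root mask as PNG (0 background, 255 foreground)
#'
#' @param mask a `RootMask` or 0/1 matrix.
#' @param path file path.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "RootMask")) mask$mask else mask
  png::writePNG(m * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @param dpi resolution to attach on read.
#' @export
read_mask_png <- function(path, dpi = 600) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  structure(list(mask = matrix(as.integer(img > 0.5), nrow(img), ncol(img)),
                 dpi = dpi, truth = NULL), class = "RootMask")
}
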