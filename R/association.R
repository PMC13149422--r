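#' Kinship matrix from a presence/absence k-mer matrix
#'
#' Centered cross-product relatedness: `K = Xc %*% t(Xc) / m` where `Xc` is
#' the column-centered presence matrix over `m` k-mers — the standard
#' realised-relatedness estimator for a binary marker matrix. A per-column
#' standardised variant (each column divided by its standard deviation before
#' the cross-product) is available with `normalise = TRUE`.
#'
#' @param km a `kmer_matrix` (>= 2 samples, >= 1 column).
#' @param normalise standardise columns to unit variance first.
#' @return list with `samples` and `K` (symmetric PSD matrix).
#' @export
kinship_from_pa <- function(km, normalise = FALSE) {
  stopifnot(inherits(km, "kmer_matrix"))
  X <- km$presence
  if (ncol(X) < 1) stop("k-mer matrix has zero columns")
  if (nrow(X) < 2) stop("need at least 2 samples")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (normalise) {
    s <- apply(X, 2, sd)
    s[s == 0] <- 1
    Xc <- sweep(Xc, 2, s, "/")
  }
  K <- tcrossprod(Xc) / ncol(X)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(X), rownames(X))
  list(samples = rownames(X), K = K)
}

# Profile ML log-likelihood of y = X b + u + e, u ~ N(0, sg2 K), e ~ N(0, se2 I)
# at variance ratio lambda = sg2/se2, after rotation by the eigenvectors of K.
# Ty, TX are U'y, U'X; d the eigenvalues. Returns logL and the profiled
# estimates.
.lmm_profile <- function(lambda, Ty, TX, d) {
  n <- length(Ty)
  v <- lambda * d + 1
  w <- 1 / v
  XtWX <- crossprod(TX, TX * w)
  XtWy <- crossprod(TX, Ty * w)
  b <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
  if (is.null(b)) return(list(logL = -Inf))
  r <- Ty - TX %*% b
  rss <- sum(w * r^2)
  se2 <- rss / n
  logL <- -0.5 * n * (log(2 * pi) + log(se2) + 1) - 0.5 * sum(log(v))
  list(logL = logL, beta = drop(b), se2 = se2, sg2 = lambda * se2)
}

# Maximise the profile likelihood over lambda on a log10 grid in [1e-5, 1e5],
# refined by Brent (golden-section/parabolic) search in the bracketing
# interval.
.lmm_fit <- function(Ty, TX, d, grid_points = 21L) {
  lg <- seq(-5, 5, length.out = grid_points)
  ll <- vapply(lg, function(g) .lmm_profile(10^g, Ty, TX, d)$logL, numeric(1))
  i <- which.max(ll)
  lo <- lg[max(1L, i - 1L)]
  hi <- lg[min(length(lg), i + 1L)]
  opt <- if (lo < hi) {
    optimize(function(g) .lmm_profile(10^g, Ty, TX, d)$logL,
             interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
  } else list(maximum = lg[i], objective = ll[i])
  cand <- if (opt$objective >= ll[i]) opt$maximum else lg[i]
  fit <- .lmm_profile(10^cand, Ty, TX, d)
  fit$lambda <- 10^cand
  fit
}

#' Fit the null (intercept-only) linear mixed model
#'
#' Maximum-likelihood fit of `y = mu + u + e` with `u ~ N(0, sg2 K)` and
#' `e ~ N(0, se2 I)`, by eigendecomposition of `K` and one-dimensional
#' optimisation of the profile likelihood over the variance ratio
#' `lambda = sg2/se2` (log10 grid on `[1e-5, 1e5]` refined by Brent search).
#' ML rather than REML because the downstream likelihood-ratio test compares
#' models with different fixed effects.
#'
#' @param y numeric trait vector, one value per accession (length >= 10,
#'   non-constant, finite).
#' @param K kinship matrix (or the list from [kinship_from_pa()]); symmetric
#'   positive semi-definite, rows aligned with `y`.
#' @return list with `sigma_g2`, `sigma_e2`, `lambda`, `loglik`, `mu`, plus
#'   the cached rotation (`U`, `d`, `Ty`, `T1`) reused by [test_kmer()].
#' @export
fit_null_lmm <- function(y, K) {
  if (is.list(K) && !is.matrix(K)) K <- K$K
  stopifnot(is.numeric(y), is.matrix(K), nrow(K) == ncol(K),
            length(y) == nrow(K))
  if (length(y) < 10) stop("need at least 10 samples")
  if (any(!is.finite(y))) stop("non-finite phenotype values")
  if (sd(y) == 0) stop("constant phenotype")
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  if (min(eig$values) < -1e-8 * max(abs(eig$values)))
    stop("kinship matrix is not positive semi-definite")
  U <- eig$vectors
  Ty <- drop(crossprod(U, y))
  T1 <- drop(crossprod(U, rep(1, length(y))))
  fit <- .lmm_fit(Ty, cbind(T1), d)
  list(sigma_g2 = fit$sg2, sigma_e2 = fit$se2, lambda = fit$lambda,
       loglik = fit$logL, mu = fit$beta[1],
       U = U, d = d, Ty = Ty, T1 = T1, n = length(y))
}

#' Likelihood-ratio association test of one k-mer
#'
#' Adds the presence/absence column as a fixed effect to the null model,
#' re-optimises both variance components under the alternative (exact LRT; set
#' `fast = TRUE` to hold `lambda` at its null value, the score-test shortcut),
#' and tests `2 * (logLik_alt - logLik_null)` against chi-squared with 1 df.
#'
#' @param x binary presence vector aligned with the phenotype.
#' @param null_fit result of [fit_null_lmm()].
#' @param kmer optional k-mer label carried into the result.
#' @param fast skip re-optimisation of the variance ratio.
#' @return one-row data.frame (`kmer`, `beta`, `lrt_stat`, `p_value`,
#'   `neg_log10_p`), or `NULL` when the marker is constant (untestable).
#' @export
test_kmer <- function(x, null_fit, kmer = NA_character_, fast = FALSE) {
  stopifnot(length(x) == null_fit$n)
  if (length(unique(x)) < 2) return(NULL)
  Tx <- drop(crossprod(null_fit$U, x))
  TX <- cbind(null_fit$T1, Tx)
  fit <- if (fast) {
    f <- .lmm_profile(null_fit$lambda, null_fit$Ty, TX, null_fit$d)
    f$lambda <- null_fit$lambda
    f
  } else .lmm_fit(null_fit$Ty, TX, null_fit$d)
  lrt <- max(0, 2 * (fit$logL - null_fit$loglik))
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  if (p < 1e-300) {
    warning("p-value below 1e-300; floored")
    p <- 1e-300
  }
  data.frame(kmer = kmer, beta = fit$beta[2], lrt_stat = lrt, p_value = p,
             neg_log10_p = -log10(p), stringsAsFactors = FALSE)
}

# columns with both 0 and 1 present (testable markers)
matrixStats_colRange <- function(X) {
  cmax <- apply(X, 2, max)
  cmin <- apply(X, 2, min)
  cmax != cmin
}

# Vectorised association scan: for each lambda on the log10 grid, the
# profile log-likelihood of [intercept, marker] is computed for all markers
# at once via closed-form weighted 2x2 GLS; each marker's grid optimum is
# then refined with Brent search in its bracketing interval.
.lmm_scan <- function(null_fit, TXall, grid_points = 21L, fast = FALSE) {
  n <- null_fit$n
  m <- ncol(TXall)
  T1 <- null_fit$T1; Ty <- null_fit$Ty; d <- null_fit$d
  TX2 <- TXall * TXall
  grid_logL <- function(lambda) {
    w <- 1 / (lambda * d + 1)
    logdet <- sum(log(lambda * d + 1))
    a11 <- sum(w * T1 * T1)
    a1y <- sum(w * T1 * Ty)
    ayy <- sum(w * Ty * Ty)
    a1x <- drop(crossprod(T1 * w, TXall))
    axy <- drop(crossprod(Ty * w, TXall))
    axx <- drop(crossprod(w, TX2))
    det <- a11 * axx - a1x^2
    bx <- (a11 * axy - a1x * a1y) / det
    b1 <- (a1y - a1x * bx) / a11
    rss <- pmax(ayy - b1 * a1y - bx * axy, 1e-300)
    list(logL = -0.5 * n * (log(2 * pi) + log(rss / n) + 1) - 0.5 * logdet,
         bx = bx)
  }
  if (fast) {
    g <- grid_logL(null_fit$lambda)
    return(list(lrt = pmax(0, 2 * (g$logL - null_fit$loglik)), beta = g$bx))
  }
  lg <- seq(-5, 5, length.out = grid_points)
  L <- matrix(NA_real_, m, length(lg))
  for (i in seq_along(lg)) L[, i] <- grid_logL(10^lg[i])$logL
  best <- max.col(L, ties.method = "first")
  lrt <- numeric(m)
  beta <- numeric(m)
  step <- lg[2] - lg[1]
  for (j in seq_len(m)) {
    Tx <- TXall[, j]
    Tx2 <- TX2[, j]
    prof <- function(g) {
      w <- 1 / (10^g * d + 1)
      a11 <- sum(w * T1 * T1); a1y <- sum(w * T1 * Ty); ayy <- sum(w * Ty * Ty)
      a1x <- sum(w * T1 * Tx); axy <- sum(w * Ty * Tx); axx <- sum(w * Tx2)
      det <- a11 * axx - a1x^2
      bx <- (a11 * axy - a1x * a1y) / det
      b1 <- (a1y - a1x * bx) / a11
      rss <- max(ayy - b1 * a1y - bx * axy, 1e-300)
      -0.5 * n * (log(2 * pi) + log(rss / n) + 1) -
        0.5 * sum(log(10^g * d + 1))
    }
    lo <- lg[best[j]] - step
    hi <- lg[best[j]] + step
    opt <- optimize(prof, interval = c(max(-5, lo), min(5, hi)),
                    maximum = TRUE, tol = 1e-6)
    lam <- if (opt$objective >= L[j, best[j]]) opt$maximum else lg[best[j]]
    g <- .lmm_profile(10^lam, Ty, cbind(T1, Tx), d)
    lrt[j] <- max(0, 2 * (g$logL - null_fit$loglik))
    beta[j] <- g$beta[2]
  }
  list(lrt = lrt, beta = beta)
}

#' Genome-wide k-mer association scan
#'
#' Aligns the phenotype with the matrix samples (inner join, warning on
#' drops), fits the null mixed model once, and tests every k-mer column.
#' Constant (untestable) columns are excluded. The phenotype is expected at
#' accession level (e.g. the mean over replicates within a treatment).
#'
#' @param km a `kmer_matrix`.
#' @param pheno named numeric vector (names = accession ids) or data.frame
#'   with columns `accession_id` and `value`.
#' @param K kinship; defaults to [kinship_from_pa()] of `km`.
#' @param fast passed to [test_kmer()].
#' @return data.frame of association results in matrix column order.
#' @export
run_gwas <- function(km, pheno, K = NULL, fast = FALSE) {
  stopifnot(inherits(km, "kmer_matrix"))
  if (is.data.frame(pheno)) pheno <- setNames(pheno$value, pheno$accession_id)
  common <- intersect(km$samples, names(pheno))
  if (length(common) < 10) stop("fewer than 10 overlapping samples")
  if (length(common) < length(km$samples) || length(common) < length(pheno))
    warning(sprintf("dropped %d matrix and %d phenotype samples without match",
                    length(km$samples) - length(common),
                    length(pheno) - length(common)))
  X <- km$presence[common, , drop = FALSE]
  y <- pheno[common]
  if (is.null(K)) {
    kin <- kinship_from_pa(new_kmer_matrix(X, km$kmers, km$canonical,
                                           colMeans(X)))
    K <- kin$K
  } else {
    if (is.list(K) && !is.matrix(K)) K <- K$K
    K <- K[common, common]
  }
  null_fit <- fit_null_lmm(y, K)
  testable <- which(matrixStats_colRange(X))
  # rotate all marker columns at once, then grid-evaluate the profile
  # likelihood for every marker simultaneously (weighted 2x2 GLS in closed
  # form per lambda), and refine each marker's optimum by Brent search
  TXall <- crossprod(null_fit$U, X[, testable, drop = FALSE])
  scan <- .lmm_scan(null_fit, TXall, fast = fast)
  p <- pchisq(scan$lrt, df = 1, lower.tail = FALSE)
  p <- pmax(p, 1e-300)
  out <- data.frame(kmer = km$kmers[testable], beta = scan$beta,
                    lrt_stat = scan$lrt, p_value = p,
                    neg_log10_p = -log10(p), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "null_fit") <- null_fit[c("sigma_g2", "sigma_e2", "lambda",
                                      "loglik", "mu")]
  out
}

#' Two-tier significance selection
#'
#' Primary rule: keep results with `-log10 p` strictly above `primary`
#' (default 5). If none qualify, fall back to results with `-log10 p` at or
#' above `fallback` (default 4, inclusive). Otherwise the selection is empty.
#'
#' @param results data.frame from [run_gwas()].
#' @param primary strict primary threshold on `-log10 p`.
#' @param fallback inclusive fallback threshold.
#' @return the selected rows with a `tier` column (`"primary"`, `"fallback"`
#'   or `"none"`); attribute `tier` carries the label as well.
#' @export
select_significant <- function(results, primary = 5.0, fallback = 4.0) {
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  hit <- results$neg_log10_p > primary
  if (any(hit)) {
    out <- results[hit, , drop = FALSE]
    out$tier <- "primary"
  } else {
    hit <- results$neg_log10_p >= fallback
    out <- results[hit, , drop = FALSE]
    out$tier <- if (any(hit)) "fallback" else character(0)
  }
  rownames(out) <- NULL
  attr(out, "tier") <- if (nrow(out)) out$tier[1] else "none"
  out
}

#' Manhattan and QQ summary tables
#'
#' QQ table: observed `-log10 p` sorted descending against expected uniform
#' quantiles `-log10((rank - 0.5)/n)`. Manhattan table: position vs observed
#' `-log10 p` when fragment positions are supplied.
#'
#' @param results data.frame from [run_gwas()].
#' @param positions optional data.frame (`kmer`, `contig`, `pos`).
#' @return list with `qq` and (optionally) `manhattan` data.frames.
#' @export
manhattan_qq_tables <- function(results, positions = NULL) {
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  n <- nrow(results)
  ord <- order(results$neg_log10_p, decreasing = TRUE)
  qq <- data.frame(kmer = results$kmer[ord],
                   observed = results$neg_log10_p[ord],
                   expected = -log10((seq_len(n) - 0.5) / n),
                   stringsAsFactors = FALSE)
  out <- list(qq = qq)
  if (!is.null(positions)) {
    m <- merge(results, positions, by = "kmer")
    out$manhattan <- m[order(m$contig, m$pos),
                       c("kmer", "contig", "pos", "neg_log10_p")]
  }
  out
}
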