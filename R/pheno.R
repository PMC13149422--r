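#' Shoot phosphorus content
#'
#' Shoot P content (mg/pot) = shoot dry matter (g/pot) x shoot P
#' concentration (mg/g).
#'
#' @param sdm shoot dry matter, g/pot (>= 0).
#' @param conc shoot P concentration, mg/g (>= 0).
#' @return shoot P content, mg/pot.
#' @export
shoot_p_content <- function(sdm, conc) {
  if (any(sdm < 0) || any(conc < 0)) stop("negative input")
  sdm * conc
}

#' Phosphorus utilisation efficiency
#'
#' PUE (g DM per mg P) = shoot dry matter / shoot P content; how much biomass
#' a plant produces per unit of phosphorus it has taken into the shoot.
#'
#' @param sdm shoot dry matter, g/pot.
#' @param p_content shoot P content, mg/pot (> 0).
#' @return PUE in g DM per mg P.
#' @export
pue <- function(sdm, p_content) {
  if (any(p_content <= 0)) stop("p_content must be > 0")
  sdm / p_content
}

#' Stress tolerance index
#'
#' `STI = Y_p * Y_s / mean(Y_p)^2`, combining yield potential under control
#' (HP) and yield stability under stress (LP); invariant under a common
#' rescaling of all inputs. `mean_y_p` is the mean control performance over
#' all accessions in the analysis set.
#'
#' @param y_p performance under control (HP).
#' @param y_s performance under stress (LP).
#' @param mean_y_p mean HP performance of the analysis set (> 0).
#' @return STI (>= 0 for non-negative yields).
#' @export
sti <- function(y_p, y_s, mean_y_p) {
  if (any(mean_y_p <= 0)) stop("mean_y_p must be > 0")
  y_p * y_s / mean_y_p^2
}

#' Signed percent change between treatment means
#'
#' `100 * (mean_lp - mean_hp) / mean_hp`; reductions come out negative (a
#' "-24" is reported as a 24 percent reduction).
#'
#' @param mean_hp control (HP) mean (> 0).
#' @param mean_lp stress (LP) mean.
#' @return signed percent change.
#' @export
percent_change <- function(mean_hp, mean_lp) {
  if (any(mean_hp <= 0)) stop("mean_hp must be > 0")
  100 * (mean_lp - mean_hp) / mean_hp
}

.trait_means <- function(table, trait) {
  t <- table[table$trait == trait, , drop = FALSE]
  ag <- aggregate(value ~ accession_id + treatment, data = t, FUN = mean)
  ag
}

#' Rank accessions by root dry matter response and form contrast groups
#'
#' `delta_RDM = mean RDM under HP - mean RDM under LP` per accession (over
#' replicates). Accessions are ranked by signed delta (descending); from the
#' `n_extreme` largest and `n_extreme` smallest, `n_pick` each are selected
#' into the "High dRDM" and "Low dRDM" groups. The within-pool pick is a
#' pluggable hook (the original selection also balanced biostatus and origin,
#' which is not computable here); the default takes the most extreme
#' `n_pick` of each pool.
#'
#' @param table a `PhenoTable` containing an `RDM` trait.
#' @param n_extreme pool size at each end (default 30).
#' @param n_pick selected per group (default 10).
#' @param picker optional `function(pool_ids, delta, top)` returning the
#'   chosen accession ids for one pool.
#' @param trait trait name holding root dry matter.
#' @return data.frame (`accession_id`, `delta_rdm`, `rank`, `group`) with
#'   group in `{"High dRDM", "Low dRDM", "none"}`, sorted by rank.
#' @export
delta_rdm_groups <- function(table, n_extreme = 30L, n_pick = 10L,
                             picker = NULL, trait = "RDM") {
  ag <- .trait_means(table, trait)
  wide <- merge(ag[ag$treatment == "HP", c("accession_id", "value")],
                ag[ag$treatment == "LP", c("accession_id", "value")],
                by = "accession_id", suffixes = c("_hp", "_lp"),
                all = TRUE)
  miss <- !complete.cases(wide)
  if (any(miss)) {
    warning(sprintf("%d accession(s) missing a treatment; excluded",
                    sum(miss)))
    wide <- wide[!miss, , drop = FALSE]
  }
  reps <- table(table$accession_id[table$trait == trait],
                table$treatment[table$trait == trait])
  if (any(reps < 3))
    warning("fewer than 3 replicates for some accession x treatment")
  wide$delta_rdm <- wide$value_hp - wide$value_lp
  wide <- wide[order(-wide$delta_rdm, wide$accession_id), , drop = FALSE]
  wide$rank <- seq_len(nrow(wide))
  n <- nrow(wide)
  top_pool <- wide$accession_id[seq_len(min(n_extreme, n))]
  bot_pool <- wide$accession_id[seq(max(1, n - n_extreme + 1), n)]
  delta <- setNames(wide$delta_rdm, wide$accession_id)
  if (is.null(picker))
    picker <- function(pool_ids, delta, top) {
      ord <- order(delta[pool_ids], decreasing = top)
      pool_ids[ord][seq_len(min(n_pick, length(pool_ids)))]
    }
  high <- picker(top_pool, delta, TRUE)
  low <- picker(bot_pool, delta, FALSE)
  wide$group <- "none"
  wide$group[wide$accession_id %in% high] <- "High dRDM"
  wide$group[wide$accession_id %in% low] <- "Low dRDM"
  rownames(wide) <- NULL
  wide[, c("accession_id", "delta_rdm", "rank", "group")]
}

#' Per-accession phosphorus-efficiency indices
#'
#' Computes, per accession and treatment, the mean SDM and shoot P
#' concentration over replicates, then shoot P content, PUE, per-trait STI
#' (with `mean Y_p` taken over all accessions in `table`), and delta-RDM when
#' an RDM trait is present. The identity
#' `PUE * shoot_P_content = SDM` holds per accession/treatment by
#' construction.
#'
#' @param table a `PhenoTable` with traits `SDM`, `shoot_P_conc`, and
#'   optionally `RDM` and others.
#' @param sti_traits traits for which STI is computed.
#' @return data.frame keyed by `accession_id` with columns
#'   `shoot_P_content_HP/LP` (mg/pot), `PUE_HP/LP` (g DM / mg P),
#'   `STI_<trait>`, and `delta_RDM` (g).
#' @export
efficiency_indices <- function(table, sti_traits = intersect(
    c("SDM", "RDM", "SFM"), unique(table$trait))) {
  sdm <- .trait_means(table, "SDM")
  conc <- .trait_means(table, "shoot_P_conc")
  m <- merge(sdm, conc, by = c("accession_id", "treatment"),
             suffixes = c("_sdm", "_conc"))
  m$p_content <- shoot_p_content(m$value_sdm, m$value_conc)
  m$pue <- pue(m$value_sdm, m$p_content)
  wide <- function(col, nm) {
    w <- merge(m[m$treatment == "HP", c("accession_id", col)],
               m[m$treatment == "LP", c("accession_id", col)],
               by = "accession_id", suffixes = c("_HP", "_LP"))
    names(w)[-1] <- paste0(nm, c("_HP", "_LP"))
    w
  }
  out <- merge(wide("p_content", "shoot_P_content"), wide("pue", "PUE"),
               by = "accession_id")
  for (tr in sti_traits) {
    tm <- .trait_means(table, tr)
    hp <- tm[tm$treatment == "HP", ]
    lp <- tm[tm$treatment == "LP", ]
    w <- merge(hp[, c("accession_id", "value")],
               lp[, c("accession_id", "value")],
               by = "accession_id", suffixes = c("_hp", "_lp"))
    w[[paste0("STI_", tr)]] <- sti(w$value_hp, w$value_lp, mean(hp$value))
    out <- merge(out, w[, c("accession_id", paste0("STI_", tr))],
                 by = "accession_id")
  }
  if ("RDM" %in% unique(table$trait)) {
    rdm <- .trait_means(table, "RDM")
    w <- merge(rdm[rdm$treatment == "HP", c("accession_id", "value")],
               rdm[rdm$treatment == "LP", c("accession_id", "value")],
               by = "accession_id", suffixes = c("_hp", "_lp"))
    w$delta_RDM <- w$value_hp - w$value_lp
    out <- merge(out, w[, c("accession_id", "delta_RDM")],
                 by = "accession_id")
  }
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (average ranks for ties). Errors on
#' constant input, where the coefficient is undefined.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector: rho undefined")
  cor(x, y, method = "spearman")
}

#' Two-way ANOVA with a replicate block
#'
#' Fixed-effects approximation of the study's mixed model: sequential
#' (type-I) sums of squares for replicate block, treatment, group, and the
#' treatment x group interaction, in that order. Terms whose factor has a
#' single level are skipped with a warning.
#'
#' @param table data.frame with columns `value`, `treatment`, `group`,
#'   `replicate`.
#' @param trait optional: filter `table$trait == trait` first.
#' @return named vector of F-test p-values (`replicate`, `treatment`,
#'   `group`, `treatment:group`), NA for skipped terms; the `anova` table is
#'   attached as attribute `table`.
#' @export
anova_two_way <- function(table, trait = NULL) {
  if (!is.null(trait)) table <- table[table$trait == trait, , drop = FALSE]
  stopifnot(all(c("value", "treatment", "group", "replicate") %in%
                  names(table)))
  df <- data.frame(value = table$value,
                   treatment = factor(table$treatment),
                   group = factor(table$group),
                   replicate = factor(table$replicate))
  terms <- c("replicate", "treatment", "group")
  use <- terms[vapply(terms, function(t) nlevels(df[[t]]) >= 2, logical(1))]
  skipped <- setdiff(terms, use)
  if (length(skipped))
    warning(sprintf("single-level factor(s) skipped: %s",
                    paste(skipped, collapse = ", ")))
  rhs <- use
  if (all(c("treatment", "group") %in% use)) rhs <- c(rhs, "treatment:group")
  fml <- stats::as.formula(paste("value ~", paste(rhs, collapse = " + ")))
  at <- anova(lm(fml, data = df))
  p <- setNames(rep(NA_real_, 4),
                c("replicate", "treatment", "group", "treatment:group"))
  for (term in rownames(at))
    if (term %in% names(p)) p[term] <- at[term, "Pr(>F)"]
  attr(p, "table") <- at
  p
}

#' Redundancy pruning by uncorrected p-distance
#'
#' Pairwise p-distance = mismatches / pairwise-complete sites over a
#' biallelic (0/1/NA) or character-state matrix. Per round, accession pairs
#' with similarity `1 - d >= similarity_threshold` form a redundancy graph;
#' within each connected component only the accession with the least missing
#' data (ties broken lexicographically by id) is retained. Rounds repeat
#' until no change or `rounds` is reached. Pairs with zero overlapping sites
#' have undefined distance and are treated as non-redundant with a warning.
#'
#' @param snp_matrix accessions x sites matrix with rownames; NA = missing.
#' @param similarity_threshold redundancy threshold (default 0.9997).
#' @param rounds maximum pruning rounds (default 3).
#' @return character vector of retained accession ids (input order).
#' @export
pdistance_dedup <- function(snp_matrix, similarity_threshold = 0.9997,
                            rounds = 3L) {
  stopifnot(is.matrix(snp_matrix), !is.null(rownames(snp_matrix)))
  keep <- rownames(snp_matrix)
  for (round in seq_len(rounds)) {
    M <- snp_matrix[keep, , drop = FALSE]
    n <- nrow(M)
    if (n < 2) break
    obs <- !is.na(M)
    # pairwise-complete overlap and mismatch counts via indicator algebra
    states <- sort(unique(as.vector(M[obs])))
    match_cnt <- matrix(0, n, n)
    for (s in states) {
      I <- (M == s) & obs
      storage.mode(I) <- "double"
      I[is.na(I)] <- 0
      match_cnt <- match_cnt + tcrossprod(I)
    }
    O <- obs; storage.mode(O) <- "double"
    overlap <- tcrossprod(O)
    dist <- (overlap - match_cnt) / overlap # NaN where overlap == 0
    if (any(overlap[upper.tri(overlap)] == 0))
      warning("pair(s) with zero overlapping sites treated as non-redundant")
    sim <- 1 - dist
    adj <- !is.na(sim) & sim >= similarity_threshold
    diag(adj) <- FALSE
    if (!any(adj)) break
    # connected components by repeated expansion
    comp <- seq_len(n)
    repeat {
      new_comp <- comp
      for (i in seq_len(n)) {
        nb <- which(adj[i, ])
        if (length(nb)) new_comp[i] <- min(comp[i], comp[nb])
      }
      if (identical(new_comp, comp)) break
      comp <- new_comp
    }
    missing_n <- rowSums(!obs)
    ids <- rownames(M)
    retained <- unlist(lapply(split(seq_len(n), comp), function(members) {
      if (length(members) == 1) return(ids[members])
      ord <- order(missing_n[members], ids[members])
      ids[members][ord][1]
    }), use.names = FALSE)
    new_keep <- keep[keep %in% retained]
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  keep
}
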