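test_that("index arithmetic and identities hold", {
  expect_equal(shoot_p_content(2, 3), 6)
  expect_equal(shoot_p_content(0, 5), 0)
  expect_error(shoot_p_content(-1, 1), "negative")
  expect_equal(pue(1, 2), 0.5)
  expect_error(pue(1, 0), "> 0")
  # round trip: pue(s, shoot_p_content(s, c)) * c = 1
  for (s in c(0.5, 2, 4.82)) for (cc in c(1, 3.3, 4.2))
    expect_equal(pue(s, shoot_p_content(s, cc)) * cc, 1, tolerance = 1e-12)
  # STI reference point, zero, and rescale invariance
  expect_equal(sti(3, 3, 3), 1)
  expect_equal(sti(3, 0, 3), 0)
  expect_equal(sti(2, 5, 4), sti(20, 50, 40), tolerance = 1e-12)
  expect_error(sti(1, 1, 0), "> 0")
  # STI grows monotonically in the stress yield
  expect_true(all(diff(sti(2, c(1, 2, 3), 4)) > 0))
  # percent change sign conventions
  expect_equal(percent_change(4, 4), 0)
  expect_equal(percent_change(4, 3), -25)
  expect_error(percent_change(0, 1), "> 0")
  # antisymmetry identity: pc(a,b) = -pc(b,a) * b/a
  a <- 4.82; b <- 3.68
  expect_equal(percent_change(a, b), -percent_change(b, a) * b / a,
               tolerance = 1e-12)
})

test_that("delta-RDM ranking matches a sort oracle and allows negatives", {
  tab <- data.frame(
    accession_id = rep(sprintf("a%02d", 1:8), each = 6),
    treatment = rep(rep(c("HP", "LP"), each = 3), 8),
    replicate = rep(1:3, 16), trait = "RDM",
    value = 0)
  hp_means <- c(1.5, 2.0, 1.0, 3.0, 1.2, 0.9, 2.5, 1.8)
  lp_means <- c(1.0, 2.1, 0.8, 2.0, 1.3, 0.95, 1.0, 1.75)
  for (i in 1:8) {
    sel <- tab$accession_id == sprintf("a%02d", i)
    tab$value[sel & tab$treatment == "HP"] <- hp_means[i]
    tab$value[sel & tab$treatment == "LP"] <- lp_means[i]
  }
  g <- delta_rdm_groups(tab, n_extreme = 3, n_pick = 2)
  delta <- hp_means - lp_means
  ord <- order(-delta)
  expect_equal(g$delta_rdm, delta[ord], tolerance = 1e-12)
  expect_equal(g$accession_id, sprintf("a%02d", ord))
  # negative deltas (higher RDM under LP) are legal and rank last
  expect_lt(min(g$delta_rdm), 0)
  expect_identical(g$group[1:2], c("High dRDM", "High dRDM"))
  expect_identical(g$group[7:8], c("Low dRDM", "Low dRDM"))
  expect_true(all(g$group[3:6] == "none"))
  # single HP/LP example
  one <- tab[tab$accession_id == "a01", ]
  g1 <- suppressWarnings(delta_rdm_groups(one, n_extreme = 1, n_pick = 1))
  expect_equal(g1$delta_rdm, 0.5)
  # accession missing one treatment is excluded with a warning
  broken <- tab[!(tab$accession_id == "a02" & tab$treatment == "LP"), ]
  w <- testthat::capture_warnings(g2 <- delta_rdm_groups(broken, 3, 2))
  expect_true(any(grepl("missing a treatment", w)))
  expect_false("a02" %in% g2$accession_id)
})

test_that("efficiency indices satisfy their defining identity per accession", {
  tab <- simulate_pot_experiment(n_accessions = 12, seed = 9)
  idx <- efficiency_indices(tab)
  expect_equal(nrow(idx), 12)
  sdm <- aggregate(value ~ accession_id + treatment,
                   tab[tab$trait == "SDM", ], mean)
  hp <- sdm[sdm$treatment == "HP", ]
  hp <- hp[match(idx$accession_id, hp$accession_id), ]
  # PUE * shoot P content = SDM (HP side), to numerical precision
  expect_equal(idx$PUE_HP * idx$shoot_P_content_HP, hp$value,
               tolerance = 1e-9)
  # STI from the same table agrees with the direct formula
  lp <- sdm[sdm$treatment == "LP", ]
  lp <- lp[match(idx$accession_id, lp$accession_id), ]
  expect_equal(idx$STI_SDM, hp$value * lp$value / mean(hp$value)^2,
               tolerance = 1e-12)
  expect_true(all(idx$STI_SDM >= 0))
})

test_that("spearman correlation handles monotone, reversed and tied data", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, rev(1:10)), -1)
  # tie fixture against a hand-computed midrank oracle
  x <- c(1, 2, 2, 4, 5)
  y <- c(2, 1, 4, 4, 6)
  rx <- c(1, 2.5, 2.5, 4, 5)
  ry <- c(2, 1, 3.5, 3.5, 5)
  expect_equal(spearman_rho(x, y), cor(rx, ry), tolerance = 1e-12)
  # tie-free data: equals Pearson on ranks to 1e-12
  set.seed(13)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(spearman_rho(a, b), cor(rank(a), rank(b)), tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("two-way ANOVA detects treatment shifts and stays calibrated", {
  make_tab <- function(shift, seed, interaction = 0) {
    set.seed(seed)
    d <- expand.grid(replicate = 1:5, treatment = c("HP", "LP"),
                     group = c("High", "Low"), stringsAsFactors = FALSE)
    d$value <- rnorm(nrow(d)) + ifelse(d$treatment == "LP", shift, 0) +
      ifelse(d$treatment == "LP" & d$group == "Low", interaction, 0)
    d
  }
  # 3-sigma treatment shift: p < 0.001 in at least 95% of 100 seeds
  hits <- vapply(1:100, function(s)
    suppressWarnings(anova_two_way(make_tab(3, s))["treatment"] < 0.001),
    logical(1))
  expect_gte(mean(hits), 0.95)
  # pure noise: interaction p-values uniform (KS not rejected at 0.001)
  pis <- vapply(1:100, function(s)
    anova_two_way(make_tab(0, 1000 + s))["treatment:group"], numeric(1))
  expect_gt(ks.test(pis, "punif")$p.value, 0.001)
  # zero-noise additive data: interaction sum of squares is 0
  d <- expand.grid(replicate = 1:3, treatment = c("HP", "LP"),
                   group = c("High", "Low"), stringsAsFactors = FALSE)
  d$value <- 2 + (d$treatment == "LP") * 1 + (d$group == "Low") * 0.5
  p <- suppressWarnings(anova_two_way(d))
  at <- attr(p, "table")
  expect_equal(at["treatment:group", "Sum Sq"], 0, tolerance = 1e-20)
  # single-level factor is skipped with a warning
  d2 <- d[d$group == "High", ]
  w <- testthat::capture_warnings(p2 <- anova_two_way(d2))
  expect_true(any(grepl("single-level", w)))
  expect_true(is.na(p2["group"]))
})

test_that("p-distance dedup retains the least-missing representative", {
  M <- rbind(a = c(0, 1, 0, 1, NA), b = c(0, 1, 0, 1, 1),
             c = c(1, 0, 1, 0, 0))
  # a and b identical on shared sites; b has less missing -> b retained
  expect_identical(pdistance_dedup(M, 0.9997, 3), c("b", "c"))
  # all-distinct rows below the threshold are all retained
  M2 <- rbind(a = c(0, 1, 0), b = c(1, 1, 0), c = c(0, 0, 1))
  expect_identical(pdistance_dedup(M2, 0.9997, 3), c("a", "b", "c"))
  # zero-overlap pair is non-redundant, with a warning
  M3 <- rbind(a = c(0, 1, NA, NA), b = c(NA, NA, 1, 0))
  expect_warning(keep <- pdistance_dedup(M3, 0.9997, 3), "zero overlapping")
  expect_identical(keep, c("a", "b"))
})

test_that("p-distance dedup matches the quadratic oracle on random fixtures", {
  set.seed(14)
  for (rep in 1:5) {
    n <- 12; m <- 40
    M <- matrix(rbinom(n * m, 1, 0.5), n, m,
                dimnames = list(letters[1:n], NULL))
    # plant near-duplicate clusters and missingness
    M[2, ] <- M[1, ]; M[3, ] <- M[1, ]; M[3, sample(m, 1)] <- 1 - M[3, 1]
    M[7, ] <- M[6, ]
    M[sample(length(M), 25)] <- NA
    thr <- 0.95
    expect_identical(pdistance_dedup(M, thr, 3),
                     oracle_pdist_dedup(M, thr, 3))
  }
  # the audit property: no retained pair is at or above the threshold
  set.seed(15)
  M <- matrix(rbinom(300, 1, 0.5), 10, 30,
              dimnames = list(letters[1:10], NULL))
  M[2, ] <- M[1, ]
  keep <- pdistance_dedup(M, 0.97, 3)
  X <- M[keep, ]
  for (i in seq_along(keep)) for (j in seq_along(keep)) {
    if (i >= j) next
    expect_lt(1 - mean(X[i, ] != X[j, ]), 0.97)
  }
})
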