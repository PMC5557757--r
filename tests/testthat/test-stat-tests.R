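test_that("pooled t from summary statistics matches a moment-matched raw-data t-test", {
  set.seed(6)
  for (i in 1:20) {
    m1 <- runif(1, -5, 5); s1 <- runif(1, 0.5, 3); n1 <- sample(5:40, 1)
    m2 <- runif(1, -5, 5); s2 <- runif(1, 0.5, 3); n2 <- sample(5:40, 1)
    # construct samples with exactly these moments
    mk <- function(m, s, n) {
      z <- scale(rnorm(n))
      as.vector(m + s * z)
    }
    x <- mk(m1, s1, n1)
    y <- mk(m2, s2, n2)
    ours <- pooled_t_test(m1, s1, n1, m2, s2, n2)
    ref <- t.test(y, x, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate pooled t cases follow the stated conventions", {
  r <- pooled_t_test(3, 0, 5, 3, 0, 5)
  expect_equal(r$t, 0)
  expect_equal(r$cohens_d, 0)
  expect_error(pooled_t_test(3, 0, 5, 4, 0, 5), "undefined")
  same <- pooled_t_test(2.5, 1.1, 10, 2.5, 1.1, 10)
  expect_equal(same$t, 0)
})

# independent by-hand split-plot sums of squares (balanced designs)
byhand_mixed <- function(d) {
  K <- length(unique(d$w)); G <- length(unique(d$g))
  n <- length(unique(d$id)) / G
  gm <- mean(d$y)
  subj <- tapply(d$y, d$id, mean)
  grp_of <- tapply(as.character(d$g), d$id, unique)
  ss_bs <- K * sum((subj - gm)^2)
  gmeans <- tapply(subj, grp_of, mean)
  ss_group <- n * K * sum((gmeans - gm)^2)
  ss_swg <- ss_bs - ss_group
  lmeans <- tapply(d$y, d$w, mean)
  ss_level <- n * G * sum((lmeans - gm)^2)
  cellm <- tapply(d$y, list(d$g, d$w), mean)
  dev <- sweep(sweep(cellm, 1, gmeans), 2, lmeans) + gm
  ss_inter <- n * sum(dev^2)
  ss_total <- sum((d$y - gm)^2)
  ss_err_w <- ss_total - ss_bs - ss_level - ss_inter
  list(group = ss_group, swg = ss_swg, level = ss_level,
       inter = ss_inter, err_w = ss_err_w,
       F_group = (ss_group / (G - 1)) / (ss_swg / (G * n - G)),
       F_level = (ss_level / (K - 1)) / (ss_err_w / ((G * n - G) * (K - 1))),
       F_inter = (ss_inter / ((G - 1) * (K - 1))) /
         (ss_err_w / ((G * n - G) * (K - 1))))
}

test_that("mixed ANOVA matches a by-hand sums-of-squares decomposition", {
  set.seed(8)
  for (i in 1:10) {
    n <- 4; K <- sample(2:3, 1)
    d <- expand.grid(id = sprintf("S%d", 1:(2 * n)), w = paste0("L", 1:K))
    d$g <- ifelse(as.integer(sub("S", "", d$id)) <= n, "g1", "g2")
    d$y <- rnorm(nrow(d), mean = as.integer(factor(d$w)) +
                   2 * (d$g == "g1"))
    a <- mixed_anova(d, "y", "id", "g", "w")
    bh <- byhand_mixed(d)
    e <- a$effects
    expect_equal(e$F[e$effect == "group"], bh$F_group, tolerance = 1e-9)
    expect_equal(e$F[e$effect == "within"], bh$F_level, tolerance = 1e-9)
    expect_equal(e$F[e$effect == "group:within"], bh$F_inter, tolerance = 1e-9)
    expect_equal(e$ss[e$effect == "group"], bh$group, tolerance = 1e-9)
    expect_equal(e$partial_eta_sq[e$effect == "group"],
                 bh$group / (bh$group + bh$swg), tolerance = 1e-9)
  }
})

test_that("mixed ANOVA satisfies the SS partition, df and null-case identities", {
  set.seed(9)
  # unbalanced groups like the study's 16 vs 15
  d <- expand.grid(id = sprintf("S%02d", 1:31), w = c("weak", "strong"))
  d$g <- ifelse(as.integer(sub("S", "", d$id)) <= 16, "asd", "td")
  d$y <- rnorm(nrow(d))
  a <- mixed_anova(d, "y", "id", "g", "w")
  expect_equal(a$ss_total, a$ss_strata_sum, tolerance = 1e-9)
  e <- a$effects
  expect_equal(e$df_num[e$effect == "group"], 1)
  expect_equal(e$df_den[e$effect == "group"], 29) # n1 + n2 - 2
  expect_true(all(e$partial_eta_sq >= 0 & e$partial_eta_sq <= 1))

  # duplicated-group data: between-group F is exactly zero
  base <- expand.grid(id = sprintf("A%d", 1:6), w = c("l1", "l2"))
  base$y <- rnorm(nrow(base), mean = as.integer(factor(base$w)))
  dup <- rbind(transform(base, id = paste0(id, "x"), g = "g1"),
               transform(base, id = paste0(id, "y"), g = "g2"))
  a2 <- mixed_anova(dup, "y", "id", "g", "w")
  expect_equal(a2$effects$F[a2$effects$effect == "group"], 0,
               tolerance = 1e-12)

  # missing cell names the participant and level
  miss <- d[-1, ]
  expect_error(mixed_anova(miss, "y", "id", "g", "w"), "S01")
})

test_that("Bonferroni pairwise adjustment is min(1, raw * n_pairs)", {
  set.seed(10)
  mk <- function(K) {
    d <- expand.grid(id = sprintf("S%d", 1:12), w = paste0("L", 1:K))
    d$y <- rnorm(nrow(d), as.integer(factor(d$w)))
    d
  }
  d2 <- mk(2)
  r2 <- bonferroni_pairwise(d2, "y", "id", "w")
  expect_equal(r2$p_adjusted, r2$p_raw) # one pair: factor 1
  d3 <- mk(3)
  r3 <- bonferroni_pairwise(d3, "y", "id", "w")
  expect_equal(attr(r3, "n_comparisons"), 3)
  expect_equal(r3$p_adjusted, pmin(1, r3$p_raw * 3))
  # definitional oracle against direct paired t-tests
  a <- d3$y[d3$w == "L1"][order(d3$id[d3$w == "L1"])]
  b <- d3$y[d3$w == "L2"][order(d3$id[d3$w == "L2"])]
  expect_equal(r3$p_raw[r3$level1 == "L1" & r3$level2 == "L2"],
               t.test(a, b, paired = TRUE)$p.value)
})

test_that("Mann-Whitney U statistics honour the rank-sum identities", {
  set.seed(11)
  for (i in 1:20) {
    x <- sample(0:10, 8, replace = TRUE) # ties likely
    y <- sample(0:10, 6, replace = TRUE)
    r <- mann_whitney(x, y)
    expect_equal(r$U + r$U_other, length(x) * length(y))
    w <- suppressWarnings(wilcox.test(x, y))
    expect_equal(r$U, unname(w$statistic))
  }
  # null centre gives z = 0
  expect_equal(mwu_z_from_u(12, 4, 6), 0)
})

test_that("the normal approximation brackets the exact small-sample p", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(0.7, 2.9, 1.1, 1.9)
  r <- mann_whitney(x, y, tie_correction = FALSE)
  exact <- wilcox.test(x, y, exact = TRUE)$p.value
  expect_lt(abs(r$p - exact), 0.1)
})

test_that("correlation p-values follow the t transform and its symmetries", {
  expect_equal(pearson_p_from_r(0, 10), 1)
  expect_equal(pearson_p_from_r(0.4, 25), pearson_p_from_r(-0.4, 25))
  set.seed(12)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  ours <- pearson_test(x, y)
  ref <- cor.test(x, y)
  expect_equal(ours$r, unname(ref$estimate))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_error(pearson_test(rep(1, 10), rnorm(10)), "variance")
  # permutation oracle
  robs <- abs(cor(x, y))
  perm <- replicate(2000, abs(cor(x, sample(y))))
  p_perm <- mean(perm >= robs)
  expect_lt(abs(ours$p - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 2000) + 0.01)
})

test_that("the FDR table applies the rank-based critical values and strict rule", {
  one <- bh_fdr(0.01)
  expect_equal(one$q, 0.05)
  expect_true(one$significant)

  # step-up definitional oracle
  oracle_bh <- function(p, Q) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    ok <- ps < Q * seq_len(m) / m
    sig <- rep(FALSE, m)
    if (any(ok)) sig <- ps <= ps[max(which(ok))]
    out <- logical(m)
    out[o] <- sig
    out
  }
  aasp_like <- c(0.009, 0.010, 0.058, 0.068, 0.063, 0.071, 0.082, 0.095)
  tab <- bh_fdr(aasp_like, Q = 0.05)
  expect_identical(tab$significant, oracle_bh(aasp_like, 0.05))
  expect_identical(which(tab$significant), c(1L, 2L))

  set.seed(13)
  for (i in 1:20) {
    p <- round(runif(sample(3:20, 1))^2, 3)
    tab <- bh_fdr(p, Q = 0.05)
    expect_identical(tab$significant, oracle_bh(p, 0.05))
    # order invariance
    perm <- sample(seq_along(p))
    expect_identical(bh_fdr(p[perm])$significant, tab$significant[perm])
    # monotone in Q
    expect_true(all(tab$significant <= bh_fdr(p, Q = 0.2)$significant))
    # agreement with the standard step-up decisions away from exact equality
    padj <- p.adjust(p, method = "BH")
    if (!any(abs(sort(p) - 0.05 * seq_along(p) / length(p)) < 1e-12)) {
      expect_identical(tab$significant, unname(padj < 0.05))
    }
  }
})

test_that("tied p-values share the decision of the highest-ranked tied member", {
  # with ties straddling the last significant rank, all tied values share
  p <- c(0.01, 0.02, 0.02, 0.9)
  tab <- bh_fdr(p, Q = 0.05)
  expect_identical(tab$significant, c(TRUE, tab$significant[2],
                                      tab$significant[2], FALSE))
})
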