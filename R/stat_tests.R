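#' Pooled two-sample t-test from summary statistics
#'
#' Classical equal-variance (Student) two-sample t computed from group means,
#' SDs and sizes, with Cohen's d standardised by the pooled SD. The sign of
#' `t` follows `mean2 - mean1`.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1.
#' @param m2,sd2,n2 mean, SD and size of group 2.
#' @return List of class `"pooled_t"`: `t`, `df` (= n1 + n2 - 2), `p`
#'   (two-sided), `cohens_d` (absolute standardised difference), `pooled_sd`.
#' @examples
#' pooled_t_test(8.262, 1.563, 20, 8.375, 1.505, 19) # t(37) = 0.231
#' @export
pooled_t_test <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  if (sp == 0) {
    if (m1 == m2) {
      return(structure(list(t = 0, df = df, p = 1, cohens_d = 0, pooled_sd = 0),
                       class = "pooled_t"))
    }
    stop("zero pooled SD with unequal means: t is undefined")
  }
  tval <- (m2 - m1) / (sp * sqrt(1 / n1 + 1 / n2))
  structure(
    list(
      t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
      cohens_d = abs(m1 - m2) / sp, pooled_sd = sp
    ),
    class = "pooled_t"
  )
}

#' @export
print.pooled_t <- function(x, ...) {
  cat(sprintf("Pooled two-sample t: t(%d) = %.3f, p = %.3f, Cohen's d = %.2f\n",
              x$df, x$t, x$p, x$cohens_d))
  invisible(x)
}

#' Pooled t-test from raw group vectors
#'
#' @param x,y numeric vectors for the two groups.
#' @return Same as [pooled_t_test()].
#' @export
pooled_t_test_raw <- function(x, y) {
  pooled_t_test(mean(x), stats::sd(x), length(x),
                mean(y), stats::sd(y), length(y))
}

#' Mixed-design (split-plot) ANOVA with partial eta squared
#'
#' Two-by-K mixed ANOVA with one between-participant factor (group) and one
#' within-participant factor, using the standard univariate decomposition:
#' the between effect is tested against subjects-within-groups, the within
#' and interaction effects against the level-by-subjects-within-groups
#' residual. Partial eta squared is `SS_effect / (SS_effect + SS_error)` with
#' the error term of the effect's own stratum. Sums of squares are obtained
#' from [stats::aov()] with an `Error(participant)` stratum. No sphericity
#' correction is applied (uncorrected degrees of freedom are reported); this
#' is recorded in the result's `note`.
#'
#' @param data long-format data frame.
#' @param value,participant,group,within column names (strings) of the
#'   response, participant id, between factor and within factor.
#' @return Object of class `"mixed_anova"`: a data frame `effects` with one
#'   row per effect (`group`, `within`, `group:within`) carrying `F`,
#'   `df_num`, `df_den`, `p`, `partial_eta_sq`, `ss`, `ss_error`; plus
#'   `ss_total`, `ss_strata_sum`, `n_per_group`, `note`.
#' @examples
#' d <- expand.grid(participant = paste0("P", 1:6), site = c("palm", "neck"))
#' d$group <- ifelse(d$participant %in% paste0("P", 1:3), "asd", "td")
#' d$threshold <- rnorm(nrow(d), ifelse(d$site == "palm", 5, 35), 2)
#' mixed_anova(d, "threshold", "participant", "group", "site")
#' @export
mixed_anova <- function(data, value, participant, group, within) {
  d <- data.frame(
    y = data[[value]],
    id = factor(data[[participant]]),
    g = factor(data[[group]]),
    w = factor(data[[within]])
  )
  if (anyNA(d$y)) {
    i <- which(is.na(d$y))[1]
    stop("missing response for participant ", d$id[i], " at level ", d$w[i])
  }
  tab <- table(d$id, d$w)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)[1, ]
    stop("participant ", rownames(tab)[bad[1]], " does not have exactly one ",
         "observation at level ", colnames(tab)[bad[2]])
  }
  gtab <- table(unique(d[, c("id", "g")])$g)
  if (any(gtab < 2)) stop("need >= 2 participants per group")

  fit <- stats::aov(y ~ g * w + Error(id), data = d)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: id"]][[1]])
  within_s <- as.data.frame(sm[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(between))
  rn_w <- trimws(rownames(within_s))

  pull <- function(stratum, rn, eff) {
    i <- match(eff, rn)
    r <- match("Residuals", rn)
    ss_e <- stratum[i, "Sum Sq"]
    ss_r <- stratum[r, "Sum Sq"]
    data.frame(
      effect = eff,
      F = stratum[i, "F value"],
      df_num = stratum[i, "Df"], df_den = stratum[r, "Df"],
      p = stratum[i, "Pr(>F)"],
      partial_eta_sq = ss_e / (ss_e + ss_r),
      ss = ss_e, ss_error = ss_r
    )
  }
  effects <- rbind(
    pull(between, rn_b, "g"),
    pull(within_s, rn_w, "w"),
    pull(within_s, rn_w, "g:w")
  )
  effects$effect <- c("group", "within", "group:within")

  ss_total <- sum((d$y - mean(d$y))^2)
  ss_strata <- sum(between$`Sum Sq`) + sum(within_s$`Sum Sq`)
  structure(
    list(
      effects = effects, ss_total = ss_total, ss_strata_sum = ss_strata,
      n_per_group = as.integer(gtab),
      note = "uncorrected dfs; no sphericity correction applied"
    ),
    class = "mixed_anova"
  )
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Mixed-design ANOVA (between group x within factor)\n")
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-14s F(%d, %d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
                e$effect[i], e$df_num[i], e$df_den[i], e$F[i], e$p[i],
                e$partial_eta_sq[i]))
  }
  invisible(x)
}

#' Bonferroni-corrected pairwise paired t-tests across within levels
#'
#' One paired t-test per level pair, with each p-value multiplied by the
#' number of pairs (capped at 1).
#'
#' @param data long-format data frame.
#' @param value,participant,within column names (strings).
#' @param alpha significance level applied to the adjusted p.
#' @return Data frame: `level1`, `level2`, `t`, `df`, `p_raw`, `p_adjusted`,
#'   `significant`, with attribute `n_comparisons`.
#' @export
bonferroni_pairwise <- function(data, value, participant, within,
                                alpha = 0.05) {
  d <- data.frame(y = data[[value]], id = data[[participant]],
                  w = factor(data[[within]]))
  levs <- levels(d$w)
  if (length(levs) < 2) stop("need >= 2 within levels")
  pairs <- utils::combn(levs, 2)
  k <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(k), function(j) {
    a <- d[d$w == pairs[1, j], ]
    b <- d[d$w == pairs[2, j], ]
    b <- b[match(a$id, b$id), ]
    tt <- stats::t.test(a$y, b$y, paired = TRUE)
    data.frame(
      level1 = pairs[1, j], level2 = pairs[2, j],
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value, p_adjusted = min(1, tt$p.value * k)
    )
  }))
  out$significant <- out$p_adjusted < alpha
  attr(out, "n_comparisons") <- k
  out
}

#' Mann-Whitney U with normal approximation
#'
#' Rank-sum U statistic (midranks for ties) with the large-sample z
#' approximation
#' \deqn{z = (U - n_1 n_2 / 2) / \sqrt{n_1 n_2 (n_1 + n_2 + 1) / 12}}
#' optionally with the tie correction to the variance and/or a continuity
#' correction. `U` is reported for the first sample; `U + U' = n1 * n2`.
#'
#' @param x,y numeric samples.
#' @param tie_correction apply the midrank tie correction to the variance
#'   (default `TRUE`).
#' @param continuity apply a 0.5 continuity correction (default `FALSE`).
#' @return List of class `"mwu"`: `U`, `U_other`, `z`, `p` (two-sided,
#'   normal), `n1`, `n2`.
#' @export
mann_whitney <- function(x, y, tie_correction = TRUE, continuity = FALSE) {
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  z <- mwu_z_from_u(U, n1, n2,
                    ties = if (tie_correction) table(c(x, y)) else NULL,
                    continuity = continuity)
  structure(
    list(U = U, U_other = n1 * n2 - U, z = z,
         p = 2 * stats::pnorm(-abs(z)), n1 = n1, n2 = n2),
    class = "mwu"
  )
}

#' Normal-approximation z (and p) for a given U
#'
#' Reproduces the z statistic from a published U and the group sizes, with or
#' without tie information.
#'
#' @param U Mann-Whitney U statistic.
#' @param n1,n2 group sizes.
#' @param ties optional table of tied-value counts (as from `table(c(x, y))`)
#'   for the variance tie correction; `NULL` for the no-ties variance.
#' @param continuity apply a 0.5 continuity correction.
#' @return The z value.
#' @examples
#' mwu_z_from_u(164.5, 16, 15) # ~1.759
#' @export
mwu_z_from_u <- function(U, n1, n2, ties = NULL, continuity = FALSE) {
  N <- n1 + n2
  v <- n1 * n2 * (N + 1) / 12
  if (!is.null(ties)) {
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  }
  num <- U - n1 * n2 / 2
  if (continuity) num <- num - sign(num) * 0.5
  num / sqrt(v)
}

#' @export
print.mwu <- function(x, ...) {
  cat(sprintf("Mann-Whitney: U = %g, z = %.3f, p = %.3f (n1 = %d, n2 = %d)\n",
              x$U, x$z, x$p, x$n1, x$n2))
  invisible(x)
}

#' Pearson correlation with t-transform p-value
#'
#' @param x,y numeric vectors (pairwise complete, n >= 3, nonzero variance).
#' @return List of class `"pearson_r"`: `r`, `n`, `p` (two-sided).
#' @export
pearson_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  r <- stats::cor(x, y)
  structure(list(r = r, n = n, p = pearson_p_from_r(r, n)),
            class = "pearson_r")
}

#' Two-sided p-value from a correlation coefficient
#'
#' Uses the exact-null t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on
#' `n - 2` degrees of freedom.
#'
#' @param r correlation (|r| < 1).
#' @param n sample size (>= 3).
#' @return Two-sided p-value.
#' @examples
#' pearson_p_from_r(0.558, 31) # ~0.001
#' @export
pearson_p_from_r <- function(r, n) {
  stopifnot(n >= 3, abs(r) < 1)
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tval), n - 2)
}

#' @export
print.pearson_r <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, n = %d, p = %.4g\n", x$r, x$n, x$p))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR table (rank/critical-value form)
#'
#' Implements the rank-based formulation: with the p-values sorted ascending,
#' the critical value of the i-th is `q = Q * i / m`. The largest p-value
#' with `p < q` (strict), and every smaller p-value, is declared significant.
#' Tied p-values share the decision of the highest-ranked tied member.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param Q target false discovery rate (default 0.05).
#' @return Data frame in the input order: `p`, `rank` (ascending-p rank),
#'   `m`, `q` (critical value), `significant`.
#' @examples
#' bh_fdr(c(0.001, 0.003, 0.0005, 0.04, 0.2))
#' @export
bh_fdr <- function(p_values, Q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1), Q >= 0)
  m <- length(p_values)
  ord <- order(p_values)
  p_sorted <- p_values[ord]
  q_sorted <- Q * seq_len(m) / m
  below <- p_sorted < q_sorted
  sig_sorted <- rep(FALSE, m)
  if (any(below)) {
    cutoff <- p_sorted[max(which(below))]
    sig_sorted <- p_sorted <= cutoff
  }
  rank <- integer(m)
  rank[ord] <- seq_len(m)
  out <- data.frame(p = p_values, rank = rank, m = m,
                    q = Q * rank / m, significant = FALSE)
  out$significant[ord] <- sig_sorted
  out
}
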