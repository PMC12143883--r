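#' Statistical result container
#'
#' All tests in the package return this shape: one row per model term in
#' `terms` (single tests have one row), plus an optional post-hoc table.
#' Degrees of freedom may be non-integer after a sphericity correction;
#' `epsilon` is the Greenhouse-Geisser factor (1 when no correction
#' applies).
#'
#' @param test Test name.
#' @param terms data.frame with `term`, `statistic`, `df1`, `df2`,
#'   `epsilon`, `p`.
#' @param posthoc Optional data.frame with `contrast`, `p_raw`, `p_adj`,
#'   `method`.
#' @return Object of class `stat_result`.
#' @export
stat_result <- function(test, terms, posthoc = NULL) {
  stopifnot(is.data.frame(terms))
  structure(list(test = test, terms = terms, posthoc = posthoc),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$test, "\n")
  t <- x$terms
  for (i in seq_len(nrow(t))) {
    df <- if (is.na(t$df2[i])) sprintf("(%.4g)", t$df1[i]) else
      sprintf("(%.4g, %.4g)", t$df1[i], t$df2[i])
    cat(sprintf("  %s: stat %s = %.4g, p = %.4g\n",
                t$term[i], df, t$statistic[i], t$p[i]))
  }
  if (!is.null(x$posthoc) && nrow(x$posthoc)) {
    cat("  post-hoc (", x$posthoc$method[1], "):\n", sep = "")
    for (i in seq_len(nrow(x$posthoc))) {
      cat(sprintf("    %s: p_adj = %.4g\n",
                  x$posthoc$contrast[i], x$posthoc$p_adj[i]))
    }
  }
  invisible(x)
}

one_term <- function(term, statistic, df1, df2, p, epsilon = NA_real_) {
  data.frame(term = term, statistic = statistic, df1 = df1, df2 = df2,
             epsilon = epsilon, p = p)
}

#' Two-sample and paired t tests
#'
#' Classic two-tailed t tests with the sign convention mean(x) - mean(y).
#' The unpaired version uses pooled variance, df = n1 + n2 - 2 (the df
#' convention that matches reported group sizes in this literature, ruling
#' out Welch). Degenerate zero-variance, zero-difference data yield t = 0,
#' p = 1 rather than an error.
#'
#' @param x,y Numeric samples; equal length for `paired_t`.
#' @return A [stat_result()].
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(stat_result("paired t",
                         one_term("x - y", 0, length(x) - 1, NA, 1)))
    }
    return(stat_result("paired t",
                       one_term("x - y", sign(mean(d)) * Inf,
                                length(x) - 1, NA, 0)))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  stat_result("paired t",
              one_term("x - y", unname(tt$statistic),
                       unname(tt$parameter), NA, tt$p.value))
}

#' @rdname paired_t
#' @export
unpaired_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  df <- length(x) + length(y) - 2
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) / df
  if (sp2 == 0) {
    d <- mean(x) - mean(y)
    t <- if (d == 0) 0 else sign(d) * Inf
    return(stat_result("unpaired t",
                       one_term("x - y", t, df, NA, if (d == 0) 1 else 0)))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  stat_result("unpaired t",
              one_term("x - y", unname(tt$statistic),
                       unname(tt$parameter), NA, tt$p.value))
}

# Orthonormal basis of the (k-1)-dim space orthogonal to the unit vector.
orthonormal_contrasts <- function(k) {
  qr_ <- qr(cbind(rep(1, k), stats::contr.helmert(k)))
  t(qr.Q(qr_)[, -1, drop = FALSE])
}

# Greenhouse-Geisser epsilon from a k x k covariance matrix of level scores.
# A degenerate (all-zero-contrast-variance) matrix counts as spherical.
gg_epsilon <- function(S) {
  k <- nrow(S)
  D <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  if (sum(D^2) <= .Machine$double.eps * max(1, sum(diag(S))^2)) return(1)
  eps <- sum(diag(D))^2 / ((k - 1) * sum(D^2))
  min(max(eps, 1 / (k - 1)), 1)
}

# F ratio with explicit zero-numerator / zero-denominator conventions.
safe_f <- function(ss_h, df_h, ss_e, df_e) {
  if (ss_h <= 0) return(0)
  if (ss_e <= 0) return(Inf)
  (ss_h / df_h) / (ss_e / df_e)
}

# Long table -> wide subject x level matrix, erroring on incomplete designs.
table_to_wide <- function(table, value, within, subject) {
  subj <- as.character(table[[subject]])
  lev <- as.character(table[[within]])
  levels_ <- unique(lev)
  subjects_ <- unique(subj)
  wide <- matrix(NA_real_, length(subjects_), length(levels_),
                 dimnames = list(subjects_, levels_))
  wide[cbind(match(subj, subjects_), match(lev, levels_))] <- table[[value]]
  if (anyNA(wide)) {
    bad <- subjects_[apply(wide, 1, anyNA)]
    stop("incomplete within-subject design; missing cells for subject(s): ",
         paste(bad, collapse = ", "))
  }
  wide
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Standard within-subject F from the subject x level sums-of-squares
#' decomposition. The Greenhouse-Geisser epsilon is computed from the sample
#' covariance of the level scores and applied to both degrees of freedom
#' (reported always, even when epsilon = 1, matching the SPSS-style
#' "F (2.000, 12.00)" reporting convention). Post-hoc: all pairwise paired
#' t tests with Sidak adjustment.
#'
#' @param table Long-format data.frame.
#' @param value,within,subject Column names of the response, the
#'   within-subject factor, and the subject identifier.
#' @param posthoc Run pairwise comparisons?
#' @return A [stat_result()] with term `within`.
#' @export
rm_anova_gg <- function(table, value = "value", within = "condition",
                        subject = "subject", posthoc = TRUE) {
  wide <- table_to_wide(table, value, within, subject)
  n <- nrow(wide)
  k <- ncol(wide)
  stopifnot(n >= 2, k >= 2)
  gm <- mean(wide)
  lev_m <- colMeans(wide)
  subj_m <- rowMeans(wide)
  ss_cond <- n * sum((lev_m - gm)^2)
  resid <- sweep(sweep(wide, 2, lev_m), 1, subj_m) + gm
  ss_err <- sum(resid^2)
  eps <- gg_epsilon(stats::cov(wide))
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  f <- safe_f(ss_cond, df1, ss_err, df2)
  p <- stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE)
  ph <- NULL
  if (posthoc && k >= 2) {
    prs <- utils::combn(colnames(wide), 2)
    m <- ncol(prs)
    raw <- vapply(seq_len(m), function(i) {
      paired_t(wide[, prs[1, i]], wide[, prs[2, i]])$terms$p
    }, numeric(1))
    ph <- data.frame(contrast = paste(prs[1, ], "vs", prs[2, ]),
                     p_raw = raw, p_adj = sidak_adjust(raw, m),
                     method = "Sidak")
  }
  stat_result("one-way RM ANOVA (GG)",
              one_term(within, f, eps * df1, eps * df2, p, eps), ph)
}

#' Mixed (split-plot) ANOVA with Greenhouse-Geisser correction
#'
#' One between-subjects factor crossed with one complete within-subjects
#' factor. The between effect is tested against subjects-within-groups; the
#' within effect and the interaction are tested against the within-subjects
#' error, with GG epsilon computed from the pooled within-group covariance
#' of the level scores and applied to the within-term dfs. Unbalanced group
#' sizes are handled with the Type III (unweighted-marginal-means)
#' convention for the within main effect.
#'
#' @param table Long-format data.frame.
#' @param value,between,within,subject Column names.
#' @param posthoc Run Sidak-adjusted simple-effect comparisons of the
#'   between groups at each within level?
#' @return A [stat_result()] with terms `between`, `within`,
#'   `between:within`.
#' @export
mixed_anova <- function(table, value = "value", between = "group",
                        within = "condition", subject = "subject",
                        posthoc = TRUE) {
  grp_of <- tapply(as.character(table[[between]]),
                   as.character(table[[subject]]),
                   function(g) unique(g)[1])
  wide <- table_to_wide(table, value, within, subject)
  grp <- factor(unname(grp_of[rownames(wide)]))
  G <- nlevels(grp)
  n_g <- as.numeric(table(grp))
  N <- nrow(wide)
  k <- ncol(wide)
  stopifnot(G >= 2, k >= 2, all(n_g >= 2))

  # between-subjects stratum, on subject means (scaled by k)
  subj_m <- rowMeans(wide)
  gmean_w <- mean(subj_m)
  g_m <- tapply(subj_m, grp, mean)
  ss_group <- k * sum(n_g * (g_m[levels(grp)] - gmean_w)^2)
  ss_serr <- k * sum((subj_m - g_m[grp])^2)
  f_group <- safe_f(ss_group, G - 1, ss_serr, N - G)
  p_group <- stats::pf(f_group, G - 1, N - G, lower.tail = FALSE)

  # within-subjects stratum via orthonormal contrast scores
  M <- orthonormal_contrasts(k)
  Z <- wide %*% t(M)                      # N x (k-1)
  zg <- apply(Z, 2, function(z) tapply(z, grp, mean))  # G x (k-1)
  zg <- matrix(zg, nrow = G)
  u <- colMeans(zg)                        # unweighted grand contrast mean
  n_h <- G / sum(1 / n_g)
  ss_within <- G * n_h * sum(u^2)
  zw <- apply(Z, 2, function(z) tapply(z, grp, mean)[grp])
  ss_int <- sum(n_g * sweep(zg, 2, colSums(n_g * zg) / N)^2)
  ss_werr <- sum((Z - matrix(zw, nrow = N))^2)
  df_w <- k - 1
  df_i <- (G - 1) * (k - 1)
  df_e <- (N - G) * (k - 1)

  # pooled within-group covariance of level scores
  Sp <- Reduce(`+`, lapply(levels(grp), function(g) {
    (sum(grp == g) - 1) * stats::cov(wide[grp == g, , drop = FALSE])
  })) / (N - G)
  eps <- gg_epsilon(Sp)

  f_w <- safe_f(ss_within, df_w, ss_werr, df_e)
  f_i <- safe_f(ss_int, df_i, ss_werr, df_e)
  p_w <- stats::pf(f_w, eps * df_w, eps * df_e, lower.tail = FALSE)
  p_i <- stats::pf(f_i, eps * df_i, eps * df_e, lower.tail = FALSE)

  terms <- rbind(
    one_term(between, f_group, G - 1, N - G, p_group, NA_real_),
    one_term(within, f_w, eps * df_w, eps * df_e, p_w, eps),
    one_term(paste0(between, ":", within), f_i, eps * df_i, eps * df_e,
             p_i, eps))

  ph <- NULL
  if (posthoc) {
    cmp <- list()
    for (g in levels(grp)) {
      if (k == 2) {
        sub <- wide[grp == g, , drop = FALSE]
        r <- paired_t(sub[, 1], sub[, 2])
        cmp[[paste0(g, ": ", colnames(wide)[1], " vs ",
                    colnames(wide)[2])]] <- r$terms$p
      }
    }
    for (j in colnames(wide)) {
      if (G == 2) {
        a <- wide[grp == levels(grp)[1], j]
        b <- wide[grp == levels(grp)[2], j]
        cmp[[paste0(j, ": ", levels(grp)[1], " vs ",
                    levels(grp)[2])]] <- unpaired_t(a, b)$terms$p
      }
    }
    if (length(cmp)) {
      raw <- unlist(cmp)
      ph <- data.frame(contrast = names(cmp), p_raw = raw,
                       p_adj = sidak_adjust(raw, length(raw)),
                       method = "Sidak", row.names = NULL)
    }
  }
  stat_result("two-way RM (mixed) ANOVA (GG)", terms, ph)
}

#' Two-way between-subjects ANOVA (Type III)
#'
#' Fits `value ~ f1 * f2` with sum-to-zero contrasts and reports Type III
#' sums of squares (the convention under which the reported statistics of
#' unbalanced chemogenetic designs are reproducible). Post-hoc: Sidak-
#' adjusted pairwise comparisons of `f1` levels within each `f2` level.
#'
#' @param table Long-format data.frame.
#' @param value,f1,f2 Column names.
#' @param posthoc Run simple-effect comparisons?
#' @return A [stat_result()] with terms `f1`, `f2`, `f1:f2`.
#' @export
two_way_anova <- function(table, value = "value", f1 = "group",
                          f2 = "treatment", posthoc = TRUE) {
  d <- data.frame(y = table[[value]],
                  a = factor(table[[f1]]),
                  b = factor(table[[f2]]))
  if (any(table(d$a, d$b) == 0)) {
    stop("empty design cell(s) under Type III: ",
         paste(which(table(d$a, d$b) == 0), collapse = ", "))
  }
  fit <- stats::lm(y ~ a * b, data = d,
                   contrasts = list(a = "contr.sum", b = "contr.sum"))
  an <- car::Anova(fit, type = "III")
  rn <- rownames(an)
  pick <- function(nm) {
    i <- match(nm, rn)
    one_term(nm, an[i, "F value"], an[i, "Df"], an["Residuals", "Df"],
             an[i, "Pr(>F)"])
  }
  terms <- rbind(pick("a"), pick("b"), pick("a:b"))
  terms$term <- c(f1, f2, paste0(f1, ":", f2))
  ph <- NULL
  if (posthoc && nlevels(d$b) == 2) {
    lv <- levels(d$b)
    raw <- vapply(levels(d$a), function(g) {
      unpaired_t(d$y[d$a == g & d$b == lv[1]],
                 d$y[d$a == g & d$b == lv[2]])$terms$p
    }, numeric(1))
    ph <- data.frame(contrast = paste0(levels(d$a), ": ", lv[1], " vs ", lv[2]),
                     p_raw = raw, p_adj = sidak_adjust(raw, length(raw)),
                     method = "Sidak", row.names = NULL)
  }
  stat_result("two-way ANOVA (Type III)", terms, ph)
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to `[0, 1]`.
#'
#' @param p Raw p-value(s).
#' @param m Family size (number of comparisons).
#' @return Adjusted p-value(s).
#' @export
#' @examples
#' sidak_adjust(0.01, 3)  # 0.029701
sidak_adjust <- function(p, m) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1))
  pmin(pmax(1 - (1 - p)^m, 0), 1)
}

#' Kruskal-Wallis test with Dunn post-hoc
#'
#' Tie-corrected H with a chi-square reference (df = groups - 1). Post-hoc
#' follow-up uses Dunn's z on mean ranks with the same tie correction,
#' Sidak-adjusted over all pairs.
#'
#' @param groups Named list of numeric vectors (one per group).
#' @param posthoc Run Dunn comparisons?
#' @return A [stat_result()].
#' @export
kruskal_wallis <- function(groups, posthoc = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(x)) == 1L) {
    return(stat_result("Kruskal-Wallis",
                       one_term("group", 0, length(groups) - 1, NA, 1)))
  }
  kt <- stats::kruskal.test(x, g)
  ph <- NULL
  if (posthoc) {
    N <- length(x)
    r <- rank(x)
    rbar <- tapply(r, g, mean)
    n_g <- as.numeric(table(g))
    ties <- table(x)
    tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
    v0 <- N * (N + 1) / 12 - tie_term
    prs <- utils::combn(seq_along(groups), 2)
    m <- ncol(prs)
    raw <- vapply(seq_len(m), function(i) {
      a <- prs[1, i]; b <- prs[2, i]
      z <- (rbar[a] - rbar[b]) / sqrt(v0 * (1 / n_g[a] + 1 / n_g[b]))
      2 * stats::pnorm(abs(z), lower.tail = FALSE)
    }, numeric(1))
    ph <- data.frame(
      contrast = paste(names(groups)[prs[1, ]], "vs", names(groups)[prs[2, ]]),
      p_raw = raw, p_adj = sidak_adjust(raw, m), method = "Dunn-Sidak")
  }
  stat_result("Kruskal-Wallis",
              one_term("group", unname(kt$statistic),
                       unname(kt$parameter), NA, kt$p.value), ph)
}

#' Normality and homogeneity-of-variance checks
#'
#' One-sample Kolmogorov-Smirnov test of each sample against a normal with
#' its own mean and sd, plus (when groups are supplied) the Brown-Forsythe
#' variant of Levene's test (absolute deviations from group medians).
#' Constant samples are degenerate and flagged rather than tested.
#'
#' @param x Numeric sample, or all values when `groups` is given.
#' @param groups Optional factor of group membership for the Levene test.
#' @return data.frame with `ks_p`, `levene_p` (NA if no groups),
#'   `degenerate`.
#' @export
assumption_checks <- function(x, groups = NULL) {
  stopifnot(length(x) >= 3)
  if (stats::sd(x) == 0) {
    return(data.frame(ks_p = NA_real_, levene_p = NA_real_,
                      degenerate = TRUE))
  }
  ks <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  lev <- NA_real_
  if (!is.null(groups)) {
    lt <- car::leveneTest(x, factor(groups), center = stats::median)
    lev <- lt[1, "Pr(>F)"]
  }
  data.frame(ks_p = ks$p.value, levene_p = lev, degenerate = FALSE)
}
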