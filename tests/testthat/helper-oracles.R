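# Independent oracles used to check the package's implementations.
# These are deliberately naive (explicit loops, direct formulas) and share
# no code with the functions they validate.

# Brute-force within-subject ANOVA by explicit sums over cells.
oracle_rm_anova <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  gm <- mean(Y)
  ss_cond <- 0
  for (j in 1:k) ss_cond <- ss_cond + n * (mean(Y[, j]) - gm)^2
  ss_err <- 0
  for (i in 1:n) for (j in 1:k) {
    ss_err <- ss_err + (Y[i, j] - mean(Y[, j]) - mean(Y[i, ]) + gm)^2
  }
  (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
}

# Brute-force split-plot ANOVA F statistics for balanced groups.
oracle_mixed_anova <- function(Y, grp) {
  grp <- factor(grp)
  G <- nlevels(grp); N <- nrow(Y); k <- ncol(Y)
  gm <- mean(Y)
  cell <- matrix(0, G, k)
  for (g in 1:G) for (j in 1:k) cell[g, j] <- mean(Y[grp == levels(grp)[g], j])
  ng <- as.numeric(table(grp))
  gmean <- rowMeans(cell)
  lmean <- colMeans(Y)
  subj <- rowMeans(Y)
  ss_group <- k * sum(ng * (gmean - gm)^2)
  ss_serr <- 0
  for (i in 1:N) ss_serr <- ss_serr + k * (subj[i] - gmean[as.integer(grp[i])])^2
  ss_time <- N * sum((lmean - gm)^2)
  ss_int <- 0
  for (g in 1:G) for (j in 1:k) {
    ss_int <- ss_int + ng[g] * (cell[g, j] - gmean[g] - lmean[j] + gm)^2
  }
  ss_werr <- 0
  for (i in 1:N) for (j in 1:k) {
    g <- as.integer(grp[i])
    ss_werr <- ss_werr +
      (Y[i, j] - cell[g, j] - subj[i] + gmean[g])^2
  }
  c(group = (ss_group / (G - 1)) / (ss_serr / (N - G)),
    time = (ss_time / (k - 1)) / (ss_werr / ((N - G) * (k - 1))),
    interaction = (ss_int / ((G - 1) * (k - 1))) /
      (ss_werr / ((N - G) * (k - 1))))
}

# Kruskal-Wallis H from first principles (tie-corrected).
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  h <- 0
  i0 <- 0
  for (g in groups) {
    rg <- r[(i0 + 1):(i0 + length(g))]
    h <- h + length(g) * (mean(rg) - (N + 1) / 2)^2
    i0 <- i0 + length(g)
  }
  h <- 12 * h / (N * (N + 1))
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Closed-form number of LIF spikes in a constant-current step; `paint_s` is
# the simulator's painted spike width (integration pauses during it).
oracle_lif_count <- function(I_pA, lif, duration_s, paint_s = 0.0005) {
  R <- lif[["R_MOhm"]] / 1000
  tau <- lif[["tau_m_ms"]] / 1000
  drive <- R * I_pA
  th <- lif[["V_thresh_mV"]] - lif[["V_rest_mV"]]
  re <- lif[["V_reset_mV"]] - lif[["V_rest_mV"]]
  if (drive <= th) return(0L)
  t_first <- tau * log(drive / (drive - th))
  t_isi <- tau * log((drive - re) / (drive - th)) + paint_s
  if (t_first > duration_s) return(0L)
  1L + floor((duration_s - t_first) / t_isi)
}

# Greedy one-to-one matching of detections to ground-truth onsets.
match_events <- function(det_s, true_s, tol_s = 0.002) {
  used <- rep(FALSE, length(det_s))
  tp <- 0L
  for (t in true_s) {
    d <- abs(det_s - t)
    if (any(used)) d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = sum(!used), fn = length(true_s) - tp)
}

# Small long-format table builder for ANOVA tests.
wide_to_long <- function(Y, grp = NULL) {
  n <- nrow(Y); k <- ncol(Y)
  d <- data.frame(subject = rep(seq_len(n), k),
                  condition = rep(paste0("c", seq_len(k)), each = n),
                  value = c(Y))
  if (!is.null(grp)) d$group <- rep(grp, k)
  d
}
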