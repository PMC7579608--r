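# shared fixtures and independent oracles, built in code at test time

fix_montage <- make_montage(32)
fix_templates <- make_canonical_templates(fix_montage)

# segmentation with hand-set labels/correlations/gfp, one epoch per column
toy_segmentation <- function(labels, best_corr = NULL, gfp = NULL, fs = 125,
                             class_labels = c("A", "B", "C", "D")) {
  labels <- as.matrix(labels)
  if (is.null(best_corr)) best_corr <- matrix(1, nrow(labels), ncol(labels))
  if (is.null(gfp)) gfp <- matrix(1, nrow(labels), ncol(labels))
  microstatr:::new_segmentation(labels, as.matrix(best_corr), as.matrix(gfp),
                                fs, class_labels)
}

# four mutually orthogonal average-referenced generator maps over n channels
orthogonal_generators <- function(n_ch = 32, seed = 99) {
  set.seed(seed)
  raw <- matrix(rnorm(n_ch * 5), n_ch, 5)
  raw <- sweep(raw, 2, colMeans(raw))
  q <- qr.Q(qr(raw))[, 2:5]       # orthogonal, ~zero-mean columns
  q <- sweep(q, 2, colMeans(q))
  apply(q, 2, function(v) v / sqrt(sum(v^2)))
}

# brute-force mixed-ANOVA oracle: explicit cell/subject-mean sums of squares
# (independent of mixed_anova_2x2's internals)
anova_ss_oracle <- function(tab) {
  w <- reshape(data.frame(participant = tab$participant, group = tab$group,
                          condition = tab$condition, y = tab$value),
               idvar = c("participant", "group"), timevar = "condition",
               direction = "wide")
  y <- as.matrix(w[, 3:4])
  g <- w$group
  N <- nrow(y)
  grand <- mean(y)
  ss_group <- 0; ss_cond <- 0; ss_int <- 0; ss_subj <- 0; ss_werr <- 0
  gm <- tapply(rowMeans(y), g, mean)
  cm <- colMeans(y)
  for (gg in unique(g)) {
    ng <- sum(g == gg)
    ss_group <- ss_group + 2 * ng * (gm[[gg]] - grand)^2
    for (cc in 1:2) {
      cell <- mean(y[g == gg, cc])
      ss_int <- ss_int + ng * (cell - cm[cc] - gm[[gg]] + grand)^2
    }
  }
  for (cc in 1:2) ss_cond <- ss_cond + N * (cm[cc] - grand)^2
  for (s in seq_len(N)) {
    ss_subj <- ss_subj + 2 * (mean(y[s, ]) - gm[[g[s]]])^2
    for (cc in 1:2) {
      cell <- mean(y[g == g[s], cc])
      ss_werr <- ss_werr + (y[s, cc] - mean(y[s, ]) - cell + gm[[g[s]]])^2
    }
  }
  df2 <- N - 2
  list(F_group = (ss_group / 1) / (ss_subj / df2),
       F_cond = (ss_cond / 1) / (ss_werr / df2),
       F_int = (ss_int / 1) / (ss_werr / df2),
       ss = c(group = ss_group, subj = ss_subj, cond = ss_cond,
              int = ss_int, werr = ss_werr))
}

# noncentral-F tail by Poisson-weighted central-beta series (oracle for
# observed_power; independent of pf(..., ncp))
power_series_oracle <- function(f, df1, df2, alpha = 0.05) {
  fcrit <- qf(1 - alpha, df1, df2)
  lam <- f * df1
  j <- 0:500
  sum(dpois(j, lam / 2) *
        pbeta(df1 * fcrit / (df1 * fcrit + df2), df1 / 2 + j, df2 / 2,
              lower.tail = FALSE))
}

# exhaustive assignment oracle for template sorting, enumerated via
# expand.grid (a different mechanism than the package's recursion)
sort_oracle_score <- function(tpl_maps, norm_maps) {
  K <- ncol(norm_maps)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
  grid <- grid[apply(grid, 1, function(r) length(unique(r)) == K), , drop = FALSE]
  R <- abs(cor(tpl_maps, norm_maps))
  best <- -Inf; best_perm <- NULL
  for (i in seq_len(nrow(grid))) {
    sc <- sum(R[cbind(grid[i, ], seq_len(K))])
    if (sc > best) { best <- sc; best_perm <- grid[i, ] }
  }
  list(score = best, perm = unname(best_perm), n_perms = nrow(grid))
}
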