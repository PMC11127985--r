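# Independent brute-force oracles, deliberately written as plain loops over
# voxels/pairs so they share no code path with the package implementations.

oracle_overlap <- function(pred, ref) {
  p <- as.vector(pred$data); r <- as.vector(ref$data)
  inter <- 0; np <- 0; nr <- 0; uni <- 0
  for (i in seq_along(p)) {
    if (p[i]) np <- np + 1
    if (r[i]) nr <- nr + 1
    if (p[i] && r[i]) inter <- inter + 1
    if (p[i] || r[i]) uni <- uni + 1
  }
  list(dsc = 2 * inter / (np + nr), jc = inter / uni)
}

# surface voxels the slow way: any 6-neighbor missing or out of bounds
oracle_surface <- function(mask) {
  d <- dim(mask$data)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask$data[i, j, k]) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    is_surf <- FALSE
    for (m in 1:6) {
      p <- nb[m, ]
      if (any(p < 1) || any(p > d) || !mask$data[p[1], p[2], p[3]])
        is_surf <- TRUE
    }
    if (is_surf) out <- rbind(out, c(i, j, k))
  }
  out
}

oracle_surface_metrics <- function(pred, ref) {
  sp <- pred$spacing_mm
  sa <- oracle_surface(pred); sb <- oracle_surface(ref)
  pa <- sweep(sa - 1, 2, sp, `*`); pb <- sweep(sb - 1, 2, sp, `*`)
  nn <- function(from, to) {
    apply(from, 1, function(q)
      sqrt(min(colSums((t(to) - q)^2))))
  }
  dab <- nn(pa, pb); dba <- nn(pb, pa)
  list(hd_mm = max(c(dab, dba)),
       assd_mm = (sum(dab) + sum(dba)) / (length(dab) + length(dba)))
}

# AUC as the fraction of concordant positive/negative pairs (ties count 1/2);
# "score" oriented so that higher = more positive
oracle_auc <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# ICC(2,1) from two-way ANOVA mean squares fitted with stats::aov
oracle_icc21 <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  df <- data.frame(score = as.vector(mat),
                   subj = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(score ~ subj + rater, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# two-sample Kolmogorov-Smirnov: explicit ECDF supremum plus the asymptotic
# Kolmogorov series for the p-value
oracle_ks <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  d <- max(abs(fa - fb))
  en <- sqrt(length(a) * length(b) / (length(a) + length(b)))
  t <- en * d
  kterms <- vapply(1:100, function(k) (-1)^(k - 1) * exp(-2 * k^2 * t^2),
                   numeric(1))
  list(statistic = d, p_value = min(1, max(0, 2 * sum(kterms))))
}

# Spearman via explicit average ranks + Pearson formula
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      less <- sum(v < v[i]); eq <- sum(v == v[i])
      r[i] <- less + (eq + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exhaustive count of lattice pixel centers within radius_mm of a center
oracle_disc_pixel_count <- function(radius_mm, spacing) {
  half <- ceiling(radius_mm / min(spacing)) + 2
  count <- 0
  for (di in -half:half) for (dj in -half:half) {
    if ((di * spacing[1])^2 + (dj * spacing[2])^2 <= radius_mm^2 + 1e-9)
      count <- count + 1
  }
  count
}
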