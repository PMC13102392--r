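# Shared fixtures and independent oracles. Oracles are deliberately naive
# (brute force / closed form) and never call the implementation they check.

# filled disc of given radius (pixels) as a label matrix
make_disc <- function(radius_px, label = 1L, pad = 2L) {
  n <- 2L * (radius_px + pad) + 1L
  ctr <- radius_px + pad + 0.5
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if ((i - ctr)^2 + (j - ctr)^2 <= radius_px^2) m[i, j] <- label
  }
  m
}

# random 4-connected blob grown from a seed pixel
make_blob <- function(n_px, seed, label = 1L, dim = 64L) {
  set.seed(seed)
  m <- matrix(0L, dim, dim)
  r <- dim %/% 2L; c <- dim %/% 2L
  m[r, c] <- label
  frontier <- matrix(c(r, c), ncol = 2)
  while (sum(m == label) < n_px) {
    k <- sample(nrow(frontier), 1)
    sh <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))[sample(4, 1), ]
    nr <- frontier[k, 1] + sh[1]; nc <- frontier[k, 2] + sh[2]
    if (nr >= 1 && nr <= dim && nc >= 1 && nc <= dim && m[nr, nc] == 0L) {
      m[nr, nc] <- label
      frontier <- rbind(frontier, c(nr, nc))
    }
  }
  m
}

# O(n^2) all-pairs oracle over pixel corner points
brute_feret <- function(rc, pixel_size = 1) {
  xs <- c(rc[, 2] - 1, rc[, 2], rc[, 2] - 1, rc[, 2])
  ys <- c(rc[, 1] - 1, rc[, 1] - 1, rc[, 1], rc[, 1])
  best <- 0
  for (i in seq_along(xs)) {
    d2 <- (xs - xs[i])^2 + (ys - ys[i])^2
    best <- max(best, max(d2))
  }
  sqrt(best) * pixel_size
}

# O(n*m) ECDF-sweep oracle for the two-sample KS statistic
brute_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# hand BH step-up (sort, p * n / rank, cumulative min from the largest)
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# direct Welch formulas
brute_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(b) - mean(a)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# fish table drawn exactly from the intercept LMM's own model, with known
# genotype-specific residual SDs (truth for the heteroscedastic estimator)
make_lmm_fish <- function(n = 50, beta = 0, sd_control = 0.08,
                          sd_mutant = 0.08, k = 2, sigma_batch = 0.08) {
  d <- expand.grid(i = seq_len(n), genotype = c("control", "mutant"),
                   experiment = paste0("E", seq_len(k)),
                   stringsAsFactors = FALSE)
  b <- rnorm(k, 0, sigma_batch)[match(d$experiment,
                                      paste0("E", seq_len(k)))]
  la <- runif(nrow(d), 10, 13)
  sd_g <- ifelse(d$genotype == "mutant", sd_mutant, sd_control)
  d$sat_area <- exp(la)
  d$mean_feret <- exp(1 + 0.2 * la + b +
                        ifelse(d$genotype == "mutant", beta, 0) +
                        rnorm(nrow(d), 0, sd_g))
  d$fish_id <- paste0(d$experiment, "_", d$genotype, "_", d$i)
  d$gene <- "test"
  d$standard_length <- runif(nrow(d), 7, 12)
  d$total_lipid_area <- 0.6 * d$sat_area
  d$n_droplets <- 50L
  d
}
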