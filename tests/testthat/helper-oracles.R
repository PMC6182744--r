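# Independent brute-force oracles for the texture operators, written as
# explicit per-pixel loops so they share no code with the implementation.

dir_step <- function(direction) {
  switch(as.character(direction),
         `0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
         `135` = c(-1L, -1L))
}

# quantize by explicit per-pixel search over bin edges
oracle_quantize <- function(px, mk, bits) {
  L <- 2^bits
  x <- px[mk]
  lo <- min(x); hi <- max(x)
  grid <- matrix(NA_integer_, nrow(px), ncol(px))
  if (hi <= lo) { grid[mk] <- 1L; return(grid) }
  edges <- lo + (hi - lo) * (0:L) / L
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    if (!mk[i, j]) next
    v <- px[i, j]
    lev <- NA_integer_
    for (k in seq_len(L)) {
      hi_edge_closed <- (k == L)
      if (v >= edges[k] && (v < edges[k + 1] ||
                            (hi_edge_closed && v <= edges[k + 1]))) {
        lev <- k; break
      }
    }
    grid[i, j] <- lev
  }
  grid
}

# co-occurrence counts by enumerating every pixel and both orientations
oracle_glcm <- function(grid, n_levels, direction, offset) {
  st <- dir_step(direction) * offset
  counts <- matrix(0, n_levels, n_levels)
  nr <- nrow(grid); nc <- ncol(grid)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(grid[i, j])) next
    for (sgn in c(1L, -1L)) {
      i2 <- i + sgn * st[1L]; j2 <- j + sgn * st[2L]
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
      if (is.na(grid[i2, j2])) next
      counts[grid[i, j], grid[i2, j2]] <- counts[grid[i, j], grid[i2, j2]] + 1
    }
  }
  counts
}

oracle_glcm_features <- function(P) {
  L <- nrow(P)
  asm <- 0; contrast <- 0; idm <- 0; ent <- 0
  px <- numeric(L); py <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    if (p > 0) ent <- ent - p * log(p)
    px[i] <- px[i] + p; py[j] <- py[j] + p
  }
  mux <- sum((1:L) * px); muy <- sum((1:L) * py)
  sx <- sqrt(sum(((1:L) - mux)^2 * px)); sy <- sqrt(sum(((1:L) - muy)^2 * py))
  corr <- 0; ssq <- 0
  for (i in 1:L) for (j in 1:L) {
    corr <- corr + (i - mux) * (j - muy) * P[i, j]
    ssq <- ssq + (i - mux)^2 * P[i, j]
  }
  corr <- if (sx * sy > 0) corr / (sx * sy) else 0
  psum <- numeric(2 * L); pdiff <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  sa <- sum((1:(2 * L)) * psum)
  se <- -sum(ifelse(psum > 0, psum * log(psum), 0))
  de <- -sum(ifelse(pdiff > 0, pdiff * log(pdiff), 0))
  c(asm = asm, contrast = contrast, correlation = corr, sum_of_squares = ssq,
    inverse_difference_moment = idm, sum_average = sa, sum_entropy = se,
    entropy = ent, difference_entropy = de)
}

# run enumeration by walking each line pixel by pixel
oracle_rlm <- function(grid, n_levels, direction) {
  st <- dir_step(direction)
  nr <- nrow(grid); nc <- ncol(grid)
  inb <- function(i, j) i >= 1 && i <= nr && j >= 1 && j <= nc
  runs <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(grid[i, j])) next
    # start of a run: predecessor along -step is absent or different level
    pi <- i - st[1L]; pj <- j - st[2L]
    prev_same <- inb(pi, pj) && !is.na(grid[pi, pj]) &&
      grid[pi, pj] == grid[i, j]
    if (prev_same) next
    len <- 1L
    ci <- i + st[1L]; cj <- j + st[2L]
    while (inb(ci, cj) && !is.na(grid[ci, cj]) &&
           grid[ci, cj] == grid[i, j]) {
      len <- len + 1L; ci <- ci + st[1L]; cj <- cj + st[2L]
    }
    runs[[length(runs) + 1L]] <- c(grid[i, j], len)
  }
  max_len <- max(vapply(runs, `[`, integer(1), 2L))
  counts <- matrix(0, n_levels, max_len)
  for (r in runs) counts[r[1L], r[2L]] <- counts[r[1L], r[2L]] + 1
  counts
}

oracle_rlm_features <- function(counts, n_pixels) {
  C <- sum(counts)
  sre <- 0; lre <- 0
  for (i in seq_len(nrow(counts))) for (r in seq_len(ncol(counts))) {
    sre <- sre + counts[i, r] / r^2
    lre <- lre + counts[i, r] * r^2
  }
  glnu <- sum(sapply(seq_len(nrow(counts)), function(i) sum(counts[i, ])^2))
  rlnu <- sum(sapply(seq_len(ncol(counts)), function(r) sum(counts[, r])^2))
  c(short_run_emphasis = sre / C, long_run_emphasis = lre / C,
    grey_level_nonuniformity = glnu / C, run_length_nonuniformity = rlnu / C,
    fraction_in_runs = C / n_pixels)
}

# gradient features by per-pixel loop on an already-quantized grid
oracle_gradient <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  G <- c()
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    if (is.na(grid[i, j]) || is.na(grid[i - 1, j]) || is.na(grid[i + 1, j]) ||
        is.na(grid[i, j - 1]) || is.na(grid[i, j + 1])) next
    G <- c(G, sqrt((grid[i + 1, j] - grid[i - 1, j])^2 +
                   (grid[i, j + 1] - grid[i, j - 1])^2))
  }
  G
}

oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(mean = mu, variance = m2,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0)
}

# explicit two-way ANOVA variance-components ICC(A,1) oracle
oracle_icc_a1 <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  grand <- mean(tab)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(tab[i, ]) - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(tab[, j]) - grand)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    sse <- sse + (tab[i, j] - mean(tab[i, ]) - mean(tab[, j]) + grand)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# brute-force minimal assignment by enumerating all injections rows -> cols
oracle_min_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (cols in utils::combn(m, n, simplify = FALSE))
    for (p in perms(cols))
      best <- min(best, sum(cost[cbind(seq_len(n), p)]))
  best
}

# small random masked test image
random_masked_image <- function(nr, nc, seed, hole_prob = 0.2) {
  set.seed(seed)
  px <- matrix(runif(nr * nc, 0, 100), nr, nc)
  mk <- matrix(runif(nr * nc) > hole_prob, nr, nc)
  if (sum(mk) < 4) mk[] <- TRUE
  list(px = px, mk = mk)
}
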