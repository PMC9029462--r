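# Independent brute-force oracles, deliberately written against the
# definitions rather than sharing code with the package internals.

# exhaustive 8-connected labelling by repeated queue flood fill in R
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        qi <- p[1] + di; qj <- p[2] + dj
        if (qi < 1 || qi > nr || qj < 1 || qj > nc) next
        if (mask[qi, qj] && lab[qi, qj] == 0L) {
          lab[qi, qj] <- nxt
          queue[[length(queue) + 1]] <- c(qi, qj)
        }
      }
    }
  }
  attr(lab, "n_labels") <- nxt
  lab
}

# outer-contour perimeter via EBImage's contour tracer; valid for masks
# whose components are 4-connected (no diagonal-only necks)
oracle_perimeter_ebimage <- function(mask) {
  lab <- EBImage::bwlabel(mask + 0L)
  ocs <- EBImage::ocontour(lab)
  sum(vapply(ocs, function(oc) {
    if (nrow(oc) < 2) return(0)
    steps <- rbind(oc[-1, , drop = FALSE], oc[1, , drop = FALSE]) - oc
    sum(sqrt(rowSums(steps^2)))
  }, numeric(1)))
}

# explicit boundary walk in R, written from the convention's definition:
# clockwise Moore-neighbour trace from the first pixel in column-major
# order, Jacob's stopping criterion, summed step lengths per component
oracle_perimeter <- function(mask) {
  lab <- oracle_label8(mask)
  nlab <- attr(lab, "n_labels")
  if (nlab == 0) return(0)
  nr <- nrow(lab); nc <- ncol(lab)
  dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)   # clockwise from North
  dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  total <- 0
  for (L in seq_len(nlab)) {
    hits <- which(lab == L, arr.ind = FALSE)
    start <- hits[1]  # column-major first pixel
    ci <- (start - 1) %% nr + 1; cj <- (start - 1) %/% nr + 1
    ci0 <- ci; cj0 <- cj
    bdir <- 1  # North (1-based index into dr/dc)
    dir0 <- -1
    repeat {
      found <- -1
      for (k in 1:8) {
        d <- ((bdir - 1 + k) %% 8) + 1
        qi <- ci + dr[d]; qj <- cj + dc[d]
        if (qi < 1 || qi > nr || qj < 1 || qj > nc) next
        if (lab[qi, qj] == L) { found <- d; break }
      }
      if (found < 0) break                    # isolated pixel
      if (dir0 < 0) dir0 <- found
      else if (ci == ci0 && cj == cj0 && found == dir0) break
      total <- total +
        if (dr[found] != 0 && dc[found] != 0) sqrt(2) else 1
      prev <- ((found - 2) %% 8) + 1
      bi <- ci + dr[prev]; bj <- cj + dc[prev]
      ci <- ci + dr[found]; cj <- cj + dc[found]
      bdir <- which(dr == bi - ci & dc == bj - cj)
    }
  }
  total
}

# brute-force least-squares change-point search (0..2 change points),
# explicit loops and means, BIC with p = 2k + 1 parameters
oracle_changepoints <- function(y, max_cp = 2, min_segment = 2) {
  n <- length(y)
  rss_of <- function(bounds) {
    tot <- 0
    for (s in seq_len(length(bounds) - 1)) {
      seg <- y[bounds[s]:(bounds[s + 1] - 1)]
      tot <- tot + sum((seg - mean(seg))^2)
    }
    tot
  }
  cands <- list(list(k = 0L, cps = integer(0), rss = rss_of(c(1, n + 1))))
  if (max_cp >= 1) {
    best <- Inf; bcp <- NULL
    for (i in seq_len(n)) {
      if (i - 1 < min_segment || n - i + 1 < min_segment) next
      r <- rss_of(c(1, i, n + 1))
      if (r < best) { best <- r; bcp <- i }
    }
    if (!is.null(bcp))
      cands[[length(cands) + 1]] <- list(k = 1L, cps = bcp, rss = best)
  }
  if (max_cp >= 2) {
    best <- Inf; bcp <- NULL
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      if (i - 1 < min_segment || j - i < min_segment ||
          n - j + 1 < min_segment) next
      r <- rss_of(c(1, i, j, n + 1))
      if (r < best) { best <- r; bcp <- c(i, j) }
    }
    if (!is.null(bcp))
      cands[[length(cands) + 1]] <- list(k = 2L, cps = bcp, rss = best)
  }
  bic <- vapply(cands, function(f)
    n * log(max(f$rss, 1e-12) / n) + (2 * f$k + 1) * log(n), numeric(1))
  cands[[which.min(bic)]]
}

# closed-form one-way ANOVA from the textbook sums of squares
oracle_anova <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(all_v) - length(groups)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# finite-difference log-log slopes over all consecutive pairs
oracle_loglog_slopes <- function(curve) {
  lg <- log(curve$shear_rate_1_per_s); le <- log(curve$viscosity_Pa_s)
  diff(le) / diff(lg)
}

# small random blob mask: thresholded smoothed noise
random_blob_mask <- function(seed, nr = 40, nc = 60, p = 0.45) {
  set.seed(seed)
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- matrix(1 / 25, 5, 5)
  sm <- EBImage::filter2(m, k)
  sm > stats::quantile(sm, 1 - p)
}
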