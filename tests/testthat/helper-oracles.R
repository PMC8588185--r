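# Independent brute-force oracles. These loop over pixels/bins with no shared
# code with the implementation; they define expected values for the
# oracle-equivalence tests.

oracle_com <- function(values, range_bins, threshold) {
  vapply(seq_len(nrow(values)), function(i) {
    num <- 0; den <- 0
    for (j in seq_len(ncol(values))) {
      v <- values[i, j]
      if (v >= threshold && v > -999) {
        w <- 10^(v / 10)
        num <- num + range_bins[j] * w
        den <- den + w
      }
    }
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
}

oracle_limits <- function(values, range_bins, threshold, min_run = 2) {
  t(vapply(seq_len(nrow(values)), function(i) {
    on <- logical(ncol(values))
    for (j in seq_len(ncol(values)))
      on[j] <- values[i, j] >= threshold && values[i, j] > -999
    # despeckle: drop runs shorter than min_run
    j <- 1
    while (j <= length(on)) {
      if (on[j]) {
        k <- j
        while (k < length(on) && on[k + 1]) k <- k + 1
        if (k - j + 1 < min_run) on[j:k] <- FALSE
        j <- k + 1
      } else j <- j + 1
    }
    if (!any(on)) c(NA_real_, NA_real_)
    else c(range_bins[min(which(on))], range_bins[max(which(on))])
  }, numeric(2)))
}

# Recursive flood fill, 4-connectivity.
oracle_segment <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        pi <- p[1]; pj <- p[2]
        if (pi < 1 || pi > nrow(mask) || pj < 1 || pj > ncol(mask)) next
        if (!mask[pi, pj] || lab[pi, pj] != 0L) next
        lab[pi, pj] <- cur
        stack <- c(stack, list(c(pi - 1, pj), c(pi + 1, pj),
                               c(pi, pj - 1), c(pi, pj + 1)))
      }
    }
  }
  if (cur == 0L) return(list())
  regs <- lapply(seq_len(cur), function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    m <- cbind(ping = as.integer(w[, 1]), bin = as.integer(w[, 2]))
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  })
  ord <- order(vapply(regs, function(m) m[1, 1], 1L),
               vapply(regs, function(m) m[1, 2], 1L))
  regs[ord]
}

oracle_filter <- function(regions, values, min_size, min_level) {
  keep <- logical(length(regions))
  for (k in seq_along(regions)) {
    r <- regions[[k]]
    if (nrow(r) < min_size) next
    tot <- 0
    for (q in seq_len(nrow(r))) tot <- tot + values[r[q, 1], r[q, 2]]
    keep[k] <- tot / nrow(r) >= min_level
  }
  regions[keep]
}

# Closed-form OLS slope of y on 1..n.
oracle_ols_slope <- function(y) {
  n <- length(y); x <- seq_len(n)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Pixelwise morphology reference (loops, explicit 3x3 cross).
oracle_morph <- function(mask, op) {
  n <- nrow(mask); p <- ncol(mask)
  at <- function(i, j) i >= 1 && i <= n && j >= 1 && j <= p && mask[i, j]
  out <- matrix(FALSE, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    nb <- c(at(i - 1, j), at(i + 1, j), at(i, j - 1), at(i, j + 1))
    out[i, j] <- switch(op,
      dilate = mask[i, j] || any(nb),
      erode = mask[i, j] && all(nb),
      thicken = mask[i, j] || sum(nb) >= 2)
  }
  out
}

oracle_clean <- function(mask) {
  m <- oracle_morph(mask, "thicken")
  m <- oracle_morph(oracle_morph(m, "erode"), "dilate")
  oracle_morph(oracle_morph(m, "dilate"), "erode")
}

# Two-way ANOVA Type III SS by explicit design-matrix least squares.
oracle_type3 <- function(y, A, B) {
  A <- as.factor(A); B <- as.factor(B)
  old <- options(contrasts = c("contr.sum", "contr.poly")); on.exit(options(old))
  X <- model.matrix(~ A * B)
  asgn <- attr(X, "assign")
  rss <- function(M) {
    b <- qr.coef(qr(M), y)
    b[is.na(b)] <- 0
    sum((y - M %*% b)^2)
  }
  full <- rss(X)
  ss <- vapply(1:3, function(t) rss(X[, asgn != t, drop = FALSE]) - full,
               numeric(1))
  list(ss = ss, rss = full, df_res = nrow(X) - qr(X)$rank)
}

scale_series <- function(p, g) pressure_series(p$samples * g, p$sample_rate)

make_egram <- function(values, range_bins = seq_len(ncol(values)),
                       ping_interval = 1, ...) {
  echogram(values, ping_times = (seq_len(nrow(values)) - 1) * ping_interval,
           range_bins = range_bins, ...)
}
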