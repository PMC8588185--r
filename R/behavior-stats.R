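#' Stimulus level classes
#'
#' Ordered SPL classes (dB re 1 uPa): background < 120, low \[120, 140),
#' medium \[140, 150), high \[150, 170), very_high >= 170. Half-open bins;
#' the 165-170 dB region belongs to "high".
#'
#' @export
LEVEL_CLASSES <- c("background", "low", "medium", "high", "very_high")

#' Classify an SPL into a source-level class
#'
#' Total, deterministic step function over the bins documented at
#' [LEVEL_CLASSES].
#'
#' @param spl_db SPL value(s), dB re 1 uPa, finite.
#' @return character vector of level classes.
#' @examples
#' classify_level(c(93, 137, 165, 216.4))
#' @export
classify_level <- function(spl_db) {
  if (any(!is.finite(spl_db))) stop("spl_db must be finite")
  cut_idx <- findInterval(spl_db, c(120, 140, 150, 170)) + 1L
  LEVEL_CLASSES[cut_idx]
}

#' Build the per-event behavioral table
#'
#' Joins, for every scheduled event, the school-envelope aggregates and the
#' trace summaries over the event window `[start, start + duration)` and an
#' equal-length baseline window immediately before the event, and derives
#' the change variables the composite response score consumes:
#' `d_com` (mean range change, m), `d_extent` (m), `d_length` (pings),
#' `d_tilt` (m/ping). Events whose windows have no valid pings keep `NA`
#' variables; events entirely outside the data span are dropped and listed
#' in the `"skipped"` attribute.
#'
#' @param schedule an [event_schedule()].
#' @param env a [school_envelope()] data.frame.
#' @param traces list of `"fish_trace"` objects (or a [traces_table()]
#'   data.frame).
#' @param baseline_s baseline window length (s); default: the event's own
#'   duration.
#' @return data.frame, one row per retained event, with identification
#'   (`event_id`, `source_type`, `level_class`, `spl_db`), event-window
#'   means (`avg_range`, `upper_limit`, `lower_limit`, `avg_trace_length`,
#'   `avg_trace_tilt`), and the baseline-referenced deltas.
#' @export
build_event_table <- function(schedule, env, traces, baseline_s = NULL) {
  tab <- if (is.data.frame(traces)) traces else traces_table(traces)
  span <- range(env$ping_time)
  base_len <- function(i) if (is.null(baseline_s)) schedule$duration_s[i] else baseline_s
  inside <- vapply(seq_len(nrow(schedule)), function(i) {
    schedule$start_time[i] >= span[1] &&
      schedule$start_time[i] + schedule$duration_s[i] <= span[2] + 1e-9
  }, logical(1))
  skipped <- schedule$event_id[!inside]
  rows <- lapply(which(inside), function(i) {
    s <- schedule$start_time[i]; d <- schedule$duration_s[i]
    w <- data.frame(start = c(s - base_len(i), s), end = c(s, s + d))
    ag <- aggregate_envelope(env, w)
    tr <- summarize_traces_tab(tab, w)
    data.frame(
      event_id = schedule$event_id[i],
      source_type = schedule$source_type[i],
      level_class = classify_level(schedule$spl_db[i]),
      spl_db = schedule$spl_db[i],
      avg_range = ag$com_range[2],
      upper_limit = ag$upper_range[2],
      lower_limit = ag$lower_range[2],
      avg_trace_length = tr$mean_length_pings[2],
      avg_trace_tilt = tr$mean_tilt[2],
      d_com = ag$com_range[2] - ag$com_range[1],
      d_extent = ag$extent[2] - ag$extent[1],
      d_length = tr$mean_length_pings[2] - tr$mean_length_pings[1],
      d_tilt = tr$mean_tilt[2] - tr$mean_tilt[1]
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = character(0))
  attr(out, "skipped") <- skipped
  out
}

# summarize_traces() over a plain trace table; a trace is counted in every
# window its ping span overlaps
summarize_traces_tab <- function(tab, windows) {
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    sel <- tab$end_time >= windows$start[i] & tab$start_time < windows$end[i]
    tilt <- tab$tilt_slope[sel & !is.na(tab$tilt_slope)]
    data.frame(
      mean_length_pings = if (any(sel)) mean(tab$length_pings[sel]) else NA_real_,
      mean_tilt = if (length(tilt)) mean(tilt) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Composite response score
#'
#' A single response strength per event: the first principal component of
#' the z-scored change variables (`d_com`, `d_extent`, `d_length`,
#' `d_tilt`), sign-fixed so that a larger score means a stronger departure
#' from baseline. Variables are z-scored against the background-class events
#' when at least 3 exist, otherwise against all events; zero-variance
#' variables are dropped with a warning.
#'
#' @param records event table from [build_event_table()].
#' @return numeric score per record (`NA` where variables are missing), with
#'   the PCA loadings as attribute `"loadings"`.
#' @export
composite_score <- function(records) {
  vars <- c("d_com", "d_extent", "d_length", "d_tilt")
  vars <- vars[vars %in% names(records)]
  X <- as.matrix(records[vars])
  complete <- stats::complete.cases(X)
  if (sum(complete) < 3) stop("need >= 3 complete records for the composite score")
  is_bg <- records$level_class == "background" & complete
  ref <- if (sum(is_bg) >= 3) X[is_bg, , drop = FALSE]
         else X[complete, , drop = FALSE]
  mu <- colMeans(ref); sdev <- apply(ref, 2, stats::sd)
  drop <- !is.finite(sdev) | sdev == 0
  if (any(drop)) {
    warning("zero-variance variable(s) dropped from PCA: ",
            paste(vars[drop], collapse = ", "))
    if (all(drop)) stop("all variables have zero variance")
    X <- X[, !drop, drop = FALSE]; mu <- mu[!drop]; sdev <- sdev[!drop]
  }
  Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  pc <- stats::prcomp(Z[complete, , drop = FALSE], center = FALSE, scale. = FALSE)
  load <- pc$rotation[, 1]
  score <- as.numeric(Z %*% load)
  strength <- rowSums(abs(Z))
  if (stats::var(score[complete]) > 0 &&
      suppressWarnings(stats::cor(score[complete], strength[complete])) < 0) {
    score <- -score; load <- -load
  }
  score[!complete] <- NA_real_
  attr(score, "loadings") <- load
  score
}

#' Classify behavioral response strength
#'
#' Maps composite scores to response classes, monotone in `|score|`
#' (baseline-SD units): `|score| < t1` is B0 (no response),
#' `t1 <= |score| < t2` is B1 (moderate: slight changes in vertical
#' position, speed or tilt), `|score| >= t2` is B2 (severe: abrupt
#' changes).
#'
#' @param scores numeric composite scores.
#' @param t1,t2 class thresholds (defaults 0.5 and 2.0).
#' @return character vector `"B0"`/`"B1"`/`"B2"` (`NA` preserved).
#' @export
classify_behavior <- function(scores, t1 = 0.5, t2 = 2.0) {
  stopifnot(t1 >= 0, t2 > t1)
  out <- ifelse(abs(scores) < t1, "B0", ifelse(abs(scores) < t2, "B1", "B2"))
  out
}

#' Levene's test for homogeneity of variances
#'
#' Classic form: a one-way ANOVA on the absolute deviations from the group
#' means. Returns the statistic `W` (the F of that ANOVA) and its p-value
#' from `F(k - 1, N - k)`.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @return list with `W`, `p`, `df1`, `df2`.
#' @export
levene_test <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  ns <- table(groups)
  if (any(ns < 2))
    stop("group(s) with a single value: ",
         paste(names(ns)[ns < 2], collapse = ", "))
  z <- abs(values - stats::ave(values, groups))
  k <- nlevels(groups); N <- length(values)
  zbar <- mean(z); zg <- tapply(z, groups, mean)
  ssb <- sum(ns * (zg - zbar)^2)
  ssw <- sum((z - stats::ave(z, groups))^2)
  df1 <- k - 1; df2 <- N - k
  W <- if (ssb == 0) 0 else (ssb / df1) / (ssw / df2)
  p <- if (ssw == 0 && ssb == 0) 1 else stats::pf(W, df1, df2, lower.tail = FALSE)
  list(W = W, p = p, df1 = df1, df2 = df2)
}

#' Unbalanced two-way ANOVA with Type III sums of squares
#'
#' Fits `values ~ A * B` with sum-to-zero contrasts and computes marginal
#' (Type III) sums of squares: each term's SS is the increase in residual SS
#' when that term's columns are removed from the full design (all other
#' terms retained). Empty cells reduce the interaction rank (and df)
#' automatically; a term whose columns are entirely aliased raises an error
#' naming it. With `factorB = NULL` a one-way ANOVA is returned (same
#' machinery).
#'
#' @param values numeric response.
#' @param factorA,factorB factors (labels); `factorB` optional.
#' @return data.frame of class `"anova_result"`: one row per effect plus
#'   residuals, with `sum_sq`, `df`, `mean_sq`, `F`, `p`.
#' @export
two_way_anova <- function(values, factorA, factorB = NULL) {
  A <- droplevels(as.factor(factorA))
  if (nlevels(A) < 2) stop("factorA needs >= 2 levels")
  dat <- data.frame(y = values, A = A)
  if (!is.null(factorB)) {
    B <- droplevels(as.factor(factorB))
    if (nlevels(B) < 2) stop("factorB needs >= 2 levels")
    dat$B <- B
    form <- y ~ A * B
    contr <- list(A = "contr.sum", B = "contr.sum")
    term_names <- c("A", "B", "A:B")
  } else {
    form <- y ~ A
    contr <- list(A = "contr.sum")
    term_names <- "A"
  }
  mf <- stats::model.frame(form, dat)
  X <- stats::model.matrix(form, mf, contrasts.arg = contr)
  asgn <- attr(X, "assign")
  qr_full <- qr(X)
  rank_full <- qr_full$rank
  # with empty cells some interaction columns are aliased; work on the
  # full-rank basis so term df reflect the estimable contrasts only
  if (rank_full < ncol(X)) {
    keep_cols <- sort(qr_full$pivot[seq_len(rank_full)])
    X <- X[, keep_cols, drop = FALSE]
    asgn <- asgn[keep_cols]
    qr_full <- qr(X)
    rank_full <- qr_full$rank
  }
  n <- nrow(X)
  if (n <= rank_full) stop("no residual degrees of freedom")
  rss_full <- sum(qr.resid(qr_full, dat$y)^2)
  df_res <- n - rank_full
  ms_res <- rss_full / df_res
  rows <- lapply(seq_along(term_names), function(ti) {
    keep <- asgn != ti
    Xr <- X[, keep, drop = FALSE]
    qr_red <- qr(Xr)
    df_t <- rank_full - qr_red$rank
    if (df_t == 0)
      stop("singular design: term ", term_names[ti], " is aliased")
    ss <- sum(qr.resid(qr_red, dat$y)^2) - rss_full
    ss <- max(ss, 0)
    Fv <- (ss / df_t) / ms_res
    data.frame(effect = term_names[ti], sum_sq = ss, df = df_t,
               mean_sq = ss / df_t, F = Fv,
               p = stats::pf(Fv, df_t, df_res, lower.tail = FALSE))
  })
  out <- rbind(do.call(rbind, rows),
               data.frame(effect = "residuals", sum_sq = rss_full,
                          df = df_res, mean_sq = ms_res, F = NA_real_,
                          p = NA_real_))
  if (!is.null(factorB))
    out$effect <- c("source_type", "source_level", "interaction", "residuals")
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Tukey-Kramer homogeneous subsets
#'
#' All pairwise Tukey-Kramer comparisons at level `alpha` using the one-way
#' ANOVA residual mean square, then a partition of the groups (ordered by
#' mean) into maximal homogeneous subsets: a subset is a maximal run of
#' groups containing no significantly different pair, the presentation used
#' by standard post hoc tables.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param alpha familywise significance level (default 0.05).
#' @return list with `means` (data.frame: group, n, mean, subset
#'   memberships), `subsets` (list of character vectors), `pairwise`
#'   (data.frame of all comparisons with Tukey p-values), `ms_error`, `df`.
#' @export
tukey_subsets <- function(values, groups, alpha = 0.05) {
  g <- droplevels(as.factor(groups))
  k <- nlevels(g)
  if (k < 2) stop("need >= 2 groups")
  ns <- as.numeric(table(g))
  means <- as.numeric(tapply(values, g, mean))
  df_res <- length(values) - k
  if (df_res < 1) stop("no residual degrees of freedom")
  mse <- sum((values - stats::ave(values, g))^2) / df_res
  ord <- order(means)
  lv <- levels(g)[ord]; mo <- means[ord]; no <- ns[ord]
  pair <- expand.grid(i = seq_len(k), j = seq_len(k))
  pair <- pair[pair$i < pair$j, ]
  qv <- abs(mo[pair$i] - mo[pair$j]) /
    sqrt(mse / 2 * (1 / no[pair$i] + 1 / no[pair$j]))
  pv <- if (mse == 0) ifelse(is.nan(qv) | qv == 0, 1, 0)
        else stats::ptukey(qv, k, df_res, lower.tail = FALSE)
  sig <- matrix(FALSE, k, k)
  sig[cbind(pair$i, pair$j)] <- pv < alpha
  sig <- sig | t(sig)
  # maximal runs over mean-ordered groups with no significant pair inside;
  # "no significant pair" is hereditary, so runs are intervals [i, f(i)]
  # with f nondecreasing, and maximal ones are those extending a new f.
  f <- integer(k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[i:j, j + 1])) j <- j + 1L
    f[i] <- j
  }
  first <- which(c(TRUE, diff(f) > 0))
  subsets <- lapply(first, function(i) lv[i:f[i]])
  memb <- vapply(lv, function(gr)
    paste(which(vapply(subsets, function(s) gr %in% s, logical(1))),
          collapse = ","), character(1))
  list(means = data.frame(group = lv, n = no, mean = mo, subsets = memb,
                          stringsAsFactors = FALSE),
       subsets = subsets,
       pairwise = data.frame(group1 = lv[pair$i], group2 = lv[pair$j],
                             diff = mo[pair$j] - mo[pair$i], q = qv, p = pv),
       ms_error = mse, df = df_res)
}

#' Simulate a per-event behavioral table (statistics-level generator)
#'
#' Draws an event table directly at the statistical level (no echogram
#' rendering) for power/false-positive studies of the ANOVA layer: a
#' factorial design of source types x level classes with a built-in *level*
#' effect on the depth-change variable — the dive scales linearly with level
#' class up to `max_dive` at the top class — and, by default, no type
#' effect. Per-event noise is Gaussian.
#'
#' @param n_per_cell events per type x level cell (default 3).
#' @param types,levels factor levels of the design.
#' @param max_dive dive magnitude (m) at the highest level class (default
#'   3.3 m, the canonical feeding-boat dive).
#' @param type_effect additional per-type offset magnitude (m), default 0.
#' @param noise_sd per-event sd of the depth change (m), default 1.5.
#' @param seed integer seed.
#' @return data.frame with `source_type`, `level_class`, `d_com`.
#' @export
simulate_event_table <- function(n_per_cell = 3,
                                 types = c("tone", "chirp", "windmill", "ship"),
                                 levels = c("low", "medium", "high", "very_high"),
                                 max_dive = 3.3, type_effect = 0,
                                 noise_sd = 1.5, seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(source_type = types, level_class = levels,
                      rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  li <- match(grid$level_class, levels) - 1
  ti <- match(grid$source_type, types) - 1
  mu <- -max_dive * li / (length(levels) - 1) +
    type_effect * (ti - mean(ti))
  grid$d_com <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
  grid[c("source_type", "level_class", "d_com")]
}
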