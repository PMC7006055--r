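# Independent brute-force oracles, written directly from the metric
# definitions. They operate on raw event lists / traces and share no code
# with the package implementation.

oracle_drinking <- function(events, swallows, trace, window) {
  fps <- trace$fps
  t0 <- window[1]; t1 <- window[2]
  secs <- floor(t1 - t0 + 1e-9)
  cl <- sort(events$close_times)
  cl <- cl[cl >= t0 & cl < t1]

  counts <- c()
  for (k in seq_len(secs)) {
    lo <- t0 + k - 1; hi <- t0 + k
    counts <- c(counts, sum(cl >= lo & cl < hi))
  }
  lick_rate <- sum(counts) / length(counts)

  ili <- NA_real_
  if (length(cl) >= 2) {
    gaps <- c()
    for (i in 2:length(cl)) gaps <- c(gaps, cl[i] - cl[i - 1])
    ili <- 1000 * sum(gaps) / length(gaps)
  }

  sw_all <- if (is.null(swallows)) numeric(0) else sort(swallows$swallow_frame / fps)
  sw <- sw_all[sw_all >= t0 & sw_all < t1]
  swallow_rate <- 0
  isi <- lsr <- ptt <- NA_real_
  if (length(sw) > 0) {
    scounts <- c()
    for (k in seq_len(secs)) {
      scounts <- c(scounts, sum(sw >= t0 + k - 1 & sw < t0 + k))
    }
    swallow_rate <- mean(scounts)
    if (length(sw) >= 2) {
      isi <- 1000 * mean(diff(sw))
      ratios <- c()
      for (i in seq_len(length(sw) - 1)) {
        ratios <- c(ratios, sum(events$close_times > sw[i] &
                                  events$close_times <= sw[i + 1]))
      }
      lsr <- mean(ratios)
    }
    keep <- swallows$swallow_frame / fps >= t0 & swallows$swallow_frame / fps < t1
    ptt <- 1000 * mean((swallows$esophagus_entry_frame[keep] -
                          swallows$rest_frame[keep]) / fps)
  }

  val_at <- function(t) trace$values[round(t * fps) + 1]
  op <- sort(events$open_times); op <- op[op >= t0 & op < t1]
  opening <- c()
  for (tc in cl) {
    nx <- op[op > tc]
    if (length(nx)) opening <- c(opening, abs(val_at(nx[1]) - val_at(tc)) / (nx[1] - tc))
  }
  closing <- c()
  for (to in op) {
    nx <- cl[cl > to]
    if (length(nx)) closing <- c(closing, abs(val_at(nx[1]) - val_at(to)) / (nx[1] - to))
  }
  list(lick_rate = lick_rate, inter_lick_interval = ili,
       swallow_rate = swallow_rate, inter_swallow_interval = isi,
       lick_swallow_ratio = lsr, pharyngeal_transit_time = ptt,
       jaw_opening_velocity = if (length(opening)) mean(opening) else NA_real_,
       jaw_closing_velocity = if (length(closing)) mean(closing) else NA_real_)
}

oracle_eating <- function(events, swallows, rotary, trace, window) {
  fps <- trace$fps
  t0 <- window[1]; t1 <- window[2]
  secs <- floor(t1 - t0 + 1e-9)
  counts <- c()
  for (i in seq_len(nrow(rotary))) {
    counts <- c(counts, sum(events$close_times >= rotary$start_s[i] &
                              events$close_times < rotary$end_s[i]))
  }
  sw_all <- if (is.null(swallows)) numeric(0) else sort(swallows$swallow_frame / fps)
  sw <- sw_all[sw_all >= t0 & sw_all < t1]
  scounts <- c()
  for (k in seq_len(secs)) {
    scounts <- c(scounts, sum(sw >= t0 + k - 1 & sw < t0 + k))
  }
  list(mastication_rate = mean(counts),
       swallow_rate = mean(scounts),
       inter_swallow_interval = if (length(sw) >= 2) mean(diff(sw)) else NA_real_)
}

oracle_laryngeal <- function(cycles, left, right, clip_seconds = 10) {
  tl <- (seq_along(left$values) - 1) / left$fps
  cyc <- cycles$cycles
  ratios <- c()
  for (i in seq_len(nrow(cyc))) {
    sel <- tl >= cyc$start_s[i] - 1e-9 & tl <= cyc$end_s[i] + 1e-9
    al <- max(left$values[sel]) - min(left$values[sel])
    ar <- max(right$values[sel]) - min(right$values[sel])
    ratios <- c(ratios, if (al == 0 || ar == 0) NA else min(al, ar) / max(al, ar))
  }
  dl <- left$values[-1] - left$values[-length(left$values)]
  dr <- right$values[-1] - right$values[-length(right$values)]
  mc <- if (sd(dl) == 0 || sd(dr) == 0) NA_real_ else {
    # Pearson correlation from its definition
    sum((dl - mean(dl)) * (dr - mean(dr))) /
      sqrt(sum((dl - mean(dl))^2) * sum((dr - mean(dr))^2))
  }
  list(mmrr = if (all(is.na(ratios))) NA_real_ else mean(ratios, na.rm = TRUE),
       occr = if (cycles$n_left > 0) cycles$n_right / cycles$n_left else NA_real_,
       mcorr = mc,
       respiratory_rate = nrow(cyc) * 60 / clip_seconds)
}

# textbook equal-variance two-sample t-test
oracle_ttest <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, p = 2 * pt(-abs(t), df))
}

# hand-computed balanced two-way ANOVA with interaction
oracle_anova2 <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  gm <- mean(y)
  a_means <- tapply(y, A, mean); b_means <- tapply(y, B, mean)
  cell_means <- tapply(y, interaction(A, B), mean)
  n_a <- table(A); n_b <- table(B); n_cell <- table(interaction(A, B))
  ss_a <- sum(n_a * (a_means - gm)^2)
  ss_b <- sum(n_b * (b_means - gm)^2)
  ss_cells <- sum(n_cell * (cell_means - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  fitted <- cell_means[as.character(interaction(A, B))]
  ss_e <- sum((y - fitted)^2)
  df_a <- nlevels(A) - 1; df_b <- nlevels(B) - 1
  df_ab <- df_a * df_b
  df_e <- length(y) - nlevels(A) * nlevels(B)
  ms_e <- ss_e / df_e
  f <- c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab) / ms_e
  p <- pf(f, c(df_a, df_b, df_ab), df_e, lower.tail = FALSE)
  list(F = f, p = p)
}

# random alternating open/close event configuration on a 4 s, 30 fps trace
random_event_config <- function(seed) {
  set.seed(seed)
  fps <- 30
  dur <- 4
  n <- dur * fps
  trace <- motion_trace(abs(cumsum(rnorm(n, 0, 0.2))) + 0.5, fps = fps, units = "mm")
  t <- 0.02 + runif(1, 0, 0.05)
  closes <- c(); opens <- c()
  while (TRUE) {
    t <- t + runif(1, 0.04, 0.12)
    if (t >= dur - 0.05) break
    closes <- c(closes, t)
    t <- t + runif(1, 0.04, 0.12)
    if (t >= dur - 0.05) break
    opens <- c(opens, t)
  }
  ev <- suppressWarnings(cycle_events(opens, closes))
  n_sw <- sample(0:5, 1)
  swallows <- NULL
  if (n_sw > 0) {
    sf <- sort(sample(10:(n - 10), n_sw))
    swallows <- data.frame(rest_frame = sf,
                           esophagus_entry_frame = sf + sample(2:5, n_sw, TRUE),
                           swallow_frame = sf)
  }
  list(events = ev, swallows = swallows, trace = trace,
       window = c(1, 3))
}
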