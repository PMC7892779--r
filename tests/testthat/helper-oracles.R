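# Independent oracle implementations used to cross-check the package's
# fast paths. These are deliberately naive (loops, recursion, fixed grids)
# and share no code with the implementations they test.

# Flood-fill connected components over an (electrode x time) mask.
# adj: list (per electrode row) of neighbouring electrode rows.
oracle_flood_fill <- function(mask, adj_rows) {
  E <- nrow(mask); Tn <- ncol(mask)
  lab <- matrix(0L, E, Tn)
  cur <- 0L
  for (e0 in seq_len(E)) for (t0 in seq_len(Tn)) {
    if (!mask[e0, t0] || lab[e0, t0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(e0, t0))
    lab[e0, t0] <- cur
    while (length(queue)) {
      pt <- queue[[1]]; queue <- queue[-1]
      e <- pt[1]; tt <- pt[2]
      cand <- list()
      if (tt > 1) cand <- c(cand, list(c(e, tt - 1)))
      if (tt < Tn) cand <- c(cand, list(c(e, tt + 1)))
      for (e2 in adj_rows[[e]]) cand <- c(cand, list(c(e2, tt)))
      for (cd in cand) {
        if (mask[cd[1], cd[2]] && lab[cd[1], cd[2]] == 0L) {
          lab[cd[1], cd[2]] <- cur
          queue <- c(queue, list(cd))
        }
      }
    }
  }
  lab
}

# Canonical cluster summary for comparing two labelings that may number
# clusters differently: sorted list of "members|sum" strings.
oracle_cluster_summary <- function(lab, stat) {
  if (max(lab) == 0L) return(character(0))
  out <- vapply(seq_len(max(lab)), function(i) {
    idx <- which(lab == i)
    paste(paste(sort(idx), collapse = ","),
          format(sum(stat[idx]), digits = 15), sep = "|")
  }, character(1))
  sort(out)
}

# Definitional one-way RM-ANOVA F via explicit sums of squares.
# y: n x k matrix.
oracle_rm_anova_f <- function(y) {
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  ss_cond <- 0; ss_subj <- 0; ss_tot <- 0
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (mean(y[, j]) - grand)^2
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(y[i, ]) - grand)^2
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_tot <- ss_tot + (y[i, j] - grand)^2
  ss_err <- ss_tot - ss_cond - ss_subj
  (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
}

# Textbook paired t.
oracle_paired_t <- function(x1, x2) {
  d <- x1 - x2
  mean(d) / (sd(d) / sqrt(length(d)))
}

# High-precision JZS t-test BF10 on a fixed fine grid (trapezoid in
# u = log g), independent of stats::integrate.
oracle_jzs_bf <- function(t, n, r = sqrt(2) / 2, lo = -18, hi = 18,
                          n_grid = 40001L) {
  nu <- n - 1
  u <- seq(lo, hi, length.out = n_grid)
  g <- exp(u)
  a <- 1 + n * g * r^2
  logf <- -0.5 * log(a) - (nu + 1) / 2 * log1p(t^2 / (a * nu)) -
    0.5 * log(2 * pi) - 1.5 * u - 1 / (2 * g) + u
  peak <- max(logf)
  num <- sum(exp(logf - peak)) * (u[2] - u[1])
  num <- exp(log(num) + peak)
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  num / den
}

# Small null study used by several calibration tests.
tiny_null_epochs <- function(n_subjects, conditions, trials, n_electrodes,
                             srate, window, seed,
                             noise = noise_spec(alpha_power_fraction = 0,
                                                spatial_correlation_length = 1)) {
  design <- study_design(n_subjects = n_subjects,
                         trials_per_condition = trials,
                         sampling_rate = srate, epoch_window = window,
                         conditions = conditions)
  layout <- tiny_layout(n_electrodes)
  simulate_noise_epochs(design, noise, layout, seed = seed)
}

tiny_layout <- function(n_electrodes) {
  n_rings <- 2L
  while (1L + 3L * n_rings * (n_rings - 1L) < n_electrodes)
    n_rings <- n_rings + 1L
  build_default_layout(n_rings = n_rings, n_keep = n_electrodes)
}
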