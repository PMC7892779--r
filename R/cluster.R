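#' Per-subject condition-average maps
#'
#' Averages trials into one (electrode, time) map per subject and
#' condition — the exchangeability unit of the permutation test (condition
#' labels are permuted within subject at the level of these maps).
#'
#' @param epochs an `epoch_set`.
#' @param conditions condition labels to keep (`NULL` = all).
#' @param electrode_set electrode IDs to keep (`NULL` = all).
#' @param time_window `c(start, end)` in seconds (`NULL` = whole epoch).
#' @return An object of class `sc_maps`: list with `maps` (array
#'   `(subject, condition, electrode, time)`), `electrodes` (IDs), `time`.
#' @export
condition_maps <- function(epochs, conditions = NULL, electrode_set = NULL,
                           time_window = NULL) {
  cidx <- condition_index(epochs, conditions)
  eidx <- electrode_index(epochs, electrode_set)
  tidx <- time_index(epochs, time_window)
  sub <- epochs$amp[, cidx, , eidx, tidx, drop = FALSE]
  d <- dim(sub)
  # mean over the trial axis (3rd)
  m <- apply(sub, c(1, 2, 4, 5), mean)
  dimnames(m) <- list(dimnames(epochs$amp)[[1]],
                      epoch_conditions(epochs)[cidx], NULL, NULL)
  sc_maps(m, epochs$layout$id[eidx], epochs$time[tidx])
}

#' @param maps array `(subject, condition, electrode, time)`.
#' @param electrodes electrode IDs along the third axis.
#' @param time time axis in seconds.
#' @rdname condition_maps
#' @export
sc_maps <- function(maps, electrodes, time) {
  stopifnot(length(dim(maps)) == 4L,
            dim(maps)[3] == length(electrodes),
            dim(maps)[4] == length(time))
  structure(list(maps = maps, electrodes = electrodes, time = time),
            class = "sc_maps")
}

#' @export
print.sc_maps <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<sc_maps: %d subjects x %d conditions, %d electrodes x %d samples>\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

# Rows subject-major with condition fastest: row (s-1)k + c.
maps_to_matrix <- function(maps) {
  d <- dim(maps$maps)
  m <- aperm(maps$maps, c(2, 1, 3, 4))
  matrix(m, d[1] * d[2], d[3] * d[4])
}

# Vectorized one-way RM-ANOVA over the columns of Y ((n*k) x Q, rows
# subject-major/condition-fastest). Returns list(F, SS pieces).
rm_anova_engine <- function(y, n, k) {
  grand <- colMeans(y)
  ss_tot <- colSums(y^2) - n * k * grand^2
  subj_sums <- rowsum(y, rep(seq_len(n), each = k), reorder = FALSE)
  ss_subj <- colSums(subj_sums^2) / k - n * k * grand^2
  cond_sums <- rowsum(y, rep(seq_len(k), n), reorder = FALSE)
  ss_cond <- colSums(cond_sums^2) / n - n * k * grand^2
  ss_err <- pmax(ss_tot - ss_subj - ss_cond, 0)
  # guard against floating-point dust: a condition SS below machine noise
  # relative to the total is exactly zero (F = 0, not 0/0 or x/0)
  ss_cond[ss_cond <= 1e-10 * pmax(ss_tot, .Machine$double.xmin)] <- 0
  fv <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  fv[ss_cond == 0] <- 0
  list(f = fv, ss_tot = ss_tot, ss_subj = ss_subj, grand = grand)
}

#' Pointwise repeated-measures ANOVA map
#'
#' One-way RM-ANOVA at every (electrode, time) point:
#' `F = MS_condition / MS_(condition x subject)` with
#' `df = (k - 1, (k - 1)(n - 1))`. Points with zero error variance get
#' `F = Inf`, `p = 0`, with a warning.
#'
#' @param maps an `sc_maps` with `k >= 2` conditions and `n >= 2` subjects.
#' @return An object of class `stat_map`: list with `stat` and `p`
#'   (electrode x time matrices), `df`, `kind` (`"F"`), `electrodes`,
#'   `time`.
#' @export
pointwise_rm_anova <- function(maps) {
  d <- dim(maps$maps)
  n <- d[1]; k <- d[2]
  if (k < 2L) stopf("need k >= 2 conditions (got %d)", k)
  if (n < 2L) stopf("need n >= 2 subjects (got %d)", n)
  y <- maps_to_matrix(maps)
  eng <- rm_anova_engine(y, n, k)
  fv <- eng$f
  if (any(!is.finite(fv))) {
    warning("zero error variance at some points; F set to Inf", call. = FALSE)
    fv[is.nan(fv)] <- 0 # 0/0: no condition variance either
  }
  df <- c(k - 1, (k - 1) * (n - 1))
  p <- pf(fv, df[1], df[2], lower.tail = FALSE)
  stat_map(matrix(fv, d[3], d[4]), matrix(p, d[3], d[4]), df, "F",
           maps$electrodes, maps$time)
}

#' Pointwise paired-t map
#'
#' Classic paired t at every (electrode, time) point for a two-condition
#' design (`condition 1 - condition 2`), `df = n - 1`, two-sided p.
#' Points with zero difference variance get `t = +/-Inf` with a warning.
#'
#' @param maps an `sc_maps` with exactly 2 conditions.
#' @return a `stat_map` with `kind = "t"`.
#' @export
pointwise_paired_t <- function(maps) {
  d <- dim(maps$maps)
  n <- d[1]
  if (d[2] != 2L) stopf("paired t requires exactly 2 conditions (got %d)", d[2])
  if (n < 2L) stopf("need n >= 2 subjects")
  dif <- matrix(maps$maps[, 1, , ] - maps$maps[, 2, , ], n, d[3] * d[4])
  m <- colMeans(dif)
  v <- (colSums(dif^2) - n * m^2) / (n - 1)
  v <- pmax(v, 0)
  tv <- m / sqrt(v / n)
  tv[v == 0 & m == 0] <- 0
  if (any(!is.finite(tv)))
    warning("zero difference variance at some points; t set to +/-Inf",
            call. = FALSE)
  p <- 2 * pt(abs(tv), n - 1, lower.tail = FALSE)
  stat_map(matrix(tv, d[3], d[4]), matrix(p, d[3], d[4]), n - 1, "t",
           maps$electrodes, maps$time)
}

#' @param stat,p electrode x time matrices.
#' @param df degrees of freedom.
#' @param kind `"F"` or `"t"`.
#' @param electrodes electrode IDs (rows of `stat`).
#' @param time time axis (columns of `stat`).
#' @rdname pointwise_rm_anova
#' @export
stat_map <- function(stat, p, df, kind, electrodes, time) {
  structure(list(stat = stat, p = p, df = df, kind = kind,
                 electrodes = electrodes, time = time),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map (%s, df = %s): %d electrodes x %d samples, max |stat| = %.3f>\n",
              x$kind, paste(x$df, collapse = ", "), nrow(x$stat),
              ncol(x$stat), max(abs(x$stat))))
  invisible(x)
}

# One cluster: integer matrix of member (electrode_row, time_col) indices,
# summed statistic, sign (+1 for F / positive t, -1 for negative t).
make_cluster <- function(members, sum, sign) {
  list(members = members, sum = sum, sign = sign)
}

clusters_from_labels <- function(lab, statv, sign) {
  ncl <- max(lab)
  if (ncl == 0L) return(list())
  out <- vector("list", ncl)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  sums <- vapply(seq_len(ncl), function(i) sum(statv[lab == i]), numeric(1))
  for (i in seq_len(ncl))
    out[[i]] <- make_cluster(idx[labs == i, , drop = FALSE], sums[i], sign)
  out
}

#' Cluster suprathreshold points
#'
#' Groups points with uncorrected `p < threshold_p` into connected
#' components under spatio-temporal adjacency — two points are adjacent
#' iff they share an electrode and are one sample apart, or share a time
#' point and are neighbouring electrodes — and sums the statistic within
#' each component. For t maps, positive and negative points are clustered
#' separately (a cluster has one sign; its `sum` is the signed sum).
#'
#' @param stat_map a `stat_map`.
#' @param threshold_p cluster-defining uncorrected p threshold
#'   (default 0.05).
#' @param adjacency an `adjacency_graph` covering the map's electrodes.
#' @return list of clusters, sorted by decreasing `|sum|`; each cluster is
#'   a list with `members` (matrix of electrode-row/time-column indices),
#'   `sum`, `sign`.
#' @export
find_clusters <- function(stat_map, threshold_p = 0.05, adjacency) {
  adj <- adjacency_index_list(adjacency, stat_map$electrodes)
  below <- stat_map$p < threshold_p
  out <- list()
  if (stat_map$kind == "t") {
    for (sgn in c(1, -1)) {
      mask <- below & sign(stat_map$stat) == sgn
      lab <- label_clusters_cpp(mask, adj)
      out <- c(out, clusters_from_labels(lab, stat_map$stat, sgn))
    }
  } else {
    lab <- label_clusters_cpp(below, adj)
    out <- clusters_from_labels(lab, stat_map$stat, 1)
  }
  out[order(vapply(out, function(cl) -abs(cl$sum), numeric(1)))]
}

# Critical value of the pointwise statistic at threshold_p.
stat_threshold <- function(kind, df, threshold_p) {
  if (kind == "F") qf(threshold_p, df[1], df[2], lower.tail = FALSE)
  else qt(threshold_p / 2, df, lower.tail = FALSE)
}

#' Permutation null distribution of the maximum cluster sum
#'
#' Each permutation independently shuffles the condition labels within
#' every subject (for `kind = "t"`: random sign flips of the paired
#' differences), recomputes the pointwise statistic map, clusters the
#' suprathreshold points and records the maximum cluster sum (maximum
#' absolute signed sum for t; 0 when no cluster forms). Deterministic
#' given `seed`.
#'
#' @param maps an `sc_maps`.
#' @param stat_kind `"F"` (RM-ANOVA) or `"t"` (paired t; requires k = 2).
#' @param adjacency an `adjacency_graph`.
#' @param P number of permutations (default 1000).
#' @param seed integer seed.
#' @param threshold_p cluster-defining threshold (default 0.05).
#' @return An object of class `permutation_null`: numeric vector of length
#'   `P` with attributes `P`, `seed`, `threshold_p`, `stat_kind`.
#' @export
permutation_null <- function(maps, stat_kind = c("F", "t"), adjacency,
                             P = 1000L, seed = 1L, threshold_p = 0.05) {
  stat_kind <- match.arg(stat_kind)
  d <- dim(maps$maps)
  n <- d[1]; k <- d[2]; n_e <- d[3]; n_t <- d[4]
  adj <- adjacency_index_list(adjacency, maps$electrodes)
  null <- numeric(P)
  if (stat_kind == "F") {
    y <- maps_to_matrix(maps)
    grand <- colMeans(y)
    ss_tot <- colSums(y^2) - n * k * grand^2
    subj_sums <- rowsum(y, rep(seq_len(n), each = k), reorder = FALSE)
    ss_subj <- colSums(subj_sums^2) / k - n * k * grand^2
    df <- c(k - 1, (k - 1) * (n - 1))
    fcrit <- stat_threshold("F", df, threshold_p)
    with_rng(seed, {
      for (pp in seq_len(P)) {
        lab <- as.vector(vapply(seq_len(n), function(s) sample.int(k),
                                integer(k)))
        cond_sums <- rowsum(y, lab, reorder = TRUE)
        ss_cond <- colSums(cond_sums^2) / n - n * k * grand^2
        ss_cond[ss_cond <= 1e-10 * pmax(ss_tot, .Machine$double.xmin)] <- 0
        ss_err <- pmax(ss_tot - ss_subj - ss_cond, 0)
        fv <- (ss_cond / df[1]) / (ss_err / df[2])
        fv[ss_cond == 0] <- 0
        mask <- matrix(fv > fcrit, n_e, n_t)
        null[pp] <- max_cluster_sum_cpp(mask, matrix(fv, n_e, n_t), adj)
      }
    })
  } else {
    if (k != 2L) stopf("stat_kind = 't' requires exactly 2 conditions")
    dif <- matrix(maps$maps[, 1, , ] - maps$maps[, 2, , ], n, n_e * n_t)
    sumsq <- colSums(dif^2)
    tcrit <- stat_threshold("t", n - 1, threshold_p)
    with_rng(seed, {
      for (pp in seq_len(P)) {
        s <- sample(c(-1, 1), n, replace = TRUE)
        m <- drop(s %*% dif) / n
        v <- pmax((sumsq - n * m^2) / (n - 1), 0)
        tv <- m / sqrt(v / n)
        tv[v == 0 & m == 0] <- 0
        tm <- matrix(tv, n_e, n_t)
        pos <- max_cluster_sum_cpp(tm > tcrit, tm, adj)
        neg <- max_cluster_sum_cpp(tm < -tcrit, -tm, adj)
        null[pp] <- max(pos, neg)
      }
    })
  }
  structure(null, P = P, seed = seed, threshold_p = threshold_p,
            stat_kind = stat_kind, class = "permutation_null")
}

#' Monte-Carlo cluster p-values
#'
#' Compares each observed cluster's (absolute) summed statistic against
#' the permutation null of maximum cluster sums, using the add-one
#' convention `p = (1 + #\{null >= sum\}) / (1 + P)` so p-values are never
#' exactly zero. A cluster is significant iff `p < alpha`.
#'
#' @param clusters list of clusters from [find_clusters()].
#' @param null a `permutation_null`.
#' @param alpha significance level (default 0.05).
#' @param stat_map optionally, the observed `stat_map` to carry along.
#' @return An object of class `cluster_test_result`: list with `clusters`
#'   (each gaining a `p` field), `null`, `alpha`, `min_p`, `n_significant`,
#'   `any_significant`, `stat_map`.
#' @export
cluster_p_values <- function(clusters, null, alpha = 0.05, stat_map = NULL) {
  if (!length(null)) stopf("empty permutation null")
  P <- length(null)
  for (i in seq_along(clusters)) {
    b <- sum(null >= abs(clusters[[i]]$sum))
    clusters[[i]]$p <- (1 + b) / (1 + P)
  }
  pvals <- vapply(clusters, `[[`, numeric(1), "p")
  structure(list(clusters = clusters, null = null, alpha = alpha,
                 min_p = if (length(pvals)) min(pvals) else NA_real_,
                 n_significant = sum(pvals < alpha),
                 any_significant = any(pvals < alpha),
                 stat_map = stat_map),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result: %d cluster(s), %d significant at alpha = %g",
              length(x$clusters), x$n_significant, x$alpha))
  if (!is.na(x$min_p)) cat(sprintf(", min(p) = %.4g", x$min_p))
  cat(">\n")
  for (cl in x$clusters[seq_len(min(5L, length(x$clusters)))])
    cat(sprintf("  sum = %9.2f  size = %4d  p = %.4g%s\n", cl$sum,
                nrow(cl$members), cl$p, if (cl$p < x$alpha) " *" else ""))
  invisible(x)
}

#' Spatio-temporal cluster-based permutation test
#'
#' The full pipeline of the non-parametric test: optional baseline
#' correction, per-subject condition averaging, a pointwise RM-ANOVA
#' (k > 2) or paired-t (k = 2) map, clustering of suprathreshold points
#' under spatio-temporal adjacency, a within-subject label-permutation
#' null of maximum cluster sums, and Monte-Carlo cluster p-values.
#'
#' @param x an `epoch_set`, or a precomputed `sc_maps`.
#' @param conditions condition labels to compare (epoch input only;
#'   `NULL` = all). At least 2.
#' @param electrode_scope electrode IDs (`NULL` = all electrodes).
#' @param time_window analysis window in seconds (`NULL` = whole epoch).
#' @param baseline optional baseline window applied before averaging.
#' @param adjacency an `adjacency_graph`; default built from the epoch
#'   layout with `scale = 1.5`.
#' @param stat_kind `"auto"` (t for k = 2, F otherwise), `"F"`, or `"t"`.
#' @param P permutations (default 1000).
#' @param alpha significance level (default 0.05).
#' @param threshold_p cluster-defining pointwise threshold (default 0.05).
#' @param seed integer seed for the permutation stream.
#' @return a `cluster_test_result`.
#' @export
run_cluster_test <- function(x, conditions = NULL, electrode_scope = NULL,
                             time_window = NULL, baseline = NULL,
                             adjacency = NULL,
                             stat_kind = c("auto", "F", "t"), P = 1000L,
                             alpha = 0.05, threshold_p = 0.05, seed = 1L) {
  stat_kind <- match.arg(stat_kind)
  if (inherits(x, "epoch_set")) {
    if (!is.null(baseline)) x <- baseline_correct(x, baseline)
    if (is.null(adjacency)) adjacency <- build_adjacency(x$layout)
    maps <- condition_maps(x, conditions, electrode_scope, time_window)
  } else if (inherits(x, "sc_maps")) {
    maps <- x
    if (is.null(adjacency))
      stopf("adjacency must be supplied when testing precomputed maps")
  } else stopf("x must be an epoch_set or sc_maps")
  k <- dim(maps$maps)[2]
  if (k < 2L) stopf("need at least 2 conditions (got %d)", k)
  if (stat_kind == "auto") stat_kind <- if (k == 2L) "t" else "F"
  smap <- if (stat_kind == "t") pointwise_paired_t(maps)
          else pointwise_rm_anova(maps)
  clusters <- find_clusters(smap, threshold_p, adjacency)
  null <- permutation_null(maps, stat_kind, adjacency, P = P, seed = seed,
                           threshold_p = threshold_p)
  cluster_p_values(clusters, null, alpha = alpha, stat_map = smap)
}

#' Export a cluster test result
#'
#' `cluster_result_json` serializes the result (cluster summaries, null
#' distribution, configuration echo) to JSON; `cluster_table` returns a
#' per-cluster data frame suitable for TSV export.
#'
#' @param result a `cluster_test_result`.
#' @param path output file path (`NULL` returns the JSON string).
#' @return see above.
#' @export
cluster_result_json <- function(result, path = NULL) {
  payload <- list(
    alpha = result$alpha,
    min_p = result$min_p,
    n_significant = result$n_significant,
    P = attr(result$null, "P"),
    seed = attr(result$null, "seed"),
    threshold_p = attr(result$null, "threshold_p"),
    stat_kind = attr(result$null, "stat_kind"),
    clusters = cluster_table(result),
    null = as.numeric(result$null)
  )
  if (is.null(path))
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname cluster_result_json
#' @export
cluster_table <- function(result) {
  if (!length(result$clusters))
    return(data.frame(cluster = integer(), sum = numeric(), sign = numeric(),
                      size = integer(), p = numeric()))
  data.frame(
    cluster = seq_along(result$clusters),
    sum = vapply(result$clusters, `[[`, numeric(1), "sum"),
    sign = vapply(result$clusters, `[[`, numeric(1), "sign"),
    size = vapply(result$clusters, function(cl) nrow(cl$members), integer(1)),
    p = vapply(result$clusters, `[[`, numeric(1), "p")
  )
}
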