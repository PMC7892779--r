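#' Analysis configuration
#'
#' Bundles the shared knobs of the study analyses: permutation count,
#' significance level, cluster-defining threshold, adjacency scale, and
#' the master seed. Analysis-specific windows are fixed by the design
#' metadata and documented per runner.
#'
#' @param P number of permutations (default 1000).
#' @param alpha significance level (default 0.05).
#' @param threshold_p cluster-defining pointwise threshold (default 0.05).
#' @param adjacency_scale neighbour threshold multiplier (default 1.5).
#' @param seed master seed (default 1).
#' @return an object of class `analysis_config` (a list).
#' @export
analysis_config <- function(P = 1000L, alpha = 0.05, threshold_p = 0.05,
                            adjacency_scale = 1.5, seed = 1L) {
  structure(list(P = as.integer(P), alpha = alpha, threshold_p = threshold_p,
                 adjacency_scale = adjacency_scale, seed = as.integer(seed)),
            class = "analysis_config")
}

check_study_epochs <- function(epochs, need = c("indirectQ", "directQ",
                                                "declarative")) {
  design <- epochs$design
  if (is.null(design) || is.null(design$target_onset))
    stopf("epochs carry no standard study metadata")
  have <- epoch_conditions(epochs)
  for (tp in need) {
    conds <- conditions_of(design, tp)
    if (!length(conds) || !all(conds %in% have))
      stopf("missing condition type '%s' in epochs", tp)
  }
  design
}

# Average the short and long condition-average maps per subject, keeping
# one map per sentence type.
average_lengths <- function(maps, design, types) {
  d <- dim(maps$maps)
  out <- array(0, c(d[1], length(types), d[3], d[4]))
  conds <- dimnames(maps$maps)[[2]]
  for (i in seq_along(types)) {
    sel <- match(conditions_of(design, types[i]), conds)
    if (anyNA(sel)) stopf("missing conditions for type %s", types[i])
    out[, i, , ] <- apply(maps$maps[, sel, , , drop = FALSE], c(1, 3, 4),
                          mean)
  }
  dimnames(out) <- c(list(dimnames(maps$maps)[[1]], types), list(NULL, NULL))
  sc_maps(out, maps$electrodes, maps$time)
}

#' Interval analysis: SAN test between the main verb and the target word
#'
#' Three-condition (indirect question, direct question, declarative)
#' cluster permutation test over the verb-locked interval epoch, across
#' all electrodes. With `length = "both"` (the primary comparison) the
#' short and long versions are averaged per subject and the short-interval
#' window (-0.3 to 2.2 s) is used; `"short"`/`"long"` run the two-condition
#' indirect-vs-direct paired-t variant on the length-specific window
#' (-0.3 to 2.2 / 3.0 s). Baseline: the first 100 ms of the interval.
#'
#' @param epochs a verb-locked `epoch_set` with study metadata.
#' @param config an `analysis_config`.
#' @param length `"both"`, `"short"` or `"long"`.
#' @return a `cluster_test_result`.
#' @export
run_interval_analysis <- function(epochs, config = analysis_config(),
                                  length = c("both", "short", "long")) {
  length <- match.arg(length)
  design <- check_study_epochs(epochs)
  adjacency <- build_adjacency(epochs$layout, config$adjacency_scale)
  win <- design$interval_window[[if (length == "long") "long" else "short"]]
  epochs <- baseline_correct(epochs, c(win[1], win[1] + 0.1))
  if (length == "both") {
    maps <- condition_maps(epochs, time_window = win)
    maps <- average_lengths(maps, design,
                            c("indirectQ", "directQ", "declarative"))
    run_cluster_test(maps, adjacency = adjacency, stat_kind = "F",
                     P = config$P, alpha = config$alpha,
                     threshold_p = config$threshold_p, seed = config$seed)
  } else {
    conds <- c(conditions_of(design, "indirectQ", length),
               conditions_of(design, "directQ", length))
    run_cluster_test(epochs, conditions = conds, time_window = win,
                     adjacency = adjacency, stat_kind = "t", P = config$P,
                     alpha = config$alpha, threshold_p = config$threshold_p,
                     seed = config$seed)
  }
}

#' Overlap analysis: indirect vs whether questions
#'
#' Two-condition paired-t cluster test of indirect questions against
#' whether-questions (same question-selecting main verb), restricted to
#' the interval the two structures share — the adverb and embedded-subject
#' words (0.6-1.8 s post verb) — averaged across lengths. Baseline: first
#' 100 ms of the interval epoch.
#'
#' @param epochs a verb-locked `epoch_set` with study metadata.
#' @param config an `analysis_config`.
#' @return a `cluster_test_result`.
#' @export
run_whether_overlap_analysis <- function(epochs,
                                         config = analysis_config()) {
  design <- check_study_epochs(epochs, c("indirectQ", "whetherQ"))
  adjacency <- build_adjacency(epochs$layout, config$adjacency_scale)
  win0 <- design$interval_window$short
  epochs <- baseline_correct(epochs, c(win0[1], win0[1] + 0.1))
  overlap <- c(design$word_onsets$short[["adverb"]],
               design$word_onsets$short[["emb_verb"]])
  maps <- condition_maps(epochs, time_window = overlap)
  maps <- average_lengths(maps, design, c("indirectQ", "whetherQ"))
  run_cluster_test(maps, adjacency = adjacency, stat_kind = "t",
                   P = config$P, alpha = config$alpha,
                   threshold_p = config$threshold_p, seed = config$seed)
}

#' Per-word analyses between the verb and the target
#'
#' One three-condition cluster test per intervening word (adverb, embedded
#' subject, embedded verb), each on a word-locked epoch re-baselined with
#' the 100 ms before the word's onset, averaged across lengths.
#'
#' @param epochs a verb-locked `epoch_set` with study metadata.
#' @param config an `analysis_config`.
#' @param window word-locked analysis window (default `c(-0.1, 0.6)`).
#' @return named list of `cluster_test_result`s
#'   (`adverb`, `emb_subject`, `emb_verb`).
#' @export
run_per_word_analysis <- function(epochs, config = analysis_config(),
                                  window = c(-0.1, 0.6)) {
  design <- check_study_epochs(epochs)
  adjacency <- build_adjacency(epochs$layout, config$adjacency_scale)
  words <- c("adverb", "emb_subject", "emb_verb")
  seeds <- derive_seeds(config$seed, length(words))
  out <- list()
  for (i in seq_along(words)) {
    w <- words[i]
    onsets <- vapply(epoch_conditions(epochs), function(cond) {
      len <- sub("^.*\\.", "", cond)
      design$word_onsets[[len]][[w]]
    }, numeric(1))
    we <- slice_epochs(epochs, onsets, window, lock = w)
    we <- baseline_correct(we, c(-0.1, 0))
    maps <- condition_maps(we, time_window = c(0, window[2]))
    maps <- average_lengths(maps, design,
                            c("indirectQ", "directQ", "declarative"))
    out[[w]] <- run_cluster_test(maps, adjacency = adjacency,
                                 stat_kind = "F", P = config$P,
                                 alpha = config$alpha,
                                 threshold_p = config$threshold_p,
                                 seed = seeds[i])
  }
  out
}

#' Target-word analysis
#'
#' Three-condition cluster test on the target-word epoch (-0.3 to 1.0 s
#' around the wh-word/demonstrative onset, which differs between short and
#' long sentences), with a 100 ms pre-stimulus baseline, averaged across
#' lengths.
#'
#' @param epochs a verb-locked `epoch_set` with study metadata.
#' @param config an `analysis_config`.
#' @return a `cluster_test_result`.
#' @export
run_target_word_analysis <- function(epochs, config = analysis_config()) {
  design <- check_study_epochs(epochs)
  adjacency <- build_adjacency(epochs$layout, config$adjacency_scale)
  onsets <- vapply(epoch_conditions(epochs), function(cond)
    design$target_onset[[sub("^.*\\.", "", cond)]], numeric(1))
  te <- slice_epochs(epochs, onsets, design$target_window, lock = "target")
  te <- baseline_correct(te, c(-0.1, 0))
  maps <- condition_maps(te, time_window = c(0, design$target_window[2]))
  maps <- average_lengths(maps, design,
                          c("indirectQ", "directQ", "declarative"))
  run_cluster_test(maps, adjacency = adjacency, stat_kind = "F",
                   P = config$P, alpha = config$alpha,
                   threshold_p = config$threshold_p, seed = config$seed)
}

summarize_cluster_result <- function(result) {
  list(min_p = result$min_p, n_clusters = length(result$clusters),
       n_significant = result$n_significant,
       any_significant = result$any_significant,
       clusters = cluster_table(result))
}

#' Run the complete study pipeline
#'
#' Simulates (or loads) an epoch set and executes the full comparison
#' roster — interval (3-way and per length), whether-question overlap,
#' per-word, target word — plus the window-averaged Bayes-factor suite
#' and, optionally, the injection power grids. Every number in the report
#' is determined by `(config, seed)`.
#'
#' @param config an `analysis_config`.
#' @param epochs an `epoch_set`, or `NULL` to simulate.
#' @param preset generator preset when simulating (`"paper"`, `"null"`).
#' @param design,noise generator settings when simulating.
#' @param comparisons character subset of the roster (default: all).
#' @param power `NULL`, or a list of arguments for [power_grid()] (e.g.
#'   `list(component = "SAN", mu_grid = c(1, 2), n_grid = c(10),
#'   repetitions = 20)`).
#' @param out_dir directory for the JSON report and TSV tables (`NULL` =
#'   do not write).
#' @return An object of class `run_report`: list with `config`,
#'   `comparisons` (summaries), `bf_table`, `power`, `provenance`.
#' @export
run_full_study <- function(config = analysis_config(), epochs = NULL,
                           preset = c("paper", "null"),
                           design = study_design(), noise = noise_spec(),
                           comparisons = c("interval_3way", "whether_overlap",
                                           "per_word", "target_word_3way",
                                           "length_short", "length_long"),
                           power = NULL, out_dir = NULL) {
  preset <- match.arg(preset)
  known <- c("interval_3way", "whether_overlap", "per_word",
             "target_word_3way", "length_short", "length_long")
  bad <- setdiff(comparisons, known)
  if (length(bad)) stopf("unknown comparison id(s): %s",
                         paste(bad, collapse = ", "))
  seeds <- derive_seeds(config$seed, 3L)
  if (is.null(epochs)) {
    comps <- study_components(design, preset = preset)
    epochs <- simulate_study(design, noise, comps, seed = seeds[1])
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  res <- list()
  for (cmp in comparisons) {
    res[[cmp]] <- stage(cmp, switch(cmp,
      interval_3way = summarize_cluster_result(
        run_interval_analysis(epochs, config, "both")),
      whether_overlap = summarize_cluster_result(
        run_whether_overlap_analysis(epochs, config)),
      per_word = lapply(run_per_word_analysis(epochs, config),
                        summarize_cluster_result),
      target_word_3way = summarize_cluster_result(
        run_target_word_analysis(epochs, config)),
      length_short = summarize_cluster_result(
        run_interval_analysis(epochs, config, "short")),
      length_long = summarize_cluster_result(
        run_interval_analysis(epochs, config, "long"))))
  }
  bf <- stage("bayes", windowed_bf_suite(epochs, seed = seeds[2]))
  pw <- NULL
  if (!is.null(power))
    pw <- stage("power", do.call(power_grid,
                                 c(list(epochs = epochs), power,
                                   list(seed = seeds[3], P = config$P,
                                        alpha = config$alpha))))
  report <- structure(list(
    config = unclass(config),
    comparisons = res,
    bf_table = bf,
    power = if (is.null(pw)) NULL else as.data.frame(pw),
    provenance = list(package = "erpperm",
                      version = as.character(utils::packageVersion("erpperm")),
                      seed = config$seed, preset = preset,
                      epochs = epochs$provenance)
  ), class = "run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass_recursive(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    write_bf_tsv(bf, file.path(out_dir, "bayes_factors.tsv"))
    if (!is.null(pw)) write_power_grid(pw, file.path(out_dir, "power.tsv"))
  }
  report
}

unclass_recursive <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), unclass_recursive))
  x
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    if (!is.null(cmp$min_p) || nm != "per_word") {
      cat(sprintf("  %-18s min(p) = %s, %d significant cluster(s)\n", nm,
                  format(cmp$min_p, digits = 3), cmp$n_significant))
    } else {
      for (w in names(cmp))
        cat(sprintf("  per_word/%-9s min(p) = %s, %d significant cluster(s)\n",
                    w, format(cmp[[w]]$min_p, digits = 3),
                    cmp[[w]]$n_significant))
    }
  }
  cat(sprintf("  bayes factors: %d comparisons\n", nrow(x$bf_table)))
  if (!is.null(x$power))
    cat(sprintf("  power grid: %d cells\n", nrow(x$power)))
  invisible(x)
}
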