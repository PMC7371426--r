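empty_dt <- function(...) {
  cols <- list(...)
  data.table::as.data.table(stats::setNames(
    lapply(cols, function(type) vector(type, 0)), names(cols)))
}

summary_row <- function(group, values, metric, units) {
  s <- summarize_group(values, units)
  data.table::data.table(group = group, metric = metric, n = s$n,
                         mean = s$mean, sem = s$sem, q1 = s$q1,
                         median = s$median, q3 = s$q3, units = units)
}

#' Build the cohort analysis report bundle
#'
#' Runs the persistence analysis for one protocol (plus AHP/ADP analyses
#' and behavioral learning curves where the corresponding data exist) and
#' assembles the tables the study's summary tables follow: per-cell
#' metrics, per-group mean +/- SEM with quartiles, and pairwise test
#' p-values. Output ordering is deterministic; writing the same cohort
#' twice yields byte-identical files.
#'
#' @param cohort a [pf_cohort()].
#' @param protocol persistence protocol name to analyze (skipped when no
#'   cell has sweeps for it).
#' @param out_dir optional directory; when given, tables are written as CSV
#'   plus a machine-readable `report.json`.
#' @param ... passed to [detect_spikes()] via the analyses.
#' @return list of data.tables: `per_cell`, `group_summary`, `tests`,
#'   `behavior_per_animal`, `behavior_summary`.
#' @export
build_report <- function(cohort, protocol = "train20hz_250ms_2mv",
                         out_dir = NULL, ...) {
  per_cell <- empty_dt(cell_id = "character", group = "character",
                       probability = "numeric", onset_latency = "numeric",
                       mean_rate = "numeric", peak_rate = "numeric",
                       mAHP = "numeric", sAHP = "numeric",
                       adp_peak = "numeric", adp_auc = "numeric")
  group_summary <- empty_dt(group = "character", metric = "character",
                            n = "integer", mean = "numeric",
                            sem = "numeric", q1 = "numeric",
                            median = "numeric", q3 = "numeric",
                            units = "character")
  tests <- empty_dt(metric = "character", test = "character",
                    comparison = "character", statistic = "numeric",
                    p_value = "numeric")
  have_pf <- any(vapply(cohort$cells, function(cl)
    protocol %in% names(cl$sweeps), logical(1)))
  if (have_pf) {
    pt <- persistence_table(cohort, protocol, ...)
    tab <- pt$table
    ahp <- lapply(cohort$cells, function(cl)
      if ("ahp_burst50hz" %in% names(cl$sweeps)) ahp_cell(cl) else NULL)
    adp <- lapply(cohort$cells, function(cl)
      if ("adp_250ms_10mv" %in% names(cl$sweeps)) adp_cell(cl) else NULL)
    pick <- function(lst, field) vapply(tab$cell_id, function(id) {
      v <- lst[[id]]
      if (is.null(v)) NA_real_ else v[[field]]
    }, numeric(1))
    per_cell <- data.table::data.table(
      cell_id = tab$cell_id, group = tab$group,
      probability = tab$probability, onset_latency = tab$onset_latency,
      mean_rate = tab$mean_rate, peak_rate = tab$peak_rate,
      mAHP = pick(ahp, "mAHP"), sAHP = pick(ahp, "sAHP"),
      adp_peak = pick(adp, "adp_peak"), adp_auc = pick(adp, "auc"))
    data.table::setorder(per_cell, group, cell_id)
    metrics <- list(probability = c("probability", "fraction"),
                    onset_latency = c("onset_latency", "s"),
                    mean_rate = c("mean_rate", "spikes/s"),
                    mAHP = c("mAHP", "mV"), sAHP = c("sAHP", "mV"),
                    adp_peak = c("adp_peak", "mV"),
                    adp_auc = c("adp_auc", "mV*ms"))
    sumrows <- list()
    testrows <- list()
    for (m in names(metrics)) {
      units <- metrics[[m]][2]
      by_group <- split(per_cell[[m]], per_cell$group)
      by_group <- lapply(by_group, function(v) v[is.finite(v)])
      by_group <- by_group[lengths(by_group) > 0]
      if (!length(by_group)) next
      for (gname in sort(names(by_group)))
        sumrows[[length(sumrows) + 1L]] <-
          summary_row(gname, by_group[[gname]], m, units)
      nonpar <- identical(m, "probability")
      if (length(by_group) == 2 && all(lengths(by_group) >= 2)) {
        ts <- compare_two_unpaired(by_group[[1]], by_group[[2]],
                                   mode = if (nonpar) "mann_whitney"
                                          else "t_test")
        testrows[[length(testrows) + 1L]] <- data.table::data.table(
          metric = m, test = ts$test,
          comparison = paste(names(by_group), collapse = " vs "),
          statistic = ts$statistic, p_value = ts$p_value)
      } else if (length(by_group) > 2 && all(lengths(by_group) >= 2)) {
        cm <- compare_many(by_group, mode = if (nonpar) "kruskal_dunn"
                                            else "anova_tukey")
        testrows[[length(testrows) + 1L]] <- data.table::data.table(
          metric = m, test = cm$omnibus$test, comparison = "omnibus",
          statistic = cm$omnibus$statistic, p_value = cm$omnibus$p_value)
        for (pw in cm$pairwise)
          testrows[[length(testrows) + 1L]] <- data.table::data.table(
            metric = m, test = pw$test, comparison = pw$comparison,
            statistic = pw$statistic, p_value = pw$p_value)
      }
    }
    if (length(sumrows)) group_summary <- data.table::rbindlist(sumrows)
    if (length(testrows)) tests <- data.table::rbindlist(testrows)
  }
  behavior_per_animal <- empty_dt(animal_id = "character",
                                  group = "character", session = "integer",
                                  pct_cr = "numeric")
  behavior_summary <- empty_dt(group = "character", session = "integer",
                               n = "integer", mean_pct = "numeric",
                               sem_pct = "numeric")
  if (length(cohort$animals)) {
    lc <- learning_curves(cohort$animals)
    behavior_per_animal <- lc$per_animal
    behavior_summary <- lc$group_summary
    data.table::setorder(behavior_summary, group, session)
  }
  report <- list(per_cell = per_cell, group_summary = group_summary,
                 tests = tests, behavior_per_animal = behavior_per_animal,
                 behavior_summary = behavior_summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(report))
      data.table::fwrite(report[[nm]],
                         file.path(out_dir, paste0(nm, ".csv")))
    pf_write_json(lapply(report, as.data.frame),
                  file.path(out_dir, "report.json"))
  }
  report
}
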