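#' Run the intrinsic-properties study
#'
#' For each cell: selects the first trace with at least 10 APs
#' ([select_trace()]); computes the waveform metrics at the 2nd and 10th
#' AP and the mean over the first 10 APs; computes within-train
#' adaptation metrics ([adaptation()]) for recordings with at least 50
#' APs; then, per metric and AP position, runs a one-way ANOVA with
#' Tukey-Kramer comparisons across genotypes, bootstraps the group
#' means, and builds rate-binned tables. Cells failing trace selection
#' are excluded and logged, not fatal.
#'
#' @param cells List of [cell_recording()] objects (e.g. from
#'   [generate_cohort()]), or a directory of sweep bundles.
#' @param n_bins Rate bins for [bin_by_rate()].
#' @param boot_iter Bootstrap iterations per group (default 1000).
#' @param seed Optional RNG seed for the bootstrap.
#' @param out_dir Optional output directory for CSV/JSON reports.
#' @return A list of class `"intrinsic_report"`: `summaries` (per-cell
#'   metric rows), `stats` (per metric/position ANOVA + post hoc),
#'   `group_tables`, `bootstrap`, `binned`, `adaptation`, `excluded`.
#' @export
run_intrinsic_study <- function(cells, n_bins = 4, boot_iter = 1000,
                                seed = NULL, out_dir = NULL) {
  cells <- load_cells_arg(cells)
  if (!is.null(seed)) set.seed(seed)
  metrics <- c("height_mV", "half_width_ms", "threshold_V_mV",
               "max_slope_V_per_s", "interspike_potential_mV")
  rows <- list(); ap_rows <- list(); adapt_rows <- list()
  excluded <- character(0)
  for (cl in cells) {
    ts <- tryCatch(select_trace(cl), error = function(e) e)
    if (inherits(ts, "error")) {
      excluded <- c(excluded, sprintf("%s: %s", cl$cell_id,
                                      conditionMessage(ts)))
      next
    }
    for (pos in c("at_ap2", "at_ap10", "mean10")) {
      vals <- ts[[pos]]
      if (is.null(vals)) next
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cl$cell_id, genotype = cl$genotype, position = pos,
        metric = metrics, value = as.numeric(vals[metrics]),
        stringsAsFactors = FALSE)
    }
    ev <- ts$events
    ev$genotype <- cl$genotype
    ev$cell_id <- cl$cell_id
    ev$rate_Hz <- ts$firing_rate_Hz
    ap_rows[[length(ap_rows) + 1L]] <- ev
    ad <- adaptation(cl)
    adapt_rows[[length(adapt_rows) + 1L]] <- data.frame(
      cell_id = cl$cell_id, genotype = cl$genotype,
      eligible = ad$eligible, delta_ISI_ms = ad$delta_ISI_ms,
      delta_half_width_ms = ad$delta_half_width_ms,
      delta_interspike_mV = ad$delta_interspike_mV,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no cells passed trace selection")
  summaries <- do.call(rbind, rows)
  ap_table <- do.call(rbind, ap_rows)
  adapt <- do.call(rbind, adapt_rows)

  stats_rows <- list(); boot <- list(); tables <- list()
  for (pos in unique(summaries$position)) {
    for (m in metrics) {
      sel <- summaries[summaries$position == pos & summaries$metric == m, ]
      # the 10th-AP interspike potential is undefined when the 10th AP is
      # the trace's last; such cells drop out of that comparison only
      sel <- sel[is.finite(sel$value), ]
      if (nrow(sel) < 4L || length(unique(sel$genotype)) < 2L ||
          any(table(sel$genotype) < 2L)) next
      av <- one_way_anova(sel$value, sel$genotype)
      tk <- tukey_kramer(sel$value, sel$genotype)
      stats_rows[[paste(pos, m)]] <- data.frame(
        position = pos, metric = m, F = av$statistic, df1 = av$df[1],
        df2 = av$df[2], p = av$p_value,
        tukey = I(list(tk)), stringsAsFactors = FALSE)
      tables[[paste(pos, m)]] <- cbind(position = pos, metric = m,
                                       summarize_groups(sel$value,
                                                        sel$genotype))
      if (pos == "at_ap2")
        boot[[m]] <- lapply(split(sel$value, sel$genotype),
                            bootstrap_means, n_iter = boot_iter)
    }
  }
  report <- list(summaries = summaries,
                 stats = do.call(rbind, stats_rows),
                 group_tables = do.call(rbind, tables),
                 bootstrap = boot,
                 binned = bin_by_rate(ap_table, n_bins),
                 adaptation = adapt, excluded = excluded)
  class(report) <- "intrinsic_report"
  if (!is.null(out_dir)) write_intrinsic_report(report, out_dir)
  report
}

#' Run the paired-recording synaptic study
#'
#' For each pair: estimates passive properties from the test pulse,
#' measures the unitary IPSC amplitude from the single-pulse sweeps,
#' computes decay-corrected paired-pulse ratios per sweep (ratios are
#' computed per repeat, then averaged per interval) in current and
#' conductance units, and normalised 5-pulse-train curves (no decay
#' correction). Across genotypes it runs an unpaired two-tailed t test
#' per interval and a mixed repeated-measures ANOVA (Greenhouse-Geisser
#' corrected) over the PPR-by-interval profiles. Pairs whose series
#' resistance exceeds the 30 MOhm voltage-clamp bound are excluded and
#' logged.
#'
#' @param pairs List of synaptic [cell_recording()] objects or a bundle
#'   directory.
#' @param exclude_qc Apply the series-resistance QC exclusion (default
#'   `TRUE`).
#' @param out_dir Optional output directory.
#' @return A list of class `"synaptic_report"`: `pairs` (per-pair
#'   passive + unitary values), `ppr` (per pair x interval, current and
#'   conductance), `train` (per pair x interval x pulse), `t_tests`,
#'   `rm_anova_i`, `rm_anova_g`, `excluded`.
#' @export
run_synaptic_study <- function(pairs, exclude_qc = TRUE, out_dir = NULL) {
  pairs <- load_cells_arg(pairs)
  pair_rows <- list(); ppr_rows <- list(); train_rows <- list()
  excluded <- character(0)
  for (cl in pairs) {
    tp <- cl$sweeps[["testpulse"]]
    pm <- attr(tp, "test_pulse")
    if (is.null(pm)) pm <- list(dV_mV = -5, onset_ms = 20,
                                duration_ms = 100)
    passive <- tryCatch(measure_passive(tp, pm), error = function(e) NULL)
    if (is.null(passive)) {
      excluded <- c(excluded, sprintf("%s: passive estimation failed",
                                      cl$cell_id))
      next
    }
    if (exclude_qc && passive$R_series_MOhm > 30) {
      excluded <- c(excluded,
                    sprintf("%s: R_series %.1f MOhm exceeds 30 MOhm",
                            cl$cell_id, passive$R_series_MOhm))
      next
    }
    cp <- conductance_params(R_series_MOhm = passive$R_series_MOhm,
                             R_membrane_MOhm = passive$R_membrane_MOhm)
    singles <- grep("^single", names(cl$sweeps), value = TRUE)
    un <- unitary_amplitude(cl$sweeps[singles], cp)
    pair_rows[[cl$cell_id]] <- data.frame(
      pair_id = cl$cell_id, genotype = cl$genotype,
      R_series_MOhm = passive$R_series_MOhm,
      R_membrane_MOhm = passive$R_membrane_MOhm,
      tau_ms = passive$tau_ms, C_m_pF = passive$C_m_pF,
      unitary_nA = un$amplitude_nA, unitary_nS = un$amplitude_nS,
      stringsAsFactors = FALSE)
    for (sw in cl$sweeps[grep("^pp", names(cl$sweeps))]) {
      row <- tryCatch(ppr(sw, params = cp), error = function(e) NULL)
      if (is.null(row)) next
      row$pair_id <- cl$cell_id
      row$genotype <- cl$genotype
      ppr_rows[[length(ppr_rows) + 1L]] <- row
    }
    for (sw in cl$sweeps[grep("^tr", names(cl$sweeps))]) {
      tr <- tryCatch(train_response(sw, params = cp),
                     error = function(e) NULL)
      if (is.null(tr)) next
      tr$pair_id <- cl$cell_id
      tr$genotype <- cl$genotype
      train_rows[[length(train_rows) + 1L]] <- tr
    }
  }
  if (length(ppr_rows) == 0L) stop("no usable paired-pulse sweeps")
  ppr_all <- do.call(rbind, ppr_rows)
  # per-sweep ratios averaged per pair x interval
  ppr_pair <- stats::aggregate(
    cbind(ppr_i, ppr_g, A1_pA) ~ pair_id + genotype + delta_t_ms,
    data = ppr_all, FUN = mean)
  train_all <- if (length(train_rows)) do.call(rbind, train_rows)
  train_pair <- if (!is.null(train_all))
    stats::aggregate(cbind(norm_i, norm_g) ~
                       pair_id + genotype + delta_t_ms + pulse,
                     data = train_all, FUN = mean)

  t_rows <- list()
  for (d in sort(unique(ppr_pair$delta_t_ms))) {
    sel <- ppr_pair[ppr_pair$delta_t_ms == d, ]
    gs <- split(sel, sel$genotype)
    if (length(gs) == 2L && all(vapply(gs, nrow, integer(1)) >= 2L)) {
      ti <- unpaired_t(gs[[1]]$ppr_i, gs[[2]]$ppr_i)
      tg <- unpaired_t(gs[[1]]$ppr_g, gs[[2]]$ppr_g)
      t_rows[[as.character(d)]] <- data.frame(
        delta_t_ms = d, group1 = names(gs)[1], group2 = names(gs)[2],
        mean_i_1 = mean(gs[[1]]$ppr_i), mean_i_2 = mean(gs[[2]]$ppr_i),
        p_i = ti$p_value, mean_g_1 = mean(gs[[1]]$ppr_g),
        mean_g_2 = mean(gs[[2]]$ppr_g), p_g = tg$p_value)
    }
  }
  rm_i <- tryCatch(
    mixed_rm_anova(data.frame(value = ppr_pair$ppr_i,
                              subject = ppr_pair$pair_id,
                              within = ppr_pair$delta_t_ms,
                              between = ppr_pair$genotype)),
    error = function(e) NULL)
  rm_g <- tryCatch(
    mixed_rm_anova(data.frame(value = ppr_pair$ppr_g,
                              subject = ppr_pair$pair_id,
                              within = ppr_pair$delta_t_ms,
                              between = ppr_pair$genotype)),
    error = function(e) NULL)
  report <- list(pairs = do.call(rbind, pair_rows), ppr = ppr_pair,
                 ppr_sweeps = ppr_all, train = train_pair,
                 t_tests = do.call(rbind, t_rows), rm_anova_i = rm_i,
                 rm_anova_g = rm_g, excluded = excluded)
  class(report) <- "synaptic_report"
  if (!is.null(out_dir)) write_synaptic_report(report, out_dir)
  report
}

load_cells_arg <- function(cells) {
  if (is.character(cells) && length(cells) == 1L && dir.exists(cells)) {
    dirs <- list.dirs(cells, recursive = FALSE)
    cells <- lapply(dirs, load_cell)
  }
  stopifnot(is.list(cells), length(cells) > 0L)
  cells
}

write_intrinsic_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$summaries, file.path(out_dir, "waveform_metrics.csv"),
            row.names = FALSE)
  st <- report$stats
  st$tukey <- NULL
  write.csv(st, file.path(out_dir, "waveform_anova.csv"),
            row.names = FALSE)
  write.csv(report$group_tables, file.path(out_dir, "group_tables.csv"),
            row.names = FALSE)
  write.csv(report$adaptation, file.path(out_dir, "adaptation.csv"),
            row.names = FALSE)
  write.csv(report$binned$table, file.path(out_dir, "rate_binned.csv"),
            row.names = FALSE)
  writeLines(report$excluded, file.path(out_dir, "exclusions.log"))
  invisible(out_dir)
}

write_synaptic_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$pairs, file.path(out_dir, "pairs.csv"),
            row.names = FALSE)
  write.csv(report$ppr, file.path(out_dir, "ppr_by_interval.csv"),
            row.names = FALSE)
  if (!is.null(report$train))
    write.csv(report$train, file.path(out_dir, "train_curves.csv"),
              row.names = FALSE)
  if (!is.null(report$t_tests))
    write.csv(report$t_tests, file.path(out_dir, "ppr_t_tests.csv"),
              row.names = FALSE)
  stats <- list(
    rm_anova_current = rm_to_list(report$rm_anova_i),
    rm_anova_conductance = rm_to_list(report$rm_anova_g))
  jsonlite::write_json(stats, file.path(out_dir, "rm_anova.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(report$excluded, file.path(out_dir, "exclusions.log"))
  invisible(out_dir)
}

rm_to_list <- function(rm) {
  if (is.null(rm)) return(NULL)
  list(epsilon = rm$epsilon, effects = rm$effects)
}

#' Write a reproducibility manifest
#'
#' Records the seed, configuration digest and package version next to
#' pipeline outputs.
#'
#' @param out_dir Output directory.
#' @param seed Seed used for the run.
#' @param config Any serialisable configuration object.
#' @return Path of the manifest file, invisibly.
#' @export
write_manifest <- function(out_dir, seed, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "fsephys",
    version = as.character(utils::packageVersion("fsephys")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
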