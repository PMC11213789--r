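# Tabular and graphical agreement diagnostics: rank-spread boxplots colored
# by median Likert score, confusion-matrix heatmaps, repeated-rank plots.
# Plots are views; the emitted CSV tables are the record, and every plotted
# value is reproducible from them.

#' Rank-spread summary table
#'
#' One row per scan: the five-number rank summary over observers (whiskers
#' are min/max — with only a handful of observers, outlier fences are
#' unstable) plus the median Likert score, sorted by median rank with
#' `scan_id` as the tiebreak. The median over an even number of observers
#' is the usual mid-mean and may be non-integer.
#'
#' @param rank_matrix Subjects-by-observers matrix of PC ranks.
#' @param likert_matrix Subjects-by-observers matrix of Likert scores over
#'   the same subjects.
#' @return Data frame with columns `scan_id`, `median_rank`, `q1`, `q3`,
#'   `min`, `max`, `median_likert`.
#' @export
rank_spread_table <- function(rank_matrix, likert_matrix) {
  rank_matrix <- check_ratings(rank_matrix)
  likert_matrix <- check_ratings(likert_matrix)
  if (!setequal(rownames(rank_matrix), rownames(likert_matrix))) {
    alignment_error("rank and Likert matrices cover different scans")
  }
  likert_matrix <- likert_matrix[rownames(rank_matrix), , drop = FALSE]
  out <- data.frame(
    scan_id = rownames(rank_matrix),
    median_rank = apply(rank_matrix, 1, stats::median),
    q1 = apply(rank_matrix, 1, stats::quantile, probs = 0.25, names = FALSE),
    q3 = apply(rank_matrix, 1, stats::quantile, probs = 0.75, names = FALSE),
    min = apply(rank_matrix, 1, min),
    max = apply(rank_matrix, 1, max),
    median_likert = apply(likert_matrix, 1, stats::median),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$median_rank, out$scan_id), ]
  rownames(out) <- NULL
  out
}

#' Repeated-rank table
#'
#' For a 25 x 2 intraobserver matrix, the two session ranks per scan plus
#' their median, sorted ascending by median. Used for the repeated-rank dot
#' plots that show within-observer consistency across sessions.
#'
#' @param intra Subjects-by-2 ratings matrix (see
#'   [intraobserver_matrix()]).
#' @return Data frame with columns `scan_id`, `rank_1`, `rank_2`,
#'   `median_rank`.
#' @export
repeated_rank_table <- function(intra) {
  intra <- check_ratings(intra)
  if (ncol(intra) != 2L) {
    validation_error("an intraobserver matrix must have exactly 2 columns")
  }
  out <- data.frame(
    scan_id = rownames(intra),
    rank_1 = intra[, 1],
    rank_2 = intra[, 2],
    median_rank = (intra[, 1] + intra[, 2]) / 2,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$median_rank, out$scan_id), ]
  rownames(out) <- NULL
  out
}

confusion_long <- function(tab, extra) {
  df <- as.data.frame(as.table(tab), stringsAsFactors = FALSE)
  names(df) <- c("score_a", "score_b", "count")
  cbind(extra, df, row.names = NULL)
}

save_plot <- function(plot, path, width = 8, height = 5) {
  # headless-safe: try cairo png, fall back to pdf
  ok <- tryCatch({
    grDevices::png(path, width = width * 110, height = height * 110,
                   res = 110, type = "cairo")
    print(plot)
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    FALSE
  })
  if (!ok) {
    path <- sub("\\.png$", ".pdf", path)
    grDevices::pdf(path, width = width, height = height)
    print(plot)
    grDevices::dev.off()
  }
  path
}

#' Render the full study report
#'
#' Writes, per dataset: the rank-spread table and its boxplot figure, all
#' pairwise interobserver Likert confusion matrices (long-format CSV plus a
#' faceted heatmap); plus, per observer: the repeated-rank table/plot and
#' the intraobserver (session 1 vs session 2) confusion matrices. The file
#' set and names are deterministic; CSV content is byte-identical across
#' reruns of the same study.
#'
#' @param study An `iq_study` from [run_study()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(study, out_dir) {
  stopifnot(inherits(study, "iq_study"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_iq("iqrank_io_error", sprintf("cannot create '%s'", out_dir))
  }
  if (file.access(out_dir, 2) != 0) {
    abort_iq("iqrank_io_error", sprintf("output directory '%s' is not writable", out_dir))
  }
  files <- character()
  add <- function(p) files <<- c(files, p)
  obs_names <- names(study$config$observers)

  utils::write.csv(study$icc_table, file.path(out_dir, "icc_table.csv"),
                   row.names = FALSE)
  add(file.path(out_dir, "icc_table.csv"))

  for (dname in c("high", "low")) {
    spread <- rank_spread_table(study$matrices$inter[[dname]]$pc,
                                study$matrices$inter[[dname]]$likert)
    p_spread <- file.path(out_dir, sprintf("rank_spread_%s.csv", dname))
    utils::write.csv(spread, p_spread, row.names = FALSE)
    add(p_spread)

    spread$pos <- seq_len(nrow(spread))
    spread$likert_bin <- factor(round(spread$median_likert * 2) / 2)
    g <- ggplot2::ggplot(spread, ggplot2::aes(x = .data$pos)) +
      ggplot2::geom_boxplot(
        ggplot2::aes(ymin = .data$min, lower = .data$q1,
                     middle = .data$median_rank, upper = .data$q3,
                     ymax = .data$max, group = .data$pos,
                     fill = .data$likert_bin),
        stat = "identity"
      ) +
      ggplot2::scale_fill_viridis_d(name = "median Likert") +
      ggplot2::labs(
        x = "scans, sorted by median rank", y = "rank (1 = lowest IQ)",
        title = sprintf("Rank spread across observers (%s-variation dataset)", dname)
      ) +
      ggplot2::theme_minimal()
    add(save_plot(g, file.path(out_dir, sprintf("rank_spread_%s.png", dname))))

    pairs <- utils::combn(obs_names, 2)
    conf <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]
      b <- pairs[2, i]
      lik <- study$matrices$inter[[dname]]$likert
      confusion_long(
        confusion_matrix(lik[, a], lik[, b]),
        data.frame(observer_a = a, observer_b = b, stringsAsFactors = FALSE)
      )
    }))
    p_conf <- file.path(out_dir, sprintf("confusion_inter_%s.csv", dname))
    utils::write.csv(conf, p_conf, row.names = FALSE)
    add(p_conf)

    conf$pair <- paste(conf$observer_a, "vs", conf$observer_b)
    g <- ggplot2::ggplot(conf, ggplot2::aes(.data$score_a, .data$score_b,
                                            fill = .data$count)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 2.6) +
      ggplot2::facet_wrap(~pair) +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(
        x = "Likert score, first observer", y = "Likert score, second observer",
        title = sprintf("Interobserver Likert confusion (%s-variation dataset)", dname)
      ) +
      ggplot2::theme_minimal()
    add(save_plot(g, file.path(out_dir, sprintf("confusion_inter_%s.png", dname)),
                  width = 9, height = 7))
  }

  rep_tab <- do.call(rbind, lapply(obs_names, function(o) {
    tab <- repeated_rank_table(study$matrices$intra[[o]]$pc)
    lik <- study$matrices$intra[[o]]$likert
    tab$mean_likert <- rowMeans(lik)[tab$scan_id]
    tab$median_likert <- apply(lik, 1, stats::median)[tab$scan_id]
    cbind(observer = o, tab, row.names = NULL)
  }))
  p_rep <- file.path(out_dir, "repeated_ranks.csv")
  utils::write.csv(rep_tab, p_rep, row.names = FALSE)
  add(p_rep)

  long <- rbind(
    data.frame(observer = rep_tab$observer, scan_id = rep_tab$scan_id,
               median_rank = rep_tab$median_rank, session = "1",
               rank = rep_tab$rank_1, mean_likert = rep_tab$mean_likert),
    data.frame(observer = rep_tab$observer, scan_id = rep_tab$scan_id,
               median_rank = rep_tab$median_rank, session = "2",
               rank = rep_tab$rank_2, mean_likert = rep_tab$mean_likert)
  )
  g <- ggplot2::ggplot(long, ggplot2::aes(.data$median_rank, .data$rank)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$scan_id), color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$mean_likert, shape = .data$session)) +
    ggplot2::scale_color_viridis_c(name = "mean Likert") +
    ggplot2::facet_wrap(~observer) +
    ggplot2::labs(
      x = "median of the two session ranks", y = "rank (1 = lowest IQ)",
      title = "Repeated ranks of the original scans, per observer"
    ) +
    ggplot2::theme_minimal()
  add(save_plot(g, file.path(out_dir, "repeated_ranks.png"), width = 9, height = 6))

  conf_intra <- do.call(rbind, lapply(obs_names, function(o) {
    lik <- study$matrices$intra[[o]]$likert
    confusion_long(confusion_matrix(lik[, 1], lik[, 2]),
                   data.frame(observer = o, stringsAsFactors = FALSE))
  }))
  p_ci <- file.path(out_dir, "confusion_intra.csv")
  utils::write.csv(conf_intra, p_ci, row.names = FALSE)
  add(p_ci)

  g <- ggplot2::ggplot(conf_intra, ggplot2::aes(.data$score_a, .data$score_b,
                                                fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 2.6) +
    ggplot2::facet_wrap(~observer) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "Likert score, session 1", y = "Likert score, session 2",
      title = "Intraobserver Likert confusion (repeated originals)"
    ) +
    ggplot2::theme_minimal()
  add(save_plot(g, file.path(out_dir, "confusion_intra.png"), width = 9, height = 6))

  invisible(files)
}
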