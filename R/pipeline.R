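#' Pipeline configuration
#'
#' Bundles every knob of the full workflow (filter, distances, thresholds,
#' identification, diversity, gap tables). Defaults reproduce the standard
#' settings: K2P distances, the 0.1%-2% threshold grid in 0.1% steps, the
#' 95% intraspecific-coverage rule, Silverman-bandwidth KDE on 512 points,
#' and exact-tie best-close-match semantics.
#'
#' @param fasta,labels input file paths (see [read_labeled_fasta()]).
#' @param locus locus tag, e.g. `"COI"`.
#' @param trim optional `c(start_col, end_col)` window applied before
#'   anything else.
#' @param filter a [filter_policy()].
#' @param model `"K2P"` or `"P_DIST"`.
#' @param grid threshold grid for [optimize_threshold()].
#' @param coverage coverage for [percentile_threshold()].
#' @param kde_bw,kde_n KDE settings for [local_minima_threshold()].
#' @param tie_tol,strict_ambiguity see [best_close_match()].
#' @param out_dir directory the report bundle is written to.
#' @return A `run_config`.
#' @export
run_config <- function(fasta, labels, locus = "COI", trim = NULL,
                       filter = filter_policy(), model = "K2P",
                       grid = seq(0.001, 0.020, by = 0.001), coverage = 0.95,
                       kde_bw = "nrd0", kde_n = 512L, tie_tol = 1e-12,
                       strict_ambiguity = FALSE, out_dir = ".") {
  structure(list(fasta = fasta, labels = labels, locus = locus, trim = trim,
                 filter = filter, model = model, grid = grid,
                 coverage = coverage, kde_bw = kde_bw, kde_n = kde_n,
                 tie_tol = tie_tol, strict_ambiguity = strict_ambiguity,
                 out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    cls <- if (inherits(e, "bg_error")) class(e)[1] else "bg_stage_error"
    bg_stop(cls, sprintf("[stage %s] %s", name, conditionMessage(e)))
  })
}

#' Run the full barcoding-gap workflow
#'
#' filter -> distance matrix -> three threshold estimators ->
#' best-close-match identification at each estimated threshold ->
#' diversity statistics -> gap tables. Every artifact is written under
#' `config$out_dir`; thresholds appear in both proportion and percent in
#' every report so the two unit conventions can never be confused, and a
#' manifest itemises the configuration, the package version and every
#' excluded sequence.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the alignment, distance matrix, threshold
#'   estimates, identification reports, diversity summary, gap table and the
#'   paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, paste0(...))

  aln <- stage("read", read_labeled_fasta(config$fasta, config$labels,
                                          locus = config$locus))
  if (!is.null(config$trim))
    aln <- stage("trim", trim_alignment(aln, config$trim[1], config$trim[2]))
  aln <- stage("filter", apply_filter(aln, config$filter))
  excluded <- attr(aln, "excluded")

  dm <- stage("distances", pairwise_distance_matrix(aln, config$model))
  write_distance_matrix(dm, p("distance_matrix.tsv"))

  ests <- stage("thresholds", list(
    LOCAL_MINIMA = local_minima_threshold(dm, bw = config$kde_bw,
                                          n_grid = config$kde_n),
    THRESH_OPT = optimize_threshold(dm, aln$labels, grid = config$grid),
    PERCENTILE_95 = percentile_threshold(dm, aln$labels,
                                         coverage = config$coverage)))
  for (m in names(ests))
    write_threshold_diagnostics(ests[[m]],
                                p("threshold_", tolower(m), ".tsv"))
  jsonlite::write_json(
    lapply(ests, function(e) list(
      method = e$method, value = e$value, value_percent = 100 * e$value,
      candidates = e$candidates, candidates_percent = 100 * e$candidates,
      no_threshold = e$no_threshold)),
    p("thresholds.json"), auto_unbox = TRUE, digits = NA, na = "null",
    pretty = TRUE)

  reports <- stage("identify", {
    usable <- Filter(function(e) !e$no_threshold && !is.na(e$value), ests)
    lapply(usable, function(e)
      best_close_match(dm, aln$labels, e$value, tie_tol = config$tie_tol,
                       strict_ambiguity = config$strict_ambiguity))
  })
  for (m in names(reports))
    write_identification(reports[[m]], p("identification_", tolower(m), ".tsv"))

  div <- stage("diversity", diversity_summary(aln))
  jsonlite::write_json(unclass(div), p("diversity.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  gt <- stage("gaptable", gap_table(dm, aln$labels))
  write_species_distance_table(gt, p("species_distance_table.tsv"))
  write_gap_long(gt, p("gap_per_sequence.tsv"))

  g <- gap_exists(gt)
  manifest <- list(
    package = "barcodegap",
    version = as.character(utils::packageVersion("barcodegap")),
    config = list(fasta = config$fasta, labels = config$labels,
                  locus = config$locus, trim = config$trim,
                  filter = unclass(config$filter), model = config$model,
                  grid = config$grid, coverage = config$coverage,
                  kde_bw = config$kde_bw, kde_n = config$kde_n,
                  tie_tol = config$tie_tol,
                  strict_ambiguity = config$strict_ambiguity),
    n_input = attr(aln, "n") + nrow(excluded), n_retained = attr(aln, "n"),
    excluded = excluded,
    saturated_pairs = dm$exceptions,
    gap = list(exists = g$gap, interval = g$interval,
               interval_percent = if (g$gap) 100 * g$interval else NULL),
    thresholds_percent = lapply(ests, function(e) 100 * e$value))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)

  invisible(list(alignment = aln, distance_matrix = dm, thresholds = ests,
                 identifications = reports, diversity = div, gap_table = gt,
                 out_dir = config$out_dir))
}
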