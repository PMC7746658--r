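#' Reference report card of the 38-class limited-data benchmark
#'
#' The package bundles, as plain-text CSVs, the per-class recall/precision/F1
#' tables and the regime-level accuracy summary of the four-regime
#' PlantVillage limited-data benchmark (873 training / 4,384 testing images,
#' 26 diseased + 12 healthy classes), together with the per-class train/test
#' counts. They serve as validation fixtures for the metric routines — the
#' printed F1 cells and macro averages are recomputed from the printed
#' recall/precision values — and as a realistic unbalanced-count layout for
#' the procedural dataset generator.
#'
#' @return list with data.frames `summary` (regime, method, train/test
#'   accuracy in percent), `diseased` (26 rows; recall/precision/F1 per
#'   regime), `healthy` (12 rows), and `class_counts` (38 rows; species,
#'   class label, diseased/healthy group, train and test counts).
#' @export
benchmark_tables <- function() {
  p <- function(f) system.file("extdata", f, package = "leafgan",
                               mustWork = TRUE)
  list(summary = read.csv(p("benchmark_regime_summary.csv"),
                          check.names = FALSE),
       diseased = read.csv(p("benchmark_diseased_metrics.csv")),
       healthy = read.csv(p("benchmark_healthy_metrics.csv")),
       class_counts = read.csv(p("benchmark_class_counts.csv")))
}

#' Recompute F1 cells of a reference metric table
#'
#' For each class and regime, recomputes `F1 = 2RP/(R+P)` from the table's
#' recall and precision columns, rounds half-up to 2 decimals, and compares
#' with the printed F1 cell. The printed R and P are themselves rounded to 2
#' decimals, so the recomputed F1 can legitimately differ by one unit in the
#' last decimal; a cell counts as *consistent* when the printed F1 lies in
#' the F1 interval induced by `R +/- 0.005`, `P +/- 0.005` (F1 is monotone
#' in both arguments), and as a *strict* match when the point recomputation
#' agrees exactly.
#'
#' @param tab the `diseased` or `healthy` data.frame of [benchmark_tables()].
#' @return list with `n_cells`, `n_strict`, `n_consistent`, `strict_rate`,
#'   `match_rate` (consistent fraction), and `mismatches` (rows whose
#'   printed F1 is not even rounding-consistent).
#' @export
reproduce_f1_cells <- function(tab) {
  mism <- list()
  n_cells <- 0L; n_strict <- 0L; n_consistent <- 0L
  for (e in 1:4) {
    r <- tab[[sprintf("exp%d_recall", e)]]
    p <- tab[[sprintf("exp%d_precision", e)]]
    f_printed <- tab[[sprintf("exp%d_f1", e)]]
    f_new <- round_half_up(f1_score(r, p), 2)
    strict <- abs(f_new - f_printed) < 1e-9
    f_lo <- round_half_up(f1_score(pmax(r - 0.005, 0), pmax(p - 0.005, 0)), 2)
    f_hi <- round_half_up(f1_score(pmin(r + 0.005, 1), pmin(p + 0.005, 1)), 2)
    consistent <- f_printed >= f_lo - 1e-9 & f_printed <= f_hi + 1e-9
    n_cells <- n_cells + length(strict)
    n_strict <- n_strict + sum(strict)
    n_consistent <- n_consistent + sum(consistent)
    if (any(!consistent))
      mism[[length(mism) + 1]] <- data.frame(
        row = which(!consistent), regime = e,
        printed = f_printed[!consistent], recomputed = f_new[!consistent])
  }
  list(n_cells = n_cells, n_strict = n_strict, n_consistent = n_consistent,
       strict_rate = n_strict / n_cells,
       match_rate = n_consistent / n_cells,
       mismatches = if (length(mism)) do.call(rbind, mism)
                    else data.frame(row = integer(), regime = integer(),
                                    printed = numeric(),
                                    recomputed = numeric()))
}
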