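#' Read A-pair records from TSV
#'
#' Expects a UTF-8 tab-separated file with header columns `abbreviation`,
#' `full_form`, `concept_id`, `is_chemical` (0/1). Rows violating the record
#' invariants (empty abbreviation, full form or concept ID; `is_chemical`
#' outside \{0, 1\}) are reported with their line numbers.
#'
#' @param path file path.
#' @return Data frame of A-pairs with `is_chemical` as logical.
#' @export
read_apairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, colClasses = "character", quote = "",
                         fileEncoding = "UTF-8", check.names = FALSE)
  need <- c("abbreviation", "full_form", "concept_id", "is_chemical")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  lineno <- seq_len(nrow(d)) + 1L  # header is line 1
  bad_empty <- !nzchar(d$abbreviation) | !nzchar(d$full_form) |
    !nzchar(d$concept_id)
  bad_flag <- !d$is_chemical %in% c("0", "1")
  bad <- bad_empty | bad_flag
  if (any(bad))
    stop("malformed A-pair rows at line(s): ",
         paste(lineno[bad], collapse = ", "))
  data.frame(abbreviation = d$abbreviation, full_form = d$full_form,
             concept_id = d$concept_id,
             is_chemical = d$is_chemical == "1",
             stringsAsFactors = FALSE)
}

#' Write A-pair records to TSV
#'
#' Inverse of [read_apairs()]: columns `abbreviation`, `full_form`,
#' `concept_id`, `is_chemical` with the flag encoded as 0/1.
#'
#' @param apairs A-pair data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_apairs <- function(apairs, path) {
  stopifnot(is.data.frame(apairs),
            all(c("abbreviation", "full_form", "concept_id", "is_chemical")
                %in% names(apairs)))
  out <- data.frame(abbreviation = apairs$abbreviation,
                    full_form = apairs$full_form,
                    concept_id = apairs$concept_id,
                    is_chemical = as.integer(apairs$is_chemical))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Configuration of a full clustering experiment
#'
#' Bundles the input (an A-pair data frame, a TSV path, or a
#' [generator_config()]), the measures to evaluate, the threshold grids, the
#' weight-optimization switch and the fixed recall of the split-vs-mixed
#' comparison.
#'
#' @param apairs A-pair data frame, or NULL.
#' @param input_path path to an A-pair TSV, or NULL.
#' @param generator a [generator_config()] used when no A-pairs are supplied.
#' @param measures subset of [measure_names()] to evaluate (the weighted edit
#'   distance is driven by `optimize_weights` instead).
#' @param grid threshold grid for the reported sweeps, see [threshold_grid()].
#' @param optimize_weights if TRUE, learn per-subset weight vectors and
#'   cross-apply them.
#' @param weight_step,weight_range coordinate-descent search grid, see
#'   [optimize_weights()].
#' @param target_recall fixed recall of the split-vs-mixed comparison.
#' @param soft_tfidf_a SoftTFIDF secondary-similarity cutoff.
#' @param dice_n n-gram length for the Dice coefficient.
#' @param seed integer seed for the whole run.
#' @return A list with class `"experiment_config"`.
#' @export
experiment_config <- function(apairs = NULL, input_path = NULL,
                              generator = generator_config(),
                              measures = c("edit", "monge_elkan",
                                           "soft_tfidf", "bigram_dice"),
                              grid = "observed",
                              optimize_weights = FALSE,
                              weight_step = 0.1, weight_range = c(0, 1),
                              target_recall = 0.8,
                              soft_tfidf_a = 0.9, dice_n = 2,
                              seed = 1L) {
  measures <- match.arg(measures, measure_names(), several.ok = TRUE)
  stopifnot(length(measures) >= 1, target_recall > 0, target_recall <= 1)
  structure(list(apairs = apairs, input_path = input_path,
                 generator = generator, measures = measures, grid = grid,
                 optimize_weights = optimize_weights,
                 weight_step = weight_step, weight_range = weight_range,
                 target_recall = target_recall,
                 soft_tfidf_a = soft_tfidf_a, dice_n = dice_n,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the full clustering experiment
#'
#' Loads or generates A-pairs, splits them into chemical and non-chemical
#' subsets, generates candidate pairs within each subset, scores them with
#' every configured measure, finds each measure's best-F operating point per
#' subset, optionally learns per-subset insertion/deletion weight vectors and
#' cross-applies them (the chemical-optimized vector on the non-chemical
#' subset and vice versa), and compares split versus single-threshold
#' matching with the edit distance at the configured fixed recall.
#'
#' @param config an [experiment_config()].
#' @return A list with class `"abbrsim_experiment"`: `best_f` (per measure
#'   and subset), `split_comparison`, `weights` (NULL unless optimized),
#'   `weighted_best_f`, `pr_curves`, `sweeps`, `n_pairs`, and `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  apairs <- config$apairs
  if (is.null(apairs) && !is.null(config$input_path))
    apairs <- read_apairs(config$input_path)
  if (is.null(apairs))
    apairs <- generate_dataset(config$generator)
  stopifnot(is.data.frame(apairs), "is_chemical" %in% names(apairs))

  subsets <- list(chemical = apairs[apairs$is_chemical, , drop = FALSE],
                  other = apairs[!apairs$is_chemical, , drop = FALSE])
  cands <- lapply(subsets, generate_candidates)

  scored <- list()
  best_rows <- list()
  sweeps <- list()
  curves <- list()
  for (m in config$measures) {
    dir <- measure_direction(m)
    for (sub in names(cands)) {
      if (nrow(cands[[sub]]) == 0) next
      sc <- score_pairs(cands[[sub]], m, a = config$soft_tfidf_a,
                        n = config$dice_n)
      scored[[paste(m, sub, sep = ".")]] <- sc
      sw <- sweep_thresholds(sc, dir, config$grid)
      sweeps[[paste(m, sub, sep = ".")]] <- sw
      bf <- best_threshold(sw, dir)
      best_rows[[paste(m, sub, sep = ".")]] <-
        cbind(data.frame(measure = m, subset = sub, direction = dir), bf)
      if (sum(sc$gold) > 0)
        curves[[paste(m, sub, sep = ".")]] <- pr_curve(sc, dir)
    }
  }
  best_f <- do.call(rbind, c(best_rows, list(make.row.names = FALSE)))

  weights <- NULL
  weighted_best_f <- NULL
  if (isTRUE(config$optimize_weights)) {
    ok <- vapply(cands, function(p) nrow(p) > 0 && sum(p$gold) > 0, logical(1))
    if (all(ok)) {
      opt <- lapply(cands, optimize_weights, grid_step = config$weight_step,
                    value_range = config$weight_range)
      weights <- list(chemical = opt$chemical, other = opt$other)
      combos <- expand.grid(vector = c("chemical", "other"),
                            subset = c("chemical", "other"),
                            stringsAsFactors = FALSE)
      weighted_best_f <- do.call(rbind, lapply(seq_len(nrow(combos)),
        function(i) {
          v <- combos$vector[i]; s <- combos$subset[i]
          cbind(data.frame(vector = v, subset = s),
                evaluate_weight_vector(cands[[s]], opt[[v]]$weights))
        }))
    } else {
      warning("weight optimization skipped: a subset lacks gold-positive pairs")
    }
  }

  split_comparison <- NULL
  chem_edit <- scored[["edit.chemical"]]
  oth_edit <- scored[["edit.other"]]
  if (!is.null(chem_edit) && !is.null(oth_edit) &&
      sum(chem_edit$gold) > 0 && sum(oth_edit$gold) > 0) {
    split_comparison <- compare_split_vs_mixed(chem_edit, oth_edit,
                                               config$target_recall,
                                               "distance")
  } else {
    warning("split-vs-mixed comparison skipped: a subset is empty or has ",
            "no gold-positive pairs")
  }

  structure(list(best_f = best_f, split_comparison = split_comparison,
                 weights = weights, weighted_best_f = weighted_best_f,
                 pr_curves = curves, sweeps = sweeps,
                 n_pairs = vapply(cands, nrow, integer(1)),
                 n_apairs = vapply(subsets, nrow, integer(1)),
                 config = config),
            class = "abbrsim_experiment")
}

#' @export
print.abbrsim_experiment <- function(x, ...) {
  cat("Abbreviation full-form clustering experiment\n")
  cat(sprintf("  A-pairs: %d chemical, %d other\n",
              x$n_apairs[["chemical"]], x$n_apairs[["other"]]))
  cat(sprintf("  candidate pairs: %d chemical, %d other\n",
              x$n_pairs[["chemical"]], x$n_pairs[["other"]]))
  cat("\nBest-F operating points:\n")
  print(x$best_f, row.names = FALSE, digits = 4)
  if (!is.null(x$weighted_best_f)) {
    cat("\nWeighted edit distance (learned vectors, cross-applied):\n")
    print(x$weighted_best_f, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$split_comparison)) {
    cat(sprintf("\nSplit vs mixed thresholds at recall %.2f (edit distance):\n",
                x$config$target_recall))
    print(x$split_comparison, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write experiment outputs as TSV files plus a plain-text report
#'
#' @param report an [run_experiment()] result.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "abbrsim_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$best_f, "best_f.tsv")
  if (!is.null(report$split_comparison))
    wt(report$split_comparison, "split_comparison.tsv")
  if (!is.null(report$weighted_best_f))
    wt(report$weighted_best_f, "weighted_best_f.tsv")
  if (!is.null(report$weights)) {
    write_weight_vector(report$weights$chemical$weights,
                        file.path(dir, "weights_chemical.tsv"))
    write_weight_vector(report$weights$other$weights,
                        file.path(dir, "weights_other.tsv"))
  }
  for (nm in names(report$sweeps))
    wt(report$sweeps[[nm]], paste0("sweep_", nm, ".tsv"))
  for (nm in names(report$pr_curves))
    wt(report$pr_curves[[nm]], paste0("pr_", nm, ".tsv"))
  txt <- file.path(dir, "report.txt")
  sink(txt); on.exit(sink(), add = TRUE)
  print(report)
  invisible(dir)
}
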