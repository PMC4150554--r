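#' Parameters for ensemble variable selection
#'
#' Controls the balanced-subsampling random-forest selection ensemble:
#' `n_subsets` balanced case-control subsets are drawn, a random forest of
#' `trees` trees is fitted to each, and each forest contributes its
#' `top_k` most important variables to the occurrence tally.
#'
#' @param n_subsets Number of balanced subsets (default 500).
#' @param trees Trees per forest (default 500).
#' @param top_k Variables kept from each forest's importance ranking
#'   (default 8).
#' @param importance `"gini"` (mean decrease in impurity, the default) or
#'   `"permutation"` (mean decrease in accuracy).
#' @param alpha Significance level for the Mann-Whitney refinement step
#'   (default 0.05).
#' @param mtry Variables tried per split; `NULL` means the forest default
#'   (square root of the number of candidates).
#' @param seed Integer seed driving subset draws and forest fits.
#' @return A list of class `selection_params`.
#' @export
selection_params <- function(n_subsets = 500, trees = 500, top_k = 8,
                             importance = c("gini", "permutation"),
                             alpha = 0.05, mtry = NULL, seed = 1L) {
  stopifnot(n_subsets >= 1, trees >= 1, top_k >= 1)
  structure(list(n_subsets = n_subsets, trees = trees, top_k = top_k,
                 importance = match.arg(importance), alpha = alpha,
                 mtry = mtry, seed = seed),
            class = "selection_params")
}

#' Draw balanced case-control subsets
#'
#' Each subset combines every positive record with an equal-size random
#' sample of negatives drawn without replacement; subsets are drawn
#' independently of one another (the same negative may appear in several
#' subsets). This removes the class imbalance seen by each individual
#' forest.
#'
#' @param cohort A data frame with a binary `outcome` column.
#' @param n_subsets Number of subsets.
#' @param seed Integer seed.
#' @return A list of integer row-index vectors, each of length
#'   `2 * n_positive`.
#' @export
balanced_subsets <- function(cohort, n_subsets, seed = 1L) {
  pos <- which(cohort$outcome == 1)
  neg <- which(cohort$outcome == 0)
  if (length(pos) < 1) stop("cohort has no positive records")
  if (length(neg) < length(pos))
    stop("fewer negatives than positives; cannot balance")
  set.seed(seed)
  lapply(seq_len(n_subsets), function(i) {
    c(pos, if (length(neg) == length(pos)) neg
      else sample(neg, length(pos)))
  })
}

#' Rank variables on one subset with a random forest
#'
#' Fits a random forest to the standardized feature table of one balanced
#' subset and returns the `top_k` variables by the configured importance
#' measure, most important first. Ties are broken by the fixed column
#' order of `variables`.
#'
#' @param data Data frame holding the candidate columns and `outcome`.
#' @param variables Candidate variable names (fixed order).
#' @param params A [selection_params()].
#' @return Character vector of length `min(top_k, length(variables))`.
#' @export
rank_subset <- function(data, variables, params = selection_params()) {
  stopifnot(all(variables %in% names(data)))
  k <- min(params$top_k, length(variables))
  x <- scale(as.matrix(data[, variables, drop = FALSE]))
  x[, apply(is.na(x), 2, any)] <- 0   # constant columns standardize to 0
  y <- factor(data$outcome, levels = c(0, 1))
  mtry <- if (is.null(params$mtry)) max(1, floor(sqrt(length(variables))))
          else params$mtry
  rf <- randomForest::randomForest(
    x, y, ntree = params$trees, mtry = mtry,
    importance = params$importance == "permutation")
  imp <- if (params$importance == "permutation")
    randomForest::importance(rf, type = 1)[, 1]
  else
    randomForest::importance(rf, type = 2)[, 1]
  ord <- order(-imp[variables], seq_along(variables))
  variables[ord][seq_len(k)]
}

#' Occurrence tally over the selection ensemble
#'
#' Runs the full ensemble -- `n_subsets` balanced subsets, one forest per
#' subset, `top_k` variables retained from each -- and tallies how many
#' subsets each variable's ranking appeared in. The tally sums to
#' `top_k * n_subsets` by construction and no variable can exceed
#' `n_subsets`.
#'
#' @param cohort Data frame with candidate columns and `outcome`.
#' @param params A [selection_params()].
#' @param variables Candidate variable names; defaults to the intersection
#'   of [mace_variables()] with the cohort's columns.
#' @return An `occurrence_table`: a data frame with columns `variable`,
#'   `occurrence` and `mean_rank` (mean position within the per-subset
#'   top-k lists where the variable appeared), sorted by occurrence, then
#'   mean rank, then fixed column order. Attributes `n_subsets` and
#'   `top_k` record the ensemble size.
#' @export
ensemble_occurrences <- function(cohort, params = selection_params(),
                                 variables = intersect(mace_variables(),
                                                       names(cohort))) {
  subsets <- balanced_subsets(cohort, params$n_subsets, seed = params$seed)
  counts <- stats::setNames(integer(length(variables)), variables)
  rank_sum <- stats::setNames(numeric(length(variables)), variables)
  for (idx in subsets) {
    top <- rank_subset(cohort[idx, , drop = FALSE], variables, params)
    counts[top] <- counts[top] + 1L
    rank_sum[top] <- rank_sum[top] + seq_along(top)
  }
  mean_rank <- ifelse(counts > 0, rank_sum / counts, Inf)
  ord <- order(-counts, mean_rank, seq_along(variables))
  structure(
    data.frame(variable = variables[ord], occurrence = as.integer(counts[ord]),
               mean_rank = mean_rank[ord], row.names = NULL),
    class = c("occurrence_table", "data.frame"),
    n_subsets = params$n_subsets, top_k = params$top_k)
}

#' Two-sided Mann-Whitney test p-value
#'
#' Rank-sum comparison of two groups: exact enumeration when the combined
#' sample size is at most 20 and there are no ties, otherwise the normal
#' approximation with tie correction. Two identical constant groups give
#' p = 1.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return Two-sided p-value.
#' @examples
#' mann_whitney_p(c(1, 2, 3), c(10, 11, 12))  # exact: 0.1
#' @export
mann_whitney_p <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (stats::sd(c(x, y)) == 0 || length(unique(c(x, y))) == 1) return(1)
  exact <- (length(x) + length(y)) <= 20 && !any(duplicated(c(x, y)))
  stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
}

#' Ensemble variable selection with significance refinement
#'
#' Takes the `top_k` variables by ensemble occurrence and removes any
#' whose full-cohort Mann-Whitney p-value is not below `alpha`, i.e. a
#' variable must be both stably top-ranked by the forests and
#' statistically significant between outcome groups to survive.
#'
#' @inheritParams ensemble_occurrences
#' @return A `variable_selection`: list with the occurrence table, the
#'   per-variable p-values (all candidates), the ordered final `selected`
#'   set, the `excluded` top-k variables with their p-values, and the
#'   parameters. Warns (and records an empty selection) if nothing
#'   survives.
#' @export
select_variables <- function(cohort, params = selection_params(),
                             variables = intersect(mace_variables(),
                                                   names(cohort))) {
  occ <- ensemble_occurrences(cohort, params, variables)
  pos <- cohort$outcome == 1
  pvals <- vapply(variables, function(v)
    mann_whitney_p(cohort[[v]][pos], cohort[[v]][!pos]), numeric(1))
  top <- occ$variable[seq_len(min(params$top_k, nrow(occ)))]
  keep <- pvals[top] < params$alpha
  if (!any(keep))
    warning("no top-ranked variable is significant; selection is empty")
  structure(list(
    occurrences = occ,
    p_values = pvals,
    selected = top[keep],
    excluded = data.frame(variable = top[!keep], p = pvals[top[!keep]],
                          row.names = NULL),
    params = params
  ), class = "variable_selection")
}

#' @export
print.variable_selection <- function(x, ...) {
  cat(sprintf("Ensemble variable selection (%d subsets x %d trees, top %d)\n",
              x$params$n_subsets, x$params$trees, x$params$top_k))
  top <- utils::head(x$occurrences, x$params$top_k)
  cat("Top-ranked by occurrence:\n")
  print(data.frame(top[, c("variable", "occurrence")],
                   p = signif(x$p_values[top$variable], 3), row.names = NULL))
  cat("Selected: ", paste(x$selected, collapse = ", "), "\n")
  if (nrow(x$excluded))
    cat("Excluded (p >= alpha): ",
        paste(x$excluded$variable, collapse = ", "), "\n")
  invisible(x)
}

#' Write an occurrence table or selection report
#'
#' @param x An `occurrence_table` or `variable_selection`.
#' @param path Output path; `.csv` for occurrence tables, `.json` for
#'   selection reports.
#' @export
write_selection <- function(x, path) {
  if (inherits(x, "occurrence_table")) {
    utils::write.csv(x[, c("variable", "occurrence")], path,
                     row.names = FALSE)
  } else if (inherits(x, "variable_selection")) {
    jsonlite::write_json(list(
      selected = x$selected,
      occurrences = stats::setNames(as.list(x$occurrences$occurrence),
                                    x$occurrences$variable),
      p_values = as.list(signif(x$p_values, 6)),
      excluded = x$excluded$variable
    ), path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported object")
  invisible(path)
}
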