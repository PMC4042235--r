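# Dataset splitting, unicolumn statistics and descriptor contributions.

#' Training/test split specification
#'
#' @param train_ids,test_ids disjoint character vectors of compound ids.
#' @export
split_spec <- function(train_ids, test_ids = character(0)) {
  train_ids <- as.character(train_ids); test_ids <- as.character(test_ids)
  if (length(intersect(train_ids, test_ids)) > 0)
    stop("train and test sets overlap: ",
         paste(intersect(train_ids, test_ids), collapse = ", "))
  structure(list(train_ids = train_ids, test_ids = test_ids), class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split: %d training, %d test>\n", length(x$train_ids), length(x$test_ids)))
  invisible(x)
}

#' Interpolative test-set selection
#'
#' Automated alternative to a manual split, in the spirit of
#' sphere-exclusion designs: the test set must interpolate both in activity
#' (strictly inside the training range) and in descriptor space (no test
#' compound far from the training cloud). Interior-activity compounds are
#' ranked by their Euclidean distance from the descriptor centroid
#' (standardized principal-component space); among the most central
#' `central_fraction`, `n_test` compounds evenly spaced in activity rank
#' become the test set.
#'
#' @param m descriptor_matrix.
#' @param n_test number of test compounds.
#' @param central_fraction fraction of the most descriptor-central interior
#'   compounds eligible for the test set.
#' @return [split_spec()].
#' @export
activity_ranked_split <- function(m, n_test = 5L, central_fraction = 0.6) {
  n <- length(m$compound_ids)
  stopifnot(n_test >= 1, n_test <= n - 3)
  ord <- order(m$activities)                 # ascending activity
  interior <- ord[2:(n - 1)]                 # extremes always train
  centrality <- descriptor_centrality(m$values)
  eligible <- interior[order(centrality[interior])]
  eligible <- eligible[seq_len(max(n_test, ceiling(length(eligible) * central_fraction)))]
  eligible <- eligible[order(m$activities[eligible])]
  pick <- eligible[round(seq(1, length(eligible), length.out = n_test))]
  split_spec(setdiff(m$compound_ids, m$compound_ids[pick]), m$compound_ids[pick])
}

# descriptor-space centrality on the leading principal components
descriptor_centrality <- function(values) {
  pc <- stats::prcomp(values, center = TRUE, scale. = FALSE)
  k <- min(5L, sum(pc$sdev > 1e-8))
  Z <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, pc$sdev[seq_len(k)], `/`)
  sqrt(rowSums(Z^2))
}

#' Unicolumn statistics of an activity column
#'
#' @param activities numeric vector.
#' @return list with `average`, `max`, `min`, `std_dev` (sample), `sum`.
#' @export
unicolumn_stats <- function(activities) {
  if (length(activities) == 0) stop("empty activity vector")
  list(average = mean(activities), max = max(activities), min = min(activities),
       std_dev = if (length(activities) > 1) stats::sd(activities) else 0,
       sum = sum(activities))
}

#' Unicolumn report for a split
#'
#' One row per set with the columns of a conventional unicolumn table
#' (Average, Max, Min, Std Dev, Sum).
#'
#' @param m descriptor_matrix.
#' @param split split_spec.
#' @return data.frame.
#' @export
unicolumn_report <- function(m, split) {
  row <- function(set, ids) {
    s <- unicolumn_stats(unname(m$activities[ids]))
    data.frame(Set = set, Column = "pIC50", Average = s$average, Max = s$max,
               Min = s$min, StdDev = s$std_dev, Sum = s$sum)
  }
  rbind(row("Training", split$train_ids),
        if (length(split$test_ids) > 0) row("Test", split$test_ids))
}

#' Check that a test set is interpolative
#'
#' True iff max(train) > max(test) and min(test) > min(train) (strict): the
#' test activities then lie inside the training range and external
#' predictions interpolate rather than extrapolate.
#'
#' @param train,test numeric activity vectors.
#' @return logical with a `messages` attribute naming violated conditions.
#' @export
check_split_interpolative <- function(train, test) {
  stopifnot(length(train) > 0, length(test) > 0)
  msgs <- character(0)
  if (!(max(train) > max(test)))
    msgs <- c(msgs, "max(test) is not strictly below max(train)")
  if (!(min(test) > min(train)))
    msgs <- c(msgs, "min(test) is not strictly above min(train)")
  structure(length(msgs) == 0, messages = msgs)
}

#' Signed descriptor contribution percentages
#'
#' contribution_i = 100 * c_i * range_i / sum_j |c_j * range_j|, where
#' range_i is the training-set range of descriptor i; the sign follows the
#' coefficient and absolute contributions sum to 100.
#'
#' @param model qsar_model.
#' @param m descriptor_matrix containing the model descriptors.
#' @param train optional split_spec; ranges are taken over its training
#'   compounds (default: all rows of `m`).
#' @return named numeric vector of signed percentages.
#' @export
contribution_percentages <- function(model, m, train = NULL) {
  ids <- if (is.null(train)) m$compound_ids else train$train_ids
  idx <- match(ids, m$compound_ids)
  miss <- setdiff(model$descriptor_names, colnames(m$values))
  if (length(miss) > 0) stop("model descriptor(s) not in matrix: ",
                             paste(miss, collapse = ", "))
  X <- m$values[idx, model$descriptor_names, drop = FALSE]
  rng <- apply(X, 2, function(v) diff(range(v)))
  prod <- model$coefficients * rng
  tot <- sum(abs(prod))
  if (tot < 1e-300) stop("all coefficient x range products are zero")
  100 * prod / tot
}
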