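# Partial least squares (PLS1, NIPALS) on mean-centered descriptors.
#
# Field descriptors share kcal/mol units, so columns are centered but not
# autoscaled (configurable). The fitted latent-variable model is stored as
# its equivalent linear equation: coefficients on the original descriptor
# scale plus an intercept, which is what the model equation reports.

#' QSAR model object
#'
#' The realization of a grid-field linear model equation: selected
#' descriptor names, their coefficients, the intercept (regression
#' constant), and the number of PLS latent components behind the fit.
#'
#' @param descriptor_names character vector.
#' @param coefficients numeric vector, same length.
#' @param intercept numeric scalar.
#' @param n_components integer >= 1.
#' @param training_mean_activity mean pIC50 of the training set (used as the
#'   reference mean in external validation).
#' @export
qsar_model <- function(descriptor_names, coefficients, intercept,
                       n_components = 1L, training_mean_activity = NA_real_) {
  stopifnot(length(descriptor_names) == length(coefficients),
            n_components >= 1, is.finite(intercept), all(is.finite(coefficients)))
  structure(list(descriptor_names = as.character(descriptor_names),
                 coefficients = stats::setNames(as.numeric(coefficients), descriptor_names),
                 intercept = as.numeric(intercept),
                 n_components = as.integer(n_components),
                 training_mean_activity = as.numeric(training_mean_activity)),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  terms <- paste(sprintf("%+.6g %s", x$coefficients, x$descriptor_names), collapse = " ")
  cat(sprintf("<qsar_model (%d components): pIC50 = %s %+.6g>\n",
              x$n_components, terms, x$intercept))
  invisible(x)
}

# NIPALS PLS1 core on raw matrices; returns coefficients on original scale.
pls_nipals <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, ncomp >= 1, ncomp <= p)
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2, xbar); yc <- y - ybar
  W <- P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }  # nothing left to model
    w <- w / nw
    t <- Xc %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) { ncomp <- a - 1L; break }
    p_a <- crossprod(Xc, t) / tt
    q_a <- sum(yc * t) / tt
    Xc <- Xc - t %*% t(p_a)
    yc <- yc - q_a * t
    W[, a] <- w; P[, a] <- p_a; q[a] <- q_a
  }
  if (ncomp == 0) return(list(coef = numeric(p), intercept = ybar, ncomp = 0L))
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  PW <- crossprod(P, W)
  B <- tryCatch(W %*% solve(PW, q),
                error = function(e) stop("NIPALS failed (rank-deficient P'W): ",
                                         conditionMessage(e)))
  list(coef = as.numeric(B), intercept = ybar - sum(xbar * B), ncomp = as.integer(ncomp))
}

training_matrix <- function(m, train, selected = NULL) {
  idx <- match(train$train_ids, m$compound_ids)
  if (anyNA(idx)) stop("train ids not in matrix: ",
                       paste(train$train_ids[is.na(idx)], collapse = ", "))
  X <- m$values[idx, , drop = FALSE]
  if (!is.null(selected)) {
    miss <- setdiff(selected, colnames(X))
    if (length(miss) > 0) stop("descriptor(s) not in matrix: ", paste(miss, collapse = ", "))
    X <- X[, selected, drop = FALSE]
  }
  list(X = X, y = unname(m$activities[idx]))
}

#' Fit a PLS model on selected descriptors
#'
#' NIPALS PLS1 on centered (not autoscaled) training data. The number of
#' latent components is chosen to maximize leave-one-out q2 over
#' `1..max_components` (the "optimum component"); the fit is returned as the
#' equivalent linear equation.
#'
#' @param m descriptor_matrix.
#' @param train [split_spec()].
#' @param selected character vector of descriptor names.
#' @param max_components upper bound on latent components (default: number
#'   of selected descriptors).
#' @return [qsar_model()].
#' @export
fit_pls <- function(m, train, selected, max_components = length(selected)) {
  stopifnot(length(selected) >= 1)
  tr <- training_matrix(m, train, selected)
  n <- nrow(tr$X)
  max_components <- min(max_components, length(selected), n - 1L)
  if (stats::var(tr$y) < 1e-24) {
    return(qsar_model(selected, rep(0, length(selected)), mean(tr$y), 1L, mean(tr$y)))
  }
  best <- NULL
  for (a in seq_len(max_components)) {
    press <- 0
    for (i in seq_len(n)) {
      f <- pls_nipals(tr$X[-i, , drop = FALSE], tr$y[-i], a)
      press <- press + (tr$y[i] - (f$intercept + sum(f$coef * tr$X[i, ])))^2
    }
    q2 <- 1 - press / sum((tr$y - mean(tr$y))^2)
    if (is.null(best) || q2 > best$q2 + 1e-12) best <- list(a = a, q2 = q2)
  }
  f <- pls_nipals(tr$X, tr$y, best$a)
  qsar_model(selected, f$coef, f$intercept, max(f$ncomp, 1L), mean(tr$y))
}

#' Predict activity from descriptor values
#'
#' `intercept + sum(coefficient * value)` over the model's descriptors.
#'
#' @param object qsar_model.
#' @param newdata named numeric vector, or a data.frame/matrix with one
#'   column per descriptor (rows are compounds).
#' @param ... unused.
#' @return numeric vector of predicted pIC50.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$descriptor_names, colnames(newdata))
  if (length(miss) > 0)
    stop("missing descriptor value(s): ", paste(miss, collapse = ", "))
  as.numeric(object$intercept +
               newdata[, object$descriptor_names, drop = FALSE] %*% object$coefficients)
}

#' Write a model as JSON
#' @param model qsar_model.
#' @param path output file.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(
    descriptors = data.frame(name = model$descriptor_names,
                             coefficient = unname(model$coefficients)),
    intercept = model$intercept,
    n_components = model$n_components,
    training_mean = model$training_mean_activity),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model from JSON
#' @param path JSON file written by [write_model_json()].
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  qsar_model(j$descriptors$name, j$descriptors$coefficient, j$intercept,
             j$n_components, j$training_mean)
}
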