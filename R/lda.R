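# Linear discriminant classification of lunar birth quarter from the
# 12 growth-history traits, with leave-one-out cross-validation and
# adjacency accounting for misclassifications.

#' Fit a linear discriminant model
#'
#' Traits are standardized per column from the training data (LDA
#' predictions are scale-equivariant, but standardization stabilizes
#' the covariance numerics and gives the missing-trait imputation a
#' natural zero point: `NA` entries become the column mean). Class
#' means and the pooled within-class covariance are computed in
#' standardized space; a ridge `eps * trace(S)/p` is added if the
#' covariance is numerically singular.
#'
#' @param X Numeric matrix or data frame (n x p traits); `NA` entries
#'   are imputed as 0 after standardization, `NaN`/`Inf` are errors.
#' @param y Class labels (factor or character); every class needs at
#'   least 2 members and n must be at least 8.
#' @param levels Class levels in fixed order (defaults to
#'   [lunar_quarters()] when the labels are quarters, else the sorted
#'   unique labels). Order matters only for deterministic
#'   tie-breaking.
#' @param ridge Relative ridge for singular covariances.
#' @return Object of class `lda_model`: `levels`, `means` (k x p),
#'   `cov` (pooled, p x p), `priors` (training proportions),
#'   `center`, `scale`.
#' @export
fit_lda <- function(X, y, levels = NULL, ridge = 1e-8) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(is.nan(X)) || any(is.infinite(X))) {
    stop("non-finite (NaN/Inf) trait values")
  }
  if (is.null(levels)) {
    levels <- if (all(as.character(y) %in% lunar_quarters())) {
      lunar_quarters()
    } else sort(unique(as.character(y)))
  }
  y <- factor(as.character(y), levels = levels)
  if (anyNA(y)) stop("labels outside the declared class levels")
  n <- nrow(X); p <- ncol(X); k <- length(levels)
  if (n < 8) stop("need at least 8 training observations")
  cnt <- table(y)
  if (any(cnt < 2)) {
    stop("every class needs >= 2 members; missing/thin: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  }
  # population (ML) moments throughout, so the model is an exact
  # function of sufficient statistics (duplicating every row leaves
  # it unchanged)
  center <- colMeans(X, na.rm = TRUE)
  scl <- apply(X, 2, function(v) {
    v <- v[!is.na(v)]
    sqrt(mean((v - mean(v))^2))
  })
  scl[!is.finite(scl) | scl == 0] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scl, "/")
  Z[is.na(Z)] <- 0 # mean imputation in standardized space

  means <- matrix(vapply(levels,
                         function(cl) colMeans(Z[y == cl, , drop = FALSE]),
                         numeric(p)),
                  ncol = p, byrow = TRUE,
                  dimnames = list(levels, colnames(Z)))
  R <- Z - means[as.integer(y), , drop = FALSE]
  S <- crossprod(R) / n
  ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
  if (!ok) {
    S <- S + diag(ridge * sum(diag(S)) / p, p)
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (!ok) stop("pooled covariance singular even after regularization")
  }
  structure(list(levels = levels, means = means, cov = S,
                 priors = as.numeric(cnt) / n, center = center,
                 scale = scl, p = p),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model>", length(x$levels), "classes x", x$p, "traits;",
      "training priors:",
      paste(sprintf("%s %.2f", x$levels, x$priors), collapse = ", "),
      "\n")
  invisible(x)
}

#' Posterior class probabilities and assignments
#'
#' Gaussian equal-covariance posteriors under the chosen prior. The
#' `"equal"` (uninformative) prior weights all classes alike and is
#' the default for assigning fish whose stage composition differs
#' from the training pool (adults); `"training"` reuses the class
#' proportions of the training data. Ties break deterministically in
#' favour of the earlier class in the model's level order.
#'
#' @param model A [fit_lda()] model.
#' @param X New trait rows (matrix/data frame, or a single named
#'   vector); `NA` entries are imputed as the training column mean.
#' @param prior `"equal"` or `"training"`, or a numeric vector of
#'   class prior probabilities.
#' @return List: `class` (factor), `posterior` (n x k matrix, rows
#'   sum to 1).
#' @export
predict_lda <- function(model, X, prior = c("equal", "training")) {
  stopifnot(inherits(model, "lda_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1,
                                   dimnames = list(NULL, names(X)))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(is.nan(X)) || any(is.infinite(X))) {
    stop("non-finite (NaN/Inf) trait values")
  }
  if (is.character(prior)) {
    prior <- match.arg(prior)
    pri <- if (prior == "equal") {
      rep(1 / length(model$levels), length(model$levels))
    } else model$priors
  } else {
    stopifnot(is.numeric(prior), length(prior) == length(model$levels),
              all(prior >= 0), sum(prior) > 0)
    pri <- prior / sum(prior)
  }
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  Z[is.na(Z)] <- 0
  U <- chol(model$cov)
  # log density up to a shared constant: -1/2 * ||U^-T (z - mu)||^2
  ll <- vapply(seq_along(model$levels), function(j) {
    D <- sweep(Z, 2, model$means[j, ])
    W <- backsolve(U, t(D), transpose = TRUE)
    -0.5 * colSums(W^2) + log(pri[j])
  }, numeric(nrow(Z)))
  ll <- matrix(ll, nrow = nrow(Z),
               dimnames = list(NULL, model$levels))
  m <- apply(ll, 1, max)
  post <- exp(ll - m)
  post <- post / rowSums(post)
  cls <- factor(model$levels[apply(ll, 1, which.max)],
                levels = model$levels)
  list(class = cls, posterior = post)
}

#' Leave-one-out cross-validated classification
#'
#' Refits the model excluding each observation in turn (per-trait
#' standardization recomputed inside every fold, so no information
#' leaks from the held-out fish) and predicts it. A fold whose
#' training set loses a class, or any other fold failure, marks that
#' observation unclassifiable and counts it as an error.
#'
#' @inheritParams fit_lda
#' @param prior Prior used for the held-out prediction (`"training"`
#'   by default: validation folds share the training pool's stage
#'   composition).
#' @return List of class `loocv_result`: `accuracy`, `confusion`
#'   (k x k matrix, true class in rows), `predicted` (factor, `NA`
#'   when unclassifiable), `n_unclassifiable`.
#' @export
loocv_lda <- function(X, y, levels = NULL, prior = "training",
                      ridge = 1e-8) {
  X <- as.matrix(X)
  if (is.null(levels)) {
    levels <- if (all(as.character(y) %in% lunar_quarters())) {
      lunar_quarters()
    } else sort(unique(as.character(y)))
  }
  y <- factor(as.character(y), levels = levels)
  if (any(table(y) < 3)) stop("every class needs >= 3 members for LOOCV")
  n <- nrow(X)
  pred <- factor(rep(NA_character_, n), levels = levels)
  for (i in seq_len(n)) {
    res <- tryCatch({
      m <- fit_lda(X[-i, , drop = FALSE], y[-i], levels = levels,
                   ridge = ridge)
      predict_lda(m, X[i, , drop = FALSE], prior = prior)$class
    }, error = function(e) NA)
    pred[i] <- res
  }
  cm <- table(true = y, predicted = pred, useNA = "no")
  cm <- unclass(cm)[levels, levels, drop = FALSE]
  acc <- mean(!is.na(pred) & pred == y)
  structure(list(accuracy = acc, confusion = cm, predicted = pred,
                 n_unclassifiable = sum(is.na(pred))),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> accuracy %.3f (%d unclassifiable)\n",
              x$accuracy, x$n_unclassifiable))
  print(x$confusion)
  invisible(x)
}

#' Fraction of misclassifications landing in an adjacent quarter
#'
#' Among the off-diagonal counts of a confusion matrix over the four
#' lunar quarters, the fraction whose predicted quarter is cyclically
#' adjacent to the true quarter. With zero misclassifications the
#' quantity is undefined: the function warns and returns `NA`.
#'
#' @param cm 4 x 4 confusion matrix with quarter-labelled dimnames
#'   (true class in rows).
#' @return Proportion in `[0, 1]`, or `NA` if there are no errors.
#' @export
adjacency_fraction <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == 4, ncol(cm) == 4)
  tr <- rownames(cm); pr <- colnames(cm)
  if (is.null(tr) || is.null(pr)) {
    tr <- pr <- lunar_quarters()
  }
  off <- 0; adj <- 0
  for (i in seq_len(4)) for (j in seq_len(4)) {
    if (tr[i] == pr[j]) next
    off <- off + cm[i, j]
    if (quarter_is_adjacent(tr[i], pr[j])) adj <- adj + cm[i, j]
  }
  if (off == 0) {
    warning("no misclassifications: adjacency fraction undefined")
    return(NA_real_)
  }
  adj / off
}

#' Assign a set of fish to birth quarters and summarize
#'
#' Predicts each fish's quarter under the given prior and returns the
#' resulting birth-quarter distribution as a [stage_cohort()].
#'
#' @param model A [fit_lda()] model over quarter classes.
#' @param X Trait rows of the fish to assign.
#' @param prior Prediction prior (default `"equal"`, the
#'   uninformative choice for stages absent from the training pool).
#' @param stage Stage label to attach to the resulting cohort.
#' @return A `stage_cohort` (counts and proportions per quarter).
#' @export
assign_cohort <- function(model, X, prior = "equal", stage = "adult") {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("no fish to assign")
  pr <- predict_lda(model, X, prior = prior)
  stage_distribution(pr$class, stage = stage)
}

#' Total variation distance between two quarter distributions
#'
#' `0.5 * sum(|p_i - q_i|)`; 0 for identical distributions, 1 for
#' disjoint support.
#'
#' @param p,q Numeric probability vectors of equal length, each
#'   summing to 1 (tolerance 1e-9; non-normalized input is an error,
#'   not silently rescaled).
#' @return Distance in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  stopifnot(is.numeric(p), is.numeric(q), length(p) == length(q))
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9 ||
      any(p < 0) || any(q < 0)) {
    stop("inputs must be probability vectors summing to 1")
  }
  0.5 * sum(abs(p - q))
}
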