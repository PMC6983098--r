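# Least-squares diagonal quadratic classifier (LSDQC).
#
# Each pattern x (length L) is expanded to the augmented column
# (1, x1..xL, x1^2..xL^2); a weight matrix V (M x (1+2L)) maps augmented
# patterns to class scores and is fitted by minimizing the mean squared
# error of V.Q against one-hot targets, giving the closed-form Wiener--Hopf
# solution V = T Q' (Q Q')^-1. "Diagonal" refers to the quadratic terms
# being per-feature squares only (axis-aligned quadric boundaries, no cross
# products), which keeps training a small linear solve -- cheap enough to
# sit inside a wrapper feature-selection loop.

#' Construct a labeled dataset
#'
#' @param X Numeric matrix, N patterns x L features (no missing values).
#' @param y Integer class labels in `1..M`.
#' @param subjects Per-pattern subject identifiers; the unit of the
#'   leave-one-subject-out folds.
#' @param classes Optional class names (length M).
#' @return Object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(X, y, subjects, classes = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(y) == length(subjects),
            !anyNA(X), all(is.finite(X)))
  y <- as.integer(y)
  M <- max(y)
  stopifnot(M >= 2, all(y >= 1))
  if (is.null(classes)) classes <- paste0("C", seq_len(M))
  structure(list(X = X, y = y, subjects = as.character(subjects),
                 classes = classes, M = M),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d patterns, %d features, %d classes, %d subjects\n",
              nrow(x$X), ncol(x$X), x$M, length(unique(x$subjects))))
  invisible(x)
}

# Restrict a dataset to the features of a selection mask.
mask_dataset <- function(d, mask) {
  if (is.null(mask)) return(d)
  mask <- as.logical(mask)
  stopifnot(length(mask) == ncol(d$X), any(mask))
  d$X <- d$X[, mask, drop = FALSE]
  d
}

#' Build the augmented pattern matrix
#'
#' @param X Numeric matrix of N patterns x L features.
#' @return The `(1+2L) x N` matrix whose columns are `(1, x, x^2)`: a row
#'   of ones, the L feature rows, then the L elementwise-squared rows.
#' @examples
#' build_pattern_matrix(matrix(c(2, 3), ncol = 1))
#' @export
build_pattern_matrix <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty input", call. = FALSE)
  rbind(1, t(X), t(X)^2)
}

#' Build the one-hot target matrix
#'
#' @param y Integer labels in `1..M`.
#' @param M Number of classes (default `max(y)`).
#' @return `M x N` matrix with `T[m, n] = 1` iff pattern n is in class m.
#' @export
build_target_matrix <- function(y, M = max(y)) {
  Tm <- matrix(0, nrow = M, ncol = length(y))
  Tm[cbind(y, seq_along(y))] <- 1
  Tm
}

# Solve G W = B for W with a ridge fallback when G is numerically
# singular; eps scales with the mean diagonal so it is unit-free.
solve_normal <- function(G, B) {
  tryCatch(solve(G, B),
           error = function(e) {
             eps <- 1e-8 * sum(diag(G)) / nrow(G)
             solve(G + diag(eps, nrow(G)), B)
           })
}

#' Train the classifier (Wiener--Hopf solution)
#'
#' Computes the weight matrix `V = T Q' (Q Q')^-1` minimizing the mean
#' squared error of `V Q` against the one-hot targets. When the normal
#' matrix `Q Q'` is numerically singular a small ridge (1e-8 times its mean
#' diagonal) is added before inversion.
#'
#' @param Q Augmented pattern matrix from [build_pattern_matrix()].
#' @param T_mat Target matrix from [build_target_matrix()].
#' @return `M x (1+2L)` weight matrix.
#' @export
train_lsdqc <- function(Q, T_mat) {
  stopifnot(ncol(Q) == ncol(T_mat))
  if (all(Q == 0)) stop("degenerate all-zero pattern matrix", call. = FALSE)
  G <- Q %*% t(Q)
  t(solve_normal(G, Q %*% t(T_mat)))
}

#' Classify augmented patterns
#'
#' Scores are `Y = V Q`; each pattern is assigned the class of its maximum
#' score, ties broken deterministically toward the lowest class index.
#'
#' @param V Weight matrix.
#' @param Q Augmented pattern matrix.
#' @return Integer label vector (length `ncol(Q)`).
#' @export
classify <- function(V, Q) {
  if (ncol(V) != nrow(Q)) stop("shape mismatch between V and Q", call. = FALSE)
  Y <- V %*% Q
  max.col(t(Y), ties.method = "first")
}

#' Mean squared error of the classifier outputs
#'
#' @param V Weight matrix.
#' @param Q Augmented pattern matrix.
#' @param T_mat Target matrix.
#' @return `(1/N) ||V Q - T||^2` (squared Frobenius norm per pattern).
#' @export
mse <- function(V, Q, T_mat) {
  sum((V %*% Q - T_mat)^2) / ncol(Q)
}

#' Leave-one-subject-out outputs for one subject
#'
#' Trains on all subjects except `s` and evaluates the resulting classifier
#' on subject `s`'s patterns.
#'
#' @param d A [labeled_dataset()] with at least two subjects.
#' @param mask Optional selection mask over the dataset's features (logical
#'   or 0/1; `NULL` selects all).
#' @param s Held-out subject identifier.
#' @return List with `Y` (M x Ns score matrix), `labels` (predicted),
#'   `truth`, and the trained `V`.
#' @export
loso_outputs <- function(d, mask = NULL, s) {
  stopifnot(inherits(d, "labeled_dataset"))
  if (!s %in% d$subjects) stop("unknown subject: ", s, call. = FALSE)
  if (length(unique(d$subjects)) < 2) {
    stop("leave-one-subject-out needs at least two subjects", call. = FALSE)
  }
  d <- mask_dataset(d, mask)
  test <- d$subjects == s
  Q_tr <- build_pattern_matrix(d$X[!test, , drop = FALSE])
  T_tr <- build_target_matrix(d$y[!test], d$M)
  V <- train_lsdqc(Q_tr, T_tr)
  Q_te <- build_pattern_matrix(d$X[test, , drop = FALSE])
  list(Y = V %*% Q_te, labels = classify(V, Q_te), truth = d$y[test], V = V)
}

#' Leave-one-subject-out error of a feature subset
#'
#' Runs k-fold validation with one fold per subject (k = S): for each
#' subject, a classifier is trained on the remaining subjects and its
#' decisions on the held-out subject are scored. The reported error is the
#' average of the per-fold error rates; the per-fold MSE is the test-fold
#' output error `(1/Ns) ||V Q_s - T_s||^2`.
#'
#' @inheritParams loso_outputs
#' @return List with `error` (mean of per-fold errors), `per_fold_error`,
#'   `per_fold_mse` (both named by subject).
#' @export
kfold_error <- function(d, mask = NULL) {
  stopifnot(inherits(d, "labeled_dataset"))
  subs <- unique(d$subjects)
  pe <- pm <- stats::setNames(numeric(length(subs)), subs)
  for (s in subs) {
    o <- loso_outputs(d, mask, s)
    pe[s] <- mean(o$labels != o$truth)
    T_te <- build_target_matrix(o$truth, d$M)
    pm[s] <- sum((o$Y - T_te)^2) / length(o$truth)
  }
  list(error = mean(pe), per_fold_error = pe, per_fold_mse = pm)
}

#' Outer LOSO test error with per-fold selection masks
#'
#' Scores the leave-one-subject-out test error when each fold uses its own
#' selected mask (as returned by [ga_select()]): fold s's classifier is
#' trained on the other subjects with fold s's mask and scored on subject
#' s. Because each mask was selected without its own held-out subject, this
#' is an unbiased outer test of the whole select-then-classify procedure.
#'
#' @param d A [labeled_dataset()].
#' @param masks List of selection masks, one per subject in
#'   `unique(d$subjects)` order.
#' @return List with `error` (mean of per-fold error rates) and
#'   `per_fold_error`.
#' @export
loso_error_with_masks <- function(d, masks) {
  subs <- unique(d$subjects)
  stopifnot(length(masks) == length(subs))
  pe <- stats::setNames(numeric(length(subs)), subs)
  for (i in seq_along(subs)) {
    o <- loso_outputs(d, masks[[i]], subs[i])
    pe[subs[i]] <- mean(o$labels != o$truth)
  }
  list(error = mean(pe), per_fold_error = pe)
}

#' Export a trained model as JSON
#'
#' @param V Weight matrix.
#' @param mask Selection mask the model was trained under.
#' @param classes Class names.
#' @param path Output path.
#' @export
export_model <- function(V, mask, classes, path) {
  jsonlite::write_json(
    list(classes = classes, mask = as.integer(mask), V = V),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Import a model written by [export_model()]
#' @param path JSON path.
#' @return List with `classes`, `mask`, `V`.
#' @export
import_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$V <- as.matrix(m$V)
  m
}
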