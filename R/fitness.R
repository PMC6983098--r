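# Wrapper fitness functions for the GA feature search.
#
# SDEO (standard design-error optimization): the classifier's MSE over the
# design subjects of the current outer fold -- the conventional wrapper
# criterion, which rewards any feature that helps fit the design set.
#
# KFBEO (k-fold-based error optimization): an inner leave-one-subject-out
# loop over the S-1 design subjects -- each inner model is trained with one
# more subject held out and scored on that subject -- averaged over the
# inner folds. Features whose apparent usefulness comes from
# subject-specific idiosyncrasies do not transfer to the inner held-out
# subject, so KFBEO penalizes them where SDEO cannot.
#
# Both are evaluated through per-subject sufficient statistics of the full
# augmented pattern matrix (G_k = Q_k Q_k', H_k = T_k Q_k'), from which any
# fold x mask training reduces to subsetting rows/columns and one small
# solve: ||V Q - T||^2 = tr(V G V') - 2 tr(V H') + N for one-hot targets.

#' Precompute per-subject sufficient statistics for fitness evaluation
#'
#' @param d A [labeled_dataset()].
#' @return Object of class `fold_context` holding, for every subject, the
#'   cross-products of its full augmented pattern matrix with itself and
#'   with its targets. Any (fold, mask) fitness evaluates from these alone.
#' @export
fold_context <- function(d) {
  stopifnot(inherits(d, "labeled_dataset"))
  Qf <- build_pattern_matrix(d$X)
  Tf <- build_target_matrix(d$y, d$M)
  subs <- unique(d$subjects)
  G <- H <- vector("list", length(subs))
  Ns <- integer(length(subs))
  for (i in seq_along(subs)) {
    k <- d$subjects == subs[i]
    Qk <- Qf[, k, drop = FALSE]
    G[[i]] <- Qk %*% t(Qk)
    H[[i]] <- Tf[, k, drop = FALSE] %*% t(Qk)
    Ns[i] <- sum(k)
  }
  structure(list(subjects = subs, G = G, H = H, N = Ns, L = ncol(d$X)),
            class = "fold_context")
}

# augmented-row indices (1, x_sel, x_sel^2) for a selection mask
aug_index <- function(mask, L) {
  sel <- which(as.logical(mask))
  c(1L, 1L + sel, 1L + L + sel)
}

check_fitness_args <- function(ctx, mask, s) {
  if (!s %in% ctx$subjects) stop("unknown subject: ", s, call. = FALSE)
  if (length(mask) != ctx$L) {
    stop("mask length ", length(mask), " != feature count ", ctx$L,
         call. = FALSE)
  }
  if (!any(as.logical(mask))) {
    stop("mask selects no features", call. = FALSE)
  }
}

sse_from_stats <- function(V, G, H, n) {
  max(0, sum(V * (V %*% G)) - 2 * sum(V * H) + n)
}

#' SDEO wrapper fitness for one outer fold
#'
#' Mean squared error of the classifier trained and evaluated entirely on
#' the design subjects (everyone except `s`). The held-out subject `s`
#' contributes nothing to the value.
#'
#' @param d A [labeled_dataset()] (ignored when `ctx` is supplied).
#' @param mask Selection mask over the dataset's features (>= 1 selected).
#' @param s Outer held-out subject.
#' @param ctx Optional precomputed [fold_context()].
#' @return Nonnegative scalar fitness (lower is better).
#' @export
sdeo_fitness <- function(d, mask, s, ctx = NULL) {
  if (is.null(ctx)) ctx <- fold_context(d)
  check_fitness_args(ctx, mask, s)
  idx <- aug_index(mask, ctx$L)
  des <- which(ctx$subjects != s)
  G <- Reduce(`+`, ctx$G[des])[idx, idx, drop = FALSE]
  H <- Reduce(`+`, ctx$H[des])[, idx, drop = FALSE]
  n <- sum(ctx$N[des])
  V <- t(solve_normal(G, t(H)))
  sse_from_stats(V, G, H, n) / n
}

#' KFBEO wrapper fitness for one outer fold
#'
#' Inner leave-one-subject-out estimate over the design subjects: for each
#' design subject n, a model is trained excluding both `s` and n and scored
#' on n's patterns; the squared errors are pooled over the S-1 inner folds
#' and normalized by the total design pattern count.
#'
#' @inheritParams sdeo_fitness
#' @return Nonnegative scalar fitness (lower is better).
#' @export
kfbeo_fitness <- function(d, mask, s, ctx = NULL) {
  if (is.null(ctx)) ctx <- fold_context(d)
  check_fitness_args(ctx, mask, s)
  if (length(ctx$subjects) < 3) {
    stop("KFBEO needs at least 3 subjects (a nonempty design set must ",
         "remain after holding out the inner fold)", call. = FALSE)
  }
  idx <- aug_index(mask, ctx$L)
  des <- which(ctx$subjects != s)
  Gsub <- lapply(ctx$G[des], function(g) g[idx, idx, drop = FALSE])
  Hsub <- lapply(ctx$H[des], function(h) h[, idx, drop = FALSE])
  Nsub <- ctx$N[des]
  G_all <- Reduce(`+`, Gsub)
  H_all <- Reduce(`+`, Hsub)
  sse <- 0
  for (j in seq_along(des)) {
    V <- t(solve_normal(G_all - Gsub[[j]], t(H_all - Hsub[[j]])))
    sse <- sse + sse_from_stats(V, Gsub[[j]], Hsub[[j]], Nsub[j])
  }
  sse / sum(Nsub)
}
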