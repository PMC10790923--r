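# ReliefF feature weighting (deterministic full pass), the square-root k
# rule, and the elbow cut-off on the sorted weight curve.

#' Neighbourhood size for ReliefF by the square-root rule
#'
#' k is the square root of the number of features, rounded (half-even), then
#' incremented when even so that k is odd.
#'
#' @param n_features Number of features (>= 1).
#' @return Odd integer k >= 1.
#' @examples
#' choose_k(6)   # 3
#' choose_k(16)  # 5
#' @export
choose_k <- function(n_features) {
  if (n_features < 1) stop("n_features must be at least 1")
  k <- round(sqrt(n_features))
  if (k %% 2 == 0) k <- k + 1
  max(as.integer(k), 1L)
}

#' ReliefF feature weights
#'
#' Deterministic full-pass ReliefF for binary labels: every sample serves as
#' a reference; its k nearest same-class neighbours (hits) decrease and its k
#' nearest other-class neighbours (misses, weighted by the miss-class prior
#' over one minus the reference-class prior) increase each feature's weight
#' by the range-normalised absolute difference, averaged over references and
#' neighbours. Features are min-max normalised internally and distances are
#' Manhattan in that normalised space, so a constant feature receives weight
#' exactly 0. Ties in neighbour distance are broken by sample order, which
#' keeps the pass deterministic.
#'
#' @param x Numeric matrix (samples x features).
#' @param y Binary labels (factor or vector with exactly 2 levels).
#' @param k Neighbourhood size; must be smaller than the smaller class.
#' @return Named numeric vector of feature weights in \code{[-1, 1]}.
#' @export
relieff_weights <- function(x, y, k = choose_k(ncol(x))) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("relieff_weights requires complete features")
  y <- factor(y)
  if (nlevels(y) != 2) stop("relieff_weights expects binary labels")
  counts <- table(y)
  if (any(counts <= k))
    stop("each class must have more than k = ", k, " members")
  n <- nrow(x); p <- ncol(x)
  rng <- apply(x, 2, function(col) diff(range(col)))
  scale <- ifelse(rng > 0, rng, 1)
  xn <- sweep(sweep(x, 2, apply(x, 2, min)), 2, scale, "/")
  xn[, rng == 0] <- 0
  priors <- counts / n
  w <- numeric(p)
  d <- as.matrix(stats::dist(xn, method = "manhattan"))
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    other <- which(y != y[i])
    hits <- same[order(d[i, same])][seq_len(k)]
    misses <- other[order(d[i, other])][seq_len(k)]
    miss_coef <- priors[levels(y) != y[i]] / (1 - priors[y[i]])
    hit_diff <- colSums(abs(xn[hits, , drop = FALSE] -
                              matrix(xn[i, ], k, p, byrow = TRUE)))
    miss_diff <- colSums(abs(xn[misses, , drop = FALSE] -
                               matrix(xn[i, ], k, p, byrow = TRUE)))
    w <- w + (as.numeric(miss_coef) * miss_diff - hit_diff) / (n * k)
  }
  names(w) <- if (is.null(colnames(x))) sprintf("f%d", seq_len(p))
              else colnames(x)
  w
}

#' Elbow cut-off on a sorted weight curve
#'
#' Finds the elbow of the descending weight curve as the point of maximum
#' perpendicular distance from the chord joining \code{(1, w[1])} to
#' \code{(n, w[n])}; the features strictly above the elbow point are kept
#' (the elbow itself is the first point of the flat tail). With a collinear
#' (linearly decaying) curve there is no elbow and all positive-weight
#' features are kept; fewer than 3 weights also keep everything.
#'
#' @param sorted_weights Numeric vector, non-increasing.
#' @return Number of features to keep (in \code{1..n}).
#' @export
elbow_cutoff <- function(sorted_weights) {
  n <- length(sorted_weights)
  if (n < 3) return(n)
  if (any(diff(sorted_weights) > 1e-12))
    stop("weights must be sorted in descending order")
  x <- seq_len(n)
  chord <- c(n - 1, sorted_weights[n] - sorted_weights[1])
  # perpendicular distance of (x, w) from the chord through the end points
  dist <- abs(chord[1] * (sorted_weights - sorted_weights[1]) -
                chord[2] * (x - 1)) / sqrt(sum(chord^2))
  if (max(dist) < 1e-9) {
    kept <- sum(sorted_weights > 0)
    return(if (kept >= 1) kept else n)
  }
  max(which.max(dist) - 1L, 1L)
}

#' Rank and select features with ReliefF
#'
#' Runs [choose_k()] (unless overridden), [relieff_weights()] on the training
#' partition, sorts the weights in descending order, and fixes the selection
#' by [elbow_cutoff()] or an explicit manual cut-off.
#'
#' @param train_x Training feature matrix.
#' @param train_y Training labels (binary).
#' @param k_override Optional explicit ReliefF k (e.g. 15 for the 96-column
#'   fNIRS stream, where the square-root rule is not what was used in
#'   practice).
#' @param manual_cutoff Optional explicit number of features to keep.
#' @return Object of class \code{"ranked_feature_set"}: \code{features}
#'   (names in rank order), \code{weights} (sorted), \code{k},
#'   \code{cutoff}, \code{method} (\code{"elbow_auto"} or \code{"manual"})
#'   and \code{selected} (the kept names).
#' @export
select_features <- function(train_x, train_y, k_override = NULL,
                            manual_cutoff = NULL) {
  k <- if (is.null(k_override)) choose_k(ncol(train_x)) else
    as.integer(k_override)
  w <- relieff_weights(train_x, train_y, k)
  ord <- order(w, decreasing = TRUE)
  sorted <- w[ord]
  if (is.null(manual_cutoff)) {
    cutoff <- elbow_cutoff(as.numeric(sorted))
    method <- "elbow_auto"
  } else {
    cutoff <- min(as.integer(manual_cutoff), length(w))
    method <- "manual"
  }
  structure(list(features = names(sorted), weights = as.numeric(sorted),
                 k = k, cutoff = cutoff, method = method,
                 selected = names(sorted)[seq_len(cutoff)]),
            class = "ranked_feature_set")
}

#' @export
print.ranked_feature_set <- function(x, ...) {
  cat("ReliefF ranking: k =", x$k, ", cutoff =", x$cutoff, "of",
      length(x$features), "features (", x$method, ")\n")
  top <- utils::head(data.frame(feature = x$features,
                                weight = signif(x$weights, 4)), x$cutoff)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Plot a ranked weight curve with its cut-off
#'
#' @param x A \code{ranked_feature_set}.
#' @param ... Passed to [plot()].
#' @export
plot.ranked_feature_set <- function(x, ...) {
  graphics::plot(seq_along(x$weights), x$weights, type = "b", pch = 16,
                 xlab = "rank", ylab = "ReliefF weight", ...)
  graphics::abline(v = x$cutoff + 0.5, lty = 2, col = "red")
  invisible(x)
}
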