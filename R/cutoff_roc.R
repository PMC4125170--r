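# ROC cutoff selection ---------------------------------------------------

#' ROC curve of a score against a binary label
#'
#' Operating points are swept over the distinct score values (tied scores
#' form a single threshold step; a subject is called positive when score >=
#' threshold). The area under the curve is computed by the trapezoidal rule
#' and equals the concordance probability with half credit for ties.
#'
#' @param scores Numeric scores (finite).
#' @param labels Binary labels (0/1 or logical); both classes must occur.
#' @return Object of class \code{roc_result}: list with \code{points} (data
#'   frame: threshold, fpr, tpr) and \code{auc}. The first point is the
#'   all-negative operating point (threshold Inf).
#' @export
roc_curve <- function(scores, labels) {
  y <- as.integer(labels)
  if (any(!is.finite(scores))) stop_domain("scores must be finite")
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0 || nn == 0) stop_domain("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yo <- y[o]
  last <- cumsum(rle(s)$lengths)         # end index of each tied block
  tp <- cumsum(yo)[last]; fp <- cumsum(1 - yo)[last]
  points <- data.frame(threshold = c(Inf, s[last]),
                       fpr = c(0, fp / nn), tpr = c(0, tp / np))
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  structure(list(points = points, auc = auc), class = "roc_result")
}

#' Cutoff closest to the ideal corner (0, 1)
#'
#' Chooses the operating point minimizing the Euclidean distance
#' \code{sqrt((1 - sens)^2 + (1 - spec)^2)} to the top-left corner of ROC
#' space; ties are broken toward the point with higher specificity.
#'
#' @param roc A \code{roc_result} from [roc_curve()].
#' @return List with \code{cutoff} (score threshold), \code{sensitivity},
#'   \code{specificity}, \code{distance}.
#' @export
closest_to_01_cutoff <- function(roc) {
  pts <- roc$points
  if (nrow(pts) < 2) stop_domain("ROC needs at least 2 operating points")
  d <- sqrt(pts$fpr^2 + (1 - pts$tpr)^2)
  best <- which(d <= min(d) + 1e-12)
  best <- best[order(pts$fpr[best])][1]   # ties: higher specificity
  list(cutoff = pts$threshold[best], sensitivity = pts$tpr[best],
       specificity = 1 - pts$fpr[best], distance = d[best])
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC curve: %d operating points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}
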