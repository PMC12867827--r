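# Segmentation evaluation: confusion-count metrics (Dice, recall, accuracy,
# precision, Jaccard) and contour-distance metrics (Hausdorff distance,
# mean absolute contour distance) with explicit empty-mask conventions.

#' Per-class confusion counts
#'
#' Binarises both masks at \code{classId} and counts true/false
#' positives/negatives per pixel.
#'
#' @param predMask,trueMask integer label matrices of the same shape.
#' @param classId the label to binarise at.
#' @return Named integer vector with elements \code{tp}, \code{tn},
#'   \code{fp}, \code{fn}; the four always sum to the pixel count.
#' @examples
#' p <- matrix(c(1, 1, 1, 0), 2, 2)
#' t <- matrix(c(0, 1, 1, 1), 2, 2)
#' confusionCounts(p, t, 1)
#' @export
confusionCounts <- function(predMask, trueMask, classId) {
  stopifnot2(all(dim(predMask) == dim(trueMask)),
             "predMask and trueMask must have the same shape")
  p <- predMask == classId
  t <- trueMask == classId
  c(tp = sum(p & t), tn = sum(!p & !t), fp = sum(p & !t), fn = sum(!p & t))
}

#' Confusion-count metrics
#'
#' Overlap and pixel-accuracy metrics from confusion counts:
#' \code{dscScore} = 2TP / (2TP + FP + FN) (Dice),
#' \code{recallScore} = TP / (TP + FN),
#' \code{precisionScore} = TP / (TP + FP),
#' \code{accScore} = (TP + TN) / total,
#' \code{jaccardScore} = TP / (TP + FP + FN) (intersection over union).
#' When a denominator is zero (e.g. both masks empty) the metric is defined
#' as 1, so perfect agreement on an absent structure scores perfectly.
#' The identity DSC = 2 JC / (1 + JC) holds whenever defined.
#'
#' @param counts a vector from [confusionCounts()].
#' @return A fraction in [0, 1].
#' @export
dscScore <- function(counts) {
  den <- 2 * counts[["tp"]] + counts[["fp"]] + counts[["fn"]]
  if (den == 0) 1 else 2 * counts[["tp"]] / den
}

#' @rdname dscScore
#' @export
recallScore <- function(counts) {
  den <- counts[["tp"]] + counts[["fn"]]
  if (den == 0) 1 else counts[["tp"]] / den
}

#' @rdname dscScore
#' @export
precisionScore <- function(counts) {
  den <- counts[["tp"]] + counts[["fp"]]
  if (den == 0) 1 else counts[["tp"]] / den
}

#' @rdname dscScore
#' @export
accScore <- function(counts) {
  (counts[["tp"]] + counts[["tn"]]) / sum(counts)
}

#' @rdname dscScore
#' @export
jaccardScore <- function(counts) {
  den <- counts[["tp"]] + counts[["fp"]] + counts[["fn"]]
  if (den == 0) 1 else counts[["tp"]] / den
}

#' Extract the contour of a labelled region
#'
#' A contour pixel is a foreground pixel (\code{mask == classId}) with at
#' least one background pixel among its 4-neighbours, or lying on the image
#' edge. Pixel centers are the point coordinates.
#'
#' @param mask integer label matrix.
#' @param classId the class whose boundary to extract.
#' @param spacing pixel spacing in mm, attached to the result.
#' @return An n x 2 matrix of (row, col) coordinates with attribute
#'   \code{spacing}; zero rows when the class is absent.
#' @examples
#' m <- matrix(0L, 6, 6); m[2:5, 2:5] <- 1L
#' nrow(extractContour(m, 1))  # 12 perimeter pixels
#' @export
extractContour <- function(mask, classId, spacing = 1.0) {
  fg <- mask == classId
  H <- nrow(fg); W <- ncol(fg)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- fg
  nb <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  boundary <- fg & !nb
  idx <- which(boundary, arr.ind = TRUE)
  out <- unname(idx)
  colnames(out) <- c("row", "col")
  attr(out, "spacing") <- spacing
  out
}

# Directed nearest-neighbour distances from each point of a to b (pixels).
directedDistances <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

contourSpacing <- function(a, b, spacing) {
  if (!is.null(spacing)) return(spacing)
  s <- attr(a, "spacing")
  if (is.null(s)) s <- attr(b, "spacing")
  if (is.null(s)) 1.0 else s
}

#' Hausdorff distance between two contours
#'
#' The maximum of the two directed sup-inf Euclidean distances between the
#' point sets, in mm. Conventions: both sets empty gives 0 (perfect
#' agreement on an absent structure); exactly one empty gives NA with a
#' warning, to be excluded from aggregation.
#'
#' @param a,b contour point matrices from [extractContour()].
#' @param spacing mm per pixel; defaults to the contours' own spacing
#'   attribute (or 1).
#' @return Distance in mm, or NA if exactly one contour is empty.
#' @export
hausdorffDistance <- function(a, b, spacing = NULL) {
  sp <- contourSpacing(a, b, spacing)
  na <- NROW(a); nb <- NROW(b)
  if (na == 0 && nb == 0) return(0)
  if (na == 0 || nb == 0) {
    warning("one contour is empty; Hausdorff distance undefined (NA)")
    return(NA_real_)
  }
  max(max(directedDistances(a, b)), max(directedDistances(b, a))) * sp
}

#' Mean absolute contour distance
#'
#' The average over points of \code{a} of the distance to the nearest point
#' of \code{b}, in mm (one-directional). Set \code{symmetric = TRUE} to
#' average the two directed means. Empty-set conventions as in
#' [hausdorffDistance()]. MAD never exceeds the Hausdorff distance.
#'
#' @inheritParams hausdorffDistance
#' @param symmetric average both directions (default FALSE, the
#'   one-directional form).
#' @return Distance in mm, or NA if exactly one contour is empty.
#' @export
meanAbsDistance <- function(a, b, spacing = NULL, symmetric = FALSE) {
  sp <- contourSpacing(a, b, spacing)
  na <- NROW(a); nb <- NROW(b)
  if (na == 0 && nb == 0) return(0)
  if (na == 0 || nb == 0) {
    warning("one contour is empty; mean absolute distance undefined (NA)")
    return(NA_real_)
  }
  m <- mean(directedDistances(a, b))
  if (symmetric) m <- (m + mean(directedDistances(b, a))) / 2
  m * sp
}

#' Evaluate a predicted mask against ground truth
#'
#' Computes all seven metrics (DSC, recall, accuracy, precision, Jaccard,
#' Hausdorff distance, mean absolute contour distance) for every foreground
#' class plus their unweighted macro average. Distance metrics that are
#' undefined because exactly one of the masks lacks the class are NA and are
#' excluded from the macro average (with the warning from the distance
#' functions).
#'
#' @param predMask,trueMask integer label matrices of the same shape.
#' @param spacing mm per pixel.
#' @param numClasses total number of classes including background.
#' @return A data.frame with one row per foreground class and a final
#'   \code{macro} row; columns \code{class, dsc, recall, acc, precision,
#'   jc, hd, mad}.
#' @export
evaluateSegmentation <- function(predMask, trueMask, spacing = 1.0,
                                 numClasses = 4L) {
  stopifnot2(all(dim(predMask) == dim(trueMask)),
             "predMask and trueMask must have the same shape")
  rows <- lapply(seq_len(numClasses - 1L), function(k) {
    cc <- confusionCounts(predMask, trueMask, k)
    ca <- extractContour(predMask, k, spacing)
    cb <- extractContour(trueMask, k, spacing)
    data.frame(class = k,
               dsc = dscScore(cc), recall = recallScore(cc),
               acc = accScore(cc), precision = precisionScore(cc),
               jc = jaccardScore(cc),
               hd = hausdorffDistance(ca, cb, spacing),
               mad = meanAbsDistance(ca, cb, spacing))
  })
  per <- do.call(rbind, rows)
  macro <- data.frame(class = "macro",
                      dsc = mean(per$dsc), recall = mean(per$recall),
                      acc = mean(per$acc), precision = mean(per$precision),
                      jc = mean(per$jc),
                      hd = mean(per$hd, na.rm = TRUE),
                      mad = mean(per$mad, na.rm = TRUE))
  per$class <- as.character(per$class)
  out <- rbind(per, macro)
  rownames(out) <- NULL
  out
}
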