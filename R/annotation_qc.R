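#' Intersection-over-union of two interval sets
#'
#' Agreement between two annotators' TiB interval sets: the total time both
#' labelled as in bed (intersection) divided by the total time at least one
#' did (union), computed in continuous time on the intervals themselves.
#' Two empty sets agree vacuously and score 1. A minute-rasterized variant
#' is provided for cross-checking; the two agree exactly on minute-aligned
#' sets and within one boundary minute per interval otherwise.
#'
#' @param a,b [interval_set()] objects.
#' @return A score in `[0, 1]`.
#' @export
interval_iou <- function(a, b) {
  u <- interval_measure(interval_union(a, b))
  if (u == 0) return(1)
  interval_measure(interval_intersection(a, b)) / u
}

#' @rdname interval_iou
#' @param start,n_minutes Raster grid used by the rasterized variant.
#' @export
rasterized_iou <- function(a, b, start, n_minutes) {
  ra <- rasterize(a, start, n_minutes)
  rb <- rasterize(b, start, n_minutes)
  u <- sum(ra | rb)
  if (u == 0) return(1)
  sum(ra & rb) / u
}

#' Dual-annotator quality-control filter
#'
#' Keeps only recordings whose two annotator tracks agree with IoU strictly
#' greater than the threshold, and builds the consensus label track for the
#' kept recordings as the intersection of the two annotations (so the
#' consensus is a subset of either annotator's rating).
#'
#' @param pairs List of annotation pairs, each a list with interval sets `a`
#'   and `b` (and optionally an `id`).
#' @param threshold IoU inclusion threshold (default 0.9; strict `>`).
#' @return List with `report` (data.frame: `id`, `iou`, `kept`) and
#'   `consensus` (named list of consensus [interval_set()]s for kept pairs).
#' @export
qc_filter <- function(pairs, threshold = 0.9) {
  stopifnot_scalar_prob(threshold, "threshold")
  ids <- vapply(seq_along(pairs), function(i)
    as.character(pairs[[i]]$id %||% i), "")
  iou <- vapply(pairs, function(p) interval_iou(p$a, p$b), 0)
  kept <- iou > threshold
  consensus <- lapply(pairs[kept], function(p) interval_intersection(p$a, p$b))
  names(consensus) <- ids[kept]
  list(report = data.frame(id = ids, iou = iou, kept = kept),
       consensus = consensus)
}
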