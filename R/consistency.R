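#' Top-fraction node mask
#'
#' Selects the `ceiling(fraction * N)` nodes with the highest metric
#' values. Ties at the rank cut are resolved deterministically by
#' ordering on (value descending, node index ascending) and cutting at
#' exactly `ceiling(fraction * N)` nodes.
#'
#' @param metric a `metric_volume` (or plain numeric vector of nodal
#'   values).
#' @param fraction fraction of nodes to keep, in `(0, 1]`.
#' @return logical vector over nodes (`TRUE` = selected).
#' @export
top_fraction_mask <- function(metric, fraction) {
  values <- if (inherits(metric, "metric_volume")) metric$values else metric
  if (length(values) == 0L) stop("empty metric")
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
  n_top <- ceiling(fraction * length(values))
  sel <- order(-values, seq_along(values))[seq_len(n_top)]
  out <- logical(length(values))
  out[sel] <- TRUE
  out
}

#' Session consistency of a node set
#'
#' Per node, the fraction of sessions in which it belongs to the mask.
#'
#' @param masks list of logical node vectors (one per session, common
#'   node map).
#' @param source_metric,top_fraction optional provenance recorded in
#'   the result.
#' @param node_map optional node map for volume export.
#' @return an object of class `consistency_volume` with fields
#'   `values` (fractions in `[0, 1]`), `level = "session"`,
#'   `denominator`, `source_metric`, `top_fraction`, `node_map`.
#' @export
session_overlap <- function(masks, source_metric = NA_character_,
                            top_fraction = NA_real_, node_map = NULL) {
  .overlap(masks, "session", source_metric, top_fraction, node_map)
}

#' Cross-subject consistency of per-subject node sets
#'
#' Per node, the fraction of subjects whose (typically
#' session-thresholded) node set contains it.
#'
#' @inheritParams session_overlap
#' @param masks list of logical node vectors, one per subject.
#' @return a `consistency_volume` with `level = "subject"`.
#' @export
subject_meta_map <- function(masks, source_metric = NA_character_,
                             top_fraction = NA_real_, node_map = NULL) {
  .overlap(masks, "subject", source_metric, top_fraction, node_map)
}

.overlap <- function(masks, level, source_metric, top_fraction, node_map) {
  if (length(masks) < 1L) stop("need at least one mask")
  n <- length(masks[[1]])
  if (any(vapply(masks, length, 1L) != n))
    stop("masks disagree on node count; node maps are inconsistent")
  counts <- Reduce(`+`, lapply(masks, as.integer))
  structure(list(values = counts / length(masks), level = level,
                 denominator = length(masks),
                 source_metric = source_metric, top_fraction = top_fraction,
                 node_map = node_map),
            class = "consistency_volume")
}

#' @export
print.consistency_volume <- function(x, ...) {
  cat(sprintf("<consistency_volume> %s-level over %d, %d nodes, %d nonzero\n",
              x$level, x$denominator, length(x$values), sum(x$values > 0)))
  invisible(x)
}

#' Threshold a consistency volume
#'
#' Keeps nodes present in at least `min_fraction` of the sessions or
#' subjects (inclusive comparison, so "at least 3 of 5 sessions"
#' corresponds to `min_fraction = 0.6` and generalises to other
#' denominators).
#'
#' @param cv a `consistency_volume` (or plain numeric fraction vector).
#' @param min_fraction threshold in `(0, 1]`.
#' @return logical node vector.
#' @export
threshold_consistency <- function(cv, min_fraction) {
  if (min_fraction <= 0 || min_fraction > 1)
    stop("'min_fraction' must be in (0, 1]")
  values <- if (inherits(cv, "consistency_volume")) cv$values else cv
  values >= min_fraction
}

#' Nodes connected to a set of top nodes
#'
#' Returns every node adjacent to at least one node of `top_nodes`. A
#' top node itself appears in the result only if it is adjacent to
#' another top node, unless `include_top = TRUE` forces the whole top
#' set in.
#'
#' @param net a `binary_network`.
#' @param top_nodes logical node vector within the network's node set.
#' @param include_top always include the top set itself?
#' @return logical node vector.
#' @export
connected_to_top_nodes <- function(net, top_nodes, include_top = FALSE) {
  stopifnot(inherits(net, "binary_network"))
  if (length(top_nodes) != net$n_nodes)
    stop("'top_nodes' length must equal the network's node count")
  out <- logical(net$n_nodes)
  if (net$n_edges > 0) {
    e <- net$edges
    out[e[top_nodes[e[, 1]], 2]] <- TRUE
    out[e[top_nodes[e[, 2]], 1]] <- TRUE
  }
  if (include_top) out <- out | top_nodes
  out
}

#' Group-level connectivity map
#'
#' Keeps nodes whose connection set is present in at least
#' `subject_threshold` of the subjects (inclusive), i.e. at 0.5 a
#' majority of participants must show the connection.
#'
#' @param subject_sets list of logical node vectors, one per subject
#'   (typically session-overlapped connection sets).
#' @param subject_threshold fraction of subjects required, in `(0, 1]`.
#' @return logical node vector.
#' @export
group_connectivity_map <- function(subject_sets, subject_threshold = 0.5) {
  cv <- subject_meta_map(subject_sets)
  threshold_consistency(cv, subject_threshold)
}

#' Write a consistency volume (or node set) as NIfTI
#'
#' @param cv a `consistency_volume`, or a logical node vector together
#'   with a `node_map`.
#' @param path output path.
#' @param node_map node map (required when `cv` is a plain vector).
#' @return the path, invisibly.
#' @export
write_consistency_volume <- function(cv, path, node_map = NULL) {
  if (inherits(cv, "consistency_volume")) {
    values <- cv$values
    if (is.null(node_map)) node_map <- cv$node_map
  } else values <- as.numeric(cv)
  if (is.null(node_map)) stop("a node map is required to write a volume")
  mv <- .new_metric_volume("consistency", values, node_map)
  write_metric_volume(mv, path, missing = 0)
}
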