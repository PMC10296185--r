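#' @title Per-frame participant distance graphs and their closeness
#' @description At a fixed frame, every participant contributes one C-vector
#'   (their hemodynamic state over the long channels). Pairwise Euclidean
#'   distances between these vectors are the edge lengths of a complete
#'   weighted graph with one node per participant; node closeness summarises
#'   how near each participant sits to the rest of the group, and the mean
#'   over nodes is the frame's intersubject similarity score.
#' @name similarity
NULL

# Resolve a channel id or index to a column index; NULL passes through.
.resolve_channel <- function(group, channel) {
  if (is.null(channel)) return(NULL)
  if (is.character(channel)) {
    idx <- match(channel, group$channel_ids)
    if (is.na(idx)) stop("unknown channel '", channel, "'.", call. = FALSE)
    return(idx)
  }
  idx <- as.integer(channel)
  if (idx < 1L || idx > length(group$channel_ids))
    stop("channel index out of range.", call. = FALSE)
  idx
}

# Core engine: mean closeness at every frame for a list of T x C matrices.
# Works on plain matrices (no group_dataset overhead) so the permutation loop
# can call it directly. `keep` is a column index vector or NULL for all.
# Returns a length-T vector, or stops at the first degenerate frame.
.closeness_engine <- function(mats, keep = NULL) {
  n <- length(mats)
  if (!is.null(keep)) mats <- lapply(mats, function(m) m[, keep, drop = FALSE])
  t_len <- nrow(mats[[1]])
  node_sum <- matrix(0, t_len, n)
  for (i in seq_len(n - 1L)) {
    mi <- mats[[i]]
    for (j in seq.int(i + 1L, n)) {
      d <- sqrt(.rowSums((mi - mats[[j]])^2, t_len, ncol(mi)))
      node_sum[, i] <- node_sum[, i] + d
      node_sum[, j] <- node_sum[, j] + d
    }
  }
  if (any(node_sum == 0)) {
    fr <- which(.rowSums(node_sum == 0, t_len, n) > 0)
    stop("degenerate frame(s) ", paste(utils::head(fr - 1L, 5), collapse = ", "),
         if (length(fr) > 5) ", ..." else "",
         ": some participants have identical states (zero distance to all ",
         "others); closeness is undefined there.", call. = FALSE)
  }
  .rowMeans((n - 1) / node_sum, t_len, n)
}

#' Between-participant distance matrix at one frame
#'
#' Computes the symmetric `N x N` matrix of pairwise Euclidean distances
#' between participants' channel vectors at a single time frame. Used as the
#' (edge-length) adjacency matrix of the complete weighted participant graph.
#'
#' @param group a [group_dataset()].
#' @param frame 0-based frame index.
#' @param exclude_channel optional channel id (or index) dropped from the
#'   state vectors before distances are taken.
#' @return an object of class `frame_distance_matrix`: a list with `values`
#'   (the `N x N` matrix, participant ids as dimnames) and `frame`.
#' @examples
#' g <- group_dataset(list(matrix(0, 2, 2), matrix(1, 2, 2),
#'                         matrix(2, 2, 2)), fs = 1)
#' frame_distance_matrix(g, 0)$values
#' @export
frame_distance_matrix <- function(group, frame, exclude_channel = NULL) {
  stopifnot(inherits(group, "group_dataset"))
  frame <- as.integer(frame)
  if (length(frame) != 1L || is.na(frame) || frame < 0L ||
      frame >= group$n_frames)
    stop("`frame` must be a 0-based index in [0, ", group$n_frames - 1L, "].",
         call. = FALSE)
  keep <- setdiff(seq_along(group$channel_ids),
                  .resolve_channel(group, exclude_channel))
  if (!length(keep)) stop("no channels retained.", call. = FALSE)
  states <- t(vapply(group$data, function(m) m[frame + 1L, keep],
                     numeric(length(keep))))
  d <- as.matrix(stats::dist(states))
  dimnames(d) <- list(group$participants, group$participants)
  structure(list(values = d, frame = frame), class = "frame_distance_matrix")
}

#' Mean node closeness of a distance graph
#'
#' Node closeness in a weighted graph is `(N - 1)` divided by the sum of the
#' node's shortest-path distances to every other node (Freeman-normalised, so
#' values are comparable across group sizes). Because the edge lengths here
#' are Euclidean distances, the metric triangle inequality makes every direct
#' edge the shortest path, so the row-sum of the distance matrix equals the
#' shortest-path distance sum; this identity is exercised against a
#' graph-search oracle in the test suite.
#'
#' @param dist a [frame_distance_matrix()] or a bare symmetric matrix of
#'   pairwise distances with zero diagonal.
#' @return scalar mean of the `N` node closeness values (units: inverse data
#'   units).
#' @examples
#' m <- matrix(2, 3, 3); diag(m) <- 0
#' mean_closeness(m)  # each node: 2/(2+2) = 0.5
#' @export
mean_closeness <- function(dist) {
  d <- if (inherits(dist, "frame_distance_matrix")) dist$values else
    as.matrix(dist)
  n <- nrow(d)
  if (n < 3L) stop("closeness needs >= 3 nodes.", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0) || any(d < 0))
    stop("`dist` must be symmetric and nonnegative with zero diagonal.",
         call. = FALSE)
  row_sum <- rowSums(d)
  if (any(row_sum == 0))
    stop("degenerate frame: a node is at distance zero from every other ",
         "(all participants identical).", call. = FALSE)
  mean((n - 1) / row_sum)
}

#' Per-frame mean closeness over a whole recording
#'
#' Applies [frame_distance_matrix()] + [mean_closeness()] at every frame
#' (computed in vectorised form). With `exclude_channel`, the named channel is
#' dropped from all state vectors -- the primitive behind leave-one-channel-out
#' relevance mapping.
#'
#' @inheritParams frame_distance_matrix
#' @return an object of class `closeness_series`: list with `values`
#'   (length-T numeric), `frame_indices` (0-based), `fs`, `t0`.
#' @seealso [intersubject_similarity_test()], [channel_relevance()]
#' @export
closeness_series <- function(group, exclude_channel = NULL) {
  stopifnot(inherits(group, "group_dataset"))
  excl <- .resolve_channel(group, exclude_channel)
  if (!is.null(excl) && length(group$channel_ids) < 2L)
    stop("cannot exclude the only channel.", call. = FALSE)
  keep <- setdiff(seq_along(group$channel_ids), excl)
  values <- .closeness_engine(group$data, keep)
  structure(list(values = values,
                 frame_indices = seq_len(group$n_frames) - 1L,
                 fs = group$fs, t0 = group$t0),
            class = "closeness_series")
}

#' @export
print.closeness_series <- function(x, ...) {
  cat("<closeness_series> ", length(x$values), " frames @ ", format(x$fs),
      " Hz; mean ", format(mean(x$values), digits = 5), ", range [",
      format(min(x$values), digits = 5), ", ",
      format(max(x$values), digits = 5), "]\n", sep = "")
  invisible(x)
}
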