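#' Average degree of a weighted FC matrix
#'
#' Node degree c_i is the mean Fisher-z connectivity of node i to all other
#' nodes; the average degree C = (1/N) sum_i c_i, which equals the mean of
#' all off-diagonal z entries. A standard network-density measure for
#' weighted connectivity matrices.
#'
#' @param fc an `fc_matrix` with the z slot filled ([fisher_z()]), or a
#'   plain symmetric numeric matrix (used as-is, diagonal excluded).
#' @param on `"z"` (default) or `"r"`: which matrix the degrees are
#'   computed on.
#' @return scalar average degree.
#' @export
average_degree <- function(fc, on = c("z", "r")) {
  on <- match.arg(on)
  m <- fc_values(fc, on)
  mean(m[row(m) != col(m)])
}

# Pull the requested value matrix out of an fc_matrix (or accept a bare
# matrix).
fc_values <- function(fc, on = "r") {
  if (inherits(fc, "fc_matrix")) {
    m <- if (on == "z") fc$z else fc$r
    if (is.null(m)) stop("fc_matrix has no '", on, "' values (run fisher_z?)")
    return(m)
  }
  if (is.matrix(fc)) return(fc)
  stop("expected an fc_matrix or a matrix")
}

#' Binarize an FC matrix at a threshold
#'
#' Edge i-j is present iff the FC value is >= tau; the diagonal is always
#' zero. By default the correlation (r) matrix is thresholded, reading the
#' thresholds 0.1-0.5 as correlation levels; set `on = "z"` to threshold
#' the Fisher-z matrix, or `absolute = TRUE` to threshold |value| for
#' sensitivity analyses.
#'
#' @param fc an `fc_matrix` or plain symmetric matrix.
#' @param tau threshold in (0, 1).
#' @param on `"r"` (default) or `"z"`.
#' @param absolute threshold the absolute value instead.
#' @return list of class `binary_graph` with logical `adjacency` and `tau`.
#' @export
binarize <- function(fc, tau, on = c("r", "z"), absolute = FALSE) {
  on <- match.arg(on)
  stopifnot(tau > 0, tau < 1)
  m <- fc_values(fc, on)
  v <- if (absolute) abs(m) else m
  adj <- !is.na(v) & v >= tau
  diag(adj) <- FALSE
  adj <- adj | t(adj)   # symmetric by construction for symmetric input
  structure(list(adjacency = adj, tau = tau, on = on, absolute = absolute),
            class = "binary_graph")
}

# Unweighted single-source shortest-path lengths by breadth-first search.
# Returns Inf for unreachable nodes.
bfs_distances <- function(adj, from) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  dist[from] <- 0
  frontier <- from
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(adj[v, ] & is.infinite(dist))
      if (length(nb)) {
        dist[nb] <- d
        nxt <- c(nxt, nb)
      }
    }
    frontier <- nxt
  }
  dist
}

#' Global efficiency of a binarized graph
#'
#' E(G) = 1/(N(N-1)) * sum over ordered pairs i != j of 1/d_ij, with d_ij
#' the unweighted shortest-path length (breadth-first search) and
#' 1/d_ij = 0 for unreachable pairs — the binary-efficiency convention of
#' the Brain Connectivity Toolbox. The empty graph has E = 0, the complete
#' graph E = 1.
#'
#' @param g a `binary_graph` from [binarize()], or a logical/0-1 adjacency
#'   matrix.
#' @return scalar in [0, 1].
#' @export
global_efficiency <- function(g) {
  adj <- if (inherits(g, "binary_graph")) g$adjacency else (g != 0)
  diag(adj) <- FALSE
  n <- nrow(adj)
  if (n < 2) return(0)
  total <- 0
  for (i in seq_len(n)) {
    d <- bfs_distances(adj, i)
    inv <- 1 / d[-i]
    inv[!is.finite(inv)] <- 0
    total <- total + sum(inv)
  }
  total / (n * (n - 1))
}

#' Graph metrics for one subject across windows
#'
#' For each available window: the average degree (on Fisher-z values) and
#' the global efficiency of the graph binarized at each threshold (on r
#' values). Missing windows are reported in the `missing_windows`
#' attribute, never silently dropped.
#'
#' @param fc_by_window named list of Fisher-transformed `fc_matrix`
#'   objects, names = window end minutes (see [fc_by_windows()]).
#' @param thresholds binarization thresholds (default 0.1-0.5 step 0.1).
#' @param expected_windows windows the caller intended (default: the names
#'   of `fc_by_window`).
#' @param ad_on,bin_on which matrix AD / binarization use ("z"/"r").
#' @return Long data.frame: `subject_id`, `window_end_min`, `metric`
#'   (`"AD"` or `"Eglob"`), `threshold` (`NA` for AD), `value`.
#' @export
metrics_for_subject <- function(fc_by_window,
                                thresholds = seq(0.1, 0.5, by = 0.1),
                                expected_windows = NULL,
                                ad_on = "z", bin_on = "r") {
  have <- as.numeric(names(fc_by_window))
  if (is.null(expected_windows)) expected_windows <- have
  missing_w <- setdiff(expected_windows, have)
  rows <- lapply(fc_by_window, function(fc) {
    w <- fc$window$end
    sid <- fc$subject_id
    ad_row <- data.frame(subject_id = sid, window_end_min = w,
                         metric = "AD", threshold = NA_real_,
                         value = average_degree(fc, on = ad_on),
                         stringsAsFactors = FALSE)
    eg_rows <- data.frame(subject_id = sid, window_end_min = w,
                          metric = "Eglob", threshold = thresholds,
                          value = vapply(thresholds, function(tau)
                            global_efficiency(binarize(fc, tau, on = bin_on)),
                            0.0),
                          stringsAsFactors = FALSE)
    rbind(ad_row, eg_rows)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "missing_windows") <- missing_w
  out
}
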