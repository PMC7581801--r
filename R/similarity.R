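# Euclidean-distance trajectory similarity -----------------------------------
#
# Conditions are compared through cohort-mean rotation trajectories: each
# animal's DBS-on window is re-zeroed at onset, resampled to a common
# uniform grid, and the pointwise mean across animals is taken before
# distances are computed (published similarity tables print one value per
# condition pair, not per animal).

#' Cohort-mean rotation trace of one condition
#'
#' @param trajs list of [angular_trajectory()] objects, one per animal.
#' @param protocol the `session_protocol` all animals followed.
#' @param label ON-episode label naming the condition.
#' @param grid_n number of uniform grid points spanning the window
#'   (default 30, i.e. 1 Hz over a 30-s episode).
#' @param units `"rotations"` (default) or `"degrees"`.
#' @return An object of class `condition_trace` with fields `label`,
#'   `values` (length `grid_n`), `units` and `n_animals`.
#' @export
condition_trace <- function(trajs, protocol, label, grid_n = 30,
                            units = c("rotations", "degrees")) {
  units <- match.arg(units)
  stopifnot(length(trajs) >= 1, grid_n >= 2)
  wins <- episode_windows(protocol)
  w <- wins[wins$label == label, , drop = FALSE]
  if (nrow(w) != 1) {
    stop("condition '", label, "' not found (or not unique) in protocol",
         call. = FALSE)
  }
  grid <- seq(w$start_s, w$end_s, length.out = grid_n)
  per_animal <- vapply(trajs, function(tr) {
    stopifnot(inherits(tr, "angular_trajectory"))
    v <- stats::approx(tr$time_s, tr$angle_deg, xout = grid, rule = 2)$y
    v <- v - v[1]
    if (units == "rotations") v / 360 else v
  }, numeric(grid_n))
  values <- if (is.matrix(per_animal)) rowMeans(per_animal) else per_animal
  structure(list(label = label, values = values, units = units,
                 n_animals = length(trajs)),
            class = "condition_trace")
}

#' @export
print.condition_trace <- function(x, ...) {
  cat(sprintf("<condition_trace> '%s': %d points (%s), end value %.3f\n",
              x$label, length(x$values), x$units,
              x$values[length(x$values)]))
  invisible(x)
}

#' Euclidean distance between two condition traces
#'
#' @param a,b `condition_trace` objects on the same grid and in the same
#'   units.
#' @return `sqrt(sum((a - b)^2))`.
#' @export
euclidean_distance <- function(a, b) {
  stopifnot(inherits(a, "condition_trace"), inherits(b, "condition_trace"))
  if (length(a$values) != length(b$values)) {
    stop("traces have different grid lengths", call. = FALSE)
  }
  if (!identical(a$units, b$units)) {
    stop("traces have different units", call. = FALSE)
  }
  sqrt(sum((a$values - b$values)^2))
}

#' Pairwise Euclidean-distance matrix of condition traces
#'
#' @param traces list of `condition_trace` objects on a common grid.
#' @return A symmetric `similarity_matrix` (labelled square matrix,
#'   zero diagonal) with a `units` attribute.
#' @export
ed_matrix <- function(traces) {
  stopifnot(length(traces) >= 2)
  labels <- vapply(traces, function(x) x$label, character(1))
  n <- length(traces)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- euclidean_distance(traces[[i]], traces[[j]])
    }
  }
  structure(m, units = traces[[1]]$units, class = c("similarity_matrix",
                                                    "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d conditions (%s)\n", nrow(x),
              attr(x, "units")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Write a similarity matrix as a labelled delimited table
#'
#' @param m a `similarity_matrix`.
#' @param path output path (tab-separated, labels in the first row and
#'   column).
#' @return `path`, invisibly.
#' @export
write_ed_matrix <- function(m, path) {
  d <- data.frame(condition = rownames(m), unclass(m),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
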