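#' DTW configuration
#'
#' @param point_cost Pointwise cost between aligned samples:
#'   `"absolute"` (default; the Euclidean distance between scalar
#'   points) or `"squared"`.
#' @param band_radius Optional Sakoe-Chiba band radius in samples
#'   (`NULL` = unconstrained full dynamic program).  When sequences
#'   differ in length the radius is widened to at least the length
#'   difference.
#' @param downsample_factor Integer decimation factor applied before
#'   alignment (every `f`-th sample; default 1, no decimation).
#' @param normalization Per-sequence normalization: `"none"` (default;
#'   raw amplitudes are compared) or `"zscore"`.
#' @return Object of class `dtw_config`.
#' @export
dtw_config <- function(point_cost = c("absolute", "squared"),
                       band_radius = NULL,
                       downsample_factor = 1L,
                       normalization = c("none", "zscore")) {
  point_cost <- match.arg(point_cost)
  normalization <- match.arg(normalization)
  if (!is.null(band_radius)) {
    band_radius <- as.integer(band_radius)
    if (band_radius < 1L) stop("'band_radius' must be >= 1", call. = FALSE)
  }
  downsample_factor <- as.integer(downsample_factor)
  if (downsample_factor < 1L)
    stop("'downsample_factor' must be >= 1", call. = FALSE)
  structure(list(point_cost = point_cost, band_radius = band_radius,
                 downsample_factor = downsample_factor,
                 normalization = normalization),
            class = "dtw_config")
}

prep_sequence <- function(x, config, what = "sequence") {
  if (inherits(x, "ecg_signal")) x <- x$samples
  x <- as.numeric(x)
  if (length(x) == 0L)
    stop(sprintf("empty %s", what), call. = FALSE)
  bad <- which(!is.finite(x))
  if (length(bad))
    stop(sprintf("non-finite value in %s at index %d", what, bad[1]),
         call. = FALSE)
  if (config$downsample_factor > 1L)
    x <- x[seq(1L, length(x), by = config$downsample_factor)]
  if (config$normalization == "zscore") {
    s <- stats::sd(x)
    x <- if (s > 0) (x - mean(x)) / s else x - mean(x)
  }
  x
}

#' Dynamic time warping distance between two sequences
#'
#' Cumulative alignment cost `D[n, m]` of the standard dynamic program
#' `D[i,j] = cost(x_i, y_j) + min(D[i-1,j], D[i,j-1], D[i-1,j-1])`
#' anchored at `D[1,1] = cost(x_1, y_1)`.  No step weighting and no
#' path-length normalization is applied, so distances grow with
#' sequence length.  Symmetric in its arguments; zero exactly when a
#' zero-cost monotone alignment exists.
#'
#' @param x,y Numeric sequences or [ecg_signal()] objects.
#' @param config A [dtw_config()].
#' @return Non-negative scalar distance.
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 2, 3))        # 0
#' dtw_distance(c(0, 1), c(1, 0))              # 2
#' @export
dtw_distance <- function(x, y, config = dtw_config()) {
  stopifnot(inherits(config, "dtw_config"))
  xv <- prep_sequence(x, config, "'x'")
  yv <- prep_sequence(y, config, "'y'")
  band <- if (is.null(config$band_radius)) -1L else config$band_radius
  dtw_cost_cpp(xv, yv, config$point_cost == "squared", band)
}

#' All-pairs DTW distance matrix
#'
#' Computes the `n(n-1)/2` pairwise distances once each and mirrors
#' them.  Every pair is an independent computation, so the result is
#' bitwise identical for any `workers` count and any evaluation order.
#'
#' @param signals List of [ecg_signal()] objects or numeric vectors
#'   (names become the matrix ids).
#' @param config A [dtw_config()].
#' @param workers Number of worker processes (forked via
#'   `parallel::mclapply`; serial on Windows).
#' @param verbose Log progress messages?
#' @return Symmetric numeric matrix with zero diagonal and the signal
#'   ids as dimnames.
#' @export
pairwise_dtw <- function(signals, config = dtw_config(), workers = 1L,
                         verbose = FALSE) {
  stopifnot(inherits(config, "dtw_config"))
  n <- length(signals)
  if (n < 2L) stop("need at least 2 signals", call. = FALSE)
  ids <- names(signals)
  if (is.null(ids))
    ids <- vapply(seq_along(signals), function(i) {
      s <- signals[[i]]
      if (inherits(s, "ecg_signal") && !is.na(s$record_id)) s$record_id
      else sprintf("S%04d", i)
    }, "")
  prepped <- vector("list", n)
  for (i in seq_len(n)) {
    prepped[[i]] <- tryCatch(prep_sequence(signals[[i]], config),
                             error = function(e)
                               stop(sprintf("signal '%s': %s", ids[i],
                                            conditionMessage(e)),
                                    call. = FALSE))
  }
  band <- if (is.null(config$band_radius)) -1L else config$band_radius
  sq <- config$point_cost == "squared"
  pr <- utils::combn(n, 2L)
  ii <- pr[1, ]; jj <- pr[2, ]
  np <- length(ii)
  workers <- max(1L, as.integer(workers))
  run_chunk <- function(idx) dtw_pairs_cpp(prepped, ii[idx], jj[idx], sq,
                                           band)
  if (workers > 1L && .Platform$OS.type == "unix") {
    chunks <- split(seq_len(np), cut(seq_len(np), workers, labels = FALSE))
    res <- parallel::mclapply(chunks, run_chunk, mc.cores = workers)
    dvals <- unlist(res, use.names = FALSE)
  } else {
    if (verbose) {
      dvals <- numeric(np)
      bs <- max(1L, ceiling(np / 10))
      for (b in seq(1L, np, by = bs)) {
        idx <- b:min(np, b + bs - 1L)
        dvals[idx] <- run_chunk(idx)
        message(sprintf("pairwise_dtw: %d/%d pairs", max(idx), np))
      }
    } else dvals <- run_chunk(seq_len(np))
  }
  bad <- which(!is.finite(dvals))
  if (length(bad))
    stop(sprintf("DTW failed for pair (%s, %s)", ids[ii[bad[1]]],
                 ids[jj[bad[1]]]), call. = FALSE)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  D[cbind(ii, jj)] <- dvals
  D[cbind(jj, ii)] <- dvals
  D
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square", call. = FALSE)
  if (any(!is.finite(d)))
    stop("distance matrix has non-finite entries", call. = FALSE)
  if (any(d < 0))
    stop("distance matrix has negative entries", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop("distance matrix diagonal must be zero", call. = FALSE)
  invisible(d)
}
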