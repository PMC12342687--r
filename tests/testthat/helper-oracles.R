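# Independent oracles used to validate the implementation.

# --- DTW: exhaustive enumeration of monotone alignment paths ----------
# A path starts at (1,1), ends at (n,m), and moves by (1,0), (0,1) or
# (1,1).  The oracle evaluates the total point cost of every path and
# takes the minimum.  Paths are cached per (n, m) shape.
.path_cache <- new.env(parent = emptyenv())

enumerate_paths <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  paths <- list()
  walk <- function(i, j, trail) {
    trail[[length(trail) + 1L]] <- c(i, j)
    if (i == n && j == m) {
      paths[[length(paths) + 1L]] <<- do.call(rbind, trail)
      return(invisible())
    }
    if (i < n) walk(i + 1L, j, trail)
    if (j < m) walk(i, j + 1L, trail)
    if (i < n && j < m) walk(i + 1L, j + 1L, trail)
    invisible()
  }
  walk(1L, 1L, list())
  .path_cache[[key]] <- paths
  paths
}

dtw_bruteforce <- function(x, y, squared = FALSE) {
  cost <- outer(x, y, function(a, b) if (squared) (a - b)^2 else abs(a - b))
  paths <- enumerate_paths(length(x), length(y))
  min(vapply(paths, function(p) sum(cost[p]), 0))
}

# --- Partition metrics: explicit O(n^2) pair enumeration --------------
pairs_oracle <- function(la, lb) {
  n <- length(la)
  both <- 0L; either <- 0L; agree <- 0L; total <- 0L
  a_co <- 0L; b_co <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sa <- la[i] == la[j]; sb <- lb[i] == lb[j]
    total <- total + 1L
    if (sa && sb) both <- both + 1L
    if (sa || sb) either <- either + 1L
    if (sa == sb) agree <- agree + 1L
    if (sa) a_co <- a_co + 1L
    if (sb) b_co <- b_co + 1L
  }
  list(jaccard = if (either == 0) NA_real_ else both / either,
       rand = agree / total, both = both, a = a_co, b = b_co,
       total = total)
}

# All set partitions of n items as label vectors (restricted growth
# strings).
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, mx) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (v in 0:(mx + 1L)) grow(c(labels, v), max(mx, v))
    invisible()
  }
  grow(integer(0), -1L)
  out
}

make_partition <- function(labels, method = "test") {
  partition(sprintf("i%02d", seq_along(labels)),
            as.integer(labels) - min(as.integer(labels)),
            k = max(as.integer(labels) - min(as.integer(labels))) + 1L,
            method = method)
}
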