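#' @useDynLib gaussflex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Mutual Gauss integral of two line segments
#'
#' Closed-form total mutual contribution of two line segments to the writhe
#' of a polygonal curve. The absolute value equals the probability that the
#' two segments cross when projected along a uniformly random direction; the
#' sign encodes the crossing handedness (positive = right-handed).
#'
#' @param a0,a1 numeric length-3 endpoints of the first segment.
#' @param b0,b1 numeric length-3 endpoints of the second segment.
#' @return A single dimensionless number in \[-1, 1\].
#' @examples
#' segment_writhe(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1), c(1, 1, -1))
#' @export
segment_writhe <- function(a0, a1, b0, b1) {
  pts <- list(a0, a1, b0, b1)
  for (p in pts) {
    if (length(p) != 3L || !all(is.finite(p))) {
      stop("segment endpoints must be finite length-3 vectors", call. = FALSE)
    }
  }
  if (sum((a1 - a0)^2) == 0 || sum((b1 - b0)^2) == 0) {
    stop("degenerate input: zero-length segment", call. = FALSE)
  }
  .cpp_segment_writhe(as.numeric(a0), as.numeric(a1),
                      as.numeric(b0), as.numeric(b1))
}

#' Pairwise segment writhe matrix of a C-alpha trace
#'
#' Fills the symmetric matrix W with the mutual Gauss-integral contribution of
#' every pair of nonadjacent backbone segments. Segments sharing an endpoint
#' (and the diagonal) are exactly zero: adjacent segments subtend no solid
#' angle.
#'
#' @param trace a [ca_trace] object, or an n x 3 coordinate matrix with n >= 3.
#' @return An (n-1) x (n-1) symmetric numeric matrix.
#' @export
writhe_matrix <- function(trace) {
  coords <- trace_coords(trace)
  n <- nrow(coords)
  if (n < 3L) stop("degenerate input: trace needs at least 3 points", call. = FALSE)
  steps <- coords[-1L, , drop = FALSE] - coords[-n, , drop = FALSE]
  bad <- which(rowSums(steps^2) == 0)
  if (length(bad)) {
    stop(sprintf("degenerate input: zero-length segment at residue pair %d-%d",
                 bad[1L], bad[1L] + 1L), call. = FALSE)
  }
  .cpp_writhe_matrix(coords)
}

trace_coords <- function(trace) {
  if (inherits(trace, "ca_trace")) return(trace$coords)
  coords <- as.matrix(trace)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coordinates must have 3 columns", call. = FALSE)
  coords
}

# ---------------------------------------------------------------------------
# Chord patterns and the descriptor registry
# ---------------------------------------------------------------------------

#' Chord pattern of a generalized Gauss integral
#'
#' A chord pattern of order k is a perfect matching of the 2k index slots
#' 1..2k; each chord (a, b) contributes the factor `W[i_a, i_b]` (or its
#' absolute value when the chord's abs flag is set) to the invariant sum.
#'
#' @param chords list of integer pairs matching the slots 1..2k exactly once.
#' @param abs_flags logical, one per chord; `TRUE` applies `abs()` to that
#'   chord's factor. Defaults to all `FALSE`.
#' @return A `chord_pattern` object.
#' @examples
#' chord_pattern(list(c(1, 3), c(2, 4)))            # crossing, order 2
#' chord_pattern(list(c(1, 2)), abs_flags = TRUE)   # average crossing number
#' @export
chord_pattern <- function(chords, abs_flags = NULL) {
  chords <- lapply(chords, function(ch) sort(as.integer(ch)))
  k <- length(chords)
  if (!k %in% 1:3) stop("pattern order must be 1, 2 or 3", call. = FALSE)
  slots <- sort(unlist(chords))
  if (!identical(slots, seq_len(2L * k))) {
    stop("chords must form a perfect matching of slots 1..2k", call. = FALSE)
  }
  if (is.null(abs_flags)) abs_flags <- rep(FALSE, k)
  abs_flags <- as.logical(abs_flags)
  if (length(abs_flags) != k) stop("need one abs flag per chord", call. = FALSE)
  ord <- order(vapply(chords, `[`, integer(1), 1L))
  structure(list(order = k, chords = chords[ord], abs_flags = abs_flags[ord]),
            class = "chord_pattern")
}

# All perfect matchings of 1..2k, canonical (within-chord sorted, chords by
# first slot), in lexicographic order. Slot 1 always pairs first.
all_matchings <- function(k) {
  rec <- function(slots) {
    if (!length(slots)) return(list(list()))
    first <- slots[1L]
    rest <- slots[-1L]
    out <- list()
    for (p in rest) {
      sub <- rec(setdiff(rest, p))
      out <- c(out, lapply(sub, function(m) c(list(c(first, p)), m)))
    }
    out
  }
  rec(seq_len(2L * k))
}

matching_key <- function(chords) paste(vapply(chords, paste, "", collapse = ","),
                                       collapse = ";")

pattern_id <- function(pattern) {
  ms <- all_matchings(pattern$order)
  keys <- vapply(ms, matching_key, "")
  id <- match(matching_key(pattern$chords), keys)
  if (is.na(id)) stop("unrecognized chord pattern", call. = FALSE)
  id
}

pattern_name <- function(pattern) {
  paste0("I", paste(mapply(function(ch, ab) {
    if (ab) sprintf("|%d,%d|", ch[1], ch[2]) else sprintf("(%d,%d)", ch[1], ch[2])
  }, pattern$chords, pattern$abs_flags), collapse = ""))
}

#' @export
print.chord_pattern <- function(x, ...) {
  cat("chord pattern", pattern_name(x), "(order", x$order, ")\n")
  invisible(x)
}

#' Evaluate a generalized Gauss integral on a writhe matrix
#'
#' Computes the sum over strictly increasing index tuples of the product of
#' writhe-matrix entries selected by the chord pattern. Order 1 gives the
#' writhe `I(1,2)` and, with the abs flag, the average crossing number
#' `I|1,2|`; orders 2 and 3 give the higher-order correlations. Orders 1-2
#' run in O(n^2), order 3 in O(n^3) via cumulative-sum reductions.
#'
#' @param W symmetric writhe matrix from [writhe_matrix()].
#' @param pattern a [chord_pattern].
#' @return A single numeric value.
#' @export
invariant <- function(W, pattern) {
  stopifnot(inherits(pattern, "chord_pattern"))
  n <- nrow(W)
  if (n < 2L * pattern$order) {
    stop(sprintf("degenerate input: %d segments cannot support an order-%d pattern",
                 n, pattern$order), call. = FALSE)
  }
  mats <- lapply(seq_along(pattern$chords), function(i) {
    if (pattern$abs_flags[i]) abs(W) else W
  })
  id <- pattern_id(pattern)
  switch(pattern$order,
         .cpp_order1(mats[[1L]]),
         .cpp_order2(id, mats[[1L]], mats[[2L]]),
         .cpp_order3(id, mats[[1L]], mats[[2L]], mats[[3L]]))
}

#' The default 30-component descriptor registry
#'
#' Fixed descriptor order: (1) backbone length N; (2) writhe `I(1,2)`;
#' (3) average crossing number `I|1,2|`; (4-15) the three order-2 matchings
#' (1,2)(3,4), (1,3)(2,4), (1,4)(2,3), each in the four abs variants
#' none/first/second/both; (16-30) the fifteen order-3 perfect matchings of
#' slots 1..6, without abs. The registry is an ordinary list and can be
#' replaced wholesale (see [read_registry()]).
#'
#' @return A `gi_registry` object of size 30.
#' @export
default_registry <- function() {
  descs <- list(list(name = "N", order = 0L, pattern = NULL))
  descs <- c(descs, lapply(list(FALSE, TRUE), function(ab) {
    p <- chord_pattern(list(c(1, 2)), ab)
    list(name = pattern_name(p), order = 1L, pattern = p)
  }))
  for (m in all_matchings(2L)) {
    for (flags in list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))) {
      p <- chord_pattern(m, flags)
      descs <- c(descs, list(list(name = pattern_name(p), order = 2L, pattern = p)))
    }
  }
  for (m in all_matchings(3L)) {
    p <- chord_pattern(m)
    descs <- c(descs, list(list(name = pattern_name(p), order = 3L, pattern = p)))
  }
  gi_registry(descs)
}

#' Construct a descriptor registry
#'
#' @param descriptors list of entries `list(name, order, pattern)`; `order` 0
#'   denotes the chain-length descriptor (no pattern).
#' @return A `gi_registry` object.
#' @export
gi_registry <- function(descriptors) {
  names <- vapply(descriptors, `[[`, "", "name")
  if (anyDuplicated(names)) stop("descriptor names must be unique", call. = FALSE)
  structure(list(descriptors = descriptors, size = length(descriptors)),
            class = "gi_registry")
}

#' @export
print.gi_registry <- function(x, ...) {
  cat("GI descriptor registry,", x$size, "descriptors:\n")
  cat(" ", paste(registry_names(x), collapse = " "), "\n")
  invisible(x)
}

#' @rdname gi_registry
#' @param registry a `gi_registry`.
#' @export
registry_names <- function(registry) {
  vapply(registry$descriptors, `[[`, "", "name")
}

#' Read / write a descriptor registry as JSON
#'
#' The JSON encoding is an ordered array of objects with fields `name`,
#' `order`, `chords` (array of slot pairs) and `abs_flags`.
#'
#' @param path file path.
#' @export
read_registry <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  descs <- lapply(raw, function(d) {
    order <- as.integer(d$order)
    if (order == 0L) {
      list(name = d$name, order = 0L, pattern = NULL)
    } else {
      p <- chord_pattern(lapply(d$chords, unlist),
                         vapply(d$abs_flags, isTRUE, TRUE))
      list(name = d$name, order = order, pattern = p)
    }
  })
  gi_registry(descs)
}

#' @rdname read_registry
#' @param registry a `gi_registry`.
#' @export
write_registry <- function(registry, path) {
  out <- lapply(registry$descriptors, function(d) {
    if (d$order == 0L) {
      list(name = d$name, order = 0L)
    } else {
      list(name = d$name, order = d$order,
           chords = lapply(d$pattern$chords, as.integer),
           abs_flags = as.logical(d$pattern$abs_flags))
    }
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Compute the Gauss-integral descriptor vector of a trace
#'
#' Evaluates every descriptor of the registry on the trace's writhe matrix;
#' the length descriptor reports the number of residues. The result is
#' invariant to rigid motions and (except for N) to uniform scaling, and the
#' components without abs flags change sign under mirror reflection.
#'
#' @param trace a [ca_trace] or n x 3 coordinate matrix, n >= 7.
#' @param registry a `gi_registry`; defaults to [default_registry()].
#' @return Named numeric vector, one value per descriptor.
#' @export
compute_gi_vector <- function(trace, registry = default_registry()) {
  coords <- trace_coords(trace)
  n <- nrow(coords)
  if (n < 7L) {
    stop("degenerate input: need at least 7 residues for order-3 descriptors",
         call. = FALSE)
  }
  W <- writhe_matrix(coords)
  vals <- vapply(registry$descriptors, function(d) {
    if (d$order == 0L) as.numeric(n) else invariant(W, d$pattern)
  }, numeric(1))
  names(vals) <- registry_names(registry)
  vals
}

#' Monte-Carlo average crossing number estimate
#'
#' Projects the polygonal curve along uniformly random directions and counts
#' planar self-crossings between nonadjacent segments. The mean converges to
#' the average crossing number `I|1,2|`; used as an independent check of the
#' closed-form engine.
#'
#' @param trace a [ca_trace] or n x 3 coordinate matrix.
#' @param n_projections number of random directions (>= 1).
#' @param seed integer RNG seed.
#' @return Mean crossing count (non-negative), with attribute `"se"` holding
#'   the Monte-Carlo standard error.
#' @export
acn_projection_estimate <- function(trace, n_projections = 1e4, seed = 1L) {
  coords <- trace_coords(trace)
  n <- nrow(coords)
  stopifnot(n_projections >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- as.integer(n_projections)
  u <- matrix(stats::rnorm(3 * m), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  # Orthonormal in-plane basis per direction
  ref <- matrix(rep(c(1, 0, 0), each = m), ncol = 3)
  flip <- abs(u[, 1]) > 0.9
  ref[flip, ] <- matrix(rep(c(0, 1, 0), each = sum(flip)), ncol = 3)
  e1 <- ref - u * rowSums(ref * u)
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(u[, 2] * e1[, 3] - u[, 3] * e1[, 2],
              u[, 3] * e1[, 1] - u[, 1] * e1[, 3],
              u[, 1] * e1[, 2] - u[, 2] * e1[, 1])
  px <- coords %*% t(e1)   # n x m
  py <- coords %*% t(e2)
  ns <- n - 1L
  counts <- numeric(m)
  orient <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  for (i in seq_len(ns - 2L)) {
    for (j in seq.int(i + 2L, ns)) {
      o1 <- orient(px[i, ], py[i, ], px[i + 1L, ], py[i + 1L, ], px[j, ], py[j, ])
      o2 <- orient(px[i, ], py[i, ], px[i + 1L, ], py[i + 1L, ], px[j + 1L, ], py[j + 1L, ])
      o3 <- orient(px[j, ], py[j, ], px[j + 1L, ], py[j + 1L, ], px[i, ], py[i, ])
      o4 <- orient(px[j, ], py[j, ], px[j + 1L, ], py[j + 1L, ], px[i + 1L, ], py[i + 1L, ])
      counts <- counts + as.numeric(o1 * o2 < 0 & o3 * o4 < 0)
    }
  }
  est <- mean(counts)
  attr(est, "se") <- stats::sd(counts) / sqrt(m)
  est
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
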