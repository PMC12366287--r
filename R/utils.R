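# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

MAX_COUNT <- 65535  # 16-bit dynamic range; frames are held in counts

stop2 <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf, allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x)))
    stop2(name, " must be a single number")
  if (!is.na(x) && (x < min || x > max))
    stop2(name, " must be in [", min, ", ", max, "], got ", x)
  invisible(x)
}

#' @noRd
# Offsets (di, dj) of pixels within a disc of the given radius.
disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(di = -r:r, dj = -r:r)
  g <- g[g$di^2 + g$dj^2 <= radius^2, , drop = FALSE]
  g
}

# Linear pixel indices of a disc centred at 0-based (x, y) in an nrow x ncol
# matrix, clipped to the image.
disc_indices <- function(x, y, radius, nrow, ncol) {
  off <- disc_offsets(radius)
  i <- round(y) + 1L + off$di
  j <- round(x) + 1L + off$dj
  keep <- i >= 1L & i <= nrow & j >= 1L & j <= ncol
  cbind(i[keep], j[keep])
}

# Derive a per-module RNG seed from the top-level seed, kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

# Add a Gaussian spot (amplitude at centre, sd sigma) to a frame in place.
# x, y are 0-based pixel-centre coordinates.
add_spot <- function(frame, x, y, amplitude, sigma) {
  r <- ceiling(4 * sigma)
  i0 <- max(1L, round(y) + 1L - r); i1 <- min(nrow(frame), round(y) + 1L + r)
  j0 <- max(1L, round(x) + 1L - r); j1 <- min(ncol(frame), round(x) + 1L + r)
  if (i0 > i1 || j0 > j1) return(frame)
  ii <- i0:i1; jj <- j0:j1
  dy2 <- ((ii - 1L) - y)^2
  dx2 <- ((jj - 1L) - x)^2
  patch <- amplitude * exp(-(outer(dy2, dx2, "+")) / (2 * sigma^2))
  frame[ii, jj] <- frame[ii, jj] + patch
  frame
}

# Cluster sorted 1-d coordinates by splitting at gaps larger than half the
# expected pitch; returns integer cluster ids in the order of v.
cluster_1d <- function(v, pitch) {
  ord <- order(v)
  s <- v[ord]
  brk <- c(FALSE, diff(s) > pitch / 2)
  ids <- cumsum(brk) + 1L
  out <- integer(length(v))
  out[ord] <- ids
  out
}
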