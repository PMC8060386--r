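# Brute-force reference implementations of the texture matrices, written as
# plain triple loops over voxels and neighbor offsets, independent of the
# package's compiled builders. All take a 3D integer array of 0-based levels
# with NA outside the VOI.

allOffsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

dirs13 <- allOffsets26[
  allOffsets26[, 3] > 0 |
  (allOffsets26[, 3] == 0 & allOffsets26[, 2] > 0) |
  (allOffsets26[, 3] == 0 & allOffsets26[, 2] == 0 & allOffsets26[, 1] > 0),
  , drop = FALSE]

inBounds <- function(v, d) all(v >= 1) && all(v <= d)

oracleGlcm <- function(arr, nlev) {
  d <- dim(arr)
  m <- matrix(0, nlev, nlev)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- arr[x, y, z]
    if (is.na(a)) next
    for (o in seq_len(nrow(allOffsets26))) {
      v <- c(x, y, z) + allOffsets26[o, ]
      if (!inBounds(v, d)) next
      b <- arr[v[1], v[2], v[3]]
      if (is.na(b)) next
      m[a + 1, b + 1] <- m[a + 1, b + 1] + 1
    }
  }
  m
}

oracleGldm <- function(arr, nlev, alpha = 0) {
  d <- dim(arr)
  m <- matrix(0, nlev, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- arr[x, y, z]
    if (is.na(a)) next
    dep <- 0
    for (o in seq_len(nrow(allOffsets26))) {
      v <- c(x, y, z) + allOffsets26[o, ]
      if (!inBounds(v, d)) next
      b <- arr[v[1], v[2], v[3]]
      if (!is.na(b) && abs(a - b) <= alpha) dep <- dep + 1
    }
    m[a + 1, dep + 1] <- m[a + 1, dep + 1] + 1
  }
  m
}

oracleGlrlm <- function(arr, nlev) {
  d <- dim(arr)
  m <- matrix(0, nlev, max(d))
  for (o in seq_len(nrow(dirs13))) {
    off <- dirs13[o, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- arr[x, y, z]
      if (is.na(a)) next
      prev <- c(x, y, z) - off
      if (inBounds(prev, d) && !is.na(arr[prev[1], prev[2], prev[3]]) &&
          arr[prev[1], prev[2], prev[3]] == a) next
      len <- 1
      nxt <- c(x, y, z) + off
      while (inBounds(nxt, d) && !is.na(arr[nxt[1], nxt[2], nxt[3]]) &&
             arr[nxt[1], nxt[2], nxt[3]] == a) {
        len <- len + 1
        nxt <- nxt + off
      }
      m[a + 1, len] <- m[a + 1, len] + 1
    }
  }
  m
}

# flood fill over 26-connected equal-level components; returns two-column
# matrix (level, size)
oracleZones <- function(arr) {
  d <- dim(arr)
  seen <- array(FALSE, d)
  zones <- NULL
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- arr[x, y, z]
    if (is.na(a) || seen[x, y, z]) next
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (o in seq_len(nrow(allOffsets26))) {
        v <- cur + allOffsets26[o, ]
        if (!inBounds(v, d)) next
        b <- arr[v[1], v[2], v[3]]
        if (is.na(b) || seen[v[1], v[2], v[3]] || b != a) next
        seen[v[1], v[2], v[3]] <- TRUE
        queue[[length(queue) + 1]] <- v
      }
    }
    zones <- rbind(zones, c(a, size))
  }
  zones
}

oracleGlszm <- function(arr, nlev) {
  z <- oracleZones(arr)
  m <- matrix(0, nlev, max(z[, 2]))
  for (i in seq_len(nrow(z)))
    m[z[i, 1] + 1, z[i, 2]] <- m[z[i, 1] + 1, z[i, 2]] + 1
  m
}

oracleNgtdm <- function(arr, nlev) {
  d <- dim(arr)
  n <- numeric(nlev)
  s <- numeric(nlev)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- arr[x, y, z]
    if (is.na(a)) next
    nb <- c()
    for (o in seq_len(nrow(allOffsets26))) {
      v <- c(x, y, z) + allOffsets26[o, ]
      if (!inBounds(v, d)) next
      b <- arr[v[1], v[2], v[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (!length(nb)) next
    n[a + 1] <- n[a + 1] + 1
    s[a + 1] <- s[a + 1] + abs(a - mean(nb))
  }
  cbind(n, s)
}

# sort-based percentile oracle (linear interpolation between order
# statistics at p*(n-1), the type-7 convention)
oracleQuantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  xs[lo] + (h - floor(h)) * (xs[hi] - xs[lo])
}

# explicit rank-formula Spearman on data without ties
oracleSpearmanNoTies <- function(x, y) {
  n <- length(x)
  dsq <- sum((rank(x) - rank(y))^2)
  1 - 6 * dsq / (n * (n^2 - 1))
}
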