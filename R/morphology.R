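# Small 3-D binary morphology primitives (6-connectivity), vectorized over
# whole arrays. Sufficient for brain-mask cleanup on phantom-sized grids.

# shift a 3-D array by one voxel along `axis` (+1/-1), padding with `fill`
shift3 <- function(a, axis, by, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- list(1:d[1], 1:d[2], 1:d[3])
  n <- d[axis]
  if (by == 1L) {
    dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1)
  } else {
    dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

neighbor_or <- function(m) {
  out <- m
  for (ax in 1:3) {
    out <- out | shift3(m, ax, 1L, FALSE)
    out <- out | shift3(m, ax, -1L, FALSE)
  }
  out
}

binary_dilate <- function(m, iter = 1L) {
  m <- m > 0
  for (i in seq_len(iter)) m <- neighbor_or(m)
  m
}

binary_erode <- function(m, iter = 1L) {
  m <- m > 0
  for (i in seq_len(iter)) {
    out <- m
    for (ax in 1:3) {
      out <- out & shift3(m, ax, 1L, FALSE)
      out <- out & shift3(m, ax, -1L, FALSE)
    }
    m <- out
  }
  m
}

binary_close <- function(m, iter = 1L) {
  binary_erode(binary_dilate(m, iter), iter)
}

# fill background cavities not reachable from the array border
fill_holes <- function(m) {
  m <- m > 0
  bg <- !m
  seed <- array(FALSE, dim(m))
  d <- dim(m)
  seed[c(1, d[1]), , ] <- TRUE
  seed[, c(1, d[2]), ] <- TRUE
  seed[, , c(1, d[3])] <- TRUE
  reach <- seed & bg
  repeat {
    grown <- neighbor_or(reach) & bg
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  m | (bg & !reach)
}

# 6-connected component labels by iterative max-label propagation;
# returns an integer-valued array, 0 = background
connected_components <- function(m) {
  m <- m > 0
  lab <- array(0, dim(m))
  lab[m] <- seq_len(sum(m))
  repeat {
    new <- lab
    for (ax in 1:3) {
      new <- pmax(new, shift3(lab, ax, 1L, 0))
      new <- pmax(new, shift3(lab, ax, -1L, 0))
    }
    new[!m] <- 0
    if (identical(new, lab)) break
    lab <- new
  }
  # compact labels
  u <- sort(unique(lab[lab > 0]))
  if (length(u)) lab[] <- match(lab, c(0, u)) - 1L
  lab
}

largest_component <- function(m) {
  m <- m > 0
  out <- array(FALSE, dim(m))
  if (!any(m)) return(out)
  # label within the foreground bounding box only
  idx <- arrayInd(which(m), dim(m))
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  sub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  lab <- connected_components(sub)
  sizes <- tabulate(lab[lab > 0])
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- lab == which.max(sizes)
  out
}

# Otsu threshold: maximize between-class variance on a 256-bin histogram
otsu_threshold <- function(x, nbins = 256L) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  w1 <- 1 - w0
  num <- (mu_t * w0 - mu0)^2
  den <- w0 * w1
  bcv <- ifelse(den > 0, num / den, 0)
  mids[which.max(bcv)]
}
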