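# Internal numeric helpers shared by the segmentation and synthesis code.

# Symmetric (edge-inclusive) reflection padding by r pixels on each side.
reflectPad <- function(x, r) {
  if (r == 0L) return(x)
  nr <- nrow(x); nc <- ncol(x)
  if (r > nr || r > nc)
    stop("window larger than image dimensions", call. = FALSE)
  ri <- c(r:1, 1:nr, nr:(nr - r + 1L))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1L))
  x[ri, ci, drop = FALSE]
}

# Column-wise then row-wise cumulative sums (integral image), zero-padded on
# top/left so window sums reduce to four lookups.
integralImage <- function(x) {
  S <- matrix(0, nrow(x) + 1L, ncol(x) + 1L)
  cs <- apply(x, 2L, cumsum)
  S[-1L, -1L] <- t(apply(cs, 1L, cumsum))
  S
}

# Moving-window sum over a w x w window centered at each pixel, reflection
# padded at the borders. w must be odd. Output has the shape of x.
boxSum <- function(x, w) {
  if (w %% 2L != 1L || w < 1L)
    stop("window size must be an odd positive integer", call. = FALSE)
  r <- (w - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  if (w > nr || w > nc)
    stop("window larger than image dimensions", call. = FALSE)
  S <- integralImage(reflectPad(x, r))
  i <- seq_len(nr); j <- seq_len(nc)
  S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
    S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]
}

# 8-connected labeling: EBImage's bwlabel (4-connected) plus a union-find
# merge of labels that touch diagonally.
labelMask8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]   # down-right diagonal
  a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]   # down-left diagonal
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(nlab)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- findRoot(pairs[k, 1L]); rb <- findRoot(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nlab), findRoot, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# Centroids (0-based x = column, y = row) and areas of labeled components.
labelCentroids <- function(lab) {
  sel <- which(lab > 0L)
  if (length(sel) == 0L)
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0)))
  l <- lab[sel]
  nr <- nrow(lab)
  rows <- (sel - 1L) %% nr          # 0-based row -> y
  cols <- (sel - 1L) %/% nr         # 0-based col -> x
  area <- tabulate(l)
  sx <- rowsum(cols, l); sy <- rowsum(rows, l)
  lev <- as.integer(rownames(sx))
  data.frame(label = lev, x = as.numeric(sx) / area[lev],
             y = as.numeric(sy) / area[lev], area = area[lev])
}

# Draw n angles from a von Mises distribution with mean mu and concentration
# kappa (Best & Fisher 1979 rejection sampler). kappa = 0 gives uniform
# angles on (-pi, pi].
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  rr <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- stats::runif(1); u2 <- stats::runif(1)
      z <- cos(pi * u1)
      f <- (1 + rr * z) / (rr + z)
      cc <- kappa * (rr - f)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
        u3 <- stats::runif(1)
        out[i] <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f)))
        break
      }
    }
  }
  out + mu
}

# Euclidean distance matrix between two 2-column point matrices.
crossDist <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

symmetrize <- function(M) (M + t(M)) / 2
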