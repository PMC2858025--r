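#' Iterative unique nearest neighbor (UNN) association
#'
#' Greedily associates track predictions with measurements: in each loop the
#' globally best (minimal Euclidean distance) pair among the not-yet-assigned
#' tracks and measurements is fixed, until either all tracks or all
#' measurements are allocated. Associating only the single best pair per loop
#' guards against unreasonable track-to-measurement associations; note that
#' the rule is greedy, not a globally optimal assignment. No distance gating
#' is applied here — gating is the monitoring module's first threshold.
#'
#' Ties in distance are broken towards the lexicographically smallest
#' (track, measurement) index pair, which makes the result deterministic.
#'
#' @param predicted numeric matrix (n x 2) of predicted track positions (px).
#' @param measurements numeric matrix (m x 2) of measured centroids (px).
#' @return list with components \code{pairs} (data.frame \code{track},
#'   \code{measurement}, \code{distance}, rows in the order the pairs were
#'   fixed; indices are 1-based row numbers of the inputs),
#'   \code{unmatchedTracks} and \code{unmatchedMeasurements} (integer
#'   vectors).
#' @examples
#' p <- rbind(c(0, 0), c(10, 0))
#' m <- rbind(c(1, 0))
#' unnAssociate(p, m)  # track 1 paired, track 2 unmatched
#' @export
unnAssociate <- function(predicted, measurements) {
  predicted <- toPointMatrix(predicted)
  measurements <- toPointMatrix(measurements)
  nt <- nrow(predicted); nm <- nrow(measurements)
  pairs <- data.frame(track = integer(0), measurement = integer(0),
                      distance = numeric(0))
  if (nt == 0L || nm == 0L)
    return(list(pairs = pairs, unmatchedTracks = seq_len(nt),
                unmatchedMeasurements = seq_len(nm)))
  D <- crossDist(predicted, measurements)
  freeT <- rep(TRUE, nt); freeM <- rep(TRUE, nm)
  res <- matrix(0, min(nt, nm), 3L)
  for (k in seq_len(min(nt, nm))) {
    sub <- D[freeT, freeM, drop = FALSE]
    best <- min(sub)
    # ties: smallest track index, then smallest measurement index
    hits <- which(sub == best, arr.ind = TRUE)
    hit <- hits[order(hits[, 1L], hits[, 2L])[1L], ]
    ti <- which(freeT)[hit[1L]]
    mi <- which(freeM)[hit[2L]]
    res[k, ] <- c(ti, mi, D[ti, mi])
    freeT[ti] <- FALSE; freeM[mi] <- FALSE
  }
  list(pairs = data.frame(track = as.integer(res[, 1L]),
                          measurement = as.integer(res[, 2L]),
                          distance = res[, 3L]),
       unmatchedTracks = which(freeT),
       unmatchedMeasurements = which(freeM))
}

toPointMatrix <- function(x) {
  if (is(x, "CentroidSet")) return(centroids(x))
  x <- as.matrix(x)
  if (length(x) == 0L) return(matrix(numeric(0), 0L, 2L))
  if (ncol(x) != 2L) stop("point matrix must have two columns", call. = FALSE)
  storage.mode(x) <- "double"
  x
}
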