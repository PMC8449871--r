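# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (and EBImage): plain flood fill, plain normal
# equations, explicit leave-one-out refits.

# 4-connected flood-fill labelling of a logical matrix; returns a list with
# the component count and pixel areas.  O(pixels), queue-based.
floodFillLabel <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nlab <- 0L
  areas <- integer(0)
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] > 0L) next
    nlab <- nlab + 1L
    queue <- start
    lab[start] <- nlab
    area <- 0L
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      area <- area + 1L
      i <- ((p - 1L) %% nr) + 1L
      j <- ((p - 1L) %/% nr) + 1L
      for (q in c(if (i > 1L) p - 1L, if (i < nr) p + 1L,
                  if (j > 1L) p - nr, if (j < nc) p + nr)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nlab
          queue <- c(queue, q)
        }
      }
    }
    areas <- c(areas, area)
  }
  list(n = nlab, areas = areas, labels = lab)
}

# OLS by explicit normal equations (X includes no intercept; one is added)
normalEquationsFit <- function(X, y) {
  Xi <- cbind(`(Intercept)` = 1, X)
  drop(solve(t(Xi) %*% Xi, t(Xi) %*% y))
}

# PRESS by explicit refit-without-row-i predictions
explicitPress <- function(X, y) {
  Xi <- cbind(1, X)
  n <- length(y)
  sum(vapply(seq_len(n), function(i) {
    b <- solve(t(Xi[-i, ]) %*% Xi[-i, ], t(Xi[-i, ]) %*% y[-i])
    (y[i] - drop(Xi[i, , drop = FALSE] %*% b))^2
  }, numeric(1)))
}

# random coded test designs: replicated +/-1 vertices plus centre points,
# enough runs for all two-factor interactions
randomCodedDesign <- function(nrun = 40L, seed = 1L) {
  set.seed(seed)
  d <- as.data.frame(matrix(sample(c(-1, 0, 1), nrun * 5, replace = TRUE,
                                   prob = c(0.45, 0.1, 0.45)), nrun, 5))
  names(d) <- LETTERS[1:5]
  d$block <- rep(1:2, length.out = nrun)
  d$run <- seq_len(nrun)
  d
}
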