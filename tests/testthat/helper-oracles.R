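# Independent oracles, coded as direct transcriptions of the textbook
# definitions. They deliberately share no code with the package internals.

# --- neighbor joining: plain-loop transcription of the Saitou-Nei
# formulas; ties broken by the first (i, j) pair found scanning i < j.
njOracle <- function(d, labels = rownames(d)) {
  act <- as.list(labels)
  while (nrow(d) > 3) {
    n <- nrow(d)
    r <- numeric(n)
    for (i in 1:n) for (k in 1:n) r[i] <- r[i] + d[i, k]
    best <- c(NA, NA); bestQ <- Inf
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      q <- (n - 2) * d[i, j] - r[i] - r[j]
      if (q < bestQ) { bestQ <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    newClade <- sprintf("(%s:%.10g,%s:%.10g)", act[[i]], max(bi, 0),
                        act[[j]], max(bj, 0))
    newRow <- numeric(n)
    for (k in 1:n) newRow[k] <- (d[i, k] + d[j, k] - d[i, j]) / 2
    keep <- setdiff(1:n, c(i, j))
    d2 <- matrix(0, length(keep) + 1, length(keep) + 1)
    d2[seq_along(keep), seq_along(keep)] <- d[keep, keep]
    d2[length(keep) + 1, seq_along(keep)] <- newRow[keep]
    d2[seq_along(keep), length(keep) + 1] <- newRow[keep]
    d <- d2
    act <- c(act[keep], newClade)
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                                act[[1]], max(la, 0), act[[2]], max(lb, 0),
                                act[[3]], max(lc, 0)))
}

# --- global affine-gap alignment score by exhaustive recursion over all
# alignments (gap of length k costs open + k * ext, charged per run)
bruteNWScore <- function(a, b, sm, open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  rec <- function(i, j, prev) {
    if (i > la && j > lb) return(0)
    best <- -Inf
    if (i <= la && j <= lb) {
      best <- max(best, sm[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= la) {
      cost <- ext + if (prev != "A") open else 0
      best <- max(best, -cost + rec(i + 1, j, "A"))
    }
    if (j <= lb) {
      cost <- ext + if (prev != "B") open else 0
      best <- max(best, -cost + rec(i, j + 1, "B"))
    }
    best
  }
  rec(1, 1, "start")
}

# --- SAM-style permutation FDR/q by brute force over explicit splits
bruteQvalues <- function(mat, isStress, s0) {
  dstat <- function(cols1, cols2) {
    x <- mat[, cols1, drop = FALSE]; y <- mat[, cols2, drop = FALSE]
    n1 <- length(cols1); n2 <- length(cols2)
    s <- sqrt((1 / n1 + 1 / n2) *
                (rowSums((x - rowMeans(x))^2) +
                 rowSums((y - rowMeans(y))^2)) / (n1 + n2 - 2))
    (rowMeans(x) - rowMeans(y)) / (s + s0)
  }
  n <- ncol(mat); n1 <- sum(isStress)
  dObs <- dstat(which(isStress), which(!isStress))
  splits <- combn(n, n1)
  G <- length(dObs)
  q <- numeric(G)
  for (g in 1:G) {
    t <- abs(dObs[g])
    fdrs <- numeric(0)
    for (tprime in sort(abs(dObs)[abs(dObs) <= t])) {
      exceed <- numeric(ncol(splits))
      for (p in seq_len(ncol(splits))) {
        g1 <- splits[, p]
        exceed[p] <- sum(abs(dstat(g1, setdiff(1:n, g1))) >= tprime)
      }
      obs <- sum(abs(dObs) >= tprime)
      fdrs <- c(fdrs, median(exceed) / obs)
    }
    q[g] <- min(1, min(fdrs))
  }
  q
}

# --- Robinson-Foulds distance via phangorn (independent library)
rfDist <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))
}

# random additive distance matrix from a random tree, with its topology
randomAdditiveCase <- function(nLeaves) {
  tr <- ape::rtree(nLeaves, rooted = FALSE,
                   br = function(n) runif(n, 0.1, 1))
  d <- ape::cophenetic.phylo(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tr, d = d)
}
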