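# Shared fixtures and independent oracles, all built in code.

# compact phantom geometry for unit tests
smallGeom <- function(nSlices = 5L) {
  g <- defaultGeometry()
  g$dim <- c(64L, 64L)
  g$nSlices <- as.integer(nSlices)
  g$center <- c(32.5, 32.5)
  g$endoRadius <- 12
  g$epiRadius <- 18
  g$spacing <- c(1.2, 1.2)
  g$muscleRows <- c(52L, 62L)
  g$muscleCols <- c(15L, 50L)
  g
}

# deterministic preset: fixed subject mean, no pixel noise
zeroNoisePreset <- function(group = "control", meanT1 = 946,
                            t2Ratio = 1.56, ...) {
  p <- groupPreset(group)
  p$meanT1 <- c(meanT1, 0)
  p$t2Ratio <- c(t2Ratio, 0)
  p$noiseSD <- c(T1 = 0, T2W = 0, LGE = 0)
  p$qcExclude <- c(T1 = 0, T2W = 0, LGE = 0)
  utils::modifyList(p, list(...))
}

# classic stack-based flood fill; written independently of labelComponents
floodFillLabel <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  k <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    k <- k + 1L
    stack <- start
    lab[start] <- k
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      pr <- (p - 1L) %% nr + 1L
      pc <- (p - 1L) %/% nr + 1L
      for (j in seq_len(nrow(nb))) {
        r <- pr + nb[j, 1]; c <- pc + nb[j, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- k
          stack <- c(stack, (c - 1L) * nr + r)
        }
      }
    }
  }
  lab
}

# component pixel-sets as canonical sorted list, for comparing labelings
componentSets <- function(lab) {
  if (max(lab) == 0L) return(list())
  sets <- split(which(lab > 0L), lab[lab > 0L])
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, numeric(1), 1))]
}

# brute-force AUC over all between-class pairs (ties count 1/2)
aucPairOracle <- function(scores, truth) {
  x <- scores[truth]; y <- scores[!truth]
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}

# DeLong variance components by explicit summation
delongDirectOracle <- function(sa, sb, truth) {
  x1 <- sa[truth]; y1 <- sa[!truth]
  x2 <- sb[truth]; y2 <- sb[!truth]
  m <- length(x1); n <- length(y1)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- function(x, y) vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
  v01 <- function(x, y) vapply(y, function(yj) mean(psi(x, yj)), numeric(1))
  a1 <- mean(outer(x1, y1, psi)); a2 <- mean(outer(x2, y2, psi))
  V10 <- cbind(v10(x1, y1), v10(x2, y2))
  V01 <- cbind(v01(x1, y1), v01(x2, y2))
  cv <- function(u, v) sum((u - mean(u)) * (v - mean(v))) / (length(u) - 1)
  var <- (cv(V10[, 1], V10[, 1]) + cv(V10[, 2], V10[, 2]) -
            2 * cv(V10[, 1], V10[, 2])) / m +
         (cv(V01[, 1], V01[, 1]) + cv(V01[, 2], V01[, 2]) -
            2 * cv(V01[, 1], V01[, 2])) / n
  list(aucA = a1, aucB = a2, var = var,
       z = (a1 - a2) / sqrt(var))
}

# Cochran's Q by direct summation over the defining sums
cochranQOracle <- function(m) {
  m <- m * 1
  k <- ncol(m)
  Cj <- colSums(m); Ri <- rowSums(m); N <- sum(m)
  num <- 0
  for (j in seq_len(k)) num <- num + (Cj[j] - N / k)^2
  Q <- k * (k - 1) * num / sum(Ri * (k - Ri))
  unname(Q)
}
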