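# Subject-level diagnostic evaluation of single and combined tissue
# criteria: 2x2 counts, sensitivity/specificity/accuracy/PPV/NPV, rank-based
# AUC, DeLong comparison of correlated AUCs, McNemar and Cochran's Q.

.roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize one binary criterion against truth
#'
#' Computes the 2x2 counts and the five Table-style metrics on the
#' evaluable subset (decisions may be NA for non-evaluable subjects, e.g.
#' LGE in controls without contrast). Metrics are percentages; the
#' \code{display} element carries the half-up integer rounding used in
#' printed tables, the unrounded values are retained.
#'
#' @param decisions logical vector (NA = not evaluable).
#' @param truth logical vector, TRUE = patient.
#' @return object of class \code{diagnosticSummary}: list with counts
#'   (TP, FP, TN, FN), evaluable n per arm, metrics (unrounded %) and
#'   display (rounded %).
#' @export
summarizeCriterion <- function(decisions, truth) {
  if (length(decisions) != length(truth)) stop("length mismatch")
  if (any(is.na(truth))) stop("missing truth labels")
  ok <- !is.na(decisions)
  d <- decisions[ok]; y <- truth[ok]
  TP <- sum(d & y); FN <- sum(!d & y)
  TN <- sum(!d & !y); FP <- sum(d & !y)
  div <- function(a, b) if (b == 0) NA_real_ else 100 * a / b
  metrics <- c(sensitivity = div(TP, TP + FN),
               specificity = div(TN, TN + FP),
               accuracy = div(TP + TN, TP + TN + FP + FN),
               ppv = div(TP, TP + FP),
               npv = div(TN, TN + FN))
  structure(list(counts = c(TP = TP, FP = FP, TN = TN, FN = FN),
                 n = c(patients = TP + FN, controls = TN + FP),
                 metrics = metrics,
                 display = .roundHalfUp(metrics)),
            class = "diagnosticSummary")
}

#' @export
print.diagnosticSummary <- function(x, ...) {
  cat(sprintf("diagnostic summary (n = %d patients / %d controls)\n",
              x$n["patients"], x$n["controls"]))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$counts["TP"], x$counts["FP"],
              x$counts["TN"], x$counts["FN"]))
  m <- x$display
  cat(sprintf("  SN %g%%  SP %g%%  Acc %g%%  PPV %g%%  NPV %g%%\n",
              m["sensitivity"], m["specificity"], m["accuracy"],
              m["ppv"], m["npv"]))
  invisible(x)
}

#' Reconstruct 2x2 counts from printed sensitivity/specificity
#'
#' Internal-consistency tool for printed diagnostic tables: given SN, SP
#' (percent) and the arm sizes, rebuilds TP/FN/TN/FP (rounding to whole
#' subjects) and returns the full summary.
#'
#' @param snPct,spPct printed sensitivity and specificity, percent.
#' @param nPatients,nControls arm sizes.
#' @return a \code{diagnosticSummary}.
#' @export
countsFromPrinted <- function(snPct, spPct, nPatients, nControls) {
  TP <- round(snPct / 100 * nPatients)
  TN <- round(spPct / 100 * nControls)
  decisions <- c(rep(TRUE, TP), rep(FALSE, nPatients - TP),
                 rep(TRUE, nControls - TN), rep(FALSE, TN))
  truth <- c(rep(TRUE, nPatients), rep(FALSE, nControls))
  summarizeCriterion(decisions, truth)
}

#' Combine binary criteria with an any-k-of-n rule
#'
#' TRUE iff at least k of the n constituent decisions are TRUE (k = n is
#' the all-of rule). Subjects with any non-evaluable constituent are
#' dropped (NA) and their count reported via the \code{nDropped} attribute.
#'
#' @param decisions list or data.frame of logical vectors (the criteria).
#' @param k minimum number of positive constituents.
#' @return logical vector with attribute \code{nDropped}.
#' @export
combineCriteria <- function(decisions, k) {
  m <- as.matrix(as.data.frame(decisions))
  n <- ncol(m)
  if (k < 1 || k > n) stop("k must be in 1..", n)
  hasNA <- apply(m, 1, base::anyNA)
  pos <- rowSums(m) >= k
  pos[hasNA] <- NA
  if (any(hasNA))
    message(sum(hasNA), " subject(s) dropped from combination (non-evaluable constituent)")
  structure(pos, nDropped = sum(hasNA))
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney concordance formulation: the probability that a random
#' patient scores above a random control, with tied pairs counting one
#' half. Constant scores give 0.5 with a warning.
#'
#' @param scores numeric vector (higher = more disease-like).
#' @param truth logical vector, TRUE = patient.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, truth) {
  ok <- !is.na(scores) & !is.na(truth)
  scores <- scores[ok]; truth <- truth[ok]
  m <- sum(truth); n <- sum(!truth)
  if (m == 0 || n == 0) stop("need at least one subject per class")
  if (length(unique(scores)) == 1L) {
    warning("constant scores; AUC is 0.5")
    return(0.5)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - m * (m + 1) / 2) / (m * n)
}

# placement values: V10[i] = P-hat(score_i > control), V01[j] = P-hat(patient > score_j)
.delongPlacements <- function(scores, truth) {
  x <- scores[truth]; y <- scores[!truth]
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = m, n = n)
}

#' DeLong comparison of two correlated AUCs
#'
#' Paired scores on the same subjects; the variance of the AUC difference
#' is built from the empirical covariance of the placement values and the
#' two-sided p-value from the normal approximation. Degenerate (zero)
#' variance yields a missing p with a diagnostic message unless the AUCs
#' are identical (then z = 0, p = 1).
#'
#' @param scoresA,scoresB paired score vectors.
#' @param truth logical vector, TRUE = patient.
#' @return list: aucA, aucB, z, p.
#' @export
delongCompare <- function(scoresA, scoresB, truth) {
  if (length(scoresA) != length(scoresB) || length(scoresA) != length(truth))
    stop("scores must be paired on identical subjects")
  pa <- .delongPlacements(scoresA, truth)
  pb <- .delongPlacements(scoresB, truth)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  dAuc <- pa$auc - pb$auc
  if (v <= 0) {
    if (abs(dAuc) < 1e-12) return(list(aucA = pa$auc, aucB = pb$auc, z = 0, p = 1))
    message("degenerate DeLong variance; p not computable")
    return(list(aucA = pa$auc, aucB = pb$auc, z = NA_real_, p = NA_real_))
  }
  z <- dAuc / sqrt(v)
  list(aucA = pa$auc, aucB = pb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' McNemar test on paired binary decisions
#'
#' Two-sided test on the discordant pairs: exact binomial (doubled smaller
#' tail, capped at 1) when the number of discordant pairs is below 25,
#' otherwise the continuity-corrected chi-square. Zero discordant pairs
#' give p = 1.
#'
#' @param a,b paired logical decision vectors (e.g. two criteria on the
#'   truth-positive subset).
#' @param exactLimit discordant-pair count below which the exact test is
#'   used (default 25).
#' @return list: b10 (a only), b01 (b only), method, statistic, p.
#' @export
mcnemarTest <- function(a, b, exactLimit = 25) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  b10 <- sum(a & !b); b01 <- sum(!a & b)
  nd <- b10 + b01
  if (nd == 0) return(list(b10 = 0L, b01 = 0L, method = "exact",
                           statistic = NA_real_, p = 1))
  if (nd < exactLimit) {
    p <- min(1, 2 * stats::pbinom(min(b10, b01), nd, 0.5))
    list(b10 = b10, b01 = b01, method = "exact", statistic = NA_real_, p = p)
  } else {
    stat <- (abs(b10 - b01) - 1)^2 / nd
    list(b10 = b10, b01 = b01, method = "chi-square",
         statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
  }
}

#' Cochran's Q test over three or more paired binary criteria
#'
#' Q with k - 1 degrees of freedom against the chi-square distribution;
#' for k = 2 Q reduces to McNemar's chi-square without continuity
#' correction. Constant rows everywhere give Q = 0, p = 1.
#'
#' @param decisions data.frame or matrix of logical columns (criteria),
#'   rows = subjects.
#' @return list: Q, df, p.
#' @export
cochranQ <- function(decisions) {
  m <- as.matrix(as.data.frame(decisions)) * 1
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2) stop("need at least 2 criteria")
  Cj <- colSums(m); Ri <- rowSums(m); N <- sum(m)
  denom <- k * N - sum(Ri^2)
  if (denom == 0) return(list(Q = 0, df = k - 1L, p = 1))
  Q <- (k - 1) * (k * sum(Cj^2) - N^2) / denom
  list(Q = Q, df = k - 1L, p = stats::pchisq(Q, k - 1, lower.tail = FALSE))
}
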