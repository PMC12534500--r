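#' Paired t-tests across units with BH-FDR correction
#'
#' One paired two-tailed t-test per unit (electrode or network edge)
#' comparing two within-subject conditions, followed by Benjamini-Hochberg
#' step-up adjustment across all non-degenerate units of the family (one
#' band x one comparison = one family). Units with zero within-pair
#' variance have no defined t-test; they are flagged degenerate and
#' excluded from the FDR family rather than assigned p = 1.
#'
#' @param a,b numeric subject x unit matrices for the two conditions, same
#'   dimensions, rows = same subjects in both.
#' @param alpha significance level applied to the adjusted p-values
#'   (default 0.05).
#' @param units unit labels; default the column names of \code{a}.
#' @param comparison optional label stored in the output.
#' @return data.frame (unit, t, df, p, q, significant, degenerate).
#' @export
pairedTFdr <- function(a, b, alpha = 0.05, units = colnames(a),
                       comparison = NA_character_) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("condition matrices must have identical dimensions")
  if (nrow(a) < 3)
    stop("need at least 3 complete pairs per unit")
  if (is.null(units)) units <- paste0("unit", seq_len(ncol(a)))
  diffs <- b - a
  n <- nrow(diffs)
  res <- data.frame(unit = units, t = NA_real_, df = n - 1L, p = NA_real_,
                    q = NA_real_, significant = FALSE, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(diffs))) {
    d <- diffs[, j]
    if (stats::sd(d) == 0) {
      res$degenerate[j] <- TRUE
      next
    }
    tt <- stats::t.test(b[, j], a[, j], paired = TRUE)
    res$t[j] <- unname(tt$statistic)
    res$p[j] <- tt$p.value
  }
  ok <- !res$degenerate
  if (any(res$degenerate))
    message(sprintf("excluded %d degenerate (zero-variance) unit(s) from the FDR family: %s",
                    sum(res$degenerate),
                    paste(res$unit[res$degenerate], collapse = ", ")))
  res$q[ok] <- stats::p.adjust(res$p[ok], method = "BH")
  res$significant <- !is.na(res$q) & res$q < alpha
  if (!is.na(comparison)) res$comparison <- comparison
  res
}

#' Two-way repeated-measures ANOVA (intervention x time)
#'
#' Fully within-subject two-factor ANOVA on a complete balanced design:
#' each effect (intervention, time, interaction) is tested against its own
#' subject-by-effect interaction error stratum, via \code{aov} with an
#' \code{Error(subject/(arm*time))} term. No sphericity correction by
#' default; \code{correction = "GG"} applies the Greenhouse-Geisser
#' epsilon adjustment to the degrees of freedom and p-value of each
#' within-subject effect.
#'
#' @param data data.frame with columns \code{subject}, \code{arm},
#'   \code{time}, \code{value}; every subject must have every arm x time
#'   cell exactly once (no imputation).
#' @param correction "none" (default) or "GG".
#' @return data.frame (effect, F, dfNum, dfDen, p, epsilon).
#' @export
rmAnova <- function(data, correction = c("none", "GG")) {
  correction <- match.arg(correction)
  need <- c("subject", "arm", "time", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns subject, arm, time, value")
  data$subject <- factor(data$subject)
  data$arm <- factor(data$arm)
  data$time <- factor(data$time)
  tab <- table(data$subject, data$arm, data$time)
  if (any(tab != 1))
    stop("incomplete or unbalanced design: every subject needs every arm x time cell exactly once")
  fit <- stats::aov(value ~ arm * time + Error(subject / (arm * time)),
                    data = data)
  sm <- summary(fit)
  scaleSS <- sum(data$value^2) + 1e-300
  pick <- function(stratum, term) {
    tb <- sm[[stratum]][[1]]
    i <- match(term, trimws(rownames(tb)))
    c(F = tb[i, "F value"], dfNum = tb[i, "Df"],
      dfDen = tb[nrow(tb), "Df"], p = tb[i, "Pr(>F)"],
      ss = tb[i, "Sum Sq"])
  }
  rows <- rbind(
    intervention = pick("Error: subject:arm", "arm"),
    time = pick("Error: subject:time", "time"),
    interaction = pick("Error: subject:arm:time", "arm:time")
  )
  out <- data.frame(effect = rownames(rows), F = rows[, "F"],
                    dfNum = rows[, "dfNum"], dfDen = rows[, "dfDen"],
                    p = rows[, "p"], epsilon = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  # an effect with (numerically) zero sum of squares has no signal: its
  # F ratio is 0/0 noise, so report F = 0, p = 1
  zero <- !is.finite(out$F) | rows[, "ss"] <= 1e-12 * scaleSS
  out$F[zero] <- 0; out$p[zero] <- 1
  if (correction == "GG") {
    eps <- c(ggEpsilon(data, "arm"), ggEpsilon(data, "time"),
             ggEpsilonInteraction(data))
    out$epsilon <- eps
    adj <- !is.na(eps)
    out$p[adj] <- stats::pf(out$F[adj], out$dfNum[adj] * eps[adj],
                            out$dfDen[adj] * eps[adj], lower.tail = FALSE)
    out$p[zero] <- 1
  }
  out
}

# Greenhouse-Geisser epsilon for a one-way within factor: built from the
# covariance of the subject x level matrix (averaging over the other
# factor), projected on orthonormal contrasts.
ggEpsilon <- function(data, factorName) {
  agg <- stats::aggregate(value ~ subject + data[[factorName]], data = data,
                          FUN = mean)
  names(agg)[2] <- "lev"
  Y <- stats::reshape(agg, idvar = "subject", timevar = "lev",
                      direction = "wide")
  Y <- as.matrix(Y[, -1, drop = FALSE])
  epsilonFromCov(stats::cov(Y), ncol(Y) - 1)
}

ggEpsilonInteraction <- function(data) {
  a <- levels(data$arm); b <- levels(data$time)
  data$cell <- interaction(data$arm, data$time)
  Y <- stats::reshape(data[, c("subject", "cell", "value")],
                      idvar = "subject", timevar = "cell",
                      direction = "wide")
  Y <- as.matrix(Y[, -1, drop = FALSE])
  Ca <- stats::contr.helmert(length(a))
  Cb <- stats::contr.helmert(length(b))
  # interaction() varies the first factor (arm) fastest, so the cell
  # order matches kron(time contrasts, arm contrasts)
  C <- qr.Q(qr(Cb %x% Ca))
  M <- t(C) %*% stats::cov(Y) %*% C
  k <- ncol(C)
  (sum(diag(M)))^2 / (k * sum(M^2))
}

epsilonFromCov <- function(S, dfc) {
  k <- ncol(S)
  C <- qr.Q(qr(stats::contr.helmert(k)))
  M <- t(C) %*% S %*% C
  (sum(diag(M)))^2 / (dfc * sum(M^2))
}

#' Correlation between wake band-power change and first-cycle sleep power
#'
#' Pearson product-moment correlation (default) between the z-scored
#' post-minus-baseline wake band-power change at the target electrode and
#' the same band's power during the NREM period of the first sleep cycle,
#' across subjects; the two-tailed p comes from the t transform of r.
#' Spearman available by flag.
#'
#' @param wakeChange numeric vector (one value per subject).
#' @param sleepPower numeric vector, same subjects and order.
#' @param method "pearson" (default) or "spearman".
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
wakeSleepCorrelation <- function(wakeChange, sleepPower,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(wakeChange, sleepPower)
  x <- wakeChange[ok]; y <- sleepPower[ok]
  if (length(x) < 3)
    stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance in one of the vectors")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' A priori sample size for a paired two-tailed t-test
#'
#' Smallest integer n such that the two-tailed paired t-test at level
#' \code{alpha}, with noncentrality parameter \eqn{d \sqrt{n}} and
#' \eqn{n - 1} degrees of freedom, attains the target power; computed by
#' iterating n upward with the noncentral t distribution.
#'
#' @param d within-pair effect size (Cohen's dz), > 0.
#' @param alpha significance level, in (0, 1).
#' @param power target power 1 - beta, in (0, 1).
#' @param tails 1 or 2 (default 2).
#' @param nMax iteration cap (default 1e6).
#' @return required sample size (integer number of pairs).
#' @examples
#' pairedTSampleSize(0.5, 0.05, 0.9)  # 44
#' @export
pairedTSampleSize <- function(d, alpha = 0.05, power = 0.9, tails = 2,
                              nMax = 1e6) {
  if (!(alpha > 0 && alpha < 1) || !(power > 0 && power < 1))
    stop("alpha and power must lie in (0, 1)")
  if (d <= 0) stop("effect size d must be positive")
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2")
  if (power <= alpha)
    stop("unattainable inputs: target power must exceed alpha")
  for (n in 2:nMax) {
    if (pairedTPower(d, n, alpha, tails) >= power) return(n)
  }
  stop("sample size exceeds iteration cap")
}

#' @rdname pairedTSampleSize
#' @param n number of pairs.
#' @return \code{pairedTPower}: the power of the test at n pairs.
#' @export
pairedTPower <- function(d, n, alpha = 0.05, tails = 2) {
  df <- n - 1
  ncp <- d * sqrt(n)
  tcrit <- stats::qt(1 - alpha / tails, df)
  pow <- stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
  if (tails == 2)
    pow <- pow + stats::pt(-tcrit, df, ncp = ncp)
  pow
}
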