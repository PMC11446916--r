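# Transcriptomic arm: nCounter-style normalization, Mann-Whitney DEG with
# median-based log2FC, the 9-gene pauperization score with upper-quartile
# classification, and survival association.

#' nCounter-style background correction and normalization
#'
#' Per sample, the background is the mean plus 2 SD of the negative-control
#' counts, and counts below it are raised to it. Two sequential
#' multiplicative scalings follow: each sample is scaled by (cohort
#' arithmetic mean of per-sample positive-control means) / (its own
#' positive-control mean), then identically using the housekeeping-gene
#' means computed on the positive-control-scaled data.
#'
#' @param raw Genes x samples count matrix with row and column names.
#' @param neg_probes,pos_probes Row names of the negative / positive control
#'   probes.
#' @param hk_genes Row names of the housekeeping genes (default CNOT4,
#'   HDAC3, DDX50, CC2D1B).
#' @return Normalized matrix; attributes `background`, `pos_factors`,
#'   `hk_factors` record the per-sample corrections.
#' @export
ncounter_normalize <- function(raw, neg_probes, pos_probes,
                               hk_genes = c("CNOT4", "HDAC3", "DDX50", "CC2D1B")) {
  if (is.null(rownames(raw)) || is.null(colnames(raw)))
    stop_config("raw matrix must have gene row names and sample column names")
  for (set in list(neg_probes, pos_probes, hk_genes)) {
    miss <- setdiff(set, rownames(raw))
    if (length(miss))
      stop_config(sprintf("control rows missing from matrix: %s",
                          paste(miss, collapse = ", ")))
  }
  neg <- raw[neg_probes, , drop = FALSE]
  sds <- apply(neg, 2, stats::sd)
  sds[is.na(sds)] <- 0
  bg <- colMeans(neg) + 2 * sds
  x <- raw
  x <- pmax(x, matrix(bg, nrow(x), ncol(x), byrow = TRUE))
  pos_mean <- colMeans(x[pos_probes, , drop = FALSE])
  pos_f <- mean(pos_mean) / pos_mean
  x <- sweep(x, 2, pos_f, "*")
  hk_mean <- colMeans(x[hk_genes, , drop = FALSE])
  hk_f <- mean(hk_mean) / hk_mean
  x <- sweep(x, 2, hk_f, "*")
  structure(x, background = bg, pos_factors = pos_f, hk_factors = hk_f)
}

#' Mann-Whitney differential expression with median-based log2 fold change
#'
#' Per gene, a two-sided Mann-Whitney-Wilcoxon test (exact for small
#' tie-free samples) comparing pauperized vs normal samples, and
#' `log2((median_pauperized + eps) / (median_normal + eps))` with a
#' half-count offset `eps`.
#'
#' @param matrix Genes x samples matrix on the normalized linear scale.
#' @param groups Logical per sample, `TRUE` = pauperized.
#' @param eps Median offset (default 0.5 count).
#' @return `data.frame` with columns `gene`, `log2fc`, `p`.
#' @export
differential_expression <- function(matrix, groups, eps = 0.5) {
  groups <- as.logical(groups)
  if (length(groups) != ncol(matrix))
    stop_input("groups length must equal the number of samples")
  if (sum(groups) < 2 || sum(!groups) < 2)
    stop_input("need at least 2 samples per group")
  res <- t(apply(matrix, 1, function(x) {
    p <- suppressWarnings(stats::wilcox.test(x[groups], x[!groups]))$p.value
    fc <- log2((stats::median(x[groups]) + eps) / (stats::median(x[!groups]) + eps))
    c(fc, p)
  }))
  data.frame(gene = rownames(matrix), log2fc = res[, 1], p = res[, 2],
             row.names = NULL)
}

#' The Emerin-pauperization transcriptomic score
#'
#' Per sample, the mean over the 9 signature genes of `log2(count +
#' pseudocount)`; samples strictly above the cohort's third quartile
#' (linear-interpolation quantile) are flagged high.
#'
#' @param matrix Genes x samples matrix on the linear normalized scale.
#' @param signature Signature genes (default [emd_signature()]).
#' @param pseudocount Offset inside the log (default 1; set 0 for strictly
#'   positive matrices).
#' @return `data.frame` with columns `sample`, `score`, `high_flag`;
#'   attribute `q3` records the cutoff.
#' @export
pauperization_score <- function(matrix, signature = emd_signature(),
                                pseudocount = 1) {
  signature <- as.character(signature)
  miss <- setdiff(signature, rownames(matrix))
  if (length(miss))
    stop_input(sprintf("signature gene(s) missing from matrix: %s",
                       paste(miss, collapse = ", ")))
  score <- colMeans(log2(matrix[signature, , drop = FALSE] + pseudocount))
  q3 <- stats::quantile(score, 0.75, type = 7, names = FALSE)
  structure(data.frame(sample = colnames(matrix), score = as.numeric(score),
                       high_flag = as.numeric(score) > q3, row.names = NULL),
            q3 = q3)
}

# log-rank test implemented from the observed - expected / variance form;
# cross-checked against survival::survdiff in the test suite
logrank_test <- function(time, event, group) {
  group <- as.logical(group)
  tt <- sort(unique(time[event == 1]))
  o1 <- sum(event == 1 & group)
  e1 <- 0; v <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group)
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (o1 - e1)^2 / v
  list(observed = o1, expected = e1, variance = v, chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Survival association of a binary grouping
#'
#' Kaplan-Meier curves per group, the log-rank test (statistic implemented
#' from its observed-minus-expected form), and a Cox proportional-hazards
#' hazard ratio with 95% Wald confidence interval for the group indicator
#' (fitted with the survival package).
#'
#' @param surv `data.frame` with columns `time` (> 0) and `event` (0/1).
#' @param groups Logical per subject, `TRUE` = high-risk group (the HR
#'   numerator).
#' @return Object of class `survival_result`: `hr`, `ci95`, `logrank_chisq`,
#'   `logrank_p`, `km` (a `survfit` object), `n`, `n_events`. `hr` is `NA`
#'   (with a warning) when a group has no events.
#' @export
survival_association <- function(surv, groups) {
  groups <- as.logical(groups)
  if (any(surv$time <= 0)) stop_input("survival times must be positive")
  if (!all(surv$event %in% c(0, 1))) stop_input("event must be 0/1")
  if (length(groups) != nrow(surv))
    stop_input("groups length must equal the number of subjects")
  lr <- logrank_test(surv$time, surv$event, groups)
  km <- survival::survfit(survival::Surv(surv$time, surv$event) ~ groups)
  ev <- tapply(surv$event, groups, sum)
  if (any(ev == 0) || length(ev) < 2) {
    warning("a group has zero events: hazard ratio undefined")
    hr <- NA_real_; ci <- c(NA_real_, NA_real_)
  } else {
    fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ groups)
    s <- summary(fit)
    hr <- unname(s$conf.int[1, "exp(coef)"])
    ci <- unname(s$conf.int[1, c("lower .95", "upper .95")])
  }
  structure(list(hr = hr, ci95 = ci, logrank_chisq = lr$chisq,
                 logrank_p = lr$p, km = km, n = nrow(surv),
                 n_events = sum(surv$event)),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("survival association: n = %d (%d events)\n", x$n, x$n_events))
  if (is.na(x$hr)) cat("  HR: undefined (a group has no events)\n")
  else cat(sprintf("  HR = %.3f (95%% CI %.3f-%.3f)\n", x$hr, x$ci95[1], x$ci95[2]))
  cat(sprintf("  log-rank chi-square = %.3f, p = %.4g\n",
              x$logrank_chisq, x$logrank_p))
  invisible(x)
}
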