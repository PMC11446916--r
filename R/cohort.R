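#' The 9-gene Emerin-pauperization signature
#'
#' Gene identifiers whose mean log2 expression defines the pauperization
#' score: CXCR4, APOE, SPARC, VIM, GSN, ANXA2P2, SFRP1, COL18A1, FN1.
#'
#' @return Character vector of the 9 gene symbols, class `emd_signature`.
#' @export
emd_signature <- function() {
  structure(c("CXCR4", "APOE", "SPARC", "VIM", "GSN", "ANXA2P2",
              "SFRP1", "COL18A1", "FN1"),
            class = "emd_signature")
}

#' Parameters for synthetic expression/survival cohorts
#'
#' Describes a cohort in which a fraction of samples carries the Emerin
#' pauperization expression shift (signature genes up by `effect_log2` on the
#' log2 scale) and experiences proportionally higher hazard. Expression is
#' log-normal: per-gene baselines are uniform on the log2 scale and per-sample
#' values add unit-SD Gaussian log2 noise. Survival times are exponential with
#' hazard ratio `true_hr` for pauperized samples; censoring is administrative,
#' uniform on (0, b) with b solved so the expected censored fraction equals
#' `censor_frac`.
#'
#' @param n_samples Cohort size (at least 8, so a quartile split is
#'   meaningful).
#' @param signature_genes Gene identifiers carrying the effect (default the
#'   9-gene signature).
#' @param n_noise_genes Number of unaffected genes.
#' @param effect_log2 Mean log2 shift of signature genes in pauperized
#'   samples.
#' @param frac_pauperized Proportion of pauperized samples, in (0, 1).
#' @param true_hr Hazard ratio of pauperized vs normal samples (> 0).
#' @param censor_frac Expected proportion censored, in \[0, 1).
#' @param baseline_hazard Event hazard per month for normal samples (default
#'   log(2)/60: median survival 60 months).
#' @param seed RNG seed.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_samples = 200L,
                          signature_genes = emd_signature(),
                          n_noise_genes = 91L,
                          effect_log2 = 1,
                          frac_pauperized = 0.25,
                          true_hr = 1.75,
                          censor_frac = 0.3,
                          baseline_hazard = log(2) / 60,
                          seed = 1L) {
  p <- as.list(environment())
  p$signature_genes <- as.character(signature_genes)
  if (p$n_samples < 8) stop_config("n_samples must be at least 8")
  if (!(p$frac_pauperized > 0 && p$frac_pauperized < 1))
    stop_config("frac_pauperized must be in (0, 1)")
  if (p$true_hr <= 0) stop_config("true_hr must be positive")
  if (p$n_noise_genes < 0) stop_config("n_noise_genes must be non-negative")
  if (p$censor_frac < 0 || p$censor_frac >= 1)
    stop_config("censor_frac must be in [0, 1)")
  structure(p, class = "cohort_params")
}

# administrative censoring horizon: solve E[censored] = target for C ~ U(0, b)
censor_horizon <- function(rates, target) {
  pc <- function(b) mean((1 - exp(-rates * b)) / (rates * b)) - target
  stats::uniroot(pc, lower = 1e-6, upper = 1e9, tol = 1e-10)$root
}

#' Generate a synthetic expression and survival cohort
#'
#' @param params A [cohort_params()] object.
#' @return List with elements `matrix` (genes x samples, linear normalized
#'   scale), `labels` (logical, TRUE = pauperized), and `survival`
#'   (`data.frame` with columns `sample`, `time`, `event`).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  with_seed(p$seed, {
    n <- as.integer(p$n_samples)
    genes <- c(p$signature_genes,
               if (p$n_noise_genes > 0) sprintf("NOISE%03d", seq_len(p$n_noise_genes)))
    g <- length(genes)
    samples <- sprintf("S%03d", seq_len(n))
    n_paup <- max(1L, round(p$frac_pauperized * n))
    labels <- c(rep(TRUE, n_paup), rep(FALSE, n - n_paup))

    mu <- stats::runif(g, 4, 10)
    log2x <- matrix(stats::rnorm(g * n, mean = mu, sd = 1), g, n)
    sig <- genes %in% p$signature_genes
    log2x[sig, labels] <- log2x[sig, labels] + p$effect_log2
    mat <- 2^log2x
    dimnames(mat) <- list(genes, samples)

    rate <- p$baseline_hazard * ifelse(labels, p$true_hr, 1)
    tt <- stats::rexp(n, rate)
    if (p$censor_frac > 0) {
      b <- censor_horizon(rate, p$censor_frac)
      cens <- stats::runif(n, 0, b)
      surv <- data.frame(sample = samples, time = pmin(tt, cens),
                         event = as.integer(tt <= cens))
    } else {
      surv <- data.frame(sample = samples, time = tt, event = 1L)
    }
    list(matrix = mat, labels = labels, survival = surv)
  })
}
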