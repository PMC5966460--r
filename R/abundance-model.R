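#' Bayesian binomial logistic-normal paired model for one taxon
#'
#' Models a taxon's paired treatment/control read counts with a binomial
#' likelihood, a log10-normal measurement layer whose per-observation
#' standard deviations come from the positive-control-calibrated
#' measurement-error model, and a paired log-ratio hierarchy:
#' \deqn{yT_i ~ Bin(nReadsT_i, pT_i), \quad yC_i ~ Bin(nReadsC_i, pC_i)}
#' \deqn{log10(pT_i) ~ N(log10(tpT_i), sigmaT_i), \quad
#'       log10(pC_i) ~ N(log10(tpC_i), sigmaC_i)}
#' \deqn{Delta_i = log10(tpT_i / tpC_i) ~ N(effect, sd_delta)}
#' The posterior mean of `effect` — the mean of log10 ratios of true
#' relative abundances — is the reported effect size (0.301 reads as a
#' ~2-fold change). Priors: N(0, 1) on `effect`, half-N(0, 1) on
#' `sd_delta`, and logit-scale N(logit(pooled observed proportion), 2) on
#' the true control proportions. `sigmaT_i`/`sigmaC_i` are evaluated from
#' the error model at the taxon's median observed log10 relative abundance
#' within the respective arm (`sigma_per = "arm"`, the default) or per
#' observation.
#'
#' @param data Data frame with one row per subject pair and integer columns
#'   `yT`, `nT`, `yC`, `nC` (taxon count and total reads, treatment and
#'   control).
#' @param error_model A [fit_measurement_error_model()] object.
#' @param settings An [mcmc_settings()].
#' @param seed Integer seed.
#' @param engine `"jags"` (default) or `"metropolis"`.
#' @param sigma_per `"arm"` or `"observation"`.
#' @param psrf_warn Convergence warning threshold on the effect's R-hat.
#' @return Object of class `abundance_fit` (with `tidy()`, `glance()`), or
#'   `NULL` with a warning when the taxon has zero counts throughout one
#'   arm (the model cannot locate that arm's abundance).
#' @examples
#' pc <- gen_positive_controls(study_config(n_taxa = 30, seed = 1))
#' mem <- fit_measurement_error_model(pc)
#' d <- tibble::tibble(yT = c(60, 52, 71, 48, 66, 58), nT = 50000,
#'                     yC = c(30, 25, 31, 28, 24, 33), nC = 50000)
#' fit <- fit_abundance_model(d, mem, fast_mcmc_settings(), seed = 1)
#' glance(fit)
#' @export
fit_abundance_model <- function(data, error_model,
                                settings = mcmc_settings(), seed = 1L,
                                engine = c("jags", "metropolis"),
                                sigma_per = c("arm", "observation"),
                                psrf_warn = 1.1) {
  engine <- match.arg(engine)
  sigma_per <- match.arg(sigma_per)
  stopifnot(inherits(error_model, "measurement_error_model"))
  need <- c("yT", "nT", "yC", "nC")
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` must have columns %s", toString(need)))
  }
  yT <- as.integer(data$yT); nT <- as.integer(data$nT)
  yC <- as.integer(data$yC); nC <- as.integer(data$nC)
  if (any(yT > nT) || any(yC > nC)) abort("counts exceed totals")
  n <- length(yT)
  if (n < 3) abort("need at least 3 pairs")
  if (all(yT == 0) || all(yC == 0)) {
    warn("taxon has zero counts in every sample of one arm; skipping")
    return(NULL)
  }

  obs_lt <- log10(pmax(yT, 0.5) / nT)
  obs_lc <- log10(pmax(yC, 0.5) / nC)
  sigmaT <- if (sigma_per == "arm") {
    rep(predict(error_model, median(obs_lt[yT > 0])), n)
  } else {
    predict(error_model, obs_lt)
  }
  sigmaC <- if (sigma_per == "arm") {
    rep(predict(error_model, median(obs_lc[yC > 0])), n)
  } else {
    predict(error_model, obs_lc)
  }
  eta0 <- qlogis((sum(yT) + sum(yC)) / (sum(nT) + sum(nC)))

  spec <- abundance_model_spec(yT, nT, yC, nC, sigmaT, sigmaC, eta0, engine)
  chains <- sample_posterior(spec, settings, seed)
  summ <- summarize_chains(chains)
  eff <- filter(summ, .data$term == "effect")
  converged <- is.finite(eff$psrf) && eff$psrf <= psrf_warn
  if (!converged) {
    warn(sprintf("abundance model did not converge: PSRF(effect) = %.3f",
                 eff$psrf))
  }
  p_value <- posterior_tail_p(as.vector(param_matrix(chains, "effect")))

  structure(list(
    summary = summ,
    effect = eff,
    p_value = p_value,
    converged = converged,
    n_pairs = n,
    sigmaT = sigmaT,
    sigmaC = sigmaC,
    chains = chains,
    settings = settings,
    engine = engine,
    data = tibble(yT = yT, nT = nT, yC = yC, nC = nC)
  ), class = "abundance_fit")
}

abundance_model_spec <- function(yT, nT, yC, nC, sigmaT, sigmaC, eta0, engine) {
  n <- length(yT)
  if (engine == "jags") {
    code <- "
      model {
        for (i in 1:N) {
          yT[i] ~ dbin(pT[i], nT[i])
          yC[i] ~ dbin(pC[i], nC[i])
          pT[i] <- pow(10, lpT[i])
          pC[i] <- pow(10, lpC[i])
          lpT[i] ~ dnorm(ltpT[i], precT[i]) T(, -0.0001)
          lpC[i] ~ dnorm(ltpC[i], precC[i]) T(, -0.0001)
          ltpT[i] <- ltpC[i] + delta[i]
          ltpC[i] <- log(tpC[i]) / 2.302585092994046
          logit(tpC[i]) <- eta[i]
          eta[i] ~ dnorm(eta0, 0.25)
          delta[i] ~ dnorm(effect, prec_delta)
        }
        effect ~ dnorm(0, 1)
        sd_delta ~ dnorm(0, 1) T(0.001,)
        prec_delta <- pow(sd_delta, -2)
      }"
    lt_init <- pmin(log10(pmax(yT, 0.5) / nT), -0.001)
    lc_init <- pmin(log10(pmax(yC, 0.5) / nC), -0.001)
    jags_spec(
      code = code,
      data = list(yT = yT, nT = nT, yC = yC, nC = nC, N = n,
                  precT = sigmaT^-2, precC = sigmaC^-2, eta0 = eta0),
      monitor = c("effect", "sd_delta", "delta"),
      inits = function(chain) {
        list(effect = 0, sd_delta = 0.2,
             eta = qlogis(pmin(pmax(10^lc_init, 1e-8), 0.5)),
             delta = lt_init - lc_init, lpT = lt_init, lpC = lc_init)
      }
    )
  } else {
    lt_init <- pmin(log10(pmax(yT, 0.5) / nT), -0.001)
    lc_init <- pmin(log10(pmax(yC, 0.5) / nC), -0.001)
    ln10 <- log(10)
    init <- c(
      effect = 0, log_sd_delta = log(0.2),
      setNames(qlogis(pmin(pmax(10^lc_init, 1e-8), 0.5)),
               paste0("eta", seq_len(n))),
      setNames(lt_init - lc_init, paste0("delta", seq_len(n))),
      setNames(lt_init, paste0("lpT", seq_len(n))),
      setNames(lc_init, paste0("lpC", seq_len(n)))
    )
    log_density_spec(
      log_density = function(theta) {
        effect <- theta[1]
        sd_delta <- exp(theta[2])
        eta <- theta[2 + seq_len(n)]
        delta <- theta[2 + n + seq_len(n)]
        lpT <- theta[2 + 2 * n + seq_len(n)]
        lpC <- theta[2 + 3 * n + seq_len(n)]
        if (any(lpT > -1e-4) || any(lpC > -1e-4)) return(-Inf)
        ltpC <- log(plogis(eta)) / ln10
        ltpT <- ltpC + delta
        sum(dbinom(yT, nT, 10^lpT, log = TRUE)) +
          sum(dbinom(yC, nC, 10^lpC, log = TRUE)) +
          sum(dnorm(lpT, ltpT, sigmaT, log = TRUE)) +
          sum(dnorm(lpC, ltpC, sigmaC, log = TRUE)) +
          sum(dnorm(delta, effect, sd_delta, log = TRUE)) +
          dnorm(effect, 0, 1, log = TRUE) +
          half_normal_lp(sd_delta, 1) + theta[2] +
          sum(dnorm(eta, eta0, 2, log = TRUE))
      },
      init = init, step = 0.05, init_jitter = 0.02
    )
  }
}

#' @rdname fit_abundance_model
#' @param x An `abundance_fit`.
#' @param ... Unused.
#' @export
tidy.abundance_fit <- function(x, ...) x$summary

#' @rdname fit_abundance_model
#' @export
glance.abundance_fit <- function(x, ...) {
  tibble(
    estimate = x$effect$estimate,
    conf.low = x$effect$conf.low,
    conf.high = x$effect$conf.high,
    p_value = x$p_value,
    psrf = x$effect$psrf,
    converged = x$converged,
    n_pairs = x$n_pairs
  )
}

#' @export
print.abundance_fit <- function(x, ...) {
  cat(sprintf(
    "<abundance_fit (binomial logistic-normal, %s): effect = %.3f [%.3f, %.3f], p = %.3g, PSRF = %.3f%s>\n",
    x$engine, x$effect$estimate, x$effect$conf.low, x$effect$conf.high,
    x$p_value, x$effect$psrf, if (x$converged) "" else ", NOT CONVERGED"))
  invisible(x)
}
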