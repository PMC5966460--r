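#' Model specifications for posterior sampling
#'
#' [sample_posterior()] accepts two kinds of model specification behind one
#' interface. `log_density_spec()` wraps an arbitrary (unnormalized)
#' log-posterior function and is sampled with the package's adaptive
#' componentwise random-walk Metropolis kernel. `jags_spec()` wraps a BUGS
#' model definition and is sampled through JAGS; the two bundled microbiome
#' models use this route.
#'
#' @param log_density Function mapping a parameter vector to a single finite
#'   log-density value (up to a constant).
#' @param init Named numeric vector of initial values; names become the
#'   parameter names of the chains.
#' @param step Initial random-walk step size (adapted during warm-up).
#' @param init_jitter Standard deviation of the Gaussian jitter applied to
#'   `init` to overdisperse chain starting points (0 starts all chains at
#'   `init`).
#' @return An object of class `log_density_spec` or `jags_spec`.
#' @examples
#' spec <- log_density_spec(function(x) -x^2 / 2, init = c(x = 0))
#' @export
log_density_spec <- function(log_density, init, step = 0.5, init_jitter = 0.5) {
  if (!is.function(log_density)) abort("`log_density` must be a function")
  if (is.null(names(init)) || any(names(init) == "")) {
    abort("`init` must be a fully named numeric vector")
  }
  structure(list(log_density = log_density, init = init, step = step,
                 init_jitter = init_jitter),
            class = "log_density_spec")
}

#' @rdname log_density_spec
#' @param code BUGS model code as a single string.
#' @param data Named list of data passed to JAGS.
#' @param monitor Character vector of parameters to record.
#' @param inits Optional `function(chain)` returning a named list of initial
#'   values for that chain.
#' @export
jags_spec <- function(code, data, monitor, inits = NULL) {
  structure(list(code = code, data = data, monitor = monitor, inits = inits),
            class = "jags_spec")
}

#' Draw posterior samples
#'
#' Runs `settings$n_chains` independent chains of `settings$n_iter`
#' iterations, discards the first half of each chain as warm-up (during
#' which the random-walk kernel adapts, or JAGS runs its adaptive phase),
#' and keeps every `settings$thin`-th remaining iteration. Fully
#' reproducible for a fixed `seed`.
#'
#' @param model A [log_density_spec()] or [jags_spec()].
#' @param settings An [mcmc_settings()]; the default mirrors the study
#'   protocol (3 chains x 10,000 iterations, thinning 10).
#' @param seed Integer seed.
#' @return A `chain_set`: 3-d array of draws indexed by
#'   (iteration, chain, parameter) with attributes, supporting [psrf()],
#'   [summarize_chains()], `tidy()` and `as.matrix()`.
#' @examples
#' spec <- log_density_spec(function(x) -x^2 / 2, init = c(x = 0))
#' ch <- sample_posterior(spec, fast_mcmc_settings(), seed = 1)
#' summarize_chains(ch)
#' @export
sample_posterior <- function(model, settings = mcmc_settings(), seed = 1L) {
  stopifnot(inherits(settings, "mcmc_settings"))
  seed <- as.integer(seed)
  if (inherits(model, "log_density_spec")) {
    sample_metropolis(model, settings, seed)
  } else if (inherits(model, "jags_spec")) {
    sample_jags(model, settings, seed)
  } else {
    abort("`model` must be a log_density_spec or jags_spec")
  }
}

sample_metropolis <- function(spec, settings, seed) {
  npar <- length(spec$init)
  pnames <- names(spec$init)
  warm <- settings$warmup
  n_keep <- (settings$n_iter - warm) %/% settings$thin
  draws <- array(NA_real_, dim = c(n_keep, settings$n_chains, npar),
                 dimnames = list(NULL, NULL, pnames))

  for (ch in seq_len(settings$n_chains)) {
    set.seed(seed + 7919L * ch)
    theta <- spec$init + rnorm(npar, 0, spec$init_jitter)
    lp <- suppressWarnings(spec$log_density(theta))
    if (!is.finite(lp)) {
      theta <- spec$init
      lp <- suppressWarnings(spec$log_density(theta))
    }
    if (!is.finite(lp)) {
      bad <- pnames[!is.finite(spec$init)]
      detail <- if (length(bad)) paste0(" (non-finite initial value for: ",
                                        toString(bad), ")") else ""
      abort(sprintf(
        "log-density is not finite at the initial point [%s]%s",
        paste(pnames, "=", signif(spec$init, 4), collapse = ", "), detail))
    }
    ls <- rep(log(spec$step), npar)
    acc <- numeric(npar)
    k <- 0L
    for (it in seq_len(settings$n_iter)) {
      for (j in seq_len(npar)) {
        prop <- theta
        prop[j] <- theta[j] + exp(ls[j]) * rnorm(1)
        lpp <- suppressWarnings(spec$log_density(prop))
        if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
          theta <- prop
          lp <- lpp
          acc[j] <- acc[j] + 1
        }
      }
      if (it <= warm && it %% 50 == 0) {
        # adapt each coordinate toward ~44% acceptance, then freeze
        rate <- acc / 50
        ls <- ls + ifelse(rate > 0.44, 1, -1) * min(0.25, 2 / sqrt(it / 50))
        ls <- pmin(pmax(ls, -20), 20)
        acc[] <- 0
      }
      if (it > warm && (it - warm) %% settings$thin == 0) {
        k <- k + 1L
        draws[k, ch, ] <- theta
      }
    }
  }
  chain_set(draws, settings)
}

sample_jags <- function(spec, settings, seed) {
  inits <- lapply(seq_len(settings$n_chains), function(ch) {
    ini <- if (!is.null(spec$inits)) spec$inits(ch) else list()
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- (abs(seed) %% 1000000L) * 1000L + ch
    ini
  })
  # warm-up budget split between JAGS's adaptive phase and a plain burn-in,
  # so sampling never starts mid-adaptation
  n_adapt <- max(100L, settings$warmup %/% 2L)
  model <- suppressWarnings(rjags::jags.model(
    textConnection(spec$code), data = spec$data,
    n.chains = settings$n_chains, n.adapt = n_adapt,
    inits = inits, quiet = TRUE
  ))
  stats::update(model, n.iter = settings$warmup - n_adapt,
                progress.bar = "none")
  draws_coda <- rjags::coda.samples(
    model, variable.names = spec$monitor,
    n.iter = settings$n_iter - settings$warmup, thin = settings$thin,
    progress.bar = "none"
  )
  pnames <- colnames(draws_coda[[1]])
  n_keep <- nrow(draws_coda[[1]])
  draws <- array(NA_real_, dim = c(n_keep, settings$n_chains, length(pnames)),
                 dimnames = list(NULL, NULL, pnames))
  for (ch in seq_along(draws_coda)) draws[, ch, ] <- as.matrix(draws_coda[[ch]])
  chain_set(draws, settings)
}

#' Chain-set container
#'
#' @param draws 3-d numeric array indexed by (iteration, chain, parameter),
#'   with parameter names in the third dimnames slot.
#' @param settings The [mcmc_settings()] used (optional, stored for audit).
#' @return An object of class `chain_set`.
#' @export
chain_set <- function(draws, settings = NULL) {
  if (length(dim(draws)) != 3) {
    abort("`draws` must be a 3-d array (iteration, chain, parameter)")
  }
  structure(draws, class = "chain_set", settings = settings)
}

#' @export
print.chain_set <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<chain_set: %d retained iterations x %d chains x %d parameters>\n",
              d[1], d[2], d[3]))
  print(summarize_chains(x), ...)
  invisible(x)
}

#' @export
as.matrix.chain_set <- function(x, ...) {
  d <- dim(x)
  out <- matrix(aperm(unclass(x), c(1, 2, 3)), nrow = d[1] * d[2], ncol = d[3])
  colnames(out) <- dimnames(x)[[3]]
  out
}

param_matrix <- function(chains, param) {
  stopifnot(inherits(chains, "chain_set"))
  pnames <- dimnames(chains)[[3]]
  if (!param %in% pnames) abort(sprintf("no parameter called '%s'", param))
  unclass(chains)[, , which(pnames == param), drop = TRUE]
}

#' Potential scale reduction factor (Gelman-Rubin R-hat)
#'
#' `sqrt(((n - 1) / n * W + B / n) / W)` where `W` is the mean within-chain
#' variance and `B` the between-chain variance of length-`n` chains. Values
#' near 1 indicate that the chains are sampling the same distribution; the
#' package's model fits warn above 1.1.
#'
#' @param chains A `chain_set`, or a numeric matrix with one column per
#'   chain.
#' @return Named numeric vector of R-hat values (one per parameter).
#' @examples
#' set.seed(1)
#' psrf(cbind(rnorm(500), rnorm(500)))
#' @export
psrf <- function(chains) {
  if (inherits(chains, "chain_set")) {
    pnames <- dimnames(chains)[[3]]
    out <- vapply(pnames,
                  function(p) psrf_matrix(param_matrix(chains, p)),
                  numeric(1))
    return(out)
  }
  if (is.matrix(chains)) return(c(psrf = psrf_matrix(chains)))
  abort("`chains` must be a chain_set or a matrix (iterations x chains)")
}

psrf_matrix <- function(mat) {
  m <- ncol(mat)
  n <- nrow(mat)
  if (m < 2) abort("PSRF needs at least 2 chains")
  if (n < 4) abort("PSRF needs chains of length >= 4")
  w <- mean(apply(mat, 2, var))
  b <- n * var(colMeans(mat))
  if (w == 0) return(if (b == 0) 1 else Inf)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Posterior summary of a chain set
#'
#' Posterior mean, central 95% credible interval, split-chain-free R-hat and
#' a crude effective sample size (via [coda::effectiveSize()]) for every
#' recorded parameter.
#'
#' @param chains A `chain_set`.
#' @param conf_level Credible-interval mass. Default 0.95.
#' @return Tibble with columns `term`, `estimate`, `conf.low`, `conf.high`,
#'   `psrf`, `n_eff`.
#' @export
summarize_chains <- function(chains, conf_level = 0.95) {
  stopifnot(inherits(chains, "chain_set"))
  pnames <- dimnames(chains)[[3]]
  alpha <- (1 - conf_level) / 2
  rhat <- psrf(chains)
  rows <- lapply(pnames, function(p) {
    mat <- param_matrix(chains, p)
    flat <- as.vector(mat)
    ne <- sum(vapply(seq_len(ncol(mat)),
                     function(ch) unname(coda::effectiveSize(mat[, ch])),
                     numeric(1)))
    tibble(
      term = p,
      estimate = mean(flat),
      conf.low = unname(quantile(flat, alpha, type = 7)),
      conf.high = unname(quantile(flat, 1 - alpha, type = 7)),
      psrf = unname(rhat[p]),
      n_eff = ne
    )
  })
  list_rbind(rows)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname summarize_chains
#' @param x A `chain_set`.
#' @param ... Passed on.
#' @export
tidy.chain_set <- function(x, ...) summarize_chains(x, ...)

#' Posterior tail p-value
#'
#' Two-sided tail probability `2 * min(P(draw > 0), P(draw < 0))` of an
#' effect's posterior. The empirical tail fraction is used whenever the
#' minority tail contains at least one draw; when no draw crosses zero the
#' empirical estimate (resolution `1 / n_draws`) under-states the evidence,
#' so the tail is refined by a normal approximation to the posterior,
#' `2 * pnorm(-|mean| / sd)`, capped at the empirical resolution and
#' floored at 1e-16. This lets strong effects reach the very small
#' q-values a false-discovery-rate threshold of 1% requires when testing
#' many taxa, while weak effects keep their exact empirical tails.
#'
#' @param draws Numeric vector of posterior draws of an effect.
#' @return A single p-value in `(0, 1]`.
#' @export
posterior_tail_p <- function(draws) {
  if (length(draws) == 0) abort("empty draws")
  p_emp <- 2 * min(mean(draws > 0), mean(draws < 0))
  if (p_emp > 0) return(min(p_emp, 1))
  s <- sd(draws)
  if (!is.finite(s) || s == 0) return(1e-16)
  p_norm <- 2 * stats::pnorm(-abs(mean(draws)) / s)
  max(min(1 / length(draws), p_norm), 1e-16)
}
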