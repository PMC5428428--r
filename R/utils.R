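# Internal helpers shared across modules.

#' @importFrom rlang .data abort warn inform
#' @importFrom stats lm glm coef vcov pchisq pnorm qnorm quantile rnorm rbinom
#'   runif binomial predict sd var complete.cases setNames aov kruskal.test
#'   chisq.test as.formula rbeta
#' @importFrom utils head
NULL

# Deterministic substream seeds: one master seed, fixed per-component offsets,
# so adding a downstream draw never perturbs upstream ones. Kept below 2^31.
substream_seed <- function(seed, component) {
  offsets <- c(
    participants = 101L, diet = 211L, recalls = 307L, genotypes = 401L,
    outcomes = 503L, ffq = 601L, anthropometry = 701L
  )
  if (!component %in% names(offsets)) {
    abort(paste0("unknown RNG substream: ", component))
  }
  # double arithmetic avoids integer overflow for large master seeds
  as.integer((as.numeric(seed) * 997 + offsets[[component]]) %% 2147483647)
}

# Truncated normal via inverse-CDF; vectorised over all arguments.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wald p-value for a single coefficient of an lm/glm fit.
wald_p <- function(fit, term) {
  est <- coef(fit)[[term]]
  se <- sqrt(diag(vcov(fit)))[[term]]
  # a numerically perfect fit (zero residual variance) carries no evidence
  if (abs(est) < 1e-8 && se < 1e-8) {
    return(1)
  }
  z <- est / se
  if (inherits(fit, "glm")) 2 * pnorm(-abs(z)) else {
    2 * stats::pt(-abs(z), df = fit$df.residual)
  }
}
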