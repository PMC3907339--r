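#' Derive a reproducible sub-stream seed for a named pipeline stage
#'
#' A single master seed fans out to independent, named sub-streams so that
#' each simulation stage (frequencies, genotypes, phenotypes, call sets, ...)
#' is individually reproducible regardless of how many draws earlier stages
#' consumed.
#'
#' @param seed Master integer seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 2654435 %% 2147483647) %% 2147483647)
}

with_stage_seed <- function(seed, stage, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(substream_seed(seed, stage))
  }
  force(code)
}

# OLS of y on cbind(x, covariates, intercept); returns beta/se/p/df for x.
# Complete-case over the supplied rows; caller subsets beforehand.
ols_term_test <- function(y, x, covariates = NULL) {
  X <- cbind(x = x, Intercept = 1, covariates)
  fit <- lm.fit(X, y)
  df <- length(y) - fit$rank
  if (df <= 0 || is.na(fit$coefficients[1L])) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, df = df,
                estimable = FALSE))
  }
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  R <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  # unscaled covariance via R^-1 R^-T, mapped back to pivoted order
  Rinv <- backsolve(R, diag(fit$rank))
  xpxinv <- tcrossprod(Rinv)
  pivot <- fit$qr$pivot[seq_len(fit$rank)]
  pos <- match(1L, pivot)
  if (is.na(pos)) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, df = df,
                estimable = FALSE))
  }
  beta <- unname(fit$coefficients[1L])
  se <- sqrt(sigma2 * xpxinv[pos, pos])
  tval <- beta / se
  list(beta = beta, se = se,
       p = 2 * pt(abs(tval), df, lower.tail = FALSE), df = df,
       estimable = TRUE)
}

# residual-maker: y - X (X'X)^-1 X' y for X with intercept prepended
project_out <- function(y, X) {
  n_obs <- if (is.matrix(y)) nrow(y) else length(y)
  X <- cbind(rep(1, n_obs), X)
  qr_x <- qr(X)
  if (is.matrix(y)) {
    y - qr.fitted(qr_x, y)
  } else {
    as.numeric(y - qr.fitted(qr_x, y))
  }
}

`%||%` <- rlang::`%||%`
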