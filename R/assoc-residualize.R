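#' Residualize a trait on the standard covariate set
#'
#' Regresses the trait (log-transformed for the right-skewed traits TG, FG
#' and FI under the default `"auto"` rule) on age, age squared, sex,
#' oral-contraceptive use, pregnancy status and cohort indicator in the
#' combined sample, returning the residuals used by every downstream
#' association test. T2D cases are excluded from the glycemic traits FG and
#' FI. The `"inverse_normal"` option additionally maps the residuals to
#' standard-normal quantiles by rank (ties broken by average rank).
#'
#' @param phenotypes Phenotype tibble (columns `id`, `cohort`,
#'   `case_status`, `age`, `sex`, `oc_use`, `pregnant` and the trait).
#' @param trait Trait column name.
#' @param transformation `"auto"` (log for TG/FG/FI, none otherwise),
#'   `"log"`, `"none"`, or `"inverse_normal"` (applied to the residuals of
#'   the auto-transformed regression).
#' @param log_traits Traits receiving the log transform under `"auto"`.
#' @param exclude_cases_for Traits from which T2D cases are excluded.
#' @return Tibble with `id` and `residual`; attributes `trait`,
#'   `transformation`, `covariates` and `excluded` (tibble of dropped
#'   individuals with reasons).
#' @export
residualize <- function(phenotypes, trait,
                        transformation = c("auto", "log", "none",
                                           "inverse_normal"),
                        log_traits = c("TG", "FG", "FI"),
                        exclude_cases_for = c("FG", "FI")) {
  transformation <- match.arg(transformation)
  covars <- c("age", "sex", "oc_use", "pregnant", "cohort")
  need <- c("id", covars, trait)
  miss <- setdiff(need, names(phenotypes))
  if (length(miss)) {
    abort(paste("phenotype table lacks columns:", paste(miss, collapse = ", ")))
  }
  dat <- phenotypes
  excluded <- tibble::tibble(id = character(), reason = character())
  if (trait %in% exclude_cases_for && "case_status" %in% names(dat)) {
    drop <- dat$case_status == 1
    excluded <- dplyr::bind_rows(excluded, tibble::tibble(
      id = dat$id[drop], reason = "T2D case excluded for glycemic trait"))
    dat <- dat[!drop, ]
  }
  y <- dat[[trait]]
  use_log <- transformation == "log" ||
    (transformation %in% c("auto", "inverse_normal") && trait %in% log_traits)
  if (use_log) {
    bad <- which(y <= 0)
    if (length(bad)) {
      abort(paste0("log transform of ", trait, " impossible for ",
                   length(bad), " non-positive values (ids: ",
                   paste(head(dat$id[bad], 5), collapse = ", "), ")"))
    }
    y <- log(y)
  }
  X <- cbind(age = dat$age, age2 = dat$age^2, sex = dat$sex,
             oc_use = dat$oc_use, pregnant = dat$pregnant,
             cohortB = as.numeric(dat$cohort == "B"))
  keep <- complete.cases(X) & !is.na(y)
  if (any(!keep)) {
    excluded <- dplyr::bind_rows(excluded, tibble::tibble(
      id = dat$id[!keep], reason = "missing trait or covariate"))
  }
  fit <- lm.fit(cbind(1, X[keep, , drop = FALSE]), y[keep])
  res <- fit$residuals
  if (transformation == "inverse_normal") {
    res <- qnorm((rank(res, ties.method = "average") - 0.5) / length(res))
  }
  out <- tibble::tibble(id = dat$id[keep], residual = unname(res))
  attr(out, "trait") <- trait
  attr(out, "transformation") <- if (transformation == "inverse_normal") {
    "inverse_normal"
  } else if (use_log) "log" else "none"
  attr(out, "covariates") <- colnames(X)
  attr(out, "excluded") <- excluded
  out
}
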