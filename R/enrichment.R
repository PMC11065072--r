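#' @importFrom stats glm.fit binomial pnorm qnorm setNames
NULL

# Build the enrichment design matrix. Category enters one-hot with the
# largest category as the reference level; n_targets enters untransformed
# (log1p optionally). Returns list(x, dropped_category).
.enrich_design <- function(pairs, term, adjust, log_targets = FALSE) {
  n <- nrow(pairs)
  x <- cbind("(Intercept)" = rep(1, n), as.numeric(pairs[[term]]))
  colnames(x)[2] <- term
  dropped_cat <- FALSE
  if ("category" %in% adjust) {
    cats <- table(pairs$category)
    if (length(cats) < 2) {
      dropped_cat <- TRUE
    } else {
      ref <- names(cats)[which.max(cats)]
      for (lev in setdiff(names(cats), ref)) {
        x <- cbind(x, as.numeric(pairs$category == lev))
        colnames(x)[ncol(x)] <- paste0("category", lev)
      }
    }
  }
  if ("n_targets" %in% adjust) {
    v <- if (log_targets) log1p(pairs$n_targets) else as.numeric(pairs$n_targets)
    x <- cbind(x, n_targets = v)
  }
  list(x = x, dropped_category = dropped_cat)
}

# Minimal weighted logistic fit with Wald inference, shared by the public
# fitter and the permutation fast path.
.logit_fit <- function(y, x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  separated <- FALSE
  fit <- withCallingHandlers(
    glm.fit(x, y, weights = w, family = binomial()),
    warning = function(cw) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(cw)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  p1 <- seq_len(fit$rank)
  piv <- fit$qr$pivot[p1]
  covm <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  se <- rep(NA_real_, ncol(x))
  se[piv] <- sqrt(diag(covm))
  est <- fit$coefficients
  if (any(!is.finite(est[piv]))) separated <- TRUE
  list(estimate = est, stderr = se, separated = separated,
       converged = fit$converged, aliased = is.na(est))
}

#' Fit the candidate-drug enrichment model
#'
#' Logistic regression of the clinical outcome flag on the candidate flag,
#' optionally adjusted for the complex disease category (one-hot, largest
#' category as reference) and the drug's number of known gene targets
#' (untransformed integer by default). The reported odds ratio is the
#' exponentiated candidate coefficient with a Wald 95% confidence interval
#' and two-sided Wald p-value.
#'
#' Balanced weights (`weights = "balanced"`) give each outcome class equal
#' total weight, `w = N / (2 * N_class)`, the common device for checking
#' that class imbalance does not drive the coefficient.
#'
#' Perfect separation is reported, not regularized away: the result carries
#' `separated = TRUE` and an infinite odds-ratio sentinel, with a warning.
#'
#' @param pairs a `pair_table` (see [build_pair_table()]), or any data.frame
#'   with the needed columns.
#' @param adjust character subset of `c("category", "n_targets")`.
#' @param weights `"none"` or `"balanced"`.
#' @param term name of the 0/1 exposure column to report the odds ratio for
#'   (default `"is_candidate"`).
#' @param log_targets use `log1p(n_targets)` instead of the raw count.
#' @param conf_level confidence level for the Wald interval.
#' @return object of class `enrichment_result`: list with `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `coefficients` (data.frame of term,
#'   estimate, stderr), `n_rows`, `n_outcome_pos`, `separated`.
#' @examples
#' pt <- data.frame(is_candidate = rep(c(1, 0), c(100, 100)),
#'                  outcome = rep(c(1, 0, 1, 0), c(30, 70, 10, 90)))
#' fit_enrichment(pt, adjust = character())  # OR = (30*90)/(70*10)
#' @export
fit_enrichment <- function(pairs, adjust = c("category", "n_targets"),
                           weights = c("none", "balanced"),
                           term = "is_candidate", log_targets = FALSE,
                           conf_level = 0.95) {
  weights <- match.arg(weights)
  if (!nrow(pairs)) stop("empty pair table", call. = FALSE)
  y <- as.numeric(pairs$outcome)
  if (length(unique(y)) < 2)
    stop("outcome has a single class; need both positive and negative rows",
         call. = FALSE)
  if (length(unique(pairs[[term]])) < 2)
    stop(sprintf("'%s' has a single level; need both exposed and unexposed rows",
                 term), call. = FALSE)
  des <- .enrich_design(pairs, term, adjust, log_targets)
  w <- NULL
  if (weights == "balanced") {
    n1 <- sum(y == 1); n0 <- sum(y == 0); n <- length(y)
    w <- ifelse(y == 1, n / (2 * n1), n / (2 * n0))
  }
  ft <- .logit_fit(y, des$x, w)
  est <- ft$estimate[term]
  se <- ft$stderr[match(term, colnames(des$x))]
  if (is.na(est) || is.na(se))
    stop("candidate term is aliased in the design; cannot estimate odds ratio",
         call. = FALSE)
  z <- qnorm(1 - (1 - conf_level) / 2)
  separated <- ft$separated || abs(est) > 15
  if (separated) {
    warning("possible perfect separation; odds ratio reported as a sentinel",
            call. = FALSE)
    or <- if (est > 0) Inf else 0
    ci <- c(NA_real_, NA_real_)
    p <- NA_real_
  } else {
    or <- exp(est)
    ci <- exp(est + c(-1, 1) * z * se)
    p <- 2 * pnorm(-abs(est / se))
  }
  structure(list(
    odds_ratio = unname(or), ci_low = unname(ci[1]), ci_high = unname(ci[2]),
    p_value = unname(p),
    coefficients = data.frame(term = colnames(des$x),
                              estimate = unname(ft$estimate),
                              stderr = unname(ft$stderr)),
    n_rows = length(y), n_outcome_pos = sum(y == 1),
    separated = separated, weights = weights,
    dropped_category = des$dropped_category, term = term
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment of outcome on '%s' (%d rows, %d positive)\n",
              x$term, x$n_rows, x$n_outcome_pos))
  if (x$separated) cat("  ** possible perfect separation **\n")
  cat(sprintf("  odds ratio %.4g  [%.4g, %.4g]  p = %.3g\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Enrichment per complex disease category
#'
#' Refits the enrichment model within each disease category (the category
#' covariate is constant within a stratum and is dropped). Categories where
#' the outcome or the candidate flag has a single level are skipped with a
#' warning.
#'
#' @param pairs a `pair_table`.
#' @param adjust covariates for the within-stratum fits (category is removed
#'   automatically).
#' @param weights passed to [fit_enrichment()].
#' @return named list of `enrichment_result`, one per usable category.
#' @export
fit_by_category <- function(pairs, adjust = "n_targets",
                            weights = "none") {
  adjust <- setdiff(adjust, "category")
  out <- list()
  for (cat in sort(unique(pairs$category))) {
    sub <- pairs[pairs$category == cat, , drop = FALSE]
    if (!nrow(sub) || length(unique(sub$outcome)) < 2 ||
        length(unique(sub$is_candidate)) < 2) {
      warning(sprintf("category '%s' skipped: single outcome or candidate class",
                      cat), call. = FALSE)
      next
    }
    out[[cat]] <- fit_enrichment(sub, adjust = adjust, weights = weights)
  }
  out
}

#' Enrichment per drug development phase
#'
#' For each phase group, rebuilds the pair table with the `phase_k` outcome
#' (positive iff the pair's most advanced evidence is exactly that phase) and
#' refits the enrichment model, so a drug in trials at several phases counts
#' once, at its most advanced phase. `pooled_I_III` uses the
#' `investigated_only` outcome (any Phase I-III trial, not indicated).
#'
#' @param bundle a `comorbid_bundle`.
#' @param phases phase groups to fit (default the three trial phases plus
#'   indicated).
#' @param pooled also fit the pooled Phase I-III ("investigated only") model.
#' @param adjust,weights passed to [fit_enrichment()].
#' @param include_unknown passed to [build_pair_table()].
#' @return named list of `enrichment_result` (names are phase groups, plus
#'   `"pooled_I_III"` when `pooled = TRUE`).
#' @export
fit_by_phase <- function(bundle,
                         phases = c("PHASE_I", "PHASE_II", "PHASE_III",
                                    "INDICATED"),
                         pooled = TRUE, adjust = c("category", "n_targets"),
                         weights = "none", include_unknown = TRUE) {
  cands <- candidate_sets(bundle)
  out <- list()
  for (ph in phases) {
    pt <- build_pair_table(bundle, outcome_def = "phase_k", phase = ph,
                           include_unknown = include_unknown,
                           candidates = cands)
    if (length(unique(pt$outcome)) < 2) {
      warning(sprintf("phase '%s' skipped: no positive pairs", ph),
              call. = FALSE)
      next
    }
    out[[ph]] <- fit_enrichment(pt, adjust = adjust, weights = weights)
  }
  if (pooled) {
    pt <- build_pair_table(bundle, outcome_def = "investigated_only",
                           include_unknown = include_unknown,
                           candidates = cands)
    if (length(unique(pt$outcome)) >= 2)
      out[["pooled_I_III"]] <- fit_enrichment(pt, adjust = adjust,
                                              weights = weights)
  }
  out
}
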