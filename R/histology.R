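#' Speckle-count expression classification
#'
#' A cell is classified "high" for a speckle-quantified probe (e.g. GZMB)
#' when it contains at least `threshold` speckles.
#'
#' @param speckle_count Nonnegative integer speckle count(s).
#' @param threshold Minimum speckle count for the high class.
#' @return Logical vector.
#' @export
classify_speckle_high <- function(speckle_count, threshold = 5L) {
  stopifnot(all(speckle_count >= 0), threshold >= 0)
  speckle_count >= threshold
}

#' Poisson regression of probe-positive counts on cohort
#'
#' Fits `count ~ cohort` by maximum likelihood (IRLS via [stats::glm()]) with
#' MC as the reference level and, when `use_offset` is `TRUE`, `log(dapi_total)`
#' as an offset so coefficients are log rate ratios per DAPI-stained cell.
#' In the two-group case the fitted rate ratio equals the closed form
#' `(sum counts_B / sum offsets_B) / (sum counts_A / sum offsets_A)`.
#' RNAscope counts use the DAPI offset; IHC counts (already normalized per
#' field or per 100 enterocytes) default to no offset.
#'
#' @param records Data frame of image counts: `cohort`, `count`, a `probe`
#'   column when `probe` is given, and `dapi_total` when `use_offset`.
#' @param probe Optional probe name to subset `records` on.
#' @param use_offset Use `log(dapi_total)` as offset.
#' @param reference Reference cohort level.
#' @return A `count_fit`: the `glm` fit, coefficient table (`term, estimate,
#'   se, z, p, rate_ratio`), probe and flags.
#' @export
poisson_fit <- function(records, probe = NULL, use_offset = TRUE,
                        reference = "MC") {
  .require_cols(records, c("cohort", "count"), "count table")
  if (!is.null(probe)) {
    .require_cols(records, "probe", "count table")
    records <- records[records$probe == probe, , drop = FALSE]
    if (nrow(records) == 0L) stop(sprintf("no records for probe '%s'", probe),
                                  call. = FALSE)
  }
  if (length(unique(records$cohort)) < 2L) {
    stop("need at least 2 cohorts with at least 1 image each", call. = FALSE)
  }
  if (any(records$count < 0)) stop("negative counts", call. = FALSE)
  records$cohort <- .cohort_factor(records$cohort, reference)

  if (use_offset) {
    .require_cols(records, "dapi_total", "count table")
    if (any(records$dapi_total <= 0)) stop("dapi_total must be positive",
                                           call. = FALSE)
    fit <- glm(count ~ cohort + offset(log(dapi_total)),
               family = poisson(), data = records,
               control = list(epsilon = 1e-8, maxit = 50L))
  } else {
    fit <- glm(count ~ cohort, family = poisson(), data = records,
               control = list(epsilon = 1e-8, maxit = 50L))
  }
  if (!fit$converged) stop("Poisson IRLS did not converge in 50 iterations",
                           call. = FALSE)

  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), z = unname(z),
                      p = 2 * pnorm(-abs(unname(z))),
                      rate_ratio = exp(unname(est)),
                      stringsAsFactors = FALSE, row.names = NULL)
  boundary <- tapply(records$count, records$cohort, sum) == 0
  if (any(boundary)) {
    warning("cohort(s) with all-zero counts; coefficient at the boundary: ",
            paste(names(boundary)[boundary], collapse = ", "))
  }
  structure(list(fit = fit, coefficients = coefs, probe = probe,
                 reference = reference, use_offset = use_offset,
                 dispersion = NULL,
                 boundary_cohorts = names(boundary)[boundary]),
            class = "count_fit")
}

#' Quasi-Poisson dispersion adjustment of a Poisson fit
#'
#' Estimates the dispersion as Pearson chi-squared over residual degrees of
#' freedom, scales the standard errors by its square root, and recomputes
#' p-values from a t distribution on the residual df. A dispersion of 0
#' (all observations exactly at their fitted means) is flagged degenerate.
#'
#' @param fit A converged `count_fit` from [poisson_fit()].
#' @return The `count_fit` with `dispersion`, a `quasi` coefficient table
#'   (`se_quasi, t, p_quasi`) and a `degenerate` flag added.
#' @export
quasipoisson_adjust <- function(fit) {
  stopifnot(inherits(fit, "count_fit"))
  df <- df.residual(fit$fit)
  if (df <= 0) stop("residual degrees of freedom <= 0; cannot estimate dispersion",
                    call. = FALSE)
  dispersion <- sum(residuals(fit$fit, type = "pearson")^2) / df
  if (dispersion < 1e-12) dispersion <- 0  # IRLS round-off on a saturated fit
  coefs <- fit$coefficients
  coefs$se_quasi <- coefs$se * sqrt(dispersion)
  coefs$t <- ifelse(coefs$se_quasi > 0, coefs$estimate / coefs$se_quasi,
                    NA_real_)
  coefs$p_quasi <- 2 * pt(-abs(coefs$t), df = df)
  fit$coefficients <- coefs
  fit$dispersion <- dispersion
  fit$residual_df <- df
  fit$degenerate <- dispersion == 0
  if (fit$degenerate) {
    warning("dispersion is 0: all observations at their fitted means")
  }
  fit
}

# Contrast rows (non-intercept cohort terms) of a count_fit's coefficients.
.contrast_rows <- function(fit) {
  coefs <- fit$coefficients
  coefs <- coefs[coefs$term != "(Intercept)", , drop = FALSE]
  coefs$cohort <- sub("^cohort", "", coefs$term)
  coefs
}

#' Dual-comparison significance of cohort effects across probes
#'
#' Applies the study-level decision rules to a set of per-probe count fits:
#' \describe{
#'   \item{`ihc`}{p-values are BH-adjusted across stains within each
#'     comparison; a stain is significant only when the adjusted p-value is
#'     below `alpha` for BOTH comparisons (MC vs chronic diarrhea AND MC vs
#'     unaffected).}
#'   \item{`rnascope`}{a raw p-value cutoff of `alpha` per comparison, again
#'     requiring both comparisons; agreement between the Poisson and the
#'     quasi-Poisson p-values is reported per probe, and discordance (one
#'     regression significant, the other not) is flagged.}
#' }
#'
#' @param fits Named list (probe -> `count_fit`); pass fits through
#'   [quasipoisson_adjust()] first to populate the quasi-Poisson columns.
#' @param mode `"ihc"` or `"rnascope"`.
#' @param comparisons Cohorts contrasted against the reference; both must be
#'   present in every testable fit.
#' @param alpha Significance cutoff.
#' @return List with `contrasts` (probe x comparison table of rate ratios and
#'   p-values) and `probes` (per probe: significance flags and, in rnascope
#'   mode, the Poisson / quasi-Poisson discordance flag).
#' @export
cohort_significance <- function(fits, mode = c("ihc", "rnascope"),
                                comparisons = c("chronic_diarrhea",
                                                "unaffected"),
                                alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(length(fits) >= 1L, !is.null(names(fits)))
  has_quasi <- vapply(fits, function(f) "p_quasi" %in% names(f$coefficients),
                      TRUE)

  rows <- list()
  for (probe in names(fits)) {
    cr <- .contrast_rows(fits[[probe]])
    for (comp in comparisons) {
      r <- cr[cr$cohort == comp, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        probe = probe, comparison = comp,
        testable = nrow(r) == 1L,
        rate_ratio = if (nrow(r) == 1L) r$rate_ratio else NA_real_,
        p_poisson = if (nrow(r) == 1L) r$p else NA_real_,
        p_quasi = if (nrow(r) == 1L && "p_quasi" %in% names(r)) r$p_quasi
                  else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  contrasts <- do.call(rbind, rows)

  if (mode == "ihc") {
    contrasts$p_adj <- NA_real_
    for (comp in comparisons) {
      fam <- which(contrasts$comparison == comp & contrasts$testable)
      if (length(fam) > 0L) {
        contrasts$p_adj[fam] <- bh_adjust(contrasts$p_poisson[fam])
      }
    }
  }

  per_probe <- lapply(names(fits), function(probe) {
    sub <- contrasts[contrasts$probe == probe, , drop = FALSE]
    testable <- all(sub$testable) && nrow(sub) == length(comparisons)
    if (mode == "ihc") {
      sig <- testable && all(sub$p_adj < alpha)
      data.frame(probe = probe, testable = testable, significant = sig,
                 stringsAsFactors = FALSE)
    } else {
      sig_pois <- testable && all(sub$p_poisson < alpha)
      sig_quasi <- if (has_quasi[[probe]]) {
        testable && all(sub$p_quasi < alpha)
      } else {
        NA
      }
      data.frame(probe = probe, testable = testable,
                 significant_poisson = sig_pois,
                 significant_quasipoisson = sig_quasi,
                 significant = sig_pois && isTRUE(sig_quasi),
                 discordant = !is.na(sig_quasi) && xor(sig_pois, sig_quasi),
                 stringsAsFactors = FALSE)
    }
  })
  list(contrasts = contrasts, probes = do.call(rbind, per_probe),
       mode = mode, alpha = alpha)
}

#' @export
print.count_fit <- function(x, ...) {
  cat(sprintf("Poisson count fit%s (reference: %s%s)\n",
              if (!is.null(x$probe)) paste0(" for ", x$probe) else "",
              x$reference,
              if (x$use_offset) ", log(DAPI) offset" else ", no offset"))
  print(x$coefficients, row.names = FALSE, digits = 4)
  if (!is.null(x$dispersion)) {
    cat(sprintf("dispersion (Pearson chi2/df): %.4f on %d df\n",
                x$dispersion, x$residual_df))
  }
  invisible(x)
}
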