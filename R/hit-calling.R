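#' Fit a Gaussian mixture to normalized screen values by EM
#'
#' Maximum-likelihood fit of a k-component (k = 1 or 2) univariate Gaussian
#' mixture by expectation-maximization. For k = 1 (without the outlier
#' component) the closed-form MLE is returned (mean and 1/n-denominator
#' SD). Otherwise the EM is initialized deterministically from moment
#' splits of the sample at several quantiles (a median split alone can
#' trap EM in a bulk-splitting local optimum when the mixture is highly
#' unbalanced) and the highest-likelihood converged fit is kept; if a
#' component variance collapses below `sd_floor`, the fit restarts (up to
#' 5 times) from seeded random responsibilities. The log-likelihood is
#' asserted non-decreasing at every iteration. Components are returned
#' ordered by ascending mean.
#'
#' With `noise = TRUE`, a uniform "outlier" component over the observed
#' value range is added alongside the Gaussians (the standard robust
#' mixture device, cf. the noise component of model-based clustering).
#' This keeps a handful of extreme values — e.g. genuine rescuing
#' treatments far to the right of the background distribution — from
#' distorting the fitted background components. Gaussian weights are then
#' reported renormalized to sum to 1, with the fitted outlier mass in
#' `noise_weight`.
#'
#' @param values Numeric vector of normalized ratios (n >= 10 k).
#' @param k Number of Gaussian components, 1 or 2.
#' @param seed Integer seed controlling restart jitter.
#' @param tol Convergence tolerance on the relative log-likelihood change.
#' @param max_iter Maximum EM iterations.
#' @param sd_floor Lower bound on component SDs (variance-collapse guard).
#' @param noise Add a uniform outlier component (default `FALSE`).
#' @param noise_weight Fixed mixing mass of the outlier component (not
#'   estimated; default 0.02). A fixed small contamination mass absorbs
#'   only points that are implausible under every Gaussian component,
#'   whereas a freely estimated mass also bites into the bulk tails.
#' @return An object of class `mixture_fit`: `k`, `weights`, `means`,
#'   `sds`, `noise_weight`, `loglik`, `bic` (-2 loglik + p log n with
#'   p = 3k - 1 free parameters, +1 when the outlier component is
#'   estimated), `n_iter`, `converged`, `seed`, `n`, and the
#'   per-iteration `loglik_trace`.
#' @export
fit_gmm <- function(values, k = 2, seed = 1, tol = 1e-8, max_iter = 500,
                    sd_floor = 1e-4, noise = FALSE, noise_weight = 0.02) {
  values <- as.numeric(values)
  if (!k %in% c(1, 2)) abort("k must be 1 or 2", class = "mmpscreen_invalid_input")
  n <- length(values)
  if (n < 10 * k) {
    abort(sprintf("need at least %d values for k = %d", 10 * k, k),
          class = "mmpscreen_invalid_input")
  }
  if (k == 1 && !noise) {
    mu <- mean(values)
    sigma <- max(sqrt(mean((values - mu)^2)), sd_floor)
    ll <- sum(dnorm(values, mu, sigma, log = TRUE))
    return(new_mixture_fit(1L, 1, mu, sigma, 0, ll, n, n_iter = 0L,
                           converged = TRUE, seed = seed, trace = ll))
  }
  rng <- range(values)
  span <- max(diff(rng), sd_floor)
  log_unif <- -log(1.2 * span) # uniform density over the widened range

  # deterministic split at a quantile; group moments seed the EM
  init_quantile_split <- function(q) {
    if (k == 1) {
      par <- list(w = 1, mu = mean(values),
                  sigma = max(sd_mle(values), sd_floor))
    } else {
      cut <- unname(quantile(values, q, type = 7))
      lo <- values[values <= cut]
      hi <- values[values > cut]
      if (length(hi) == 0 || length(lo) == 0) { # degenerate ties
        lo <- values[seq_len(floor(n / 2))]
        hi <- values[-seq_len(floor(n / 2))]
      }
      par <- list(w = c(length(lo), length(hi)) / n,
                  mu = c(mean(lo), mean(hi)),
                  sigma = pmax(c(sd_mle(lo), sd_mle(hi)), sd_floor))
    }
    if (noise) {
      par$w <- c(par$w * (1 - noise_weight), noise_weight)
    }
    par
  }

  ncomp <- k + as.integer(noise)
  run_em <- function(par) {
    w <- par$w; mu <- par$mu; sigma <- par$sigma
    trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      # E-step in log space for numerical stability
      lp <- vapply(seq_len(k), function(j) {
        log(w[j]) + dnorm(values, mu[j], sigma[j], log = TRUE)
      }, numeric(n))
      if (noise) lp <- cbind(lp, log(w[ncomp]) + log_unif)
      m <- do.call(pmax, as.data.frame(lp))
      lse <- m + log(rowSums(exp(lp - m)))
      ll <- sum(lse)
      if (ll < ll_old - 1e-9 * max(1, abs(ll_old))) {
        abort("EM log-likelihood decreased", class = "mmpscreen_em_error")
      }
      trace <- c(trace, ll)
      if (is.finite(ll_old) &&
          abs(ll - ll_old) < tol * max(1, abs(ll_old))) {
        return(list(w = w, mu = mu, sigma = sigma, loglik = ll,
                    n_iter = it, converged = TRUE, trace = trace))
      }
      ll_old <- ll
      resp <- exp(lp - lse)
      # M-step
      nk <- colSums(resp)
      gk <- nk[seq_len(k)]
      w <- if (noise) {
        c((1 - noise_weight) * gk / sum(gk), noise_weight)
      } else {
        nk / n
      }
      mu <- colSums(resp[, seq_len(k), drop = FALSE] * values) / gk
      sigma <- sqrt(colSums(resp[, seq_len(k), drop = FALSE] *
                              outer(values, mu, "-")^2) / gk)
      if (any(!is.finite(sigma)) || any(sigma < sd_floor) ||
          any(gk < .Machine$double.eps)) {
        return(list(collapsed = TRUE))
      }
    }
    list(w = w, mu = mu, sigma = sigma, loglik = ll_old, n_iter = max_iter,
         converged = FALSE, trace = trace)
  }

  splits <- if (k == 1) 0.5 else c(0.5, 0.1, 0.25, 0.75, 0.9)
  fits <- purrr::map(splits, function(q) run_em(init_quantile_split(q)))
  fits <- purrr::keep(fits, ~ is.null(.x$collapsed))
  if (length(fits) == 0) {
    # all deterministic starts collapsed; seeded random-responsibility
    # restarts, up to 5
    restart <- 0L
    fit <- list(collapsed = TRUE)
    while (!is.null(fit$collapsed) && restart < 5L) {
      restart <- restart + 1L
      fit <- withr::with_seed(seed + restart, {
        r <- runif(n, 0.25, 0.75) # jittered responsibilities
        if (k == 2) {
          nk <- c(sum(r), sum(1 - r))
          mu <- c(sum(r * values), sum((1 - r) * values)) / nk
          sigma <- pmax(sqrt(c(sum(r * (values - mu[1])^2),
                               sum((1 - r) * (values - mu[2])^2)) / nk),
                        sd_floor)
          w <- nk / n
        } else {
          mu <- mean(values) + sd(values) * runif(1, -0.5, 0.5)
          sigma <- max(sd(values), sd_floor)
          w <- 1
        }
        if (noise) w <- c(w * (1 - noise_weight), noise_weight)
        run_em(list(w = w, mu = mu, sigma = sigma))
      })
    }
    if (!is.null(fit$collapsed)) {
      abort("EM failed to converge: variance collapse persisted across restarts",
            class = "mmpscreen_em_error")
    }
  } else {
    fit <- fits[[which.max(purrr::map_dbl(fits, "loglik"))]]
  }
  ord <- order(fit$mu)
  gw <- fit$w[seq_len(k)][ord]
  noise_w <- if (noise) fit$w[ncomp] else 0
  new_mixture_fit(as.integer(k), gw / sum(gw), fit$mu[ord], fit$sigma[ord],
                  noise_w, fit$loglik, n, fit$n_iter, fit$converged, seed,
                  fit$trace)
}

sd_mle <- function(x) sqrt(mean((x - mean(x))^2))

new_mixture_fit <- function(k, weights, means, sds, noise_weight, loglik,
                            n, n_iter, converged, seed, trace) {
  p <- 3L * k - 1L # the outlier mass, when present, is fixed, not fitted
  structure(list(
    k = k, weights = weights, means = means, sds = sds,
    noise_weight = noise_weight,
    loglik = loglik, bic = -2 * loglik + p * log(n),
    n_iter = n_iter, converged = converged, seed = seed, n = n,
    loglik_trace = trace
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit k=%d, loglik=%.3f, BIC=%.2f, %s in %d iter>\n",
              x$k, x$loglik, x$bic,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  for (j in seq_len(x$k)) {
    cat(sprintf("  comp %d: weight %.4f, mean %.4f, sd %.4f\n",
                j, x$weights[j], x$means[j], x$sds[j]))
  }
  invisible(x)
}

#' Mixture log-likelihood of a sample at given parameters
#'
#' Direct evaluation of the two-component Gaussian mixture log-likelihood;
#' used for diagnostics and brute-force comparisons.
#'
#' @param values Numeric vector.
#' @param weights,means,sds Mixture parameters (equal-length vectors).
#' @return Scalar log-likelihood.
#' @export
mixture_loglik <- function(values, weights, means, sds) {
  dens <- vapply(seq_along(weights),
                 function(j) weights[j] * dnorm(values, means[j], sds[j]),
                 numeric(length(values)))
  sum(log(rowSums(dens)))
}

#' Classify a screen's value distribution as bimodal or unimodal
#'
#' Fits k = 1 and k = 2 mixtures and labels the sample bimodal only when
#' all three hold: BIC improves by more than 10 going from one to two
#' components, the smaller fitted weight is at least 0.05, and the
#' component separation |mu2 - mu1| / max(sd1, sd2) is at least 2. These
#' cutoffs operationalize "clearly bimodal": a decisive model-selection
#' margin, a non-negligible minor population, and well-separated modes.
#'
#' @param values Numeric vector (n >= 20).
#' @param seed Integer seed (forwarded to [fit_gmm()]).
#' @param robust Fit both models with the uniform outlier component
#'   (default `TRUE`), so that a few genuine far-right rescuers do not
#'   masquerade as (or obscure) a background mode.
#' @return An object of class `modality_assessment`: `label`
#'   (`"bimodal"`/`"unimodal"`), `delta_bic`, `min_weight`, `separation`,
#'   and the two fits (`fit1`, `fit2`).
#' @export
assess_modality <- function(values, seed = 1, robust = TRUE) {
  if (length(values) < 20) {
    abort("assess_modality needs n >= 20", class = "mmpscreen_invalid_input")
  }
  fit1 <- fit_gmm(values, k = 1, seed = seed, noise = robust)
  fit2 <- fit_gmm(values, k = 2, seed = seed, noise = robust)
  delta_bic <- fit1$bic - fit2$bic
  min_weight <- min(fit2$weights)
  separation <- abs(diff(fit2$means)) / max(fit2$sds)
  label <- if (delta_bic > 10 && min_weight >= 0.05 && separation >= 2) {
    "bimodal"
  } else {
    "unimodal"
  }
  structure(list(label = label, delta_bic = delta_bic,
                 min_weight = min_weight, separation = separation,
                 fit1 = fit1, fit2 = fit2),
            class = "modality_assessment")
}

#' @export
print.modality_assessment <- function(x, ...) {
  cat(sprintf("<modality: %s (dBIC=%.1f, min weight=%.3f, separation=%.2f)>\n",
              x$label, x$delta_bic, x$min_weight, x$separation))
  invisible(x)
}

#' Call screen hits with a distribution-appropriate 2-SD rule
#'
#' Hits are treatments whose replicate-aggregated normalized ratio is at
#' least 2 SD above a reference mean (inclusive). For a bimodal screen the
#' reference is the dominant high-response mixture component (the component
#' with the larger mean of a converged k = 2 fit), avoiding the variance
#' inflation of pooled statistics under population mixing. For a unimodal
#' screen the reference is the pooled sample mean and SD.
#'
#' For the bimodal rule the dominant component's mean and SD are
#' re-estimated from its member values (maximum-responsibility
#' assignment) by right-truncated Gaussian maximum likelihood, with the
#' truncation point at the largest member value. The upper flank of the
#' background component is exactly where rescuing treatments separate
#' from it, so the observed component support may be right-censored;
#' ignoring this shrinks the fitted SD and biases the threshold downward.
#' When the member maximum lies deep in the component tail, the
#' truncation correction vanishes and the estimate coincides with the
#' plain component MLE.
#'
#' @param aggregated Tibble from [aggregate_replicates()] (columns
#'   `treatment_id`, `aggregate`).
#' @param assessment A `modality_assessment` from [assess_modality()].
#' @param fit A converged k = 2 `mixture_fit`; required when the
#'   assessment is bimodal (typically `assessment$fit2`).
#' @return An object of class `hit_call_result`: `rule`
#'   (`"gmm_component"` or `"pooled_sd"`), `threshold`, `reference_mean`,
#'   `reference_sd`, `pooled_mean`, `pooled_sd`, `hits` (tibble of
#'   `treatment_id`, `value`), `n_hits`.
#' @export
call_hits <- function(aggregated, assessment, fit = NULL) {
  values <- aggregated$aggregate
  pooled_mean <- mean(values)
  pooled_sd <- sd(values)
  if (assessment$label == "bimodal") {
    if (is.null(fit)) {
      abort("bimodal screen requires a k = 2 mixture fit",
            class = "mmpscreen_missing_model")
    }
    if (fit$k != 2 || !fit$converged) {
      abort("supplied fit must be a converged k = 2 mixture",
            class = "mmpscreen_missing_model")
    }
    hi <- which.max(fit$means)
    rule <- "gmm_component"
    ref <- dominant_component_reference(values, fit, hi)
    ref_mean <- ref$mean
    ref_sd <- ref$sd
  } else {
    rule <- "pooled_sd"
    ref_mean <- pooled_mean
    ref_sd <- pooled_sd
  }
  threshold <- ref_mean + 2 * ref_sd
  hits <- aggregated |>
    filter(.data$aggregate >= threshold) |>
    arrange(desc(.data$aggregate)) |>
    transmute(treatment_id = .data$treatment_id, value = .data$aggregate)
  structure(list(
    rule = rule, threshold = threshold,
    reference_mean = ref_mean, reference_sd = ref_sd,
    pooled_mean = pooled_mean, pooled_sd = pooled_sd,
    hits = hits, n_hits = nrow(hits)
  ), class = "hit_call_result")
}

# Re-estimate the dominant component's (mean, sd) from its
# maximum-responsibility members by right-truncated Gaussian ML; the
# truncation point is the largest member value. Falls back to the fitted
# component parameters for tiny memberships or failed optimization.
dominant_component_reference <- function(values, fit, hi) {
  dens <- vapply(seq_len(fit$k), function(j) {
    (1 - fit$noise_weight) * fit$weights[j] *
      dnorm(values, fit$means[j], fit$sds[j])
  }, numeric(length(values)))
  if (fit$noise_weight > 0) {
    span <- max(diff(range(values)), 1e-8)
    dens <- cbind(dens, fit$noise_weight / (1.2 * span))
  }
  member <- max.col(dens) == hi
  x_all <- values[member]
  fallback <- list(mean = fit$means[hi], sd = fit$sds[hi])
  if (length(x_all) < 10) return(fallback)
  tml <- function(x) {
    b <- max(x)
    nll <- function(par) {
      mu <- par[1]; sigma <- exp(par[2])
      -sum(dnorm(x, mu, sigma, log = TRUE)) +
        length(x) * pnorm((b - mu) / sigma, log.p = TRUE)
    }
    opt <- tryCatch(
      stats::optim(c(median(x), log(fit$sds[hi])), nll, method = "BFGS"),
      error = function(e) NULL
    )
    if (is.null(opt) || opt$convergence != 0 || !all(is.finite(opt$par))) {
      return(NULL)
    }
    list(mean = opt$par[1], sd = exp(opt$par[2]))
  }
  # self-consistent censored fit: estimate using only member values
  # below the current threshold, then update the threshold. Seeded from
  # the fitted component (never outlier-inflated), so the iteration
  # cannot latch onto a high fixed point that swallows candidate hits.
  est <- fallback
  for (i in 1:6) {
    thr <- est$mean + 2 * est$sd
    x <- x_all[x_all <= thr]
    if (length(x) < 10) return(fallback)
    est_new <- tml(x)
    if (is.null(est_new)) return(est)
    if (abs(est_new$mean - est$mean) < 1e-6 &&
        abs(est_new$sd - est$sd) < 1e-6) {
      return(est_new)
    }
    est <- est_new
  }
  est
}

#' @export
print.hit_call_result <- function(x, ...) {
  cat(sprintf("<hit_call_result: rule %s, threshold %.4f, %d hits>\n",
              x$rule, x$threshold, x$n_hits))
  invisible(x)
}

#' Run the full screening pipeline on a dataset
#'
#' Convenience wrapper: plate normalization, duplicate aggregation, QC,
#' modality assessment, and hit calling.
#'
#' @param ds A [screen_dataset()].
#' @param seed Integer seed for the mixture fits.
#' @param force_rule `"auto"` (use the modality assessment), `"gmm"`, or
#'   `"pooled"`.
#' @return List with `normalized`, `aggregated`, `qc`, `assessment`,
#'   `result`.
#' @export
run_screen_pipeline <- function(ds, seed = 1,
                                force_rule = c("auto", "gmm", "pooled")) {
  force_rule <- match.arg(force_rule)
  normalized <- normalize_screen(ds)
  aggregated <- aggregate_replicates(normalized)
  qc <- qc_screen(ds, normalized)
  assessment <- assess_modality(aggregated$aggregate, seed = seed)
  if (force_rule == "gmm") assessment$label <- "bimodal"
  if (force_rule == "pooled") assessment$label <- "unimodal"
  result <- call_hits(aggregated, assessment, fit = assessment$fit2)
  list(normalized = normalized, aggregated = aggregated, qc = qc,
       assessment = assessment, result = result)
}

#' Assemble a screen report (hit call + QC + scatter data)
#'
#' @param result A `hit_call_result`.
#' @param qc A `screen_qc_report` from the same screen.
#' @param aggregated The aggregated tibble the hits were called on
#'   (provides the scatter-plot data: treatment index vs. value with hits
#'   flagged).
#' @return List of class `screen_report` with `rule`, `threshold`, fit
#'   reference parameters, `hits`, `qc_summary` and `scatter`.
#' @export
screen_report <- function(result, qc, aggregated) {
  scatter <- aggregated |>
    arrange(.data$treatment_id) |>
    mutate(index = row_number(),
           is_hit = .data$treatment_id %in% result$hits$treatment_id) |>
    select("index", "treatment_id", value = "aggregate", "is_hit")
  structure(list(
    rule = result$rule,
    threshold = result$threshold,
    reference_mean = result$reference_mean,
    reference_sd = result$reference_sd,
    pooled_mean = result$pooled_mean,
    pooled_sd = result$pooled_sd,
    n_hits = result$n_hits,
    hits = result$hits,
    qc_summary = list(
      z_prime = setNames(qc$plates$z_prime, qc$plates$plate_id),
      cv_mean = qc$cv_mean, cv_median = qc$cv_median,
      frac_cv_lt_10 = qc$frac_cv_lt_10, all_pass_cv15 = qc$all_pass_cv15
    ),
    scatter = scatter
  ), class = "screen_report")
}

#' Write a screen report to JSON (and the hit list to CSV)
#'
#' @param report A `screen_report`.
#' @param json_path Output JSON path.
#' @param hits_csv_path Optional CSV path for the hit list.
#' @return `json_path`, invisibly.
#' @export
write_screen_report <- function(report, json_path, hits_csv_path = NULL) {
  payload <- report[c("rule", "threshold", "reference_mean", "reference_sd",
                      "pooled_mean", "pooled_sd", "n_hits")]
  payload$hits <- report$hits
  payload$qc_summary <- report$qc_summary
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(hits_csv_path)) {
    readr::write_csv(report$hits, hits_csv_path, progress = FALSE)
  }
  invisible(json_path)
}
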