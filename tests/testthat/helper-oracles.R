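# Independent brute-force oracles the implementation is checked against.
# These deliberately avoid the package's own code paths.

# least-squares line by iterative grid refinement (no closed form, no lm)
ols_grid_oracle <- function(x, y, rounds = 30) {
  b0 <- stats::cov(x, y) / stats::var(x) # centre the grid only
  a0 <- mean(y) - b0 * mean(x)
  span_b <- max(abs(b0), 1)
  span_a <- max(abs(a0), 1)
  best <- c(b0, a0)
  for (r in seq_len(rounds)) {
    bs <- seq(best[1] - span_b, best[1] + span_b, length.out = 21)
    as <- seq(best[2] - span_a, best[2] + span_a, length.out = 21)
    sse <- outer(bs, as, function(b, a) {
      vapply(seq_along(b), function(i) sum((y - b[i] * x - a[i])^2), 0)
    })
    idx <- arrayInd(which.min(sse), dim(sse))
    best <- c(bs[idx[1]], as[idx[2]])
    span_b <- span_b / 5
    span_a <- span_a / 5
  }
  c(slope = best[1], intercept = best[2])
}

mae_oracle <- function(pred, truth) {
  s <- 0
  for (i in seq_along(pred)) s <- s + abs(pred[i] - truth[i])
  s / length(pred)
}

pearson_oracle <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

combined_score_oracle <- function(mae_hct, r_hct, mae_ecv, r_ecv) {
  norm <- function(v, invert) {
    v <- if (invert) -v else v
    if (max(v) == min(v)) return(rep(1, length(v)))
    (v - min(v)) / (max(v) - min(v))
  }
  (norm(mae_hct, TRUE) + norm(r_hct, FALSE) +
     norm(mae_ecv, TRUE) + norm(r_ecv, FALSE)) / 4
}

# cohort whose haematocrit is pure noise, independent of attenuation
noise_cohort <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      patient_id = sprintf("N%04d", seq_len(n)),
      sex = "male",
      bmi = stats::rlnorm(n, log(27), 0.2),
      age = stats::rnorm(n, 80, 7),
      egfr = stats::rnorm(n, 60, 15),
      creatinine = stats::rlnorm(n, log(90), 0.3),
      hu_blood = stats::rnorm(n, 49, 4),
      hct = stats::rnorm(n, 0.40, 0.05),
      ecv_true = stats::rnorm(n, 0.32, 0.03),
      dhu_blood = stats::rnorm(n, 60, 8)
    ) |>
      dplyr::mutate(dhu_myo = ecv_true * dhu_blood / (1 - hct))
  })
}

# single-stratum specification helper: one calibration line per sex
single_line_spec <- function(n_male = 200, n_female = 0, slope = 1,
                             intercept = -9, r_squared = 0.5, hct_sd = 5) {
  sg <- tibble::tibble(
    sex = c("male", "female"), bmi_low = -Inf, bmi_high = Inf,
    slope = slope, intercept = intercept, hct_mean = 40, hct_sd = hct_sd,
    r_squared = r_squared
  )
  cohort_spec(n_male = n_male, n_female = n_female, subgroups = sg)
}

# independent re-implementation of the gated bin search (lm/cor.test based)
bin_search_oracle <- function(cohort, covariate, k_range = 2:5, alpha = 0.05,
                              min_bin_n = 5L, max_candidates = 2000L) {
  x <- cohort[[covariate]]
  hu <- cohort$hu_blood
  y <- cohort$hct * 100

  lattice_for <- function(k) {
    for (step in c(0.05, 0.10, 0.20)) {
      lat <- unique(unname(stats::quantile(x, seq(0.10, 0.90, by = step))))
      if (k - 1 <= length(lat) && choose(length(lat), k - 1) <= max_candidates) {
        return(utils::combn(lat, k - 1, simplify = FALSE))
      }
    }
    list()
  }
  candidates <- unlist(lapply(k_range, lattice_for), recursive = FALSE)
  gate_alpha <- alpha / length(candidates)

  loo_pred <- function(xs, ys) {
    if (length(xs) < 4 || stats::sd(xs) == 0) {
      if (stats::sd(xs) == 0) return(rep(mean(ys), length(ys)))
      f <- stats::lm(ys ~ xs)
      return(unname(stats::fitted(f)))
    }
    f <- stats::lm(ys ~ xs)
    h <- pmin(stats::hatvalues(f), 1 - 1e-8)
    unname(ys - stats::residuals(f) / (1 - h))
  }
  cohort_metrics <- function(pred_pct) {
    pred <- pred_pct / 100
    con <- (1 - cohort$hct) * cohort$dhu_myo / cohort$dhu_blood
    syn <- (1 - pred) * cohort$dhu_myo / cohort$dhu_blood
    c(mae_hct = mean(abs(pred - cohort$hct)),
      r_hct = stats::cor(pred, cohort$hct),
      mae_ecv = mean(abs(syn - con)), r_ecv = stats::cor(syn, con))
  }
  loo_metrics <- function(edges) {
    bin <- findInterval(x, c(-Inf, edges, Inf))
    pred <- numeric(length(y))
    for (j in seq_len(length(edges) + 1)) {
      sel <- bin == j
      pred[sel] <- loo_pred(hu[sel], y[sel])
    }
    cohort_metrics(pred)
  }

  assess <- function(edges) {
    bin <- findInterval(x, c(-Inf, edges, Inf))
    k <- length(edges) + 1
    if (any(tabulate(bin, k) < max(min_bin_n, 3))) return(NULL)
    for (j in seq_len(k)) {
      sel <- bin == j
      if (stats::sd(hu[sel]) == 0) return(NULL)
      ct <- stats::cor.test(hu[sel], y[sel])
      if (ct$p.value >= gate_alpha) return(NULL)
    }
    # adjacent-slope tests from the full interaction model
    fit <- stats::lm(y ~ hu * factor(bin))
    V <- stats::vcov(fit)
    cf <- stats::coef(fit)
    int_names <- grep("^hu:factor", names(cf), value = TRUE)
    slopes_rel <- c(0, unname(cf[int_names])) # relative to bin 1
    for (j in seq_len(k - 1)) {
      L <- stats::setNames(numeric(length(cf)), names(cf))
      if (j >= 2) L[int_names[j - 1]] <- -1
      L[int_names[j]] <- 1
      est <- sum(L * cf)
      se <- sqrt(drop(t(L) %*% V %*% L))
      p <- 2 * stats::pt(-abs(est / se), df = fit$df.residual)
      if (p >= gate_alpha) return(NULL)
    }
    m <- loo_metrics(edges)
    # prune: must beat each one-boundary-removed reduction out of sample
    for (dr in seq_along(edges)) {
      red <- loo_metrics(edges[-dr])
      if (!(m[["mae_hct"]] < red[["mae_hct"]] && m[["r_hct"]] > red[["r_hct"]])) {
        return(NULL)
      }
    }
    list(edges = edges, metrics = m)
  }

  retained <- Filter(Negate(is.null), lapply(candidates, assess))
  if (length(retained) == 0) return(NULL)
  mm <- do.call(rbind, lapply(retained, function(r) r$metrics))
  scores <- combined_score_oracle(mm[, "mae_hct"], mm[, "r_hct"],
                                  mm[, "mae_ecv"], mm[, "r_ecv"])
  ord <- order(-scores,
               vapply(retained, function(r) length(r$edges), 0L),
               vapply(retained, function(r) r$edges[1], 0))
  list(edges = retained[[ord[1]]]$edges, score = scores[ord[1]])
}
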