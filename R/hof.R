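# Huisman-Olff-Fresco (HOF) hierarchy of species response curves, fitted by
# maximum likelihood with a binomial error model on read counts, the
# environmental axis rescaled to [0, 1]:
#   I    flat
#   II   monotone sigmoid
#   III  monotone with plateau
#   IV   symmetric unimodal
#   V    skewed unimodal
#   VI   bimodal, equal maxima
#   VII  bimodal, unequal maxima
hof_types <- c("I", "II", "III", "IV", "V", "VI", "VII")
hof_npar <- c(I = 1L, II = 2L, III = 3L, IV = 3L, V = 4L, VI = 4L, VII = 5L)

hof_curve <- function(type, theta, x) {
  lg <- function(z) 1 / (1 + exp(pmin(pmax(z, -500), 500)))
  hump <- function(a, b, c, xx) lg(a + b * xx) * lg(c - b * xx)
  p <- switch(type,
    I   = rep(lg(theta[1L]), length(x)),
    II  = lg(theta[1L] + theta[2L] * x),
    III = lg(theta[1L] + theta[2L] * x) * lg(theta[3L]),
    IV  = hump(theta[1L], theta[2L], theta[3L], x),
    V   = lg(theta[1L] + theta[2L] * x) * lg(theta[3L] - theta[4L] * x),
    VI  = hump(theta[1L], theta[2L], theta[3L], x) +
          hump(theta[1L], theta[2L], theta[3L], x - theta[4L]),
    VII = hump(theta[1L], theta[2L], theta[3L], x) +
          lg(-theta[5L]) * hump(theta[1L], theta[2L], theta[3L], x - theta[4L]))
  pmin(pmax(p, 1e-10), 1 - 1e-10)
}

hof_nll <- function(theta, type, x, k, N) {
  p <- hof_curve(type, theta, x)
  v <- -sum(dbinom(k, N, p, log = TRUE))
  if (!is.finite(v)) 1e10 else v
}

hof_starts <- function(type, x, k, N) {
  rel <- k / N
  pbar <- min(max(mean(rel), 1e-4), 1 - 1e-4)
  pmax_ <- min(max(max(rel), 2e-4), 1 - 1e-4)
  a0 <- log(1 / pbar - 1)
  xc <- if (sum(k) > 0) sum(x * k) / sum(k) else 0.5
  s <- log(1 / sqrt(pmax_) - 1)
  slope_sign <- if (isTRUE(suppressWarnings(cor(x, rel)) > 0)) -1 else 1
  switch(type,
    I   = list(a0),
    II  = list(c(a0, slope_sign * 5), c(a0, slope_sign * 15),
               c(a0, -slope_sign * 5)),
    III = list(c(a0, slope_sign * 5, -1), c(a0, slope_sign * 15, 0)),
    IV  = lapply(c(5, 10, 20), function(b)
            c(s - b * xc, b, s + b * xc)),
    V   = lapply(c(5, 10, 20), function(b)
            c(s - b * xc, b, s + b * xc, b)),
    VI  = lapply(c(8, 16), function(b)
            c(s - b * (xc * 0.6), b, s + b * (xc * 0.6), 0.5)),
    VII = lapply(c(8, 16), function(b)
            c(s - b * (xc * 0.6), b, s + b * (xc * 0.6), 0.5, 0)))
}

fit_one_hof <- function(type, x, k, N, extra_starts = list()) {
  best <- NULL
  for (st in c(hof_starts(type, x, k, N), extra_starts)) {
    fit <- tryCatch(
      optim(st, hof_nll, type = type, x = x, k = k, N = N,
            method = if (length(st) == 1L) "Brent" else "Nelder-Mead",
            lower = if (length(st) == 1L) -50 else -Inf,
            upper = if (length(st) == 1L) 50 else Inf,
            control = list(maxit = 2000)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    # quasi-Newton polish from the simplex solution
    pol <- tryCatch(
      suppressWarnings(optim(fit$par, hof_nll, type = type, x = x, k = k,
                             N = N, method = "BFGS",
                             control = list(maxit = 200))),
      error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$value) && pol$value < fit$value) {
      fit <- pol
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best
}

# Fit all seven types with hierarchical warm starts: each model is also
# started from the best fit of the simpler models it nests.
fit_hof_family <- function(x, k, N) {
  fits <- setNames(vector("list", length(hof_types)), hof_types)
  warm <- function(type) {
    switch(type,
      II = if (!is.null(fits$I)) list(c(fits$I$par, 2), c(fits$I$par, -2)),
      III = if (!is.null(fits$II)) list(c(fits$II$par, -2)),
      IV = NULL,
      V = if (!is.null(fits$IV))
        list(c(fits$IV$par, fits$IV$par[2L]),
             c(fits$IV$par, 0.7 * fits$IV$par[2L])),
      VI = if (!is.null(fits$IV))
        list(c(fits$IV$par, 0.4), c(fits$IV$par, -0.4)),
      VII = if (!is.null(fits$VI)) list(c(fits$VI$par, 0)))
  }
  for (t in hof_types) {
    fits[[t]] <- fit_one_hof(t, x, k, N, extra_starts = warm(t) %||% list())
  }
  fits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Does a fitted response on a grid show two pronounced modes (edges count),
# the secondary at >= 15% of the primary with a clear trough between?
hof_is_bimodal <- function(p) {
  n <- length(p)
  ismax <- c(p[1L] > p[2L],
             p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n],
             p[n] > p[n - 1L])
  ix <- which(ismax)
  if (length(ix) < 2L) return(FALSE)
  hts <- p[ix]
  top2 <- ix[order(hts, decreasing = TRUE)[1:2]]
  trough <- min(p[min(top2):max(top2)])
  sec <- min(p[top2])
  sec >= 0.15 * max(hts) && trough <= 0.8 * sec
}

# AICc model choice with a parsimony margin (the simplest model within
# `margin` of the best score wins) and a bimodality guard: a selected
# VI/VII whose fitted curve is not genuinely bimodal is demoted to the
# best of I-V.
hof_select <- function(fits, aicc, margin = 2) {
  pick_within <- function(types) {
    cand <- aicc[types]
    cand <- cand[is.finite(cand)]
    if (!length(cand)) return(NULL)
    names(cand)[cand <= min(cand) + margin][1L]
  }
  model <- pick_within(hof_types)
  if (is.null(model)) return(NULL)
  if (model %in% c("VI", "VII") && !is.null(fits[[model]])) {
    pg <- hof_curve(model, fits[[model]]$par, seq(0, 1, length.out = 501L))
    if (!hof_is_bimodal(pg)) model <- pick_within(hof_types[1:5]) %||% model
  }
  model
}

#' Fit the HOF model hierarchy to one OTU
#'
#' Fits all seven response-curve types by binomial maximum likelihood on the
#' rescaled environmental axis and selects the best by AICc, optionally
#' stabilized by refitting on bootstrap resamples and taking the modal
#' choice. The niche optimum is the argmax of the fitted response within the
#' observed environmental range; type I (flat) has no optimum.
#'
#' @param k per-sample read counts of the OTU.
#' @param N per-sample total read counts.
#' @param env per-sample environmental values (e.g. pH).
#' @param n_boot bootstrap resamples for model-choice stabilization
#'   (0 = off).
#' @param seed RNG seed for the bootstrap.
#' @return list: `model`, `optimum`, `included`, `edge`, `aicc` (named
#'   vector over all types), `theta`.
#' @export
hof_fit <- function(k, N, env, n_boot = 0, seed = NULL) {
  if (length(unique(env)) < 2L) stop("env must vary", call. = FALSE)
  rng <- range(env)
  x <- (env - rng[1L]) / diff(rng)
  n <- length(k)
  fits <- fit_hof_family(x, k, N)
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no HOF model converged", call. = FALSE)
  aicc <- rep(NA_real_, length(hof_types))
  names(aicc) <- hof_types
  for (t in hof_types[ok]) {
    p <- hof_npar[[t]]
    aicc[t] <- 2 * fits[[t]]$value + 2 * p +
      if (n - p - 1 > 0) 2 * p * (p + 1) / (n - p - 1) else Inf
  }
  model <- hof_select(fits, aicc)
  if (n_boot > 0) {
    choices <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        ix <- sample.int(n, n, replace = TRUE)
        f <- fit_hof_family(x[ix], k[ix], N[ix])
        sc <- vapply(seq_along(f), function(j) {
          if (is.null(f[[j]])) return(Inf)
          p <- hof_npar[[j]]
          2 * f[[j]]$value + 2 * p +
            if (n - p - 1 > 0) 2 * p * (p + 1) / (n - p - 1) else Inf
        }, numeric(1))
        names(sc) <- hof_types
        hof_select(f, sc) %||% NA_character_
      }, character(1))
    })
    tab <- table(factor(choices, levels = hof_types))
    if (any(tab > 0)) model <- hof_types[which.max(tab)]
    if (is.null(fits[[model]])) model <- hof_select(fits, aicc)
  }
  theta <- fits[[model]]$par
  if (model == "I") {
    return(list(model = model, optimum = NA_real_, included = FALSE,
                edge = FALSE, aicc = aicc, theta = theta))
  }
  xg <- seq(0, 1, length.out = 501L)
  pg <- hof_curve(model, theta, xg)
  xo <- xg[which.max(pg)]
  edge <- xo <= 0.005 || xo >= 0.995
  list(model = model, optimum = rng[1L] + xo * diff(rng), included = TRUE,
       edge = edge, aicc = aicc, theta = theta)
}

#' HOF niche optima for all OTUs of a table
#'
#' Applies [hof_fit()] to every OTU present in at least `min_occ` samples
#' spanning more than one distinct environmental value. OTUs whose best fit
#' is the flat type I have no niche optimum and are flagged excluded.
#'
#' @param table community table (taxa x samples).
#' @param env per-sample environmental values aligned with the columns.
#' @param n_boot bootstrap resamples for model-choice stabilization
#'   (default 0).
#' @param min_occ minimum occupancy for fitting (default 5).
#' @param seed RNG seed.
#' @return data frame `otu`, `model`, `optimum`, `aicc` (of the selected
#'   model), `included`, `edge`.
#' @export
hof_optima <- function(table, env, n_boot = 0, min_occ = 5, seed = NULL) {
  table <- as_community_table(table)
  if (!is.null(names(env))) env <- env[colnames(table)]
  if (length(env) != ncol(table) || anyNA(env)) {
    stop("env must provide a value for every sample", call. = FALSE)
  }
  N <- colSums(table)
  rows <- lapply(seq_len(nrow(table)), function(i) {
    k <- table[i, ]
    occ <- sum(k > 0)
    if (occ < min_occ || length(unique(env[k > 0])) < 2L) {
      return(data.frame(otu = rownames(table)[i], model = NA_character_,
                        optimum = NA_real_, aicc = NA_real_,
                        included = FALSE, edge = FALSE,
                        stringsAsFactors = FALSE))
    }
    f <- tryCatch(hof_fit(as.numeric(k), as.numeric(N), env,
                          n_boot = n_boot, seed = child_seed(seed, i)),
                  error = function(e) NULL)
    if (is.null(f)) {
      return(data.frame(otu = rownames(table)[i], model = NA_character_,
                        optimum = NA_real_, aicc = NA_real_,
                        included = FALSE, edge = FALSE,
                        stringsAsFactors = FALSE))
    }
    data.frame(otu = rownames(table)[i], model = f$model,
               optimum = f$optimum, aicc = f$aicc[[f$model]],
               included = f$included, edge = f$edge,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
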