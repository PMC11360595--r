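# Monte Carlo propagation of exposure-factor uncertainty through the
# drinking-water dose/risk equations. All sampled factors are independent and
# enter multiplicatively, which gives a closed-form product-of-means oracle
# for the mean risk (see analytic_mean_risk()).

#' Distribution specification for an uncertain input
#'
#' Four families cover the exposure model: `point` (a constant), `lognormal`
#' parameterised by its ARITHMETIC mean and standard deviation (moment
#' matching: `sigma^2 = log(1 + s^2/m^2)`, `mu = log(m) - sigma^2/2`),
#' `uniform` on `[min, max]`, and `triangular` with `(min, mode, max)`.
#'
#' @param kind One of `"point"`, `"lognormal"`, `"uniform"`, `"triangular"`.
#' @param value Constant for `point`.
#' @param mean,sd Arithmetic moments for `lognormal` (both positive).
#' @param min,max Bounds for `uniform`/`triangular` (`min < max`).
#' @param mode Mode for `triangular` (`min <= mode <= max`).
#' @return A list of class `dist_spec`.
#' @export
dist_spec <- function(kind = c("point", "lognormal", "uniform", "triangular"),
                      value = NULL, mean = NULL, sd = NULL,
                      min = NULL, max = NULL, mode = NULL) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    point = {
      if (is.null(value) || !is.finite(value)) stop("point needs a finite value", call. = FALSE)
      list(kind = kind, value = value)
    },
    lognormal = {
      if (is.null(mean) || is.null(sd) || mean <= 0 || sd <= 0) {
        stop("lognormal needs arithmetic mean > 0 and sd > 0", call. = FALSE)
      }
      list(kind = kind, mean = mean, sd = sd)
    },
    uniform = {
      if (is.null(min) || is.null(max) || !(min < max)) {
        stop("uniform needs min < max", call. = FALSE)
      }
      list(kind = kind, min = min, max = max)
    },
    triangular = {
      if (is.null(min) || is.null(mode) || is.null(max) ||
          !(min < max) || mode < min || mode > max) {
        stop("triangular needs min <= mode <= max with min < max", call. = FALSE)
      }
      list(kind = kind, min = min, mode = mode, max = max)
    })
  class(spec) <- "dist_spec"
  spec
}

#' Coerce a config entry to a dist_spec
#'
#' Accepts an existing `dist_spec`, a bare number (interpreted as a point
#' distribution), or a list with a `kind` field as read from YAML.
#'
#' @param x Specification in any accepted form.
#' @return A `dist_spec`.
#' @export
as_dist_spec <- function(x) {
  if (inherits(x, "dist_spec")) return(x)
  if (is.numeric(x) && length(x) == 1) return(dist_spec("point", value = x))
  if (is.list(x) && !is.null(x$kind)) {
    return(do.call(dist_spec, x))
  }
  stop("cannot interpret distribution specification", call. = FALSE)
}

# inverse-CDF triangular sampler; no triangular family ships with base R
rtriangular <- function(n, min, mode, max) {
  u <- stats::runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' Sample from a distribution specification
#'
#' Draws are non-negative for every family admissible in the exposure model;
#' a configuration that could produce negative values (negative uniform or
#' triangular bounds) is rejected rather than clamped.
#'
#' @param spec A [dist_spec()] (or anything [as_dist_spec()] accepts).
#' @param n Number of draws.
#' @param seed Optional integer seed (local to this call).
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(spec, n, seed = NULL) {
  spec <- as_dist_spec(spec)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- switch(spec$kind,
    point = rep(spec$value, n),
    lognormal = {
      p <- lognormal_params(spec$mean, spec$sd)
      stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog)
    },
    uniform = stats::runif(n, spec$min, spec$max),
    triangular = rtriangular(n, spec$min, spec$mode, spec$max))
  if (any(draws < 0)) {
    stop("distribution produced negative draws; check its bounds", call. = FALSE)
  }
  draws
}

#' Moment-matched log-normal parameters
#'
#' Maps an arithmetic mean/sd pair `(m, s)` to the log-scale parameters:
#' `sdlog^2 = log(1 + s^2/m^2)` and `meanlog = log(m) - sdlog^2/2`.
#'
#' @param mean,sd Arithmetic mean and standard deviation, both positive.
#' @return List with `meanlog` and `sdlog`.
#' @export
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Mean of a distribution specification (closed form)
#' @param spec A [dist_spec()].
#' @return The distribution's expectation.
#' @export
dist_mean <- function(spec) {
  spec <- as_dist_spec(spec)
  switch(spec$kind,
    point = spec$value,
    lognormal = spec$mean,
    uniform = (spec$min + spec$max) / 2,
    triangular = (spec$min + spec$mode + spec$max) / 3)
}

#' Monte Carlo configuration for one risk endpoint
#'
#' Binds the sampled symbols of the dose equation (C, IR, EF, ED, BW) and
#' the fixed AT, SF/RfD to distribution specifications. Defaults come from
#' the packaged exposure-factor configuration; the concentration distribution
#' is looked up by element and medium.
#'
#' @param element `"As"` (carcinogenic, CR) or `"Hg"` (non-carcinogenic, HQ).
#' @param medium `"ice"` or `"water"`.
#' @param group `"adult"` or `"child"`.
#' @param iterations Number of iterations (default 10000).
#' @param seed Integer seed for reproducibility.
#' @param config Assessment configuration list (see [load_config()]).
#' @param overrides Named list of `dist_spec`s replacing individual symbols
#'   (`C`, `IR`, `EF`, `ED`, `BW`, `AT`).
#' @return A list of class `mc_config` with fields `element`, `medium`,
#'   `group`, `metric`, `iterations`, `seed`, `dists` (symbol -> dist_spec),
#'   `sf` or `rfd`, `threshold`, and `c_unit`.
#' @export
mc_config <- function(element = c("As", "Hg"), medium = c("ice", "water"),
                      group = c("adult", "child"), iterations = 10000,
                      seed = NULL, config = load_config(), overrides = list()) {
  element <- match.arg(element)
  medium <- match.arg(medium)
  group <- match.arg(group)
  stopifnot(iterations >= 1)
  metric <- if (element == "As") "CR" else "HQ"
  context <- if (element == "As") "carcinogenic" else "noncarcinogenic"

  pe <- config$probabilistic_exposure[[group]]
  cd <- NULL
  for (entry in config$concentration_distributions) {
    if (entry$element == element && entry$medium == medium) cd <- entry
  }
  if (is.null(cd)) {
    stop("no concentration distribution configured for ", element, " in ",
         medium, call. = FALSE)
  }
  c_unit <- cd$unit
  cd$element <- NULL; cd$medium <- NULL; cd$unit <- NULL

  dists <- list(
    C = as_dist_spec(cd),
    IR = as_dist_spec(pe$IR),
    EF = as_dist_spec(pe$EF),
    ED = as_dist_spec(pe$ED),
    BW = as_dist_spec(pe$BW),
    AT = as_dist_spec(pe[[paste0("AT_", context)]])
  )
  for (nm in names(overrides)) {
    if (!nm %in% names(dists)) stop("unknown symbol in overrides: ", nm, call. = FALSE)
    dists[[nm]] <- as_dist_spec(overrides[[nm]])
  }

  out <- list(element = element, medium = medium, group = group,
              metric = metric, context = context, iterations = iterations,
              seed = seed, dists = dists, c_unit = c_unit,
              sf = config$toxicity$sf_kg_d_mg$As,
              rfd = config$toxicity$rfd_mg_kg_d$Hg,
              threshold = if (metric == "CR") config$thresholds$cr_acceptable
                          else config$thresholds$hq_acceptable)
  class(out) <- "mc_config"
  out
}

#' Run the Monte Carlo risk simulation
#'
#' Draws each symbol independently per iteration, converts the concentration
#' to mg/L, propagates through the dose equation and the CR or HQ formula,
#' and summarises the resulting empirical risk distribution. The per-symbol
#' draw matrix is retained for sensitivity analysis.
#'
#' @param cfg An [mc_config()].
#' @return A list of class `mc_result` with `summary` (an `MCSummary`-style
#'   list: mean, median, p5, p95, exceedance_probability, n_draws, seed),
#'   `risk` (per-iteration values), `draws` (tibble of per-symbol draws) and
#'   the echoed `config`.
#' @export
run_monte_carlo <- function(cfg) {
  stopifnot(inherits(cfg, "mc_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$iterations
  draws <- lapply(cfg$dists, sample_distribution, n = n)
  c_mg_L <- convert_concentration(draws$C, cfg$c_unit, "mg/L")
  add <- c_mg_L * draws$IR * draws$EF * draws$ED / (draws$BW * draws$AT)
  risk <- if (cfg$metric == "CR") add * cfg$sf else add / cfg$rfd
  out <- list(
    summary = summarize_mc(risk, threshold = cfg$threshold, seed = cfg$seed),
    risk = risk,
    draws = tibble::as_tibble(draws),
    config = cfg
  )
  class(out) <- "mc_result"
  out
}

#' Summarise a simulated risk distribution
#'
#' @param risk Per-iteration risk values.
#' @param threshold Exceedance threshold.
#' @param seed Seed to echo into the summary.
#' @return A list: `mean`, `median`, `p5`, `p95`, `exceedance_probability`,
#'   `n_draws`, `seed`.
#' @export
summarize_mc <- function(risk, threshold, seed = NULL) {
  stopifnot(length(risk) >= 1)
  list(mean = mean(risk),
       median = stats::median(risk),
       p5 = mc_percentile(risk, 5),
       p95 = mc_percentile(risk, 95),
       exceedance_probability = exceedance_probability(risk, threshold),
       n_draws = length(risk),
       seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Fraction of draws strictly above a threshold
#' @param draws Numeric vector of simulated values.
#' @param threshold Positive threshold.
#' @return A fraction in `[0, 1]`.
#' @export
exceedance_probability <- function(draws, threshold) {
  stopifnot(length(draws) >= 1, threshold > 0)
  mean(draws > threshold)
}

#' Empirical percentile with linear interpolation
#' @param draws Numeric vector (non-empty).
#' @param q Percentile in (0, 100).
#' @return The empirical quantile (type 7: linear interpolation between order
#'   statistics).
#' @export
mc_percentile <- function(draws, q) {
  if (length(draws) == 0) stop("no draws", call. = FALSE)
  stopifnot(q > 0, q < 100)
  unname(stats::quantile(draws, q / 100, type = 7))
}

#' Closed-form mean risk under independent multiplicative inputs
#'
#' Because every sampled factor enters the dose equation multiplicatively
#' and independently, `E[CR] = SF * E[C] * E[IR] * E[EF] * E[ED] * E[1/BW] / AT`
#' (and `E[HQ]` likewise with `1/RfD`). `E[1/BW]` uses the log-normal
#' closed form `exp(-meanlog + sdlog^2/2)`; for a point BW it is `1/BW`.
#' Serves as the independent oracle for the simulated mean.
#'
#' @param cfg An [mc_config()].
#' @return The analytic mean of the simulated risk.
#' @export
analytic_mean_risk <- function(cfg) {
  stopifnot(inherits(cfg, "mc_config"))
  bw <- cfg$dists$BW
  e_inv_bw <- switch(bw$kind,
    point = 1 / bw$value,
    lognormal = {
      p <- lognormal_params(bw$mean, bw$sd)
      exp(-p$meanlog + p$sdlog^2 / 2)
    },
    stop("E[1/BW] closed form available for point and lognormal BW only",
         call. = FALSE))
  at <- cfg$dists$AT
  if (at$kind != "point") stop("AT must be a point distribution", call. = FALSE)
  e_c_mg_L <- convert_concentration(dist_mean(cfg$dists$C), cfg$c_unit, "mg/L")
  e_add <- e_c_mg_L * dist_mean(cfg$dists$IR) * dist_mean(cfg$dists$EF) *
    dist_mean(cfg$dists$ED) * e_inv_bw / at$value
  if (cfg$metric == "CR") e_add * cfg$sf else e_add / cfg$rfd
}
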