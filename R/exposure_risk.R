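# Deterministic drinking-water exposure model. Concentrations entering the
# dose equation must already be in mg/L; callers convert explicitly through
# convert_concentration(), so a ug/L value cannot slip in unnoticed.

#' Exposure-factor set for a population group
#'
#' Bundles the drinking-water exposure factors: intake rate IR (L/d),
#' exposure frequency EF (d/a), exposure duration ED (a), body weight BW (kg)
#' and averaging time AT (d). ED and AT are context-dependent (carcinogenic
#' vs non-carcinogenic averaging), so both are held per context.
#'
#' Defaults reproduce the published deterministic risk table: adult IR 2 L/d,
#' BW 66.1 kg, EF 365 d/a, ED 70 a, AT 25550 d in both contexts; child IR
#' 1.0 L/d, BW 22.9 kg, carcinogenic ED 70 a / AT 25550 d, non-carcinogenic
#' ED 10 a / AT 3650 d. An alternative child intake rate of 0.7 L/d is in
#' circulation for this population but is inconsistent with the published
#' child risks, so it is available only as an explicit override.
#'
#' @param group `"adult"` or `"child"`.
#' @param IR,EF,BW Scalars overriding the group defaults.
#' @param ED_carcinogenic,ED_noncarcinogenic,AT_carcinogenic,AT_noncarcinogenic
#'   Context-specific durations (a) and averaging times (d).
#' @return A list of class `exposure_parameters`.
#' @export
exposure_parameters <- function(group = c("adult", "child"),
                                IR = NULL, EF = NULL, BW = NULL,
                                ED_carcinogenic = NULL,
                                ED_noncarcinogenic = NULL,
                                AT_carcinogenic = NULL,
                                AT_noncarcinogenic = NULL) {
  group <- match.arg(group)
  defaults <- list(
    adult = list(IR = 2.0, EF = 365, BW = 66.1,
                 ED_carcinogenic = 70, ED_noncarcinogenic = 70,
                 AT_carcinogenic = 25550, AT_noncarcinogenic = 25550),
    child = list(IR = 1.0, EF = 365, BW = 22.9,
                 ED_carcinogenic = 70, ED_noncarcinogenic = 10,
                 AT_carcinogenic = 25550, AT_noncarcinogenic = 3650)
  )[[group]]
  p <- utils::modifyList(defaults, Filter(Negate(is.null), list(
    IR = IR, EF = EF, BW = BW,
    ED_carcinogenic = ED_carcinogenic,
    ED_noncarcinogenic = ED_noncarcinogenic,
    AT_carcinogenic = AT_carcinogenic,
    AT_noncarcinogenic = AT_noncarcinogenic)))
  if (any(unlist(p) <= 0)) stop("all exposure factors must be positive", call. = FALSE)
  p$group <- group
  class(p) <- "exposure_parameters"
  p
}

#' Average daily dose through drinking water
#'
#' `ADD = C * IR * EF * ED / (BW * AT)` in mg/kg/d. ED is in years and is
#' multiplied by EF (d/a) to give exposure days, divided by the averaging
#' time AT (d); no leap-year handling. The context selects which ED/AT pair
#' of the parameter set applies.
#'
#' @param c_mg_L Concentration in mg/L (convert first; see
#'   [convert_concentration()]).
#' @param params An [exposure_parameters()] object.
#' @param context `"carcinogenic"` or `"noncarcinogenic"`.
#' @return Dose in mg/kg/d.
#' @export
average_daily_dose <- function(c_mg_L, params,
                               context = c("carcinogenic", "noncarcinogenic")) {
  context <- match.arg(context)
  stopifnot(inherits(params, "exposure_parameters"))
  if (any(c_mg_L < 0)) stop("concentration must be non-negative", call. = FALSE)
  ed <- params[[paste0("ED_", context)]]
  at <- params[[paste0("AT_", context)]]
  if (params$BW <= 0 || at <= 0) stop("BW and AT must be positive", call. = FALSE)
  c_mg_L * params$IR * params$EF * ed / (params$BW * at)
}

risk_result <- function(metric, value, threshold, group = NA_character_,
                        element = NA_character_, medium = NA_character_,
                        add = NA_real_) {
  tibble::tibble(group = group, element = element, medium = medium,
                 metric = metric, add = add, value = value,
                 exceeds_threshold = value > threshold)
}

#' Carcinogenic risk
#'
#' `CR = ADD * SF`. The acceptability threshold is strict: a risk exactly at
#' 1e-4 classifies as acceptable.
#'
#' @param add Average daily dose (mg/kg/d).
#' @param sf Cancer slope factor ((kg d)/mg; 1.5 for As).
#' @param threshold Maximum acceptable risk (default 1e-4).
#' @param group,element,medium Optional labels carried into the result.
#' @return A tibble row: `metric = "CR"`, `value`, `exceeds_threshold`.
#' @export
carcinogenic_risk <- function(add, sf, threshold = 1e-4,
                              group = NA_character_, element = NA_character_,
                              medium = NA_character_) {
  if (any(add < 0) || sf <= 0) stop("add >= 0 and sf > 0 required", call. = FALSE)
  risk_result("CR", add * sf, threshold, group, element, medium, add)
}

#' Hazard quotient
#'
#' `HQ = ADD / RfD`; values above 1 flag non-carcinogenic concern (strict
#' inequality).
#'
#' @param add Average daily dose (mg/kg/d).
#' @param rfd Reference dose (mg/kg/d; 0.0003 for Hg).
#' @param threshold Acceptability threshold (default 1).
#' @param group,element,medium Optional labels.
#' @return A tibble row: `metric = "HQ"`.
#' @export
hazard_quotient <- function(add, rfd, threshold = 1,
                            group = NA_character_, element = NA_character_,
                            medium = NA_character_) {
  if (rfd <= 0) stop("rfd must be positive", call. = FALSE)
  if (any(add < 0)) stop("add must be non-negative", call. = FALSE)
  risk_result("HQ", add / rfd, threshold, group, element, medium, add)
}

#' Hazard index
#'
#' Sum of hazard quotients across elements/routes; here the non-carcinogenic
#' burden is Hg-only, so HI usually equals the single Hg HQ.
#'
#' @param hqs Numeric vector of HQ values, or a tibble from
#'   [hazard_quotient()].
#' @param threshold Acceptability threshold (default 1).
#' @param group,medium Optional labels.
#' @return A tibble row: `metric = "HI"`.
#' @export
hazard_index <- function(hqs, threshold = 1,
                         group = NA_character_, medium = NA_character_) {
  v <- if (is.data.frame(hqs)) hqs$value else hqs
  if (length(v) == 0) stop("at least one HQ is required", call. = FALSE)
  risk_result("HI", sum(v), threshold, group, NA_character_, medium)
}

#' Classify a risk result against its threshold
#'
#' CR is judged against the maximum acceptable carcinogenic risk (1e-4):
#' `"acceptable"` / `"unacceptable"`. HQ and HI against 1: `"negligible"` /
#' `"non-carcinogenic risk"`. Thresholds are strict inequalities.
#'
#' @param result A tibble from [carcinogenic_risk()], [hazard_quotient()] or
#'   [hazard_index()].
#' @param cr_threshold,hq_threshold Classification thresholds.
#' @return Character labels, one per row.
#' @export
classify_risk <- function(result, cr_threshold = 1e-4, hq_threshold = 1) {
  stopifnot(all(result$metric %in% c("CR", "HQ", "HI")))
  ifelse(result$metric == "CR",
         ifelse(result$value > cr_threshold, "unacceptable", "acceptable"),
         ifelse(result$value > hq_threshold, "non-carcinogenic risk",
                "negligible"))
}

#' Deterministic risk table over groups, elements and media
#'
#' Computes CR (As, carcinogenic) and HQ/HI (Hg, non-carcinogenic) for each
#' group and medium from mean concentrations, reproducing the layout of the
#' published deterministic risk table.
#'
#' @param means A validated measurement tibble of mean concentrations (one
#'   row per element and medium; ice and water rows are used).
#' @param config Assessment configuration (see [load_config()]).
#' @param groups Population groups to evaluate.
#' @return A tibble with columns `group`, `element`, `medium`, `metric`,
#'   `add`, `value`, `exceeds_threshold`, `class`.
#' @export
risk_table <- function(means, config = load_config(),
                       groups = c("adult", "child")) {
  m <- validate_measurements(means)
  m <- m[m$medium %in% c("ice", "water"), ]
  rows <- list()
  for (g in groups) {
    det <- config$deterministic_exposure[[if (g == "child") "child" else g]]
    p <- exposure_parameters(g, IR = det$IR, EF = det$EF, BW = det$BW,
                             ED_carcinogenic = det$ED_carcinogenic,
                             ED_noncarcinogenic = det$ED_noncarcinogenic,
                             AT_carcinogenic = det$AT_carcinogenic,
                             AT_noncarcinogenic = det$AT_noncarcinogenic)
    for (i in seq_len(nrow(m))) {
      el <- m$element[i]
      c_mg_L <- convert_concentration(m$concentration[i], m$unit[i], "mg/L")
      if (el == "As") {
        add <- average_daily_dose(c_mg_L, p, "carcinogenic")
        rows[[length(rows) + 1]] <- carcinogenic_risk(
          add, config$toxicity$sf_kg_d_mg$As,
          threshold = config$thresholds$cr_acceptable,
          group = g, element = el, medium = m$medium[i])
      } else if (el == "Hg") {
        add <- average_daily_dose(c_mg_L, p, "noncarcinogenic")
        hq <- hazard_quotient(add, config$toxicity$rfd_mg_kg_d$Hg,
                              threshold = config$thresholds$hq_acceptable,
                              group = g, element = el, medium = m$medium[i])
        hi <- hazard_index(hq, threshold = config$thresholds$hq_acceptable,
                           group = g, medium = m$medium[i])
        rows[[length(rows) + 1]] <- hq
        rows[[length(rows) + 1]] <- hi
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$class <- classify_risk(out, cr_threshold = config$thresholds$cr_acceptable,
                             hq_threshold = config$thresholds$hq_acceptable)
  out
}
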