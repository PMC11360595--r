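# Class scales. Each classifier is a pure function of the index value so that
# labels can always be re-derived from stored values (no label drift).

pi_class <- function(value) {
  ifelse(value < 1, "clean",
    ifelse(value < 2, "slight pollution",
      ifelse(value < 3, "moderate pollution", "severe pollution")))
}

# Seven classes on half-open intervals, lower bound inclusive above the first:
# (-Inf,0], (0,1), [1,2), [2,3), [3,4), [4,5), [5,Inf)
igeo_class <- function(value) {
  labels <- c("no pollution", "mild pollution", "partial moderate pollution",
              "moderate pollution", "heavy pollution", "severe pollution",
              "extremely severe pollution")
  # exactly 0 stays in the first class; above it the lower bound is inclusive
  idx <- ifelse(value <= 0, 1L, pmin(floor(value), 5) + 2L)
  labels[idx]
}

# Contiguous RAC scale: [0,1) no risk, [1,10] low, (10,30] medium,
# (30,50] high, (50,100] extremely high.
rac_class <- function(percent) {
  ifelse(percent < 1, "no risk",
    ifelse(percent <= 10, "low risk",
      ifelse(percent <= 30, "medium risk",
        ifelse(percent <= 50, "high risk", "extremely high risk"))))
}

#' Single-factor pollution index
#'
#' Ratio of a measured water concentration to its regulatory standard,
#' `Pi = Ci / Si`, classified as clean (< 1), slight (1 to < 2), moderate
#' (2 to < 3) or severe pollution (>= 3). Both concentrations must be in the
#' same unit (conventionally ug/L against the irrigation-water limit).
#'
#' @param ci Measured concentration (ug/L), non-negative.
#' @param si Standard value (ug/L), positive.
#' @param element,site_id Optional labels carried into the result.
#' @return A tibble with columns `index`, `value`, `class`, plus any labels.
#' @examples
#' single_factor_index(5.72, 50)   # 0.1144, clean
#' @export
single_factor_index <- function(ci, si, element = NA_character_,
                                site_id = NA_character_) {
  if (any(si <= 0)) stop("standard value si must be positive", call. = FALSE)
  if (any(ci < 0)) stop("concentration ci must be non-negative", call. = FALSE)
  value <- ci / si
  tibble::tibble(index = "Pi", site_id = site_id, element = element,
                 value = value, class = pi_class(value))
}

#' Geo-accumulation index
#'
#' `Igeo = log2(Cn / (K * Bn))` with background value `Bn` and the
#' natural-fluctuation constant `K` (default 1.5). Classified on seven levels
#' from no pollution (`Igeo <= 0`) to extremely severe (`Igeo >= 5`).
#' A zero concentration has no finite log: it is an error unless
#' `zero_as_below_scale = TRUE`, in which case the value is `-Inf` with the
#' lowest class.
#'
#' @param cn Measured sediment concentration (mg/kg), positive.
#' @param bn Background value (mg/kg), positive.
#' @param k Background-fluctuation constant, positive (default 1.5).
#' @param element,site_id Optional labels.
#' @param zero_as_below_scale Opt-in sentinel handling for `cn = 0`.
#' @return A tibble with columns `index`, `value`, `class`.
#' @examples
#' geo_accumulation_index(0.075, 0.025)  # log2(2) = 1, partial moderate
#' @export
geo_accumulation_index <- function(cn, bn, k = 1.5, element = NA_character_,
                                   site_id = NA_character_,
                                   zero_as_below_scale = FALSE) {
  if (any(bn <= 0) || k <= 0) stop("bn and k must be positive", call. = FALSE)
  if (any(cn < 0)) stop("cn must be non-negative", call. = FALSE)
  if (any(cn == 0) && !zero_as_below_scale) {
    stop("cn = 0 has undefined Igeo; set zero_as_below_scale = TRUE to get -Inf",
         call. = FALSE)
  }
  value <- log2(cn / (k * bn))
  tibble::tibble(index = "Igeo", site_id = site_id, element = element,
                 value = value, class = igeo_class(value))
}

#' Risk assessment code from BCR speciation
#'
#' Percentage of the metal's total sediment burden held in the
#' acid-extractable F1 fraction, `RAC = 100 * F1 / (F1+F2+F3+F4)`; a proxy
#' for mobility and bioavailability. Classes: no risk (< 1%), low (1-10%),
#' medium (> 10-30%), high (> 30-50%), extremely high (> 50%).
#'
#' @param spec A validated speciation tibble (columns `f1`..`f4`; label
#'   columns are carried through).
#' @return A tibble with columns `index`, `value` (percent), `class`.
#' @export
risk_assessment_code <- function(spec) {
  spec <- validate_speciation(spec)
  total <- spec$f1 + spec$f2 + spec$f3 + spec$f4
  value <- 100 * spec$f1 / total
  tibble::tibble(index = "RAC",
                 site_id = spec$site_id, element = spec$element,
                 depth_top_cm = spec$depth_top_cm,
                 depth_bottom_cm = spec$depth_bottom_cm,
                 value = value, class = rac_class(value))
}

#' Classify a RAC percentage
#' @param percent RAC value(s) in percent.
#' @return Character class labels.
#' @export
classify_rac <- function(percent) rac_class(percent)

#' Sediment quality guideline classification
#'
#' Compares a sediment concentration with the Threshold Effect Level and the
#' Probable Effect Level. Values equal to either bound fall in the middle
#' class (biotoxic effects occur occasionally between TEL and PEL, bounds
#' included).
#'
#' @param c Sediment concentration (mg/kg).
#' @param tel,pel Guideline thresholds (mg/kg), `0 < tel < pel`.
#' @return Character labels: `"rare biotoxic effects"`,
#'   `"occasional biotoxic effects"` or `"frequent biotoxic effects"`.
#' @examples
#' sqg_classify(0.035, 0.17, 0.48)  # rare biotoxic effects
#' @export
sqg_classify <- function(c, tel, pel) {
  stopifnot(tel > 0, tel < pel)
  ifelse(c < tel, "rare biotoxic effects",
    ifelse(c <= pel, "occasional biotoxic effects",
           "frequent biotoxic effects"))
}

#' Summarise per-layer RAC values
#'
#' Arithmetic mean, range, and the fraction of layers in each risk class.
#'
#' @param rac A tibble with columns `value` (or `rac_percent`) in percent.
#' @return A list with `mean`, `min`, `max` and `class_fractions` (named
#'   numeric, proportions in class order).
#' @export
summarize_rac <- function(rac) {
  v <- if ("value" %in% names(rac)) rac$value else rac$rac_percent
  if (is.null(v) || length(v) == 0) stop("no RAC values to summarise", call. = FALSE)
  cls <- factor(rac_class(v),
                levels = c("no risk", "low risk", "medium risk",
                           "high risk", "extremely high risk"))
  list(mean = mean(v), min = min(v), max = max(v),
       class_fractions = prop.table(table(cls)))
}

#' Per-layer pollution index table
#'
#' Batch entry point: computes the single-factor index for water records, the
#' geo-accumulation index for sediment records, and the RAC for speciation
#' records, returning one long table of per-layer index values with classes.
#'
#' @param measurements Validated measurement tibble (water rows feed Pi,
#'   sediment rows feed Igeo; ice rows are assessed against the same water
#'   standard when `include_ice = TRUE`).
#' @param speciation Optional validated speciation tibble for RAC.
#' @param standards Output of [default_standards()].
#' @param include_ice Score melted-ice concentrations against the water
#'   standard as well (default TRUE).
#' @return A tibble with columns `index`, `site_id`, `element`, `medium`,
#'   `depth_top_cm`, `depth_bottom_cm`, `value`, `class`.
#' @export
compute_indices <- function(measurements, speciation = NULL,
                            standards = default_standards(),
                            include_ice = TRUE) {
  m <- validate_measurements(measurements)
  st <- standards$table
  out <- list()

  aqueous_media <- if (include_ice) c("water", "ice") else "water"
  aq <- m[m$medium %in% aqueous_media, ]
  if (nrow(aq) > 0) {
    si <- st$si_ug_L[match(aq$element, st$element)]
    ci <- convert_concentration(aq$concentration, aq$unit, "ug/L")
    out$pi <- dplyr::mutate(
      single_factor_index(ci, si, element = aq$element, site_id = aq$site_id),
      medium = aq$medium, depth_top_cm = aq$depth_top_cm,
      depth_bottom_cm = aq$depth_bottom_cm)
  }

  sed <- m[m$medium == "sediment" & m$concentration > 0, ]
  if (nrow(sed) > 0) {
    bn <- st$bn_mg_kg[match(sed$element, st$element)]
    out$igeo <- dplyr::mutate(
      geo_accumulation_index(sed$concentration, bn, k = standards$k,
                             element = sed$element, site_id = sed$site_id),
      medium = "sediment", depth_top_cm = sed$depth_top_cm,
      depth_bottom_cm = sed$depth_bottom_cm)
  }

  if (!is.null(speciation) && nrow(speciation) > 0) {
    out$rac <- dplyr::mutate(risk_assessment_code(speciation),
                             medium = "sediment")
  }

  cols <- c("index", "site_id", "element", "medium",
            "depth_top_cm", "depth_bottom_cm", "value", "class")
  dplyr::select(dplyr::bind_rows(out), dplyr::all_of(cols))
}
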