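# Domain vocabularies are closed: anything outside them is rejected at the
# boundary rather than carried through the pipeline.
fr_elements <- c("Hg", "As")
fr_media <- c("ice", "water", "sediment")
fr_units <- c("ng/L", "ug/L", "mg/L", "mg/kg")

# multiplicative factor to mg/L for the mass-per-volume units
fr_to_mg_L <- c("ng/L" = 1e-6, "ug/L" = 1e-3, "mg/L" = 1)

#' Normalise a concentration unit string
#'
#' Accepts the micro sign or the ASCII "u" spelling and returns the canonical
#' ASCII form used throughout the package.
#'
#' @param unit Character vector of unit strings.
#' @return Character vector with units in canonical form
#'   (`"ng/L"`, `"ug/L"`, `"mg/L"`, `"mg/kg"`).
#' @export
normalize_unit <- function(unit) {
  u <- gsub("µ|μ", "u", unit)
  bad <- !u %in% fr_units
  if (any(bad)) {
    stop("unknown unit(s): ", paste(unique(unit[bad]), collapse = ", "),
         call. = FALSE)
  }
  u
}

#' Convert a concentration between mass-per-volume units
#'
#' Exact decimal scaling between ng/L, ug/L and mg/L. Mass-per-mass sediment
#' units (mg/kg) have no volume basis and cannot be converted to or from the
#' per-litre units; asking for such a conversion is an error, never a silent
#' pass-through.
#'
#' @param value Numeric vector of concentrations.
#' @param from,to Unit strings (micro sign or "u" spelling both accepted).
#' @return Numeric vector in the target unit.
#' @examples
#' convert_concentration(2.34, "ug/L", "mg/L")  # 0.00234
#' convert_concentration(7.90, "ng/L", "mg/L")  # 7.9e-06
#' @export
convert_concentration <- function(value, from, to) {
  from <- normalize_unit(from)
  to <- normalize_unit(to)
  if (any(from == "mg/kg") || any(to == "mg/kg")) {
    if (all(from == to)) return(value)
    stop("cannot convert between mg/kg and per-litre units", call. = FALSE)
  }
  value * unname(fr_to_mg_L[from]) / unname(fr_to_mg_L[to])
}

#' Construct validated measurement records
#'
#' One record holds a single concentration at (site, medium, depth layer,
#' element). Depth layers are `[top, bottom)` intervals in cm measured downward
#' from the medium's upper surface. Units must be consistent with the medium:
#' sediment concentrations are mg/kg, ice and water concentrations are
#' per-litre.
#'
#' @param site_id Character site labels (e.g. "J13").
#' @param medium One of `"ice"`, `"water"`, `"sediment"`.
#' @param depth_top_cm,depth_bottom_cm Layer bounds in cm, `bottom > top >= 0`.
#' @param element `"Hg"` or `"As"`.
#' @param concentration Non-negative numeric.
#' @param unit Concentration unit, `"mg/kg"` iff medium is sediment.
#' @return A tibble with one row per record.
#' @export
measurement_record <- function(site_id, medium, depth_top_cm, depth_bottom_cm,
                               element, concentration, unit) {
  rec <- tibble::tibble(
    site_id = as.character(site_id),
    medium = as.character(medium),
    depth_top_cm = as.numeric(depth_top_cm),
    depth_bottom_cm = as.numeric(depth_bottom_cm),
    element = as.character(element),
    concentration = as.numeric(concentration),
    unit = normalize_unit(as.character(unit))
  )
  validate_measurements(rec)
}

fail_rows <- function(what, rows) {
  stop(what, " at row(s) ", paste(utils::head(rows, 10), collapse = ", "),
       call. = FALSE)
}

#' Validate a measurement table
#'
#' Checks the closed element/medium/unit vocabularies, depth ordering,
#' non-negative concentrations, and medium/unit consistency. Errors name the
#' offending row numbers.
#'
#' @param x A data frame in the measurement schema.
#' @return The validated table (invisibly unchanged), as a tibble.
#' @export
validate_measurements <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("site_id", "medium", "depth_top_cm", "depth_bottom_cm",
                "element", "concentration", "unit")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("measurement table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x$unit <- normalize_unit(x$unit)
  if (any(bad <- !x$medium %in% fr_media)) fail_rows("unknown medium", which(bad))
  if (any(bad <- !x$element %in% fr_elements)) fail_rows("unknown element", which(bad))
  if (any(bad <- is.na(x$concentration) | x$concentration < 0)) {
    fail_rows("negative or missing concentration", which(bad))
  }
  if (any(bad <- is.na(x$depth_top_cm) | x$depth_top_cm < 0)) {
    fail_rows("negative depth_top_cm", which(bad))
  }
  if (any(bad <- !(x$depth_bottom_cm > x$depth_top_cm))) {
    fail_rows("depth_bottom_cm must exceed depth_top_cm", which(bad))
  }
  sediment_unit <- x$unit == "mg/kg"
  if (any(bad <- sediment_unit != (x$medium == "sediment"))) {
    fail_rows("unit inconsistent with medium (mg/kg iff sediment)", which(bad))
  }
  x
}

#' Read a measurement file
#'
#' Comma-delimited UTF-8 text with header
#' `site_id,medium,depth_top_cm,depth_bottom_cm,element,concentration,unit`.
#'
#' @param path File path.
#' @param medium Optional: restrict/verify that all rows belong to one medium.
#' @return A validated tibble of measurement records.
#' @export
read_measurements <- function(path, medium = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         site_id = readr::col_character(),
                         medium = readr::col_character(),
                         depth_top_cm = readr::col_double(),
                         depth_bottom_cm = readr::col_double(),
                         element = readr::col_character(),
                         concentration = readr::col_double(),
                         unit = readr::col_character()
                       ))
  if (nrow(x) == 0) stop("empty measurement file: ", path, call. = FALSE)
  x <- validate_measurements(x)
  if (!is.null(medium)) {
    medium <- match.arg(medium, fr_media)
    if (any(bad <- x$medium != medium)) {
      fail_rows(paste0("expected medium '", medium, "'"), which(bad))
    }
  }
  x
}

#' Write a measurement table
#' @param x Validated measurement tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(x, path) {
  readr::write_csv(validate_measurements(x), path)
  invisible(path)
}

#' Construct validated speciation records
#'
#' BCR sequential-extraction fractions for one sediment layer and element:
#' acid-extractable (F1), Fe/Mn-oxide-bound (F2), organic/sulfide-bound (F3)
#' and residual (F4) masses in mg/kg.
#'
#' @param site_id,depth_top_cm,depth_bottom_cm,element As in
#'   [measurement_record()].
#' @param f1,f2,f3,f4 Non-negative fraction masses (mg/kg); their sum must be
#'   positive.
#' @return A tibble with one row per record.
#' @export
speciation_record <- function(site_id, depth_top_cm, depth_bottom_cm, element,
                              f1, f2, f3, f4) {
  rec <- tibble::tibble(
    site_id = as.character(site_id),
    depth_top_cm = as.numeric(depth_top_cm),
    depth_bottom_cm = as.numeric(depth_bottom_cm),
    element = as.character(element),
    f1 = as.numeric(f1), f2 = as.numeric(f2),
    f3 = as.numeric(f3), f4 = as.numeric(f4)
  )
  validate_speciation(rec)
}

#' Validate a speciation table
#' @param x Data frame in the speciation schema.
#' @return The validated tibble.
#' @export
validate_speciation <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("site_id", "depth_top_cm", "depth_bottom_cm", "element",
                "f1", "f2", "f3", "f4")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("speciation table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(bad <- !x$element %in% fr_elements)) fail_rows("unknown element", which(bad))
  fr <- as.matrix(x[, c("f1", "f2", "f3", "f4")])
  if (any(bad <- apply(fr, 1, function(v) any(is.na(v) | v < 0)))) {
    fail_rows("negative or missing fraction", which(bad))
  }
  if (any(bad <- rowSums(fr) <= 0)) fail_rows("all-zero fractions", which(bad))
  if (any(bad <- !(x$depth_bottom_cm > x$depth_top_cm))) {
    fail_rows("depth_bottom_cm must exceed depth_top_cm", which(bad))
  }
  x
}

#' Read a speciation file
#'
#' Comma-delimited text with header
#' `site_id,depth_top_cm,depth_bottom_cm,element,f1,f2,f3,f4`.
#'
#' @param path File path.
#' @return A validated speciation tibble.
#' @export
read_speciation <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         site_id = readr::col_character(),
                         element = readr::col_character(),
                         .default = readr::col_double()
                       ))
  if (nrow(x) == 0) stop("empty speciation file: ", path, call. = FALSE)
  validate_speciation(x)
}

#' Write a speciation table
#' @param x Validated speciation tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_speciation <- function(x, path) {
  readr::write_csv(validate_speciation(x), path)
  invisible(path)
}

#' Packaged per-layer risk assessment code values
#'
#' The published per-layer RAC percentages (the share of the acid-extractable
#' F1 fraction in the total metal burden) for 10 sediment cores: 32 layers per
#' element. Missing layers (cores shorter than 25 cm) are absent rows, not
#' zeros. Depth labels are the bottoms of 5-cm slices.
#'
#' @return A tibble with columns `site_id`, `depth_cm`, `element`,
#'   `rac_percent`.
#' @export
load_rac_fixture <- function() {
  path <- system.file("extdata", "table5_rac.csv", package = "frozenrisk")
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    site_id = readr::col_character(),
                    depth_cm = readr::col_double(),
                    element = readr::col_character(),
                    rac_percent = readr::col_double()
                  ))
}

#' Packaged published mean concentrations
#'
#' Two variants are carried as named fixtures and neither is "corrected":
#' `"distribution"` holds the arithmetic means of the fitted concentration
#' distributions used by the probabilistic model (Hg ice 7.90 ng/L, As ice
#' 2.48 ug/L, Hg water 0.37 ug/L, As water 5.72 ug/L); `"observed"` holds the
#' reported observed averages (Hg ice 8.20 ng/L, As ice 2.34 ug/L, Hg water
#' 0.36 ug/L, As water 5.72 ug/L, plus sediment means Hg 0.035 and As 7.47
#' mg/kg). The two disagree slightly for ice Hg/As and water Hg.
#'
#' @param source `"distribution"` or `"observed"`.
#' @return A validated measurement tibble.
#' @export
printed_means <- function(source = c("distribution", "observed")) {
  source <- match.arg(source)
  f <- paste0("printed_means_", source, ".csv")
  read_measurements(system.file("extdata", f, package = "frozenrisk"))
}

#' Default standards table
#'
#' Per element: the irrigation-water quality limit Si (ug/L), the regional
#' sediment background Bn (mg/kg), and the TEL/PEL sediment quality guideline
#' thresholds (mg/kg), plus the background-fluctuation constant K = 1.5 used
#' by the geo-accumulation index.
#'
#' @param path Optional YAML config; defaults to the packaged configuration.
#' @return A list with elements `table` (tibble: element, si_ug_L, bn_mg_kg,
#'   tel_mg_kg, pel_mg_kg) and `k` (numeric).
#' @export
default_standards <- function(path = NULL) {
  cfg <- load_config(path)
  st <- cfg$standards
  tab <- dplyr::bind_rows(lapply(fr_elements, function(el) {
    tibble::tibble(element = el,
                   si_ug_L = st[[el]]$si_ug_L,
                   bn_mg_kg = st[[el]]$bn_mg_kg,
                   tel_mg_kg = st[[el]]$tel_mg_kg,
                   pel_mg_kg = st[[el]]$pel_mg_kg)
  }))
  stopifnot(all(tab$si_ug_L > 0), all(tab$bn_mg_kg > 0),
            all(tab$tel_mg_kg > 0), all(tab$tel_mg_kg < tab$pel_mg_kg))
  list(table = tab, k = st$k_background)
}

#' Load the assessment configuration
#'
#' Reads the structured key-value document holding standards, toxicity
#' values, risk thresholds, deterministic exposure factors, and the
#' probability distributions of the Monte Carlo exposure model.
#'
#' @param path YAML file; `NULL` for the packaged default.
#' @return A nested list mirroring the YAML document.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yml", package = "frozenrisk")
  }
  yaml::read_yaml(path)
}
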