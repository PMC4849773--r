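#' Clinical variable specifications
#'
#' Returns the shipped specification table for systemic and brain physiologic
#' channels: measurement units, hard plausibility bounds, and the clinically
#' accepted normal range used to discretize each channel into ordinal states.
#' Normal ranges follow published recommendations and expert consensus for
#' neurocritical-care monitoring (e.g. heart rate 60--80 bpm, intracranial
#' pressure below 20 mmHg, cerebral perfusion pressure 60--90 mmHg).
#'
#' One-sided ranges (e.g. ICP `< 20`, SPO2 `> 89`) yield exactly two ordinal
#' states; two-sided ranges yield LOW/NORMAL/HIGH. A channel with no normal
#' range at all (brain water content TW%) is discretized by patient-phase
#' tertiles, flagged in the output of [bin_record()].
#'
#' Plausibility bounds are shipped defaults, not literature values: hard
#' physical limits outside which a monitor reading is treated as artifact.
#' Override any row via `read_variable_specs()` or ordinary data-frame edits.
#'
#' @param microdialysis Include hourly microdialysis channels (interstitial
#'   lactate, pyruvate, glucose, lactate-pyruvate ratio). Default `TRUE`.
#' @return A tibble with columns `variable`, `units`, `plausibility_low`,
#'   `plausibility_high`, `normal_low`, `normal_high`, `microdialysis`.
#' @examples
#' variable_specs()
#' @export
variable_specs <- function(microdialysis = TRUE) {
  s <- tibble::tribble(
    ~variable, ~units, ~plausibility_low, ~plausibility_high, ~normal_low, ~normal_high, ~microdialysis,
    "TMP",     "degC",            30,   43,   36.5, 38.5, FALSE,
    "RR",      "cycles/min",       0,   60,   10,   18,   FALSE,
    "MV",      "L/min",            0,   30,    5,    8,   FALSE,
    "CO2EX",   "mmHg",             5,  150,   35,   45,   FALSE,
    "SPO2",    "%",                0,  100,   89,   NA,   FALSE,
    "HR",      "beats/min",       20,  250,   60,   80,   FALSE,
    "MAP",     "mmHg",            20,  250,   70,  110,   FALSE,
    "CVP",     "mmHg",            -5,   50,    2,    6,   FALSE,
    "CI",      "L/min/m2",       0.5,   15,  2.4,    4,   FALSE,
    "SVV",     "%",                0,   50,   NA,   12,   FALSE,
    "ELWI",    "ml/kg",            0,   30,    3,    7,   FALSE,
    "GEDI",    "ml/m2",          200, 2000,  680,  800,   FALSE,
    "ICP",     "mmHg",             0,  150,   NA,   20,   FALSE,
    "CPP",     "mmHg",             0,  200,   60,   90,   FALSE,
    "pbtO2",   "mmHg",             0,  150,   15,   NA,   FALSE,
    "rCBF",    "ml/100g/min",      0,  200,   35,   NA,   FALSE,
    "TW%",     "%",                0,  100,   NA,   NA,   FALSE,
    "BrT",     "degC",            30,   43,   36.5, 37.5, FALSE,
    "SjVo2",   "%",                0,  100,   50,   75,   FALSE,
    "lactate", "mmol/L",           0,   20,  2.7,  3.3,   TRUE,
    "pyruvate","umol/L",           0, 1000,   NA,   NA,   TRUE,
    "glucose", "mmol/L",           0,   20,  1.9,  2.3,   TRUE,
    "LPR",     "ratio",            0,  200,   NA,   40,   TRUE
  )
  if (!microdialysis) s <- dplyr::filter(s, !.data$microdialysis)
  validate_specs(s)
}

#' Read or write a variable-specification table as YAML
#'
#' @param path Path to a YAML file whose top level is a list of channel
#'   entries with fields matching the columns of [variable_specs()]. The
#'   shipped defaults live at
#'   `system.file("extdata", "variable_specs.yaml", package = "neurocausal")`.
#' @return `read_variable_specs()` returns a validated spec tibble;
#'   `write_variable_specs()` returns `path` invisibly.
#' @seealso [variable_specs()]
#' @examples
#' read_variable_specs(
#'   system.file("extdata", "variable_specs.yaml", package = "neurocausal")
#' )
#' @export
read_variable_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  s <- purrr::map_dfr(raw, function(x) {
    tibble(
      variable = x$variable,
      units = x$units %||% NA_character_,
      plausibility_low = as.numeric(x$plausibility_low),
      plausibility_high = as.numeric(x$plausibility_high),
      normal_low = as.numeric(x$normal_low %||% NA),
      normal_high = as.numeric(x$normal_high %||% NA),
      microdialysis = isTRUE(x$microdialysis)
    )
  })
  validate_specs(s)
}

#' @rdname read_variable_specs
#' @param specs A spec tibble as returned by [variable_specs()].
#' @export
write_variable_specs <- function(specs, path) {
  specs <- validate_specs(specs)
  entries <- purrr::pmap(specs, function(...) {
    x <- list(...)
    x[!vapply(x, function(v) is.na(v) %in% TRUE, logical(1))]
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

# Enforce the spec-table invariants: plausibility_low < plausibility_high and
# the normal range nested inside the plausibility bounds.
validate_specs <- function(specs) {
  stopifnot(is.data.frame(specs), "variable" %in% names(specs))
  if (anyDuplicated(specs$variable)) {
    stop("duplicate variable names in specification table", call. = FALSE)
  }
  bad <- specs$plausibility_low >= specs$plausibility_high
  if (any(bad, na.rm = TRUE)) {
    stop("plausibility_low must be < plausibility_high for: ",
      paste(specs$variable[which(bad)], collapse = ", "),
      call. = FALSE
    )
  }
  nl <- specs$normal_low
  nh <- specs$normal_high
  nested <- (is.na(nl) | (nl >= specs$plausibility_low & nl <= specs$plausibility_high)) &
    (is.na(nh) | (nh >= specs$plausibility_low & nh <= specs$plausibility_high)) &
    (is.na(nl) | is.na(nh) | nl < nh)
  if (any(!nested)) {
    stop("normal range must be nested within plausibility bounds for: ",
      paste(specs$variable[!nested], collapse = ", "),
      call. = FALSE
    )
  }
  as_tibble(specs)
}

# States achievable for one spec row.
spec_states <- function(normal_low, normal_high) {
  if (is.na(normal_low) && is.na(normal_high)) {
    return(c("LOW", "NORMAL", "HIGH")) # tertile-binned channel
  }
  out <- "NORMAL"
  if (!is.na(normal_low)) out <- c("LOW", out)
  if (!is.na(normal_high)) out <- c(out, "HIGH")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
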