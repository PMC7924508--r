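#' Declare a feature schema for a risk-factor table
#'
#' A schema states, for every raw column, how it is typed and therefore how it
#' is encoded into the numeric feature space:
#'
#' * `"integer"` — a numeric answer kept as one feature;
#' * `"boolean"` — a yes/no answer kept as one 0/1 feature;
#' * `"categorical"` — encoded as a one-of-K indicator block over `levels`;
#' * `"bool_integer"`, `"bool_boolean"` — an answerable question encoded as an
#'   answered-flag feature (1 = the patient answered) followed by the value
#'   itself. Refusals ("?") give flag 0 and a missing value that is later
#'   mean-imputed; the flag is kept because refusal itself can carry risk
#'   signal.
#'
#' @param columns Character vector of column names.
#' @param types Character vector of the same length with one of the five type
#'   tags above per column.
#' @param levels Named list mapping each categorical column to its non-empty
#'   character vector of levels (declared order fixes the indicator order).
#' @return A `feature_schema` tibble with columns `column`, `type`, `levels`.
#' @examples
#' feature_schema(c("Age", "Smokes"), c("integer", "bool_boolean"))
#' @export
feature_schema <- function(columns, types, levels = list()) {
  valid <- c("integer", "boolean", "categorical", "bool_integer", "bool_boolean")
  if (length(columns) != length(types)) {
    abort("`columns` and `types` must have the same length.")
  }
  if (anyDuplicated(columns)) {
    abort("Schema column names must be unique.")
  }
  bad <- setdiff(types, valid)
  if (length(bad) > 0) {
    abort(paste0("Unknown schema type(s): ", paste(bad, collapse = ", ")))
  }
  lev <- vector("list", length(columns))
  for (i in seq_along(columns)) {
    if (types[i] == "categorical") {
      l <- levels[[columns[i]]]
      if (is.null(l) || length(l) == 0) {
        abort(paste0("Categorical column '", columns[i],
                     "' needs a non-empty level set."))
      }
      lev[[i]] <- as.character(l)
    }
  }
  out <- tibble::tibble(column = as.character(columns),
                        type = as.character(types),
                        levels = lev)
  class(out) <- c("feature_schema", class(out))
  out
}

#' Default schema for the cervical-cancer risk-factor table
#'
#' Schema for the 858-patient questionnaire dialect: age and sexual/obstetric
#' history, smoking, contraception, IUD use, STD history and prior cervical
#' diagnoses. Questions a patient can decline (number of partners, first
#' intercourse, pregnancies, smoking, contraceptives, IUD, STDs) are typed
#' `bool_*` so refusals become answered-flag features. The four screening /
#' biopsy outcome columns (`Hinselmann`, `Schiller`, `Citology`, `Biopsy`) are
#' targets, not features, and are not part of this schema.
#'
#' @return A `feature_schema` tibble.
#' @export
default_risk_schema <- function() {
  cols <- c(
    "Age",                                 "integer",
    "Number of sexual partners",           "bool_integer",
    "First sexual intercourse",            "bool_integer",
    "Num of pregnancies",                  "bool_integer",
    "Smokes",                              "bool_boolean",
    "Smokes (years)",                      "integer",
    "Smokes (packs/year)",                 "integer",
    "Hormonal Contraceptives",             "bool_boolean",
    "Hormonal Contraceptives (years)",     "integer",
    "IUD",                                 "bool_boolean",
    "IUD (years)",                         "integer",
    "STDs",                                "bool_boolean",
    "STDs (number)",                       "integer",
    "STDs:condylomatosis",                 "boolean",
    "STDs:cervical condylomatosis",        "boolean",
    "STDs:vaginal condylomatosis",         "boolean",
    "STDs:vulvo-perineal condylomatosis",  "boolean",
    "STDs:syphilis",                       "boolean",
    "STDs:pelvic inflammatory disease",    "boolean",
    "STDs:genital herpes",                 "boolean",
    "STDs:molluscum contagiosum",          "boolean",
    "STDs:AIDS",                           "boolean",
    "STDs:HIV",                            "boolean",
    "STDs:Hepatitis B",                    "boolean",
    "STDs:HPV",                            "boolean",
    "STDs: Number of diagnosis",           "integer",
    "STDs: Time since first diagnosis",    "integer",
    "STDs: Time since last diagnosis",     "integer",
    "Dx:Cancer",                           "boolean",
    "Dx:CIN",                              "boolean",
    "Dx:HPV",                              "boolean",
    "Dx",                                  "boolean"
  )
  m <- matrix(cols, ncol = 2, byrow = TRUE)
  feature_schema(m[, 1], m[, 2])
}

#' Column names of the screening / biopsy target variables
#' @return Character vector of the four binary outcome columns.
#' @export
risk_target_columns <- function() {
  c("Hinselmann", "Schiller", "Citology", "Biopsy")
}

encoded_width <- function(schema) {
  sum(vapply(seq_len(nrow(schema)), function(i) {
    switch(schema$type[i],
           integer = 1L, boolean = 1L,
           bool_integer = 2L, bool_boolean = 2L,
           categorical = length(schema$levels[[i]]))
  }, integer(1)))
}
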