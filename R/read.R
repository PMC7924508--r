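#' Read a risk-factor CSV
#'
#' Reads the comma-separated questionnaire dialect: one header row, `"?"` as
#' the missing marker, numeric/boolean/categorical cells otherwise. Every
#' schema column must be present; target columns (and any extra columns you
#' name in `keep`) are carried through untouched.
#'
#' @param path Path to the CSV file.
#' @param schema A [feature_schema()] describing the feature columns.
#' @param keep Additional column names to carry through verbatim (default: the
#'   four screening/biopsy targets that are present in the file).
#' @return A tibble with one row per record. Feature cells are typed per the
#'   schema with `NA` where the file had `"?"`; an attribute `"missing"`
#'   (logical matrix over schema columns) preserves which cells were `"?"`.
#' @export
read_risk_csv <- function(path, schema = default_risk_schema(), keep = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE,
                         show_col_types = FALSE)
  missing_cols <- setdiff(schema$column, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Schema mismatch: file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (is.null(keep)) keep <- intersect(risk_target_columns(), names(raw))
  parse_cell <- function(x, type, col) {
    miss <- x == "?"
    out <- rep(NA_real_, length(x))
    if (type %in% c("integer", "bool_integer")) {
      suppressWarnings(v <- as.numeric(x))
      bad <- which(!miss & is.na(v))
      if (length(bad) > 0) {
        abort(paste0("Parse error in column '", col, "', row ", bad[1],
                     ": cannot read '", x[bad[1]], "' as a number."))
      }
      out[!miss] <- v[!miss]
    } else if (type %in% c("boolean", "bool_boolean")) {
      v <- rep(NA_real_, length(x))
      v[x %in% c("1", "1.0", "TRUE", "true")] <- 1
      v[x %in% c("0", "0.0", "FALSE", "false")] <- 0
      bad <- which(!miss & is.na(v))
      if (length(bad) > 0) {
        abort(paste0("Parse error in column '", col, "', row ", bad[1],
                     ": cannot read '", x[bad[1]], "' as a boolean."))
      }
      out[!miss] <- v[!miss]
    }
    list(value = out, missing = miss)
  }
  n <- nrow(raw)
  out <- vector("list", nrow(schema))
  names(out) <- schema$column
  miss_mat <- matrix(FALSE, n, nrow(schema), dimnames = list(NULL, schema$column))
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    type <- schema$type[i]
    x <- raw[[col]]
    if (type == "categorical") {
      miss <- x == "?"
      lev <- schema$levels[[i]]
      bad <- which(!miss & !(x %in% lev))
      if (length(bad) > 0) {
        abort(paste0("Parse error in column '", col, "', row ", bad[1],
                     ": value '", x[bad[1]], "' is not a declared level."))
      }
      v <- x
      v[miss] <- NA_character_
      out[[i]] <- v
      miss_mat[, i] <- miss
    } else {
      p <- parse_cell(x, type, col)
      out[[i]] <- p$value
      miss_mat[, i] <- p$missing
    }
  }
  res <- tibble::as_tibble(out)
  for (k in keep) res[[k]] <- suppressWarnings(as.numeric(raw[[k]]))
  attr(res, "missing") <- miss_mat
  attr(res, "schema_columns") <- schema$column
  res
}
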