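new_feature_table <- function(values, missing_mask, answered_flags) {
  stopifnot(is.matrix(values), is.matrix(missing_mask),
            identical(dim(values), dim(missing_mask)),
            length(answered_flags) == ncol(values))
  structure(list(values = values,
                 feature_names = colnames(values),
                 missing_mask = missing_mask,
                 answered_flags = answered_flags,
                 n = nrow(values), d = ncol(values)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", x$n, " records x ", x$d, " encoded features\n", sep = "")
  cat("  missing cells: ", sum(x$missing_mask),
      "; answered-flag features: ", sum(x$answered_flags), "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) c(x$n, x$d)

#' @export
as.matrix.feature_table <- function(x, ...) x$values

#' Coerce a feature table to a tibble
#' @param x A `feature_table`.
#' @param ... Unused.
#' @return Tibble of the encoded numeric features, one row per record.
#' @method as_tibble feature_table
#' @export
as_tibble.feature_table <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$values, check.names = FALSE))
}

#' Encode raw records into the numeric feature space
#'
#' Applies the encoding step only — no imputation or scaling yet, so values
#' are still on their raw scales. Boolean-crossed (`bool_*`) columns become an
#' (answered-flag, value) pair; categorical columns become a one-of-K
#' indicator block in declared level order (a missing categorical cell gets an
#' all-zero block, its refusal being carried by the missing mask); plain
#' integer/boolean columns pass through. Original missingness is preserved in
#' the `missing_mask` so downstream imputation is reversible provenance-wise.
#'
#' @param raw A data frame of raw records (as from [read_risk_csv()]); `NA`
#'   marks a missing cell.
#' @param schema The [feature_schema()] used to type the columns.
#' @return A `feature_table`: encoded value matrix (missing values as `NA`
#'   except in categorical blocks), missing mask, and answered-flag markers.
#' @export
encode_features <- function(raw, schema = default_risk_schema()) {
  missing_cols <- setdiff(schema$column, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Schema mismatch: data lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(raw)
  cols <- list(); masks <- list(); flags <- logical(0)
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    type <- schema$type[i]
    x <- raw[[col]]
    if (type == "categorical") {
      lev <- schema$levels[[i]]
      x <- as.character(x)
      bad <- which(!is.na(x) & !(x %in% lev))
      if (length(bad) > 0) {
        abort(paste0("Encoding error in column '", col, "', row ", bad[1],
                     ": value '", x[bad[1]], "' outside the declared level set."))
      }
      block <- matrix(0, n, length(lev),
                      dimnames = list(NULL, paste0(col, "=", lev)))
      for (k in seq_along(lev)) block[!is.na(x) & x == lev[k], k] <- 1
      cols[[length(cols) + 1L]] <- block
      masks[[length(masks) + 1L]] <- matrix(rep(is.na(x), length(lev)), n)
      flags <- c(flags, rep(FALSE, length(lev)))
    } else if (type %in% c("bool_integer", "bool_boolean")) {
      x <- as.numeric(x)
      flag <- as.numeric(!is.na(x))
      pair <- cbind(flag, x)
      colnames(pair) <- c(paste0(col, "::answered"), col)
      cols[[length(cols) + 1L]] <- pair
      masks[[length(masks) + 1L]] <- cbind(rep(FALSE, n), is.na(x))
      flags <- c(flags, TRUE, FALSE)
    } else {
      x <- as.numeric(x)
      m <- matrix(x, n, 1, dimnames = list(NULL, col))
      cols[[length(cols) + 1L]] <- m
      masks[[length(masks) + 1L]] <- matrix(is.na(x), n)
      flags <- c(flags, FALSE)
    }
  }
  values <- do.call(cbind, cols)
  mask <- do.call(cbind, masks)
  colnames(mask) <- colnames(values)
  new_feature_table(values, mask, flags)
}
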