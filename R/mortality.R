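#' Read an age-indexed life table from CSV
#'
#' The file must have a header `age,qx` and one row per integer age with the
#' annual probability of death `qx` in `[0,1]`; ages must increase in steps of
#' one. A real national period life table (e.g. the German Federal Statistical
#' Office table, sex-averaged) can be exported to this format and supplied to
#' every engine; [gompertz_life_table()] generates a synthetic substitute.
#'
#' @param path CSV file path (`age,qx`, dot decimal separator, UTF-8).
#' @param source Optional source label stored as metadata; defaults to the
#'   file name.
#' @return A `strokecea_lifetable`: a data frame with columns `age` and `qx`
#'   and attributes `source` and `max_age`.
#' @export
read_life_table <- function(path, source = basename(path)) {
  if (!file.exists(path))
    stop("life-table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "qx") %in% names(df)))
    stop("life table must have columns 'age' and 'qx'", call. = FALSE)
  new_life_table(df$age, df$qx, source = source)
}

# Construct and validate a life table; row numbers refer to CSV data rows
# (header = row 1).
new_life_table <- function(age, qx, source = "unspecified") {
  if (!length(age)) stop("life table is empty", call. = FALSE)
  if (any(age != round(age)))
    stop("life-table ages must be integers (row ",
         which(age != round(age))[1] + 1, ")", call. = FALSE)
  d <- diff(age)
  if (any(d != 1)) {
    i <- which(d != 1)[1]
    stop("life-table ages must increase in steps of 1; problem at row ",
         i + 2, " (age ", age[i + 1], " after age ", age[i], ")",
         call. = FALSE)
  }
  bad <- which(qx < 0 | qx > 1 | !is.finite(qx))
  if (length(bad))
    stop("life-table qx out of [0,1] at row ", bad[1] + 1, " (age ",
         age[bad[1]], ", qx = ", qx[bad[1]], ")", call. = FALSE)
  structure(data.frame(age = as.integer(age), qx = as.numeric(qx)),
            source = source, max_age = max(age),
            class = c("strokecea_lifetable", "data.frame"))
}

#' Write a life table to CSV
#'
#' Inverse of [read_life_table()]; round-trips exactly.
#'
#' @param lt A `strokecea_lifetable`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "strokecea_lifetable"))
  utils::write.csv(data.frame(age = lt$age, qx = format(lt$qx, digits = 17)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Annual probability of death at a given age
#'
#' Looks up the tabulated `qx`. Beyond the last tabulated age the table is
#' extended geometrically, `qx_max * growth^(age - max_age)`, capped at 1 —
#' life tables typically end before the model horizon (age 110).
#'
#' @param lt A `strokecea_lifetable`.
#' @param age Age(s) in whole years (vectorized).
#' @param growth Annual geometric growth factor for the extension beyond the
#'   tabulated maximum age (default 1.1).
#' @return Probability (vector) of dying within the year at each `age`.
#' @export
#' @examples
#' lt <- gompertz_life_table(gompertz_spec())
#' annual_death_prob(lt, 72)
annual_death_prob <- function(lt, age, growth = 1.1) {
  stopifnot(inherits(lt, "strokecea_lifetable"))
  age <- floor(age)
  min_age <- lt$age[1]
  max_age <- attr(lt, "max_age")
  if (any(age < min_age))
    stop("age ", min(age), " below the tabulated minimum (", min_age, ")",
         call. = FALSE)
  idx <- pmin(age, max_age) - min_age + 1L
  q <- lt$qx[idx]
  over <- age > max_age
  if (any(over))
    q[over] <- pmin(1, lt$qx[length(lt$qx)] * growth^(age[over] - max_age))
  q
}

#' @export
print.strokecea_lifetable <- function(x, ...) {
  cat("<strokecea_lifetable> ages ", x$age[1], "-", attr(x, "max_age"),
      ", source: ", attr(x, "source"), "\n", sep = "")
  invisible(NextMethod())
}
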