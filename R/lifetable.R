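#' Construct a life table
#'
#' A life table maps integer age to the annual probability of all-cause
#' death `qx`. The Markov engine looks up background mortality by
#' attained age, so the table must cover every age from the cohort's
#' initial age to initial age + horizon.
#'
#' @param age Integer ages (consecutive not required, duplicates not
#'   allowed).
#' @param qx Annual death probabilities in \[0, 1\], one per age.
#' @return A data frame of class `lifetable` with columns `age`, `qx`.
#' @export
make_lifetable <- function(age, qx) {
  age <- as.integer(age)
  qx <- as.numeric(qx)
  if (length(age) != length(qx)) {
    stop("`age` and `qx` must have equal length", call. = FALSE)
  }
  if (anyDuplicated(age)) stop("duplicated ages in life table", call. = FALSE)
  if (any(!is.finite(qx)) || any(qx < 0) || any(qx > 1)) {
    stop("life-table qx must lie in [0, 1]", call. = FALSE)
  }
  structure(data.frame(age = age, qx = qx),
            class = c("lifetable", "data.frame"))
}

#' Look up annual background death probability by age
#'
#' @param lifetable A `lifetable` object.
#' @param age Integer age(s); every age must be present in the table.
#' @return Numeric vector of annual death probabilities.
#' @export
lifetable_q <- function(lifetable, age) {
  i <- match(as.integer(age), lifetable$age)
  if (anyNA(i)) {
    stop("life table does not cover age(s): ",
         paste(unique(age[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  lifetable$qx[i]
}

#' Remaining life expectancy implied by a life table
#'
#' Computed by summing the survival curve from the given age to the end
#' of the table, plus half a year for the death year (the standard
#' mid-year convention).
#'
#' @param lifetable A `lifetable` object.
#' @param age Starting age (must be in the table).
#' @return Remaining life expectancy in years.
#' @export
life_expectancy <- function(lifetable, age) {
  ages <- lifetable$age[lifetable$age >= age]
  ages <- sort(ages)
  q <- lifetable_q(lifetable, ages)
  sum(cumprod(1 - q)) + 0.5
}

#' Read / write the two-column life-table CSV
#'
#' The on-disk format is a CSV with columns `age` and `qx` (annual
#' all-cause death probability); lines starting `#` are treated as
#' comments, which is how the CLI embeds provenance headers.
#'
#' @param path CSV file path.
#' @return `read_lifetable` returns a `lifetable`; `write_lifetable`
#'   returns `path` invisibly.
#' @export
read_lifetable <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("age", "qx") %in% names(df))) {
    stop("life-table CSV must have columns `age` and `qx`: ", path,
         call. = FALSE)
  }
  make_lifetable(df$age, df$qx)
}

#' @rdname read_lifetable
#' @param lifetable A `lifetable` object to write.
#' @param header Optional character vector of `#`-prefixed provenance
#'   lines written before the CSV body.
#' @export
write_lifetable <- function(lifetable, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(as.data.frame(lifetable), con, row.names = FALSE)
  invisible(path)
}
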