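# Period life table support for time-trade-off horizons.  The TTO poses a
# trade over the patient's remaining life expectancy, looked up by age and
# sex in a period life table supplied as CSV (columns age, sex, ex).  A
# synthetic fixture table is bundled under extdata; real period life tables
# with the same columns drop in unchanged.

#' Read a life table from CSV
#'
#' The file must have header columns `age` (integer years), `sex`
#' (`"female"` or `"male"`) and `ex` (remaining life expectancy in years).
#' Ages must be contiguous within each sex and `ex` strictly decreasing in
#' age within sex; violations are rejected with the offending row named.
#'
#' @param path Path to a CSV file.
#' @return A `life_table` (a validated data frame).
#' @export
#' @examples
#' lt <- read_life_table(system.file("extdata", "life_table_synthetic.csv",
#'                                   package = "huassess"))
#' tto_horizon(59, "female", lt)
read_life_table <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("life table file not found: %s", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort_format(sprintf("cannot parse life table CSV: %s", conditionMessage(e))))
  need <- c("age", "sex", "ex")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    abort_format(sprintf("life table is missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0L) abort_format("life table has no rows")
  if (!is.numeric(df$age) || anyNA(df$age) || any(df$age != floor(df$age)))
    abort_format("life table column 'age' must be integer years")
  if (anyNA(df$ex) || !is.numeric(df$ex) || any(df$ex <= 0))
    abort_format("life table column 'ex' must be positive numbers")
  bad_sex <- !df$sex %in% c("female", "male")
  if (any(bad_sex))
    abort_format(sprintf("life table row %d: sex must be 'female' or 'male'",
                         which(bad_sex)[1]))
  for (s in unique(df$sex)) {
    sub <- df[df$sex == s, ]
    sub <- sub[order(sub$age), ]
    if (any(duplicated(sub$age)))
      abort_format(sprintf("duplicate age %d for sex %s",
                           sub$age[duplicated(sub$age)][1], s))
    if (nrow(sub) > 1L && any(diff(sub$age) != 1L))
      abort_format(sprintf("ages are not contiguous for sex %s (gap after age %d)",
                           s, sub$age[which(diff(sub$age) != 1L)[1]]))
    inc <- diff(sub$ex) >= 0
    if (any(inc))
      abort_format(sprintf("remaining life expectancy must decrease with age: violation at age %d, sex %s",
                           sub$age[which(inc)[1] + 1L], s))
  }
  df <- df[order(df$sex, df$age), c("age", "sex", "ex")]
  rownames(df) <- NULL
  class(df) <- c("life_table", "data.frame")
  df
}

#' Time-trade-off horizon from a life table
#'
#' Returns the remaining life expectancy for the given age and sex, rounded
#' to the nearest whole year (half-years round up), with a floor of 1 year.
#' This horizon defines the duration over which TTO trades are posed.
#'
#' @param age Age in whole years; must be within the table's range.
#' @param sex `"female"` or `"male"`.
#' @param table A [life_table][read_life_table] object.
#' @return Integer number of years (>= 1).
#' @export
tto_horizon <- function(age, sex, table) {
  stopifnot(inherits(table, "life_table"))
  if (!is.character(sex) || length(sex) != 1L || !(sex %in% c("female", "male")))
    abort_validation("`sex` must be 'female' or 'male'")
  check_number(age, "age")
  row <- table[table$sex == sex & table$age == age, ]
  if (nrow(row) == 0L)
    abort_domain(sprintf("age %g (%s) is outside the life table's range [%d, %d]",
                         age, sex,
                         min(table$age[table$sex == sex]),
                         max(table$age[table$sex == sex])))
  max(1L, as.integer(floor(row$ex[1] + 0.5)))
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> %d rows; ages %d-%d; sexes: %s\n",
              nrow(x), min(x$age), max(x$age),
              paste(sort(unique(x$sex)), collapse = ", ")))
  invisible(x)
}
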