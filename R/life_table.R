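#' Synthetic background-mortality life table
#'
#' A deterministic stand-in life table for ages 18-100, approximating 2013 US
#' adult period mortality: annual death probability rising linearly from
#' 0.0008 at age 18 to 0.002 at 40, held at 0.002 through ages 40-44, then
#' Gompertz-like (doubling every 8 years, anchored at age 42) up to age 99,
#' with the terminal age 100 absorbing (`qx = 1`). It is a documented
#' approximation, not a reproduction of any published table; over a 5-year
#' horizon starting at age 40 background mortality contributes little to
#' costs and QALYs, and the table is swappable via the `life_table` arguments
#' throughout the package.
#'
#' @return A tibble with columns `age` (18-100) and `qx` (annual all-cause
#'   death probability).
#' @export
default_life_table <- function() {
  age <- 18:100
  qx <- numeric(length(age))
  qx[age <= 39] <- 0.0008 + (0.002 - 0.0008) * (age[age <= 39] - 18) / 22
  qx[age >= 40 & age <= 44] <- 0.002
  gomp <- age >= 45 & age <= 99
  qx[gomp] <- 0.002 * 2^((age[gomp] - 42) / 8)
  qx[age == 100] <- 1
  tibble::tibble(age = age, qx = pmin(qx, 1))
}

validate_life_table <- function(lt) {
  lt <- tibble::as_tibble(lt)
  if (!all(c("age", "qx") %in% names(lt))) {
    stop("life table needs columns 'age' and 'qx'", call. = FALSE)
  }
  if (any(diff(lt$age) != 1)) {
    stop("life-table ages must be contiguous whole years", call. = FALSE)
  }
  if (min(lt$age) > 18 || max(lt$age) < 100) {
    stop("life table must span at least ages 18-100", call. = FALSE)
  }
  if (any(lt$qx < 0 | lt$qx > 1)) {
    stop("life-table qx values must lie in [0, 1]", call. = FALSE)
  }
  if (lt$qx[nrow(lt)] != 1) {
    stop("terminal-age qx must equal 1", call. = FALSE)
  }
  invisible(lt)
}

#' Weekly background mortality probability at a given age
#'
#' Looks up the annual death probability `qx` for the whole-year age bracket
#' containing `age_years` and converts it to a weekly probability under a
#' constant hazard within the year: `1 - (1 - qx)^(1/52)`.
#'
#' @param age_years Age in (possibly fractional) years; must fall inside the
#'   table's range.
#' @param life_table A life table (columns `age`, `qx`).
#' @return Weekly death probability.
#' @export
background_mortality_weekly <- function(age_years, life_table = default_life_table()) {
  idx <- match(floor(age_years), life_table$age)
  if (any(is.na(idx))) {
    stop("age ", paste(age_years[is.na(idx)], collapse = ", "),
         " outside the life table range", call. = FALSE)
  }
  1 - (1 - life_table$qx[idx])^(1 / 52)
}
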