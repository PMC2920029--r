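#' Age-by-year mortality surface
#'
#' Container for a death-count surface on single years of age by calendar
#' year, together with the matching person-years at risk.  This is the data
#' structure the whole package operates on: observed (or simulated) deaths
#' `Y[A, T]` and person-years `P[A, T]` for ages `A` (rows) and years `T`
#' (columns).  A surface may carry person-years only (`deaths = NULL`),
#' e.g. population projections used for forward prediction.
#'
#' @param ages integer vector of single years of age (default 20:89).
#' @param years integer vector of consecutive calendar years.
#' @param deaths integer matrix of death counts, `length(ages)` rows by
#'   `length(years)` columns, or `NULL` for a person-years-only surface.
#' @param person_years numeric matrix of person-years at risk, same shape;
#'   must be strictly positive.
#'
#' @return An object of class `meso_surface`: a list with elements `ages`,
#'   `years`, `deaths` (matrix or `NULL`) and `person_years` (matrix), with
#'   dimnames `ages` x `years`.
#' @export
#' @examples
#' py <- matrix(1e5, 3, 2, dimnames = list(30:32, 1990:1991))
#' d  <- matrix(c(4L, 2L, 7L, 5L, 3L, 8L), 3, 2)
#' s  <- mortality_surface(30:32, 1990:1991, d, py)
#' total_deaths(s)
mortality_surface <- function(ages = 20:89, years, deaths = NULL,
                              person_years) {
  ages <- as.integer(ages)
  years <- as.integer(years)
  if (any(diff(ages) != 1L) || any(diff(years) != 1L))
    stop("ages and years must be consecutive integers")
  dn <- list(ages, years)
  person_years <- as.matrix(person_years)
  if (!all(dim(person_years) == c(length(ages), length(years))))
    stop("person_years has shape ", paste(dim(person_years), collapse = "x"),
         ", expected ", length(ages), "x", length(years))
  if (any(!is.finite(person_years)) || any(person_years <= 0))
    stop("person_years must be finite and strictly positive")
  dimnames(person_years) <- dn
  if (!is.null(deaths)) {
    deaths <- as.matrix(deaths)
    if (!all(dim(deaths) == dim(person_years)))
      stop("deaths and person_years shapes disagree")
    if (any(!is.finite(deaths)) || any(deaths < 0))
      stop("deaths must be finite and nonnegative")
    storage.mode(deaths) <- "double"
    dimnames(deaths) <- dn
  }
  structure(list(ages = ages, years = years, deaths = deaths,
                 person_years = person_years),
            class = "meso_surface")
}

#' Total observed deaths on a surface
#'
#' @param surface a [mortality_surface()].
#' @param years optional year range `c(first, last)` restricting the sum
#'   (the fit window); default is the full surface.
#' @return scalar total death count.
#' @export
total_deaths <- function(surface, years = NULL) {
  if (is.null(surface$deaths)) stop("surface carries no deaths")
  cols <- surface_year_cols(surface, years)
  sum(surface$deaths[, cols, drop = FALSE])
}

## columns of a surface covered by an inclusive year range
surface_year_cols <- function(surface, years = NULL) {
  if (is.null(years)) return(seq_along(surface$years))
  cols <- which(surface$years >= years[1] & surface$years <= years[2])
  if (length(cols) != years[2] - years[1] + 1)
    stop("surface does not cover years ", years[1], "-", years[2])
  cols
}

#' @export
print.meso_surface <- function(x, ...) {
  cat("<meso_surface> ages ", min(x$ages), "-", max(x$ages),
      ", years ", min(x$years), "-", max(x$years),
      if (is.null(x$deaths)) " (person-years only)" else
        paste0(", total deaths ", format(sum(x$deaths), big.mark = " ")),
      "\n", sep = "")
  invisible(x)
}

#' Read / write a mortality surface as CSV matrices
#'
#' Surfaces are stored as plain CSV with an `age` column followed by one
#' column per calendar year (header = the year).  Deaths and person-years
#' live in separate files with identical layout.
#'
#' @param person_years_file path of the person-years CSV.
#' @param deaths_file path of the deaths CSV, or `NULL` for a
#'   person-years-only surface.
#' @return [read_mortality_surface()] returns a `meso_surface`;
#'   [write_mortality_surface()] returns its input invisibly.
#' @export
read_mortality_surface <- function(person_years_file, deaths_file = NULL) {
  py <- read_surface_matrix(person_years_file)
  deaths <- if (!is.null(deaths_file)) read_surface_matrix(deaths_file)
  mortality_surface(ages = as.integer(rownames(py)),
                    years = as.integer(colnames(py)),
                    deaths = deaths, person_years = py)
}

#' @rdname read_mortality_surface
#' @param surface a `meso_surface`.
#' @export
write_mortality_surface <- function(surface, person_years_file,
                                    deaths_file = NULL) {
  write_surface_matrix(surface$person_years, surface$ages, person_years_file)
  if (!is.null(deaths_file)) {
    if (is.null(surface$deaths)) stop("surface carries no deaths")
    write_surface_matrix(surface$deaths, surface$ages, deaths_file)
  }
  invisible(surface)
}

read_surface_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "age") stop("expected first column 'age' in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$age
  m
}

write_surface_matrix <- function(m, ages, path) {
  df <- data.frame(age = ages, m, check.names = FALSE)
  ## full precision so surfaces round-trip bit-identically
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}
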