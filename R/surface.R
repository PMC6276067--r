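#' Age-by-year mortality surfaces
#'
#' A `mortality_surface` holds one subpopulation's central death rates
#' \eqn{m_{x,t}} (and optionally death counts \eqn{d_{x,t}} and central
#' exposures \eqn{e_{x,t}}) on a rectangular age-by-year grid.  Ages and
#' years are contiguous integer labels; the last age group may be
#' open-ended (e.g. "100+"), in which case it is carried as the integer
#' lower bound with `open_ended = TRUE` and treated as that integer point
#' on all model age scales.
#'
#' @param ages integer vector of contiguous age labels.
#' @param years integer vector of contiguous calendar years.
#' @param rates k-by-n matrix of central mortality rates (`NA` allowed).
#' @param deaths optional k-by-n matrix of death counts.
#' @param exposures optional k-by-n matrix of person-year exposures.
#' @param label population identifier (e.g. `"female"`, `"Tokyo male"`).
#' @param open_ended is the last age group open-ended?
#' @return An object of class `mortality_surface` with fields `ages`,
#'   `years`, `rates`, `deaths`, `exposures`, `label`, `open_ended`.
#' @examples
#' s <- mortality_surface(60:62, 2000:2001,
#'                        rates = matrix(c(.01, .02, .03, .011, .021, .031), 3, 2))
#' s
#' @export
mortality_surface <- function(ages, years, rates, deaths = NULL,
                              exposures = NULL, label = "pop",
                              open_ended = FALSE) {
  ages <- as.integer(ages)
  years <- as.integer(years)
  if (length(ages) < 1L || length(years) < 1L)
    stop("empty age or year range", call. = FALSE)
  if (length(ages) > 1L && any(diff(ages) != 1L))
    stop("ages must be contiguous (strictly increasing by 1)", call. = FALSE)
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("years must be contiguous (strictly increasing by 1)", call. = FALSE)
  rates <- as.matrix(rates)
  attr(rates, "zero_cells") <- NULL
  if (!all(dim(rates) == c(length(ages), length(years))))
    stop("rates must be a ", length(ages), "x", length(years), " matrix",
         call. = FALSE)
  if (any(rates < 0, na.rm = TRUE))
    stop("negative rates", call. = FALSE)
  chk <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!all(dim(m) == dim(rates)))
      stop(what, " must match the rates grid", call. = FALSE)
    m
  }
  deaths <- chk(deaths, "deaths")
  exposures <- chk(exposures, "exposures")
  if (!is.null(deaths) && any(deaths < 0, na.rm = TRUE))
    stop("negative deaths", call. = FALSE)
  if (!is.null(exposures) && any(exposures <= 0, na.rm = TRUE))
    stop("exposures must be positive", call. = FALSE)
  if (!is.null(deaths) && !is.null(exposures)) {
    de <- deaths / exposures
    ok <- is.finite(de) & is.finite(rates)
    if (any(abs(de[ok] - rates[ok]) > 1e-12 * pmax(de[ok], 1)))
      stop("rates are not deaths/exposures (relative tolerance 1e-12)",
           call. = FALSE)
  }
  dimnames(rates) <- list(ages, years)
  if (!is.null(deaths)) dimnames(deaths) <- dimnames(rates)
  if (!is.null(exposures)) dimnames(exposures) <- dimnames(rates)
  structure(list(ages = ages, years = years, rates = rates,
                 deaths = deaths, exposures = exposures,
                 label = label, open_ended = isTRUE(open_ended)),
            class = "mortality_surface")
}

#' @export
print.mortality_surface <- function(x, ...) {
  last <- if (x$open_ended) paste0(max(x$ages), "+") else max(x$ages)
  cat("Mortality surface '", x$label, "': ages ", min(x$ages), "-", last,
      " (k=", length(x$ages), "), years ", min(x$years), "-", max(x$years),
      " (n=", length(x$years), ")\n", sep = "")
  cat("  deaths/exposures: ",
      if (is.null(x$deaths)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' @export
plot.mortality_surface <- function(x, years = NULL, ...) {
  yrs <- if (is.null(years)) x$years else intersect(years, x$years)
  cols <- grDevices::hcl.colors(length(yrs), "viridis")
  lr <- log(log_safe_rates(x))
  graphics::matplot(x$ages, lr[, as.character(yrs), drop = FALSE],
                    type = "l", lty = 1, col = cols,
                    xlab = "age", ylab = "log mortality rate",
                    main = x$label, ...)
  invisible(x)
}

#' Derive central rates from deaths and exposures
#'
#' Elementwise \eqn{m = d/e}.  Cells with zero deaths get rate 0; the
#' positions of such cells are returned in the `"zero_cells"` attribute so
#' that log-domain consumers can apply the half-minimum substitution rule
#' (see [log_safe_rates()]).
#'
#' @param deaths,exposures matrices of equal dimension; all exposures > 0.
#' @return Rate matrix with attribute `zero_cells` (logical matrix).
#' @export
derive_rates <- function(deaths, exposures) {
  deaths <- as.matrix(deaths); exposures <- as.matrix(exposures)
  if (!all(dim(deaths) == dim(exposures)))
    stop("deaths and exposures must have equal dimensions", call. = FALSE)
  if (any(!is.finite(exposures)) || any(exposures <= 0))
    stop("all exposures must be positive", call. = FALSE)
  r <- deaths / exposures
  attr(r, "zero_cells") <- is.finite(deaths) & deaths == 0
  r
}

#' Rates made safe for the log transform
#'
#' Zero rates (zero observed deaths) are replaced, within each year's
#' column, by half the smallest positive rate of that column before logs
#' are taken; this keeps the ordering of cells while avoiding minus
#' infinity.  Columns that are entirely zero fall back to the smallest
#' positive rate of the whole surface.
#'
#' @param surface a [mortality_surface()] (or a bare rate matrix).
#' @return A positive rate matrix of the same dimension.
#' @export
log_safe_rates <- function(surface) {
  r <- if (inherits(surface, "mortality_surface")) surface$rates else as.matrix(surface)
  if (!any(r == 0, na.rm = TRUE)) return(r)
  gmin <- min(r[r > 0], na.rm = TRUE)
  for (j in seq_len(ncol(r))) {
    col <- r[, j]
    z <- which(!is.na(col) & col == 0)
    if (!length(z)) next
    pos <- col[!is.na(col) & col > 0]
    fill <- if (length(pos)) min(pos) / 2 else gmin / 2
    r[z, j] <- fill
  }
  r
}

#' Restrict a surface to an age window
#'
#' @param surface a [mortality_surface()].
#' @param lo,hi inclusive age bounds; must overlap the surface range.
#' @return The sliced [mortality_surface()]; all matrices are cut
#'   consistently and the open-ended flag survives only if the last age
#'   is retained.
#' @export
restrict_ages <- function(surface, lo, hi) {
  keep <- surface$ages >= lo & surface$ages <= hi
  if (lo > hi || !any(keep))
    stop("age restriction [", lo, ",", hi, "] leaves no ages", call. = FALSE)
  sl <- function(m) if (is.null(m)) NULL else m[keep, , drop = FALSE]
  mortality_surface(surface$ages[keep], surface$years,
                    sl(surface$rates), sl(surface$deaths), sl(surface$exposures),
                    label = surface$label,
                    open_ended = surface$open_ended && keep[length(keep)])
}

#' Restrict a surface to a year window
#'
#' @param surface a [mortality_surface()].
#' @param lo,hi inclusive calendar-year bounds.
#' @return The sliced [mortality_surface()].
#' @export
restrict_years <- function(surface, lo, hi) {
  keep <- surface$years >= lo & surface$years <= hi
  if (lo > hi || !any(keep))
    stop("year restriction [", lo, ",", hi, "] leaves no years", call. = FALSE)
  sl <- function(m) if (is.null(m)) NULL else m[, keep, drop = FALSE]
  mortality_surface(surface$ages, surface$years[keep],
                    sl(surface$rates), sl(surface$deaths), sl(surface$exposures),
                    label = surface$label, open_ended = surface$open_ended)
}

#' A set of populations on a shared grid
#'
#' @param ... named [mortality_surface()] objects (or a single named list),
#'   all on identical age and year grids.
#' @return An object of class `population_set`: a named list of surfaces
#'   with shared `ages`/`years` attributes.
#' @export
population_set <- function(...) {
  surfaces <- list(...)
  if (length(surfaces) == 1L && is.list(surfaces[[1L]]) &&
      !inherits(surfaces[[1L]], "mortality_surface"))
    surfaces <- surfaces[[1L]]
  if (length(surfaces) < 1L) stop("no surfaces supplied", call. = FALSE)
  if (is.null(names(surfaces)) || any(!nzchar(names(surfaces))))
    names(surfaces) <- vapply(surfaces, `[[`, "", "label")
  ref <- surfaces[[1L]]
  for (s in surfaces) {
    if (!inherits(s, "mortality_surface"))
      stop("all members must be mortality_surface objects", call. = FALSE)
    if (!identical(s$ages, ref$ages) || !identical(s$years, ref$years))
      stop("all member surfaces must share identical ages and years",
           call. = FALSE)
  }
  structure(surfaces, class = "population_set")
}

#' @export
print.population_set <- function(x, ...) {
  cat("Population set of", length(x), "surfaces:",
      paste(names(x), collapse = ", "), "\n")
  print(x[[1L]])
  invisible(x)
}

#' Read an HMD-dialect mortality table
#'
#' Parses the whitespace-delimited text format used by the Human
#' Mortality Database and its national offshoots: two header lines, then
#' columns `Year Age Female Male Total`.  The missing-value token is
#' `"."`; the open-ended age is written `"NNN+"`.
#'
#' @param path file path.
#' @param column which population column to extract: `"Female"`,
#'   `"Male"` or `"Total"`.
#' @param label label for the returned surface; defaults to the column name.
#' @return A [mortality_surface()] of rates.
#' @export
read_hmd_table <- function(path, column = c("Female", "Male", "Total"),
                           label = NULL) {
  column <- match.arg(column)
  lines <- readLines(path)
  if (length(lines) < 3L) stop("file too short to be an HMD table", call. = FALSE)
  body <- lines[-(1:2)]
  body_no <- seq_along(lines)[-(1:2)]
  keep <- nzchar(trimws(body))
  body <- body[keep]; body_no <- body_no[keep]
  toks <- strsplit(trimws(body), "[[:space:]]+")
  year <- integer(length(toks)); age <- integer(length(toks))
  open <- logical(length(toks)); val <- numeric(length(toks))
  colix <- c(Female = 3L, Male = 4L, Total = 5L)[[column]]
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) < 5L)
      stop("malformed row at line ", body_no[i], ": expected 5 columns",
           call. = FALSE)
    y <- suppressWarnings(as.integer(tk[1L]))
    if (is.na(y))
      stop("malformed row at line ", body_no[i], ": bad year '", tk[1L], "'",
           call. = FALSE)
    a_tok <- tk[2L]
    op <- grepl("\\+$", a_tok)
    a <- suppressWarnings(as.integer(sub("\\+$", "", a_tok)))
    if (is.na(a))
      stop("malformed row at line ", body_no[i], ": bad age '", a_tok, "'",
           call. = FALSE)
    v_tok <- tk[colix]
    v <- if (v_tok == ".") NA_real_ else suppressWarnings(as.numeric(v_tok))
    if (!identical(v_tok, ".") && is.na(v))
      stop("malformed row at line ", body_no[i], ": bad value '", v_tok, "'",
           call. = FALSE)
    year[i] <- y; age[i] <- a; open[i] <- op; val[i] <- v
  }
  ages <- sort(unique(age)); years <- sort(unique(year))
  if (length(ages) > 1L && any(diff(ages) != 1L))
    stop("non-contiguous ages in file (", paste(ages[c(diff(ages) != 1L, FALSE)],
         collapse = ", "), " ...)", call. = FALSE)
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("non-contiguous years in file", call. = FALSE)
  r <- matrix(NA_real_, length(ages), length(years),
              dimnames = list(ages, years))
  r[cbind(match(age, ages), match(year, years))] <- val
  mortality_surface(ages, years, r,
                    label = if (is.null(label)) column else label,
                    open_ended = any(open & age == max(ages)))
}

#' Read / write the long CSV interchange format
#'
#' The long format has header `year,age,population,deaths,exposure,rate`;
#' `deaths` and `exposure` may be empty.  [write_mortality_csv()] and
#' [read_mortality_csv()] round-trip a surface exactly on labels and to
#' full double precision on values.
#'
#' @param surface a [mortality_surface()].
#' @param path file path.
#' @return `read_mortality_csv()` returns a [mortality_surface()] (or a
#'   [population_set()] when several population labels are present);
#'   `write_mortality_csv()` returns `path` invisibly.
#' @export
write_mortality_csv <- function(surface, path) {
  surfaces <- if (inherits(surface, "population_set")) surface else list(surface)
  rows <- lapply(surfaces, function(s) {
    k <- length(s$ages); n <- length(s$years)
    data.frame(year = rep(s$years, each = k),
               age = rep(ifelse(s$open_ended & s$ages == max(s$ages),
                                paste0(s$ages, "+"), as.character(s$ages)), n),
               population = s$label,
               deaths = if (is.null(s$deaths)) NA_real_ else as.vector(s$deaths),
               exposure = if (is.null(s$exposures)) NA_real_ else as.vector(s$exposures),
               rate = as.vector(s$rates))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_mortality_csv
#' @export
read_mortality_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(age = "character"))
  need <- c("year", "age", "population", "rate")
  if (!all(need %in% names(df)))
    stop("long CSV must have columns year,age,population,deaths,exposure,rate",
         call. = FALSE)
  one <- function(d, lab) {
    open <- grepl("\\+$", d$age)
    age <- as.integer(sub("\\+$", "", d$age))
    ages <- sort(unique(age)); years <- sort(unique(d$year))
    idx <- cbind(match(age, ages), match(d$year, years))
    mk <- function(v) {
      if (all(is.na(v))) return(NULL)
      m <- matrix(NA_real_, length(ages), length(years)); m[idx] <- v; m
    }
    mortality_surface(ages, years, mk(d$rate), mk(d$deaths), mk(d$exposure),
                      label = lab, open_ended = any(open & age == max(ages)))
  }
  labs <- unique(df$population)
  if (length(labs) == 1L) return(one(df, labs))
  population_set(stats::setNames(
    lapply(labs, function(l) one(df[df$population == l, , drop = FALSE], l)),
    labs))
}
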