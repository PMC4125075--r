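# Plate-reader I/O and specific growth rates.

#' Construct a growth curve
#'
#' A labeled optical-density time series from one well. Times are in hours,
#' strictly increasing with uniform spacing; OD is dimensionless and
#' non-negative.
#'
#' @param times numeric vector of sampling times (hours).
#' @param od numeric vector of optical densities, same length as `times`.
#' @param strain,condition,well label strings.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(times, od, strain = "unknown", condition = "unknown",
                         well = "") {
  stopifnot(is.numeric(times), is.numeric(od))
  if (length(times) != length(od) || length(times) < 5)
    stop("growth_curve: times and od must have equal length >= 5")
  if (any(!is.finite(times)) || any(!is.finite(od)))
    stop("growth_curve: non-finite values")
  dt <- diff(times)
  if (any(dt <= 0)) stop("growth_curve: times must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt)))
    stop("growth_curve: time spacing must be uniform")
  if (any(od < 0)) stop("growth_curve: negative OD")
  structure(list(times = as.numeric(times), od = as.numeric(od),
                 strain = as.character(strain),
                 condition = as.character(condition),
                 well = as.character(well)),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %s / %s (well %s): %d points, %.2f-%.2f h, dt = %.4g h\n",
              x$strain, x$condition, x$well, length(x$times),
              min(x$times), max(x$times), x$times[2] - x$times[1]))
  invisible(x)
}

.dt_of <- function(times) times[2] - times[1]

#' Read a wide plate-reader CSV
#'
#' The CSV must have a `time` column (hours) and one column per well.
#' `layout` maps well names to strain/condition labels; columns without a
#' layout entry are skipped with a warning.
#'
#' @param path CSV file path.
#' @param layout named list, `layout[[well]] = list(strain =, condition =)`,
#'   or a path to a JSON/YAML file with that structure.
#' @return list of [growth_curve()] objects, one per mapped well.
#' @export
read_plate_csv <- function(path, layout) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df))
    stop("read_plate_csv: no 'time' column in ", path)
  if (is.character(layout) && length(layout) == 1) layout <- read_layout(layout)
  times <- df$time
  if (any(diff(times) <= 0))
    stop("read_plate_csv: 'time' column is not strictly increasing")
  wells <- setdiff(names(df), "time")
  unmapped <- setdiff(wells, names(layout))
  if (length(unmapped) > 0)
    warning("read_plate_csv: skipping unmapped wells: ",
            paste(unmapped, collapse = ", "))
  mapped <- intersect(wells, names(layout))
  lapply(mapped, function(w) {
    lab <- layout[[w]]
    growth_curve(times, df[[w]], strain = lab$strain,
                 condition = lab$condition, well = w)
  })
}

#' Write growth curves to a wide plate CSV
#' @param curves list of [growth_curve()] sharing one time grid.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(curves, path) {
  stopifnot(length(curves) >= 1)
  times <- curves[[1]]$times
  for (cv in curves)
    if (!isTRUE(all.equal(cv$times, times, tolerance = 1e-12)))
      stop("write_plate_csv: curves must share one time grid")
  df <- data.frame(time = times, check.names = FALSE)
  for (cv in curves) df[[cv$well]] <- cv$od
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a plate layout from JSON or YAML
#' @param path file with `{well: {strain:, condition:}}` structure.
#' @return named list of `list(strain, condition)`.
#' @export
read_layout <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("read_layout: yaml package needed for YAML layouts")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
}

#' Specific growth rate by central differences
#'
#' Computes the discrete specific growth rate
#' \deqn{\mu_i = (OD_{i+1} - OD_{i-1}) / (2 \Delta t \, OD_i)}
#' at every interior point; the endpoints are dropped. With
#' `method = "log"`, central differences are taken on \eqn{\ln OD} instead,
#' \eqn{\mu_i = (\ln OD_{i+1} - \ln OD_{i-1}) / (2\Delta t)}; the two agree
#' for slowly varying curves.
#'
#' @param curve a [growth_curve()].
#' @param method `"od"` (default) or `"log"`.
#' @param permissive if `TRUE`, interior points with OD <= 0 yield `NA`
#'   instead of an error.
#' @return object of class `growth_rate_series` with fields `times`, `mu`
#'   and the inherited labels.
#' @export
compute_growth_rate <- function(curve, method = c("od", "log"),
                                permissive = FALSE) {
  stopifnot(inherits(curve, "growth_curve"))
  method <- match.arg(method)
  od <- curve$od
  n <- length(od)
  dt <- .dt_of(curve$times)
  interior <- 2:(n - 1)
  bad <- od[interior] <= 0
  if (any(bad) && !permissive)
    stop("compute_growth_rate: OD <= 0 at interior points; ",
         "set permissive = TRUE to mask them")
  mu <- if (method == "od") {
    (od[interior + 1] - od[interior - 1]) / (2 * dt * od[interior])
  } else {
    (log(od[interior + 1]) - log(od[interior - 1])) / (2 * dt)
  }
  mu[bad] <- NA_real_
  growth_rate_series(curve$times[interior], mu, strain = curve$strain,
                     condition = curve$condition, well = curve$well)
}

#' Construct a growth-rate series
#' @param times hours; `mu` specific growth rate (1/hour), same length.
#' @param mu numeric vector.
#' @param strain,condition,well labels.
#' @return object of class `growth_rate_series`.
#' @export
growth_rate_series <- function(times, mu, strain = "unknown",
                               condition = "unknown", well = "") {
  stopifnot(length(times) == length(mu))
  structure(list(times = as.numeric(times), mu = as.numeric(mu),
                 strain = as.character(strain),
                 condition = as.character(condition),
                 well = as.character(well)),
            class = "growth_rate_series")
}

#' @export
print.growth_rate_series <- function(x, ...) {
  cat(sprintf("<growth_rate_series> %s / %s: %d points, max mu = %.3f 1/h\n",
              x$strain, x$condition, length(x$mu), max(x$mu, na.rm = TRUE)))
  invisible(x)
}
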