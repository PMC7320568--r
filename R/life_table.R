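#' Construct a period life table
#'
#' A life table holds annual probabilities of death from background
#' (non-cancer) causes, indexed by integer age. It supplies the competing
#' all-cause mortality that the Markov cohort engine combines with the
#' disease-specific transition probabilities.
#'
#' @param age integer vector of ages in years; must be strictly increasing
#'   and contiguous from its minimum.
#' @param q numeric vector of annual death probabilities, one per age,
#'   each in \[0, 1\].
#' @param provenance short label recording where the table came from.
#'
#' @return A data frame of class `"life_table"` with columns `age` and `q`
#'   and a `provenance` attribute.
#' @seealso [q_lookup()], [read_life_table()], [synth_life_table()]
#' @export
#' @examples
#' lt <- life_table(age = 0:5, q = c(0.006, rep(4e-4, 5)))
#' q_lookup(lt, 3)
life_table <- function(age, q, provenance = "unspecified") {
  if (length(age) < 1L || length(age) != length(q))
    stop("invalid-table: 'age' and 'q' must be non-empty and equal length")
  if (anyNA(age) || anyNA(q))
    stop("invalid-table: missing values in life table")
  age <- as.integer(age)
  if (any(diff(age) != 1L))
    stop("invalid-table: ages must be strictly increasing and contiguous")
  if (any(q < 0 | q > 1))
    stop("invalid-table: q outside [0,1]")
  structure(data.frame(age = age, q = as.numeric(q)),
            provenance = as.character(provenance)[1],
            class = c("life_table", "data.frame"))
}

#' @export
print.life_table <- function(x, ...) {
  cat("Period life table (", attr(x, "provenance"), "): ages ",
      min(x$age), "-", max(x$age), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 5), row.names = FALSE)
  if (nrow(x) > 5) cat("  ... ", nrow(x) - 5, " more rows\n", sep = "")
  invisible(x)
}

#' Look up the annual background death probability at a given age
#'
#' Ages above the last tabulated age clamp to the last row; any age of 120
#' years or more is treated as certain death within the year. Ages below the
#' table minimum are an error, since no extrapolation rule is defined there.
#'
#' @param table a [life_table()].
#' @param age age in years (vectorised); need not be integer, the floor is
#'   used.
#' @return numeric vector of annual death probabilities.
#' @export
q_lookup <- function(table, age) {
  stopifnot(inherits(table, "life_table"))
  age <- floor(age)
  if (any(age < table$age[1L]))
    stop("range error: age below life-table minimum (", table$age[1L], ")")
  idx <- pmin(age - table$age[1L] + 1L, nrow(table))
  q <- table$q[idx]
  q[age >= 120] <- 1
  q
}

#' Read a life table from a two-column CSV
#'
#' The file must have headers exactly `age,q`; an optional leading
#' `# provenance:` comment line is honoured and preserved by
#' [write_life_table()].
#'
#' @param path path to the CSV file.
#' @return a [life_table()].
#' @export
read_life_table <- function(path) {
  lines <- readLines(path)
  prov <- "unspecified"
  is_prov <- grepl("^#\\s*provenance:", lines)
  if (any(is_prov))
    prov <- trimws(sub("^#\\s*provenance:", "", lines[which(is_prov)[1L]]))
  lines <- lines[!grepl("^#", lines)]
  if (!identical(trimws(lines[1L]), "age,q"))
    stop("invalid-table: expected header 'age,q'")
  dat <- utils::read.csv(text = lines, header = TRUE)
  life_table(dat$age, dat$q, provenance = prov)
}

#' Write a life table as a two-column CSV
#'
#' @param table a [life_table()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "life_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ", attr(table, "provenance")), con)
  writeLines("age,q", con)
  # %.17g guarantees the decimal text round-trips to the same double
  writeLines(paste(table$age, sprintf("%.17g", table$q), sep = ","), con)
  invisible(path)
}

#' Generate a synthetic Gompertz-Makeham life table
#'
#' Annual death probabilities follow
#' `q(a) = min(1, 1 - exp(-(makeham + gompertz_scale * exp(gompertz_rate * a))))`,
#' i.e. a constant background hazard plus an exponentially age-increasing
#' senescent hazard. The defaults give a roughly human-plausible mortality
#' curve and exist so the test-suite and examples are self-contained; they
#' are not calibrated to any national table.
#'
#' @param makeham age-independent hazard per year (>= 0).
#' @param gompertz_scale senescent hazard scale per year (>= 0).
#' @param gompertz_rate exponential rate of hazard increase per year of age
#'   (>= 0).
#' @param max_age last tabulated age (>= 1).
#' @return a [life_table()] covering ages `0:max_age`.
#' @export
#' @examples
#' lt <- synth_life_table()
#' plot(lt$age, lt$q, type = "l", log = "y")
synth_life_table <- function(makeham = 5e-4, gompertz_scale = 3e-5,
                             gompertz_rate = 0.09, max_age = 110) {
  stopifnot(makeham >= 0, gompertz_scale >= 0, gompertz_rate >= 0,
            max_age >= 1)
  age <- 0:max_age
  hazard <- makeham + gompertz_scale * exp(gompertz_rate * age)
  q <- pmin(1, 1 - exp(-hazard))
  life_table(age, q,
             provenance = sprintf(
               "synthetic Gompertz-Makeham (makeham=%g, scale=%g, rate=%g)",
               makeham, gompertz_scale, gompertz_rate))
}

#' The bundled sex-combined 2016 US period life table (synthetic smooth)
#'
#' Returns the package's vendored background-mortality fixture: a smoothed,
#' sex-combined reconstruction of the 2016 US Social Security period life
#' table, built by log-linear interpolation through anchor values (it is a
#' synthetic stand-in, not a verbatim copy of the published table).
#'
#' @return a [life_table()] for ages 0-119.
#' @export
us_life_table_2016 <- function() {
  read_life_table(system.file("extdata", "life_table_us2016_synthetic.csv",
                              package = "pbtcea", mustWork = TRUE))
}
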