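#' Generate a synthetic Gompertz life table
#'
#' Builds an adult life table (ages 18-100) from a Gompertz mortality
#' hazard \eqn{\mu(x) = a e^{bx}}, with the level \eqn{a} solved so that
#' remaining life expectancy at age 40 equals \code{e40}.  This is a
#' self-consistent stand-in for a national life table (the default
#' \code{e40 = 28} years is plausible for Sierra Leonean males); it is a
#' configuration artifact, not demographic data, and should be replaced
#' by a real country table for applied work.
#'
#' @param e40 target remaining life expectancy at age 40, years.
#' @param shape Gompertz slope parameter \eqn{b} (per year of age).
#' @param ages integer age grid of the returned table.
#' @return A data frame with columns \code{age}, \code{q} (annual death
#'   probability) and \code{ex} (remaining life expectancy, years).
#' @export
#' @examples
#' lt <- generate_life_table(e40 = 28)
#' lt$ex[lt$age == 40]  # ~28
generate_life_table <- function(e40, shape = 0.09, ages = 18:100) {
  if (!is.numeric(e40) || e40 <= 0)
    stop("generate_life_table: e40 must be positive")
  if (shape <= 0)
    stop("generate_life_table: shape must be positive ",
         "(a zero hazard slope gives unbounded life expectancy)")

  grid <- 18:130  # internal grid wide enough to close out survivorship
  q_of <- function(a) {
    q <- 1 - exp(-(a / shape) * (exp(shape * (grid + 1)) - exp(shape * grid)))
    pmin(q, 1)
  }
  e_at <- function(q, age) {
    i <- match(age, grid)
    p <- cumprod(1 - q[i:length(grid)])
    # standard approximation: deaths mid-interval
    0.5 + sum(p)
  }
  f <- function(log_a) e_at(q_of(exp(log_a)), 40) - e40
  sol <- stats::uniroot(f, lower = log(1e-10), upper = log(1e-1),
                        tol = 1e-12)
  q <- q_of(exp(sol$root))
  ex <- vapply(grid, function(a) e_at(q, a), numeric(1))
  out <- data.frame(age = grid, q = q, ex = ex)
  out[out$age %in% ages, , drop = FALSE]
}

#' Read a life table from CSV
#'
#' Expects a header row and columns \code{age}, \code{q}, \code{ex}.
#'
#' @param path CSV file path.
#' @return A validated life-table data frame.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path)
  lt <- utils::read.csv(path)
  validate_life_table(lt)
  lt
}

validate_life_table <- function(lt) {
  if (!is.data.frame(lt) || !all(c("age", "q", "ex") %in% names(lt)))
    stop("life_table must be a data frame with columns age, q, ex")
  if (any(lt$q < 0 | lt$q > 1))
    stop("life_table$q must lie in [0, 1]")
  if (any(diff(lt$ex[lt$age >= 5]) >= 0 & diff(lt$age[lt$age >= 5]) > 0))
    stop("life_table$ex must be strictly decreasing in age beyond infancy")
  invisible(lt)
}

# Interpolated annual death probability at (possibly off-grid) ages.
lt_q <- function(life_table, age) {
  stats::approx(life_table$age, life_table$q, xout = age, rule = 2)$y
}

# Interpolated remaining life expectancy.
lt_ex <- function(life_table, age) {
  stats::approx(life_table$age, life_table$ex, xout = age, rule = 2)$y
}
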