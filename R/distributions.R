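#' Build the bivariate functionality-chain-length distribution (FUNC-CLD)
#'
#' Counts chains at every (chain length CL, number of functional units FUNC)
#' pair and normalizes to number fractions. Unit-width integer bins, no
#' smoothing; macromonomers and dead/branched chains are included by default
#' since the final product contains them.
#'
#' @param population A population tibble (columns `cl`, `func`, `status`),
#'   e.g. from [chain_population()], or a `kmc_trajectory` (its final
#'   population is used).
#' @param statuses Character vector of chain statuses to keep (default: all).
#' @return A `func_cld` object: long tibble with columns `cl`, `func`, `n`,
#'   `fraction`, carrying the total chain count as attribute `n_chains`.
#'   `as.matrix()` gives the dense CL x FUNC matrix.
#' @export
build_func_cld <- function(population, statuses = .STATUS_LEVELS) {
  if (inherits(population, "kmc_trajectory")) population <- population$population
  pop <- dplyr::filter(population, .data$status %in% statuses)
  if (!nrow(pop)) abort("empty population after status filtering")
  tab <- pop |>
    dplyr::count(.data$cl, .data$func, name = "n") |>
    dplyr::arrange(.data$cl, .data$func) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  structure(tab, class = c("func_cld", class(tab)),
            n_chains = nrow(pop), statuses = statuses)
}

#' @export
as.matrix.func_cld <- function(x, ...) {
  cl_max <- max(x$cl)
  func_max <- max(x$func)
  m <- matrix(0, nrow = cl_max, ncol = func_max + 1L,
              dimnames = list(cl = seq_len(cl_max), func = 0:func_max))
  m[cbind(x$cl, x$func + 1L)] <- x$fraction
  m
}

#' @export
print.func_cld <- function(x, ...) {
  md <- cld_mode(x)
  cat(sprintf("<func_cld> %d chains, CL 1..%d, FUNC 0..%d, mode at (CL = %d, FUNC = %d)\n",
              attr(x, "n_chains"), max(x$cl), max(x$func), md$cl, md$func))
  NextMethod()
}

#' Marginal chain-length and functionality distributions
#'
#' Integrates the FUNC-CLD over FUNC to get the chain-length distribution
#' (CLD) and over CL to get the functionality distribution (FUNCD). Each
#' marginal sums to one.
#'
#' @param fc A `func_cld` from [build_func_cld()].
#' @return A list with tibbles `cld` (columns `cl`, `fraction`) and `funcd`
#'   (columns `func`, `fraction`).
#' @export
marginals <- function(fc) {
  stopifnot(inherits(fc, "func_cld"))
  list(cld = marginal_cld(fc), funcd = marginal_funcd(fc))
}

#' @rdname marginals
#' @export
marginal_cld <- function(fc) {
  fc |>
    dplyr::summarise(fraction = sum(.data$fraction), .by = "cl") |>
    dplyr::arrange(.data$cl) |>
    as_tibble()
}

#' @rdname marginals
#' @export
marginal_funcd <- function(fc) {
  fc |>
    dplyr::summarise(fraction = sum(.data$fraction), .by = "func") |>
    dplyr::arrange(.data$func) |>
    as_tibble()
}

.dist_mean <- function(value, fraction) sum(value * fraction) / sum(fraction)

#' Moments of a chain-length distribution
#'
#' `x_n = sum(CL p)`, `x_w = sum(CL^2 p) / x_n`, dispersity = `x_w / x_n`.
#'
#' @param cld Tibble with columns `cl`, `fraction` (normalized), from
#'   [marginal_cld()].
#' @return One-row tibble with `x_n`, `x_w`, `dispersity`.
#' @export
cld_moments <- function(cld) {
  p <- cld$fraction / sum(cld$fraction)
  x_n <- sum(cld$cl * p)
  x_w <- sum(cld$cl^2 * p) / x_n
  tibble(x_n = x_n, x_w = x_w, dispersity = x_w / x_n)
}

#' Moments of a functionality distribution
#'
#' @param funcd Tibble with columns `func`, `fraction`, from
#'   [marginal_funcd()].
#' @return One-row tibble with `mu` (mean number of functional units per
#'   chain) and `sigma` (its standard deviation).
#' @export
funcd_moments <- function(funcd) {
  p <- funcd$fraction / sum(funcd$fraction)
  mu <- sum(funcd$func * p)
  sigma <- sqrt(max(0, sum(funcd$func^2 * p) - mu^2))
  tibble(mu = mu, sigma = sigma)
}

#' Coefficient of variation of the functionality distribution
#'
#' `C_v,FUNCD = sigma_FUNCD / mu_FUNCD`, the dispersion metric of
#' functionalization quality; values up to 0.5 are conventionally taken as
#' acceptable (see [quality_thresholds()]).
#'
#' @inheritParams funcd_moments
#' @return A single number.
#' @export
coefficient_of_variation <- function(funcd) {
  m <- funcd_moments(funcd)
  if (m$mu <= 0) {
    abort("C_v is undefined: the population is entirely non-functionalized (mu = 0)")
  }
  m$sigma / m$mu
}

#' Fraction of non-functionalized chains
#'
#' The number fraction of chains with FUNC = 0.
#'
#' @inheritParams funcd_moments
#' @return A single number in `[0, 1]`.
#' @export
fraction_nonfunctionalized <- function(funcd) {
  p <- funcd$fraction / sum(funcd$fraction)
  sum(p[funcd$func == 0])
}

#' Macromonomer and branched-chain number fractions
#'
#' @param population Population tibble or `kmc_trajectory`.
#' @return One-row tibble with `macromonomer_fraction` (chains with status
#'   macromonomer over all chains) and `branched_fraction` (chains with at
#'   least one absorbed macromonomer over all chains).
#' @export
species_fractions <- function(population) {
  if (inherits(population, "kmc_trajectory")) population <- population$population
  if (!nrow(population)) abort("empty population")
  tibble(
    macromonomer_fraction = mean(population$status == "macromonomer"),
    branched_fraction = mean(population$branch_count >= 1)
  )
}

#' Poisson reference for a functionality distribution
#'
#' The Poisson pmf with rate equal to the FUNCD mean, truncated and
#' renormalized on the observed support. A functionality distribution
#' shaped by side reactions (chain transfer) is typically broader than this
#' reference at high monomer conversion.
#'
#' @inheritParams funcd_moments
#' @return Tibble with columns `func`, `fraction` on the support
#'   `0..max(funcd$func)`.
#' @export
poisson_reference <- function(funcd) {
  m <- funcd_moments(funcd)
  support <- 0:max(funcd$func)
  p <- dpois(support, lambda = m$mu)
  tibble(func = support, fraction = p / sum(p))
}

#' Mode of the bivariate distribution
#'
#' The (CL, FUNC) cell with the largest number fraction; ties are broken
#' toward the smallest CL, then the smallest FUNC.
#'
#' @param fc A `func_cld`.
#' @return One-row tibble with `cl`, `func`, `fraction`.
#' @export
cld_mode <- function(fc) {
  best <- fc |>
    dplyr::filter(.data$fraction == max(.data$fraction)) |>
    dplyr::arrange(.data$cl, .data$func) |>
    dplyr::slice(1)
  tibble(cl = best$cl, func = best$func, fraction = best$fraction)
}
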