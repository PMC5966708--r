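#' @keywords internal
"_PACKAGE"

#' @importFrom stats dist kmeans pchisq plogis pnorm pt qnorm qt runif rbinom
#'   rbeta sd var
#' @importFrom utils read.csv write.csv
NULL

# Truncated-normal draws by inverse-CDF. sd = 0 degenerates to the (clamped) mean.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(all(upper >= lower))
  if (all(sd == 0)) return(pmin(pmax(rep_len(mean, n), lower), upper))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  u <- runif(n, plo, phi)
  pmin(pmax(qnorm(u, mean, sd), lower), upper)
}

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stop_bad("'%s' = %g is outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, used to
#' measure how well a clustering recovers the generator's latent cognitive
#' states. Thin wrapper over [mclust::adjustedRandIndex()].
#'
#' @param a,b vectors of equal length; any label type.
#' @return a number, 1 for identical partitions (up to relabeling), about 0 for
#'   independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_bad("partitions differ in length")
  mclust::adjustedRandIndex(a, b)
}
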