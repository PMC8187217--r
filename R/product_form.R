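#' Product-form functions
#'
#' A product-form function is a strictly positive function
#' \eqn{f : Z_{\ge 0} \to R_{>0}} with \eqn{f(0) = 1}, stored through its
#' successive ratios \eqn{\rho(x) = f(x) / f(x - 1)} and evaluated in log
#' space (\eqn{\log f(x) = \sum_{l \le x} \log \rho(l)}) so that
#' factorial-type decay never underflows. Stationary distributions of the
#' form \eqn{\pi(x) \propto \prod_i f_i(x_i)} are assembled from one such
#' function per species.
#'
#' @param ratio a vectorised function of the level `l >= 1` returning
#'   \eqn{\rho(l) > 0}.
#' @param tag short label describing the closed form (`"poisson"`,
#'   `"motif"`, `"table"`, `"custom"`).
#' @param params list of parameters, kept for reporting.
#' @return An object of class `"pff"`.
#' @export
pff <- function(ratio, tag = "custom", params = list()) {
  cache <- new.env(parent = emptyenv())
  cache$cum <- numeric(0)   # cum[x] = log f(x)
  structure(list(ratio = ratio, tag = tag, params = params, cache = cache),
            class = "pff")
}

#' @export
print.pff <- function(x, ...) {
  cat(sprintf("Product-form function [%s], ratios f(x)/f(x-1): %s ...\n",
    x$tag, paste(format(pff_ratio(x, 1:4), digits = 4), collapse = ", ")))
  invisible(x)
}

#' @rdname pff
#' @param f a `"pff"` object.
#' @param l positive integer level(s).
#' @return `pff_ratio()`: the ratios \eqn{f(l)/f(l-1)}.
#' @export
pff_ratio <- function(f, l) f$ratio(l)

#' @rdname pff
#' @param x nonnegative integer vector.
#' @return `pff_log()`: \eqn{\log f(x)}, with \eqn{\log f(0) = 0}.
#' @export
pff_log <- function(f, x) {
  x <- as.integer(x)
  if (any(x < 0)) stop("product-form functions are defined on x >= 0")
  m <- if (length(x)) max(x) else 0L
  have <- length(f$cache$cum)
  if (m > have) {
    lr <- log(f$ratio(seq.int(have + 1L, m)))
    if (any(!is.finite(lr))) stop("nonpositive ratio in product-form function")
    f$cache$cum <- c(f$cache$cum, (if (have) f$cache$cum[have] else 0) +
                       cumsum(lr))
  }
  out <- numeric(length(x))
  pos <- x > 0L
  out[pos] <- f$cache$cum[x[pos]]
  out
}

#' @rdname pff
#' @return `pff_eval()`: \eqn{f(x)} on the natural scale.
#' @export
pff_eval <- function(f, x) exp(pff_log(f, x))

#' Exponential tilt of a product-form function
#'
#' Multiplies every ratio by `d`, i.e. replaces \eqn{f(x)} by
#' \eqn{d^x f(x)}. On a component with a conservation relation, tilting all
#' of a part's functions by the same `d` leaves the normalised distribution
#' unchanged; the tilt is the free constant used to match shared-species
#' functions across parts.
#'
#' @param f a `"pff"`.
#' @param d positive tilt.
#' @return A new `"pff"`.
#' @export
pff_tilt <- function(f, d) {
  stopifnot(d > 0)
  if (d == 1) return(f)
  base <- f$ratio
  pff(function(l) d * base(l), tag = f$tag,
      params = c(f$params, list(tilt = d)))
}

#' Poisson-type product-form function
#'
#' \eqn{f(x) = c^x / \prod_{l \le x} \theta(l)}; with mass-action
#' \eqn{\theta(l) = l} this is the Poisson form \eqn{c^x / x!} arising at a
#' point of complex balance.
#'
#' @param c positive rate parameter.
#' @param theta a `"crn_theta"` descriptor (default mass-action).
#' @return A `"pff"` with tag `"poisson"`.
#' @export
pff_poisson <- function(c, theta = mass_action()) {
  stopifnot(c > 0)
  pff(function(l) c / theta_eval(theta, l), tag = "poisson",
      params = list(c = c, theta = theta))
}

#' Product-form functions of the two-species exchange motif
#'
#' For the motif `U <-> W` (forward rate `k1`, backward `k2`) together with
#' `2U <-> U + W` (forward `k3`, backward `k4`) under kinetics
#' \eqn{\theta_U, \theta_W}, the stationary distribution on each component
#' is \eqn{\pi(u, w) \propto f_U(u) f_W(w)} with
#' \deqn{f_U(x) = \frac{d^x}{\prod_{l \le x} \theta_U(l)} \prod_{l = 1}^{x}
#'   \frac{k_2 + k_4 \theta_U(l - 1)}{k_1 + k_3 \theta_U(l - 1)}, \qquad
#'   f_W(x) = \frac{d^x}{\prod_{l \le x} \theta_W(l)}.}
#' Mass-action reduces \eqn{f_U} to
#' \eqn{(d^x / x!) \prod_l (k_2 + k_4 (l-1)) / (k_1 + k_3 (l-1))}. The free
#' constant `d > 0` re-tilts both functions and leaves the normalised
#' distribution on a conservative component unchanged.
#'
#' @param k1,k2,k3,k4 positive rate constants as above.
#' @param theta_u,theta_w `"crn_theta"` descriptors (default mass-action).
#' @param d positive free constant.
#' @return List with elements `f_slow` (the `U` function) and `f_fast`
#'   (the `W` function).
#' @export
motif_product_form <- function(k1, k2, k3, k4,
                               theta_u = mass_action(),
                               theta_w = mass_action(), d = 1) {
  stopifnot(k1 > 0, k2 > 0, k3 > 0, k4 > 0, d > 0)
  f_slow <- pff(function(l) {
    th_prev <- theta_eval(theta_u, l - 1)
    d * (k2 + k4 * th_prev) / ((k1 + k3 * th_prev) * theta_eval(theta_u, l))
  }, tag = "motif", params = list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, d = d))
  f_fast <- pff(function(l) d / theta_eval(theta_w, l), tag = "poisson",
                params = list(c = d, theta = theta_w))
  list(f_slow = f_slow, f_fast = f_fast)
}

#' Assemble a distribution from per-species product-form functions
#'
#' Normalises \eqn{\pi(x) = (1/Z) \prod_i f_i(x_i)} over the states of a
#' finite (possibly truncated) component. The normalising constant is
#' accumulated in log space via log-sum-exp.
#'
#' @param g a `"crn"` object.
#' @param fs named list of `"pff"` objects, one per species of `g`.
#' @param comp a `"crn_component"` (or state matrix).
#' @return A `"crn_distribution"` with `form = "product"`.
#' @export
product_form_distribution <- function(g, fs, comp) {
  states <- if (inherits(comp, "crn_component")) comp$states else comp
  fs <- fs[g$species]
  if (anyNA(names(fs)) || length(fs) != length(g$species))
    stop("fs must contain one product-form function per species")
  logw <- rowSums(matrix(vapply(seq_along(g$species),
                                function(i) pff_log(fs[[i]], states[, i]),
                                numeric(nrow(states))),
                         nrow = nrow(states)))
  m <- max(logw)
  logZ <- m + log(sum(exp(logw - m)))
  new_distribution(g, comp, logp = logw - logZ, form = "product",
                   fs = fs, logZ = logZ)
}

#' Poisson product-form stationary distribution
#'
#' The stationary distribution \eqn{\pi(x) = M_\Gamma \, c^x / x!} of a
#' complex-balanced network at a point of complex balance `c`, normalised
#' over the given component; under general kinetics the factorial is
#' replaced by \eqn{\prod_{l \le x_i} \theta_i(l)}.
#'
#' @param g a `"crn"` object.
#' @param c positive vector over species (a point of complex balance).
#' @param comp a `"crn_component"`.
#' @param kin optional kinetics.
#' @return A `"crn_distribution"` with `form = "product"`.
#' @export
poisson_product_form <- function(g, c, comp, kin = NULL) {
  kin <- resolve_kinetics(g, kin)
  stopifnot(all(c > 0), length(c) == length(g$species))
  fs <- stats::setNames(lapply(seq_along(g$species), function(i)
    pff_poisson(c[[i]], kin[[i]])), g$species)
  product_form_distribution(g, fs, comp)
}

#' Test whether an explicit distribution factorises over species groups
#'
#' Least-squares fit of \eqn{\log \pi(x) = \mathrm{const} + \sum_j
#' g_j(x_{\mathrm{group}_j})} over the support, with each group function
#' gauge-fixed to zero at its first observed level. With singleton groups
#' this tests the per-species product form; with coarser blocks it tests
#' block factorisations. The residual (max absolute deviation of the fit in
#' log space), not the fitted functions, is the decision criterion: on
#' conservative components the functions are identifiable only up to
#' exponential tilts along conservation laws.
#'
#' @param dist an explicit `"crn_distribution"` with strictly positive
#'   probabilities.
#' @param grouping list of character vectors partitioning the species.
#' @param tol residual threshold below which the distribution is declared
#'   of product form.
#' @return List with `product_form` (logical), `residual`, and `tables`
#'   (per group, a data frame of projected level keys and fitted log
#'   values).
#' @export
factorize_product_form <- function(dist, grouping = as.list(dist$species),
                                   tol = 1e-8) {
  species <- dist$species
  if (!setequal(unlist(grouping), species) ||
      length(unlist(grouping)) != length(species))
    stop("grouping must partition the species")
  if (any(dist$p <= 0))
    stop("factorisation needs strictly positive probabilities")
  states <- dist$states
  y <- dist$logp
  cols <- list(); labels <- list()
  for (j in seq_along(grouping)) {
    idx <- match(grouping[[j]], species)
    key <- apply(states[, idx, drop = FALSE], 1L, paste, collapse = ",")
    lev <- unique(key)
    ## gauge: the first observed level carries log g = 0, so a group with a
    ## single level contributes no column
    mm <- matrix(0, length(key), max(0L, length(lev) - 1L))
    for (v in seq_along(lev)[-1]) mm[key == lev[v], v - 1L] <- 1
    cols[[j]] <- mm
    labels[[j]] <- lev
  }
  X <- cbind(`(const)` = 1, do.call(cbind, cols))
  fit <- stats::lm.fit(X, y)
  resid <- max(abs(fit$residuals))
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  tables <- list()
  pos <- 2L
  for (j in seq_along(grouping)) {
    nl <- length(labels[[j]])
    vals <- c(0, coefs[seq.int(pos, length.out = nl - 1L)])
    pos <- pos + nl - 1L
    tables[[j]] <- data.frame(level = labels[[j]], log_f = as.numeric(vals),
                              stringsAsFactors = FALSE)
  }
  names(tables) <- vapply(grouping, paste, character(1), collapse = ",")
  list(product_form = resid < tol, residual = resid, tables = tables)
}

#' Proportionality constant between two product-form functions
#'
#' Returns \eqn{\alpha = h(x^*) / f(x^*)} at the smallest domain point if
#' \eqn{h = \alpha f} holds on the whole domain to relative tolerance, and
#' `NULL` otherwise. This is the matching hypothesis for shared species
#' between decomposition parts.
#'
#' @param f,h `"pff"` objects.
#' @param domain nonnegative integer vector of points to compare on.
#' @param tol relative tolerance.
#' @return Positive scalar `alpha`, or `NULL` when not proportional.
#' @export
proportionality_match <- function(f, h, domain, tol = 1e-10) {
  domain <- sort(unique(as.integer(domain)))
  if (!length(domain)) stop("empty domain")
  lf <- pff_log(f, domain)
  lh <- pff_log(h, domain)
  la <- lh[1] - lf[1]
  if (any(abs(exp(lh - lf - la) - 1) > tol)) return(NULL)
  exp(la)
}

#' Ratio-test summability of a product-form distribution
#'
#' On a finite component the normalising sum is trivially finite. On an
#' infinite product of per-species ranges the verdict is taken from the
#' limiting behaviour of the successive ratios \eqn{\rho_i(x)}: limits
#' below 1 for every species give `"summable"`, a limit above 1 gives
#' `"divergent"`, and limits at 1 (or unstable estimates) give
#' `"inconclusive"` — the ratio test is only a sufficient criterion.
#'
#' @param fs list of `"pff"` objects (one per unbounded species).
#' @param finite logical: is the component finite?
#' @param probe level at which limiting ratios are probed.
#' @return `"summable"`, `"divergent"` or `"inconclusive"`.
#' @export
ratio_test_summability <- function(fs, finite = FALSE, probe = 1e7) {
  if (finite) return("summable")
  verdicts <- vapply(fs, function(f) {
    r1 <- f$ratio(round(probe))
    r2 <- f$ratio(round(2 * probe))
    r <- max(r1, r2)
    if (r < 1 - 1e-4) "summable"
    else if (min(r1, r2) > 1 + 1e-4) "divergent"
    else "inconclusive"
  }, character(1))
  if (any(verdicts == "divergent")) return("divergent")
  if (any(verdicts == "inconclusive")) return("inconclusive")
  "summable"
}
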