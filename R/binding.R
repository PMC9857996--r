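#' Ligand-depletion quenching isotherm (closed form)
#'
#' Fluorescence intensity of a protein with `n` identical, independent
#' ligand sites at total ligand `[L]0` and total protein `[P]0`, with
#' explicit ligand depletion: the fraction of occupied sites comes from
#' the quadratic mass-action solution over the total site pool
#' `S = n [P]0`, so the model stays correct when ligand is comparable to
#' the sites rather than in vast excess.
#'
#' \deqn{I = I_0 - \frac{I_0 - I_\infty}{2 n [P]_0}\left[\frac1K + [L]_0 +
#'   n[P]_0 - \sqrt{\left(\frac1K + [L]_0 + n[P]_0\right)^2 -
#'   4 n [L]_0 [P]_0}\right]}
#'
#' The discriminant is clamped at zero before the square root as a
#' floating-point guard at the stoichiometric-equivalence point.
#'
#' @param p a [BindingParams].
#' @param proteinTotal total protein, M (> 0).
#' @param ligandTotal total ligand, M (>= 0); may be a vector.
#' @return Intensity in a.u., always within `[Iinf, I0]`.
#' @seealso [equilibriumIntensity()] for an independent numerical check.
#' @export
bindingIntensity <- function(p, proteinTotal, ligandTotal) {
  stopifnot(is(p, "BindingParams"))
  validObject(p)
  if (!is.finite(proteinTotal) || proteinTotal <= 0)
    .stopf("proteinTotal must be a positive concentration (M)")
  if (any(!is.finite(ligandTotal)) || any(ligandTotal < 0))
    .stopf("ligandTotal must be finite and non-negative (M)")
  S <- p@n * proteinTotal
  b <- 1 / p@K + ligandTotal + S
  disc <- pmax(b^2 - 4 * p@n * ligandTotal * proteinTotal, 0)
  bound <- (b - sqrt(disc)) / 2           # bound ligand, M
  I <- p@I0 - (p@I0 - p@Iinf) * bound / S
  pmin(pmax(I, p@Iinf), p@I0)
}

#' Equilibrium oracle for the quenching isotherm
#'
#' Independent route to the same intensity: solve the single-site
#' mass-action balance for free ligand `L` over the total site pool
#' `S = n [P]0`,
#' `L + S K L / (1 + K L) = [L]0`,
#' by bisection on `[0, [L]0]` (to `|f| < 1e-14 [L]0 + 1e-20`), then map
#' the bound fraction linearly to intensity. Used as a numerical oracle
#' for [bindingIntensity()]; the two agree to ~1e-9 relative.
#'
#' @inheritParams bindingIntensity
#' @return Intensity in a.u.
#' @export
equilibriumIntensity <- function(p, proteinTotal, ligandTotal) {
  stopifnot(is(p, "BindingParams"))
  validObject(p)
  if (!is.finite(proteinTotal) || proteinTotal <= 0)
    .stopf("proteinTotal must be a positive concentration (M)")
  S <- p@n * proteinTotal
  vapply(ligandTotal, function(L0) {
    if (!is.finite(L0) || L0 < 0) .stopf("ligandTotal must be >= 0")
    if (L0 == 0 || S == 0) return(p@I0)
    f <- function(L) L + S * p@K * L / (1 + p@K * L) - L0
    lo <- 0; hi <- L0
    tol <- 1e-14 * L0 + 1e-20
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm) < tol) break
      if (fm > 0) hi <- mid else lo <- mid
    }
    if (abs(f(mid)) >= tol && (hi - lo) > 4 * .Machine$double.eps * L0)
      .stopf("equilibrium bisection failed to converge")
    bound <- S * p@K * mid / (1 + p@K * mid)
    p@I0 - (p@I0 - p@Iinf) * bound / S
  }, numeric(1))
}

# Model curve used inside the optimizer: q = Iinf/I0 in [0,1] keeps
# I0 >= Iinf >= 0 true at any bounded optimum; K enters as log10 K for
# conditioning.
.bindingModel <- function(L, I0, q, n, lK, P0) {
  S <- n * P0
  K <- 10^lK
  b <- 1 / K + L + S
  disc <- pmax(b^2 - 4 * n * L * P0, 0)
  bound <- (b - sqrt(disc)) / 2
  I0 - I0 * (1 - q) * bound / S
}

#' Fit the ligand-depletion quenching isotherm
#'
#' Unweighted nonlinear least squares of [bindingIntensity()] to a
#' titration, estimating `I0`, `Iinf`, the stoichiometry `n` and the
#' per-site binding constant `K`. This objective is prone to local
#' minima, so a deterministic multi-start is used: a grid of starts over
#' `n` and log-spaced `K` (plus one data-driven start), each refined by
#' Levenberg-Marquardt within bounds (`n` in [0.5, 200], `K` in
#' [1e2, 1e9] M^-1, `Iinf` constrained to `[0, I0]` by construction);
#' the lowest residual sum of squares wins. Standard errors for `n` and
#' `K` are asymptotic (local curvature at the optimum; `K` via the delta
#' method on log10 K).
#'
#' A diagnostic warning is attached when the titration never reaches the
#' fitted site capacity (`max [L]0 < n_hat [P]0`): without a saturating
#' tail, `n` and `K` are weakly identified.
#'
#' @param data a [TitrationSeries] with at least 6 points.
#' @param fixI0 fix `I0` at the intensity of the lowest-ligand point
#'   instead of fitting it (the zero-ligand intensity is often measured
#'   directly).
#' @param startN,startK numeric vectors of starting values for `n` and
#'   `K` (M^-1); the defaults span the plausible range for multivalent
#'   protein-polyphenol binding.
#' @return A [BindingFit].
#' @examples
#' tr <- simulateTitration(noiseSd = 0, seed = 1)
#' fitBinding(tr)
#' @export
fitBinding <- function(data, fixI0 = FALSE,
                       startN = c(5, 15, 25, 50, 100),
                       startK = 10^(3:7)) {
  stopifnot(is(data, "TitrationSeries"))
  validObject(data)
  L <- data@ligandTotal
  I <- data@intensity
  P0 <- data@proteinTotal
  if (length(L) < 6L)
    .stopf("need at least 6 titration points to fit the isotherm")
  if (diff(range(I)) == 0)
    .stopf("no quenching signal: intensities are constant")

  I0start <- I[which.min(L)]
  qstart <- max(min(I) / max(I0start, .Machine$double.eps), 1e-3)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                     ptol = 1e-15)
  starts <- rbind(
    expand.grid(n = startN, lK = log10(startK)),
    # data-driven start: knee of the curve near n*P0, mid-range K
    data.frame(n = max(min(max(L) / (2 * P0), 190), 1), lK = 5))

  best <- NULL
  bestRss <- Inf
  for (i in seq_len(nrow(starts))) {
    st <- if (fixI0) {
      list(q = qstart, n = starts$n[i], lK = starts$lK[i])
    } else {
      list(I0 = I0start, q = qstart, n = starts$n[i], lK = starts$lK[i])
    }
    lower <- c(I0 = 0,   q = 0, n = 0.5, lK = 2)
    upper <- c(I0 = Inf, q = 1, n = 200, lK = 9)
    if (fixI0) { lower <- lower[-1]; upper <- upper[-1] }
    fml <- if (fixI0) {
      I ~ .bindingModel(L, I0start, q, n, lK, P0)
    } else {
      I ~ .bindingModel(L, I0, q, n, lK, P0)
    }
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        fml, data = list(L = L, I = I, P0 = P0, I0start = I0start),
        start = st, lower = lower, upper = upper, control = ctrl)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (rss < bestRss) { bestRss <- rss; best <- fit }
  }
  if (is.null(best))
    .stopf("binding fit failed: no start converged")

  cf <- stats::coef(best)
  I0hat <- if (fixI0) I0start else unname(cf["I0"])
  nhat <- unname(cf["n"])
  Khat <- 10^unname(cf["lK"])
  params <- BindingParams(I0 = I0hat, Iinf = I0hat * unname(cf["q"]),
                          n = nhat, K = Khat)

  se <- c(n = NA_real_, K = NA_real_)
  vc <- tryCatch(stats::vcov(best), error = function(e) NULL)
  if (!is.null(vc) && all(is.finite(diag(vc)))) {
    se["n"] <- sqrt(vc["n", "n"])
    se["K"] <- Khat * log(10) * sqrt(vc["lK", "lK"])
  }

  warns <- character()
  if (max(L) < nhat * P0)
    warns <- c(warns, sprintf(
      "titration does not reach the fitted site capacity (max ligand %.3g M < n*[P]0 = %.3g M); n and K are weakly identified",
      max(L), nhat * P0))

  new("BindingFit", params = params, stderr = se, rss = bestRss,
      converged = TRUE, nStartsUsed = nrow(starts), warnings = warns)
}

#' Serialize a BindingFit to JSON
#'
#' @param fit a [BindingFit].
#' @return A JSON string with parameters, standard errors, rss and
#'   warnings.
#' @export
bindingFitJSON <- function(fit) {
  stopifnot(is(fit, "BindingFit"))
  p <- fit@params
  jsonlite::toJSON(list(
    I0 = p@I0, I_inf = p@Iinf, n = p@n, K_per_M = p@K,
    stderr_n = fit@stderr[["n"]], stderr_K = fit@stderr[["K"]],
    rss = fit@rss, converged = fit@converged,
    n_starts_used = fit@nStartsUsed, warnings = fit@warnings),
    auto_unbox = TRUE, digits = NA, na = "null")
}
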