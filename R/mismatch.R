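# Mismatch distributions, the sudden-expansion model, SSD and raggedness
# goodness-of-fit with a parametric bootstrap.

#' Observed mismatch distribution of one population sample
#'
#' Relative frequencies of pairwise difference counts over all gene-copy
#' pairs, computed on the analyzed (indel-free) columns.
#'
#' @param aln a [locus_alignment()] whose records are the sampled copies, or
#'   an allele alignment combined with `copies`.
#' @param copies allele/record ids of the gene copies (defaults to every
#'   record of `aln`).
#' @return numeric vector `x_0 .. x_d` (named by difference count) summing
#'   to 1, where `d` is the largest observed difference.
#' @export
mismatch_histogram <- function(aln, copies = aln$allele_ids) {
  n <- length(copies)
  if (n < 2L) stop("need at least 2 gene copies")
  dmat <- allele_diff_matrix(aln)
  idx <- match(copies, aln$allele_ids)
  if (anyNA(idx)) stop("unknown copy id(s)")
  d <- dmat[idx, idx]
  vals <- d[upper.tri(d)]
  dmax <- max(vals)
  x <- tabulate(vals + 1L, nbins = dmax + 1L) / length(vals)
  names(x) <- 0:dmax
  x
}

# equilibrium mismatch distribution (geometric)
mismatch_eq <- function(theta, j) {
  if (theta <= 0) return(as.numeric(j == 0))
  exp(j * log(theta) - (j + 1) * log(theta + 1))
}

#' Expected mismatch distribution under a sudden expansion
#'
#' Exact pair-coalescent law for a population whose mutation-scaled size
#' changed from `theta0` to `theta1` at time `tau` (units of 2*u*t) before
#' the present: conditioning on whether the pair coalesces before or after
#' the size shift gives
#' `F_j = Fhat_j(theta1) * P(Pois(lambda tau) > j) +
#'   exp(-tau/theta1) * sum_i dpois(i, tau) * Fhat_{j-i}(theta0)`
#' with `lambda = (theta1 + 1)/theta1` and `Fhat_j(theta)` the equilibrium
#' geometric distribution.  Reduces to the classical Rogers-Harpending
#' expression for large `theta1`, to the geometric law at `tau = 0` or
#' `theta1 = theta0`, and to Poisson(tau) for `theta0 = 0`,
#' `theta1 -> Inf`.
#'
#' @param tau scaled expansion time (>= 0).
#' @param theta0,theta1 ancestral and current theta (>= 0).
#' @param j difference class(es), vectorized.
#' @return probabilities `F_j`.
#' @export
expected_mismatch <- function(tau, theta0, theta1, j) {
  if (tau < 0 || theta0 < 0 || theta1 < 0)
    stop("parameters must be non-negative")
  if (tau == 0) return(mismatch_eq(theta0, j))
  if (theta1 == 0) stop("theta1 = 0 with tau > 0 is degenerate")
  lambda <- (theta1 + 1) / theta1
  J <- max(j)
  jj <- 0:J
  # pair coalesces after the shift (recent epoch, size theta1)
  recent <- mismatch_eq(theta1, jj) *
    pmax(1 - cumsum(stats::dpois(jj, lambda * tau)), 0)
  # pair predates the shift: Poisson(tau) mutations on the recent epoch
  # plus an equilibrium-theta0 count (discrete convolution)
  pw <- stats::dpois(jj, tau)
  # eq0 is geometric (rate rho), so the convolution satisfies
  # conv[m] = rho * conv[m-1] + c * pw[m]
  rho <- if (theta0 > 0) theta0 / (theta0 + 1) else 0
  cc <- if (theta0 > 0) 1 / (theta0 + 1) else 1
  conv <- numeric(J + 1L)
  conv[[1L]] <- cc * pw[[1L]]
  if (J > 0L) for (m in 2:(J + 1L))
    conv[[m]] <- rho * conv[[m - 1L]] + cc * pw[[m]]
  old <- exp(-tau / theta1) * conv
  pmax((recent + old)[j + 1L], 0)
}

#' Harpending's raggedness index
#'
#' `r = sum (x_i - x_{i-1})^2` over successive classes with the histogram
#' padded by zero classes on both ends, so both the initial rise and the
#' final fall count.
#'
#' @param x mismatch histogram (relative frequencies, classes 0..d).
#' @return raggedness index.
#' @export
raggedness <- function(x) {
  sum(diff(c(0, as.numeric(x), 0))^2)
}

# SSD between an observed histogram (classes 0..d, d = last non-zero
# class) and the model; trailing zero classes of x are ignored so zero
# padding cannot change the fit
ssd_objective <- function(x, tau, theta0, theta1) {
  nz <- which(x > 0)
  if (length(nz) == 0L) return(Inf)
  d <- max(nz) - 1L
  xx <- x[seq_len(d + 1L)]
  fe <- expected_mismatch(tau, theta0, theta1, 0:d)
  sum((xx - fe)^2)
}

#' Least-squares fit of the sudden-expansion model
#'
#' Minimizes `SSD = sum_j (x_j - F_j(tau, theta0, theta1))^2` over the
#' classes up to the largest observed difference, with `theta1`
#' reparameterized as `theta0 + delta` (so `theta1 >= theta0`) and capped
#' at 1e5.  A grid of 27 starting points seeds local refinement; ties are
#' broken toward the smallest `tau`.
#'
#' @param x observed mismatch histogram.
#' @param n_starts number of multi-start grid points actually used (the
#'   full grid is 27; reduce for bootstrap replicates).
#' @param starts optional matrix of explicit starting points (columns tau,
#'   theta0, theta1 - theta0), overriding the grid.
#' @return list with `tau`, `theta0`, `theta1`, `SSD`, `boundary` (TRUE for
#'   a degenerate all-identical sample fitted at `tau = 0`).
#' @export
fit_sudden_expansion <- function(x, n_starts = 27L, starts = NULL,
                                 iter_max = 500L) {
  x <- as.numeric(x)
  if (sum(x) <= 0) stop("empty histogram")
  if (max(which(x > 0)) == 1L)
    return(list(tau = 0, theta0 = 0, theta1 = 0, SSD = 0, boundary = TRUE))
  mbar <- sum((seq_along(x) - 1L) * x)
  obj <- function(par) {
    tau <- par[[1L]]; th0 <- par[[2L]]; th1 <- th0 + par[[3L]]
    if (anyNA(par) || tau < 0 || th0 < 0 || par[[3L]] < 0 || th1 > 1e5)
      return(1e6)
    val <- ssd_objective(x, tau, th0, th1)
    if (!is.finite(val)) 1e6 else val
  }
  if (is.null(starts)) {
    starts <- expand.grid(tau = pmax(c(0.5, 1, 2) * mbar, 0.1),
                          th0 = c(0.1, 1, max(mbar, 1)),
                          d1 = c(max(mbar, 1), 10 * max(mbar, 1), 1000))
    starts <- starts[seq_len(min(n_starts, nrow(starts))), , drop = FALSE]
  }
  starts <- as.matrix(starts)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      nlminb(as.numeric(starts[i, ]), obj, lower = c(0, 0, 0),
             control = list(iter.max = iter_max, rel.tol = 1e-9)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective - 1e-12 ||
        (abs(fit$objective - best$objective) <= 1e-12 &&
         fit$par[[1L]] < best$par[[1L]]))
      best <- fit
  }
  if (is.null(best)) {
    # derivative-based refinement can fail on pathological histograms;
    # fall back to Nelder-Mead, then to the best raw start
    for (i in seq_len(nrow(starts))) {
      fit <- tryCatch(stats::optim(as.numeric(starts[i, ]), obj,
                                   method = "Nelder-Mead",
                                   control = list(maxit = 500L)),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        cand <- list(par = pmax(fit$par, 0), objective = fit$value)
        if (is.null(best) || cand$objective < best$objective)
          best <- cand
      }
    }
  }
  if (is.null(best)) {
    vals <- apply(starts, 1L, obj)
    i <- which.min(vals)
    best <- list(par = as.numeric(starts[i, ]), objective = vals[[i]])
  }
  list(tau = best$par[[1L]], theta0 = best$par[[2L]],
       theta1 = min(best$par[[2L]] + best$par[[3L]], 1e5),
       SSD = best$objective, boundary = FALSE)
}

# simulate a mismatch histogram of n copies under the fitted expansion
# (pairwise differences straight from the genealogy; no sequences needed)
sim_mismatch_histogram <- function(n, tau, theta0, theta1) {
  gen <- coal_genealogy(n, theta = theta1, M = 0, tau_break = tau,
                        theta_old = theta0)
  carriers <- mutation_carriers(gen)
  d <- matrix(0, n, n)
  for (t_ in carriers) d[t_, -t_] <- d[t_, -t_] + 1
  vals <- d[upper.tri(d)] + t(d)[upper.tri(d)]
  dmax <- max(vals, 1)
  x <- tabulate(vals + 1L, nbins = dmax + 1L) / length(vals)
  names(x) <- 0:dmax
  x
}

#' Parametric bootstrap p-values for mismatch SSD and raggedness
#'
#' Simulates coalescent samples of the same size under the fitted sudden
#' expansion, refits the model to each, and reports
#' `p_SSD = Pr(SSD_sim >= SSD_obs)` and `p_r = Pr(r_sim >= r_obs)`.
#'
#' @param x observed mismatch histogram.
#' @param n gene copies behind `x`.
#' @param fitted result of [fit_sudden_expansion()] on `x`.
#' @param n_boot bootstrap replicates (must be positive).
#' @param n_starts multi-start points used in each refit.
#' @param iter_max optimizer iteration cap per refit.
#' @param seed integer seed.
#' @return list with `p_SSD`, `p_raggedness`, `SSD_obs`, `r_obs`.
#' @export
mismatch_bootstrap <- function(x, n, fitted, n_boot = 10000L, n_starts = 9L,
                               iter_max = 500L, seed = 1L) {
  if (n_boot < 1L) stop("n_boot must be positive")
  set.seed(seed)
  r_obs <- raggedness(x)
  # refits start from the generating (fitted) parameters plus grid points
  base_start <- c(fitted$tau, fitted$theta0,
                  max(fitted$theta1 - fitted$theta0, 0.1))
  ssd_sim <- numeric(n_boot); r_sim <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    xb <- sim_mismatch_histogram(n, fitted$tau, fitted$theta0, fitted$theta1)
    mb <- sum((seq_along(xb) - 1L) * xb)
    st <- rbind(base_start,
                c(max(mb, 0.1), 0.1, max(mb, 1)),
                c(max(0.5 * mb, 0.1), 1, 1000))
    st <- st[seq_len(min(n_starts, nrow(st))), , drop = FALSE]
    ssd_sim[[b]] <- fit_sudden_expansion(xb, starts = st,
                                         iter_max = iter_max)$SSD
    r_sim[[b]] <- raggedness(xb)
  }
  list(p_SSD = mean(ssd_sim >= fitted$SSD - 1e-12),
       p_raggedness = mean(r_sim >= r_obs - 1e-12),
       SSD_obs = fitted$SSD, r_obs = r_obs)
}
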