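# Free-energy estimators and diagnostics. MBAR is solved by self-consistent
# iteration with a switch to Newton steps on the dimensionless free-energy
# vector; uncertainties come from the MBAR asymptotic covariance. BAR is the
# two-state Bennett equation solved by bracketed root finding, and
# exponential averaging (Zwanzig) is provided as the one-sided consistency
# check that brackets BAR.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log-denominators d_n = log sum_k N_k exp(f_k - u_kn); u is K x N
mbar_logdenom <- function(u, f, logN) {
  a <- (logN + f) - u              # K x N via column recycling
  amax <- apply(a, 2L, max)
  amax + log(colSums(exp(sweep(a, 2L, amax))))
}

pinv_sym <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d, 0)
  if (!any(pos)) return(matrix(0, nrow(m), ncol(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Solve the MBAR equations
#'
#' Multistate Bennett acceptance ratio estimate of the dimensionless free
#' energies \eqn{f_k} of K thermodynamic states from samples of all states
#' cross-evaluated in all states. Solved by self-consistent iteration with a
#' Newton refinement; convergence is declared when the largest change of any
#' \eqn{f_k} per iteration falls below `tol`. The asymptotic covariance of
#' the \eqn{f_k} is returned for uncertainty estimates.
#'
#' @param ukn A `u_kn` object (see [new_u_kn()]), or a K x N matrix if
#'   `N_k` is given.
#' @param N_k Per-state sample counts when `ukn` is a bare matrix.
#' @param tol Convergence tolerance on max |delta f| per iteration.
#' @param max_iter Maximum iterations; non-convergence is an error carrying
#'   the last residual.
#' @return Object of class `mbar_result`: `f` (dimensionless, anchored at
#'   `f[1] = 0`), `Theta` (asymptotic covariance), `N_k`, `W` (N x K weight
#'   matrix, columns summing to 1), `iterations`, `residual`.
#' @examples
#' # two harmonic states with k2 = 4 k1: exact delta f = ln 2
#' set.seed(1)
#' x1 <- rnorm(2000, sd = 1); x2 <- rnorm(2000, sd = 0.5)
#' u <- rbind(c(x1^2 / 2, x2^2 / 2), c(2 * x1^2, 2 * x2^2))
#' fit <- mbar_solve(new_u_kn(u, c(2000, 2000)))
#' fit$f[2] # near log(2)
#' @export
mbar_solve <- function(ukn, N_k = NULL, tol = 1e-8, max_iter = 2000L) {
  if (inherits(ukn, "u_kn")) { u <- ukn$u; N_k <- ukn$N_k }
  else { u <- as.matrix(ukn); if (is.null(N_k)) stop("N_k required") }
  K <- nrow(u); N <- ncol(u)
  N_k <- as.numeric(N_k)
  if (any(N_k < 1)) stop("every state needs N_k >= 1")
  if (any(!is.finite(u))) stop("u_kn entries must be finite")
  logN <- log(N_k)

  scf_update <- function(f) {
    d <- mbar_logdenom(u, f, logN)
    fn <- -apply(-u - matrix(d, K, N, byrow = TRUE), 1L, logsumexp)
    fn - fn[1L]
  }
  grad_hess <- function(f) {
    d <- mbar_logdenom(u, f, logN)
    logw <- (logN + f) - u - matrix(d, K, N, byrow = TRUE)  # K x N, cols sum to 1
    W <- exp(logw)
    gr <- rowSums(W) - N_k
    H <- diag(rowSums(W), K) - tcrossprod(W)
    list(gr = gr, H = H)
  }

  f <- numeric(K)
  resid <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    fn <- scf_update(f)
    resid <- max(abs(fn - f))
    f <- fn
    if (resid < tol) break
    if (it >= 10L && resid < 1e-2) {
      # Newton refinement on the anchored subspace
      repeat {
        gh <- grad_hess(f)
        step <- tryCatch(
          solve(gh$H[-1L, -1L, drop = FALSE], -gh$gr[-1L]),
          error = function(e) NULL)
        if (is.null(step) || any(!is.finite(step))) break
        if (max(abs(step)) > 2) step <- step * 2 / max(abs(step))
        f_new <- f; f_new[-1L] <- f_new[-1L] + step
        resid_new <- max(abs(scf_update(f_new) - f_new))
        if (!is.finite(resid_new) || resid_new >= resid) break
        f <- f_new; resid <- resid_new
        it <- it + 1L
        if (resid < tol || it >= max_iter) break
      }
      if (resid < tol) break
    }
  }
  if (resid >= tol)
    stop(sprintf("MBAR did not converge in %d iterations (last residual %.3g)",
                 max_iter, resid))

  d <- mbar_logdenom(u, f, logN)
  W <- t(exp(matrix(f, K, N) - u - matrix(d, K, N, byrow = TRUE)))  # N x K
  colsum <- colSums(W)
  if (any(abs(colsum - 1) > 1e-6))
    warning("MBAR normalization identities violated (empty-overlap pathology?): max |sum W - 1| = ",
            format(max(abs(colsum - 1))))
  # asymptotic covariance: Theta = W'W [I - diag(N) W'W]^+
  S <- crossprod(W)
  Theta <- S %*% pinv_sym(diag(K) - diag(N_k, K) %*% S)
  Theta <- (Theta + t(Theta)) / 2

  structure(list(f = f, Theta = Theta, N_k = N_k, W = W,
                 iterations = it, residual = resid),
            class = "mbar_result")
}

#' @export
print.mbar_result <- function(x, ...) {
  df <- delta_f(x)
  cat(sprintf("<mbar_result> %d states, %d samples; delta f(1 -> K) = %.4f +/- %.4f kT (%d iterations)\n",
              length(x$f), sum(x$N_k), df$df, df$ddf, x$iterations))
  invisible(x)
}

#' Free-energy difference between two states of an MBAR fit
#'
#' @param fit An `mbar_result`.
#' @param i,j State indices (defaults: first and last).
#' @return List with `df` (dimensionless) and `ddf` (asymptotic standard
#'   error, dimensionless).
#' @export
delta_f <- function(fit, i = 1L, j = length(fit$f)) {
  stopifnot(inherits(fit, "mbar_result"))
  v <- fit$Theta[i, i] + fit$Theta[j, j] - 2 * fit$Theta[i, j]
  list(df = fit$f[j] - fit$f[i], ddf = sqrt(max(v, 0)))
}

#' Bennett acceptance ratio (BAR) estimate
#'
#' Two-state free-energy difference from forward and reverse work values,
#' solving the Bennett implicit equation by bracketed root finding. The
#' returned uncertainty is the standard Bennett asymptotic variance.
#'
#' @param w_forward Reduced work values \eqn{u_2(x) - u_1(x)} for samples
#'   from state 1.
#' @param w_reverse Reduced work values \eqn{u_1(x) - u_2(x)} for samples
#'   from state 2.
#' @param tol Root-finding tolerance (kT).
#' @return List with `df` (dimensionless free energy of 1 -> 2) and `ddf`.
#' @examples
#' bar(rnorm(1000, 1, 1), rnorm(1000, -1, 1))$df # near 0... plus bias terms
#' @export
bar <- function(w_forward, w_reverse, tol = 1e-10) {
  nf <- length(w_forward); nr <- length(w_reverse)
  if (nf == 0L || nr == 0L) stop("both work arrays must be nonempty")
  M <- log(nf / nr)
  # Bennett: sum_F fermi(M + wF - df) - sum_R fermi(-M + wR + df) = 0
  fermi <- function(x) 1 / (1 + exp(x))
  gfun <- function(df) sum(fermi(M + w_forward - df)) - sum(fermi(-M + w_reverse + df))
  lo <- min(-w_reverse, w_forward) - 1
  hi <- max(-w_reverse, w_forward) + 1
  glo <- gfun(lo); ghi <- gfun(hi)
  tries <- 0L
  while (sign(glo) == sign(ghi) && tries < 60L) {
    span <- hi - lo
    lo <- lo - span; hi <- hi + span
    glo <- gfun(lo); ghi <- gfun(hi)
    tries <- tries + 1L
  }
  if (sign(glo) == sign(ghi))
    stop("BAR bracket failure: no sign change after widening the bracket")
  df <- uniroot(gfun, c(lo, hi), tol = tol)$root
  fF <- fermi(M + w_forward - df)
  fR <- fermi(-M + w_reverse + df)
  v <- (mean(fF^2) / mean(fF)^2 - 1) / nf + (mean(fR^2) / mean(fR)^2 - 1) / nr
  list(df = df, ddf = sqrt(max(v, 0)))
}

#' Exponential-averaging (Zwanzig) estimate
#'
#' One-sided free-energy perturbation:
#' \eqn{\Delta f = -\ln \langle e^{-w} \rangle} over the work values of one
#' sampling direction. Bias decreases with overlap; forward and reverse
#' estimates bracket the BAR estimate.
#'
#' @param w Reduced work values (forward: \eqn{u_2-u_1} on state-1 samples;
#'   reverse: \eqn{u_1-u_2} on state-2 samples, in which case the estimate
#'   is for the 2 -> 1 direction).
#' @return List with `df` and `ddf` (delta-method standard error),
#'   dimensionless.
#' @export
exp_averaging <- function(w) {
  n <- length(w)
  if (n == 0L) stop("empty work array")
  lse <- logsumexp(-w)
  df <- -(lse - log(n))
  x <- exp(-w - max(-w))
  v <- var(x) / (n * mean(x)^2)
  list(df = df, ddf = sqrt(max(v, 0)))
}

#' MBAR phase-space overlap matrix
#'
#' \eqn{O_{ij} = \sum_n W_{ni} W_{nj} N_j}: row i gives the probability
#' mass of state i's samples that is shared with each state j. Rows sum to
#' 1; adjacent-state entries above about 0.03 indicate sufficient overlap
#' for reliable estimation.
#'
#' @param ukn A `u_kn` object (or K x N matrix with `N_k`).
#' @param fit An `mbar_result` for the same data; computed if missing.
#' @param N_k Sample counts when `ukn` is a bare matrix.
#' @return K x K matrix of class `overlap_matrix`, with attribute
#'   `min_neighbor` (smallest nearest-neighbor overlap).
#' @export
overlap_matrix <- function(ukn, fit = NULL, N_k = NULL) {
  if (is.null(fit)) fit <- mbar_solve(ukn, N_k = N_k)
  if (!inherits(fit, "mbar_result"))
    stop("'fit' must be a converged (anchored) mbar_result")
  W <- fit$W
  O <- crossprod(W) %*% diag(fit$N_k, length(fit$N_k))
  O <- O / rowSums(O)   # exact at the MBAR fixed point; removes solver-tol residue
  K <- nrow(O)
  nb <- if (K > 1L) min(O[cbind(1:(K - 1L), 2:K)], O[cbind(2:K, 1:(K - 1L))]) else 1
  structure(O, class = c("overlap_matrix", "matrix"), min_neighbor = nb)
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("<overlap_matrix> %d states; min nearest-neighbor overlap %.4f (threshold 0.03)\n",
              nrow(x), attr(x, "min_neighbor")))
  m <- unclass(x); attr(m, "min_neighbor") <- NULL
  print(round(m, 4))
  invisible(x)
}

#' Forward/reverse convergence analysis
#'
#' Re-estimates the end-to-end free-energy difference of a stage on growing
#' chronological prefixes ("forward") and growing time-reversed prefixes
#' ("reverse") of each state's samples. Agreement of the two series within
#' their combined uncertainty indicates convergence; the final fraction uses
#' the full data so forward and reverse values coincide there.
#'
#' @param ukn A `u_kn` object with chronologically ordered columns.
#' @param fractions Increasing data fractions in (0, 1]; fractions that
#'   leave any state empty are skipped with a warning.
#' @param i,j States whose difference is tracked (defaults: first, last).
#' @return Object of class `convergence_series`: a data.frame with columns
#'   `fraction`, `forward`, `forward_err`, `reverse`, `reverse_err`
#'   (dimensionless kT), with attribute `converged` (forward and reverse
#'   agree within combined error at the final fraction).
#' @export
forward_reverse <- function(ukn, fractions = seq(0.1, 1, by = 0.1),
                            i = 1L, j = NULL) {
  stopifnot(inherits(ukn, "u_kn"))
  if (any(diff(fractions) <= 0) || any(fractions <= 0) || any(fractions > 1))
    stop("fractions must increase within (0, 1]")
  K <- length(ukn$N_k)
  if (is.null(j)) j <- K
  offs <- c(0L, cumsum(ukn$N_k))
  est <- function(cols) {
    sub <- new_u_kn(ukn$u[, sort(cols), drop = FALSE],
                    vapply(seq_len(K), function(k)
                      sum(cols > offs[k] & cols <= offs[k + 1L]), 0L))
    fit <- mbar_solve(sub)
    delta_f(fit, i, j)
  }
  rows <- lapply(fractions, function(fr) {
    take <- lapply(seq_len(K), function(k) {
      nk <- ukn$N_k[k]
      m <- floor(fr * nk)
      if (m < 1L) return(NULL)
      list(fwd = offs[k] + seq_len(m), rev = offs[k] + nk - seq_len(m) + 1L)
    })
    if (any(vapply(take, is.null, TRUE))) {
      warning(sprintf("fraction %.3g yields zero samples in some state; skipped", fr))
      return(NULL)
    }
    fw <- est(unlist(lapply(take, `[[`, "fwd")))
    rv <- est(unlist(lapply(take, `[[`, "rev")))
    data.frame(fraction = fr, forward = fw$df, forward_err = fw$ddf,
               reverse = rv$df, reverse_err = rv$ddf)
  })
  out <- do.call(rbind, rows)
  last <- out[nrow(out), ]
  conv <- abs(last$forward - last$reverse) <=
    sqrt(last$forward_err^2 + last$reverse_err^2) + 1e-9
  structure(out, class = c("convergence_series", "data.frame"),
            converged = conv)
}

#' @export
print.convergence_series <- function(x, ...) {
  cat("<convergence_series> forward/reverse free-energy estimates (kT)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(if (isTRUE(attr(x, "converged"))) "converged: forward and reverse agree within combined error\n"
      else "NOT converged at final fraction\n")
  invisible(x)
}

#' Stage free energy from a reduced-potential matrix
#'
#' MBAR estimate of the free-energy difference between the first and last
#' state of a stage schedule, converted to kcal/mol.
#'
#' @param ukn A `u_kn` object.
#' @param thermo A [thermo_state()] or temperature in K.
#' @param subsample Thin to independent frames by [subsample_u_kn()] first
#'   (default `TRUE`).
#' @return List with `dG` and `err` (kcal/mol), `df`/`ddf` (kT), `fit`
#'   (`mbar_result`), `ukn_used`.
#' @export
stage_free_energy <- function(ukn, thermo = thermo_state(300), subsample = TRUE) {
  th <- as_thermo(thermo)
  used <- if (isTRUE(subsample)) subsample_u_kn(ukn) else ukn
  fit <- mbar_solve(used)
  d <- delta_f(fit)
  list(dG = d$df * th$RT_kcal, err = d$ddf * th$RT_kcal,
       df = d$df, ddf = d$ddf, fit = fit, ukn_used = used)
}
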