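#' Affine-invariant ensemble sampler with differential-evolution moves
#'
#' Runs an ensemble of walkers over a log-density. At each step the ensemble
#' is split in half and each walker proposes a jump along the difference of
#' two distinct walkers from the complementary half, scaled by
#' `2.38 / sqrt(2 d)` (with a small jitter and, occasionally, a full-length
#' "mode-hopping" jump), accepted by Metropolis-Hastings. The move is
#' symmetric, so detailed balance holds.
#'
#' @param log_prob function taking a parameter vector, returning a
#'   log-density (may be `-Inf`).
#' @param init matrix of starting positions, one row per walker.
#' @param n_steps number of ensemble steps to run.
#' @param gamma0 base scale of the differential-evolution jump.
#' @param big_jump_prob probability of proposing an unscaled jump.
#' @return List with `chain` (array `n_steps x n_walkers x n_dim`),
#'   `log_probs` (`n_steps x n_walkers`), `accept_frac` and the final
#'   positions.
#' @export
ensemble_mcmc <- function(log_prob, init, n_steps,
                          gamma0 = 2.38 / sqrt(2 * ncol(init)),
                          big_jump_prob = 0.1) {
  n_walkers <- nrow(init)
  n_dim <- ncol(init)
  if (n_walkers < 2L * n_dim) {
    stop("need at least 2 walkers per dimension (got ", n_walkers, ")")
  }
  pos <- init
  lp <- apply(pos, 1L, log_prob)
  if (any(!is.finite(lp))) {
    stop("some walkers start at zero density; choose starts inside the support")
  }
  chain <- array(NA_real_, c(n_steps, n_walkers, n_dim))
  lp_hist <- matrix(NA_real_, n_steps, n_walkers)
  halves <- list(seq_len(n_walkers %/% 2L),
                 (n_walkers %/% 2L + 1L):n_walkers)
  n_accept <- 0L
  for (step in seq_len(n_steps)) {
    for (h in 1:2) {
      mine <- halves[[h]]
      other <- halves[[3L - h]]
      for (i in mine) {
        ab <- sample(other, 2L)
        gamma <- if (stats::runif(1) < big_jump_prob) 1 else
          gamma0 * (1 + 1e-4 * stats::rnorm(1))
        prop <- pos[i, ] + gamma * (pos[ab[1L], ] - pos[ab[2L], ])
        lp_prop <- log_prob(prop)
        if (is.finite(lp_prop) &&
            log(stats::runif(1)) < lp_prop - lp[i]) {
          pos[i, ] <- prop
          lp[i] <- lp_prop
          n_accept <- n_accept + 1L
        }
      }
    }
    chain[step, , ] <- pos
    lp_hist[step, ] <- lp
  }
  list(chain = chain, log_probs = lp_hist,
       accept_frac = n_accept / (n_steps * n_walkers),
       pos = pos, lp = lp)
}

#' Integrated autocorrelation time of an ensemble chain
#'
#' FFT-based autocorrelation averaged across walkers, summed with the
#' self-consistent window (window `M` is the smallest lag with
#' `M >= c * tau(M)`). Returns one time per parameter.
#'
#' @param chain array `n_steps x n_walkers x n_dim`.
#' @param c window constant.
#' @return Numeric vector of length `n_dim`.
#' @export
autocorr_time <- function(chain, c = 5) {
  d <- dim(chain)
  vapply(seq_len(d[3L]), function(p) {
    acf_mean <- autocorr_fn_mean(chain[, , p, drop = FALSE])
    taus <- 2 * cumsum(acf_mean) - 1
    window <- which(seq_along(taus) >= c * taus)
    if (length(window)) taus[window[1L]] else taus[length(taus)]
  }, numeric(1))
}

# normalized autocorrelation function averaged over walkers
autocorr_fn_mean <- function(x3) {
  n <- dim(x3)[1L]
  n_w <- dim(x3)[2L]
  m <- 2L^ceiling(log2(2L * n))
  total <- numeric(n)
  for (w in seq_len(n_w)) {
    x <- x3[, w, 1L]
    x <- x - mean(x)
    f <- stats::fft(c(x, rep(0, m - n)))
    ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)]
    if (ac[1L] <= 0) ac <- c(1, rep(0, n - 1L)) else ac <- ac / ac[1L]
    total <- total + ac
  }
  total / n_w
}

#' Convergence check for the ensemble chain
#'
#' The burn-in is considered over once (a) the relative change between the
#' two most recent autocorrelation-time estimates is below `rel_tol` and
#' (b) the current estimate is below `chain_length / trust_factor` — earlier
#' estimates being too short to trust.
#'
#' @param tau_history numeric vector of successive mean autocorrelation-time
#'   estimates (at least two).
#' @param chain_length current number of ensemble steps.
#' @param rel_tol threshold on the relative change.
#' @param trust_factor the chain must be this many times longer than the
#'   autocorrelation time.
#' @return List with `converged`, `tau`, `rel_change` and `trust_limit`.
#' @examples
#' check_convergence(c(100, 99.9), 10000)$converged  # TRUE
#' @export
check_convergence <- function(tau_history, chain_length,
                              rel_tol = 5.0e-2, trust_factor = 50) {
  if (length(tau_history) < 2L) {
    return(list(converged = FALSE, tau = utils::tail(tau_history, 1L),
                rel_change = NA_real_,
                trust_limit = chain_length / trust_factor))
  }
  k <- length(tau_history)
  tau <- tau_history[k]
  rel_change <- abs(tau - tau_history[k - 1L]) / tau
  list(
    converged = rel_change < rel_tol && tau < chain_length / trust_factor,
    tau = tau,
    rel_change = rel_change,
    trust_limit = chain_length / trust_factor
  )
}

# Build a fast closure over a compiled cohort that evaluates the
# log-posterior directly from the flat parameter vector, precomputing the
# state table and graph indexing once. Kept in exact agreement with
# log_posterior() (asserted in the tests); used by the sampler where the
# generic path's per-call validation and reconstruction would dominate.
make_log_posterior <- function(groups, graph, p_early = 0.3, t_max = 10L) {
  V <- length(graph$lnl_names)
  n <- 2L^V
  nA <- nrow(graph$lnl_arcs)
  S <- lnl_states(V)
  col1 <- lapply(seq_len(V), function(v) as.numeric(S[, v] == 1L))
  healthy <- lapply(seq_len(V), function(v) S[, v] == 0L)
  arc_child <- match(graph$lnl_arcs[, "child"], graph$lnl_names)
  arc_parent <- match(graph$lnl_arcs[, "parent"], graph$lnl_names)
  idx_bi <- seq_len(V)
  idx_bc <- V + seq_len(V)
  idx_mix <- 2L * V + 1L
  idx_arc <- 2L * V + 1L + seq_len(nA)
  idx_padv <- 2L * V + nA + 2L
  idx_pe <- 2L * V + nA + 3L
  ts <- 0:t_max

  build_A <- function(b, t_arc) {
    A <- matrix(1, n, n)
    for (v in seq_len(V)) {
      q <- rep(1 - b[v], n)
      for (k in which(arc_child == v)) {
        q <- q * (1 - t_arc[k])^S[, arc_parent[k]]
      }
      h <- healthy[[v]]
      fac0 <- q * h
      fac1 <- (1 - q) * h + !h
      c1 <- col1[[v]]
      A <- A * (tcrossprod(fac0, 1 - c1) + tcrossprod(fac1, c1))
    }
    A
  }
  evolve <- function(A) {
    L <- matrix(0, t_max + 1L, n)
    v <- c(1, rep(0, n - 1L))
    L[1L, ] <- v
    for (t in seq_len(t_max)) {
      v <- as.vector(v %*% A)
      L[t + 1L, ] <- v
    }
    L
  }

  function(theta) {
    if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 1)) {
      return(-Inf)
    }
    b_i <- theta[idx_bi]
    b_c <- theta[idx_bc]
    mix <- theta[idx_mix]
    t_arc <- theta[idx_arc]
    pe <- theta[idx_pe]
    lam_i <- evolve(build_A(b_i, t_arc))
    lam_cF <- evolve(build_A(b_c, t_arc)) * (1 - pe)^ts
    A_cT <- build_A(mix * b_i + (1 - mix) * b_c, t_arc)
    lam_cT <- matrix(0, t_max + 1L, n)
    for (t in seq_len(t_max)) {
      lam_cT[t + 1L, ] <- as.vector((pe * lam_cF[t, ] + lam_cT[t, ]) %*% A_cT)
    }
    prior <- list(early = stats::dbinom(ts, t_max, p_early),
                  advanced = stats::dbinom(ts, t_max, theta[idx_padv]))
    total <- 0
    for (sl in groups) {
      p_t <- prior[[sl$t_group]]
      M <- if (is.na(sl$midline)) {
        crossprod(lam_i, p_t * (lam_cF + lam_cT))
      } else if (sl$midline) {
        crossprod(lam_i, p_t * lam_cT)
      } else {
        crossprod(lam_i, p_t * lam_cF)
      }
      lik <- rowSums((sl$oi %*% M) * sl$oc)
      ll <- ifelse(lik > 0, pmax(log(pmax(lik, 1e-320)), LOG_FLOOR), LOG_FLOOR)
      total <- total + sum(sl$n * ll)
    }
    total
  }
}

#' Log-posterior of the flat parameter vector
#'
#' Uniform prior over the unit cube: inside the cube the log-posterior
#' equals the cohort log-likelihood; outside (or for non-finite entries) it
#' is `-Inf`.
#'
#' @param theta flat parameter vector in [theta_names()] order.
#' @param cohort a cohort data.frame or a precompiled cohort.
#' @param graph a [lymph_graph()].
#' @param p_early,t_max fixed model constants.
#' @return Log-density.
#' @export
log_posterior <- function(theta, cohort, graph = lymph_graph(),
                          p_early = 0.3, t_max = 10L) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta > 1)) {
    return(-Inf)
  }
  groups <- if (inherits(cohort, "compiled_cohort")) cohort
            else compile_cohort(cohort, graph)
  params <- theta_to_params(theta, graph, p_early = p_early, t_max = t_max)
  compiled_log_likelihood(groups, progression_engine(params))
}
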