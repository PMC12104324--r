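#' One-step transition matrix of the progression model
#'
#' Builds the `2^V x 2^V` stochastic matrix of one-step transitions between
#' involvement states. A healthy level `v` becomes involved during one step
#' with probability
#' `1 - (1 - b_v) * prod_r (1 - t_rv)` over its currently involved parents
#' `r`; involvement events across levels are conditionally independent given
#' the current state; involved levels stay involved (no self-healing), so any
#' transition that would clear a level has probability zero and the
#' all-involved state is absorbing.
#'
#' @param graph a [lymph_graph()].
#' @param tumor_spread named per-level probabilities of direct tumor spread.
#' @param arc_spread named per-arc probabilities (`"parent->child"`).
#' @return A `2^V x 2^V` matrix; rows sum to one.
#' @examples
#' g <- lymph_graph("A", lnl_arcs = NULL)
#' transition_matrix(g, c(A = 0.5), numeric(0))
#' @export
transition_matrix <- function(graph, tumor_spread, arc_spread) {
  stopifnot(inherits(graph, "lymph_graph"))
  b <- check_level_probs(tumor_spread, graph$lnl_names, "tumor_spread")
  t_arc <- check_level_probs(arc_spread, arc_names(graph), "arc_spread")
  V <- length(graph$lnl_names)
  S <- lnl_states(V)
  n <- nrow(S)
  A <- matrix(1, n, n)
  for (v in seq_len(V)) {
    # P(stay healthy) for rows where v is healthy, given the current parents
    q <- rep(1 - b[[v]], n)
    for (r in graph$parents[[v]]) {
      nm <- paste0(graph$lnl_names[r], "->", graph$lnl_names[v])
      q <- q * (1 - t_arc[[nm]])^S[, r]
    }
    healthy <- S[, v] == 0L
    # column factor: P(next state of v | current row)
    fac0 <- q * healthy                          # next = 0
    fac1 <- (1 - q) * healthy + !healthy         # next = 1
    col1 <- as.numeric(S[, v] == 1L)
    A <- A * (tcrossprod(fac0, 1 - col1) + tcrossprod(fac1, col1))
  }
  A
}

#' Observation (confusion) matrix of a diagnostic modality
#'
#' The probability of observing each diagnosis pattern given each true hidden
#' involvement pattern, factorizing over levels through the modality's
#' sensitivity and specificity: `P(Z=1|X=1) = sensitivity` and
#' `P(Z=0|X=0) = specificity` per level. Perfect sensitivity and specificity
#' give the identity matrix.
#'
#' @param sensitivity,specificity scalars or per-level vectors in \[0,1\].
#' @param num_lnls number of levels `V`.
#' @return A `2^V x 2^V` row-stochastic matrix; entry (i, j) is the
#'   probability of diagnosis pattern j given true pattern i.
#' @examples
#' observation_matrix(0.81, 0.76, 1)
#' @export
observation_matrix <- function(sensitivity, specificity, num_lnls) {
  V <- as.integer(num_lnls)
  sens <- rep_len(sensitivity, V)
  spec <- rep_len(specificity, V)
  if (any(sens < 0 | sens > 1 | spec < 0 | spec > 1)) {
    stop("sensitivity and specificity must be in [0, 1]")
  }
  S <- lnl_states(V)
  n <- nrow(S)
  B <- matrix(1, n, n)
  for (v in seq_len(V)) {
    x1 <- S[, v] == 1L                       # rows: true state of level v
    z1 <- matrix(S[, v] == 1L, n, n, byrow = TRUE)  # cols: observed state
    pv1 <- ifelse(x1, sens[v], 1 - spec[v])  # P(Z_v = 1 | X_v)
    B <- B * ifelse(z1, pv1, 1 - pv1)
  }
  B
}

#' Binomial prior over the number of progression steps before diagnosis
#'
#' The unobserved number of time steps between disease onset and diagnosis is
#' given a binomial prior with `t_max` trials, so its mean is `t_max * p`.
#' A larger `p` encodes later diagnosis (advanced T-category).
#'
#' @param p binomial success probability.
#' @param t_max number of time steps.
#' @return Numeric vector of length `t_max + 1` with the prior mass at
#'   `t = 0, ..., t_max`; sums to one.
#' @examples
#' sum(0:10 * time_prior(0.3, 10))  # mean 3
#' @export
time_prior <- function(p, t_max = 10L) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
    stop("`p` must be a probability in [0, 1]")
  }
  t_max <- as.integer(t_max)
  if (t_max < 0L) stop("`t_max` must be >= 0")
  stats::dbinom(0:t_max, t_max, p)
}

#' Evolve the hidden-state distribution over time
#'
#' Starting from the all-healthy state, repeatedly applies the transition
#' matrix and stacks the resulting distributions: row `k + 1` is the
#' distribution over hidden states after `k` steps.
#'
#' @param A transition matrix from [transition_matrix()].
#' @param t_max number of steps to evolve.
#' @return A `(t_max + 1) x 2^V` matrix; each row sums to one.
#' @export
state_evolution <- function(A, t_max = 10L) {
  n <- nrow(A)
  t_max <- as.integer(t_max)
  L <- matrix(0, t_max + 1L, n)
  v <- c(1, rep(0, n - 1L))
  L[1L, ] <- v
  if (t_max > 0L) {
    for (t in seq_len(t_max)) {
      v <- as.vector(v %*% A)
      L[t + 1L, ] <- v
    }
  }
  L
}

#' Per-state diagnosis factor for one side of the neck
#'
#' Converts one observed per-level diagnosis (involved / healthy / missing)
#' into a vector over all hidden states: entry i is the probability of the
#' observed findings given hidden state i. Missing levels contribute a factor
#' of one, which is equivalent to summing over all their completions. With a
#' perfect modality the vector is an indicator of the states compatible with
#' the diagnosis.
#'
#' @param diagnosis numeric/logical vector of length `V` with entries 1
#'   (involved), 0 (healthy) or `NA` (not examined).
#' @param sensitivity,specificity scalars or per-level vectors.
#' @return Numeric vector of length `2^V`.
#' @export
diagnosis_factor <- function(diagnosis, sensitivity = 1, specificity = 1) {
  V <- length(diagnosis)
  sens <- rep_len(sensitivity, V)
  spec <- rep_len(specificity, V)
  S <- lnl_states(V)
  o <- rep(1, nrow(S))
  for (v in seq_len(V)) {
    z <- diagnosis[[v]]
    if (is.na(z)) next
    fac <- if (z == 1) c(1 - spec[v], sens[v]) else c(spec[v], 1 - sens[v])
    o <- o * fac[S[, v] + 1L]
  }
  o
}

#' Unilateral diagnosis likelihood
#'
#' Probability of observing one side's diagnosis for a patient of the given
#' T-group, marginalized over the unknown diagnosis time and over any levels
#' without a finding.
#'
#' @param diagnosis per-level observed statuses (1 / 0 / `NA`).
#' @param t_group `"early"` or `"advanced"`.
#' @param graph a [lymph_graph()].
#' @param tumor_spread,arc_spread spread probabilities as in
#'   [transition_matrix()].
#' @param p_early,p_adv,t_max time-prior parameters.
#' @param sensitivity,specificity observation model of the reporting modality
#'   (defaults to a perfect modality).
#' @return A probability in \[0, 1\].
#' @export
unilateral_likelihood <- function(diagnosis, t_group, graph, tumor_spread,
                                  arc_spread, p_early = 0.3, p_adv = 0.45,
                                  t_max = 10L, sensitivity = 1, specificity = 1) {
  t_group <- match.arg(t_group, c("early", "advanced"))
  if (length(diagnosis) != length(graph$lnl_names)) {
    stop("`diagnosis` must have one entry per LNL")
  }
  A <- transition_matrix(graph, tumor_spread, arc_spread)
  L <- state_evolution(A, t_max)
  p_t <- time_prior(if (t_group == "early") p_early else p_adv, t_max)
  state_dist <- as.vector(p_t %*% L)
  o <- diagnosis_factor(diagnosis, sensitivity, specificity)
  sum(state_dist * o)
}
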