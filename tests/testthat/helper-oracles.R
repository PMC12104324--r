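# Shared toy graphs, parameter sets and brute-force oracles.
#
# The oracles enumerate the model's elementary random events directly
# (per-step Bernoulli spread events along each arc, per-step midline
# crossing), independently of the matrix machinery they are used to check.

toy_graph_1 <- function() lymph_graph("II", lnl_arcs = NULL)

toy_graph_2 <- function() {
  lymph_graph(c("II", "III"), lnl_arcs = cbind(parent = "II", child = "III"))
}

toy_params_2 <- function(graph = toy_graph_2(), t_max = 3L) {
  lymph_params(
    graph,
    ipsi_spread = c(II = 0.3, III = 0.1),
    contra_spread = c(II = 0.2, III = 0.05),
    mixing = 0.5,
    arc_spread = c("II->III" = 0.3),
    p_adv = 0.45,
    midline_prob = 0.15,
    t_max = t_max
  )
}

# random valid parameter set for a given graph
random_params <- function(graph, t_max = 10L) {
  V <- length(graph$lnl_names)
  nA <- nrow(graph$lnl_arcs)
  theta_to_params(stats::runif(2 * V + nA + 3), graph, t_max = t_max)
}

# One-step spread by exhaustive enumeration of the independent Bernoulli
# events: for each healthy level there is one tumor-seeding event and one
# event per involved parent; the level becomes involved if any event fires.
# Returns the distribution over next states given the current state vector.
oracle_one_step <- function(x, graph, tumor_spread, arc_spread) {
  V <- length(x)
  lnl <- graph$lnl_names
  events <- list()  # each: list(level, prob)
  for (v in seq_len(V)) {
    if (x[v] == 1) next
    events[[length(events) + 1L]] <- list(v = v, p = tumor_spread[[v]])
    for (r in graph$parents[[v]]) {
      if (x[r] == 1) {
        nm <- paste0(lnl[r], "->", lnl[v])
        events[[length(events) + 1L]] <- list(v = v, p = arc_spread[[nm]])
      }
    }
  }
  n_states <- 2^V
  out <- numeric(n_states)
  n_ev <- length(events)
  for (mask in 0:(2^n_ev - 1)) {
    p <- 1
    fired <- rep(FALSE, V)
    if (n_ev > 0) {
      for (e in seq_len(n_ev)) {
        if (bitwAnd(bitwShiftR(mask, e - 1L), 1L)) {
          p <- p * events[[e]]$p
          fired[events[[e]]$v] <- TRUE
        } else {
          p <- p * (1 - events[[e]]$p)
        }
      }
    }
    nx <- pmax(x, as.integer(fired))
    idx <- sum(nx * 2^((V - 1):0)) + 1L
    out[idx] <- out[idx] + p
  }
  out
}

# distribution over states after t steps, by repeated event enumeration
oracle_state_dist <- function(graph, tumor_spread, arc_spread, t_steps) {
  V <- length(graph$lnl_names)
  S <- lnl_states(V)
  dist <- c(1, rep(0, 2^V - 1))
  for (s in seq_len(t_steps)) {
    nxt <- numeric(2^V)
    for (i in which(dist > 0)) {
      nxt <- nxt + dist[i] *
        oracle_one_step(S[i, ], graph, tumor_spread, arc_spread)
    }
    dist <- nxt
  }
  dist
}

# Exhaustive oracle for the joint bilateral distribution with midline
# dynamics: evolves the full joint distribution over (ipsi state, contra
# state, crossed flag) step by step, branching explicitly on the crossing
# event (a crossing at step t already spreads with the mixed rates at step
# t), then mixes over the binomial time prior.
oracle_joint <- function(params, t_group) {
  g <- params$graph
  V <- length(g$lnl_names)
  S <- lnl_states(V)
  n <- 2^V
  mixed <- mixed_contra_spread(params)
  pe <- params$midline_prob
  # dist[[eps + 1]][i, j]: P(ipsi = i, contra = j, crossed = eps)
  dist <- list(matrix(0, n, n), matrix(0, n, n))
  dist[[1]][1, 1] <- 1
  acc <- list(matrix(0, n, n), matrix(0, n, n))
  p_t <- time_prior(if (t_group == "early") params$p_early else params$p_adv,
                    params$t_max)
  acc[[1]] <- acc[[1]] + p_t[1] * dist[[1]]
  acc[[2]] <- acc[[2]] + p_t[1] * dist[[2]]
  for (t in seq_len(params$t_max)) {
    nxt <- list(matrix(0, n, n), matrix(0, n, n))
    for (e in 1:2) {
      for (i in which(rowSums(dist[[e]]) > 0)) {
        step_i <- oracle_one_step(S[i, ], g, params$ipsi_spread,
                                  params$arc_spread)
        for (j in which(dist[[e]][i, ] > 0)) {
          mass <- dist[[e]][i, j]
          if (e == 1) {
            # stays lateralized
            step_lat <- oracle_one_step(S[j, ], g, params$contra_spread,
                                        params$arc_spread)
            nxt[[1]] <- nxt[[1]] + (1 - pe) * mass * outer(step_i, step_lat)
            # crosses now: this step already uses the mixed rates
            step_mix <- oracle_one_step(S[j, ], g, mixed, params$arc_spread)
            nxt[[2]] <- nxt[[2]] + pe * mass * outer(step_i, step_mix)
          } else {
            step_mix <- oracle_one_step(S[j, ], g, mixed, params$arc_spread)
            nxt[[2]] <- nxt[[2]] + mass * outer(step_i, step_mix)
          }
        }
      }
    }
    dist <- nxt
    acc[[1]] <- acc[[1]] + p_t[t + 1] * dist[[1]]
    acc[[2]] <- acc[[2]] + p_t[t + 1] * dist[[2]]
  }
  list(lateralized = acc[[1]], crossed = acc[[2]])
}

# direct double-loop evaluation of the diagnosis posterior on tiny graphs
oracle_posterior <- function(scenario, params) {
  g <- params$graph
  V <- length(g$lnl_names)
  S <- lnl_states(V)
  n <- 2^V
  prior <- if (is.na(scenario$midline_extension)) {
    joint_state_dist(params, scenario$t_group, FALSE) +
      joint_state_dist(params, scenario$t_group, TRUE)
  } else {
    joint_state_dist(params, scenario$t_group, scenario$midline_extension)
  }
  obs_prob <- function(side, state) {
    p <- 1
    for (v in seq_len(V)) {
      z <- side$status[[v]]
      if (is.na(z)) next
      p1 <- if (state[v] == 1) side$sensitivity[v] else 1 - side$specificity[v]
      p <- p * if (z == 1) p1 else 1 - p1
    }
    p
  }
  post <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      post[i, j] <- obs_prob(scenario$ipsi, S[i, ]) *
        obs_prob(scenario$contra, S[j, ]) * prior[i, j]
    }
  }
  post / sum(post)
}
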