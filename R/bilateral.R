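#' Contralateral state evolution with midline-crossing dynamics
#'
#' A tumor starts lateralized and crosses the mid-sagittal plane with
#' probability `midline_prob` at each time step. While lateralized, the
#' contralateral neck evolves under the lateralized transition matrix; from
#' the crossing step onwards it evolves under the matrix built from the mixed
#' tumor-spread rates. This function returns the joint distributions
#' `P(contra state, crossed | t)` for both values of the crossing flag:
#' `lam_false` row `t+1` is `(1 - midline_prob)^t` times the lateralized
#' evolution, and `lam_true` satisfies the recursion in which the probability
#' mass crossing at step `t+1` is propagated with the crossed-state matrix.
#'
#' @param params a [lymph_params()] object.
#' @return List with matrices `lam_false` and `lam_true`, each
#'   `(t_max + 1) x 2^V`; row sums of `lam_false` equal
#'   `(1 - midline_prob)^t` and the two matrices' row sums add to one.
#' @export
midline_evolution <- function(params) {
  stopifnot(inherits(params, "lymph_params"))
  g <- params$graph
  t_max <- params$t_max
  pe <- params$midline_prob
  A_lat <- transition_matrix(g, params$contra_spread, params$arc_spread)
  A_crossed <- transition_matrix(g, mixed_contra_spread(params), params$arc_spread)
  lam_false <- state_evolution(A_lat, t_max) * (1 - pe)^(0:t_max)
  lam_true <- matrix(0, t_max + 1L, nrow(A_lat))
  if (t_max > 0L) {
    for (t in seq_len(t_max)) {
      lam_true[t + 1L, ] <-
        as.vector((pe * lam_false[t, ] + lam_true[t, ]) %*% A_crossed)
    }
  }
  list(lam_false = lam_false, lam_true = lam_true)
}

# Precompute everything about theta that is shared across patients:
# ipsilateral evolution, both contralateral evolutions, time priors.
progression_engine <- function(params) {
  stopifnot(inherits(params, "lymph_params"))
  g <- params$graph
  A_ipsi <- transition_matrix(g, params$ipsi_spread, params$arc_spread)
  lam_ipsi <- state_evolution(A_ipsi, params$t_max)
  contra <- midline_evolution(params)
  structure(
    list(
      graph = g,
      t_max = params$t_max,
      lam_ipsi = lam_ipsi,
      lam_contra_false = contra$lam_false,
      lam_contra_true = contra$lam_true,
      prior_early = time_prior(params$p_early, params$t_max),
      prior_adv = time_prior(params$p_adv, params$t_max)
    ),
    class = "progression_engine"
  )
}

#' Joint distribution over bilateral involvement and midline extension
#'
#' The probability of every pair of (ipsilateral, contralateral) hidden
#' involvement states together with one value of the midline-extension flag,
#' for a given T-group: the two sides evolve independently given the
#' diagnosis time, so the joint is the ipsilateral evolution matrix times the
#' diagonal time prior times the chosen contralateral evolution matrix.
#' Summing the returned matrix over both values of `midline` gives one.
#'
#' @param params a [lymph_params()] object.
#' @param t_group `"early"` or `"advanced"`.
#' @param midline logical; which value of the midline-extension flag.
#' @return A `2^V x 2^V` matrix; rows index ipsilateral states, columns
#'   contralateral states.
#' @export
joint_state_dist <- function(params, t_group, midline) {
  engine <- if (inherits(params, "progression_engine")) params
            else progression_engine(params)
  engine_joint(engine, t_group, midline)
}

engine_joint <- function(engine, t_group, midline) {
  t_group <- match.arg(t_group, c("early", "advanced"))
  p_t <- if (t_group == "early") engine$prior_early else engine$prior_adv
  lam_c <- if (isTRUE(midline)) engine$lam_contra_true else engine$lam_contra_false
  crossprod(engine$lam_ipsi, p_t * lam_c)
}

# log-likelihood floor for impossible records (keeps the sampler finite)
LOG_FLOOR <- -1e10

#' Log-likelihood of one patient record
#'
#' The log-probability of a patient's observed involvement under the
#' bilateral model. Involvement reported in the cohort is the consensus
#' status and is treated as the true hidden state (a perfect reporting
#' modality); levels without a finding are marginalized out, and if the
#' midline-extension flag is unknown both values are summed over.
#'
#' @param params a [lymph_params()] or a precomputed engine.
#' @param t_group `"early"` or `"advanced"`.
#' @param midline `TRUE`, `FALSE`, or `NA` (unknown).
#' @param ipsi,contra per-level statuses (1 / 0 / `NA`), in graph level order.
#' @return Log-probability (floored at `-1e10` for zero-probability records).
#' @export
patient_log_likelihood <- function(params, t_group, midline, ipsi, contra) {
  engine <- if (inherits(params, "progression_engine")) params
            else progression_engine(params)
  if (length(t_group) != 1L || is.na(t_group)) {
    stop("patient record must carry a T-group")
  }
  oi <- diagnosis_factor(ipsi)
  oc <- diagnosis_factor(contra)
  lik <- 0
  eps_values <- if (is.na(midline)) c(FALSE, TRUE) else isTRUE(midline)
  for (e in eps_values) {
    M <- engine_joint(engine, t_group, e)
    lik <- lik + as.numeric(oi %*% M %*% oc)
  }
  if (lik <= 0) return(LOG_FLOOR)
  max(log(lik), LOG_FLOOR)
}

# Collapse a cohort into unique (t_group, midline, ipsi pattern, contra
# pattern) groups with counts and precomputed per-state diagnosis factors,
# stacked per (t_group, midline) slice so each theta evaluation reduces to a
# few dense matrix products.
compile_cohort <- function(cohort, graph) {
  df <- as.data.frame(cohort)
  lnl <- graph$lnl_names
  ipsi_cols <- paste0("consensus_ipsi_", lnl)
  contra_cols <- paste0("consensus_contra_", lnl)
  missing_cols <- setdiff(c("t_group", "midline_extension", ipsi_cols, contra_cols),
                          names(df))
  if (length(missing_cols)) {
    stop("cohort lacks required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(is.na(df$t_group))) {
    stop("record(s) without a T-group: rows ",
         paste(which(is.na(df$t_group)), collapse = ", "))
  }
  key <- do.call(paste, c(
    df[c("t_group", "midline_extension", ipsi_cols, contra_cols)],
    sep = "|"
  ))
  first <- !duplicated(key)
  counts <- as.integer(table(factor(key, levels = key[first])))
  idx <- which(first)
  slice_key <- paste(df$t_group[idx],
                     ifelse(is.na(df$midline_extension[idx]), "NA",
                            df$midline_extension[idx]))
  slices <- lapply(split(seq_along(idx), slice_key), function(k) {
    rows <- idx[k]
    list(
      t_group = as.character(df$t_group[rows[1L]]),
      midline = df$midline_extension[rows[1L]],
      oi = t(vapply(rows, function(i)
        diagnosis_factor(as.numeric(df[i, ipsi_cols])), numeric(2^length(lnl)))),
      oc = t(vapply(rows, function(i)
        diagnosis_factor(as.numeric(df[i, contra_cols])), numeric(2^length(lnl)))),
      n = counts[k]
    )
  })
  structure(slices, class = c("compiled_cohort", "list"))
}

#' Cohort log-likelihood
#'
#' Sum of per-patient log-likelihoods over a cohort table. Patients are
#' grouped by their distinct (T-group, midline flag, involvement pattern)
#' combination so the expensive matrices are touched once per distinct
#' pattern.
#'
#' @param cohort a cohort data.frame (see [read_cohort()] / [simulate_cohort()]).
#' @param params a [lymph_params()] object.
#' @return The cohort log-likelihood (scalar).
#' @export
cohort_log_likelihood <- function(cohort, params) {
  stopifnot(inherits(params, "lymph_params"))
  groups <- if (inherits(cohort, "compiled_cohort")) cohort
            else compile_cohort(cohort, params$graph)
  engine <- progression_engine(params)
  compiled_log_likelihood(groups, engine)
}

compiled_log_likelihood <- function(slices, engine) {
  total <- 0
  for (sl in slices) {
    if (is.na(sl$midline)) {
      M <- engine_joint(engine, sl$t_group, FALSE) +
        engine_joint(engine, sl$t_group, TRUE)
    } else {
      M <- engine_joint(engine, sl$t_group, sl$midline)
    }
    lik <- rowSums((sl$oi %*% M) * sl$oc)
    ll <- ifelse(lik > 0, pmax(log(pmax(lik, 1e-320)), LOG_FLOOR), LOG_FLOOR)
    total <- total + sum(sl$n * ll)
  }
  total
}
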