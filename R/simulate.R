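#' Simulate a synthetic patient cohort
#'
#' Generative counterpart of the bilateral progression model: per patient, a
#' diagnosis time is drawn from the binomial time prior of their T-group; the
#' ipsilateral neck evolves stochastically under the ipsilateral spread
#' rates; the tumor crosses the mid-sagittal plane with the per-step crossing
#' probability, and from the crossing step onwards the contralateral neck
#' evolves under the mixed spread rates (the crossing step itself already
#' uses them, matching the likelihood recursion). The true involvement at
#' diagnosis is then passed through the chosen reporting modality's
#' confusion probabilities.
#'
#' @param params a [lymph_params()] object (generating truth).
#' @param n_early,n_advanced number of early- and advanced-T patients.
#' @param modality reporting modality for the recorded statuses; the default
#'   `"consensus"` records the true hidden state.
#' @param missing_rate per-cell probability that a recorded status is
#'   dropped (reported as missing).
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return A `lymph_cohort` data.frame conforming to the [read_cohort()]
#'   schema, with the simulated statuses in `<modality>_<side>_<level>`
#'   columns and derived consensus columns.
#' @examples
#' simulate_cohort(ref_params(), n_early = 5, n_advanced = 5, seed = 1)
#' @export
simulate_cohort <- function(params, n_early, n_advanced,
                            modality = "consensus", missing_rate = 0,
                            seed = NULL) {
  stopifnot(inherits(params, "lymph_params"))
  if (n_early < 0 || n_advanced < 0 || n_early + n_advanced < 1) {
    stop("need a positive number of patients")
  }
  if (missing_rate < 0 || missing_rate > 1) stop("`missing_rate` must be in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- params$graph
  n <- n_early + n_advanced
  t_group <- rep(c("early", "advanced"), c(n_early, n_advanced))
  p_time <- ifelse(t_group == "early", params$p_early, params$p_adv)
  t_diag <- stats::rbinom(n, params$t_max, p_time)

  sim <- simulate_progression(params, t_diag)

  conf <- modality_lookup(modality)
  obs_ipsi <- observe_states(sim$ipsi, conf$sensitivity, conf$specificity)
  obs_contra <- observe_states(sim$contra, conf$sensitivity, conf$specificity)
  if (missing_rate > 0) {
    drop1 <- matrix(stats::runif(length(obs_ipsi)) < missing_rate, nrow = n)
    drop2 <- matrix(stats::runif(length(obs_contra)) < missing_rate, nrow = n)
    obs_ipsi[drop1] <- NA
    obs_contra[drop2] <- NA
  }

  df <- data.frame(
    id = sprintf("sim-%06d", seq_len(n)),
    t_category = ifelse(t_group == "early", 2L, 3L),
    midline_extension = sim$midline,
    stringsAsFactors = FALSE
  )
  for (v in seq_along(g$lnl_names)) {
    df[[paste0(modality, "_ipsi_", g$lnl_names[v])]] <- obs_ipsi[, v]
    df[[paste0(modality, "_contra_", g$lnl_names[v])]] <- obs_contra[, v]
  }
  out <- as_cohort(df, g)
  attr(out, "t_diag") <- sim$t_diag
  out
}

# vectorized joint evolution of both necks and the crossing flag
simulate_progression <- function(params, t_diag) {
  g <- params$graph
  V <- length(g$lnl_names)
  n <- length(t_diag)
  b_contra_mixed <- mixed_contra_spread(params)
  ipsi <- matrix(0L, n, V)
  contra <- matrix(0L, n, V)
  crossed <- rep(FALSE, n)
  t_max <- max(t_diag, 0L)
  for (step in seq_len(t_max)) {
    active <- t_diag >= step
    if (!any(active)) break
    # the tumor may grow over the midline at this step; if it does, the
    # increased contralateral rates already apply to this step's spread
    grows <- active & !crossed & (stats::runif(n) < params$midline_prob)
    crossed <- crossed | grows
    b_contra <- matrix(rep(params$contra_spread, each = n), n, V)
    b_contra[crossed, ] <- matrix(rep(b_contra_mixed, each = n), n, V)[crossed, ]
    ipsi_new <- spread_step(ipsi, params$ipsi_spread, params, g, n, V)
    contra_new <- spread_step(contra, b_contra, params, g, n, V)
    ipsi[active, ] <- ipsi_new[active, ]
    contra[active, ] <- contra_new[active, ]
  }
  list(ipsi = ipsi, contra = contra, midline = crossed, t_diag = t_diag)
}

# one synchronous involvement-spread step for all patients
spread_step <- function(state, tumor_spread, params, g, n, V) {
  if (!is.matrix(tumor_spread)) {
    tumor_spread <- matrix(rep(tumor_spread, each = n), n, V)
  }
  stay_healthy <- 1 - tumor_spread
  for (v in seq_len(V)) {
    for (r in g$parents[[v]]) {
      nm <- paste0(g$lnl_names[r], "->", g$lnl_names[v])
      stay_healthy[, v] <- stay_healthy[, v] *
        (1 - params$arc_spread[[nm]])^state[, r]
    }
  }
  newly <- matrix(stats::runif(n * V), n, V) >= stay_healthy
  out <- state
  out[state == 0L & newly] <- 1L
  out
}

observe_states <- function(truth, sensitivity, specificity) {
  p_pos <- ifelse(truth == 1L, sensitivity, 1 - specificity)
  obs <- matrix(stats::runif(length(truth)) < p_pos,
                nrow = nrow(truth), ncol = ncol(truth))
  obs
}
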