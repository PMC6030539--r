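#' Polymorphic evolutionary simulation on a trait lattice
#'
#' Relaxes the adaptive-dynamics assumptions of continuous traits and a
#' complete separation of time scales: the host trait lives on a discrete
#' lattice spanning `[beta_A, d * beta_A]`, every epoch the full multi-strain
#' ecological system is integrated for a fixed window, strains below the
#' persistence threshold are culled, and mutants are seeded into lattice
#' sites adjacent to a parent chosen with probability proportional to
#' abundance. Mutants enter as susceptible juveniles (newborn genotypes) at a
#' small fraction of the parent's density. The trajectory is reproducible
#' bit-for-bit for a fixed seed.
#'
#' @param params A [model_params()] object.
#' @param beta_init Initial trait (snapped to the nearest lattice site);
#'   defaults to `beta_A`.
#' @param lattice_n Number of lattice sites (default 61).
#' @param mutation_prob Probability of one mutation event per epoch
#'   (default 1).
#' @param epochs Number of evolutionary epochs (default 2000).
#' @param seed Integer RNG seed (required for reproducibility).
#' @param t_window Ecological integration window per epoch (default 200).
#' @param mutant_frac Seeded mutant density as a fraction of the parent's
#'   density (default 1e-4).
#' @param persistence_threshold Strains below this total density are culled
#'   (default 1e-7).
#' @param record_every Record the abundance distribution every this many
#'   epochs (default 10).
#' @return An object of class `jsev_evo`: list with `trait_lattice`,
#'   `epoch_times`, `abundance` (epochs x lattice matrix of per-strain total
#'   host density), `final_traits` (abundance-weighted modes at the last
#'   epoch), `outcome` (see [detect_outcome()]), `params`, `seed`.
#' @export
simulate_evolution <- function(params, beta_init = NULL, lattice_n = 61,
                               mutation_prob = 1, epochs = 2000, seed = 1,
                               t_window = 200, mutant_frac = 1e-4,
                               persistence_threshold = 1e-7,
                               record_every = 10) {
  stopifnot(inherits(params, "jsev_params"), lattice_n >= 3, epochs >= 1,
            mutation_prob >= 0, mutation_prob <= 1)
  set.seed(seed)
  lo <- params$beta_A; hi <- params$d * params$beta_A
  lattice <- seq(lo, hi, length.out = lattice_n)
  if (is.null(beta_init)) beta_init <- lo
  init_idx <- which.min(abs(lattice - beta_init))

  tr <- tradeoff_value(lattice, params)   # rates per lattice site, precomputed
  a_all <- tr$a; g_all <- tr$g

  # population: 4 x lattice_n matrix, occupied columns only integrated
  pop <- matrix(0, 4, lattice_n)
  eq <- .resident_equilibrium(lattice[init_idx], params)
  if (eq$extinct) {
    pop[, init_idx] <- 0
  } else pop[, init_idx] <- eq$state

  rec_epochs <- unique(c(seq(1, epochs, by = record_every), epochs))
  abundance <- matrix(0, length(rec_epochs), lattice_n)
  rec_i <- 1

  ext_thresh <- 1e-6
  for (ep in seq_len(epochs)) {
    active <- which(colSums(pop) > 0)
    if (length(active)) {
      beta_act <- lattice[active]
      a_act <- a_all[active]; g_act <- g_all[active]
      y0 <- as.vector(pop[, active, drop = FALSE])
      k <- length(active)
      fun <- function(t, y, parms) {
        m <- matrix(y, nrow = 4)
        list(as.vector(.multi_rhs_core(m, beta_act, params,
                                       a = a_act, g = g_act)))
      }
      sol <- deSolve::lsoda(pmax(y0, 0), c(0, t_window), fun, parms = NULL,
                            rtol = 1e-8, atol = 1e-12)
      m <- matrix(pmax(sol[nrow(sol), -1], 0), nrow = 4)
      pop[] <- 0
      pop[, active] <- m
      # cull strains below the persistence threshold
      tot <- colSums(pop)
      pop[, tot < persistence_threshold] <- 0
    }
    tot <- colSums(pop)
    # mutation: one event per epoch with probability mutation_prob,
    # parent chosen proportional to abundance, adjacent site, newborn S_J
    if (sum(tot) > ext_thresh && mutation_prob > 0 &&
        stats::runif(1) < mutation_prob) {
      occ <- which(tot > 0)
      parent <- if (length(occ) == 1) occ
                else sample(occ, 1, prob = tot[occ])
      dir <- if (parent == 1) 1L
             else if (parent == lattice_n) -1L
             else sample(c(-1L, 1L), 1)
      child <- parent + dir
      pop[1, child] <- pop[1, child] + mutant_frac * tot[parent]
    }
    if (rec_i <= length(rec_epochs) && ep == rec_epochs[rec_i]) {
      abundance[rec_i, ] <- colSums(pop)
      rec_i <- rec_i + 1
    }
    if (sum(tot) <= ext_thresh && ep < epochs) {
      # host extinct: fill remaining records with zeros and stop
      while (rec_i <= length(rec_epochs)) {
        abundance[rec_i, ] <- 0; rec_i <- rec_i + 1
      }
      break
    }
  }
  traj <- structure(list(trait_lattice = lattice,
                         epoch_times = rec_epochs,
                         abundance = abundance,
                         params = params, seed = seed,
                         beta_init = lattice[init_idx],
                         persistence_threshold = persistence_threshold),
                    class = "jsev_evo")
  traj$final_traits <- .final_modes(traj)
  traj$outcome <- detect_outcome(traj, params)
  traj
}

# Occupied runs (modes) of an abundance vector: list of index ranges of
# contiguous cells above the threshold, merged across gaps shorter than
# `gap` cells.
.mode_runs <- function(ab, threshold, gap = 3) {
  occ <- ab > threshold
  if (!any(occ)) return(list())
  idx <- which(occ)
  runs <- list(); start <- idx[1]; prev <- idx[1]
  for (i in idx[-1]) {
    if (i - prev > gap) { runs[[length(runs) + 1]] <- c(start, prev); start <- i }
    prev <- i
  }
  runs[[length(runs) + 1]] <- c(start, prev)
  runs
}

.final_modes <- function(traj) {
  ab <- traj$abundance[nrow(traj$abundance), ]
  runs <- .mode_runs(ab, traj$persistence_threshold)
  vapply(runs, function(r) {
    ix <- r[1]:r[2]
    traj$trait_lattice[ix[which.max(ab[ix])]]
  }, numeric(1))
}

#' Classify the outcome of an evolutionary trajectory
#'
#' `host_extinct` when the final total density is below the extinction
#' threshold; `branched` when at least two persistent modes separated by at
#' least three empty lattice cells coexist over the final 10% of epochs;
#' `fixed_min`/`fixed_max` when the final mode sits in the first/last lattice
#' cell; `converged_interior` otherwise.
#'
#' @param traj A `jsev_evo` trajectory.
#' @param params A [model_params()] object (unused fields tolerated; kept for
#'   interface symmetry).
#' @return One of `"host_extinct"`, `"branched"`, `"fixed_min"`,
#'   `"fixed_max"`, `"converged_interior"`.
#' @export
detect_outcome <- function(traj, params = traj$params) {
  stopifnot(inherits(traj, "jsev_evo"))
  ab <- traj$abundance
  n_rec <- nrow(ab)
  if (n_rec == 0) stop("empty trajectory")
  final <- ab[n_rec, ]
  if (sum(final) < 1e-6) return("host_extinct")
  tail_rows <- max(1, ceiling(0.9 * n_rec)):n_rec
  branched_all <- all(vapply(tail_rows, function(i) {
    length(.mode_runs(ab[i, ], traj$persistence_threshold)) >= 2
  }, logical(1)))
  if (branched_all) return("branched")
  runs <- .mode_runs(final, traj$persistence_threshold)
  main <- runs[[which.max(vapply(runs, function(r)
    max(final[r[1]:r[2]]), numeric(1)))]]
  peak <- (main[1]:main[2])[which.max(final[main[1]:main[2]])]
  if (peak == 1) return("fixed_min")
  if (peak == length(final)) return("fixed_max")
  "converged_interior"
}

#' @export
print.jsev_evo <- function(x, ...) {
  cat(sprintf("Evolutionary trajectory: %d epochs recorded, lattice %d sites on [%g, %g]\n",
              nrow(x$abundance), length(x$trait_lattice),
              min(x$trait_lattice), max(x$trait_lattice)))
  cat(sprintf("  started at beta_J = %g, outcome: %s\n", x$beta_init, x$outcome))
  if (length(x$final_traits))
    cat(sprintf("  final trait mode(s): %s (ratio to beta_A: %s)\n",
                paste(signif(x$final_traits, 4), collapse = ", "),
                paste(signif(x$final_traits / x$params$beta_A, 3),
                      collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.jsev_evo <- function(x, ...) {
  data.frame(epoch = rep(x$epoch_times, times = length(x$trait_lattice)),
             trait = rep(x$trait_lattice, each = length(x$epoch_times)),
             abundance = as.vector(x$abundance))
}

#' Basin dependence around an evolutionary repeller
#'
#' Runs the polymorphic simulation from just below and just above a repeller
#' and reports the two outcomes. Around a plain repeller these are
#' `fixed_min` and `fixed_max`; with a second singular strategy in the upper
#' basin the documented alternatives (e.g. `converged_interior` at a CSS)
#' occur instead.
#'
#' @param params A [model_params()] object.
#' @param repeller A one-row subset of a `jsev_singular` strategies table (or
#'   list with `beta_J_star` and `label == "repeller"`).
#' @param seed Integer RNG seed.
#' @param offset Start offset from the repeller, as a fraction of the trait
#'   interval (default 0.1).
#' @param ... Passed to [simulate_evolution()].
#' @return Named list `outcome_from_below`, `outcome_from_above` plus the two
#'   trajectories.
#' @export
repeller_bistability <- function(params, repeller, seed = 1, offset = 0.1,
                                 ...) {
  if (is.data.frame(repeller)) repeller <- as.list(repeller[1, ])
  if (!identical(repeller$label, "repeller"))
    stop("the supplied singular strategy is not a repeller")
  span <- params$beta_A * (params$d - 1)
  b_star <- repeller$beta_J_star
  below <- max(params$beta_A, b_star - offset * span)
  above <- min(params$d * params$beta_A, b_star + offset * span)
  t1 <- simulate_evolution(params, beta_init = below, seed = seed, ...)
  t2 <- simulate_evolution(params, beta_init = above, seed = seed + 1, ...)
  list(outcome_from_below = t1$outcome, outcome_from_above = t2$outcome,
       trajectory_below = t1, trajectory_above = t2)
}
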