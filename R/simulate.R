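#' Effect-size scenario tables
#'
#' Multiplicative effect sizes used by the semi-synthetic benchmark.
#' `condition_gamma` returns the per-condition factors for the condition
#' scenarios (1, 2, 3): the reference (first) condition keeps factor 1 and
#' the other condition is multiplied by 10, 3 or 2 respectively.
#' `time_gamma` returns the per-time factors for the time scenarios
#' (1, ..., 4) of a 3-time-point design: (1, 5, 10), (1, 2, 3),
#' (1, 1.5, 2) and (1, 1.2, 1.5).
#'
#' @param scenario scenario number.
#' @param conditions,times level labels (in level order) used to name the
#'   returned vector.
#' @return Named numeric vector of multiplicative factors.
#' @export
condition_gamma <- function(scenario, conditions) {
  vals <- c(10, 3, 2)
  if (!scenario %in% seq_along(vals)) stop("unknown condition scenario")
  if (length(conditions) != 2L)
    stop("condition scenarios are defined for 2 conditions")
  stats::setNames(c(1, vals[scenario]), conditions)
}

#' @rdname condition_gamma
#' @export
time_gamma <- function(scenario, times) {
  tab <- rbind(c(1, 5, 10), c(1, 2, 3), c(1, 1.5, 2), c(1, 1.2, 1.5))
  if (!scenario %in% seq_len(nrow(tab))) stop("unknown time scenario")
  if (length(times) != 3L)
    stop("time scenarios are defined for 3 time points")
  stats::setNames(tab[scenario, ], times)
}

#' Simulation recipe
#'
#' Bundles the parameters of one semi-synthetic dataset: the effect under
#' test, the mode (`H0` null transform, `H1` effect injection into `k`
#' whole pathways, `VSize` partial injection of `p_tilde` metabolites of
#' the largest pathway), the multiplicative factor tables and the noise
#' factor of the time transforms.
#'
#' @param effect `"condition"`, `"time"` or `"condition_time"`.
#' @param mode `"H0"`, `"H1"` or `"VSize"`.
#' @param gamma_d named factors per condition (H1/VSize with a condition
#'   component).
#' @param gamma_t named factors per time point (H1/VSize with a time
#'   component).
#' @param k number of differential pathways.
#' @param p_tilde number of differential metabolites in the largest
#'   pathway (VSize only).
#' @param noise_factor multiplier of the quantification range defining the
#'   Gaussian noise variance of the time transforms.
#' @param seed integer seed making the dataset reproducible.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(effect = c("condition", "time", "condition_time"),
                          mode = c("H1", "H0", "VSize"),
                          gamma_d = NULL, gamma_t = NULL,
                          k = 3L, p_tilde = NULL,
                          noise_factor = 0.05, seed = NULL) {
  effect <- match.arg(effect)
  mode <- match.arg(mode)
  if (k < 1L) stop("k must be >= 1")
  if (!is.null(gamma_d) && any(gamma_d <= 0)) stop("gamma_d must be positive")
  if (!is.null(gamma_t) && any(gamma_t <= 0)) stop("gamma_t must be positive")
  if (mode == "VSize" && (is.null(p_tilde) || p_tilde < 1L))
    stop("VSize mode requires p_tilde >= 1")
  if (mode != "H0") {
    if (effect %in% c("condition", "condition_time") && is.null(gamma_d))
      stop("gamma_d required for a condition effect")
    if (effect %in% c("time", "condition_time") && is.null(gamma_t))
      stop("gamma_t required for a time effect")
  }
  structure(list(effect = effect, mode = mode, gamma_d = gamma_d,
                 gamma_t = gamma_t, k = as.integer(k), p_tilde = p_tilde,
                 noise_factor = noise_factor, seed = seed),
            class = "scenario_spec")
}

#' Null transform: permute condition labels
#'
#' Erases any condition effect by permuting the condition labels across
#' individuals. Permutation happens at the individual level (every
#' individual keeps a single label across its time points, and the label
#' multiset over individuals is preserved) so the within-individual
#' correlation structure and any time effect are untouched; the value
#' matrix is not modified.
#'
#' @param qt a [quant_table].
#' @param seed optional integer seed.
#' @return A [quant_table] with permuted condition labels.
#' @export
permute_condition <- function(qt, seed = NULL) {
  stopifnot(inherits(qt, "quant_table"))
  if (!is.null(seed)) set.seed(seed)
  d <- qt$design
  if (nlevels(d$condition) < 2L) {
    warning("single condition: nothing to permute")
    return(qt)
  }
  ind <- levels(d$individual)
  cond <- vapply(ind, function(i)
    as.character(d$condition[d$individual == i][1L]), "")
  perm <- stats::setNames(sample(cond), ind)
  d$condition <- factor(unname(perm[as.character(d$individual)]),
                        levels = levels(d$condition))
  quant_table(qt$values, d)
}

#' Null transform: erase the time effect
#'
#' Replaces every later-time observation by the same individual's
#' first-time-point observation, then adds i.i.d. Gaussian noise
#' `b ~ N(0, sigma_b^2)` to all rows, with
#' `sigma_b^2 = noise_factor * (max(X) - min(X))` computed on the
#' pre-noise matrix. Negative post-noise quantifications are floored at 0
#' to preserve nonnegativity.
#'
#' @param qt a [quant_table]; every individual must be observed at the
#'   first time point.
#' @param noise_factor range multiplier defining the noise variance.
#' @param seed optional integer seed.
#' @return A [quant_table] with no remaining time signal.
#' @export
erase_time <- function(qt, noise_factor = 0.05, seed = NULL) {
  stopifnot(inherits(qt, "quant_table"))
  if (!is.null(seed)) set.seed(seed)
  if (nlevels(qt$design$time) < 2L) stop("need at least 2 time points")
  M <- .repeat_first_time(qt)
  s2 <- noise_factor * (max(M) - min(M))
  if (s2 > 0)
    M <- M + matrix(stats::rnorm(length(M), sd = sqrt(s2)),
                    nrow(M), ncol(M))
  M[M < 0] <- 0
  quant_table(M, qt$design)
}

#' Inject a multiplicative condition effect
#'
#' Multiplies the quantification of every target metabolite by the factor
#' of the row's condition: `X[i, j] <- X[i, j] * gamma_d[condition(i)]`.
#' Non-target metabolites are untouched.
#'
#' @param qt a [quant_table].
#' @param target_metabolites character vector of quantified metabolites.
#' @param gamma_d named positive factors, one per condition level.
#' @return The transformed [quant_table].
#' @export
inject_condition_effect <- function(qt, target_metabolites, gamma_d) {
  stopifnot(inherits(qt, "quant_table"))
  targets <- .check_targets(qt, target_metabolites)
  lev <- levels(qt$design$condition)
  unknown <- setdiff(names(gamma_d), lev)
  if (length(unknown))
    stop("unknown condition key(s) in gamma_d: ",
         paste(unknown, collapse = ", "))
  if (!all(lev %in% names(gamma_d)))
    stop("gamma_d must name every condition level")
  M <- qt$values
  fac <- unname(gamma_d[as.character(qt$design$condition)])
  M[, targets] <- M[, targets, drop = FALSE] * fac
  quant_table(M, qt$design)
}

#' Inject a multiplicative time effect
#'
#' Rebuilds target metabolites from the first-time-point block `S`
#' (repeated across time points) as `S * gamma_t[time] + b`, with
#' `b ~ N(0, sigma_b^2)` and
#' `sigma_b^2 = noise_factor * (max(S * gamma) - min(S * gamma))` computed
#' on the transformed target sub-matrix. By default non-target metabolites
#' are rebuilt from `S` plus noise of the same law, so that only target
#' pathways carry any time signal (`nontargets = "keep"` leaves them
#' untouched instead). Negative post-noise values are floored at 0.
#'
#' @inheritParams erase_time
#' @param target_metabolites character vector of quantified metabolites.
#' @param gamma_t named positive factors, one per time level.
#' @param nontargets `"erase"` (rebuild from `S` + noise, default) or
#'   `"keep"`.
#' @return The transformed [quant_table].
#' @export
inject_time_effect <- function(qt, target_metabolites, gamma_t,
                               noise_factor = 0.05, seed = NULL,
                               nontargets = c("erase", "keep")) {
  stopifnot(inherits(qt, "quant_table"))
  nontargets <- match.arg(nontargets)
  if (!is.null(seed)) set.seed(seed)
  targets <- .check_targets(qt, target_metabolites)
  lev <- levels(qt$design$time)
  unknown <- setdiff(names(gamma_t), lev)
  if (length(unknown))
    stop("unknown time key(s) in gamma_t: ", paste(unknown, collapse = ", "))
  if (!all(lev %in% names(gamma_t)))
    stop("gamma_t must name every time level")
  S <- .repeat_first_time(qt)
  fac <- unname(gamma_t[as.character(qt$design$time)])
  Tg <- S[, targets, drop = FALSE] * fac
  s2 <- noise_factor * (max(Tg) - min(Tg))
  noise <- function(n) if (s2 > 0) stats::rnorm(n, sd = sqrt(s2)) else 0
  M <- qt$values
  M[, targets] <- Tg + noise(length(Tg))
  if (nontargets == "erase") {
    other <- setdiff(colnames(M), targets)
    M[, other] <- S[, other, drop = FALSE] + noise(length(S) - length(Tg))
  }
  M[M < 0] <- 0
  quant_table(M, qt$design)
}

#' Build a null (H0) semi-synthetic dataset
#'
#' Applies the null transform matching the effect under test: condition
#' labels are permuted ([permute_condition]) for the condition effect, the
#' time signal is erased ([erase_time]) for the time effect, and both
#' transforms are applied in that order for `"condition_time"`.
#'
#' @param qt the base [quant_table].
#' @param effect effect whose null is simulated.
#' @param noise_factor noise factor of the time-erasure transform.
#' @param seed optional integer seed.
#' @return A [quant_table].
#' @export
make_h0_dataset <- function(qt,
                            effect = c("condition", "time",
                                       "condition_time"),
                            noise_factor = 0.05, seed = NULL) {
  effect <- match.arg(effect)
  if (!is.null(seed)) set.seed(seed)
  out <- qt
  if (effect %in% c("condition", "condition_time"))
    out <- permute_condition(out)
  if (effect %in% c("time", "condition_time"))
    out <- erase_time(out, noise_factor = noise_factor)
  out
}

#' Build an H1 semi-synthetic dataset
#'
#' Draws `spec$k` pathways uniformly without replacement, takes the union
#' of their members as target metabolites and injects the requested
#' effect: [inject_condition_effect] for `"condition"`,
#' [inject_time_effect] for `"time"`, and for `"condition_time"` the time
#' effect is simulated first and the condition effect applied on top.
#'
#' @param qt the base [quant_table].
#' @param ps a [pathway_set], already filtered against `qt`.
#' @param spec a [scenario_spec] (mode `"H1"`).
#' @return list with `qt` (transformed table), `selected_pathways`,
#'   `target_metabolites` and `spec`.
#' @export
make_h1_dataset <- function(qt, ps, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$k > length(ps$pathways))
    stop("k exceeds the number of pathways")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  selected <- sample(names(ps$pathways), spec$k)
  targets <- unique(unlist(ps$pathways[selected], use.names = FALSE))
  list(qt = .inject_effects(qt, targets, spec),
       selected_pathways = selected,
       target_metabolites = targets,
       spec = spec)
}

#' Build a pathway-size (VSize) semi-synthetic dataset
#'
#' Takes the largest pathway, draws `spec$p_tilde` of its members as
#' differential, and additionally injects the effect into all members of
#' `k - 1` other randomly selected pathways, using the same injection
#' process as [make_h1_dataset].
#'
#' @inheritParams make_h1_dataset
#' @param spec a [scenario_spec] with mode `"VSize"` and `p_tilde` set.
#' @return list with `qt`, `vsize_pathway`, `p_tilde`, `vsize_members`
#'   (the drawn members), `selected_pathways` (the other k - 1),
#'   `target_metabolites` and `spec`.
#' @export
make_vsize_dataset <- function(qt, ps, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$mode != "VSize") stop("spec$mode must be 'VSize'")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  sizes <- lengths(ps$pathways)
  big <- names(sizes)[which.max(sizes)]
  if (spec$p_tilde > sizes[[big]])
    stop("p_tilde exceeds the size of the largest pathway (", sizes[[big]],
         ")")
  members <- sample(ps$pathways[[big]], spec$p_tilde)
  others <- character(0)
  if (spec$k > 1L)
    others <- sample(setdiff(names(ps$pathways), big), spec$k - 1L)
  targets <- unique(c(members,
                      unlist(ps$pathways[others], use.names = FALSE)))
  list(qt = .inject_effects(qt, targets, spec),
       vsize_pathway = big,
       p_tilde = spec$p_tilde,
       vsize_members = members,
       selected_pathways = others,
       target_metabolites = targets,
       spec = spec)
}

.inject_effects <- function(qt, targets, spec) {
  out <- qt
  if (spec$effect %in% c("time", "condition_time"))
    out <- inject_time_effect(out, targets, spec$gamma_t,
                              noise_factor = spec$noise_factor)
  if (spec$effect %in% c("condition", "condition_time"))
    out <- inject_condition_effect(out, targets, spec$gamma_d)
  out
}

.check_targets <- function(qt, targets) {
  targets <- unique(as.character(targets))
  missing <- setdiff(targets, colnames(qt$values))
  if (length(missing))
    stop("target metabolite(s) not quantified: ",
         paste(missing, collapse = ", "))
  targets
}

# first-time-point block of each individual repeated at all its time
# points; errors when an individual lacks the first time point
.repeat_first_time <- function(qt) {
  d <- qt$design
  t1 <- levels(d$time)[1L]
  at1 <- d$individual[d$time == t1]
  absent <- setdiff(levels(d$individual), as.character(at1))
  if (length(absent))
    stop("individual(s) missing the first time point: ",
         paste(absent, collapse = ", "))
  first_row <- stats::setNames(match(paste(at1, t1),
                                     paste(d$individual, d$time)),
                               as.character(at1))
  M <- qt$values[first_row[as.character(d$individual)], , drop = FALSE]
  dimnames(M) <- dimnames(qt$values)
  M
}
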