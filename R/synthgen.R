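#' Specification of the synthetic base generator
#'
#' Parameters of the fully synthetic stand-in for an NMR-quantified
#' longitudinal feces metabolome study: a small two-condition cohort
#' followed over a few time points, with ~100-130 quantified metabolites
#' organised in a few dozen overlapping pathways. The default targets
#' reproduce the structure of such a study: 16 individuals split over 2
#' conditions, 3 time points, 120 metabolites, 40 pathways of size 2-32
#' with mean size about 6 and each pathway metabolite belonging to about 4
#' pathways on average.
#'
#' @param n_individuals number of individuals (split evenly over the two
#'   conditions).
#' @param n_times number of time points.
#' @param n_metabolites number of quantified metabolites.
#' @param n_pathways number of pathways.
#' @param size_range allowed pathway sizes (the upper bound is always
#'   realized by one pathway, giving a well-defined largest pathway for
#'   pathway-size experiments).
#' @param target_mean_size target mean pathway size.
#' @param target_mean_membership target mean number of pathways per
#'   pathway metabolite.
#' @param individual_sd SD of the per-individual random intercept on the
#'   log scale.
#' @param pathway_corr target correlation (log scale) between metabolites
#'   sharing a home pathway; in \[0, 1).
#' @param resid_sd residual SD on the log scale.
#' @param baseline_log_mean_range range of per-metabolite baseline log
#'   means (uniformly drawn), spreading quantifications over orders of
#'   magnitude as relative abundances are.
#' @param n_missing number of randomly removed later-time observations
#'   (incomplete design); first-time observations are never removed.
#' @param seed integer seed.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_individuals = 16L, n_times = 3L,
                           n_metabolites = 120L, n_pathways = 40L,
                           size_range = c(2L, 32L),
                           target_mean_size = 6,
                           target_mean_membership = 4,
                           individual_sd = 0.1, pathway_corr = 0.3,
                           resid_sd = 0.2,
                           baseline_log_mean_range = c(0, 3),
                           n_missing = 0L, seed = NULL) {
  stopifnot(n_individuals >= 4L, n_individuals %% 2L == 0L,
            n_times >= 2L, n_metabolites >= 10L, n_pathways >= 2L,
            size_range[1L] >= 2L, size_range[2L] >= size_range[1L],
            target_mean_size >= size_range[1L],
            target_mean_membership >= 1,
            individual_sd >= 0, resid_sd >= 0,
            pathway_corr >= 0, pathway_corr < 1,
            n_missing >= 0L)
  if (target_mean_membership > n_pathways)
    stop("target_mean_membership cannot exceed n_pathways")
  pool <- round(n_pathways * target_mean_size / target_mean_membership)
  if (pool > n_metabolites)
    stop("infeasible targets: mean size/membership require more than ",
         "n_metabolites pathway metabolites")
  if (pool < size_range[2L])
    stop("infeasible targets: the metabolite pool is smaller than the ",
         "maximum pathway size")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_times = as.integer(n_times),
                 n_metabolites = as.integer(n_metabolites),
                 n_pathways = as.integer(n_pathways),
                 size_range = as.integer(size_range),
                 target_mean_size = target_mean_size,
                 target_mean_membership = target_mean_membership,
                 individual_sd = individual_sd,
                 pathway_corr = pathway_corr,
                 resid_sd = resid_sd,
                 baseline_log_mean_range = baseline_log_mean_range,
                 n_missing = as.integer(n_missing),
                 seed = seed),
            class = "generator_spec")
}

#' Generate an overlapping pathway structure
#'
#' Samples pathway sizes (one pathway pinned at the maximum size, the
#' rest shifted-Poisson around the mean-size target) and draws members
#' uniformly from a metabolite pool sized so that the realized mean
#' membership matches its target; redraws (up to 20 times) until both
#' realized statistics are within 25% of their targets.
#'
#' @param spec a [generator_spec].
#' @return A [pathway_set] (pathway ids `pw_01`, ..., member ids matching
#'   [generate_base] columns).
#' @export
generate_pathways <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  .generate_pathways_impl(spec)
}

.generate_pathways_impl <- function(spec) {
  n_p <- spec$n_pathways
  smin <- spec$size_range[1L]
  smax <- spec$size_range[2L]
  pool_n <- round(n_p * spec$target_mean_size / spec$target_mean_membership)
  met_ids <- sprintf("met_%03d", seq_len(spec$n_metabolites))
  for (try in seq_len(20L)) {
    pool <- sample(met_ids, pool_n)
    lambda <- max(0.1,
                  (n_p * spec$target_mean_size - smax) / (n_p - 1L) - smin)
    sizes <- c(smax, pmin(smax, smin + stats::rpois(n_p - 1L, lambda)))
    members <- lapply(sizes, function(s) sample(pool, s))
    used <- unique(unlist(members, use.names = FALSE))
    mean_size <- mean(sizes)
    mean_membership <- sum(sizes) / length(used)
    ok_size <- abs(mean_size - spec$target_mean_size) <=
      0.25 * spec$target_mean_size
    ok_mem <- abs(mean_membership - spec$target_mean_membership) <=
      0.25 * spec$target_mean_membership
    if (ok_size && ok_mem) {
      names(members) <- sprintf("pw_%02d", seq_len(n_p))
      return(pathway_set(members))
    }
  }
  stop("could not realize the pathway structure targets; ",
       "check the generator spec for feasibility")
}

#' Generate a synthetic base quantification table
#'
#' Simulates a null base dataset (no condition and no time effect) with
#' the correlation structure the pathway tests assume: on the log scale,
#' metabolite `j` at observation `(i, t)` is
#' `mu_j + u_i + c_{it, p(j)} + e`, with a per-individual random intercept
#' `u_i`, a per-observation fluctuation `c` shared by all metabolites
#' whose home pathway is `p(j)` (inducing within-pathway correlation
#' `pathway_corr`), and i.i.d. residuals. Values are exponentiated, so
#' quantifications are strictly positive log-normal relative abundances
#' and multiplicative injected effects act additively on the log scale.
#' Metabolites in several pathways take the fluctuation of their first
#' ("home") assignment; overlap still leaks signal across pathways, as in
#' real pathway catalogues.
#'
#' @param spec a [generator_spec].
#' @param pathways optional [pathway_set]; generated from `spec` when
#'   omitted.
#' @return A [quant_table] (conditions `control`/`treated`, times
#'   `t1 < t2 < ...`).
#' @seealso [generate_dataset] for the pathway set and table together.
#' @export
generate_base <- function(spec, pathways = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (is.null(pathways)) pathways <- .generate_pathways_impl(spec)
  .generate_base_impl(spec, pathways)
}

.generate_base_impl <- function(spec, pathways) {
  n <- spec$n_individuals
  Tt <- spec$n_times
  m <- spec$n_metabolites
  ind <- sprintf("ind_%02d", seq_len(n))
  times <- paste0("t", seq_len(Tt))
  cond <- rep(c("control", "treated"), each = n / 2L)
  design <- data.frame(
    sample_id = paste0(rep(ind, Tt), "_", rep(times, each = n)),
    individual = rep(ind, Tt),
    time = rep(times, each = n),
    condition = rep(cond, Tt),
    stringsAsFactors = FALSE)
  if (spec$n_missing > 0L) {
    later <- which(design$time != times[1L])
    if (spec$n_missing >= length(later))
      stop("n_missing leaves no later-time observations")
    design <- design[-sample(later, spec$n_missing), , drop = FALSE]
  }
  n_obs <- nrow(design)
  met_ids <- sprintf("met_%03d", seq_len(m))

  # variance partition on the log scale: total within-pathway covariance
  # (individual + shared fluctuation) set to pathway_corr * total variance
  s2_e <- spec$resid_sd^2
  s2_u <- spec$individual_sd^2
  s2_c <- spec$pathway_corr * s2_e / (1 - spec$pathway_corr) - s2_u
  if (spec$pathway_corr == 0) s2_c <- 0
  if (s2_c < 0) {
    warning("individual_sd alone exceeds the requested pathway_corr; ",
            "shared-fluctuation variance floored at 0")
    s2_c <- 0
  }

  home <- rep(NA_integer_, m)
  names(home) <- met_ids
  for (l in seq_along(pathways$pathways)) {
    mem <- pathways$pathways[[l]]
    new <- mem[is.na(home[mem])]
    home[new] <- l
  }

  mu <- stats::runif(m, spec$baseline_log_mean_range[1L],
                     spec$baseline_log_mean_range[2L])
  u <- stats::setNames(stats::rnorm(n, sd = spec$individual_sd), ind)
  C <- matrix(stats::rnorm(n_obs * length(pathways$pathways),
                           sd = sqrt(s2_c)),
              n_obs, length(pathways$pathways))
  logX <- matrix(mu, n_obs, m, byrow = TRUE) +
    u[design$individual] +
    matrix(stats::rnorm(n_obs * m, sd = spec$resid_sd), n_obs, m)
  in_pw <- !is.na(home)
  logX[, in_pw] <- logX[, in_pw] + C[, home[in_pw], drop = FALSE]
  X <- exp(logX)
  dimnames(X) <- list(design$sample_id, met_ids)
  quant_table(X, design)
}

#' Generate a consistent pathway set and base table
#'
#' Convenience wrapper seeding the generator once and returning the
#' pathway structure together with the base quantification table built on
#' it.
#'
#' @param spec a [generator_spec].
#' @return list with `pathways` (a [pathway_set]) and `qt`
#'   (a [quant_table]).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  pathways <- .generate_pathways_impl(spec)
  list(pathways = pathways, qt = .generate_base_impl(spec, pathways))
}
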