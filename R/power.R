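#' Repeated-measures ANOVA power scenario
#'
#' Describes one of the a priori sample-size scenarios: a within-subjects
#' repeated-measures F test (effect of the repeated factor) or the
#' within-between interaction F test, parameterised by Cohen's f, the
#' number of repeated measurements m, the correlation rho among repeated
#' measures, and the nonsphericity correction epsilon.
#'
#' @param design `"within"` or `"within_between_interaction"`.
#' @param alpha test level.
#' @param f Cohen's effect size f.
#' @param n_groups number of between-subject groups (1 for pure within).
#' @param m number of repeated measurements.
#' @param rho correlation among repeated measures.
#' @param eps nonsphericity correction (1 = sphericity holds).
#' @param target_power power the design aims for.
#' @param f_is_adjusted set `TRUE` when the supplied effect size already
#'   absorbs the repeated-measures correlation, in which case the
#'   noncentrality omits the 1/(1 - rho) factor (the two conventions
#'   offered by common power software).
#' @return list of class `mpmri_power_scenario`.
#' @export
power_scenario <- function(design = c("within", "within_between_interaction"),
                           alpha = 0.05, f = 0.25, n_groups = 1L, m = 5L,
                           rho = 0.8, eps = 1, target_power = 0.8,
                           f_is_adjusted = FALSE) {
  design <- match.arg(design)
  stopifnot(alpha > 0, alpha < 1, f >= 0, m >= 2, rho >= 0, rho < 1,
            target_power > 0, target_power < 1)
  if (design == "within_between_interaction" && n_groups < 2)
    stop("interaction design needs at least 2 groups")
  structure(list(design = design, alpha = alpha, f = f,
                 n_groups = as.integer(n_groups), m = as.integer(m),
                 rho = rho, eps = eps, target_power = target_power,
                 f_is_adjusted = isTRUE(f_is_adjusted)),
            class = "mpmri_power_scenario")
}

#' The three published sample-size scenarios
#'
#' Time effect within one cohort (f = 0.35, m = 5), the time x diet
#' interaction over two cohorts (f = 0.25, m = 5), and the
#' time-by-area x diet interaction (f = 0.15, m = 5 x 4 = 20), all at
#' alpha = 0.05 with correlation 0.8 among repeated measures.
#'
#' @param target_power target power used when solving for n (the source
#'   analysis states only the significance level; 0.8 is the
#'   conventional default).
#' @return named list of three [power_scenario()] objects.
#' @export
paper_power_scenarios <- function(target_power = 0.8) {
  list(
    time_within = power_scenario("within", alpha = 0.05, f = 0.35,
                                 n_groups = 1, m = 5, rho = 0.8,
                                 target_power = target_power),
    time_diet_interaction = power_scenario("within_between_interaction",
                                 alpha = 0.05, f = 0.25, n_groups = 2, m = 5,
                                 rho = 0.8, target_power = target_power),
    time_area_diet_interaction = power_scenario("within_between_interaction",
                                 alpha = 0.05, f = 0.15, n_groups = 2, m = 20,
                                 rho = 0.8, target_power = target_power)
  )
}

#' Analytic power of a repeated-measures ANOVA design
#'
#' Power from the noncentral F distribution with noncentrality
#' lambda = f^2 N m eps / (1 - rho), numerator df (m - 1) eps for the
#' within effect and (groups - 1)(m - 1) eps for the interaction, and
#' denominator df (N - groups)(m - 1) eps.
#'
#' @param scenario an [power_scenario()].
#' @param n_per_group subjects per group.
#' @return power in (0, 1).
#' @export
rm_anova_power <- function(scenario, n_per_group) {
  stopifnot(inherits(scenario, "mpmri_power_scenario"), n_per_group >= 2)
  s <- scenario
  N <- n_per_group * s$n_groups
  df1 <- switch(s$design,
    within = (s$m - 1) * s$eps,
    within_between_interaction = (s$n_groups - 1) * (s$m - 1) * s$eps)
  df2 <- (N - s$n_groups) * (s$m - 1) * s$eps
  lambda <- s$f^2 * N * s$m * s$eps /
    (if (isTRUE(s$f_is_adjusted)) 1 else 1 - s$rho)
  crit <- stats::qf(1 - s$alpha, df1, df2)
  1 - stats::pf(crit, df1, df2, ncp = lambda)
}

#' Smallest group size reaching the target power
#'
#' @param scenario an [power_scenario()].
#' @param target_power overrides the scenario's target.
#' @return smallest integer n_per_group with
#'   `rm_anova_power(scenario, n) >= target_power`.
#' @export
solve_n <- function(scenario, target_power = scenario$target_power) {
  for (n in 2:10000) {
    if (rm_anova_power(scenario, n) >= target_power) return(n)
  }
  stop("target power not attainable below n = 10000")
}

#' Consensus group size over several scenarios
#'
#' @param scenarios list of [power_scenario()] objects.
#' @param target_power optional common target.
#' @return the maximum of the per-scenario [solve_n()] solutions.
#' @export
consensus_n <- function(scenarios, target_power = NULL) {
  stopifnot(length(scenarios) >= 1)
  max(vapply(scenarios, function(s)
    solve_n(s, target_power %||% s$target_power), numeric(1)))
}

#' Monte-Carlo power of a repeated-measures design
#'
#' Simulates the design (compound-symmetric subjects, effect pattern
#' scaled to the scenario's f) and counts rejections of the classical
#' repeated-measures F test, as an independent check on
#' [rm_anova_power()].
#'
#' @param scenario an [power_scenario()].
#' @param n_per_group subjects per group.
#' @param nsim number of simulated experiments.
#' @param seed RNG seed.
#' @return empirical power.
#' @export
simulate_rm_anova_power <- function(scenario, n_per_group, nsim = 2000,
                                    seed = 1) {
  s <- scenario
  N <- n_per_group * s$n_groups
  m <- s$m
  # effect pattern with mean-square f^2 (sigma = 1)
  pat <- sin(seq(0, 2 * pi, length.out = m + 1))[seq_len(m)]
  pat <- pat - mean(pat)
  pat <- pat * s$f / sqrt(mean(pat^2))
  sd_subj <- sqrt(s$rho); sd_err <- sqrt(1 - s$rho)
  df1 <- switch(s$design, within = m - 1,
                within_between_interaction = (s$n_groups - 1) * (m - 1))
  df2 <- (N - s$n_groups) * (m - 1)
  crit <- stats::qf(1 - s$alpha, df1, df2)
  group <- rep(seq_len(s$n_groups), each = n_per_group)
  # interaction pattern: opposite-signed time profile across groups
  gsign <- if (s$n_groups > 1) ifelse(group == 1, 1, -1) else rep(1, N)
  with_seed(seed, {
    rej <- 0L
    for (i in seq_len(nsim)) {
      subj <- stats::rnorm(N, sd = sd_subj)
      E <- matrix(stats::rnorm(N * m, sd = sd_err), N, m)
      Ym <- switch(s$design,
        within = outer(rep(1, N), pat),
        within_between_interaction = outer(gsign, pat))
      Y <- Ym + subj + E
      if (s$design == "within") {
        tm <- colMeans(Y)
        gm <- mean(Y)
        sm <- rowMeans(Y)
        ms_t <- N * sum((tm - gm)^2) / (m - 1)
        res <- Y - outer(sm, rep(1, m)) - outer(rep(1, N), tm) + gm
        ms_e <- sum(res^2) / ((N - 1) * (m - 1))
      } else {
        # group x time interaction F with subjects nested in groups
        gt <- rowsum(Y, group) / n_per_group          # group x time means
        tm <- colMeans(Y); gmn <- rowMeans(gt); gm <- mean(Y)
        int <- sweep(sweep(gt, 2, tm), 1, gmn) + gm
        ms_t <- n_per_group * sum(int^2) / df1
        sm <- rowMeans(Y)
        res <- Y - sm %o% rep(1, m) - gt[group, ] + gmn[group]
        ms_e <- sum(res^2) / df2
      }
      if (ms_t / ms_e > crit) rej <- rej + 1L
    }
    rej / nsim
  })
}
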