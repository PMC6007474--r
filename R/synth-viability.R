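#' Specification for a simulated two-agent viability experiment
#'
#' Describes an AlamarBlue-style plate layout with four groups -- untreated
#' control, agent A alone, agent B alone, and the A+B combination -- whose
#' true surviving fractions follow Bliss independence exactly
#' (\code{f_a * f_b}) or deviate from it by a stated shift. Replicate values
#' are drawn with multiplicative Gaussian noise at coefficient of variation
#' \code{cv}.
#'
#' @param f_a,f_b Surviving fraction under each single agent, in [0, 1].
#' @param interaction One of "bliss", "synergistic", "antagonistic".
#' @param interaction_shift Magnitude of the departure from the Bliss product
#'   (subtracted for synergy, added for antagonism; result clipped to [0, 1]).
#' @param n_replicates Replicates per group, >= 2.
#' @param cv Coefficient of variation of replicate noise.
#' @param dose Optional dose label attached to the B and A+B groups.
#' @param seed Integer seed or NULL.
#' @return A list of class \code{viability_sim_spec}.
#' @export
viability_sim_spec <- function(f_a = 0.8, f_b = 0.7,
                               interaction = c("bliss", "synergistic",
                                               "antagonistic"),
                               interaction_shift = 0.2, n_replicates = 6L,
                               cv = 0.05, dose = NA_character_, seed = NULL) {
  interaction <- match.arg(interaction)
  stopifnot(f_a >= 0, f_a <= 1, f_b >= 0, f_b <= 1,
            interaction_shift >= 0, cv >= 0)
  if (n_replicates < 2L)
    stop("n_replicates must be >= 2 (downstream ANOVA needs replication)")
  structure(list(f_a = f_a, f_b = f_b, interaction = interaction,
                 interaction_shift = interaction_shift,
                 n_replicates = as.integer(n_replicates), cv = cv,
                 dose = dose, seed = seed),
            class = "viability_sim_spec")
}

# true combination survival under the stated interaction structure
true_combination_fraction <- function(spec) {
  base <- spec$f_a * spec$f_b
  switch(spec$interaction,
         bliss = base,
         synergistic = max(0, base - spec$interaction_shift),
         antagonistic = min(1, base + spec$interaction_shift))
}

#' Simulate a long-format viability table with known interaction structure
#'
#' Draws replicate metabolic-activity fractions around the true group means of
#' a [viability_sim_spec()]. The control group's true mean is 1; noisy values
#' are clipped below at 0.
#'
#' @param spec A \code{viability_sim_spec}.
#' @return A data.frame with columns \code{group} (control/A/B/AB),
#'   \code{dose}, \code{replicate}, \code{value}, plus attribute
#'   \code{truth} (the four true group means).
#' @examples
#' tab <- make_viability_table(viability_sim_spec(cv = 0, f_a = 0.8, f_b = 0.7))
#' subset(tab, group == "AB")$value  # all 0.56 under Bliss with cv = 0
#' @export
make_viability_table <- function(spec) {
  stopifnot(inherits(spec, "viability_sim_spec"))
  means <- c(control = 1, A = spec$f_a, B = spec$f_b,
             AB = true_combination_fraction(spec))
  with_seed_if(spec$seed, {
    n <- spec$n_replicates
    tab <- do.call(rbind, lapply(names(means), function(g) {
      mu <- means[[g]]
      vals <- if (spec$cv > 0) mu * (1 + stats::rnorm(n, 0, spec$cv)) else rep(mu, n)
      data.frame(group = g,
                 dose = if (g %in% c("B", "AB")) spec$dose else NA_character_,
                 replicate = seq_len(n), value = pmax(vals, 0))
    }))
    attr(tab, "truth") <- means
    tab
  })
}
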