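# Projected-additive (Bliss independence) drug-synergy classification from
# plate-reader viability tables: the combination's expected surviving
# fraction under independence is the product of the single-agent surviving
# fractions; observed combinations significantly below it are synergistic,
# above it antagonistic, otherwise additive.

#' Normalize raw viability readings to metabolic-activity fractions
#'
#' Every value is divided by the mean of the control group, so the untreated
#' control exhibits 100% metabolic activity (fraction 1) on average. The
#' operation is idempotent: normalizing an already-normalized table changes
#' nothing.
#'
#' @param table data.frame with columns \code{group}, \code{replicate},
#'   \code{value} (and optionally \code{dose}).
#' @param control_group Label of the control group.
#' @return The table with \code{value} in fraction units.
#' @export
normalize_viability <- function(table, control_group = "control") {
  stopifnot(is.data.frame(table), all(c("group", "value") %in% names(table)))
  ctrl <- table$value[table$group == control_group]
  if (length(ctrl) < 2L)
    stop("control group '", control_group, "' needs >= 2 replicates")
  m <- mean(ctrl)
  if (!is.finite(m) || m <= 0)
    stop("control-group mean must be positive; got ", format(m))
  table$value <- table$value / m
  table
}

#' Projected-additive sample under Bliss independence
#'
#' The expected surviving fraction of a combination of independently acting
#' agents is the product of the single-agent surviving fractions. Replicate
#' projected values are formed by matched-index pairing by default
#' (\code{fa[i] * fb[i]}, giving a sample of independent products whose
#' variance matches the product's true sampling variance); all pairwise
#' products \code{fa[i] * fb[j]} are available via \code{pairing =
#' "pairwise"}, but note that pairwise products share replicates and are not
#' independent observations.
#'
#' When the surviving fractions were normalized by a noisy control mean, the
#' observed combination sample carries one power of that shared constant but
#' a plain product of two normalized fractions carries two, which shifts the
#' projected group relative to the observed group by an amount invisible to
#' the within-group ANOVA residual and inflates the false non-additive rate.
#' Supplying the matched normalized control replicates as \code{fc} forms
#' \code{fa[i] * fb[i] / fc[i]}, restoring the single shared power of the
#' normalization constant (it cancels in the group contrast) and folding the
#' control's replicate noise into the projected sample where the test can see
#' it. [synergy_report()] does this automatically.
#'
#' @param fa,fb Non-negative surviving-fraction replicates of each agent.
#' @param pairing "matched" (default) or "pairwise".
#' @param fc Optional matched normalized control replicates (matched pairing
#'   only); mean approximately 1 after [normalize_viability()].
#' @return Numeric vector of projected surviving fractions.
#' @examples
#' projected_additive(c(0.9, 0.8), c(0.6, 0.5), pairing = "pairwise")
#' @export
projected_additive <- function(fa, fb, pairing = c("matched", "pairwise"),
                               fc = NULL) {
  pairing <- match.arg(pairing)
  if (length(fa) == 0L || length(fb) == 0L)
    stop("both single-agent samples must be non-empty")
  if (any(fa < 0) || any(fb < 0))
    stop("surviving fractions must be non-negative")
  if (pairing == "pairwise") {
    if (!is.null(fc))
      stop("fc is only meaningful for matched pairing")
    return(as.vector(outer(fa, fb)))
  }
  if (length(fa) != length(fb))
    stop("matched pairing needs equal replicate counts (",
         length(fa), " vs ", length(fb), "); use pairing = \"pairwise\"")
  if (is.null(fc)) return(fa * fb)
  if (length(fc) != length(fa))
    stop("matched pairing needs equal replicate counts for fc (",
         length(fc), " vs ", length(fa), ")")
  if (any(fc <= 0))
    stop("control surviving fractions must be positive")
  fa * fb / fc
}

#' Classify one observed-vs-projected contrast
#'
#' Compares the observed combination activities with the projected-additive
#' sample by one-way ANOVA (for two groups, equivalent to the pooled t-test).
#' Observed activity significantly lower than projected is synergistic,
#' significantly higher antagonistic, non-significant additive. Two
#' degenerate identical zero-variance samples are additive with p = 1;
#' zero residual variance with distinct means classifies by direction with
#' p = 0 (both flagged).
#'
#' @param observed,projected Surviving-fraction samples, each of size >= 2.
#' @param alpha Two-sided significance level (default 0.05).
#' @param dose_label Label carried into the result.
#' @return List of class \code{synergy_call}: dose_label, observed_sample,
#'   projected_sample, observed_mean, projected_mean, p_value,
#'   classification, degenerate flag.
#' @export
classify_interaction <- function(observed, projected, alpha = 0.05,
                                 dose_label = NA_character_) {
  stopifnot(length(observed) >= 2L, length(projected) >= 2L,
            alpha > 0, alpha < 1)
  obs_m <- mean(observed); proj_m <- mean(projected)
  y <- c(observed, projected)
  g <- factor(rep(c("observed", "projected"),
                  c(length(observed), length(projected))))
  degenerate <- FALSE
  resid_var <- sum((observed - obs_m)^2) + sum((projected - proj_m)^2)
  if (resid_var <= .Machine$double.eps * sum(y^2)) {
    degenerate <- TRUE
    p <- if (isTRUE(all.equal(obs_m, proj_m))) 1 else 0
  } else {
    fit <- stats::aov(y ~ g)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
  }
  cls <- if (p >= alpha) "additive"
         else if (obs_m < proj_m) "synergistic"
         else "antagonistic"
  structure(list(dose_label = dose_label, observed_sample = observed,
                 projected_sample = projected, observed_mean = obs_m,
                 projected_mean = proj_m, p_value = p, classification = cls,
                 degenerate = degenerate),
            class = "synergy_call")
}

#' @export
print.synergy_call <- function(x, ...) {
  cat(sprintf("<synergy_call> %s: observed %.3f vs projected %.3f, p = %.3g -> %s\n",
              ifelse(is.na(x$dose_label), "(single dose)", x$dose_label),
              x$observed_mean, x$projected_mean, x$p_value, x$classification))
  invisible(x)
}

#' @export
as.data.frame.synergy_call <- function(x, ...) {
  data.frame(dose = x$dose_label, observed_mean = x$observed_mean,
             projected_mean = x$projected_mean, p_value = x$p_value,
             classification = x$classification,
             n_observed = length(x$observed_sample),
             n_projected = length(x$projected_sample))
}

#' Synergy report across dose levels
#'
#' Normalizes the table, forms the projected-additive sample at each dose
#' (agent A fixed, agent B and the combination AB varying with dose) and
#' classifies every observed-vs-projected contrast. With matched pairing and
#' equal replicate counts the normalized control replicates enter the
#' projection (see \code{fc} in [projected_additive()]), which keeps the
#' false non-additive rate at the nominal level despite the shared
#' control-mean normalization. With
#' \code{multiplicity = "joint"} (default) all observed and projected groups
#' enter one one-way ANOVA and the per-dose p-values are Tukey
#' HSD-adjusted over the whole family; \code{"per_dose"} tests each dose
#' separately without adjustment.
#'
#' @param table Long-format data.frame with columns group
#'   (control/A/B/AB), dose (for B and AB rows), replicate, value.
#' @param dose_levels Doses to analyze; defaults to all doses present in the
#'   AB group, in order of appearance.
#' @param alpha Significance level.
#' @param pairing Passed to [projected_additive()].
#' @param multiplicity "joint" or "per_dose".
#' @param control_group Label of the control group.
#' @return data.frame with one row per dose: dose, observed_mean,
#'   projected_mean, p_value, classification, n_observed, n_projected. The
#'   individual \code{synergy_call} objects are attached as attribute
#'   \code{calls}.
#' @export
synergy_report <- function(table, dose_levels = NULL, alpha = 0.05,
                           pairing = c("matched", "pairwise"),
                           multiplicity = c("joint", "per_dose"),
                           control_group = "control") {
  pairing <- match.arg(pairing)
  multiplicity <- match.arg(multiplicity)
  stopifnot(is.data.frame(table),
            all(c("group", "replicate", "value") %in% names(table)))
  if (!"dose" %in% names(table)) table$dose <- NA_character_
  table <- normalize_viability(table, control_group)
  if (is.null(dose_levels))
    dose_levels <- unique(table$dose[table$group == "AB"])
  if (length(dose_levels) == 0L) {
    out <- data.frame(dose = character(0), observed_mean = numeric(0),
                      projected_mean = numeric(0), p_value = numeric(0),
                      classification = character(0), n_observed = integer(0),
                      n_projected = integer(0))
    attr(out, "calls") <- list()
    return(out)
  }

  fa <- table$value[table$group == "A"]
  fcv <- table$value[table$group == control_group]
  samples <- list()
  for (d in dose_levels) {
    sel <- function(g) table$value[table$group == g &
                                     (is.na(d) & is.na(table$dose) |
                                        !is.na(table$dose) & table$dose %in% d)]
    fb <- sel("B"); obs <- sel("AB")
    if (length(fa) == 0L || length(fb) < 2L || length(obs) < 2L) {
      warning("dose level '", d, "' missing a required group; skipped")
      next
    }
    fc <- if (pairing == "matched" && length(fcv) == length(fa)) fcv else NULL
    samples[[as.character(d)]] <- list(
      observed = obs,
      projected = projected_additive(fa, fb, pairing, fc = fc),
      dose = d)
  }
  if (length(samples) == 0L) {
    out <- data.frame(dose = character(0), observed_mean = numeric(0),
                      projected_mean = numeric(0), p_value = numeric(0),
                      classification = character(0), n_observed = integer(0),
                      n_projected = integer(0))
    attr(out, "calls") <- list()
    return(out)
  }

  calls <- lapply(samples, function(s)
    classify_interaction(s$observed, s$projected, alpha, dose_label = s$dose))

  if (multiplicity == "joint" && length(samples) > 1L) {
    # one ANOVA over all observed/projected groups, Tukey HSD family-wise
    y <- unlist(lapply(samples, function(s) c(s$observed, s$projected)))
    g <- unlist(lapply(names(samples), function(nm) {
      s <- samples[[nm]]
      rep(paste0(c("obs_", "proj_"), nm),
          c(length(s$observed), length(s$projected)))
    }))
    if (stats::var(y) > 0) {
      tuk <- stats::TukeyHSD(stats::aov(y ~ factor(g)))[[1]]
      for (nm in names(samples)) {
        pair <- paste0("proj_", nm, "-obs_", nm)
        alt <- paste0("obs_", nm, "-proj_", nm)
        row <- if (pair %in% rownames(tuk)) pair
               else if (alt %in% rownames(tuk)) alt else NA
        if (!is.na(row)) {
          p <- tuk[row, "p adj"]
          calls[[nm]]$p_value <- p
          calls[[nm]]$classification <-
            if (p >= alpha) "additive"
            else if (calls[[nm]]$observed_mean < calls[[nm]]$projected_mean)
              "synergistic" else "antagonistic"
        }
      }
    }
  }

  out <- do.call(rbind, lapply(calls, as.data.frame))
  rownames(out) <- NULL
  attr(out, "calls") <- calls
  out
}
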