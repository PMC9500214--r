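# Statistical analysis: pooled trial-level regressions per clamp type,
# two-way repeated-measures ANOVA with partial eta squared, Tukey post-hocs
# and paired Cohen's d.

#' Classify the strength of a squared Pearson correlation
#'
#' Bounds: >0.8 very strong, 0.6-0.8 strong, 0.4-0.6 moderate, 0.2-0.4 weak,
#' <0.2 very weak. Boundary values take the lower bin's label (0.8 ->
#' "strong", 0.6 -> "moderate", ...).
#'
#' @param r2 Squared correlation(s) in \[0, 1\].
#' @return Character vector of strength labels.
#' @export
classify_r2 <- function(r2) {
  if (any(!is.finite(r2)) || any(r2 < 0 | r2 > 1)) stop("r2 must be in [0, 1]")
  labs <- c("very weak", "weak", "moderate", "strong", "very strong")
  labs[pmax(findInterval(r2, c(0, 0.2, 0.4, 0.6, 0.8), left.open = TRUE), 1)]
}

#' Pooled trial-level association between two summary variables
#'
#' Squared Pearson correlation, two-sided p value and OLS slope/intercept of
#' `y` on `x`, computed within each clamp type and reported alongside the
#' cross-clamp "average" row whose R-squared is the arithmetic mean of the
#' per-clamp values (how average R-squared values are quoted alongside the
#' per-clamp ones).
#'
#' @param table Trial summary table (long format, one row per trial).
#' @param x,y Column names of the regressors.
#' @param by Grouping column, default `"clamp_type"`; `NULL` pools everything.
#' @return data.frame of class `fpclamp_association`: `group`, `x`, `y`, `n`,
#'   `r2`, `p`, `slope`, `intercept`, `strength`.
#' @export
association <- function(table, x, y, by = "clamp_type") {
  stopifnot(x %in% names(table), y %in% names(table))
  one <- function(d, label) {
    d <- d[stats::complete.cases(d[, c(x, y)]), ]
    if (nrow(d) < 3) stop("need at least 3 paired observations per group")
    if (stats::sd(d[[x]]) == 0 || stats::sd(d[[y]]) == 0) {
      stop("zero variance in x or y; association undefined")
    }
    ct <- stats::cor.test(d[[x]], d[[y]])
    fit <- stats::lm.fit(cbind(1, d[[x]]), d[[y]])
    r2 <- unname(ct$estimate^2)
    data.frame(group = label, x = x, y = y, n = nrow(d), r2 = r2,
               p = ct$p.value, slope = fit$coefficients[2],
               intercept = fit$coefficients[1],
               strength = classify_r2(r2), stringsAsFactors = FALSE,
               row.names = NULL)
  }
  if (is.null(by)) {
    out <- one(table, "pooled")
  } else {
    groups <- sort(unique(table[[by]]))
    out <- do.call(rbind, lapply(groups, function(g) {
      one(table[table[[by]] == g, ], g)
    }))
    avg <- data.frame(group = "average", x = x, y = y, n = sum(out$n),
                      r2 = mean(out$r2), p = max(out$p),
                      slope = mean(out$slope), intercept = mean(out$intercept),
                      strength = classify_r2(mean(out$r2)),
                      stringsAsFactors = FALSE)
    out <- rbind(out, avg)
  }
  class(out) <- c("fpclamp_association", "data.frame")
  out
}

#' Two-way repeated-measures ANOVA with effect sizes and post-hocs
#'
#' Within-subject two-way ANOVA of `dv` on clamp type and condition intensity
#' over a complete balanced design (one observation per participant x clamp x
#' intensity cell). Each effect is tested against its own subject-interaction
#' stratum; partial eta squared is `SS_effect / (SS_effect + SS_error)`.
#' When an effect is significant at `alpha`, Tukey post-hocs (studentized
#' range on the stratum's mean square) compare intensity levels (collapsed
#' over clamp), and paired comparisons between clamp types are run at each
#' intensity; every post-hoc carries a paired Cohen's d. No sphericity
#' correction is applied.
#'
#' @param table Trial summary table with `participant_id`, `clamp_type`,
#'   `intensity` and the dependent variable column.
#' @param dv Name of the dependent-variable column.
#' @param alpha Significance level gating post-hocs, default 0.05.
#' @return List of class `fpclamp_anova`: `effects` (df, SS, F, p, partial
#'   eta squared per effect) and `posthoc` (pairwise contrasts with Tukey p
#'   and Cohen's d; empty when no parent effect is significant).
#' @export
rm_anova <- function(table, dv, alpha = 0.05) {
  stopifnot(dv %in% names(table))
  a_lv <- if (all(table$clamp_type %in% c("speed", "fp"))) {
    intersect(c("speed", "fp"), unique(table$clamp_type))
  } else sort(unique(table$clamp_type))
  d <- data.frame(id = factor(table$participant_id),
                  A = factor(table$clamp_type, levels = a_lv),
                  B = factor(table$intensity,
                             levels = sort(unique(table$intensity))),
                  y = table[[dv]])
  if (anyNA(d$y)) stop("missing values in dv; complete design required")
  nS <- nlevels(d$id); nA <- nlevels(d$A); nB <- nlevels(d$B)
  if (nrow(d) != nS * nA * nB || any(table(d$id, d$A, d$B) != 1)) {
    stop("design must be complete and balanced: one row per cell per participant")
  }
  m <- mean(d$y)
  m_s <- tapply(d$y, d$id, mean); m_a <- tapply(d$y, d$A, mean)
  m_b <- tapply(d$y, d$B, mean)
  m_ab <- tapply(d$y, list(d$A, d$B), mean)
  m_sa <- tapply(d$y, list(d$id, d$A), mean)
  m_sb <- tapply(d$y, list(d$id, d$B), mean)

  ss_a <- nS * nB * sum((m_a - m)^2)
  ss_b <- nS * nA * sum((m_b - m)^2)
  ss_ab <- nS * sum((m_ab - outer(m_a, rep(1, nB)) -
                       outer(rep(1, nA), m_b) + m)^2)
  ss_s <- nA * nB * sum((m_s - m)^2)
  ss_sa <- nB * sum((m_sa - outer(m_s, rep(1, nA)) -
                       outer(rep(1, nS), m_a) + m)^2)
  ss_sb <- nA * sum((m_sb - outer(m_s, rep(1, nB)) -
                       outer(rep(1, nS), m_b) + m)^2)
  ss_tot <- sum((d$y - m)^2)
  ss_sab <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_sa - ss_sb

  eff <- data.frame(
    effect = c("clamp", "intensity", "clamp:intensity"),
    df1 = c(nA - 1, nB - 1, (nA - 1) * (nB - 1)),
    df2 = c((nA - 1) * (nS - 1), (nB - 1) * (nS - 1),
            (nA - 1) * (nB - 1) * (nS - 1)),
    ss = c(ss_a, ss_b, ss_ab),
    ss_error = c(ss_sa, ss_sb, ss_sab),
    stringsAsFactors = FALSE
  )
  eff$F <- (eff$ss / eff$df1) / (eff$ss_error / eff$df2)
  # degenerate constant input: no effect and no error variance
  degen <- eff$ss < 1e-12 & eff$ss_error < 1e-12
  eff$F[degen] <- 0
  eff$p <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  eff$p[degen] <- 1
  eff$partial_eta_sq <- eff$ss / (eff$ss + eff$ss_error)
  eff$partial_eta_sq[degen] <- 0

  cohen_d_paired <- function(diffs) mean(diffs) / stats::sd(diffs)
  post <- list()
  # intensity pairs (collapsed over clamp), Tukey on the B x subject stratum
  if (eff$p[eff$effect == "intensity"] <= alpha && nB > 1) {
    ms <- ss_sb / ((nB - 1) * (nS - 1))
    se <- sqrt(ms / (nS * nA))
    lv <- levels(d$B)
    for (i in seq_len(nB - 1)) for (j in (i + 1):nB) {
      diff <- m_b[j] - m_b[i]
      q <- abs(diff) / se
      per_subj <- m_sb[, j] - m_sb[, i]
      post[[length(post) + 1]] <- data.frame(
        effect = "intensity", contrast = paste(lv[j], "vs", lv[i]),
        estimate = unname(diff),
        p = stats::ptukey(q, nB, (nB - 1) * (nS - 1), lower.tail = FALSE),
        cohen_d = cohen_d_paired(per_subj), stringsAsFactors = FALSE)
    }
  }
  # clamp contrast at each intensity (paired), when clamp main effect or the
  # interaction is significant
  sig_clamp <- eff$p[eff$effect == "clamp"] <= alpha ||
    eff$p[eff$effect == "clamp:intensity"] <= alpha
  if (sig_clamp && nA == 2) {
    lv <- levels(d$B); la <- levels(d$A)
    wide <- stats::reshape(d, idvar = c("id", "B"), timevar = "A",
                           direction = "wide")
    for (b in lv) {
      db <- wide[wide$B == b, ]
      diffs <- db[[paste0("y.", la[2])]] - db[[paste0("y.", la[1])]]
      tt <- stats::t.test(diffs)
      post[[length(post) + 1]] <- data.frame(
        effect = "clamp", contrast = sprintf("%s vs %s @ %s", la[2], la[1], b),
        estimate = mean(diffs), p = tt$p.value,
        cohen_d = cohen_d_paired(diffs), stringsAsFactors = FALSE)
    }
  }
  posthoc <- if (length(post)) do.call(rbind, post) else
    data.frame(effect = character(0), contrast = character(0),
               estimate = numeric(0), p = numeric(0), cohen_d = numeric(0))
  structure(list(dv = dv, effects = eff, posthoc = posthoc, alpha = alpha),
            class = "fpclamp_anova")
}

#' @export
print.fpclamp_anova <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA on '%s'\n", x$dv))
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-16s F(%d,%d) = %7.2f, p = %.4g, eta_p^2 = %.3f\n",
                eff$effect[i], eff$df1[i], eff$df2[i], eff$F[i], eff$p[i],
                eff$partial_eta_sq[i]))
  }
  if (nrow(x$posthoc)) {
    cat(sprintf("  %d post-hoc contrasts (see $posthoc)\n", nrow(x$posthoc)))
  }
  invisible(x)
}

#' Association between within-trial speed variability and metabolic outcomes
#'
#' Self-paced (F_P clamp) trials only: regresses net metabolic power and cost
#' of transport on the within-trial SD of belt speed. In the calibrated
#' cohort metabolic noise is independent of speed variability, so both
#' associations are expected null.
#'
#' @param table Trial summary table containing `speed_sd_within`.
#' @return `fpclamp_association` data.frame with one row per outcome.
#' @export
speed_variability_check <- function(table) {
  d <- table[table$clamp_type == "fp", ]
  if (nrow(d) == 0) stop("no F_P-clamp trials in the table")
  rbind(association(d, "speed_sd_within", "net_power", by = NULL),
        association(d, "speed_sd_within", "cot", by = NULL))
}
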